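# Shared fixtures and oracles. Everything is generated in code at test time.

# tiny dataset for mechanical checks (fast to build, enough structure)
tiny_dataset <- function(seed = 7L) {
  make_dataset(synth_spec(n_labeled_per_class = 4L, n_unlabeled = 32L,
                          n_test_per_class = 4L, seed = seed))
}

# the default study conditions, built once per test session on first use
.fixture_env <- new.env()
get_default_ds <- function() {
  if (is.null(.fixture_env$ds)) .fixture_env$ds <- make_dataset(synth_spec())
  .fixture_env$ds
}

# small encoder for gradient/fit checks
tiny_encoder <- function() encoder_config(stage_widths = c(4L, 6L, 8L, 10L))

# brute-force dense attention over all tokens (independent oracle)
dense_attention_oracle <- function(X, Wq, Wk, Wv) {
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  S <- Q %*% t(K) / sqrt(ncol(X))
  A <- exp(S - apply(S, 1, max))
  A <- A / rowSums(A)
  A %*% V
}

# O(n^2) Mann-Whitney AUC with half credit for ties (independent oracle)
pairwise_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# heads bundle with all-zero weights (uniform probabilities)
zero_heads <- function(K, E) {
  h <- spemix:::sp_heads_init(E, K, seed = 1L)
  h$close$W[] <- 0; h$close$b[] <- 0
  h$multi$W[] <- 0; h$multi$b[] <- 0
  h$open$W[] <- 0; h$open$b[] <- 0
  h
}

# random simplex vector
runif_simplex <- function(n) { x <- runif(n); x / sum(x) }
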
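# Adam optimizer over named lists of parameter arrays, plus the EMA teacher
# update and the cosine learning-rate schedule.

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(par, grads, opt, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    par[[nm]] <- par[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(par = par, opt = opt)
}

#' Exponential-moving-average teacher update
#'
#' `theta_teacher <- m * theta_teacher + (1 - m) * theta_student`, applied
#' elementwise. Accepts numeric arrays or (nested) named lists of arrays
#' with identical shapes. With constant student parameters the recursion
#' has the closed form
#' `theta_t(n) = m^n * theta_t(0) + (1 - m^n) * theta_s`.
#'
#' @param theta_teacher,theta_student matching parameter collections.
#' @param m momentum coefficient in (0, 1]; `m = 1` leaves the teacher
#'   unchanged.
#' @return updated teacher parameters.
#' @export
ema_update <- function(theta_teacher, theta_student, m) {
  stopifnot(m > 0, m <= 1)
  rec <- function(t, s) {
    if (is.numeric(t)) {
      if (!is.numeric(s) || length(t) != length(s)) {
        stop("teacher/student parameter shapes do not match")
      }
      return(m * t + (1 - m) * s)
    }
    if (is.list(t)) {
      if (!is.list(s) || length(t) != length(s)) {
        stop("teacher/student parameter shapes do not match")
      }
      for (i in seq_along(t)) t[[i]] <- rec(t[[i]], s[[i]])
      return(t)
    }
    t
  }
  rec(theta_teacher, theta_student)
}

#' Cosine learning-rate schedule
#'
#' `lr(t) = base_lr * 0.5 * (1 + cos(pi * t / T))`: starts at `base_lr`,
#' halves at `T/2`, reaches 0 at `T`. No warm-up.
#'
#' @param step current optimization step (0-based).
#' @param total_steps schedule horizon `T`.
#' @param base_lr initial learning rate.
#' @return learning rate at `step`.
#' @export
cosine_lr <- function(step, total_steps, base_lr) {
  if (step > total_steps) {
    warning("step exceeds total_steps; clamping to the schedule end")
    step <- total_steps
  }
  stopifnot(step >= 0, total_steps > 0)
  base_lr * 0.5 * (1 + cos(pi * step / total_steps))
}
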
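# First-order GPS autocleavage kinetics: one-phase decay with the plateau
# fixed at 100 % cleavage product,
#     f(t) = 100 + (f0 - 100) * exp(-k * t),
# fitted by nonlinear least squares over (k, f0); half-life = ln(2) / k.

#' Cleavage fraction from band intensities
#'
#' Percentage of cleaved protein from densitometric band intensities:
#' `100 * ntf / (ntf + fl)`, where `ntf` is the N-terminal-fragment band
#' and `fl` the uncleaved full-length band. Scale-invariant in the common
#' intensity unit.
#'
#' @param ntf_intensity,fl_intensity nonnegative band intensities
#'   (vectorised).
#' @return Cleavage fraction(s) in percent.
#' @examples
#' cleavage_fraction(24.5, 75.5)
#' @export
cleavage_fraction <- function(ntf_intensity, fl_intensity) {
  if (any(ntf_intensity < 0) || any(fl_intensity < 0))
    stop("band intensities must be nonnegative")
  tot <- ntf_intensity + fl_intensity
  if (any(tot <= 0)) stop("NTF and full-length intensities are both zero")
  100 * ntf_intensity / tot
}

#' Fit first-order autocleavage kinetics (one-phase decay, plateau 100 %)
#'
#' Fits `f(t) = 100 + (f0 - 100) * exp(-k * t)` to a cleavage time course
#' by nonlinear least squares over the rate constant `k` (per day,
#' constrained positive) and the initial cleavage `f0` (percent at t = 0,
#' the elution/purification timepoint). Initialisation is deterministic:
#' `k` from a log-linear regression of `100 - f` on `t`, `f0` from the
#' earliest timepoint. Standard errors come from the Jacobian at the
#' optimum. Replicate observations at a timepoint are fitted as
#' independent points by default; `aggregate = "mean"` fits the
#' per-timepoint means instead.
#'
#' @param data data frame with columns `time_days` and `fraction_percent`
#'   (optionally `replicate`); alternatively supply the two vectors via
#'   `time_days`/`fraction_percent` directly.
#' @param time_days,fraction_percent numeric vectors, used when `data` is
#'   missing.
#' @param aggregate `"none"` (default) or `"mean"`.
#' @return Object of class `decay_fit` with components `k` (per day),
#'   `f0` (percent), `half_life` (days, `= log(2)/k`), `se` (named,
#'   for k and f0), `rss`, `fitted`, `residuals`, `data`, `n`.
#' @seealso [extrapolate()], [predict.decay_fit()]
#' @examples
#' ts <- synth_kinetics(k = log(2) / 100, f0 = 2, sigma = 0,
#'                      times = c(0, 1, 2, 4, 7, 10, 14), seed = 1)
#' fit <- fit_one_phase_decay(ts)
#' coef(fit)
#' @export
fit_one_phase_decay <- function(data = NULL, time_days = NULL,
                                fraction_percent = NULL,
                                aggregate = c("none", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(data)) {
    data <- data.frame(time_days = time_days,
                       fraction_percent = fraction_percent)
  }
  if (!all(c("time_days", "fraction_percent") %in% names(data)))
    stop("data needs columns time_days and fraction_percent")
  t <- as.numeric(data$time_days)
  f <- as.numeric(data$fraction_percent)
  if (any(!is.finite(t)) || any(!is.finite(f))) stop("non-finite observations")
  if (any(f < 0 | f > 100)) stop("fractions must lie in [0, 100] percent")
  if (aggregate == "mean") {
    agg <- stats::aggregate(f, by = list(t = t), FUN = mean)
    t <- agg$t; f <- agg$x
  }
  if (length(unique(t)) < 3L) stop("need at least 3 distinct timepoints")
  if (all(f >= 100 - 1e-9)) stop("degenerate series: cleavage already complete")

  # deterministic initialisation: log-linear decay of the uncleaved fraction
  u <- pmax(100 - f, 1e-6)
  sl <- stats::coef(stats::lm(log(u) ~ t))[[2L]]
  k0 <- max(-sl, 1e-6)
  f00 <- f[which.min(t)][1L]

  model <- function(p) 100 + (p[2L] - 100) * exp(-p[1L] * t)
  fit <- minpack.lm::nls.lm(
    par = c(k = k0, f0 = f00),
    lower = c(1e-12, -Inf),
    fn = function(p) f - model(p),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 1000L))
  if (fit$info %in% c(0L, 9L))
    stop("one-phase decay fit did not converge: ", fit$message)
  est <- fit$par
  res <- fit$fvec
  rss <- sum(res^2)
  dfree <- length(t) - 2L
  # standard errors from the Jacobian at the optimum
  se <- tryCatch({
    covm <- solve(fit$hessian) * rss / max(dfree, 1L)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) c(NA_real_, NA_real_))
  structure(list(k = est[["k"]],
                 f0 = est[["f0"]],
                 half_life = log(2) / est[["k"]],
                 se = c(k = se[[1L]], f0 = se[[2L]]),
                 rss = rss,
                 fitted = model(est),
                 residuals = res,
                 data = data.frame(time_days = t, fraction_percent = f),
                 n = length(t),
                 aggregate = aggregate),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat("One-phase decay fit (plateau fixed at 100 % cleavage)\n")
  cat(sprintf("  k         = %.*g per day (SE %.*g)\n", digits, x$k, digits, x$se[["k"]]))
  cat(sprintf("  f0        = %.*g %% (SE %.*g)\n", digits, x$f0, digits, x$se[["f0"]]))
  cat(sprintf("  half-life = %.*g days\n", digits, x$half_life))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  dfree <- object$n - 2L
  out <- list(coefficients = cbind(Estimate = c(k = object$k, f0 = object$f0),
                                   `Std. Error` = object$se),
              half_life = object$half_life,
              rss = object$rss,
              sigma = sqrt(object$rss / max(dfree, 1L)),
              df = dfree,
              n = object$n)
  class(out) <- "summary.decay_fit"
  out
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  cat("One-phase decay fit (plateau fixed at 100 % cleavage)\n")
  print(x$coefficients)
  cat(sprintf("half-life %.4g days; RSS %.4g on %d residual df (n = %d)\n",
              x$half_life, x$rss, x$df, x$n))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(k = object$k, f0 = object$f0, half_life = object$half_life)
}

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' Model values of a fitted decay at new times
#'
#' @param object a `decay_fit`.
#' @param newdata optional data frame with column `time_days` (default:
#'   the fitted timepoints).
#' @param ... unused.
#' @return Numeric vector of model cleavage fractions (percent). Values
#'   are reported raw; back-extrapolation before t = 0 may fall below 0.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_days else newdata$time_days
  100 + (object$f0 - 100) * exp(-object$k * t)
}

#' Extrapolate a fitted decay to an arbitrary timepoint
#'
#' Evaluates the fitted curve at `t` days (negative values reach back
#' before purification, e.g. -2 days for the transfection timepoint). The
#' raw model value is returned, with attribute `outside_range` flagging
#' values outside \[0, 100\] percent.
#'
#' @param fit a `decay_fit`.
#' @param t time(s) in days.
#' @return Numeric vector of model fractions with attribute
#'   `outside_range`.
#' @export
extrapolate <- function(fit, t) {
  stopifnot(inherits(fit, "decay_fit"))
  v <- predict(fit, data.frame(time_days = t))
  attr(v, "outside_range") <- v < 0 | v > 100
  v
}

#' @export
plot.decay_fit <- function(x, xlim = NULL, ...) {
  d <- x$data
  if (is.null(xlim)) xlim <- range(c(0, d$time_days))
  tt <- seq(xlim[1L], xlim[2L], length.out = 200L)
  graphics::plot(d$time_days, d$fraction_percent, xlim = xlim,
                 xlab = "time after purification (days)",
                 ylab = "cleavage fraction (%)", ...)
  graphics::lines(tt, predict(x, data.frame(time_days = tt)))
  invisible(x)
}

#' Simulate time courses from a fitted decay
#'
#' Draws `nsim` replicate series at the fitted timepoints with Gaussian
#' noise at the residual standard deviation.
#'
#' @param object a `decay_fit`.
#' @param nsim number of simulated series.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame of simulated `fraction_percent` columns, one per
#'   simulation, with `time_days` first.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sdev <- sqrt(object$rss / max(object$n - 2L, 1L))
  t <- object$data$time_days
  mu <- predict(object)
  draw <- function() pmin(pmax(mu + stats::rnorm(length(t), 0, sdev), 0), 100)
  sims <- if (is.null(seed)) replicate(nsim, draw())
  else .with_seed(seed, replicate(nsim, draw()))
  out <- data.frame(time_days = t)
  sims <- matrix(sims, nrow = length(t))
  for (i in seq_len(nsim)) out[[paste0("sim", i)]] <- sims[, i]
  out
}
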
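#' Fit single-exponential nuclear export kinetics
#'
#' Fits `n0 * exp(-t / tau)` to a nuclear-intensity segment that starts at a
#' light-on transition (t = 0 at the transition), by Levenberg-Marquardt
#' nonlinear least squares. The export rate is `1 / tau`. Because a real
#' trace decays to the light steady state rather than to zero, the
#' post-transition asymptote (mean of the final `asymptote_frac` of the
#' segment) is subtracted before fitting unless `subtract_asymptote = FALSE`.
#'
#' @param intensity nuclear intensity values (>= 5 samples)
#' @param times times in seconds from the transition, strictly increasing
#' @param subtract_asymptote subtract the tail-mean plateau before fitting
#' @param asymptote_frac fraction of the segment tail used for the plateau
#' @return object of class `kinetics_fit`: `n0`, `tau` (seconds),
#'   `direction`, `rmse`, `n_traces_averaged`, `low_coverage` (TRUE when the
#'   segment is shorter than `tau / 2`)
#' @export
fit_export <- function(intensity, times, subtract_asymptote = TRUE,
                       asymptote_frac = 0.1) {
  fit_exponential(intensity, times, direction = "export",
                  subtract_asymptote = subtract_asymptote,
                  asymptote_frac = asymptote_frac)
}

#' Fit single-exponential nuclear import kinetics
#'
#' Mirror of [fit_export()] for a segment starting at a light-off
#' transition, using the saturating model `n0 * (1 - exp(-t / tau))` after
#' subtracting the pre-transition baseline (estimated from the first sample
#' unless `subtract_asymptote = FALSE`, in which case the raw trace is used).
#'
#' @inheritParams fit_export
#' @return a `kinetics_fit` (see [fit_export()])
#' @export
fit_import <- function(intensity, times, subtract_asymptote = TRUE,
                       asymptote_frac = 0.1) {
  fit_exponential(intensity, times, direction = "import",
                  subtract_asymptote = subtract_asymptote,
                  asymptote_frac = asymptote_frac)
}

fit_exponential <- function(intensity, times, direction,
                            subtract_asymptote = TRUE, asymptote_frac = 0.1,
                            n_traces_averaged = 1L) {
  stopifnot(length(intensity) == length(times))
  if (length(times) < 5L) stop("need at least 5 samples to fit")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  t0 <- times - times[1L]

  if (direction == "export") {
    ntail <- max(1L, ceiling(asymptote_frac * length(intensity)))
    base <- if (subtract_asymptote)
      mean(utils::tail(intensity, ntail)) else 0
    y <- intensity - base
    if (y[1L] <= max(utils::tail(y, ntail)) + 1e-12 ||
        stats::sd(y) == 0 || sum(y > 0) < 3L)
      stop("segment is not decreasing: export fit is degenerate")
    total <- y[1L]
    tau0 <- t0[which(y <= total / exp(1))[1L]]
    if (is.na(tau0) || tau0 <= 0) tau0 <- max(t0) / 2
    fit <- minpack.lm::nlsLM(y ~ n0 * exp(-t0 / tau),
                             start = list(n0 = total, tau = tau0),
                             lower = c(0, 1e-6),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    base <- if (subtract_asymptote) intensity[1L] else 0
    y <- intensity - base
    yl <- mean(utils::tail(y, max(1L, ceiling(asymptote_frac * length(y)))))
    if (yl <= y[1L] + 1e-12 || stats::sd(y) == 0)
      stop("segment is not increasing: import fit is degenerate")
    tau0 <- t0[which(y >= yl * (1 - exp(-1)))[1L]]
    if (is.na(tau0) || tau0 <= 0) tau0 <- max(t0) / 2
    fit <- minpack.lm::nlsLM(y ~ n0 * (1 - exp(-t0 / tau)),
                             start = list(n0 = yl, tau = tau0),
                             lower = c(0, 1e-6),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  structure(list(n0 = unname(cf["n0"]), tau = unname(cf["tau"]),
                 direction = direction,
                 rmse = sqrt(mean(stats::resid(fit)^2)),
                 n_traces_averaged = n_traces_averaged,
                 low_coverage = max(t0) < unname(cf["tau"]) / 2),
            class = "kinetics_fit")
}

#' Average traces, then fit a single exponential
#'
#' Pointwise mean of the traces is computed first and a single fit performed
#' on the averaged trace (the estimator used for translocation kinetics:
#' traces are averaged and then fitted).
#'
#' @param traces list of numeric vectors sharing the `times` grid
#' @param times times in seconds, strictly increasing
#' @param direction `"export"` or `"import"`
#' @param ... passed to [fit_export()] / [fit_import()]
#' @return a `kinetics_fit` with `n_traces_averaged = length(traces)`
#' @export
average_then_fit <- function(traces, times, direction = c("export", "import"),
                             ...) {
  direction <- match.arg(direction)
  if (length(traces) == 0L) stop("no traces supplied")
  len <- vapply(traces, length, 0L)
  if (any(len != length(times)))
    stop("all traces must share the time grid (resampling error)")
  avg <- Reduce(`+`, traces) / length(traces)
  fit <- if (direction == "export") fit_export(avg, times, ...)
  else fit_import(avg, times, ...)
  fit$n_traces_averaged <- length(traces)
  fit
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("%s kinetics: tau = %.2f s (rate %.4f /s), n0 = %.2f, rmse = %.3f, traces = %d%s\n",
              x$direction, x$tau, 1 / x$tau, x$n0, x$rmse,
              x$n_traces_averaged,
              if (isTRUE(x$low_coverage)) " [low coverage]" else ""))
  invisible(x)
}
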
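#' Difference curve between an embryo and its control cohort
#'
#' Interpolates every control foci-count trace linearly onto the embryo's
#' time grid (restricted to the overlapping time support), averages the
#' controls pointwise, and subtracts that control mean from the embryo trace.
#'
#' @param embryo a `foci_count_trace` (columns `time_min`, `foci_count`)
#' @param controls non-empty list of `foci_count_trace`s
#' @return data.frame `time_min`, `difference`, `control_mean`
#' @export
difference_curve <- function(embryo, controls) {
  if (length(controls) < 1L) stop("at least one control trace required")
  lo <- max(vapply(controls, function(x) min(x$time_min), 0))
  hi <- min(vapply(controls, function(x) max(x$time_min), 0))
  keep <- embryo$time_min >= lo - 1e-9 & embryo$time_min <= hi + 1e-9
  if (!any(keep)) stop("no temporal overlap between embryo and controls")
  tt <- embryo$time_min[keep]
  cm <- rowMeans(vapply(controls, function(x)
    stats::approx(x$time_min, x$foci_count, xout = tt)$y,
    numeric(length(tt))))
  data.frame(time_min = tt,
             difference = embryo$foci_count[keep] - cm,
             control_mean = cm)
}

#' Smooth a difference curve and differentiate it
#'
#' Centered moving average (default window 5 frames; shrinking symmetric
#' windows at the ends) followed by a centered finite difference; the first
#' and last points use one-sided differences.
#'
#' @param diff_curve data.frame with `time_min` and `difference` (or any
#'   second column of values)
#' @param window moving-average window in frames (odd, < series length)
#' @return data.frame `time_min`, `smoothed`, `derivative`
#'   (value units per minute)
#' @export
smooth_and_differentiate <- function(diff_curve, window = 5) {
  tt <- diff_curve$time_min
  y <- diff_curve[[2L]]
  n <- length(y)
  if (n <= window) stop("series must be longer than the smoothing window")
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  h <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    k <- min(h, i - 1L, n - i)        # symmetric shrink at the edges
    mean(y[(i - k):(i + k)])
  }, 0)
  d <- numeric(n)
  d[1L] <- (sm[2L] - sm[1L]) / (tt[2L] - tt[1L])
  d[n] <- (sm[n] - sm[n - 1L]) / (tt[n] - tt[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    d[i] <- (sm[i + 1L] - sm[i - 1L]) / (tt[i + 1L] - tt[i - 1L])
  }
  data.frame(time_min = tt, smoothed = sm, derivative = d)
}

#' Response time from the maximum post-shift derivative
#'
#' The response time is the time after the light shift at which the smoothed
#' embryo-minus-control difference changes fastest in the expected direction:
#' the time of maximum of `sign * derivative` restricted to `t >= shift_time`,
#' minus the shift time. Ties are broken by the earliest time.
#'
#' @param deriv data.frame from [smooth_and_differentiate()]
#' @param shift_time light-shift time in minutes
#' @param expected_sign `+1` for a rising response, `-1` for a falling one
#' @param embryo_id optional identifier carried through
#' @return object of class `response_time_result` (partial: the exclusion
#'   rule is applied by [apply_exclusion()]): `embryo_id`, `response_time`
#'   (minutes after the shift), `peak_derivative`
#' @export
response_time <- function(deriv, shift_time, expected_sign = 1,
                          embryo_id = NA_character_) {
  stopifnot(expected_sign %in% c(-1, 1))
  post <- deriv$time_min >= shift_time - 1e-9
  if (!any(post)) stop("no samples at or after the shift time")
  s <- expected_sign * deriv$derivative[post]
  tt <- deriv$time_min[post]
  i <- which.max(s)                    # first index on ties = earliest time
  structure(list(embryo_id = embryo_id,
                 response_time = tt[i] - shift_time,
                 peak_derivative = s[i],
                 included = NA, exclusion_reason = NULL,
                 max_abs_difference = NA_real_, control_peak = NA_real_),
            class = "response_time_result")
}

#' Apply the control-relative exclusion rule
#'
#' Embryos whose maximum absolute change in foci count is less than 25% of
#' the corresponding peak of the control-mean trace are flagged as
#' non-responders and excluded (inclusive at exactly 25%).
#'
#' @param result a `response_time_result` from [response_time()]
#' @param diff_curve the embryo's difference curve (from
#'   [difference_curve()], with `control_mean`)
#' @param threshold exclusion threshold as a fraction of the control peak
#' @return the result with `max_abs_difference`, `control_peak`, `included`
#'   and (when excluded) `exclusion_reason` filled in; `response_time` is
#'   kept only for included embryos
#' @export
apply_exclusion <- function(result, diff_curve, threshold = 0.25) {
  mad_ <- max(abs(diff_curve$difference))
  peak <- max(diff_curve$control_mean)
  result$max_abs_difference <- mad_
  result$control_peak <- peak
  result$included <- mad_ >= threshold * peak
  if (!result$included) {
    result$exclusion_reason <- sprintf(
      "max |difference| %.2f < %.0f%% of control peak %.2f",
      mad_, 100 * threshold, peak)
    result$response_time <- NA_real_
  }
  result
}

#' Summarise a cohort of response-time results
#'
#' @param results list of finalized `response_time_result`s
#' @return list: `mean_response_time`, `sem` (NA for a single included
#'   embryo), `sd`, `n_included`, `n_excluded`, `response_times`
#' @export
cohort_summary <- function(results) {
  inc <- Filter(function(r) isTRUE(r$included), results)
  exc <- Filter(function(r) identical(r$included, FALSE), results)
  if (length(inc) == 0L)
    stop("no included embryos; exclusion reasons: ",
         paste(vapply(exc, function(r) r$exclusion_reason, ""),
               collapse = "; "))
  rt <- vapply(inc, function(r) r$response_time, 0)
  list(mean_response_time = mean(rt),
       sd = if (length(rt) > 1L) stats::sd(rt) else NA_real_,
       sem = if (length(rt) > 1L) stats::sd(rt) / sqrt(length(rt))
             else NA_real_,
       n_included = length(rt), n_excluded = length(exc),
       response_times = rt)
}

#' Expected foci-response sign for a perturbation
#'
#' Dark means nuclear TF present. A gene activated by the nuclear TF gains
#' foci after a light-to-dark shift and loses them after dark-to-light; a
#' repressed gene responds with the opposite signs.
#'
#' @param preset a [gene_preset()]
#' @param direction `"ltd"` or `"dtl"`
#' @return `+1` or `-1`
#' @export
expected_response_sign <- function(preset, direction = c("ltd", "dtl")) {
  direction <- match.arg(direction)
  up <- (preset$sign == "activated") == (direction == "ltd")
  if (up) 1 else -1
}

#' Run the full response-time workflow for one cohort
#'
#' For each perturbed embryo: difference curve against the control mean,
#' smoothing + differentiation, max-derivative response time, and the 25%
#' exclusion rule; then the cohort summary.
#'
#' @param embryos list of perturbed `foci_count_trace`s
#' @param controls list of control `foci_count_trace`s
#' @param shift_time light-shift time in minutes
#' @param expected_sign `+1` or `-1`
#' @param window smoothing window in frames
#' @param threshold exclusion threshold (fraction of the control peak)
#' @return list: `results` (per embryo), `summary` (from [cohort_summary()])
#' @export
analyze_response_cohort <- function(embryos, controls, shift_time,
                                    expected_sign = 1, window = 5,
                                    threshold = 0.25) {
  results <- lapply(seq_along(embryos), function(i) {
    dc <- difference_curve(embryos[[i]], controls)
    dv <- smooth_and_differentiate(dc[, c("time_min", "difference")], window)
    r <- response_time(dv, shift_time, expected_sign,
                       embryo_id = sprintf("embryo_%02d", i))
    apply_exclusion(r, dc, threshold)
  })
  list(results = results, summary = cohort_summary(results))
}

#' Simulate a perturbation + control response-time cohort
#'
#' Generates `n_embryos` perturbed foci-count traces (light shift at
#' `shift_time`) and `n_controls` constant-condition controls with the given
#' preset, all at the trace level with default noise, using seeds
#' `seed, seed+1, ...`.
#'
#' @param preset a [gene_preset()] (or preset name)
#' @param direction `"ltd"` or `"dtl"`
#' @param n_embryos,n_controls cohort sizes
#' @param shift_time light-shift time in minutes
#' @param duration movie duration in minutes; default
#'   `shift_time + max(25, onset_delay + 13)`
#' @param seed base RNG seed
#' @param ... passed to [simulate_foci_count_trace()]
#' @return list: `embryos`, `controls` (lists of `foci_count_trace`),
#'   `shift_time`, `expected_sign`, `true_delay`
#' @export
simulate_response_cohort <- function(preset, direction = c("ltd", "dtl"),
                                     n_embryos = 8, n_controls = 8,
                                     shift_time = 5, duration = NULL,
                                     seed = 1L, ...) {
  direction <- match.arg(direction)
  if (is.character(preset)) preset <- gene_preset(preset)
  delay <- preset_onset_delay(preset, direction)
  if (is.null(duration))
    duration <- shift_time +
      max(25, (if (is.finite(delay)) delay else 0) + 13)
  pert <- shift_protocol(shift_time, duration, direction)
  # controls stay in the pre-shift condition for the whole movie
  ctrl_light <- direction == "ltd"
  ctrl <- constant_protocol(duration, light_on = ctrl_light)
  seed <- as.integer(seed)
  embryos <- lapply(seq_len(n_embryos), function(i)
    simulate_foci_count_trace(preset, pert, seed = seed + i - 1L, ...))
  controls <- lapply(seq_len(n_controls), function(i)
    simulate_foci_count_trace(preset, ctrl,
                              seed = seed + n_embryos + i - 1L, ...))
  list(embryos = embryos, controls = controls, shift_time = shift_time,
       expected_sign = expected_response_sign(preset, direction),
       true_delay = delay)
}
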
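# Independent oracles used to freeze expected values.

# Moving-average + centered-difference by explicit convolution, written
# independently of the package's implementation.
oracle_smooth_diff <- function(times, values, window = 5) {
  n <- length(values)
  h <- (window - 1) %/% 2
  sm <- sapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    sum(values[(i - k):(i + k)]) / (2 * k + 1)
  })
  d <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1) d[i] <- (sm[2] - sm[1]) / (times[2] - times[1])
    else if (i == n) d[i] <- (sm[n] - sm[n - 1]) / (times[n] - times[n - 1])
    else d[i] <- (sm[i + 1] - sm[i - 1]) / (times[i + 1] - times[i - 1])
  }
  list(smoothed = sm, derivative = d)
}

# Grid-search single-exponential fit (decaying), independent of nlsLM.
oracle_fit_export_grid <- function(y, t) {
  taus <- seq(5, 200, by = 0.25)
  sse <- sapply(taus, function(tau) {
    basis <- exp(-t / tau)
    n0 <- sum(y * basis) / sum(basis^2)   # closed-form LS amplitude
    sum((y - n0 * basis)^2)
  })
  taus[which.min(sse)]
}

# Small noise-free rendering config used across image tests.
tiny_config <- function(duration = 3, seed = 7, ...) {
  movie_config(n_nuclei = 40, field_size = c(60, 40), pixel_size = 0.4,
               n_z = 4, duration = duration, read_noise_sd = 0,
               shot_noise = FALSE, focus_visible_prob = 1,
               intensity_cv = 0, seed = seed, ...)
}

# A bare foci-count trace data.frame for workflow tests.
make_trace <- function(times, counts) {
  structure(data.frame(frame = seq_along(times), time_min = times,
                       foci_count = counts,
                       mean_focus_intensity = NA_real_),
            class = c("foci_count_trace", "data.frame"))
}
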
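#' Gene response presets for the synthetic generator
#'
#' Each preset encodes the qualitative stimulus-response class observed for
#' one anterior gap gene when nuclear transcription-factor (TF) levels are
#' switched optogenetically, as a delayed first-order relaxation of the
#' per-nucleus foci-activation probability:
#'
#' * `hb_like` - direct activation, fast and symmetric: foci rise within
#'   ~1.7 min of a light-to-dark shift (TF gain) and fall within ~3.3 min of
#'   a dark-to-light shift (TF loss).
#' * `gt_like` - direct activation with strong history dependence: onset
#'   delays 5.9 min (TF gain) and 9 min (TF loss). The response is
#'   bi-phasic: a quarter of the plateau change completes quickly at onset
#'   (the detectable response), while the remainder relaxes toward the new
#'   plateau over tens of minutes (the history dependence).
#' * `Kr_like` - delayed inverted response: foci fall only after a ~22 min
#'   delay following TF gain; no detectable response to TF loss within the
#'   movie (infinite onset delay).
#' * `kni_like` - fast inverted response: foci rise within ~2.9 min of TF
#'   loss; TF gain triggers a similarly fast but smaller-amplitude decrease
#'   (amplitude asymmetry 0.5).
#'
#' @param name one of `"hb_like"`, `"gt_like"`, `"Kr_like"`, `"kni_like"`
#' @return object of class `gene_preset` with fields `name`, `sign`
#'   (`"activated"` or `"repressed"` by nuclear TF), `onset_delay_ltd` /
#'   `onset_delay_dtl` (minutes after a light-to-dark / dark-to-light shift
#'   before the foci rate starts changing), `relaxation_time` (minutes),
#'   `amplitude_asymmetry` (fraction in `[0,1]`; the plateau change in the
#'   foci-decreasing direction is `1 - a` of the increasing-direction change),
#'   `fast_fraction` / `fast_time` (fraction of each onset's change carried
#'   by a fast initial component and its time constant in minutes; non-zero
#'   only for `gt_like`), `p_high` and `p_low` (activation-probability
#'   plateaus).
#' @export
gene_preset <- function(name = c("hb_like", "gt_like", "Kr_like", "kni_like")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("hb_like", "gt_like", "Kr_like", "kni_like"))
    stop("unknown gene preset: ", paste(name, collapse = ", "))
  par <- switch(name,
    hb_like  = list(sign = "activated", onset_delay_ltd = 1.7,
                    onset_delay_dtl = 3.3, relaxation_time = 1,
                    amplitude_asymmetry = 0, fast_fraction = 0,
                    fast_time = 1),
    gt_like  = list(sign = "activated", onset_delay_ltd = 5.9,
                    onset_delay_dtl = 9, relaxation_time = 30,
                    amplitude_asymmetry = 0, fast_fraction = 0.25,
                    fast_time = 1),
    Kr_like  = list(sign = "repressed", onset_delay_ltd = 22,
                    onset_delay_dtl = Inf, relaxation_time = 3,
                    amplitude_asymmetry = 0, fast_fraction = 0,
                    fast_time = 1),
    kni_like = list(sign = "repressed", onset_delay_ltd = 2.9,
                    onset_delay_dtl = 2.9, relaxation_time = 1.5,
                    amplitude_asymmetry = 0.5, fast_fraction = 0,
                    fast_time = 1))
  structure(c(list(name = name), par, list(p_high = 0.9, p_low = 0.05)),
            class = "gene_preset")
}

#' Direction-appropriate onset delay of a preset
#'
#' @param preset a [gene_preset()]
#' @param direction `"ltd"` (light-to-dark, nuclear TF gain) or `"dtl"`
#'   (dark-to-light, nuclear TF loss)
#' @return delay in minutes (may be `Inf` for a non-responding direction)
#' @export
preset_onset_delay <- function(preset, direction = c("ltd", "dtl")) {
  direction <- match.arg(direction)
  if (direction == "ltd") preset$onset_delay_ltd else preset$onset_delay_dtl
}

# steady-state activation probability for a given light state
preset_target <- function(preset, light_on) {
  # dark = TF nuclear; an activated gene is high in the dark
  if (preset$sign == "activated")
    ifelse(light_on, preset$p_low, preset$p_high)
  else
    ifelse(light_on, preset$p_high, preset$p_low)
}

#' Simulate the per-nucleus foci-activation probability
#'
#' The probability that a nucleus displays an active transcription focus
#' follows a delayed relaxation: it starts at the steady state of the
#' initial light condition; after each light transition it holds its value
#' for the direction-appropriate onset delay, then relaxes exponentially
#' toward the plateau of the new condition. A preset with
#' `fast_fraction > 0` splits each onset's change into a fast component
#' (time constant `fast_time`) and a slow remainder (`relaxation_time`),
#' giving a detectable initial response followed by a gradual,
#' history-dependent approach. When the change is in the foci-decreasing
#' direction, the plateau change is scaled by `1 - amplitude_asymmetry`.
#'
#' @param preset a [gene_preset()]
#' @param protocol an [illumination_protocol()]
#' @param times strictly increasing time grid in minutes covered by the
#'   protocol
#' @return numeric vector of probabilities in `[0, 1]` at `times`
#' @export
#' @examples
#' pr <- gene_preset("hb_like")
#' p <- simulate_foci_rate(pr, shift_protocol(10, 30, "ltd"),
#'                         seq(0, 30, by = 0.5))
simulate_foci_rate <- function(preset, protocol, times) {
  stopifnot(inherits(preset, "gene_preset"),
            inherits(protocol, "illumination_protocol"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  span <- protocol_span(protocol)
  if (times[1L] < span[1L] - 1e-9 || times[length(times)] > span[2L] + 1e-9)
    stop("protocol does not cover the requested times (protocol-coverage error)")

  trans <- light_transitions(protocol)
  state0 <- protocol$segments$light_on[1L]
  p0 <- preset_target(preset, state0)
  if (length(trans) == 0L) return(rep(p0, length(times)))

  # onset events: (time the response starts, plateau it relaxes toward)
  onsets <- numeric(0)
  targets <- numeric(0)
  # probability value at each onset is resolved while integrating below
  dirs <- ifelse(light_state(protocol, trans + 1e-9), "dtl", "ltd")
  delays <- vapply(dirs, function(d) preset_onset_delay(preset, d), 0)
  keep <- is.finite(delays)
  onsets <- trans[keep] + delays[keep]
  raw_targets <- preset_target(preset, light_state(protocol, trans + 1e-9))[keep]
  o <- order(onsets)
  onsets <- onsets[o]; raw_targets <- raw_targets[o]

  # integrate on the union grid of times and onset points; the probability
  # is target + fast deficit + slow deficit, each deficit decaying with its
  # own time constant
  grid <- sort(unique(c(times, onsets[onsets <= times[length(times)]])))
  p <- numeric(length(grid))
  target <- p0; def_fast <- 0; def_slow <- 0
  next_onset <- 1L
  prev_t <- grid[1L]
  for (i in seq_along(grid)) {
    t <- grid[i]
    dt <- t - prev_t
    if (dt > 0) {
      def_fast <- def_fast * exp(-dt / preset$fast_time)
      def_slow <- def_slow * exp(-dt / preset$relaxation_time)
    }
    while (next_onset <= length(onsets) && onsets[next_onset] <= t + 1e-9) {
      cur <- target + def_fast + def_slow
      tgt <- raw_targets[next_onset]
      change <- tgt - cur
      if (change < 0)  # foci-decreasing (inhibitory) direction
        tgt <- cur + (1 - preset$amplitude_asymmetry) * change
      deficit <- cur - tgt
      def_fast <- preset$fast_fraction * deficit
      def_slow <- (1 - preset$fast_fraction) * deficit
      target <- tgt
      next_onset <- next_onset + 1L
    }
    p[i] <- target + def_fast + def_slow
    prev_t <- t
  }
  pmin(pmax(p[match(times, grid)], 0), 1)
}
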
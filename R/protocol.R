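#' Build an illumination protocol
#'
#' An illumination protocol is the time (and optionally space) schedule of the
#' blue-light stimulus that drives nuclear export of a LEXY-tagged protein.
#' It is a contiguous, non-overlapping sequence of segments, each either
#' light-on or light-off, covering the whole movie.
#'
#' @param segments data.frame with columns `start` and `end` (minutes) and
#'   `light_on` (logical). Segments must be contiguous (each `end` equals the
#'   next `start`), non-overlapping and in increasing time order. An optional
#'   `mask` list-column may carry a spatial rectangle
#'   `c(x0, x1, y0, y1)` in micrometres restricting illumination; `NULL`
#'   means full-field.
#' @param edge_softness optical blur of the mask edge in micrometres
#'   (the spatial precision of patterned illumination is on the order of
#'   10 um, i.e. one to two cell diameters); must be >= 0.
#'
#' @return object of class `illumination_protocol`
#' @export
#' @examples
#' p <- illumination_protocol(data.frame(
#'   start = c(0, 10), end = c(10, 40), light_on = c(TRUE, FALSE)))
#' light_state(p, c(5, 15))
illumination_protocol <- function(segments, edge_softness = 10) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "light_on") %in% names(segments)))
  if (nrow(segments) < 1L)
    stop("protocol needs at least one segment")
  if (edge_softness < 0)
    stop("edge_softness must be >= 0")
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  if (any(segments$end <= segments$start))
    stop("each segment must have end > start")
  if (nrow(segments) > 1L) {
    gaps <- segments$start[-1L] - segments$end[-nrow(segments)]
    if (any(abs(gaps) > 1e-9))
      stop("protocol segments must be contiguous and non-overlapping")
  }
  structure(list(segments = segments, edge_softness = edge_softness),
            class = "illumination_protocol")
}

#' Constant-illumination protocol helper
#'
#' @param duration movie duration in minutes
#' @param light_on logical; constant light (TRUE) or constant dark (FALSE)
#' @return `illumination_protocol`
#' @export
constant_protocol <- function(duration, light_on = FALSE) {
  illumination_protocol(data.frame(start = 0, end = duration,
                                   light_on = light_on))
}

#' Single-shift protocol helper
#'
#' Light-to-dark (`"ltd"`) acutely increases nuclear TF (import in the dark);
#' dark-to-light (`"dtl"`) acutely removes it (light-driven export).
#'
#' @param shift_time time of the light shift in minutes
#' @param duration total duration in minutes (> shift_time)
#' @param direction `"ltd"` or `"dtl"`
#' @return `illumination_protocol`
#' @export
shift_protocol <- function(shift_time, duration, direction = c("ltd", "dtl")) {
  direction <- match.arg(direction)
  stopifnot(shift_time > 0, duration > shift_time)
  illumination_protocol(data.frame(
    start = c(0, shift_time), end = c(shift_time, duration),
    light_on = if (direction == "ltd") c(TRUE, FALSE) else c(FALSE, TRUE)))
}

#' Protocol time span
#' @param protocol an `illumination_protocol`
#' @return numeric length-2, start and end time in minutes
#' @export
protocol_span <- function(protocol) {
  s <- protocol$segments
  c(s$start[1L], s$end[nrow(s)])
}

#' Light state at given times
#'
#' @param protocol an `illumination_protocol`
#' @param times numeric vector of times (minutes); must lie within the
#'   protocol span
#' @return logical vector, TRUE where the light is on. Segment start times are
#'   inclusive; the final segment's end time is inclusive too.
#' @export
light_state <- function(protocol, times) {
  span <- protocol_span(protocol)
  if (any(times < span[1L] - 1e-9 | times > span[2L] + 1e-9))
    stop("times outside protocol coverage")
  s <- protocol$segments
  idx <- findInterval(pmin(times, span[2L] - 1e-12), s$start)
  idx[idx < 1L] <- 1L
  s$light_on[idx]
}

#' Times at which the light state switches
#' @param protocol an `illumination_protocol`
#' @return numeric vector of transition times (minutes), possibly empty
#' @export
light_transitions <- function(protocol) {
  s <- protocol$segments
  if (nrow(s) < 2L) return(numeric(0))
  flips <- which(s$light_on[-1L] != s$light_on[-nrow(s)])
  s$start[flips + 1L]
}
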
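#' Segment nuclei in a single nuclear-channel frame
#'
#' Gaussian blur (default sigma 1 um), global Otsu threshold, then a
#' distance-transform watershed to split touching nuclei. Components smaller
#' than `min_area_frac` of the expected nuclear area are discarded.
#'
#' @param img numeric `[x, y]` matrix (z-max of the nuclear channel)
#' @param pixel_size micrometres per pixel
#' @param blur_sigma Gaussian sigma in micrometres
#' @param nuclear_radius expected nuclear radius in micrometres (sets the
#'   minimum-area filter)
#' @param min_area_frac minimum component area as a fraction of
#'   `pi * nuclear_radius^2`
#' @return list: `labels` (integer `[x, y]` label matrix, 0 = background) and
#'   `regions` data.frame (`label`, `x_um`, `y_um`, `area_um2`,
#'   `mean_intensity` from the unblurred image). An all-zero image yields
#'   zero regions with a warning.
#' @export
segment_nuclei <- function(img, pixel_size, blur_sigma = 1,
                           nuclear_radius = 2.5, min_area_frac = 0.25) {
  stopifnot(is.matrix(img))
  empty <- list(labels = matrix(0L, nrow(img), ncol(img)),
                regions = data.frame(label = integer(0), x_um = numeric(0),
                                     y_um = numeric(0), area_um2 = numeric(0),
                                     mean_intensity = numeric(0)))
  if (max(img) <= 0) {
    warning("all-zero image: no nuclei segmented")
    return(empty)
  }
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img / max(img)),
                                 sigma = blur_sigma / pixel_size))
  th <- EBImage::otsu(EBImage::Image(sm))
  mask <- sm > th
  if (!any(mask)) {
    warning("threshold removed all pixels: no nuclei segmented")
    return(empty)
  }
  dm <- EBImage::distmap(EBImage::Image(mask))
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labm <- EBImage::imageData(lab)
  storage.mode(labm) <- "integer"

  min_area_px <- min_area_frac * pi * (nuclear_radius / pixel_size)^2
  areas <- tabulate(labm[labm > 0])
  keep <- which(areas >= min_area_px)
  if (!length(keep)) {
    warning("all components below minimum area: no nuclei segmented")
    return(empty)
  }
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  labm[labm > 0] <- relab[labm[labm > 0]]

  idx <- which(labm > 0, arr.ind = TRUE)
  lv <- labm[labm > 0]
  # intensity over an eroded interior: mask-edge pixels are partial-volume
  # mixtures of nucleus and background and would bias the mean
  depth <- max(2, ceiling(blur_sigma / pixel_size))
  core <- EBImage::imageData(dm) > depth & labm > 0
  inten <- vapply(seq_along(keep), function(l) {
    sel <- core & labm == l
    if (!any(sel)) sel <- labm == l
    mean(img[sel])
  }, 0)
  regions <- data.frame(
    label = seq_along(keep),
    x_um = as.numeric(tapply(idx[, 1] - 0.5, lv, mean)) * pixel_size,
    y_um = as.numeric(tapply(idx[, 2] - 0.5, lv, mean)) * pixel_size,
    area_um2 = as.numeric(tapply(lv, lv, length)) * pixel_size^2,
    mean_intensity = inten)
  list(labels = labm, regions = regions)
}

#' Track nuclei across frames by greedy nearest-centroid linking
#'
#' Matches each frame's regions to the previous frame's live tracks in order
#' of increasing centroid distance; matches beyond `gate` are rejected and
#' unmatched regions start new tracks. Track ids are stable and never reused.
#'
#' @param region_list list of per-frame `regions` data.frames from
#'   [segment_nuclei()] (>= 2 frames)
#' @param times frame times in minutes (same length as `region_list`)
#' @param gate maximum allowed centroid displacement per frame (um);
#'   default one nuclear radius
#' @return data.frame of nucleus traces: `nucleus_id`, `frame`, `time_min`,
#'   `x_um`, `y_um`, `mean_intensity`, `area_um2`
#' @export
track_nuclei <- function(region_list, times = seq_along(region_list),
                         gate = 2.5) {
  stopifnot(length(region_list) >= 2L,
            length(times) == length(region_list))
  next_id <- 1L
  prev <- NULL          # data.frame: id, x, y
  rows <- vector("list", length(region_list))
  for (t in seq_along(region_list)) {
    reg <- region_list[[t]]
    n <- nrow(reg)
    ids <- rep(NA_integer_, n)
    if (!is.null(prev) && n > 0 && nrow(prev) > 0) {
      d <- outer(reg$x_um, prev$x, `-`)^2 + outer(reg$y_um, prev$y, `-`)^2
      cand <- which(d <= gate^2, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        used_new <- logical(n); used_old <- logical(nrow(prev))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_new[i] && !used_old[j]) {
            ids[i] <- prev$id[j]
            used_new[i] <- TRUE; used_old[j] <- TRUE
          }
        }
      }
    }
    fresh <- which(is.na(ids))
    if (length(fresh)) {
      ids[fresh] <- seq.int(next_id, next_id + length(fresh) - 1L)
      next_id <- next_id + length(fresh)
    }
    rows[[t]] <- if (n > 0) data.frame(
      nucleus_id = ids, frame = t, time_min = times[t],
      x_um = reg$x_um, y_um = reg$y_um,
      mean_intensity = reg$mean_intensity, area_um2 = reg$area_um2)
    else NULL
    prev <- if (n > 0) data.frame(id = ids, x = reg$x_um, y = reg$y_um)
    else prev[0, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  out[order(out$nucleus_id, out$frame), , drop = FALSE]
}

#' Segment and track a whole movie's nuclear channel
#'
#' @param movie an `embryo_movie`
#' @param ... passed to [segment_nuclei()]
#' @param gate tracking gate in micrometres (default the config's nuclear
#'   radius)
#' @return nucleus-trace data.frame as from [track_nuclei()]
#' @export
extract_traces <- function(movie, ..., gate = movie$config$nuclear_radius) {
  stopifnot(inherits(movie, "embryo_movie"))
  nt <- dim(movie$frames)[5]
  px <- movie$config$pixel_size
  regs <- lapply(seq_len(nt), function(t) {
    segment_nuclei(zmax_project(movie$frames[, , , 1, t]), px,
                   nuclear_radius = movie$config$nuclear_radius, ...)$regions
  })
  track_nuclei(regs, times = movie$times, gate = gate)
}

#' Estimate nuclear-cycle timing from a mean nuclear-intensity trace
#'
#' Nuclear-envelope breakdown produces a profound transient loss of
#' nuclear-reporter intensity. The dip is detected where the trace falls
#' below `dip_frac` of its running median; the subsequent recovery marks
#' envelope re-formation, which anchors the NC14 clock at 5.6 min. When
#' several dips occur, the earliest is used.
#'
#' @param time time grid in minutes
#' @param intensity mean nuclear intensity at `time`
#' @param dip_frac dip threshold as a fraction of the running median
#' @param window running-median window in frames (odd)
#' @return object of class `cycle_timing`: `available`,
#'   `envelope_breakdown_time`, `reformation_time`, `nc14_clock_offset`
#'   (minutes to add to movie time so re-formation maps to 5.6 min)
#' @export
extract_cycle_timing <- function(time, intensity, dip_frac = 0.5,
                                 window = 5) {
  stopifnot(length(time) == length(intensity))
  unavailable <- structure(list(available = FALSE,
                                envelope_breakdown_time = NA_real_,
                                reformation_time = NA_real_,
                                nc14_clock_offset = NA_real_),
                           class = "cycle_timing")
  if (length(intensity) < window) return(unavailable)
  rm <- stats::runmed(intensity, k = window, endrule = "median")
  dip <- intensity < dip_frac * rm
  if (!any(dip)) return(unavailable)
  b <- which(dip)[1L]
  after <- which(!dip & seq_along(dip) > b)
  if (!length(after)) return(unavailable)
  r <- after[1L]
  structure(list(available = TRUE,
                 envelope_breakdown_time = time[b],
                 reformation_time = time[r],
                 nc14_clock_offset = 5.6 - time[r]),
            class = "cycle_timing")
}

#' Convert movie time to the NC14 clock
#' @param timing a `cycle_timing` with `available = TRUE`
#' @param time_min movie times in minutes
#' @return NC14 times in minutes (re-formation = 5.6 min)
#' @export
nc14_time <- function(timing, time_min) {
  if (!isTRUE(timing$available))
    stop("cycle timing unavailable; use movie time")
  time_min + timing$nc14_clock_offset
}
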
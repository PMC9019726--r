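#' Maximum-intensity projection over z
#'
#' @param stack numeric array `[x, y, z]` (or a 2-D matrix, returned as-is)
#' @return numeric `[x, y]` matrix of per-pixel maxima over z
#' @export
zmax_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(length(dim(stack)) == 3L)
  if (dim(stack)[3] == 1L) return(stack[, , 1L])
  apply(stack, c(1, 2), max)
}

#' Detect diffraction-limited foci in a projected frame
#'
#' Band-pass filters the image with a difference of Gaussians (small sigma =
#' `filter_sigma`, large sigma = `3 * filter_sigma`) to suppress both pixel
#' noise and structures larger than a focus, thresholds at the frame's
#' background median plus `threshold_k` robust SDs (MAD x 1.4826), and keeps
#' connected components within an area window. Centroids are
#' intensity-weighted on the band-passed image.
#'
#' @param img numeric `[x, y]` matrix (z-max projected foci channel)
#' @param pixel_size micrometres per pixel
#' @param filter_sigma small Gaussian sigma in micrometres (match the PSF)
#' @param threshold_k robust-SD multiplier for the detection threshold
#' @param area_window component area window `c(min, max)` in pixels
#' @param saturation_level intensity treated as sensor saturation
#' @return data.frame with `x_um`, `y_um`, `intensity` (peak raw value),
#'   `area_px`; attribute `saturated` flags frames with > 1% saturated pixels
#' @export
detect_foci <- function(img, pixel_size, filter_sigma = 0.3, threshold_k = 5,
                        area_window = c(2, 100), saturation_level = 65535) {
  stopifnot(is.matrix(img))
  saturated <- mean(img >= saturation_level) > 0.01
  if (saturated)
    warning("more than 1% of pixels saturated; detection may undercount")
  s1 <- max(filter_sigma / pixel_size, 0.3)
  dog <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = s1)) -
    as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 3 * s1))
  med <- stats::median(dog)
  rsd <- stats::mad(dog, constant = 1.4826)
  thr <- med + threshold_k * rsd
  mask <- dog > thr
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), area_px = integer(0))
  if (!any(mask) || rsd == 0)
    return(structure(empty, saturated = saturated))
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  labm <- EBImage::imageData(lab)
  areas <- tabulate(as.integer(labm))
  keep <- which(areas >= area_window[1] & areas <= area_window[2])
  if (!length(keep)) return(structure(empty, saturated = saturated))
  idx <- which(labm > 0, arr.ind = TRUE)
  lv <- labm[labm > 0]
  sel <- lv %in% keep
  idx <- idx[sel, , drop = FALSE]; lv <- lv[sel]
  w <- pmax(dog[idx] - med, 0)
  sw <- tapply(w, lv, sum)
  cx <- tapply(w * (idx[, 1] - 0.5), lv, sum) / sw
  cy <- tapply(w * (idx[, 2] - 0.5), lv, sum) / sw
  peak <- tapply(img[idx], lv, max)
  out <- data.frame(x_um = as.numeric(cx) * pixel_size,
                    y_um = as.numeric(cy) * pixel_size,
                    intensity = as.numeric(peak),
                    area_px = as.integer(areas[keep][match(names(sw),
                                                           as.character(keep))]))
  out <- out[order(out$x_um, out$y_um), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, saturated = saturated)
}

#' Count foci inside a rectangular ROI
#'
#' Inclusion is half-open on both axes: a focus exactly on the lower edge is
#' counted, one exactly on the upper edge is not.
#'
#' @param foci data.frame with `x_um`, `y_um` (and optionally `intensity`)
#' @param roi `c(x0, x1, y0, y1)` in micrometres
#' @param field optional field extent `c(x, y)`; if given, the ROI must lie
#'   within it
#' @return list: `foci_count`, `mean_focus_intensity` (NA when count is 0)
#' @export
count_in_roi <- function(foci, roi, field = NULL) {
  stopifnot(length(roi) == 4L, roi[2] > roi[1], roi[4] > roi[3])
  if (!is.null(field) &&
      (roi[1] < 0 || roi[3] < 0 || roi[2] > field[1] || roi[4] > field[2]))
    stop("ROI extends outside the image field")
  if (nrow(foci) == 0L)
    return(list(foci_count = 0L, mean_focus_intensity = NA_real_))
  inside <- foci$x_um >= roi[1] & foci$x_um < roi[2] &
    foci$y_um >= roi[3] & foci$y_um < roi[4]
  n <- sum(inside)
  mfi <- if (n > 0 && !is.null(foci$intensity))
    mean(foci$intensity[inside]) else NA_real_
  list(foci_count = as.integer(n), mean_focus_intensity = mfi)
}

#' Centered ROI helper
#'
#' @param field field extent `c(x, y)` in micrometres
#' @param width ROI extent along x (default 150 um)
#' @param height ROI extent along y (default 40 um)
#' @return `c(x0, x1, y0, y1)` centered in the field
#' @export
centered_roi <- function(field, width = 150, height = 40) {
  if (width > field[1] || height > field[2])
    stop("ROI larger than the field")
  c((field[1] - width) / 2, (field[1] + width) / 2,
    (field[2] - height) / 2, (field[2] + height) / 2)
}

#' Build a foci-count trace from a movie
#'
#' Per frame: z-max projection of the foci channel, difference-of-Gaussians
#' detection, ROI counting. Foci are detected independently per frame (no
#' temporal linking). When cycle timing is supplied the NC14 clock is added.
#'
#' @param movie an `embryo_movie`
#' @param roi `c(x0, x1, y0, y1)` in micrometres; default: centered ROI
#'   clipped to at most 150 x 40 um
#' @param timing optional `cycle_timing` from [extract_cycle_timing()]
#' @param filter_sigma,threshold_k,area_window passed to [detect_foci()]
#' @return `foci_count_trace` data.frame: `frame`, `time_min`,
#'   `nc14_time_min` (NA without timing), `foci_count`,
#'   `mean_focus_intensity`; attribute `roi`
#' @export
foci_trace <- function(movie, roi = NULL, timing = NULL,
                       filter_sigma = movie$config$psf_sigma,
                       threshold_k = 5, area_window = c(2, 100)) {
  stopifnot(inherits(movie, "embryo_movie"))
  field <- movie$config$field_size
  if (is.null(roi))
    roi <- centered_roi(field, min(150, field[1]), min(40, field[2]))
  nt <- dim(movie$frames)[5]
  px <- movie$config$pixel_size
  rows <- lapply(seq_len(nt), function(t) {
    proj <- zmax_project(movie$frames[, , , 2, t])
    f <- detect_foci(proj, px, filter_sigma, threshold_k, area_window)
    cnt <- count_in_roi(f, roi, field)
    data.frame(frame = t, time_min = movie$times[t],
               foci_count = cnt$foci_count,
               mean_focus_intensity = cnt$mean_focus_intensity)
  })
  out <- do.call(rbind, rows)
  out$nc14_time_min <- if (!is.null(timing) && isTRUE(timing$available))
    nc14_time(timing, out$time_min) else NA_real_
  out <- out[, c("frame", "time_min", "nc14_time_min", "foci_count",
                 "mean_focus_intensity")]
  structure(out, class = c("foci_count_trace", "data.frame"), roi = roi)
}
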
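#' Write a movie to disk as multi-page TIFF with sidecar metadata
#'
#' Pages are ordered T (slowest), then Z, then C; each page is a Y-X plane.
#' Pixels are clipped to `[0, 65535]` and stored as 16-bit unsigned. A YAML
#' sidecar carries the calibration and illumination protocol; ground truth
#' (when present) is written as plain CSV tables.
#'
#' @param movie an `embryo_movie`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_movie <- function(movie, dir) {
  stopifnot(inherits(movie, "embryo_movie"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(movie$frames)                      # x y z c t
  pages <- vector("list", d[3] * d[4] * d[5])
  k <- 1L
  for (t in seq_len(d[5])) for (z in seq_len(d[3])) for (c in seq_len(d[4])) {
    # writeTIFF takes row-major [y, x] matrices in [0, 1]
    pages[[k]] <- t(pmin(pmax(round(movie$frames[, , z, c, t]), 0),
                         65535)) / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(pages, file.path(dir, "movie.tif"),
                  bits.per.sample = 16L)
  cfg <- movie$config
  meta <- list(
    pixel_size_um = cfg$pixel_size, z_step_um = cfg$z_step,
    frame_interval_min = cfg$frame_interval,
    field_size_um = as.numeric(cfg$field_size),
    n_z = cfg$n_z, n_channels = 2L, n_frames = d[5],
    channels = c("nuclear_reporter", "ms2_foci"),
    page_order = "T-Z-C",
    protocol = list(
      edge_softness_um = movie$protocol$edge_softness,
      segments = lapply(seq_len(nrow(movie$protocol$segments)), function(i)
        list(start_min = movie$protocol$segments$start[i],
             end_min = movie$protocol$segments$end[i],
             light_on = movie$protocol$segments$light_on[i]))))
  yaml::write_yaml(meta, file.path(dir, "movie.yaml"))
  gt <- movie$ground_truth
  if (!is.null(gt)) {
    utils::write.csv(gt$nuclei, file.path(dir, "truth_nuclei.csv"),
                     row.names = FALSE)
    if (!is.null(gt$foci))
      utils::write.csv(gt$foci, file.path(dir, "truth_foci.csv"),
                       row.names = FALSE)
  }
  invisible(dir)
}

#' Read a movie written by [write_movie()]
#'
#' @param dir directory containing `movie.tif` and `movie.yaml`
#' @return an `embryo_movie` (frames, times, partial config from the
#'   sidecar; ground-truth tables if present)
#' @export
read_movie <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "movie.yaml"))
  pages <- tiff::readTIFF(file.path(dir, "movie.tif"), all = TRUE)
  nz <- meta$n_z; nc <- meta$n_channels; nt <- meta$n_frames
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  frames <- array(0, dim = c(nx, ny, nz, nc, nt))
  k <- 1L
  for (t in seq_len(nt)) for (z in seq_len(nz)) for (c in seq_len(nc)) {
    frames[, , z, c, t] <- t(pages[[k]]) * 65535
    k <- k + 1L
  }
  segs <- do.call(rbind, lapply(meta$protocol$segments, function(s)
    data.frame(start = s$start_min, end = s$end_min,
               light_on = s$light_on)))
  gt <- NULL
  if (file.exists(file.path(dir, "truth_nuclei.csv"))) {
    gt <- structure(list(
      nuclei = utils::read.csv(file.path(dir, "truth_nuclei.csv")),
      foci = if (file.exists(file.path(dir, "truth_foci.csv")))
        utils::read.csv(file.path(dir, "truth_foci.csv")) else NULL),
      class = "ground_truth")
  }
  cfg <- movie_config(pixel_size = meta$pixel_size_um, n_z = nz,
                      z_step = meta$z_step_um,
                      frame_interval = meta$frame_interval_min,
                      duration = max((nt - 1) * meta$frame_interval_min,
                                     meta$frame_interval_min),
                      field_size = unlist(meta$field_size_um))
  structure(list(frames = frames,
                 times = (seq_len(nt) - 1) * meta$frame_interval_min,
                 config = cfg,
                 protocol = illumination_protocol(
                   segs, meta$protocol$edge_softness_um),
                 ground_truth = gt),
            class = "embryo_movie")
}

#' Write a foci-count trace as CSV
#' @param trace a `foci_count_trace`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_foci_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read a foci-count trace CSV
#' @param path CSV path with at least `time_min` and `foci_count`
#' @return a `foci_count_trace`
#' @export
read_foci_trace <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_min", "foci_count") %in% names(df)))
  structure(df, class = c("foci_count_trace", "data.frame"))
}
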
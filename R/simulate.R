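#' Configuration for synthetic embryo movies
#'
#' Describes the imaging geometry and noise of a simulated two-channel,
#' z-stacked time-lapse: channel 1 carries the nuclear reporter (NLS-tagged,
#' light-exportable), channel 2 the MS2/MCP transcription foci. Defaults
#' emulate confocal/two-photon imaging of an NC14 embryo surface: a 150 x 60
#' um field at 0.3 um/pixel, 8 z-slices 1.1 um apart, one frame every 30 s.
#'
#' @param n_nuclei number of nuclei in the field (monolayer)
#' @param field_size c(x, y) field extent in micrometres
#' @param pixel_size micrometres per pixel
#' @param n_z number of z-slices
#' @param z_step z spacing in micrometres
#' @param frame_interval minutes between frames
#' @param duration movie duration in minutes
#' @param psf_sigma lateral Gaussian width of a diffraction-limited focus (um)
#' @param psf_sigma_z axial Gaussian width of a focus (um)
#' @param nuclear_radius nuclear disk radius (um)
#' @param foci_amplitude peak focus intensity above background (a.u.)
#' @param background camera background level (a.u.)
#' @param read_noise_sd additive Gaussian read noise SD (a.u.)
#' @param shot_noise logical; apply Poisson shot noise to expected counts
#' @param focus_visible_prob per-frame probability that an active focus is
#'   captured (occasional misses from z-drift / sectioning)
#' @param intensity_cv per-nucleus brightness coefficient of variation
#' @param drift_um_per_frame slow common drift of the nuclear monolayer (um)
#' @param cycle_dip optional `list(start, end, depth)`: between `start` and
#'   `end` minutes the nuclear-channel intensity is multiplied by `depth`,
#'   emulating the loss of nuclear signal at envelope breakdown
#' @param seed integer RNG seed
#' @return object of class `movie_config`
#' @export
movie_config <- function(n_nuclei = 220, field_size = c(150, 60),
                         pixel_size = 0.3, n_z = 8, z_step = 1.1,
                         frame_interval = 0.5, duration = 10,
                         psf_sigma = 0.3, psf_sigma_z = 1.2,
                         nuclear_radius = 2.5, foci_amplitude = 800,
                         background = 100, read_noise_sd = 10,
                         shot_noise = TRUE, focus_visible_prob = 0.98,
                         intensity_cv = 0.05, drift_um_per_frame = 0,
                         cycle_dip = NULL, seed = 1L) {
  cfg <- list(n_nuclei = n_nuclei, field_size = field_size,
              pixel_size = pixel_size, n_z = n_z, z_step = z_step,
              frame_interval = frame_interval, duration = duration,
              psf_sigma = psf_sigma, psf_sigma_z = psf_sigma_z,
              nuclear_radius = nuclear_radius,
              foci_amplitude = foci_amplitude, background = background,
              read_noise_sd = read_noise_sd, shot_noise = shot_noise,
              focus_visible_prob = focus_visible_prob,
              intensity_cv = intensity_cv,
              drift_um_per_frame = drift_um_per_frame,
              cycle_dip = cycle_dip, seed = as.integer(seed))
  pos <- c("n_nuclei", "pixel_size", "n_z", "z_step", "frame_interval",
           "duration", "psf_sigma", "psf_sigma_z", "nuclear_radius",
           "foci_amplitude", "background")
  for (f in pos) if (any(cfg[[f]] <= 0)) stop(f, " must be > 0")
  if (any(field_size <= 0)) stop("field_size must be > 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  if (focus_visible_prob < 0 || focus_visible_prob > 1)
    stop("focus_visible_prob must be in [0, 1]")
  structure(cfg, class = "movie_config")
}

# Jittered hexagonal monolayer of nucleus centres; errors if the field
# cannot hold n_nuclei at the requested radius.
place_nuclei <- function(config) {
  A <- prod(config$field_size)
  r <- config$nuclear_radius
  spacing <- sqrt(2 * A / (sqrt(3) * config$n_nuclei))
  grid_points <- function(s) {
    ys <- seq(r, config$field_size[2] - r, by = s * sqrt(3) / 2)
    do.call(rbind, lapply(seq_along(ys), function(i) {
      off <- if (i %% 2 == 0) s / 2 else 0
      xs <- seq(r + off, config$field_size[1] - r, by = s)
      cbind(x = xs, y = ys[i])
    }))
  }
  pts <- grid_points(spacing)
  # border margins eat grid sites: tighten the lattice, down to contact
  while (nrow(pts) < config$n_nuclei && spacing * 0.95 >= 2 * r) {
    spacing <- spacing * 0.95
    pts <- grid_points(spacing)
  }
  if (nrow(pts) < config$n_nuclei || spacing < 2 * r)
    stop("field too small to pack ", config$n_nuclei,
         " nuclei of radius ", r, " um (packing error)")
  pts <- pts[sample.int(nrow(pts), config$n_nuclei), , drop = FALSE]
  jit <- max(spacing / 2 - r, 0) * 0.8
  pts + matrix(stats::runif(2 * nrow(pts), -jit, jit), ncol = 2)
}

#' Render a synthetic two-channel embryo movie with ground truth
#'
#' Combines a translocation model (nuclear-channel dynamics), an illumination
#' protocol and a gene response preset (foci-channel dynamics) into a pixel
#' movie. Nuclei are disks carrying the simulated nuclear intensity; each
#' active nucleus shows one diffraction-limited focus rendered as a 3-D
#' Gaussian. Per-nucleus activity uses static activation thresholds
#' (`u_i ~ U(0,1)`, active iff rate `p(t) > u_i`), so nucleus-to-nucleus
#' heterogeneity is stable over time, plus an independent per-frame capture
#' probability. Identical `(config, seed)` gives bit-identical output.
#'
#' @param config a [movie_config()]
#' @param protocol an [illumination_protocol()] covering the movie
#' @param model a [translocation_model()]
#' @param preset a [gene_preset()]
#' @return object of class `embryo_movie`: list with `frames` (numeric array
#'   `[x, y, z, channel, t]`), `times` (minutes), `config`, `protocol`, and
#'   `ground_truth` (class `ground_truth`: `nuclei` per nucleus-frame table,
#'   `foci` per visible focus-frame table, `rate`, `nuclear_trace`,
#'   `response_time` = the preset's onset delay for the protocol's first
#'   light shift)
#' @export
render_movie <- function(config, protocol, model = translocation_model(),
                         preset = gene_preset("hb_like")) {
  stopifnot(inherits(config, "movie_config"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  times <- seq(0, config$duration, by = config$frame_interval)
  nt <- length(times)
  nx <- round(config$field_size[1] / config$pixel_size)
  ny <- round(config$field_size[2] / config$pixel_size)
  nz <- config$n_z

  centres0 <- place_nuclei(config)
  n <- config$n_nuclei
  bright <- exp(stats::rnorm(n, 0, config$intensity_cv))
  u <- stats::runif(n)                       # static activation thresholds
  focus_off <- matrix(stats::runif(2 * n, -0.3, 0.3), ncol = 2) *
    config$nuclear_radius
  focus_z <- sample.int(nz, n, replace = TRUE)

  nuc_trace <- simulate_nuclear_trace(model, protocol, times)
  dipf <- rep(1, nt)
  if (!is.null(config$cycle_dip))
    dipf[times >= config$cycle_dip$start & times < config$cycle_dip$end] <-
      config$cycle_dip$depth
  rate <- simulate_foci_rate(preset, protocol, times)

  active <- outer(rate, u, `>`)              # nt x n
  visible <- active & matrix(stats::runif(nt * n) < config$focus_visible_prob,
                             nt, n)

  px <- config$pixel_size
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  zpos <- (seq_len(nz) - 1) * config$z_step

  frames <- array(0, dim = c(nx, ny, nz, 2, nt))
  nuclei_rows <- vector("list", nt)
  foci_rows <- vector("list", nt)
  sig2 <- 2 * config$psf_sigma^2
  sig2z <- 2 * config$psf_sigma_z^2
  r2 <- config$nuclear_radius^2

  for (t in seq_len(nt)) {
    centres <- centres0 + (t - 1) * config$drift_um_per_frame
    ch1 <- matrix(config$background, nx, ny)
    ch2 <- array(0, dim = c(nx, ny, nz))
    nuc_int <- nuc_trace[t] * dipf[t] * bright
    for (i in seq_len(n)) {
      cx <- centres[i, 1]; cy <- centres[i, 2]
      ix <- which(abs(xs - cx) <= config$nuclear_radius)
      iy <- which(abs(ys - cy) <= config$nuclear_radius)
      if (length(ix) && length(iy)) {
        d2 <- outer((xs[ix] - cx)^2, (ys[iy] - cy)^2, `+`)
        ch1[ix, iy] <- ch1[ix, iy] + nuc_int[i] * (d2 <= r2)
      }
      if (visible[t, i]) {
        fx <- cx + focus_off[i, 1]; fy <- cy + focus_off[i, 2]
        # nascent-spot brightness tracks the initiation rate
        amp <- config$foci_amplitude * bright[i] * (0.6 + 0.4 * rate[t])
        jx <- which(abs(xs - fx) <= 4 * config$psf_sigma)
        jy <- which(abs(ys - fy) <= 4 * config$psf_sigma)
        if (length(jx) && length(jy)) {
          g <- outer(exp(-(xs[jx] - fx)^2 / sig2),
                     exp(-(ys[jy] - fy)^2 / sig2))
          gz <- exp(-(zpos - zpos[focus_z[i]])^2 / sig2z)
          for (z in seq_len(nz))
            ch2[jx, jy, z] <- ch2[jx, jy, z] + amp * g * gz[z]
        }
      }
    }
    for (z in seq_len(nz)) {
      frames[, , z, 1, t] <- ch1
      frames[, , z, 2, t] <- config$background + ch2[, , z]
    }
    if (config$shot_noise)
      frames[, , , , t] <- array(
        stats::rpois(nx * ny * nz * 2, lambda = frames[, , , , t]),
        dim = c(nx, ny, nz, 2))
    if (config$read_noise_sd > 0)
      frames[, , , , t] <- frames[, , , , t] +
        stats::rnorm(nx * ny * nz * 2, 0, config$read_noise_sd)
    frames[, , , , t][frames[, , , , t] < 0] <- 0

    nuclei_rows[[t]] <- data.frame(
      nucleus_id = seq_len(n), frame = t, time_min = times[t],
      x_um = centres[, 1], y_um = centres[, 2],
      intensity = nuc_int, active = active[t, ])
    vis <- which(visible[t, ])
    foci_rows[[t]] <- if (length(vis)) data.frame(
      nucleus_id = vis, frame = t, time_min = times[t],
      x_um = centres[vis, 1] + focus_off[vis, 1],
      y_um = centres[vis, 2] + focus_off[vis, 2],
      z = focus_z[vis],
      amplitude = config$foci_amplitude * bright[vis] *
        (0.6 + 0.4 * rate[t]))
    else NULL
  }

  trans <- light_transitions(protocol)
  rt <- NA_real_
  if (length(trans)) {
    dir1 <- if (light_state(protocol, trans[1] + 1e-9)) "dtl" else "ltd"
    rt <- preset_onset_delay(preset, dir1)
  }
  gt <- structure(list(
    nuclei = do.call(rbind, nuclei_rows),
    foci = do.call(rbind, foci_rows),
    rate = rate, nuclear_trace = nuc_trace,
    response_time = rt), class = "ground_truth")

  structure(list(frames = frames, times = times, config = config,
                 protocol = protocol, preset = preset, model = model,
                 ground_truth = gt),
            class = "embryo_movie")
}

#' Ground-truth foci count inside an ROI
#'
#' Counts the generator's visible foci per frame with the same half-open
#' inclusion convention as [count_in_roi()].
#'
#' @param gt a `ground_truth` object (or an `embryo_movie`)
#' @param roi `c(x0, x1, y0, y1)` in micrometres
#' @return integer vector, one count per frame
#' @export
ground_truth_counts <- function(gt, roi) {
  if (inherits(gt, "embryo_movie")) gt <- gt$ground_truth
  nt <- length(gt$rate)
  counts <- integer(nt)
  f <- gt$foci
  if (!is.null(f)) {
    inside <- f$x_um >= roi[1] & f$x_um < roi[2] &
      f$y_um >= roi[3] & f$y_um < roi[4]
    tab <- table(factor(f$frame[inside], levels = seq_len(nt)))
    counts <- as.integer(tab)
  }
  counts
}

#' Simulate a foci-count trace without pixel rendering
#'
#' Draws per-frame ROI foci counts directly from the generator's activity
#' model (static per-nucleus thresholds on the simulated activation
#' probability, with the per-frame capture probability), i.e. exactly the
#' ground-truth ROI counts a rendered movie would carry, at a fraction of the
#' cost. Used to build response-time cohorts.
#'
#' @param preset a [gene_preset()]
#' @param protocol an [illumination_protocol()]
#' @param n_nuclei number of nuclei inside the counting ROI (default 140,
#'   one nucleus per ~42 um^2 of NC14 surface in a 40 x 150 um^2 ROI)
#' @param frame_interval minutes between frames
#' @param focus_visible_prob per-frame capture probability of an active focus
#' @param foci_amplitude mean focus intensity (a.u.) for the intensity trace
#' @param amp_cv relative SD of a single focus intensity
#' @param seed integer RNG seed
#' @return a `foci_count_trace` data.frame with columns `frame`, `time_min`,
#'   `foci_count`, `mean_focus_intensity` (NA where count is 0)
#' @export
simulate_foci_count_trace <- function(preset, protocol, n_nuclei = 140,
                                      frame_interval = 0.5,
                                      focus_visible_prob = 0.98,
                                      foci_amplitude = 800, amp_cv = 0.2,
                                      seed = 1L) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  span <- protocol_span(protocol)
  times <- seq(span[1], span[2], by = frame_interval)
  rate <- simulate_foci_rate(preset, protocol, times)
  u <- stats::runif(n_nuclei)
  nt <- length(times)
  visible <- outer(rate, u, `>`) &
    matrix(stats::runif(nt * n_nuclei) < focus_visible_prob, nt, n_nuclei)
  count <- as.integer(rowSums(visible))
  mfi <- ifelse(count > 0,
                foci_amplitude * (0.6 + 0.4 * rate) *
                  (1 + stats::rnorm(nt, 0, amp_cv / sqrt(pmax(count, 1)))),
                NA_real_)
  structure(data.frame(frame = seq_len(nt), time_min = times,
                       foci_count = count, mean_focus_intensity = mfi),
            class = c("foci_count_trace", "data.frame"))
}
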
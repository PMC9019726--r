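#' Render a synthetic fixed-embryo image pair for boundary analysis
#'
#' Produces an ellipse-shaped embryo whose surface-rim intensity follows a
#' falling sigmoid along the anterior-posterior (A-P) axis,
#' `amplitude / (1 + exp((x - boundary) / sharpness)) + base`, with anterior
#' at 0% egg length (EL) and posterior at 100% EL, together with a
#' uniform-intensity reference embryo (a histone-GFP-like internal standard)
#' of the same geometry. The surface band is a continuous bright rim
#' (individual surface nuclei are not resolved).
#'
#' @param boundary_position sigmoid midpoint in %EL, strictly inside (0, 100)
#' @param sharpness sigmoid width in %EL; `0` gives a hard step
#' @param seed integer RNG seed (used only when `noise_sd > 0`)
#' @param amplitude rim intensity of the fully-on anterior plateau (a.u.)
#' @param reference_level rim intensity of the uniform reference embryo
#' @param base interior (yolk) intensity (a.u.)
#' @param noise_sd additive Gaussian pixel noise SD (a.u.)
#' @param size_px image size `c(nx, ny)` in pixels
#' @param band_frac rim thickness as a fraction of the elliptical radius
#' @return list with `embryo` and `reference` (numeric `[x, y]` matrices) and
#'   `truth` (`boundary_position`, `sharpness`, `amplitude`, `base`)
#' @export
render_profile_image <- function(boundary_position, sharpness = 5, seed = 1L,
                                 amplitude = 1000, reference_level = 800,
                                 base = 250, noise_sd = 0,
                                 size_px = c(240, 120), band_frac = 0.2) {
  if (boundary_position <= 0 || boundary_position >= 100)
    stop("boundary_position must be strictly inside (0, 100) %EL")
  if (sharpness < 0) stop("sharpness must be >= 0")
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  nx <- size_px[1]; ny <- size_px[2]
  cx <- nx / 2; cy <- ny / 2
  a <- 0.45 * nx; b <- 0.38 * ny
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  rell <- sqrt(((xg - cx) / a)^2 + ((yg - cy) / b)^2)
  inside <- rell <= 1
  band <- inside & rell >= (1 - band_frac)
  el <- (xg - (cx - a)) / (2 * a) * 100        # %EL along the major axis

  sig <- if (sharpness == 0) as.numeric(el < boundary_position)
         else 1 / (1 + exp((el - boundary_position) / sharpness))

  make <- function(rim) {
    img <- matrix(20, nx, ny)                  # slide background
    img[inside] <- base
    img[band] <- base + rim[band]
    if (noise_sd > 0) img <- img + stats::rnorm(nx * ny, 0, noise_sd)
    img[img < 0] <- 0
    img
  }
  embryo <- make(amplitude * sig)
  reference <- make(matrix(reference_level, nx, ny))
  list(embryo = embryo, reference = reference,
       truth = list(boundary_position = boundary_position,
                    sharpness = sharpness, amplitude = amplitude,
                    base = base))
}
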
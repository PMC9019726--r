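#' Extract an A-P expression profile from a fixed-embryo image
#'
#' Finds the embryo contour (threshold, largest connected component, hole
#' filling), fits an ellipse by second moments, and averages the intensity of
#' a surface band just inside the contour into bins of percent egg length
#' (%EL) along the major axis, anterior = 0, posterior = 100.
#'
#' @param img numeric `[x, y]` matrix (single embryo fully in frame)
#' @param bin_width %EL bin width
#' @param band_frac band thickness as a fraction of the elliptical radius
#' @param min_pixels minimum band pixels for a bin to be reported
#' @param min_area minimum embryo area in pixels before declaring "no embryo"
#' @return an `expression_profile` data.frame with columns `position_el` and
#'   `intensity`, attribute `normalization_state = "raw"`
#' @export
extract_profile <- function(img, bin_width = 2, band_frac = 0.2,
                            min_pixels = 10, min_area = 500) {
  stopifnot(is.matrix(img))
  rng <- range(img)
  if (diff(rng) <= 0) stop("no embryo found in image")
  # the embryo body must separate from the slide background, not from its
  # own bright rim: threshold relative to the border (slide) level
  border <- c(img[1, ], img[nrow(img), ], img[, 1], img[, ncol(img)])
  bg <- stats::median(border)
  th <- bg + 0.15 * (stats::quantile(img, 0.995) - bg)
  mask <- EBImage::fillHull(EBImage::bwlabel(img > th))
  tab <- tabulate(as.integer(EBImage::imageData(mask)))
  if (!length(tab) || max(tab) < min_area) stop("no embryo found in image")
  lab <- which.max(tab)
  m <- EBImage::imageData(mask) == lab

  idx <- which(m, arr.ind = TRUE)
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  cv <- stats::cov(cbind(idx[, 1] - cx, idx[, 2] - cy))
  eig <- eigen(cv, symmetric = TRUE)
  axis1 <- eig$vectors[, 1]              # major axis direction
  if (axis1[1] < 0) axis1 <- -axis1      # anterior at low x by convention
  a <- 2 * sqrt(eig$values[1])           # semi-axes of a solid ellipse
  b <- 2 * sqrt(eig$values[2])
  u <- (idx[, 1] - cx) * axis1[1] + (idx[, 2] - cy) * axis1[2]
  v <- -(idx[, 1] - cx) * axis1[2] + (idx[, 2] - cy) * axis1[1]
  rell <- sqrt((u / a)^2 + (v / b)^2)
  band <- rell >= (1 - band_frac) & rell <= 1.02
  el <- (u + a) / (2 * a) * 100

  bins <- seq(0, 100, by = bin_width)
  bi <- cut(el[band], breaks = bins, include.lowest = TRUE)
  vals <- img[m][band]
  counts <- tapply(vals, bi, length)
  means <- tapply(vals, bi, mean)
  centre <- (bins[-1] + bins[-length(bins)]) / 2
  ok <- !is.na(counts) & counts >= min_pixels
  new_profile(data.frame(position_el = centre[ok],
                         intensity = as.numeric(means[ok])), "raw")
}

new_profile <- function(df, state) {
  stopifnot(all(diff(df$position_el) > 0))
  structure(df, class = c("expression_profile", "data.frame"),
            normalization_state = state)
}

#' Normalize a profile to reference embryos
#'
#' Divides the profile by the mean over reference embryos of each reference's
#' maximum intensity, so that 1 corresponds to the mean maximal intensity of
#' the uniform internal-standard embryos co-mounted on the slide.
#'
#' @param profile an `expression_profile`
#' @param references list of `expression_profile`s from reference embryos
#' @return profile with `normalization_state = "reference_normalized"`
#' @export
normalize_to_reference <- function(profile, references) {
  if (length(references) < 1L) stop("at least one reference profile required")
  ref_max <- mean(vapply(references, function(r) max(r$intensity), 0))
  if (ref_max <= 0) stop("reference maximum is zero")
  out <- profile
  out$intensity <- profile$intensity / ref_max
  new_profile(as.data.frame(out), "reference_normalized")
}

#' Min-max normalize a profile to [0, 1]
#'
#' @param profile an `expression_profile` (non-constant)
#' @return profile with values `(x - min) / (max - min)` and
#'   `normalization_state = "minmax"`
#' @export
minmax_normalize <- function(profile) {
  rng <- range(profile$intensity)
  if (diff(rng) <= 0) stop("cannot min-max normalize a constant profile")
  out <- profile
  out$intensity <- (profile$intensity - rng[1]) / diff(rng)
  new_profile(as.data.frame(out), "minmax")
}

#' Half-maximal boundary position of the anterior expression domain
#'
#' Scans the min-max-normalized profile from anterior to posterior and
#' returns the position of the last downward 0.5-crossing, linearly
#' interpolated between bins: the posterior boundary of the anterior domain.
#'
#' @param profile an `expression_profile` in `minmax` normalization state
#' @return list of class `boundary_estimate`: `boundary_position` (%EL),
#'   `crossing_direction = "falling"`
#' @export
half_max_boundary <- function(profile) {
  if (!identical(attr(profile, "normalization_state"), "minmax"))
    profile <- minmax_normalize(profile)
  y <- profile$intensity
  p <- profile$position_el
  cross <- which(y[-length(y)] >= 0.5 & y[-1] < 0.5)
  if (!length(cross)) stop("no downward 0.5-crossing in profile")
  i <- cross[length(cross)]
  pos <- p[i] + (y[i] - 0.5) / (y[i] - y[i + 1]) * (p[i + 1] - p[i])
  structure(list(boundary_position = pos, crossing_direction = "falling"),
            class = "boundary_estimate")
}

#' Rank genotypes by expression-boundary position
#'
#' A more posterior boundary of the anterior expression domain reflects a
#' higher-activity construct, so genotypes are ordered by decreasing mean
#' boundary position.
#'
#' @param boundaries data.frame with columns `genotype` and `boundary_el`
#'   (one row per embryo)
#' @return data.frame, one row per genotype ordered by decreasing mean
#'   boundary: `genotype`, `n`, `mean_el`, `q25`, `median_el`, `q75`, `rank`,
#'   `tie` (TRUE where adjacent means are equal; order then follows first
#'   appearance in the input)
#' @export
activity_series <- function(boundaries) {
  stopifnot(all(c("genotype", "boundary_el") %in% names(boundaries)))
  gts <- unique(boundaries$genotype)
  rows <- do.call(rbind, lapply(gts, function(g) {
    b <- boundaries$boundary_el[boundaries$genotype == g]
    data.frame(genotype = g, n = length(b), mean_el = mean(b),
               q25 = unname(stats::quantile(b, 0.25)),
               median_el = stats::median(b),
               q75 = unname(stats::quantile(b, 0.75)))
  }))
  ord <- order(-rows$mean_el)          # stable: ties keep input order
  rows <- rows[ord, , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rows$tie <- c(FALSE, diff(rows$mean_el) == 0) |
    c(diff(rows$mean_el) == 0, FALSE)
  rownames(rows) <- NULL
  rows
}
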
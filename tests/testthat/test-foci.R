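test_that("z-max projection takes per-column maxima", {
  single <- matrix(1:12, 3, 4)
  expect_identical(zmax_project(single), single)
  st <- array(0, dim = c(3, 4, 5))
  for (z in 1:5) st[, , z] <- z
  st[2, 2, 3] <- 99
  proj <- zmax_project(st)
  expect_equal(proj[2, 2], 99)
  expect_equal(proj[1, 1], 5)
})

test_that("projection peak matches the ground-truth focus amplitude", {
  mv <- render_movie(tiny_config(), constant_protocol(3))
  proj <- zmax_project(mv$frames[, , , 2, 1])
  gt <- mv$ground_truth$foci[mv$ground_truth$foci$frame == 1, ]
  expect_equal(max(proj), mv$config$background + max(gt$amplitude),
               tolerance = 0.05)
})

test_that("blank frames yield no foci", {
  set.seed(2)
  img <- matrix(100 + stats::rnorm(120 * 80, 0, 5), 120, 80)
  f <- detect_foci(img, pixel_size = 0.4)
  expect_equal(nrow(f), 0)
})

test_that("well-separated bright spots are found with sub-pixel accuracy", {
  px <- 0.4
  nx <- 200; ny <- 160
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  set.seed(9)
  truth <- expand.grid(x = seq(8, 72, by = 16), y = seq(8, 56, by = 12))
  img <- matrix(100, nx, ny)
  for (i in seq_len(nrow(truth)))
    img <- img + 500 * outer(exp(-(xs - truth$x[i])^2 / (2 * 0.3^2)),
                             exp(-(ys - truth$y[i])^2 / (2 * 0.3^2)))
  img <- img + stats::rnorm(nx * ny, 0, 5)
  f <- detect_foci(img, px, filter_sigma = 0.3)
  expect_equal(nrow(f), nrow(truth))   # 25 spots at 10x background SD
  err <- vapply(seq_len(nrow(truth)), function(i)
    min(sqrt((f$x_um - truth$x[i])^2 + (f$y_um - truth$y[i])^2)), 0)
  expect_lt(max(err), px)
})

test_that("spots closer than the filter scale merge into one focus", {
  px <- 0.4
  xs <- (seq_len(100) - 0.5) * px
  ys <- (seq_len(60) - 0.5) * px
  img <- matrix(100, 100, 60)
  for (x0 in c(20, 20.4))              # separation ~ filter_sigma
    img <- img + 500 * outer(exp(-(xs - x0)^2 / (2 * 0.3^2)),
                             exp(-(ys - 12)^2 / (2 * 0.3^2)))
  f <- detect_foci(img, px, filter_sigma = 0.3)
  expect_equal(nrow(f), 1)
})

test_that("ROI counting is half-open: lower edge in, upper edge out", {
  foci <- data.frame(x_um = c(10, 50, 10, 30), y_um = c(5, 20, 20, 12),
                     intensity = c(1, 1, 1, 1))
  roi <- c(10, 50, 5, 20)
  out <- count_in_roi(foci, roi)
  expect_equal(out$foci_count, 2L)     # the two lower-edge foci
  expect_equal(count_in_roi(foci[0, ], roi)$foci_count, 0L)
  expect_error(count_in_roi(foci, c(-5, 50, 0, 20), field = c(60, 40)),
               "outside")
})

test_that("counting is equivariant under a common translation", {
  mv <- render_movie(tiny_config(), constant_protocol(3))
  proj <- zmax_project(mv$frames[, , , 2, 1])
  f <- detect_foci(proj, mv$config$pixel_size)
  shift_px <- 10
  shifted <- matrix(100, nrow(proj), ncol(proj))
  shifted[(shift_px + 1):nrow(proj), ] <- proj[1:(nrow(proj) - shift_px), ]
  f2 <- detect_foci(shifted, mv$config$pixel_size)
  roi <- c(10, 50, 5, 35)
  roi2 <- roi + c(shift_px * 0.4, shift_px * 0.4, 0, 0)
  expect_equal(count_in_roi(f2, roi2)$foci_count,
               count_in_roi(f, roi)$foci_count)
})

test_that("raising the detection threshold never increases counts", {
  mv <- render_movie(tiny_config(seed = 12), constant_protocol(3))
  proj <- zmax_project(mv$frames[, , , 2, 1])
  counts <- vapply(c(3, 5, 8, 12, 20), function(k)
    nrow(detect_foci(proj, mv$config$pixel_size, threshold_k = k)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("noise-free trace equals ground truth; intensity tracks counts", {
  cfg <- tiny_config(duration = 6)
  mv <- render_movie(cfg, shift_protocol(1.5, 6, "dtl"))
  roi <- c(5, 55, 5, 35)
  tr <- foci_trace(mv, roi = roi)
  expect_identical(tr$foci_count, ground_truth_counts(mv, roi))
  ok <- tr$foci_count > 0
  expect_gt(stats::cor(tr$foci_count[ok], tr$mean_focus_intensity[ok]), 0.8)
})
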
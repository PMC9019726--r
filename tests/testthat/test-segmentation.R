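test_that("a blank frame yields zero nuclei with a warning", {
  expect_warning(res <- segment_nuclei(matrix(0, 50, 50), 0.4), "all-zero")
  expect_equal(nrow(res$regions), 0)
})

test_that("noise-free disks are all recovered with sub-pixel centroids", {
  mv <- render_movie(tiny_config(), constant_protocol(3))
  seg <- segment_nuclei(zmax_project(mv$frames[, , , 1, 1]),
                        mv$config$pixel_size)
  truth <- mv$ground_truth$nuclei[mv$ground_truth$nuclei$frame == 1, ]
  expect_equal(nrow(seg$regions), nrow(truth))
  err <- vapply(seq_len(nrow(truth)), function(i)
    min(sqrt((seg$regions$x_um - truth$x_um[i])^2 +
               (seg$regions$y_um - truth$y_um[i])^2)), 0)
  expect_lt(max(err), mv$config$pixel_size)   # < 1 pixel
})

test_that("heavily overlapping disks give one or two nuclei", {
  px <- 0.4
  img <- matrix(0, 100, 60)
  xs <- (seq_len(100) - 0.5) * px
  ys <- (seq_len(60) - 0.5) * px
  for (c0 in list(c(18, 12), c(20, 12))) {   # centres 2 um apart, r = 2.5
    d2 <- outer((xs - c0[1])^2, (ys - c0[2])^2, `+`)
    img[d2 <= 2.5^2] <- 200
  }
  seg <- segment_nuclei(img, px)
  expect_true(nrow(seg$regions) %in% c(1L, 2L))
})

test_that("tracking keeps drifting nuclei on unbroken, stable tracks", {
  cfg <- tiny_config(drift_um_per_frame = 0.2)
  mv <- render_movie(cfg, constant_protocol(3))
  tr <- extract_traces(mv)
  lens <- table(tr$nucleus_id)
  expect_equal(length(lens), cfg$n_nuclei)
  expect_true(all(lens == length(mv$times)))
  # per-frame displacement stays under the gate
  disp <- stats::aggregate(cbind(x_um, y_um) ~ nucleus_id, tr, function(v)
    max(abs(diff(v))))
  expect_lt(max(disp$x_um, disp$y_um), cfg$nuclear_radius)
})

test_that("a disappearing nucleus ends its track without id reuse", {
  reg <- function(x) data.frame(label = seq_along(x), x_um = x,
                                y_um = rep(5, length(x)),
                                area_um2 = rep(20, length(x)),
                                mean_intensity = rep(100, length(x)))
  frames <- list(reg(c(5, 15)), reg(c(5, 15)), reg(5), reg(c(5, 15)))
  tr <- track_nuclei(frames, gate = 2)
  id2 <- tr$nucleus_id[tr$frame == 1 & tr$x_um == 15]
  expect_equal(sort(tr$frame[tr$nucleus_id == id2]), c(1, 2))
  # reappearing nucleus starts a fresh track
  id_new <- tr$nucleus_id[tr$frame == 4 & tr$x_um == 15]
  expect_false(id_new %in% c(id2, tr$nucleus_id[tr$frame == 1]))
})

test_that("tracked mean intensity reproduces the simulated nuclear trace", {
  cfg <- tiny_config(duration = 4)
  mv <- render_movie(cfg, shift_protocol(1, 4, "dtl"))
  tr <- extract_traces(mv)
  per_frame <- tapply(tr$mean_intensity, tr$frame, mean)
  expected <- cfg$background + mv$ground_truth$nuclear_trace
  rel <- abs(per_frame - expected) / expected
  expect_lt(max(rel), 0.02)
})

test_that("cycle timing anchors NC14 at re-formation = 5.6 min", {
  times <- 0:25
  inten <- rep(100, 26)
  inten[times >= 10 & times < 12] <- 20       # breakdown dip
  ct <- extract_cycle_timing(times, inten)
  expect_true(ct$available)
  expect_equal(ct$reformation_time, 12)
  expect_equal(nc14_time(ct, 20), 5.6 + (20 - 12))
})

test_that("flat traces leave timing unavailable; earliest dip wins", {
  ct <- extract_cycle_timing(0:20, rep(80, 21))
  expect_false(ct$available)
  expect_error(nc14_time(ct, 5), "unavailable")
  inten <- rep(100, 31)
  inten[11:12] <- 20
  inten[21:22] <- 20
  ct2 <- extract_cycle_timing(0:30, inten)
  expect_equal(ct2$envelope_breakdown_time, 10)
  expect_equal(ct2$reformation_time, 12)
})
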
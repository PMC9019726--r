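test_that("profile normalization follows the reference-maximum rule", {
  mk <- function(v) optoembryo:::new_profile(
    data.frame(position_el = seq_along(v) * 10, intensity = v), "raw")
  prof <- mk(c(50, 200, 120))
  refs <- list(mk(c(100, 80)), mk(c(300, 250)))   # maxima 100 and 300
  out <- normalize_to_reference(prof, refs)
  expect_equal(max(out$intensity), 200 / 200)     # peak 200 / mean-max 200
  expect_equal(attr(out, "normalization_state"), "reference_normalized")
  self <- normalize_to_reference(prof, list(prof))
  expect_equal(max(self$intensity), 1)
  expect_error(normalize_to_reference(prof, list()), "reference")
  expect_error(normalize_to_reference(prof, list(mk(c(0, 0)))), "zero")
})

test_that("min-max normalization maps to [0,1] and kills affine transforms", {
  mk <- function(v) optoembryo:::new_profile(
    data.frame(position_el = seq_along(v) * 10, intensity = v), "raw")
  expect_equal(minmax_normalize(mk(c(2, 4, 6)))$intensity, c(0, 0.5, 1))
  set.seed(5)
  v <- stats::runif(20, 10, 400)
  expect_equal(minmax_normalize(mk(3.7 * v + 55))$intensity,
               minmax_normalize(mk(v))$intensity)
  expect_error(minmax_normalize(mk(rep(4, 5))), "constant")
  noisy <- minmax_normalize(mk(v))
  expect_true(all(noisy$intensity >= 0 & noisy$intensity <= 1))
})

test_that("half-max boundary interpolates the last falling 0.5-crossing", {
  mk <- function(p, v) optoembryo:::new_profile(
    data.frame(position_el = p, intensity = v), "minmax")
  # step from 1 to 0 between bins at 44 and 46 %EL
  b <- half_max_boundary(mk(c(40, 42, 44, 46, 48), c(1, 1, 1, 0, 0)))
  expect_equal(b$boundary_position, 45)
  expect_equal(b$crossing_direction, "falling")
  # non-monotone profile: the posterior (last) crossing wins
  b2 <- half_max_boundary(mk(seq(10, 90, 10),
                             c(1, 0.4, 0.8, 1, 1, 0.9, 0.6, 0.4, 0)))
  expect_gt(b2$boundary_position, 60)
  expect_error(half_max_boundary(mk(c(10, 50, 90), c(0, 0.5, 1))),
               "crossing")
})

test_that("noise-free sigmoid embryos are quantified almost exactly", {
  img <- render_profile_image(45, sharpness = 3)
  prof <- extract_profile(img$embryo)
  ref <- extract_profile(img$reference)
  expect_lt(stats::sd(ref$intensity) / mean(ref$intensity), 0.05)
  mm <- minmax_normalize(normalize_to_reference(prof, list(ref)))
  expect_equal(half_max_boundary(mm)$boundary_position, 45, tolerance = 0.5 / 45)
  sig <- 1 / (1 + exp((mm$position_el - 45) / 3))
  expect_lt(sqrt(mean((mm$intensity - sig)^2)), 0.02)
  # hard step limit
  st <- render_profile_image(45, sharpness = 0)
  bs <- half_max_boundary(minmax_normalize(extract_profile(st$embryo)))
  expect_lt(abs(bs$boundary_position - 45), 1)
  expect_error(extract_profile(matrix(100, 60, 40)), "no embryo")
})

test_that("noisy replicate boundaries are recovered without bias", {
  for (true_b in c(35, 55)) {
    bs <- vapply(1:20, function(s) {
      im <- render_profile_image(true_b, sharpness = 3, seed = s,
                                 noise_sd = 40)
      half_max_boundary(minmax_normalize(
        extract_profile(im$embryo)))$boundary_position
    }, 0)
    expect_lt(abs(mean(bs) - true_b), 1)    # |bias| < 1 %EL
  }
})

test_that("genotype cohorts are ranked into the correct activity series", {
  set.seed(31)
  bnd <- do.call(rbind, lapply(seq_along(c(47, 45, 43)), function(i) {
    tb <- c(47, 45, 43)[i]
    data.frame(genotype = c("high", "mid", "low")[i],
               boundary_el = tb + stats::rnorm(6, 0, 0.3))
  }))
  ser <- activity_series(bnd)
  expect_equal(ser$genotype, c("high", "mid", "low"))
  expect_equal(ser$rank, 1:3)
  expect_false(any(ser$tie))
  one <- activity_series(data.frame(genotype = "only", boundary_el = 44))
  expect_equal(nrow(one), 1)
  tied <- activity_series(data.frame(genotype = c("a", "b", "a", "b"),
                                     boundary_el = c(44, 44, 46, 46)))
  expect_equal(tied$genotype, c("a", "b"))   # stable input order
  expect_true(all(tied$tie))
})
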
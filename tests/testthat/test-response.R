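test_that("difference curve subtracts the interpolated control mean", {
  tt <- seq(0, 10, by = 0.5)
  ctrl <- make_trace(tt, rep(20, length(tt)))
  emb <- make_trace(tt, rep(20, length(tt)))
  dc <- difference_curve(emb, list(ctrl))
  expect_equal(dc$difference, rep(0, length(tt)))
  emb5 <- make_trace(tt, rep(25, length(tt)))
  expect_equal(difference_curve(emb5, list(ctrl, ctrl))$difference,
               rep(5, length(tt)))
  late <- make_trace(tt + 100, rep(20, length(tt)))
  expect_error(difference_curve(emb, list(late)), "overlap")
  expect_error(difference_curve(emb, list()), "control")
})

test_that("smoothing and differentiation agree with a convolution oracle", {
  set.seed(21)
  tt <- seq(0, 20, by = 0.5)
  y <- cumsum(stats::rnorm(length(tt)))
  dv <- smooth_and_differentiate(data.frame(time_min = tt, difference = y))
  orc <- oracle_smooth_diff(tt, y)
  expect_equal(dv$smoothed, orc$smoothed)
  expect_equal(dv$derivative, orc$derivative)
})

test_that("linear ramps and constants differentiate exactly", {
  tt <- seq(0, 10, by = 0.5)
  dv <- smooth_and_differentiate(data.frame(time_min = tt,
                                            difference = 3 * tt))
  inner <- 4:(length(tt) - 3)          # full smoothing support
  expect_equal(dv$derivative[inner], rep(3, length(inner)))
  dvc <- smooth_and_differentiate(data.frame(time_min = tt,
                                             difference = rep(7, 21)))
  expect_equal(dvc$derivative, rep(0, 21))
  expect_error(smooth_and_differentiate(
    data.frame(time_min = 1:4, difference = 1:4)), "longer")
  expect_error(smooth_and_differentiate(
    data.frame(time_min = 1:10, difference = 1:10), window = 4), "odd")
})

test_that("a unit step puts the maximum derivative at the step", {
  tt <- seq(0, 20, by = 0.5)
  y <- as.numeric(tt >= 10)
  dv <- smooth_and_differentiate(data.frame(time_min = tt, difference = y))
  orc <- oracle_smooth_diff(tt, y)
  expect_equal(dv$time_min[which.max(dv$derivative)],
               tt[which.max(orc$derivative)])
  # earliest of the tied plateau: within half the smoothing window of the step
  expect_lte(abs(dv$time_min[which.max(dv$derivative)] - 10), 1.25)
})

test_that("response time finds a step response within half a window", {
  tt <- seq(0, 30, by = 0.5)
  shift <- 5
  y <- 30 * pmax(0, 1 - exp(-(tt - shift - 4) / 1)) * (tt >= shift + 4)
  dv <- smooth_and_differentiate(data.frame(time_min = tt, difference = y))
  r <- response_time(dv, shift_time = shift, expected_sign = 1)
  expect_lt(abs(r$response_time - 4), 1.25 + 0.5)
  expect_error(response_time(dv, shift_time = 100), "after the shift")
})

test_that("response time ignores pre-shift changes and breaks ties early", {
  tt <- seq(0, 20, by = 0.5)
  d <- rep(0, length(tt))
  d[tt == 3] <- 10                      # large pre-shift derivative
  d[tt %in% c(8, 12)] <- 5              # tied post-shift maxima
  dv <- data.frame(time_min = tt, smoothed = NA, derivative = d)
  r <- response_time(dv, shift_time = 5)
  expect_equal(r$response_time, 8 - 5)
})

test_that("the exclusion rule is inclusive at exactly 25%", {
  tt <- seq(0, 10, by = 0.5)
  base <- response_time(
    smooth_and_differentiate(data.frame(time_min = tt, difference = tt)),
    shift_time = 0)
  dc24 <- data.frame(time_min = tt, difference = c(rep(0, 20), 24),
                     control_mean = rep(100, 21))
  expect_false(apply_exclusion(base, dc24)$included)
  dc25 <- data.frame(time_min = tt, difference = c(rep(0, 20), -25),
                     control_mean = rep(100, 21))
  r25 <- apply_exclusion(base, dc25)
  expect_true(r25$included)
  expect_equal(r25$max_abs_difference, 25)
  expect_equal(r25$control_peak, 100)
})

test_that("cohort summary computes mean and SEM over included embryos", {
  mk <- function(rt, inc) structure(list(response_time = rt, included = inc,
                                         exclusion_reason = if (!inc) "flat"),
                                    class = "response_time_result")
  s <- cohort_summary(list(mk(2, TRUE), mk(3, TRUE), mk(4, TRUE),
                           mk(NA, FALSE)))
  expect_equal(s$mean_response_time, 3)
  expect_equal(s$sem, 1 / sqrt(3))
  expect_equal(s$n_included, 3)
  expect_equal(s$n_excluded, 1)
  single <- cohort_summary(list(mk(5, TRUE)))
  expect_true(is.na(single$sem))
  expect_error(cohort_summary(list(mk(NA, FALSE))), "flat")
})

test_that("planted non-responders are excluded, and only they", {
  pr <- gene_preset("hb_like")
  pert <- shift_protocol(5, 30, "dtl")
  ctrl <- constant_protocol(30, light_on = FALSE)
  embryos <- c(
    lapply(1:8, function(s) simulate_foci_count_trace(pr, pert, seed = s)),
    # non-responders: never see the shift
    lapply(9:10, function(s) simulate_foci_count_trace(pr, ctrl, seed = s)))
  controls <- lapply(11:18, function(s)
    simulate_foci_count_trace(pr, ctrl, seed = s))
  ana <- analyze_response_cohort(embryos, controls, shift_time = 5,
                                 expected_sign = -1)
  inc <- vapply(ana$results, function(r) r$included, TRUE)
  expect_equal(inc, c(rep(TRUE, 8), FALSE, FALSE))
})

test_that("response time is invariant to common offsets and time shifts", {
  pr <- gene_preset("hb_like")
  co <- simulate_response_cohort(pr, "ltd", n_embryos = 2, n_controls = 3,
                                 seed = 42)
  base <- analyze_response_cohort(co$embryos, co$controls, co$shift_time,
                                  co$expected_sign)$summary$mean_response_time
  plus <- function(tr, dt, dc) {
    tr$time_min <- tr$time_min + dt
    tr$foci_count <- tr$foci_count + dc
    tr
  }
  shifted <- analyze_response_cohort(
    lapply(co$embryos, plus, dt = 0, dc = 11),
    lapply(co$controls, plus, dt = 0, dc = 11),
    co$shift_time, co$expected_sign)$summary$mean_response_time
  expect_equal(shifted, base)
  delayed <- analyze_response_cohort(
    lapply(co$embryos, plus, dt = 7, dc = 0),
    lapply(co$controls, plus, dt = 7, dc = 0),
    co$shift_time + 7, co$expected_sign)$summary$mean_response_time
  expect_equal(delayed, base)
})

test_that("cohort means recover the generator onset delay", {
  co <- simulate_response_cohort("hb_like", "ltd", seed = 7)
  an <- analyze_response_cohort(co$embryos, co$controls, co$shift_time,
                                co$expected_sign)
  expect_lt(abs(an$summary$mean_response_time - co$true_delay), 1.25 + 0.5)
  expect_equal(an$summary$n_included, 8)
})
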
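test_that("rigid-pack prediction is constant and scale invariant", {
  grid <- c(5, 10, 20, 40)
  pred <- rigid_pack_prediction(grid, calibration = c(10, 0.04))
  expect_true(all(pred$predicted_rate == 0.04))
  pred2 <- rigid_pack_prediction(2 * grid, calibration = c(10, 0.04))
  expect_identical(pred$predicted_rate, pred2$predicted_rate)
  expect_error(rigid_pack_prediction(c(0, 5), c(10, 0.04)),
               class = "epijam_invalid_config")
})

test_that("rate-speed test handles exact relations and degenerate input", {
  x <- c(5, 7, 9, 11, 13, 15)
  flat <- rate_speed_test(data.frame(vrms = x, rate = 0.04),
                          n_boot = 200, seed = 1)
  expect_equal(flat$slope, 0)
  expect_equal(flat$p_value, 1)

  line <- rate_speed_test(data.frame(vrms = x, rate = 0.003 * x),
                          n_boot = 200, seed = 1)
  expect_equal(line$slope, 0.003, tolerance = 1e-12)
  expect_lt(line$p_value, 1e-12)

  degen <- rate_speed_test(data.frame(vrms = rep(5, 6), rate = runif(6)),
                           n_boot = 100, seed = 1)
  expect_identical(degen$status, "degenerate")
  expect_error(rate_speed_test(data.frame(vrms = 1:3, rate = 1:3)),
               class = "epijam_empty_input")
})

test_that("4PL fitting recovers noiseless parameters and rejects bad input", {
  s <- generate_sigmoid_series(seq(10, 150, 10), 1, 3, 90, 8)
  fit <- fit_sigmoid(s)
  expect_true(fit$converged)
  expect_equal(fit$bottom, 1, tolerance = 1e-6)
  expect_equal(fit$top, 3, tolerance = 1e-6)
  expect_equal(fit$logec50_h, 90, tolerance = 1e-6)
  expect_equal(fit$hill, 8, tolerance = 1e-5)
  expect_false(fit$extrapolated)

  expect_error(
    fit_sigmoid(data.frame(time_h = seq(10, 100, 10), value = 2)),
    class = "epijam_degenerate_series")
  expect_error(
    fit_sigmoid(data.frame(time_h = c(10, 20, 30), value = c(1, 2, 3))),
    class = "epijam_empty_input")
})

test_that("4PL fit is exactly equivariant under time scaling and value affinity", {
  s <- generate_sigmoid_series(seq(10, 150, 10), 1, 3, 90, 8,
                               noise_sigma = 0.08, seed = 5)
  f0 <- fit_sigmoid(s)
  sc <- data.frame(time_h = 3 * s$time_h, value = s$value)
  f_sc <- fit_sigmoid(sc)
  expect_equal(f_sc$logec50_h, 3 * f0$logec50_h, tolerance = 1e-8)
  expect_equal(f_sc$hill, f0$hill, tolerance = 1e-8)

  av <- data.frame(time_h = s$time_h, value = 2.5 * s$value + 4)
  f_av <- fit_sigmoid(av)
  expect_equal(f_av$bottom, 2.5 * f0$bottom + 4, tolerance = 1e-7)
  expect_equal(f_av$top, 2.5 * f0$top + 4, tolerance = 1e-7)
  expect_equal(f_av$logec50_h, f0$logec50_h, tolerance = 1e-7)
})

test_that("EC50 recovery stays within 3 h at 5% noise", {
  errs <- vapply(1:60, function(s) {
    srs <- generate_sigmoid_series(seq(10, 150, 10), 1, 3, 90, 8,
                                   noise_sigma = 0.1, seed = 1000 + s)
    abs(fit_sigmoid(srs)$logec50_h - 90)
  }, numeric(1))
  expect_lte(median(errs), 3)
})

test_that("onset detection finds breakpoints and knows when there is none", {
  t <- seq(0, 140, 2)
  y <- ifelse(t < 60, 10, 10 - 0.1 * (t - 60))
  on <- detect_onset(t, y, n_boot = 100, seed = 1)
  expect_identical(on$status, "ok")
  expect_equal(on$onset_h, 60, tolerance = 2)
  expect_equal(on$slope_pre, 0, tolerance = 1e-8)
  expect_equal(on$slope_post, -0.1, tolerance = 1e-8)

  set.seed(2)
  flat <- detect_onset(t, rnorm(length(t), 10, 0.3), n_boot = 50, seed = 2)
  expect_identical(flat$status, "no_change_point")

  # invariance under adding a constant
  on2 <- detect_onset(t, y + 57.3, n_boot = 100, seed = 1)
  expect_identical(on2$onset_h, on$onset_h)
  expect_identical(on2$ci_h, on$ci_h)
})

test_that("onset recovery from noisy crowding time courses", {
  tt <- seq(70, 119, 1)
  sch <- data.frame(time_h = c(0, tt),
                    v0 = c(15, 15 - 0.25 * (tt - 70)))
  hits <- vapply(1:20, function(s) {
    cfg <- monolayer_config(n_cells = 60, box_um = 200, mode = "fluid",
                            n_frames = 120, dt = 1, noise_sigma = 1,
                            seed = 7000 + s)
    tr <- generate_crowding_timecourse(cfg, sch)
    tc <- vrms_timecourse(tr, 2)
    on <- detect_onset(tc$t_mid, tc$vrms, n_boot = 50, seed = s)
    abs(on$onset_h - 70) <= 5
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
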
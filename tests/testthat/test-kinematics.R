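test_that("vrms matches hand-computed values and handles degenerate input", {
  u <- velocity_field(matrix(3, 8, 8), matrix(4, 8, 8), spacing_um = 10)
  expect_equal(vrms(u)$vrms, 5)
  expect_equal(vrms(u, subtract_mean = TRUE)$vrms, 0)
  z <- velocity_field(matrix(0, 8, 8), matrix(0, 8, 8), spacing_um = 10)
  expect_equal(vrms(z)$vrms, 0)

  two <- velocity_field(matrix(c(1, 0), 1, 2), matrix(0, 1, 2),
                        spacing_um = 10)
  expect_equal(vrms(two)$vrms, sqrt(0.5))

  bad <- velocity_field(matrix(NA_real_, 4, 4), matrix(NA_real_, 4, 4),
                        spacing_um = 10)
  expect_error(vrms(bad), class = "epijam_empty_input")
})

test_that("vrms is rotation invariant and scales linearly", {
  for (s in 1:5) {
    set.seed(s)
    f <- velocity_field(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8),
                        spacing_um = 10)
    th <- runif(1, 0, 2 * pi)
    rot <- velocity_field(cos(th) * f$vx - sin(th) * f$vy,
                          sin(th) * f$vx + cos(th) * f$vy, spacing_um = 10)
    expect_equal(vrms(rot)$vrms, vrms(f)$vrms, tolerance = 1e-12)
    k <- runif(1, 0.1, 5)
    scl <- velocity_field(k * f$vx, k * f$vy, spacing_um = 10)
    expect_equal(vrms(scl)$vrms, k * vrms(f)$vrms, tolerance = 1e-12)
  }
})

test_that("vrms time course tracks the generator", {
  st <- generate_static(monolayer_config(n_cells = 30, box_um = 120,
                                         mode = "static", n_frames = 8,
                                         seed = 2))
  tc <- vrms_timecourse(st$trajectories, 2)
  expect_true(all(tc$vrms == 0))

  cfg <- monolayer_config(n_cells = 100, box_um = 250, mode = "fluid",
                          v0 = 10, fluid_t1_gain = 0, n_frames = 40,
                          dt = 0.5, seed = 9)
  sim <- generate_fluid(cfg)
  tc2 <- vrms_timecourse(sim$trajectories, 4)
  expect_lt(max(abs(tc2$vrms - 10)) / 10, 0.05)
})

test_that("PIV recovers known displacements and flags bad windows", {
  ph <- render_phantom_pair(192, dx_px = 3.0, dy_px = -2.0,
                            texture_seed = 5)
  f0 <- piv(ph$frame_a, ph$frame_a, 32, 0.5)
  expect_lt(max(abs(attr(f0, "dx_px")[attr(f0, "valid_px")]),
                abs(attr(f0, "dy_px")[attr(f0, "valid_px")])), 1e-9)

  fl <- piv(ph$frame_a, ph$frame_b, 32, 0.5, dt_h = 0.5, um_per_px = 2)
  ok <- attr(fl, "valid_px")
  hit <- abs(attr(fl, "dx_px")[ok] - 3) < 0.2 &
         abs(attr(fl, "dy_px")[ok] + 2) < 0.2
  expect_gte(mean(hit), 0.95)
  # physical conversion: y-up, um/h
  expect_equal(mean(fl$vx[fl$valid]), 3 * 2 / 0.5, tolerance = 0.1)
  expect_equal(mean(fl$vy[fl$valid]), 2 * 2 / 0.5, tolerance = 0.1)

  expect_error(piv(ph$frame_a, ph$frame_b[1:64, 1:64]),
               class = "epijam_shape_mismatch")
  expect_error(piv(ph$frame_a[1:20, 1:20], ph$frame_b[1:20, 1:20],
                   window_px = 32),
               class = "epijam_invalid_config")

  invalid_frac <- vapply(1:10, function(s) {
    set.seed(s)
    a <- matrix(rnorm(128^2), 128, 128)
    b <- matrix(rnorm(128^2), 128, 128)
    mean(!attr(piv(a, b, 32, 0.5), "valid_px"))
  }, numeric(1))
  expect_gte(mean(invalid_frac), 0.9)
})

test_that("velocity correlation is normalized, degenerate-safe and rotation invariant", {
  u <- velocity_field(matrix(3, 20, 20), matrix(4, 20, 20), spacing_um = 10)
  expect_identical(velocity_correlation(u)$status, "insufficient_data")

  xi_noise <- vapply(1:10, function(s) {
    set.seed(s)
    f <- velocity_field(matrix(rnorm(900), 30, 30),
                        matrix(rnorm(900), 30, 30), spacing_um = 10)
    cp <- velocity_correlation(f, n_bins = 20)
    expect_true(cp$below_resolution)
    cp$xi_v_um
  }, numeric(1))
  expect_true(all(xi_noise <= 1.5 * 10))

  f <- synth_correlated_field(24, 10, 40, 5, seed = 3)
  cp <- velocity_correlation(f, n_bins = 16)
  expect_equal(cp$c_r[1], 1, tolerance = 1e-6)
  expect_true(all(abs(cp$c_r) <= 1 + 1e-6, na.rm = TRUE))
  th <- 0.7
  rot <- velocity_field(cos(th) * f$vx - sin(th) * f$vy,
                        sin(th) * f$vx + cos(th) * f$vy, spacing_um = 10)
  cp_r <- velocity_correlation(rot, n_bins = 16)
  expect_equal(cp_r$c_r, cp$c_r, tolerance = 1e-10)
  expect_equal(cp_r$xi_v_um, cp$xi_v_um, tolerance = 1e-8)
})

test_that("binned correlation equals the all-pairs oracle, with invalid nodes", {
  f <- synth_correlated_field(16, 10, 30, 4, seed = 8)
  set.seed(8)
  f$valid[sample(256, 30)] <- FALSE
  cp <- velocity_correlation(f, r_max = 70, n_bins = 12)
  oc <- oracle_velocity_correlation(f, 70, 12)
  expect_lt(max(abs(cp$c_r - oc), na.rm = TRUE), 1e-10)
})

test_that("strain decomposition is exact on affine fields", {
  k <- 0.2
  dil <- analytic_field(9, 10, function(x, y) k * x, function(x, y) k * y)
  sr <- strain_rate(dil)
  expect_lt(max(abs(sr$isotropic - k), na.rm = TRUE), 1e-10)
  expect_lt(max(sr$deviatoric, na.rm = TRUE), 1e-10)

  g <- 0.3
  shear <- analytic_field(9, 10, function(x, y) g * y, function(x, y) 0 * x)
  ss <- strain_rate(shear)
  expect_lt(max(abs(ss$isotropic), na.rm = TRUE), 1e-10)
  expect_lt(max(abs(ss$deviatoric - g / sqrt(2)), na.rm = TRUE), 1e-10)
  ss2 <- strain_rate(shear, convention = "max_shear")
  expect_lt(max(abs(ss2$deviatoric - g / 2), na.rm = TRUE), 1e-10)

  w <- 0.15
  rotf <- analytic_field(9, 10, function(x, y) -w * y, function(x, y) w * x)
  rr <- strain_rate(rotf)
  expect_lt(max(abs(rr$isotropic), na.rm = TRUE), 1e-10)
  expect_lt(max(rr$deviatoric, na.rm = TRUE), 1e-10)

  # isotropic + deviatoric parts reconstruct the symmetric gradient
  mixed <- analytic_field(9, 10,
                          function(x, y) 0.1 * x + 0.3 * y,
                          function(x, y) 0.2 * x - 0.05 * y)
  sm <- strain_rate(mixed)
  resid <- pmax(abs((sm$exx - sm$isotropic)^2 + sm$exy^2 +
                    sm$exy^2 + (sm$eyy - sm$isotropic)^2 -
                    sm$deviatoric^2))
  expect_lt(max(resid, na.rm = TRUE), 1e-10)
})

test_that("nodes with too few valid neighbours are flagged invalid", {
  f <- analytic_field(7, 10, function(x, y) 0.1 * x, function(x, y) 0.1 * y)
  f$valid[1:4, 1:4] <- FALSE
  sr <- strain_rate(f)
  expect_false(sr$valid[2, 2])   # only sparse valid support
  expect_true(sr$valid[6, 6])
  expect_true(is.na(sr$isotropic[2, 2]))
})
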
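test_that("rigid-pack cells within a pack move identically at zero noise", {
  cfg <- monolayer_config(n_cells = 100, box_um = 200, mode = "rigid_pack",
                          L_c = 100, v0 = 10, interface_t1_rate = 0,
                          n_frames = 10, dt = 0.5, noise_sigma = 0, seed = 1)
  sim <- generate_rigid_pack(cfg)
  vel <- trajectory_velocities(sim$trajectories)
  vel$pack <- sim$packs[as.character(vel$cell_id)]
  disp <- aggregate(cbind(vx_um_h, vy_um_h) ~ frame + pack, vel,
                    function(v) diff(range(v)))
  expect_lt(max(disp$vx_um_h, disp$vy_um_h), 1e-9)
  expect_identical(nrow(sim$events), 0L)
})

test_that("rigid-pack ground-truth events bridge two packs and count follows the Poisson rate", {
  cfg <- monolayer_config(n_cells = 64, box_um = 200, mode = "rigid_pack",
                          L_c = 100, v0 = 10, interface_t1_rate = 0.05,
                          n_frames = 50, dt = 0.5, seed = 7)
  sim <- generate_rigid_pack(cfg)
  ev <- sim$events
  expect_gt(nrow(ev), 0)
  packs <- sim$packs
  spans <- apply(ev[, c("loser_a", "loser_b", "gainer_a", "gainer_b")], 1,
                 function(q) length(unique(packs[as.character(q)])) >= 2)
  expect_true(all(spans))
  # eligible transitions: frames k .. n_frames - k (0-based), k = 2
  duration_h <- (cfg$n_frames - 3) * cfg$dt
  lambda <- cfg$interface_t1_rate * length(sim$interface_cells) * duration_h
  band <- qpois(c(0.025, 0.975), lambda)
  expect_gte(nrow(ev), band[1])
  expect_lte(nrow(ev), band[2])
})

test_that("identical configuration and seed give bit-identical simulations", {
  cfg <- monolayer_config(n_cells = 40, box_um = 150, mode = "fluid", v0 = 8,
                          fluid_t1_gain = 0.004, n_frames = 20, dt = 0.5,
                          seed = 3)
  a <- generate_fluid(cfg)
  b <- generate_fluid(cfg)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$events, b$events)
  expect_identical(a$graphs, b$graphs)
})

test_that("fluid regime: static limit, speed accuracy, and rate proportional to v0", {
  cfg0 <- monolayer_config(n_cells = 40, box_um = 150, mode = "fluid",
                           v0 = 0, fluid_t1_gain = 0.003, n_frames = 10,
                           dt = 0.5, seed = 5)
  s0 <- generate_fluid(cfg0)
  expect_identical(nrow(s0$events), 0L)
  p0 <- s0$trajectories[s0$trajectories$frame == 0, c("x_um", "y_um")]
  p9 <- s0$trajectories[s0$trajectories$frame == 9, c("x_um", "y_um")]
  expect_equal(p0, p9, ignore_attr = TRUE)

  cfg <- monolayer_config(n_cells = 100, box_um = 250, mode = "fluid",
                          v0 = 12, fluid_t1_gain = 0, n_frames = 50,
                          dt = 0.5, seed = 6)
  sim <- generate_fluid(cfg)
  st <- vrms(trajectory_velocities(sim$trajectories))
  expect_lt(abs(st$mean_speed - 12) / 12, 0.05)

  counts <- vapply(c(4, 8, 16), function(v0) {
    cfg <- monolayer_config(n_cells = 64, box_um = 200, mode = "fluid",
                            v0 = v0, fluid_t1_gain = 0.003, n_frames = 50,
                            dt = 0.5, seed = 11)
    nrow(generate_fluid(cfg)$events)
  }, numeric(1))
  # expected proportions 1:2:4; chi-square on the generated totals
  p <- chisq.test(counts, p = c(1, 2, 4) / 7)$p.value
  expect_gt(p, 0.01)
})

test_that("ground-truth event totals are Poisson with the configured rate", {
  lambda <- 0.003 * 10 * 36 * 0.5 * (16 - 3)  # gain*v0*n*dt * transitions
  counts <- vapply(1:100, function(s) {
    cfg <- monolayer_config(n_cells = 36, box_um = 120, mode = "fluid",
                            v0 = 10, fluid_t1_gain = 0.003, n_frames = 16,
                            dt = 0.5, seed = 4000 + s)
    nrow(generate_fluid(cfg)$events)
  }, numeric(1))
  qs <- qpois(c(0.2, 0.4, 0.6, 0.8), lambda)
  obs <- table(cut(counts, c(-Inf, qs, Inf)))
  pr <- diff(c(0, ppois(qs, lambda), 1))
  p <- suppressWarnings(chisq.test(as.vector(obs), p = pr)$p.value)
  expect_gt(p, 0.01)
})

test_that("crowding time course follows its speed schedule", {
  cfg <- monolayer_config(n_cells = 60, box_um = 200, mode = "fluid",
                          n_frames = 100, dt = 1, noise_sigma = 0, seed = 4)
  flat <- generate_crowding_timecourse(
    cfg, data.frame(time_h = 0, v0 = 10))
  tc <- vrms_timecourse(flat, 1)
  expect_lt(max(abs(tc$vrms - 10)) / 10, 1e-9)

  tt <- seq(70, 95, 1)
  sch <- data.frame(time_h = c(0, tt),
                    v0 = c(15, pmax(15 - 0.4 * (tt - 70), 5)))
  tr <- generate_crowding_timecourse(cfg, sch)
  tc2 <- vrms_timecourse(tr, 1)
  v_sched <- attr(tr, "schedule_v0")[seq_len(nrow(tc2))]
  expect_lt(max(abs(tc2$vrms - v_sched) / v_sched), 0.02)

  expect_warning(
    generate_crowding_timecourse(
      cfg, data.frame(time_h = c(0, 50), v0 = c(5, 10))),
    "monotone")
})

test_that("phantom image pairs realize their displacement ground truth", {
  same <- render_phantom_pair(96, dx_px = 0, dy_px = 0, texture_seed = 2)
  expect_identical(same$frame_a, same$frame_b)

  sh <- render_phantom_pair(96, dx_px = 3, dy_px = -2, texture_seed = 2)
  expect_true(all(sh$dx_px == 3) && all(sh$dy_px == -2))
  # integer shifts are exact: frame_b is the periodically rolled frame_a
  rolled <- sh$frame_a[((seq_len(96) - 1 - (-2)) %% 96) + 1,
                       ((seq_len(96) - 1 - 3) %% 96) + 1]
  expect_equal(sh$frame_b, rolled, tolerance = 1e-12)

  expect_error(render_phantom_pair(96, dx_px = 20, window_px = 32),
               class = "epijam_displacement_too_large")
})

test_that("fluorescence phantom ground truth matches its construction", {
  ph <- render_fluorescence_phantom(
    n_cells = 12, box_um = 80, um_per_px = 0.5, junction_level = 200,
    cytoplasm_level = 100, nucleus_level = 300, nucleus_radius_um = 3,
    seed = 3)
  expect_equal(ph$ground_truth$contrast_ratio, 2)
  expect_equal(ph$ground_truth$cyto_nuclear_ratio, 1 / 3)
  expect_true(all(ph$image[ph$masks$junction > 0] == 200))
  expect_true(all(ph$image[ph$masks$nucleus > 0] == 300))

  pp <- render_fluorescence_phantom(
    n_cells = 12, box_um = 100, um_per_px = 0.5, junction_level = 100,
    cytoplasm_level = 100, n_puncta = 50, background_margin_px = 0,
    background_level = 100, seed = 9)
  expect_identical(pp$ground_truth$n_puncta, 50L)
  expect_equal(pp$ground_truth$puncta_density_per_um2, 0.005)
  expect_false(pp$ground_truth$puncta_crowded)
  expect_warning(
    crowded <- render_fluorescence_phantom(
      n_cells = 4, box_um = 20, um_per_px = 0.5, n_puncta = 60,
      background_margin_px = 0, seed = 1),
    "separation")
  expect_true(crowded$ground_truth$puncta_crowded)
})

test_that("sigmoid series are exact on the curve and reproducible", {
  tt <- seq(10, 150, 10)
  s0 <- generate_sigmoid_series(tt, 1, 3, 90, 8, noise_sigma = 0)
  expect_equal(s0$value, sigmoid_4pl(tt, 1, 3, 90, 8), tolerance = 1e-12)
  expect_equal(sigmoid_4pl(90, 1, 3, 90, 8), 2)  # midpoint identity
  a <- generate_sigmoid_series(tt, 1, 3, 90, 8, noise_sigma = 0.1, seed = 42)
  b <- generate_sigmoid_series(tt, 1, 3, 90, 8, noise_sigma = 0.1, seed = 42)
  expect_identical(a$value, b$value)
})
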
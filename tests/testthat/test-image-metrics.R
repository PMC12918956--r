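test_that("compartments partition each cell", {
  ph <- render_fluorescence_phantom(n_cells = 12, box_um = 80,
                                    um_per_px = 0.5, nucleus_level = 300,
                                    nucleus_radius_um = 3, seed = 3)
  m <- ph$masks
  expect_true(all((m$junction > 0) + (m$cytoplasm > 0) + (m$nucleus > 0) <= 1))
  inside <- m$labels > 0
  covered <- (m$junction > 0) | (m$cytoplasm > 0) | (m$nucleus > 0)
  expect_identical(covered, inside)
})

test_that("intensity ratios reproduce phantom ground truth", {
  ph <- render_fluorescence_phantom(n_cells = 12, box_um = 80,
                                    um_per_px = 0.5, junction_level = 200,
                                    cytoplasm_level = 100,
                                    nucleus_level = 300,
                                    nucleus_radius_um = 3, seed = 3)
  expect_equal(junction_contrast(ph$image, ph$masks)$ratio, 2,
               tolerance = 1e-9)
  cn <- cyto_nuclear_ratio(ph$image, ph$masks)
  expect_equal(cn$ratio, 100 / 300, tolerance = 1e-9)
  inv <- cyto_nuclear_ratio(ph$image, ph$masks, inverse = TRUE)
  expect_equal(inv$ratio, 3, tolerance = 1e-9)

  # nucleus 300 / cytoplasm 150 phantom: printed orientation gives 0.5
  ph2 <- render_fluorescence_phantom(n_cells = 12, box_um = 80,
                                     um_per_px = 0.5, junction_level = 150,
                                     cytoplasm_level = 150,
                                     nucleus_level = 300,
                                     nucleus_radius_um = 3, seed = 4)
  expect_equal(cyto_nuclear_ratio(ph2$image, ph2$masks)$ratio, 0.5,
               tolerance = 1e-9)

  uni <- matrix(100, 60, 60)
  masks <- compartment_masks(ph$labels[1:60, 1:60], um_per_px = 0.5,
                             junction_width_px = 2)
  expect_equal(junction_contrast(uni, masks)$ratio, 1, tolerance = 1e-9)
})

test_that("ratios are stable under noise and image rescaling", {
  errs <- vapply(1:15, function(s) {
    p <- render_fluorescence_phantom(n_cells = 12, box_um = 80,
                                     um_per_px = 0.5, junction_level = 200,
                                     cytoplasm_level = 100, noise_sd = 5,
                                     seed = s)
    bg <- p$labels == 0
    abs(junction_contrast(p$image, p$masks, background_mask = bg)$ratio - 2) / 2
  }, numeric(1))
  expect_lt(max(errs), 0.03)

  p <- render_fluorescence_phantom(n_cells = 12, box_um = 80,
                                   um_per_px = 0.5, seed = 5)
  bg <- p$labels == 0
  r1 <- junction_contrast(p$image, p$masks, background_mask = bg)$ratio
  r2 <- junction_contrast(3.7 * p$image, p$masks, background_mask = bg)$ratio
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("puncta counting matches construction and a component-count oracle", {
  p <- render_fluorescence_phantom(n_cells = 16, box_um = 100,
                                   um_per_px = 0.5, junction_level = 100,
                                   cytoplasm_level = 100, n_puncta = 50,
                                   puncta_amplitude = 150,
                                   puncta_sigma_px = 2,
                                   background_margin_px = 0,
                                   background_level = 100, seed = 9)
  pd <- puncta_density(p$image, spot_scale_px = 4, um_per_px = 0.5)
  expect_identical(pd$count, 50L)
  expect_equal(pd$density_per_um2, 0.005)
  # oracle: threshold the noiseless excess intensity above the overlap level
  # of two spots at the generator's minimum separation, count components
  expect_identical(oracle_count_components(p$image > 100 + 100), 50L)

  blank <- puncta_density(matrix(0, 100, 100), spot_scale_px = 4)
  expect_identical(blank$count, 0L)

  # recall/precision across noise, above the documented SNR of 4
  prs <- vapply(1:8, function(s) {
    pn <- render_fluorescence_phantom(n_cells = 16, box_um = 100,
                                      um_per_px = 0.5,
                                      junction_level = 100,
                                      cytoplasm_level = 100, n_puncta = 50,
                                      puncta_amplitude = 80,
                                      puncta_sigma_px = 2, noise_sd = 15,
                                      background_margin_px = 0,
                                      background_level = 100, seed = s)
    r <- puncta_density(pn$image, spot_scale_px = 4, um_per_px = 0.5)
    gt <- pn$ground_truth$puncta
    d2 <- outer(gt$x_um, r$centroids_um$x_um, "-")^2 +
          outer(gt$y_um, r$centroids_um$y_um, "-")^2
    c(mean(apply(d2, 1, min) <= 4), mean(apply(d2, 2, min) <= 4))
  }, numeric(2))
  expect_gte(mean(prs[1, ]), 0.9)  # recall
  expect_gte(mean(prs[2, ]), 0.9)  # precision
})

test_that("fold change to control is exact on constructed groups with calibrated CI", {
  expect_equal(normalize_to_control(rep(5, 10), rep(5, 10),
                                    n_boot = 100, seed = 1)$fold_change, 1)
  expect_equal(normalize_to_control(1.6 * (1:20), 1:20,
                                    n_boot = 100, seed = 1)$fold_change, 1.6)
  expect_error(normalize_to_control(1:5, numeric(0)),
               class = "epijam_empty_input")
  expect_error(normalize_to_control(1:5, rep(0, 5)),
               class = "epijam_degenerate_series")

  cover <- vapply(1:60, function(s) {
    set.seed(s)
    ctrl <- rnorm(30, 100, 20)
    trt <- rnorm(30, 160, 32)
    fc <- normalize_to_control(trt, ctrl, n_boot = 400, seed = s)
    fc$ci[1] <= 1.6 && fc$ci[2] >= 1.6
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})
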
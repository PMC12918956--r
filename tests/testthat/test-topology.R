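test_that("point contacts are not adjacency; honeycomb centre has degree 6", {
  m <- rbind(cbind(matrix(1L, 5, 5), matrix(2L, 5, 5)),
             cbind(matrix(3L, 5, 5), matrix(4L, 5, 5)))
  g <- build_neighbor_graph(m, um_per_px = 1)
  keys <- epijam:::graph_edge_keys(g)
  expect_setequal(keys, c("1|2", "1|3", "2|4", "3|4"))  # no diagonals

  ang <- 2 * pi * (0:5) / 6
  tess <- voronoi_tessellation(c(100, 100 + 20 * cos(ang)),
                               c(100, 100 + 20 * sin(ang)),
                               1:7, 200, periodic = FALSE)
  g7 <- build_neighbor_graph(tess)
  expect_identical(unname(graph_degree(g7)["1"]), 6L)
  expect_error(build_neighbor_graph(matrix(0L, 4, 4)),
               class = "epijam_empty_input")
})

test_that("polygon-route adjacency equals the pixel-adjacency oracle", {
  set.seed(11)
  n <- 50; box <- 200
  x <- runif(n, 0, box); y <- runif(n, 0, box)
  tess <- voronoi_tessellation(x, y, 1:n, box, periodic = FALSE)
  g <- build_neighbor_graph(tess)
  mask <- rasterize_labels(x, y, 1:n, box, n_px = 400, periodic = FALSE)
  oracle <- oracle_mask_adjacency(mask, um_per_px = box / 400,
                                  eps_edge = g$eps_edge)
  expect_setequal(epijam:::graph_edge_keys(g), oracle)
})

test_that("shape metrics reproduce analytic polygons and both conventions", {
  sq <- shape_metrics(list(`1` = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))))
  expect_equal(sq$shape_index, 4)
  expect_equal(sq$aspect_ratio, 1, tolerance = 1e-12)

  hexa <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
  q_hex <- shape_metrics(list(`1` = hexa))$shape_index
  expect_equal(q_hex, 6 / sqrt(3 * sqrt(3) / 2), tolerance = 1e-12)

  rect <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
  sr <- shape_metrics(list(`1` = rect))
  expect_equal(sr$aspect_ratio, 2, tolerance = 1e-10)
  expect_equal(sr$shape_index, 6 / sqrt(2), tolerance = 1e-12)
  sr2 <- shape_metrics(list(`1` = rect), convention = "p_over_a")
  expect_equal(sr2$shape_index, 3)  # perimeter 6 / area 2

  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(shape_metrics(list(`1` = bowtie)),
               class = "epijam_invalid_polygon")
})

test_that("every tessellated cell respects the circle bound on q", {
  set.seed(21)
  tess <- voronoi_tessellation(runif(60, 0, 200), runif(60, 0, 200),
                               1:60, 200, periodic = TRUE)
  sm <- shape_metrics(tess)
  expect_true(all(sm$shape_index >= 2 * sqrt(pi) - 1e-9))
})

test_that("mask-route q of rasterized disks approaches the circle bound monotonely", {
  qs <- vapply(c(10, 20, 40, 80), function(r) {
    n <- 2 * r + 11; cx <- (n + 1) / 2
    g <- expand.grid(seq_len(n), seq_len(n))
    m <- matrix(as.integer((g[, 1] - cx)^2 + (g[, 2] - cx)^2 <= r^2), n, n)
    shape_metrics(m, um_per_px = 1)$shape_index
  }, numeric(1))
  expect_true(all(diff(abs(qs - 2 * sqrt(pi))) < 0))  # error shrinks
  expect_lt(abs(qs[4] - 2 * sqrt(pi)), 0.02)
  # rasterization tolerance on the circle bound, documented for small discs
  expect_true(all(qs >= 2 * sqrt(pi) - 0.25))
})

test_that("a scripted quad flip yields exactly one event with the right quartet", {
  graphs <- quad_flip_sequence(n_frames = 8, flip_at = 4)
  ev <- detect_t1(graphs, k = 2)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$frame, 4L)
  expect_identical(c(ev$loser_a, ev$loser_b), c(1L, 2L))
  expect_identical(c(ev$gainer_a, ev$gainer_b), c(3L, 4L))

  static <- quad_flip_sequence(n_frames = 10, flip_at = 99)
  expect_identical(nrow(detect_t1(static, k = 2)), 0L)
})

test_that("detection recovers the generator's ground truth", {
  cfg <- monolayer_config(n_cells = 64, box_um = 200, mode = "rigid_pack",
                          L_c = 100, v0 = 10, interface_t1_rate = 0.05,
                          n_frames = 50, dt = 0.5, seed = 7)
  sim <- generate_rigid_pack(cfg)
  ev <- detect_t1(sim$graphs, k = 2)
  key <- function(e) paste(e$frame, e$loser_a, e$loser_b, e$gainer_a,
                           e$gainer_b)
  precision <- mean(key(ev) %in% key(sim$events))
  recall <- mean(key(sim$events) %in% key(ev))
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("detection is invariant under relabeling and time reversal", {
  graphs <- random_graph_sequence(20, 16, swap_prob = 0.7, seed = 31)
  ev <- detect_t1(graphs, k = 2)
  # relabel ids by a fixed permutation
  set.seed(1)
  perm <- sample(100L)  # id -> perm[id]
  relab <- lapply(graphs, function(g) {
    epijam:::new_neighbor_graph(
      perm[g$cells],
      data.frame(a = pmin(perm[g$edges$a], perm[g$edges$b]),
                 b = pmax(perm[g$edges$a], perm[g$edges$b]),
                 shared_um = g$edges$shared_um),
      integer(0), g$frame, g$time_h, g$eps_edge)
  })
  ev_r <- detect_t1(relab, k = 2)
  key <- function(e, f = identity) {
    sorted_pair <- function(a, b) paste(pmin(a, b), pmax(a, b))
    sort(paste(e$frame, sorted_pair(f(e$loser_a), f(e$loser_b)),
               sorted_pair(f(e$gainer_a), f(e$gainer_b))))
  }
  expect_identical(key(ev, function(i) perm[i]), key(ev_r))

  # time reversal: losers and gainers swap, frames mirror
  n <- length(graphs)
  rev_graphs <- lapply(seq_len(n), function(i) {
    g <- graphs[[n + 1 - i]]
    epijam:::new_neighbor_graph(g$cells, g$edges, integer(0), i - 1L,
                                (i - 1L) * 0.5, g$eps_edge)
  })
  ev_t <- detect_t1(rev_graphs, k = 2)
  fwd <- sort(paste(n - 1 - ev$frame + 1,
                    paste(ev$gainer_a, ev$gainer_b),
                    paste(ev$loser_a, ev$loser_b)))
  bwd <- sort(paste(ev_t$frame, paste(ev_t$loser_a, ev_t$loser_b),
                    paste(ev_t$gainer_a, ev_t$gainer_b)))
  expect_identical(fwd, bwd)
})

test_that("detection equals the brute-force oracle on random sequences", {
  for (s in 1:12) {
    graphs <- random_graph_sequence(sample(10:25, 1), sample(8:20, 1),
                                    swap_prob = 0.8, seed = 300 + s)
    ev <- detect_t1(graphs, k = 2)
    orc <- oracle_detect_t1(graphs, k = 2)
    key <- function(e) sort(paste(e$frame, e$loser_a, e$loser_b,
                                  e$gainer_a, e$gainer_b))
    expect_identical(key(ev), key(orc))
  }
})

test_that("T1 rates are events per interior cell per hour", {
  graphs <- lapply(0:5, function(f) {
    epijam:::new_neighbor_graph(
      1:100, data.frame(a = 1L, b = 2L, shared_um = 5),
      boundary = 91:100, f, f * 1.0, 1)
  })
  ev <- structure(
    data.frame(frame = c(1L, 2L, 3L), time_h = c(1, 2, 2.5),
               loser_a = 1L, loser_b = 2L, gainer_a = 3L, gainer_b = 4L,
               x_um = 0, y_um = 0),
    class = c("t1_events", "data.frame"))
  r <- t1_rate(ev, graphs, bin_width_h = 3)
  expect_equal(r$rate_per_cell_h[1], 3 / (90 * 3))
  r_all <- t1_rate(ev, graphs, bin_width_h = 3, include_boundary = TRUE)
  expect_equal(r_all$rate_per_cell_h[1], 3 / (100 * 3))
  expect_identical(r$n_events, r_all$n_events)  # denominator-only change
  r0 <- t1_rate(ev[0, ], graphs, bin_width_h = 3)
  expect_true(all(r0$rate_per_cell_h == 0))
})

test_that("12 events over 100 cells in a 3 h bin give 0.04 events per cell per hour", {
  graphs <- lapply(0:2, function(f) {
    epijam:::new_neighbor_graph(1:100,
                                data.frame(a = 1L, b = 2L, shared_um = 5),
                                integer(0), f, f * 1.0, 1)
  })
  ev <- structure(
    data.frame(frame = 1L, time_h = rep(1, 12), loser_a = 1L, loser_b = 2L,
               gainer_a = 3L, gainer_b = 4L, x_um = 0, y_um = 0),
    class = c("t1_events", "data.frame"))
  r <- t1_rate(ev, graphs, bin_width_h = 3)
  expect_equal(r$rate_per_cell_h, 0.04)
})

test_that("T1 participants move like their neighbours unless scripted faster", {
  cfg <- monolayer_config(n_cells = 80, box_um = 220, mode = "fluid",
                          v0 = 10, fluid_t1_gain = 0.004, n_frames = 40,
                          dt = 0.5, seed = 12)
  sim <- generate_fluid(cfg)
  sc <- t1_speed_comparison(sim$events, sim$trajectories, sim$graphs)
  expect_lt(abs(sc$median_t1 - sc$median_neighbor) / sc$median_neighbor, 0.1)
  expect_gt(sc$p_value, 0.05)

  cfg2 <- monolayer_config(n_cells = 80, box_um = 220, mode = "fluid",
                           v0 = 10, fluid_t1_gain = 0.01, n_frames = 60,
                           dt = 0.5, seed = 12, t1_speed_factor = 2)
  sim2 <- generate_fluid(cfg2)
  expect_gte(nrow(sim2$events), 50)
  sc2 <- t1_speed_comparison(sim2$events, sim2$trajectories, sim2$graphs)
  expect_lt(sc2$p_value, 0.01)
  expect_gt(sc2$median_t1 / sc2$median_neighbor, 1.5)
})
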
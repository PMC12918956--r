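#' Monolayer generator configuration
#'
#' Parameters of the synthetic monolayer dynamics generators. Units are
#' micrometres and hours throughout. The two dynamic regimes mirror the two
#' hypotheses the topology analyses discriminate between: `rigid_pack` moves
#' cells in coherent clusters of diameter about `L_c` and confines scripted T1
#' neighbor exchanges to cluster interfaces at `interface_t1_rate` events per
#' interface cell per hour; `fluid` moves cells individually by a persistent
#' random walk and distributes T1 events uniformly over internal junctions at
#' rate `fluid_t1_gain * v0` events per cell per hour, so the ground-truth T1
#' rate grows linearly with speed.
#'
#' @param n_cells Number of cells (>= 4).
#' @param box_um Side of the square field of view.
#' @param mode One of `"rigid_pack"`, `"fluid"`, `"static"`.
#' @param L_c Pack diameter (micrometres), rigid-pack mode only.
#' @param v0 Cell (or pack) speed, micrometres per hour.
#' @param interface_t1_rate Scripted events per interface cell per hour
#'   (rigid-pack mode).
#' @param fluid_t1_gain Dimensionless slope linking the per-cell T1 rate to
#'   `v0` (fluid mode).
#' @param n_frames Number of frames.
#' @param dt Frame interval, hours.
#' @param noise_sigma Positional jitter SD (micrometres), applied per frame.
#' @param seed Integer seed; identical configurations with identical seeds
#'   give bit-identical output.
#' @param periodic Torus boundary (default) or bounded box with flagged
#'   boundary cells.
#' @param persistence_h Heading persistence time of the fluid random walk.
#' @param align Dimensionless neighbour-alignment strength (0 = off) in the
#'   fluid regime; larger values lengthen the velocity correlation length.
#' @param t1_speed_factor Factor applied to the displacement of the four
#'   participating cells over the two frames around each scripted event
#'   (1 = participants move like everyone else; 2 = twice the ambient
#'   speed). Supports testing whether rearranging cells move faster.
#' @return A validated list of class `monolayer_config`.
#' @export
monolayer_config <- function(n_cells = 400L, box_um = 500,
                             mode = c("fluid", "rigid_pack", "static"),
                             L_c = NULL, v0 = 10,
                             interface_t1_rate = NULL, fluid_t1_gain = NULL,
                             n_frames = 50L, dt = 0.5, noise_sigma = 0,
                             seed = 1L, periodic = TRUE,
                             persistence_h = 4, align = 0,
                             t1_speed_factor = 1) {
  mode <- match.arg(mode)
  if (n_cells < 4L) {
    stop_epijam("n_cells must be >= 4", class = "epijam_invalid_config")
  }
  if (dt <= 0) stop_epijam("dt must be > 0", class = "epijam_invalid_config")
  if (v0 < 0) stop_epijam("v0 must be >= 0", class = "epijam_invalid_config")
  if (noise_sigma < 0) {
    stop_epijam("noise_sigma must be >= 0", class = "epijam_invalid_config")
  }
  if (mode == "rigid_pack") {
    if (is.null(L_c) || is.null(interface_t1_rate)) {
      stop_epijam("rigid_pack mode needs L_c and interface_t1_rate",
                  class = "epijam_invalid_config")
    }
    if (L_c > box_um) {
      stop_epijam("pack size L_c exceeds box_um",
                  class = "epijam_invalid_config")
    }
    if (interface_t1_rate < 0) {
      stop_epijam("interface_t1_rate must be >= 0",
                  class = "epijam_invalid_config")
    }
  }
  if (mode == "fluid") {
    if (is.null(fluid_t1_gain)) fluid_t1_gain <- 0
    if (fluid_t1_gain < 0) {
      stop_epijam("fluid_t1_gain must be >= 0",
                  class = "epijam_invalid_config")
    }
  }
  structure(
    list(n_cells = as.integer(n_cells), box_um = box_um, mode = mode,
         L_c = L_c, v0 = v0, interface_t1_rate = interface_t1_rate,
         fluid_t1_gain = fluid_t1_gain, n_frames = as.integer(n_frames),
         dt = dt, noise_sigma = noise_sigma, seed = as.integer(seed),
         periodic = periodic, persistence_h = persistence_h, align = align,
         t1_speed_factor = t1_speed_factor),
    class = "monolayer_config"
  )
}

# Jittered square lattice of n points in [0, box)^2; deterministic under the
# caller's RNG state. Jitter is 30% of the lattice spacing, which keeps the
# Voronoi tessellation non-degenerate while breaking lattice symmetry.
seed_positions <- function(n, box) {
  n_side <- ceiling(sqrt(n))
  s <- box / n_side
  gx <- (rep(seq_len(n_side), n_side) - 0.5) * s
  gy <- (rep(seq_len(n_side), each = n_side) - 0.5) * s
  keep <- sample.int(n_side^2, n)
  x <- gx[keep] + stats::rnorm(n, 0, 0.3 * s / 2)
  y <- gy[keep] + stats::rnorm(n, 0, 0.3 * s / 2)
  cbind(x = wrap_coord(x, box), y = wrap_coord(y, box))
}

# --- scripted T1 engine -----------------------------------------------------

# Mutable adjacency state used while evolving a graph through scripted swaps.
# Scripted events must stay individually detectable: losing edges must have
# been stable for k frames (the `birth` guard), a lost pair may not be
# re-gained for k frames (`forbidden`, keyed by pair with an expiry frame),
# and quartets within one transition must be disjoint (`used_cells`, managed
# by the caller).
t1_state_init <- function(graph) {
  keys <- graph_edge_keys(graph)
  birth <- rep(0L, length(keys))
  names(birth) <- keys
  len <- graph$edges$shared_um
  names(len) <- keys
  adj <- graph_adjacency(graph)
  list(birth = birth, len = len, adj = adj,
       forbidden = integer(0),
       nominal_len = if (length(len)) 0.5 * stats::median(len) else 1)
}

state_graph <- function(st, cells, boundary, frame, time_h, eps_edge) {
  keys <- names(st$birth)
  ab <- edge_key_split(keys)
  edges <- data.frame(a = ab[, "a"], b = ab[, "b"],
                      shared_um = as.numeric(st$len[keys]))
  new_neighbor_graph(cells, edges, boundary, frame, time_h, eps_edge)
}

# Candidate losing edges: stable for >= k frames, disjoint from this
# transition's earlier quartets, and passing `edge_ok`.
state_candidates <- function(st, f, k, edge_ok, used_cells) {
  keys <- names(st$birth)
  if (!length(keys)) return(character(0))
  ab <- edge_key_split(keys)
  stable <- st$birth <= f - k
  free <- !(ab[, "a"] %in% used_cells) & !(ab[, "b"] %in% used_cells)
  ok <- stable & free & edge_ok(ab[, "a"], ab[, "b"])
  keys[ok]
}

# Eligible gaining pairs for losing edge (a, b): unordered pairs of distinct
# common neighbours of a and b that are not already adjacent, not recently
# lost (forbidden), and disjoint from this transition's earlier quartets.
gaining_pairs <- function(st, a, b, f, used_cells) {
  com <- intersect(st$adj[[as.character(a)]], st$adj[[as.character(b)]])
  com <- setdiff(com, used_cells)
  if (length(com) < 2L) return(NULL)
  prs <- utils::combn(sort(com), 2L)
  keys <- edge_key(prs[1L, ], prs[2L, ])
  banned <- keys %in% names(st$forbidden)[st$forbidden >= f]
  keep <- !(keys %in% names(st$birth)) & !banned
  if (!any(keep)) return(NULL)
  prs[, keep, drop = FALSE]
}

state_apply_swap <- function(st, a, b, cc, dd, f, k) {
  key_lose <- edge_key(a, b)
  key_gain <- edge_key(cc, dd)
  st$birth <- st$birth[names(st$birth) != key_lose]
  st$len <- st$len[names(st$len) != key_lose]
  st$birth[key_gain] <- f
  st$len[key_gain] <- st$nominal_len
  st$adj[[as.character(a)]] <- setdiff(st$adj[[as.character(a)]], b)
  st$adj[[as.character(b)]] <- setdiff(st$adj[[as.character(b)]], a)
  st$adj[[as.character(cc)]] <- sort(c(st$adj[[as.character(cc)]], dd))
  st$adj[[as.character(dd)]] <- sort(c(st$adj[[as.character(dd)]], cc))
  st$forbidden <- st$forbidden[st$forbidden >= f]
  st$forbidden[key_lose] <- f + k - 1L
  st
}

empty_t1_events <- function() {
  data.frame(frame = integer(0), time_h = numeric(0),
             loser_a = integer(0), loser_b = integer(0),
             gainer_a = integer(0), gainer_b = integer(0),
             x_um = numeric(0), y_um = numeric(0))
}

# --- generators -------------------------------------------------------------

#' Generate synthetic monolayer dynamics
#'
#' Runs the generator selected by `config$mode` and returns trajectories,
#' per-frame neighbor graphs and the ground-truth list of scripted T1 events.
#' The initial adjacency is the Voronoi tessellation of the initial centroids;
#' thereafter the graph evolves only through the scripted neighbor exchanges,
#' so the returned event list is the exact topological ground truth for the
#' sequence. Scripted swaps are instantaneous at a frame boundary and the four
#' participating cells are frozen for `k = 2` frames, matching the detector's
#' default persistence window.
#'
#' @param config A `monolayer_config`.
#' @return A `monolayer_sim`: `trajectories` (a [trajectory_set()]), `graphs`
#'   (list of `neighbor_graph`, one per frame), `events` (ground-truth T1
#'   table), `tessellation` (frame 0), `packs` (named pack id per cell,
#'   rigid-pack mode), `interface_cells` (ids on pack interfaces at frame 0),
#'   and the `config`.
#' @export
generate_monolayer <- function(config) {
  stopifnot(inherits(config, "monolayer_config"))
  switch(config$mode,
         rigid_pack = generate_rigid_pack(config),
         fluid = generate_fluid(config),
         static = generate_static(config))
}

run_scripted_monolayer <- function(config, base_positions_fn, lambda_fn,
                                   edge_ok_fn, k = 2L) {
  cfg <- config
  n <- cfg$n_cells
  ids <- seq_len(n)
  with_seed(cfg$seed, {
    pos0 <- seed_positions(n, cfg$box_um)
    setup <- base_positions_fn(pos0)  # list(pos_array [n, 2, n_frames], meta)
    pos <- setup$pos
    tess <- voronoi_tessellation(pos0[, 1L], pos0[, 2L], ids, cfg$box_um,
                                 periodic = cfg$periodic)
    g0 <- build_neighbor_graph(tess, frame = 0L, time_h = 0)
    st <- t1_state_init(g0)
    edge_ok <- edge_ok_fn(setup$meta, g0)
    times <- (seq_len(cfg$n_frames) - 1L) * cfg$dt
    graphs <- vector("list", cfg$n_frames)
    graphs[[1L]] <- g0
    events <- list()
    if (cfg$noise_sigma > 0) {
      jit <- array(stats::rnorm(n * 2L * cfg$n_frames, 0, cfg$noise_sigma),
                   dim = c(n, 2L, cfg$n_frames))
      jit[, , 1L] <- 0  # frame 0 positions are the tessellated ones
      pos <- pos + jit
    }
    backlog <- 0L   # events drawn but not placeable in their frame
    for (f in seq_len(cfg$n_frames - 1L)) {  # transition into frame f (0-based)
      if (f >= k && f <= cfg$n_frames - k) {
        lam <- lambda_fn(st, setup$meta)
        n_ev <- stats::rpois(1L, lam * cfg$dt) + backlog
        backlog <- 0L
        used_cells <- integer(0)
        for (e in seq_len(n_ev)) {
          cand <- state_candidates(st, f, k, edge_ok, used_cells)
          cand <- Filter(function(kk) {
            ab <- edge_key_split(kk)
            !is.null(gaining_pairs(st, ab[1L, "a"], ab[1L, "b"], f,
                                   used_cells))
          }, cand)
          if (!length(cand)) {
            # all disjoint quartets for this transition are consumed; defer
            # the remainder to the next frame (totals stay Poisson)
            backlog <- n_ev - (e - 1L)
            if (backlog > max(10, 4 * lam * cfg$dt)) {
              stop_epijam(
                "scripted T1 rate too high: events overlap within the ",
                "persistence window faster than quartets become available ",
                "(frame ", f, ")",
                class = "epijam_t1_overflow")
            }
            break
          }
          pick <- cand[[sample.int(length(cand), 1L)]]
          ab <- edge_key_split(pick)
          a <- ab[1L, "a"]; b <- ab[1L, "b"]
          prs <- gaining_pairs(st, a, b, f, used_cells)
          j <- sample.int(ncol(prs), 1L)
          cc <- prs[1L, j]; dd <- prs[2L, j]
          st <- state_apply_swap(st, a, b, cc, dd, f, k)
          used_cells <- c(used_cells, a, b, cc, dd)
          quart <- c(a, b, cc, dd)
          # quartet centroid via minimal images around the first cell
          px <- pos[quart, 1L, f + 1L]
          py <- pos[quart, 2L, f + 1L]
          if (cfg$periodic) {
            px <- px[1L] + c(0, wrap_diff(px[-1L] - px[1L], cfg$box_um))
            py <- py[1L] + c(0, wrap_diff(py[-1L] - py[1L], cfg$box_um))
          }
          events[[length(events) + 1L]] <- data.frame(
            frame = f, time_h = times[f + 1L],
            loser_a = min(a, b), loser_b = max(a, b),
            gainer_a = min(cc, dd), gainer_b = max(cc, dd),
            x_um = wrap_coord(mean(px), cfg$box_um),
            y_um = wrap_coord(mean(py), cfg$box_um))
        }
      }
      graphs[[f + 1L]] <- state_graph(st, g0$cells, g0$boundary, f,
                                      times[f + 1L], g0$eps_edge)
    }
    ev <- if (length(events)) do.call(rbind, events) else empty_t1_events()
    fac <- cfg$t1_speed_factor %||% 1
    if (fac != 1 && nrow(ev)) {
      # boost the displacement of each event's quartet over the two frames
      # around completion, propagating the offset to later frames
      for (i in seq_len(nrow(ev))) {
        f <- ev$frame[i]
        for (cell in c(ev$loser_a[i], ev$loser_b[i],
                       ev$gainer_a[i], ev$gainer_b[i])) {
          step1 <- pos[cell, , f + 1L] - pos[cell, , f]
          rng <- (f + 1L):cfg$n_frames
          pos[cell, , rng] <- pos[cell, , rng] + (fac - 1) * step1
          if (f + 2L <= cfg$n_frames) {
            step2 <- pos[cell, , f + 2L] - pos[cell, , f + 1L]
            rng2 <- (f + 2L):cfg$n_frames
            pos[cell, , rng2] <- pos[cell, , rng2] + (fac - 1) * step2
          }
        }
      }
    }
    traj <- data.frame(
      frame = rep(seq_len(cfg$n_frames) - 1L, each = n),
      time_h = rep(times, each = n),
      cell_id = rep(ids, cfg$n_frames),
      x_um = wrap_coord(as.vector(pos[, 1L, ]), cfg$box_um),
      y_um = wrap_coord(as.vector(pos[, 2L, ]), cfg$box_um))
    structure(
      list(trajectories = trajectory_set(traj, cfg$box_um, cfg$periodic),
           graphs = graphs, events = ev, tessellation = tess,
           packs = setup$meta$packs %||% NULL,
           interface_cells = setup$meta$interface_cells %||% integer(0),
           config = cfg, persistence_k = k),
      class = "monolayer_sim")
  })
}

#' @rdname generate_monolayer
#' @export
generate_rigid_pack <- function(config) {
  stopifnot(config$mode == "rigid_pack")
  cfg <- config
  base_fn <- function(pos0) {
    n_tile <- max(1L, round(cfg$box_um / cfg$L_c))
    tile <- cfg$box_um / n_tile
    packs <- as.integer(
      pmin(floor(pos0[, 1L] / tile), n_tile - 1L) +
      n_tile * pmin(floor(pos0[, 2L] / tile), n_tile - 1L)) + 1L
    names(packs) <- as.character(seq_len(cfg$n_cells))
    n_packs <- max(packs)
    ang <- stats::runif(n_packs, 0, 2 * pi)
    vp <- cbind(cos(ang), sin(ang)) * cfg$v0
    pos <- array(0, dim = c(cfg$n_cells, 2L, cfg$n_frames))
    for (f in seq_len(cfg$n_frames)) {
      drift <- vp[packs, , drop = FALSE] * (f - 1L) * cfg$dt
      pos[, , f] <- pos0 + drift
    }
    list(pos = pos, meta = list(packs = packs))
  }
  edge_ok_fn <- function(meta, g0) {
    packs <- meta$packs
    function(a, b) packs[as.character(a)] != packs[as.character(b)]
  }
  lambda_fn <- function(st, meta) {
    packs <- meta$packs
    iface <- vapply(names(st$adj), function(nm) {
      nb <- st$adj[[nm]]
      length(nb) > 0L && any(packs[as.character(nb)] != packs[nm])
    }, logical(1L))
    cfg$interface_t1_rate * sum(iface)
  }
  sim <- run_scripted_monolayer(cfg, base_fn, lambda_fn, edge_ok_fn)
  packs <- sim$packs
  iface0 <- vapply(sim$graphs[[1L]]$cells, function(cid) {
    nb <- c(sim$graphs[[1L]]$edges$b[sim$graphs[[1L]]$edges$a == cid],
            sim$graphs[[1L]]$edges$a[sim$graphs[[1L]]$edges$b == cid])
    length(nb) > 0L && any(packs[as.character(nb)] != packs[as.character(cid)])
  }, logical(1L))
  sim$interface_cells <- sim$graphs[[1L]]$cells[iface0]
  sim
}

#' @rdname generate_monolayer
#' @export
generate_fluid <- function(config) {
  stopifnot(config$mode == "fluid")
  cfg <- config
  base_fn <- function(pos0) {
    n <- cfg$n_cells
    theta <- stats::runif(n, 0, 2 * pi)
    pos <- array(0, dim = c(n, 2L, cfg$n_frames))
    pos[, , 1L] <- pos0
    cur <- pos0
    for (f in seq_len(cfg$n_frames - 1L)) {
      if (cfg$align > 0) {
        # nudge headings toward the local mean heading (crude Vicsek term)
        mx <- mean(cos(theta)); my <- mean(sin(theta))
        theta <- theta + cfg$align * sin(atan2(my, mx) - theta) * cfg$dt
      }
      cur <- cur + cfg$v0 * cfg$dt * cbind(cos(theta), sin(theta))
      pos[, , f + 1L] <- cur
      theta <- theta + sqrt(2 * cfg$dt / cfg$persistence_h) *
        stats::rnorm(n)
    }
    list(pos = pos, meta = list())
  }
  edge_ok_fn <- function(meta, g0) {
    interior <- setdiff(g0$cells, g0$boundary)
    function(a, b) (a %in% interior) & (b %in% interior)
  }
  lambda_fn <- function(st, meta) {
    cfg$fluid_t1_gain * cfg$v0 * cfg$n_cells
  }
  run_scripted_monolayer(cfg, base_fn, lambda_fn, edge_ok_fn)
}

#' @rdname generate_monolayer
#' @export
generate_static <- function(config) {
  cfg <- config
  cfg$v0 <- 0
  base_fn <- function(pos0) {
    pos <- array(0, dim = c(cfg$n_cells, 2L, cfg$n_frames))
    for (f in seq_len(cfg$n_frames)) pos[, , f] <- pos0
    list(pos = pos, meta = list())
  }
  edge_ok_fn <- function(meta, g0) function(a, b) rep(FALSE, length(a))
  lambda_fn <- function(st, meta) 0
  run_scripted_monolayer(cfg, base_fn, lambda_fn, edge_ok_fn)
}

#' @export
print.monolayer_sim <- function(x, ...) {
  cat(sprintf("monolayer_sim (%s): %d cells, %d frames, dt = %g h, %d ground-truth T1 events\n",
              x$config$mode, x$config$n_cells, x$config$n_frames,
              x$config$dt, nrow(x$events)))
  invisible(x)
}

#' Generate a crowding time course with a scheduled speed decline
#'
#' Emulates a monolayer crowding experiment: cells move as in the fluid
#' regime, but the speed follows a stepwise schedule (constant from each
#' schedule row's `time_h` until the next), typically a high plateau followed
#' by a decay to a low plateau. Windowed V_rms of the output then reproduces
#' the schedule, which is what motility-onset detection is tested against.
#'
#' @param config A `monolayer_config` (its `v0` is ignored; `n_frames`, `dt`,
#'   `n_cells`, `box_um`, `noise_sigma`, `seed` are used).
#' @param schedule Data frame with columns `time_h` and `v0`; `v0` should be
#'   non-increasing (a warning, not an error, otherwise).
#' @return A [trajectory_set()] with attribute `schedule_v0` giving the speed
#'   applied at each frame.
#' @export
generate_crowding_timecourse <- function(config, schedule) {
  stopifnot(inherits(config, "monolayer_config"),
            all(c("time_h", "v0") %in% names(schedule)))
  schedule <- schedule[order(schedule$time_h), ]
  if (any(diff(schedule$v0) > 0)) {
    warning("crowding schedule v0 is not monotone non-increasing")
  }
  cfg <- config
  times <- (seq_len(cfg$n_frames) - 1L) * cfg$dt
  # stepwise-constant speed: last schedule row at or before each frame time
  idx <- findInterval(times, schedule$time_h, rightmost.closed = FALSE)
  idx[idx == 0L] <- 1L
  v_of_t <- schedule$v0[idx]
  n <- cfg$n_cells
  with_seed(cfg$seed, {
    pos0 <- seed_positions(n, cfg$box_um)
    theta <- stats::runif(n, 0, 2 * pi)
    pos <- array(0, dim = c(n, 2L, cfg$n_frames))
    pos[, , 1L] <- pos0
    cur <- pos0
    for (f in seq_len(cfg$n_frames - 1L)) {
      cur <- cur + v_of_t[f] * cfg$dt * cbind(cos(theta), sin(theta))
      pos[, , f + 1L] <- cur
      theta <- theta + sqrt(2 * cfg$dt / cfg$persistence_h) * stats::rnorm(n)
    }
    if (cfg$noise_sigma > 0) {
      jit <- array(stats::rnorm(n * 2L * cfg$n_frames, 0, cfg$noise_sigma),
                   dim = c(n, 2L, cfg$n_frames))
      jit[, , 1L] <- 0
      pos <- pos + jit
    }
    traj <- data.frame(
      frame = rep(seq_len(cfg$n_frames) - 1L, each = n),
      time_h = rep(times, each = n),
      cell_id = rep(seq_len(n), cfg$n_frames),
      x_um = wrap_coord(as.vector(pos[, 1L, ]), cfg$box_um),
      y_um = wrap_coord(as.vector(pos[, 2L, ]), cfg$box_um))
    out <- trajectory_set(traj, cfg$box_um, cfg$periodic)
    attr(out, "schedule_v0") <- v_of_t
    out
  })
}
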
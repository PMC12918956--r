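#' Detect T1 neighbor-exchange events in a graph sequence
#'
#' A T1 transition is the collapse of the junction shared by two adjacent
#' cells followed by the formation of a new junction between two previously
#' non-adjacent cells. Operationally, for the transition between consecutive
#' frames `f-1` and `f`: an edge A-B present at `f-1` and absent at `f` is
#' paired with an edge C-D absent at `f-1` and present at `f`, where C and D
#' are both neighbours of both A and B on both sides of the transition (the
#' quartet stays intact while its diagonal flips). The lost adjacency must
#' have been stable for at least `k` frames before the transition and the
#' gained adjacency must persist for at least `k` frames after it; this
#' suppresses segmentation flicker. Each event is reported once, at the
#' completion frame `f`. When several lost and gained edges could pair (a
#' rosette), pairs are matched greedily by the gained edge's shared length,
#' ties broken by the lowest cell-id pair, which makes the output invariant
#' under relabeling.
#'
#' @param graphs List of `neighbor_graph` objects, one per frame, in time
#'   order (0-based frames, strictly increasing times).
#' @param k Persistence window in frames (default 2).
#' @param traj Optional [trajectory_set()] used to attach quartet centroids.
#' @return Data frame of class `t1_events` with columns `frame`, `time_h`,
#'   `loser_a`, `loser_b`, `gainer_a`, `gainer_b`, `x_um`, `y_um`, and
#'   attributes `k` and `skipped_frames` (frames failing the 90% tracking
#'   continuity precondition, excluded from rate denominators).
#' @export
detect_t1 <- function(graphs, k = 2L, traj = NULL) {
  stopifnot(length(graphs) >= 2L, k >= 1L)
  n <- length(graphs)
  cells <- lapply(graphs, `[[`, "cells")
  skipped <- integer(0)
  for (f in 2:n) {
    shared <- length(intersect(cells[[f - 1L]], cells[[f]]))
    if (shared < 0.9 * max(length(cells[[f - 1L]]), length(cells[[f]]))) {
      warning("tracking continuity below 90% at frame ", graphs[[f]]$frame,
              "; frame skipped from rate denominators")
      skipped <- c(skipped, graphs[[f]]$frame)
    }
  }
  keysets <- lapply(graphs, graph_edge_keys)
  all_keys <- sort(unique(unlist(keysets)))
  present <- matrix(FALSE, length(all_keys), n,
                    dimnames = list(all_keys, NULL))
  for (f in seq_len(n)) present[keysets[[f]], f] <- TRUE
  lens <- lapply(seq_len(n), function(f) {
    g <- graphs[[f]]
    structure(g$edges$shared_um, names = graph_edge_keys(g))
  })
  adjs <- lapply(graphs, graph_adjacency)
  events <- list()
  for (f in 2:n) {          # transition into frame index f (1-based list pos)
    if (f - 1L < k || f + k - 1L > n) next  # persistence windows must fit
    lost <- all_keys[present[, f - 1L] & !present[, f]]
    gained <- all_keys[!present[, f - 1L] & present[, f]]
    if (!length(lost) || !length(gained)) next
    # keep only persistence-satisfying candidates
    lost <- lost[vapply(lost, function(kk) {
      all(present[kk, (f - k):(f - 1L)])
    }, logical(1L))]
    gained <- gained[vapply(gained, function(kk) {
      all(present[kk, f:(f + k - 1L)])
    }, logical(1L))]
    if (!length(lost) || !length(gained)) next
    # order gained candidates: longest shared edge first, then lowest ids
    gm <- edge_key_split(gained)
    glen <- as.numeric(lens[[f]][gained])
    ord <- order(-glen, gm[, "a"], gm[, "b"])
    gained <- gained[ord]
    gm <- gm[ord, , drop = FALSE]
    lm <- edge_key_split(lost)
    lord <- order(lm[, "a"], lm[, "b"])
    lost <- lost[lord]
    lm <- lm[lord, , drop = FALSE]
    used_gain <- rep(FALSE, length(gained))
    for (li in seq_along(lost)) {
      a <- lm[li, "a"]; b <- lm[li, "b"]
      nb_prev <- intersect(adjs[[f - 1L]][[as.character(a)]],
                           adjs[[f - 1L]][[as.character(b)]])
      nb_now <- intersect(adjs[[f]][[as.character(a)]],
                          adjs[[f]][[as.character(b)]])
      com <- intersect(nb_prev, nb_now)
      for (gi in seq_along(gained)) {
        if (used_gain[gi]) next
        cc <- gm[gi, "a"]; dd <- gm[gi, "b"]
        if (cc %in% com && dd %in% com &&
            !any(c(cc, dd) %in% c(a, b))) {
          used_gain[gi] <- TRUE
          events[[length(events) + 1L]] <- data.frame(
            frame = graphs[[f]]$frame, time_h = graphs[[f]]$time_h,
            loser_a = a, loser_b = b, gainer_a = cc, gainer_b = dd,
            x_um = NA_real_, y_um = NA_real_)
          break
        }
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_t1_events()
  if (!is.null(traj) && nrow(ev)) {
    box <- attr(traj, "box_um")
    periodic <- attr(traj, "periodic")
    for (i in seq_len(nrow(ev))) {
      quart <- c(ev$loser_a[i], ev$loser_b[i], ev$gainer_a[i], ev$gainer_b[i])
      rows <- traj[traj$frame == ev$frame[i] & traj$cell_id %in% quart, ]
      if (nrow(rows) == 4L) {
        px <- rows$x_um; py <- rows$y_um
        if (periodic) {
          px <- px[1L] + c(0, wrap_diff(px[-1L] - px[1L], box))
          py <- py[1L] + c(0, wrap_diff(py[-1L] - py[1L], box))
        }
        ev$x_um[i] <- wrap_coord(mean(px), box)
        ev$y_um[i] <- wrap_coord(mean(py), box)
      }
    }
  }
  ev <- ev[order(ev$frame, ev$loser_a, ev$loser_b), ]
  rownames(ev) <- NULL
  structure(ev, class = c("t1_events", "data.frame"), k = k,
            skipped_frames = skipped)
}

#' T1 rate per cell per hour, binned in time
#'
#' `R_T1` in a time bin is the number of exchange events completed in the bin
#' divided by the mean interior cell count over the bin's frames and by the
#' bin width: events per cell per hour. Bins are half-open `[t, t + width)`.
#' Boundary-flagged cells are excluded from the denominator by default;
#' including them changes only the denominator, never which events are
#' counted.
#'
#' @param events A `t1_events` table (or any data frame with `time_h`).
#' @param graphs The graph sequence the events came from (provides per-frame
#'   interior cell counts and times).
#' @param bin_width_h Bin width in hours.
#' @param include_boundary Count boundary cells in the denominator.
#' @return Data frame `t_start`, `t_mid`, `n_events`, `mean_cells`,
#'   `rate_per_cell_h`.
#' @export
t1_rate <- function(events, graphs, bin_width_h, include_boundary = FALSE) {
  if (bin_width_h <= 0) {
    stop_epijam("bin width must be > 0", class = "epijam_invalid_config")
  }
  times <- vapply(graphs, `[[`, numeric(1L), "time_h")
  counts <- vapply(graphs, function(g) {
    if (include_boundary) length(g$cells)
    else length(setdiff(g$cells, g$boundary))
  }, numeric(1L))
  skipped <- attr(events, "skipped_frames") %||% integer(0)
  frames <- vapply(graphs, `[[`, integer(1L), "frame")
  keep <- !(frames %in% skipped)
  t0 <- min(times)
  bins <- floor((times - t0) / bin_width_h)
  ev_bins <- floor((events$time_h - t0) / bin_width_h)
  out <- lapply(sort(unique(bins)), function(b) {
    sel <- bins == b & keep
    if (!any(sel)) return(NULL)
    mc <- mean(counts[sel])
    if (mc <= 0) {
      stop_epijam("empty rate denominator in bin ", b,
                  class = "epijam_empty_input")
    }
    ne <- sum(ev_bins == b)
    data.frame(t_start = t0 + b * bin_width_h,
               t_mid = t0 + (b + 0.5) * bin_width_h,
               n_events = ne, mean_cells = mc,
               rate_per_cell_h = ne / (mc * bin_width_h))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare speeds of T1-participating cells with non-rearranging neighbours
#'
#' For each detected event, the instantaneous speeds (central difference over
#' `window` frames each side) of the four participating cells at the
#' completion frame are compared with the speeds, at the same frame, of cells
#' topologically adjacent to the quartet that participate in no event at that
#' frame. The pooled distributions are compared with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param events A `t1_events` table.
#' @param traj The matching [trajectory_set()].
#' @param graphs The matching graph sequence.
#' @param window Frames on each side for the central-difference speed.
#' @return List: `t1_speeds`, `neighbor_speeds` (data frames with `speed`
#'   column), `median_t1`, `median_neighbor`, `p_value`, `n_events_used`,
#'   `n_events_excluded`.
#' @export
t1_speed_comparison <- function(events, traj, graphs, window = 1L) {
  vel <- trajectory_velocities(traj, method = "central", window = window)
  vel$speed <- sqrt(vel$vx_um_h^2 + vel$vy_um_h^2)
  frames <- vapply(graphs, `[[`, integer(1L), "frame")
  t1_rows <- list(); nb_rows <- list()
  n_excl <- 0L
  for (i in seq_len(nrow(events))) {
    f <- events$frame[i]
    quart <- c(events$loser_a[i], events$loser_b[i],
               events$gainer_a[i], events$gainer_b[i])
    gi <- match(f, frames)
    if (is.na(gi)) { n_excl <- n_excl + 1L; next }
    adj <- graph_adjacency(graphs[[gi]])
    nbs <- unique(unlist(adj[as.character(quart)]))
    participants_f <- unique(unlist(
      events[events$frame == f,
             c("loser_a", "loser_b", "gainer_a", "gainer_b")]))
    nbs <- setdiff(nbs, participants_f)
    sv <- vel[vel$frame == f, ]
    sp_q <- sv$speed[sv$cell_id %in% quart]
    sp_n <- sv$speed[sv$cell_id %in% nbs]
    if (!length(sp_n) || !length(sp_q)) { n_excl <- n_excl + 1L; next }
    t1_rows[[length(t1_rows) + 1L]] <-
      data.frame(event = i, frame = f, speed = sp_q)
    nb_rows[[length(nb_rows) + 1L]] <-
      data.frame(event = i, frame = f, speed = sp_n)
  }
  t1_sp <- do.call(rbind, t1_rows) %||%
    data.frame(event = integer(0), frame = integer(0), speed = numeric(0))
  nb_sp <- do.call(rbind, nb_rows) %||%
    data.frame(event = integer(0), frame = integer(0), speed = numeric(0))
  p <- if (!nrow(t1_sp) || !nrow(nb_sp)) {
    NA_real_
  } else if (stats::sd(c(t1_sp$speed, nb_sp$speed)) == 0) {
    1  # all speeds tied: no evidence of a difference
  } else {
    stats::wilcox.test(t1_sp$speed, nb_sp$speed, exact = FALSE)$p.value
  }
  list(t1_speeds = t1_sp, neighbor_speeds = nb_sp,
       median_t1 = stats::median(t1_sp$speed),
       median_neighbor = stats::median(nb_sp$speed),
       p_value = p,
       n_events_used = length(unique(t1_sp$event)),
       n_events_excluded = n_excl)
}
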
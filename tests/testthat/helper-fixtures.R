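# Shared fixture builders used across test files.

# A hand-built graph sequence realizing one canonical quad flip:
# cells 1..4 plus a ring of padding cells; edge 1-2 collapses and 3-4 forms
# at frame `flip_at`, with 3 and 4 neighbours of both 1 and 2 throughout.
quad_flip_sequence <- function(n_frames = 8L, flip_at = 4L, dt = 0.5) {
  base_edges <- rbind(
    c(1, 3), c(1, 4), c(2, 3), c(2, 4),    # quartet frame
    c(3, 5), c(4, 6), c(1, 5), c(2, 6))    # padding
  lapply(seq_len(n_frames) - 1L, function(f) {
    diag_edge <- if (f < flip_at) c(1, 2) else c(3, 4)
    e <- rbind(base_edges, diag_edge)
    epijam:::new_neighbor_graph(
      1:6,
      data.frame(a = pmin(e[, 1], e[, 2]), b = pmax(e[, 1], e[, 2]),
                 shared_um = 5),
      integer(0), f, f * dt, eps_edge = 1)
  })
}

# Random graph sequence for oracle comparisons: evolve a random planar-ish
# graph by random valid quartet swaps (not via the package generator).
random_graph_sequence <- function(n_cells, n_frames, swap_prob, seed) {
  set.seed(seed)
  pts <- cbind(runif(n_cells, 0, 100), runif(n_cells, 0, 100))
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  e0 <- unique(data.frame(a = pmin(dd$delsgs$ind1, dd$delsgs$ind2),
                          b = pmax(dd$delsgs$ind1, dd$delsgs$ind2)))
  e0$shared_um <- round(runif(nrow(e0), 2, 10), 3)
  edges <- e0
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    out[[f]] <- epijam:::new_neighbor_graph(
      seq_len(n_cells), edges, integer(0), f - 1L, (f - 1L) * 0.5,
      eps_edge = 1)
    # random quartet swap with probability swap_prob per frame
    if (runif(1) < swap_prob && nrow(edges) > 4) {
      adj <- lapply(seq_len(n_cells), function(i) {
        sort(c(edges$b[edges$a == i], edges$a[edges$b == i]))
      })
      cand <- sample(nrow(edges))
      for (ei in cand) {
        a <- edges$a[ei]; b <- edges$b[ei]
        com <- intersect(adj[[a]], adj[[b]])
        if (length(com) < 2) next
        prs <- utils::combn(com, 2)
        okp <- apply(prs, 2, function(p) {
          !any(edges$a == min(p) & edges$b == max(p))
        })
        if (!any(okp)) next
        p <- prs[, which(okp)[1]]
        edges <- edges[-ei, ]
        edges <- rbind(edges, data.frame(a = min(p), b = max(p),
                                         shared_um = round(runif(1, 2, 10), 3)))
        break
      }
    }
  }
  out
}

# Velocity field from matrices of functions over a grid.
analytic_field <- function(n, spacing, fx, fy) {
  xs <- outer(rep(1, n), seq_len(n) - 1) * spacing
  ys <- outer(seq_len(n) - 1, rep(1, n)) * spacing
  velocity_field(fx(xs, ys), fy(xs, ys), spacing_um = spacing)
}
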
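# Independent brute-force oracles. These deliberately share no code with the
# package implementations: plain nested loops over adjacency matrices and
# node pairs, at sizes where O(n^2)/O(n^3) is affordable.

# Full adjacency matrix of a neighbor_graph over a fixed id universe.
oracle_adj_matrix <- function(g, ids) {
  m <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      a <- as.character(g$edges$a[r]); b <- as.character(g$edges$b[r])
      m[a, b] <- TRUE
      m[b, a] <- TRUE
    }
  }
  m
}

# Brute-force T1 detection: symmetric difference of consecutive adjacency
# matrices, quartet condition checked on both sides of the transition, the
# same persistence rule, greedy lost/gained pairing ordered by gained shared
# length then lowest ids.
oracle_detect_t1 <- function(graphs, k = 2L) {
  ids <- sort(unique(unlist(lapply(graphs, `[[`, "cells"))))
  n <- length(graphs)
  adj <- lapply(graphs, oracle_adj_matrix, ids = ids)
  len_of <- function(g, a, b) {
    r <- which((g$edges$a == a & g$edges$b == b) |
               (g$edges$a == b & g$edges$b == a))
    if (length(r)) g$edges$shared_um[r[1L]] else NA_real_
  }
  out <- list()
  for (f in 2:n) {
    if (f - 1L < k || f + k - 1L > n) next
    lost <- list(); gained <- list()
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i >= j) next
        was <- adj[[f - 1L]][i, j]; is_now <- adj[[f]][i, j]
        if (was && !is_now) {
          stable <- TRUE
          for (g2 in (f - k):(f - 1L)) stable <- stable && adj[[g2]][i, j]
          if (stable) lost[[length(lost) + 1L]] <- c(ids[i], ids[j])
        }
        if (!was && is_now) {
          persists <- TRUE
          for (g2 in f:(f + k - 1L)) persists <- persists && adj[[g2]][i, j]
          if (persists) gained[[length(gained) + 1L]] <- c(ids[i], ids[j])
        }
      }
    }
    if (!length(lost) || !length(gained)) next
    glen <- vapply(gained, function(p) {
      v <- len_of(graphs[[f]], p[1L], p[2L])
      if (is.na(v)) -Inf else v
    }, numeric(1L))
    g_ord <- order(-glen,
                   vapply(gained, `[`, numeric(1L), 1L),
                   vapply(gained, `[`, numeric(1L), 2L))
    gained <- gained[g_ord]
    l_ord <- order(vapply(lost, `[`, numeric(1L), 1L),
                   vapply(lost, `[`, numeric(1L), 2L))
    lost <- lost[l_ord]
    used <- rep(FALSE, length(gained))
    for (lp in lost) {
      a <- lp[1L]; b <- lp[2L]
      for (gi in seq_along(gained)) {
        if (used[gi]) next
        cc <- gained[[gi]][1L]; dd <- gained[[gi]][2L]
        if (cc %in% c(a, b) || dd %in% c(a, b)) next
        ok <- TRUE
        for (x in c(cc, dd)) {
          for (y in c(a, b)) {
            xi <- which(ids == x); yi <- which(ids == y)
            ok <- ok && adj[[f - 1L]][xi, yi] && adj[[f]][xi, yi]
          }
        }
        if (ok) {
          used[gi] <- TRUE
          out[[length(out) + 1L]] <- data.frame(
            frame = graphs[[f]]$frame, loser_a = a, loser_b = b,
            gainer_a = cc, gainer_b = dd)
          break
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(0), loser_a = integer(0),
               loser_b = integer(0), gainer_a = integer(0),
               gainer_b = integer(0))
}

# Brute-force radially binned velocity autocorrelation (all node pairs).
oracle_velocity_correlation <- function(field, r_max, n_bins) {
  v <- field$valid
  sp <- field$spacing_um
  idx <- which(v, arr.ind = TRUE)
  dvx <- field$vx - mean(field$vx[v])
  dvy <- field$vy - mean(field$vy[v])
  edges <- seq(0, r_max, length.out = n_bins + 1L)
  num <- rep(0, n_bins + 1L)
  cnt <- rep(0, n_bins + 1L)
  for (i in seq_len(nrow(idx))) {
    for (j in seq_len(nrow(idx))) {
      r <- sp * sqrt(sum((idx[i, ] - idx[j, ])^2))
      if (r > r_max) next
      b <- if (r == 0) 1L else {
        findInterval(r, edges, rightmost.closed = TRUE, left.open = TRUE) + 1L
      }
      dot <- dvx[idx[i, 1L], idx[i, 2L]] * dvx[idx[j, 1L], idx[j, 2L]] +
             dvy[idx[i, 1L], idx[i, 2L]] * dvy[idx[j, 1L], idx[j, 2L]]
      num[b] <- num[b] + dot
      cnt[b] <- cnt[b] + 1
    }
  }
  denom <- mean(dvx[v]^2 + dvy[v]^2)
  ifelse(cnt > 0, (num / cnt) / denom, NA_real_)
}

# Pixel-level adjacency oracle on a label mask: loop over all 4-neighbour
# pixel faces, count shared faces per label pair, threshold at eps.
oracle_mask_adjacency <- function(mask, um_per_px, eps_edge) {
  counts <- new.env()
  nr <- nrow(mask); nc <- ncol(mask)
  bump <- function(a, b) {
    if (a > 0L && b > 0L && a != b) {
      key <- paste(min(a, b), max(a, b), sep = "|")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      if (r < nr) bump(mask[r, cl], mask[r + 1L, cl])
      if (cl < nc) bump(mask[r, cl], mask[r, cl + 1L])
    }
  }
  keys <- ls(counts)
  keep <- vapply(keys, function(k) counts[[k]] * um_per_px >= eps_edge,
                 logical(1L))
  sort(keys[keep])
}

# Connected-component count of a binary matrix (8-connectivity), via
# breadth-first flood fill.
oracle_count_components <- function(bin) {
  seen <- matrix(FALSE, nrow(bin), ncol(bin))
  n <- 0L
  for (r in seq_len(nrow(bin))) {
    for (cl in seq_len(ncol(bin))) {
      if (!bin[r, cl] || seen[r, cl]) next
      n <- n + 1L
      queue <- list(c(r, cl))
      seen[r, cl] <- TRUE
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (dr in -1:1) {
          for (dc in -1:1) {
            rr <- p[1L] + dr; cc <- p[2L] + dc
            if (rr >= 1L && rr <= nrow(bin) && cc >= 1L && cc <= ncol(bin) &&
                bin[rr, cc] && !seen[rr, cc]) {
              seen[rr, cc] <- TRUE
              queue[[length(queue) + 1L]] <- c(rr, cc)
            }
          }
        }
      }
    }
  }
  n
}
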
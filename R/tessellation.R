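#' Voronoi tessellation of cell centroids
#'
#' Tessellates a monolayer from its cell centroids, returning per-cell Voronoi
#' polygons and the cell-cell adjacency implied by shared Voronoi edges, with
#' shared-boundary lengths in micrometres. In periodic mode the centroids are
#' replicated on a 3x3 torus tiling before tessellating, so every cell has a
#' complete polygon and there are no window-edge artifacts; in bounded mode
#' tiles are clipped to the box and cells whose tiles touch the box border are
#' flagged as boundary cells.
#'
#' @param x,y Centroid coordinates (micrometres), y-up physical convention.
#' @param id Integer cell ids (positive, unique).
#' @param box_um Side of the square field of view (micrometres).
#' @param periodic Logical; torus topology (default) or bounded box.
#' @return An object of class `tessellation`: centroids, per-cell polygons
#'   (counter-clockwise vertex matrices), an edge table
#'   (`a`, `b`, `shared_um`) and the ids of boundary cells (empty when
#'   periodic).
#' @export
voronoi_tessellation <- function(x, y, id = seq_along(x), box_um,
                                 periodic = TRUE) {
  stopifnot(length(x) == length(y), length(id) == length(x),
            !anyDuplicated(id), all(id > 0), box_um > 0)
  n <- length(x)
  if (n < 4L) {
    stop_epijam("tessellation needs at least 4 cells, got ", n,
                class = "epijam_invalid_config")
  }
  id <- as.integer(id)
  if (periodic) {
    x <- wrap_coord(x, box_um)
    y <- wrap_coord(y, box_um)
    off <- expand.grid(dx = c(-1, 0, 1), dy = c(-1, 0, 1))
    xs <- rep(x, nrow(off)) + rep(off$dx, each = n) * box_um
    ys <- rep(y, nrow(off)) + rep(off$dy, each = n) * box_um
    orig <- rep(id, nrow(off))
    centre <- rep(off$dx == 0 & off$dy == 0, each = n)
    dd <- deldir::deldir(xs, ys,
                         rw = c(-box_um, 2 * box_um, -box_um, 2 * box_um),
                         suppressMsge = TRUE)
    seg <- dd$dirsgs
    keep <- centre[seg$ind1] | centre[seg$ind2]
    seg <- seg[keep, , drop = FALSE]
    len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
    a <- orig[seg$ind1]
    b <- orig[seg$ind2]
    ok <- a != b & len > 0
    key <- edge_key(a[ok], b[ok])
    shared <- tapply(len[ok], key, max)
    ab <- edge_key_split(names(shared))
    edges <- data.frame(a = ab[, "a"], b = ab[, "b"],
                        shared_um = as.numeric(shared), row.names = NULL)
    tl <- deldir::tile.list(dd)
    polys <- vector("list", n)
    names(polys) <- as.character(id)
    centre_idx <- which(centre)
    for (i in centre_idx) {
      polys[[as.character(orig[i])]] <-
        cbind(x = tl[[i]]$x, y = tl[[i]]$y)
    }
    boundary <- integer(0)
  } else {
    dd <- deldir::deldir(x, y, rw = c(0, box_um, 0, box_um),
                         suppressMsge = TRUE)
    seg <- dd$dirsgs
    len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
    a <- id[seg$ind1]
    b <- id[seg$ind2]
    ok <- len > 0
    key <- edge_key(a[ok], b[ok])
    shared <- tapply(len[ok], key, max)
    ab <- edge_key_split(names(shared))
    edges <- data.frame(a = ab[, "a"], b = ab[, "b"],
                        shared_um = as.numeric(shared), row.names = NULL)
    tl <- deldir::tile.list(dd)
    polys <- vector("list", n)
    names(polys) <- as.character(id)
    eps <- 1e-9 * box_um
    on_border <- logical(n)
    for (i in seq_len(n)) {
      polys[[as.character(id[i])]] <- cbind(x = tl[[i]]$x, y = tl[[i]]$y)
      on_border[i] <- any(tl[[i]]$x < eps | tl[[i]]$x > box_um - eps |
                          tl[[i]]$y < eps | tl[[i]]$y > box_um - eps)
    }
    boundary <- id[on_border]
  }
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(id = id, x = x, y = y, box_um = box_um, periodic = periodic,
         polygons = polys, edges = edges, boundary = boundary),
    class = "tessellation"
  )
}

#' @export
print.tessellation <- function(x, ...) {
  cat("Voronoi tessellation:", length(x$id), "cells,",
      nrow(x$edges), "shared edges,",
      if (x$periodic) "periodic" else "bounded",
      sprintf("box %g um\n", x$box_um))
  invisible(x)
}

#' Rasterize centroids to an integer label mask
#'
#' Nearest-centroid (discrete Voronoi) assignment on a pixel grid. Used to
#' produce label-mask fixtures from generated monolayers; respects periodic
#' boundary conditions when asked. Rows of the returned matrix follow the
#' image convention (row 1 = top of the image, y-down); conversion back to
#' physical y-up coordinates is handled by the mask readers.
#'
#' @param x,y Centroid coordinates (micrometres, y-up).
#' @param id Integer labels (positive).
#' @param box_um Field side (micrometres).
#' @param n_px Pixels per side of the output mask.
#' @param periodic Minimal-image distances if `TRUE`.
#' @return Integer matrix `n_px` x `n_px` of cell labels (no background:
#'   tessellations partition the plane), with attribute `um_per_px`.
#' @export
rasterize_labels <- function(x, y, id = seq_along(x), box_um, n_px = 200L,
                             periodic = TRUE) {
  stopifnot(length(x) == length(y), n_px >= 8L)
  id <- as.integer(id)
  s <- box_um / n_px
  px_centers <- (seq_len(n_px) - 0.5) * s
  # image row r corresponds to physical y = box - (r - 0.5) * s (y-down rows)
  ys_phys <- box_um - px_centers
  lab <- matrix(0L, n_px, n_px)
  for (r in seq_len(n_px)) {
    dy <- ys_phys[r] - y
    if (periodic) dy <- wrap_diff(dy, box_um)
    dy2 <- dy^2
    dx <- outer(px_centers, x, "-")
    if (periodic) dx <- wrap_diff(dx, box_um)
    d2 <- sweep(dx^2, 2L, dy2, "+")
    lab[r, ] <- id[max.col(-d2, ties.method = "first")]
  }
  attr(lab, "um_per_px") <- s
  lab
}
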
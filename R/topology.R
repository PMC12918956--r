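#' Build a cell neighbor graph
#'
#' Constructs the undirected cell-cell adjacency graph that underlies all
#' topological analyses. Two cells are adjacent iff their shared boundary is
#' at least `eps_edge` long; shorter contacts (in particular the point contact
#' of four cells meeting at a vertex) are treated as degenerate four-fold
#' vertices and excluded. By default `eps_edge` is 5% of the mean cell
#' diameter (diameter of the circle with the mean cell area).
#'
#' @param x A `tessellation` (polygon route) or an integer label-mask matrix
#'   (pixel route: labels positive, background 0, image row convention).
#' @param ... Passed to methods.
#' @param frame Integer frame index (0-based) stored on the graph.
#' @param time_h Frame time in hours.
#' @param eps_edge Minimum shared boundary length (micrometres); `NULL` for
#'   the 5%-of-mean-diameter default.
#' @return A `neighbor_graph`: cell ids, edge table (`a`, `b`, `shared_um`),
#'   flagged boundary cells, and the `eps_edge` used.
#' @export
build_neighbor_graph <- function(x, ..., frame = 0L, time_h = 0,
                                 eps_edge = NULL) {
  UseMethod("build_neighbor_graph")
}

new_neighbor_graph <- function(cells, edges, boundary, frame, time_h,
                               eps_edge) {
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(frame = as.integer(frame), time_h = as.numeric(time_h),
         cells = sort(as.integer(cells)), edges = edges,
         boundary = sort(as.integer(boundary)), eps_edge = eps_edge),
    class = "neighbor_graph"
  )
}

#' @rdname build_neighbor_graph
#' @export
build_neighbor_graph.tessellation <- function(x, ..., frame = 0L, time_h = 0,
                                              eps_edge = NULL) {
  mean_area <- x$box_um^2 / length(x$id)
  if (is.null(eps_edge)) eps_edge <- 0.05 * 2 * sqrt(mean_area / pi)
  edges <- x$edges[x$edges$shared_um >= eps_edge, , drop = FALSE]
  new_neighbor_graph(x$id, edges, x$boundary, frame, time_h, eps_edge)
}

#' @rdname build_neighbor_graph
#' @param um_per_px Pixel size (micrometres) for label-mask input.
#' @param periodic Treat the mask as a torus (wrap adjacency across borders).
#' @export
build_neighbor_graph.matrix <- function(x, ..., frame = 0L, time_h = 0,
                                        eps_edge = NULL, um_per_px = 1,
                                        periodic = FALSE) {
  if (!length(x) || all(x == 0L)) {
    stop_epijam("empty label mask", class = "epijam_empty_input")
  }
  storage.mode(x) <- "integer"
  labs <- sort(unique(as.vector(x)))
  labs <- labs[labs > 0L]
  mean_area <- mean(tabulate(match(x, labs))) * um_per_px^2
  if (is.null(eps_edge)) eps_edge <- 0.05 * 2 * sqrt(mean_area / pi)
  nr <- nrow(x); nc <- ncol(x)
  # shared boundary = number of 4-neighbour pixel faces between two labels
  pair_faces <- function(a, b) {
    keep <- a != b & a > 0L & b > 0L
    if (!any(keep)) return(character(0))
    edge_key(a[keep], b[keep])
  }
  keys <- c(
    pair_faces(x[-nr, , drop = FALSE], x[-1L, , drop = FALSE]),
    pair_faces(x[, -nc, drop = FALSE], x[, -1L, drop = FALSE]),
    if (periodic) pair_faces(x[nr, ], x[1L, ]),
    if (periodic) pair_faces(x[, nc], x[, 1L])
  )
  tab <- table(keys)
  shared <- as.numeric(tab) * um_per_px
  ab <- edge_key_split(names(tab))
  edges <- data.frame(a = ab[, "a"], b = ab[, "b"], shared_um = shared)
  edges <- edges[edges$shared_um >= eps_edge, , drop = FALSE]
  boundary <- if (periodic) {
    integer(0)
  } else {
    border <- unique(c(x[1L, ], x[nr, ], x[, 1L], x[, nc]))
    border[border > 0L]
  }
  new_neighbor_graph(labs, edges, boundary, frame, time_h, eps_edge)
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: frame %d (t = %g h), %d cells, %d edges, %d boundary cells\n",
              x$frame, x$time_h, length(x$cells), nrow(x$edges),
              length(x$boundary)))
  invisible(x)
}

# Adjacency list (named list of sorted integer neighbour vectors).
graph_adjacency <- function(g) {
  adj <- vector("list", length(g$cells))
  names(adj) <- as.character(g$cells)
  for (nm in names(adj)) adj[[nm]] <- integer(0)
  if (nrow(g$edges)) {
    for (i in seq_len(nrow(g$edges))) {
      a <- as.character(g$edges$a[i]); b <- as.character(g$edges$b[i])
      adj[[a]] <- c(adj[[a]], g$edges$b[i])
      adj[[b]] <- c(adj[[b]], g$edges$a[i])
    }
    adj <- lapply(adj, sort)
  }
  adj
}

graph_edge_keys <- function(g) {
  if (!nrow(g$edges)) return(character(0))
  edge_key(g$edges$a, g$edges$b)
}

#' Degree of each cell in a neighbor graph
#' @param g A `neighbor_graph`.
#' @return Named integer vector of neighbour counts.
#' @export
graph_degree <- function(g) {
  deg <- integer(length(g$cells))
  names(deg) <- as.character(g$cells)
  if (nrow(g$edges)) {
    t1 <- table(factor(g$edges$a, levels = g$cells))
    t2 <- table(factor(g$edges$b, levels = g$cells))
    deg <- as.integer(t1 + t2)
    names(deg) <- as.character(g$cells)
  }
  deg
}
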
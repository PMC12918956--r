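read_checked_csv <- function(path, columns, int_cols = character(0)) {
  if (!file.exists(path)) {
    stop_epijam("input file not found: ", path, class = "epijam_missing_file")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols)) {
    stop_epijam(path, ": missing column(s) ",
                paste(missing_cols, collapse = ", "),
                class = "epijam_schema")
  }
  extra <- setdiff(names(df), columns)
  if (length(extra)) {
    stop_epijam(path, ": unknown column(s) ", paste(extra, collapse = ", "),
                "; expected exactly: ", paste(columns, collapse = ","),
                class = "epijam_schema")
  }
  for (cl in columns) {
    bad <- which(!is.na(df[[cl]]) & !is.numeric(df[[cl]]))
    if (length(bad)) {
      stop_epijam(path, ": non-numeric value in column ", cl, " at row ",
                  bad[1L], class = "epijam_schema")
    }
  }
  for (cl in int_cols) df[[cl]] <- as.integer(df[[cl]])
  df
}

#' Trajectory CSV round trip
#'
#' Trajectories are exchanged as CSV with the exact header
#' `frame,time_h,cell_id,x_um,y_um` (physical micrometres, y-up). Readers
#' reject unknown or missing columns and duplicated `(frame, cell_id)` rows
#' with the offending row number.
#'
#' @param traj A [trajectory_set()].
#' @param path File path.
#' @param box_um,periodic Geometry to attach on read.
#' @return `read_trajectory_csv` returns a [trajectory_set()].
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, box_um, periodic = TRUE) {
  df <- read_checked_csv(path, c("frame", "time_h", "cell_id", "x_um",
                                 "y_um"),
                         int_cols = c("frame", "cell_id"))
  dup <- which(duplicated(df[c("frame", "cell_id")]))
  if (length(dup)) {
    stop_epijam(path, ": duplicated (frame, cell_id) at data row ",
                dup[1L], class = "epijam_schema")
  }
  trajectory_set(df, box_um = box_um, periodic = periodic)
}

#' Neighbor-graph edge list CSV round trip
#'
#' Graph sequences are exchanged as edge lists with header
#' `frame,cell_a,cell_b,shared_um` plus a per-frame time table embedded as
#' attributes on write and re-supplied on read.
#'
#' @param graphs List of `neighbor_graph`.
#' @param path File path.
#' @export
write_edges_csv <- function(graphs, path) {
  rows <- lapply(graphs, function(g) {
    if (!nrow(g$edges)) return(NULL)
    data.frame(frame = g$frame, time_h = g$time_h,
               cell_a = g$edges$a, cell_b = g$edges$b,
               shared_um = g$edges$shared_um)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_edges_csv
#' @param cells Optional vector of all cell ids (edge lists do not mention
#'   isolated cells).
#' @export
read_edges_csv <- function(path, cells = NULL) {
  df <- read_checked_csv(path, c("frame", "time_h", "cell_a", "cell_b",
                                 "shared_um"),
                         int_cols = c("frame", "cell_a", "cell_b"))
  frames <- sort(unique(df$frame))
  lapply(frames, function(f) {
    sub <- df[df$frame == f, ]
    ids <- cells %||% sort(unique(c(sub$cell_a, sub$cell_b)))
    new_neighbor_graph(ids,
                       data.frame(a = pmin(sub$cell_a, sub$cell_b),
                                  b = pmax(sub$cell_a, sub$cell_b),
                                  shared_um = sub$shared_um),
                       integer(0), f, sub$time_h[1L], eps_edge = NA_real_)
  })
}

#' T1 event CSV round trip
#' @param events A `t1_events` table.
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- read_checked_csv(path, c("frame", "time_h", "loser_a", "loser_b",
                                 "gainer_a", "gainer_b", "x_um", "y_um"),
                         int_cols = c("frame", "loser_a", "loser_b",
                                      "gainer_a", "gainer_b"))
  structure(df, class = c("t1_events", "data.frame"))
}

#' Velocity field CSV round trip
#'
#' Long-format `x_um,y_um,vx_um_h,vy_um_h,valid` on the regular grid.
#' @param field A [velocity_field()].
#' @param path File path.
#' @export
write_velocity_field_csv <- function(field, path) {
  nr <- nrow(field$vx); nc <- ncol(field$vx)
  df <- data.frame(
    x_um = field$origin_um[1L] + field$spacing_um *
      (rep(seq_len(nc), each = nr) - 1L),
    y_um = field$origin_um[2L] + field$spacing_um *
      (rep(seq_len(nr), nc) - 1L),
    vx_um_h = as.vector(field$vx),
    vy_um_h = as.vector(field$vy),
    valid = as.integer(as.vector(field$valid)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_velocity_field_csv
#' @export
read_velocity_field_csv <- function(path) {
  df <- read_checked_csv(path, c("x_um", "y_um", "vx_um_h", "vy_um_h",
                                 "valid"), int_cols = "valid")
  xs <- sort(unique(df$x_um)); ys <- sort(unique(df$y_um))
  if (length(xs) > 1L) {
    steps <- diff(xs)
    if (max(steps) - min(steps) > 1e-9 * max(steps)) {
      stop_epijam(path, ": grid x spacing not uniform",
                  class = "epijam_schema")
    }
  }
  spacing <- if (length(xs) > 1L) xs[2L] - xs[1L] else {
    if (length(ys) > 1L) ys[2L] - ys[1L] else 1
  }
  shape <- c(length(ys), length(xs))
  ii <- match(df$y_um, ys); jj <- match(df$x_um, xs)
  vx <- matrix(NA_real_, shape[1L], shape[2L])
  vy <- vx; vd <- matrix(FALSE, shape[1L], shape[2L])
  vx[cbind(ii, jj)] <- df$vx_um_h
  vy[cbind(ii, jj)] <- df$vy_um_h
  vd[cbind(ii, jj)] <- df$valid > 0
  velocity_field(vx, vy, spacing, origin_um = c(xs[1L], ys[1L]),
                 valid = vd)
}

#' Grayscale and label-mask TIFF round trips
#'
#' Grayscale images are written as 32-bit float TIFF; label masks as 16-bit
#' integer TIFF stacks (one page per frame). Matrices follow the image row
#' convention (row 1 = top).
#'
#' @param image Numeric matrix (any range) or list of matrices for stacks.
#' @param path File path.
#' @export
write_image_tiff <- function(image, path) {
  imgs <- if (is.list(image)) image else list(image)
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) {
    stop_epijam("input file not found: ", path, class = "epijam_missing_file")
  }
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (length(imgs) == 1L) imgs[[1L]] else imgs
}

#' @rdname write_image_tiff
#' @param labels Integer matrix or list of integer matrices (values
#'   0..65535).
#' @export
write_label_stack_tiff <- function(labels, path) {
  ll <- if (is.list(labels)) labels else list(labels)
  ll <- lapply(ll, function(m) {
    if (max(m) > 65535L) {
      stop_epijam("labels exceed 16-bit range", class = "epijam_schema")
    }
    m / 65535
  })
  tiff::writeTIFF(ll, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_label_stack_tiff <- function(path) {
  imgs <- read_image_tiff(path)
  ll <- lapply(if (is.list(imgs)) imgs else list(imgs), function(m) {
    lm <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
    lm
  })
  if (length(ll) == 1L) ll[[1L]] else ll
}

#' Write an analysis report as JSON
#'
#' Serializes fit/test results (lists of numbers and small tables) with the
#' package version and the seed used, so a report is self-describing.
#'
#' @param x Named list.
#' @param path File path.
#' @export
write_json_report <- function(x, path) {
  x$software <- paste0("epijam ",
                       as.character(utils::packageVersion("epijam")))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
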
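#' Trajectory set container
#'
#' A tidy table of cell centroid positions over time, the common substrate for
#' kinematic analyses. Columns: `frame` (0-based), `time_h`, `cell_id`,
#' `x_um`, `y_um` (physical y-up coordinates). Invariants enforced: each
#' `(frame, cell_id)` pair unique, times strictly increasing with frame, all
#' coordinates inside the box.
#'
#' @param df Data frame with the five columns above.
#' @param box_um Side of the square field (micrometres).
#' @param periodic Logical; coordinates live on a torus.
#' @return The validated data frame with class `trajectory_set` and
#'   attributes `box_um`, `periodic`.
#' @export
trajectory_set <- function(df, box_um, periodic = TRUE) {
  need <- c("frame", "time_h", "cell_id", "x_um", "y_um")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_epijam("trajectory table lacks columns: ",
                paste(missing_cols, collapse = ", "),
                class = "epijam_schema")
  }
  df <- df[need]
  dup <- which(duplicated(df[c("frame", "cell_id")]))
  if (length(dup)) {
    stop_epijam("duplicated (frame, cell_id) at row(s) ",
                paste(utils::head(dup, 5L), collapse = ", "),
                class = "epijam_schema")
  }
  ft <- unique(df[c("frame", "time_h")])
  ft <- ft[order(ft$frame), ]
  if (anyDuplicated(ft$frame) || any(diff(ft$time_h) <= 0)) {
    stop_epijam("frame times must be unique and strictly increasing",
                class = "epijam_schema")
  }
  if (any(df$x_um < 0 | df$x_um > box_um | df$y_um < 0 | df$y_um > box_um)) {
    stop_epijam("coordinates outside [0, box_um]", class = "epijam_schema")
  }
  df <- df[order(df$frame, df$cell_id), ]
  rownames(df) <- NULL
  structure(df, class = c("trajectory_set", "data.frame"),
            box_um = box_um, periodic = periodic)
}

#' Per-cell velocities from a trajectory set
#'
#' Finite-difference velocities in micrometres per hour. `forward` assigns
#' `(x[f+1] - x[f]) / dt` to frame `f`; `central` assigns
#' `(x[f+w] - x[f-w]) / (t[f+w] - t[f-w])` (window `w` frames each side).
#' Periodic boxes use minimal-image displacements. Cells absent from either
#' frame of a difference are dropped for that frame.
#'
#' @param traj A `trajectory_set`.
#' @param method `"forward"` or `"central"`.
#' @param window Half-width in frames for the central difference.
#' @return Data frame `frame`, `time_h`, `cell_id`, `x_um`, `y_um`,
#'   `vx_um_h`, `vy_um_h`.
#' @export
trajectory_velocities <- function(traj, method = c("forward", "central"),
                                  window = 1L) {
  method <- match.arg(method)
  box <- attr(traj, "box_um")
  periodic <- attr(traj, "periodic")
  frames <- sort(unique(traj$frame))
  times <- tapply(traj$time_h, traj$frame, `[`, 1L)
  w <- if (method == "forward") c(0L, 1L) else c(-window, window)
  out <- vector("list", length(frames))
  idx <- split(seq_len(nrow(traj)), traj$frame)
  for (i in seq_along(frames)) {
    f <- frames[i]
    ia <- match(f + w[1L], frames)
    ib <- match(f + w[2L], frames)
    if (is.na(ia) || is.na(ib)) next
    a <- traj[idx[[ia]], ]
    b <- traj[idx[[ib]], ]
    common <- intersect(a$cell_id, b$cell_id)
    if (!length(common)) next
    a <- a[match(common, a$cell_id), ]
    b <- b[match(common, b$cell_id), ]
    dt <- as.numeric(times[as.character(frames[ib])] -
                     times[as.character(frames[ia])])
    dx <- b$x_um - a$x_um
    dy <- b$y_um - a$y_um
    if (periodic) {
      dx <- wrap_diff(dx, box)
      dy <- wrap_diff(dy, box)
    }
    here <- traj[idx[[i]], ]
    pos <- here[match(common, here$cell_id), ]
    out[[i]] <- data.frame(frame = f,
                           time_h = as.numeric(times[as.character(f)]),
                           cell_id = common,
                           x_um = pos$x_um, y_um = pos$y_um,
                           vx_um_h = dx / dt, vy_um_h = dy / dt)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(frame = integer(0), time_h = numeric(0),
                      cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), vx_um_h = numeric(0),
                      vy_um_h = numeric(0))
  }
  rownames(res) <- NULL
  res
}
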
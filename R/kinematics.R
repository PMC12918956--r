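#' Gridded velocity field container
#'
#' A regular grid of 2-D velocity vectors (micrometres per hour) with a
#' per-node validity flag, as produced by PIV or by gridding generator
#' output. Matrix element `[i, j]` sits at physical position
#' `origin + spacing * (j - 1, i - 1)` (x along columns, y along rows, y-up).
#'
#' @param vx,vy Numeric matrices of velocity components.
#' @param spacing_um Grid spacing (micrometres), > 0.
#' @param origin_um Physical position of node `[1, 1]`, length-2.
#' @param valid Logical matrix; invalid nodes are excluded from every
#'   statistic. Defaults to finiteness of both components.
#' @param time_h Frame time (hours).
#' @return Object of class `velocity_field`.
#' @export
velocity_field <- function(vx, vy, spacing_um, origin_um = c(0, 0),
                           valid = NULL, time_h = 0) {
  stopifnot(is.matrix(vx), is.matrix(vy), all(dim(vx) == dim(vy)),
            spacing_um > 0, length(origin_um) == 2L)
  if (is.null(valid)) valid <- is.finite(vx) & is.finite(vy)
  stopifnot(all(dim(valid) == dim(vx)))
  valid <- valid & is.finite(vx) & is.finite(vy)
  structure(list(vx = vx, vy = vy, spacing_um = spacing_um,
                 origin_um = origin_um, valid = valid,
                 time_h = time_h),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d x %d nodes, spacing %g um, %d valid, t = %g h\n",
              nrow(x$vx), ncol(x$vx), x$spacing_um, sum(x$valid), x$time_h))
  invisible(x)
}

#' Root-mean-square velocity of a field
#'
#' `V_rms = sqrt(mean(|v|^2))` over valid vectors, the spatial average over
#' the field of view. Whether a global drift should be removed first is a
#' reporting choice; both the raw value and the drift-corrected value (mean
#' velocity subtracted before squaring) are always returned, and
#' `subtract_mean` selects which one `vrms` reports as the headline `vrms`.
#'
#' @param field A `velocity_field`, or a data frame with columns `vx_um_h`,
#'   `vy_um_h` (e.g. from [trajectory_velocities()]).
#' @param subtract_mean Report the drift-corrected variant as `vrms`.
#' @return List of class `velocity_stats`: `vrms`, `vrms_raw`,
#'   `vrms_drift_corrected`, `mean_speed`, `n_valid`, `time_h`.
#' @export
vrms <- function(field, subtract_mean = FALSE) {
  if (inherits(field, "velocity_field")) {
    vx <- field$vx[field$valid]
    vy <- field$vy[field$valid]
    t_h <- field$time_h
  } else {
    stopifnot(all(c("vx_um_h", "vy_um_h") %in% names(field)))
    ok <- is.finite(field$vx_um_h) & is.finite(field$vy_um_h)
    vx <- field$vx_um_h[ok]
    vy <- field$vy_um_h[ok]
    t_h <- if ("time_h" %in% names(field) && nrow(field)) {
      mean(field$time_h[ok])
    } else NA_real_
  }
  if (!length(vx)) {
    stop_epijam("no valid vectors for V_rms", class = "epijam_empty_input")
  }
  raw <- sqrt(mean(vx^2 + vy^2))
  dvx <- vx - mean(vx)
  dvy <- vy - mean(vy)
  corrected <- sqrt(mean(dvx^2 + dvy^2))
  structure(list(vrms = if (subtract_mean) corrected else raw,
                 vrms_raw = raw, vrms_drift_corrected = corrected,
                 mean_speed = mean(sqrt(vx^2 + vy^2)),
                 n_valid = length(vx), time_h = t_h),
            class = "velocity_stats")
}

#' @export
print.velocity_stats <- function(x, ...) {
  cat(sprintf("V_rms = %.4g um/h (raw %.4g, drift-corrected %.4g), mean speed %.4g, n = %d\n",
              x$vrms, x$vrms_raw, x$vrms_drift_corrected, x$mean_speed,
              x$n_valid))
  invisible(x)
}

#' Sliding-window V_rms time course
#'
#' Pools finite-difference velocities over half-open time windows
#' `[t, t + window)` and reports the raw and drift-corrected V_rms per
#' window. Windows advance by whole windows (non-overlapping) by default.
#'
#' @param traj A [trajectory_set()].
#' @param window_frames Window length in frames (>= 1).
#' @return Data frame `t_start`, `t_mid`, `vrms`, `vrms_drift_corrected`,
#'   `mean_speed`, `n`.
#' @export
vrms_timecourse <- function(traj, window_frames = 1L) {
  stopifnot(window_frames >= 1L)
  vel <- trajectory_velocities(traj, method = "forward")
  if (!nrow(vel)) {
    stop_epijam("trajectory too short for a velocity estimate",
                class = "epijam_empty_input")
  }
  frames <- sort(unique(vel$frame))
  bin <- floor((vel$frame - min(frames)) / window_frames)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- vel[bin == b, ]
    st <- vrms(sel)
    data.frame(t_start = min(sel$time_h),
               t_mid = mean(range(sel$time_h)),
               vrms = st$vrms_raw,
               vrms_drift_corrected = st$vrms_drift_corrected,
               mean_speed = st$mean_speed, n = st$n_valid)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# FFT-based cross-correlation sums of zero-padded matrices:
# returns S[di, dj] = sum_{i,j} a[i, j] * b[i + di, j + dj] for lags
# di in -(nr-1)..(nr-1), dj likewise, as a (2nr-1) x (2nc-1) matrix.
lag_corr_sums <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  pr <- 2L * nr - 1L; pc <- 2L * nc - 1L
  pa <- matrix(0, pr, pc); pb <- matrix(0, pr, pc)
  pa[seq_len(nr), seq_len(nc)] <- a
  pb[seq_len(nr), seq_len(nc)] <- b
  fa <- stats::fft(pa)
  fb <- stats::fft(pb)
  s <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / (pr * pc)
  # reorder so that lag 0 is at the centre
  s <- s[c((nr + 1L):pr, 1L:nr), c((nc + 1L):pc, 1L:nc)]
  s
}

#' Spatial velocity autocorrelation and correlation length
#'
#' Computes the radially averaged, normalized spatial autocorrelation of the
#' mean-subtracted velocity field,
#' `C(r) = <dv(x) . dv(x + r)> / <|dv|^2>`, and extracts the velocity
#' correlation length `xi_v` as the first crossing of `C(r) = 1/e`, linearly
#' interpolated between bins. The zero-separation pairs form their own first
#' bin, so `C` at the smallest bin is exactly 1. The pair accumulation is
#' FFT-based and identical (to rounding) to the brute-force sum over all node
#' pairs; invalid nodes contribute nothing.
#'
#' @param field A `velocity_field` or a list of them (profiles are pooled by
#'   accumulating pair sums and counts across fields).
#' @param r_max Largest separation (micrometres); default half the field
#'   extent.
#' @param n_bins Number of radial bins beyond the zero bin.
#' @param min_bin_fraction Minimum fraction of non-empty bins before the
#'   profile is declared `insufficient_data`.
#' @return List of class `correlation_profile`: `r_um` (bin centres), `c_r`,
#'   `counts`, `xi_v_um`, `status` (`"ok"`, `"no_crossing"`,
#'   `"insufficient_data"`), `below_resolution` (crossing inside the first
#'   off-zero bin).
#' @export
velocity_correlation <- function(field, r_max = NULL, n_bins = 20L,
                                 min_bin_fraction = 0.8) {
  fields <- if (inherits(field, "velocity_field")) list(field) else field
  stopifnot(length(fields) >= 1L, n_bins >= 2L)
  spacing <- fields[[1L]]$spacing_um
  nr <- nrow(fields[[1L]]$vx); nc <- ncol(fields[[1L]]$vx)
  if (is.null(r_max)) r_max <- 0.5 * spacing * (min(nr, nc) - 1L)
  # lag separation matrix (shared across fields of equal shape)
  lag_i <- (-(nr - 1L)):(nr - 1L)
  lag_j <- (-(nc - 1L)):(nc - 1L)
  rmat <- spacing * sqrt(outer(lag_i^2, lag_j^2, "+"))
  edges <- seq(0, r_max, length.out = n_bins + 1L)
  # bin 1 holds exactly r = 0; off-zero separations go to uniform bins
  bin_of <- function(r) {
    b <- findInterval(r, edges, rightmost.closed = TRUE, left.open = TRUE) + 1L
    b[r == 0] <- 1L
    b[r > r_max] <- NA_integer_
    b
  }
  bins <- bin_of(as.vector(rmat))
  num <- rep(0, n_bins + 1L)
  cnt <- rep(0, n_bins + 1L)
  denom <- 0
  denom_n <- 0
  for (fl in fields) {
    stopifnot(nrow(fl$vx) == nr, ncol(fl$vx) == nc)
    v <- fl$valid
    nv <- sum(v)
    if (nv < 2L) next
    dvx <- fl$vx - mean(fl$vx[v])
    dvy <- fl$vy - mean(fl$vy[v])
    dvx[!v] <- 0; dvy[!v] <- 0
    s <- lag_corr_sums(dvx, dvx) + lag_corr_sums(dvy, dvy)
    m <- round(lag_corr_sums(v * 1, v * 1))  # pair counts are integers
    ok <- !is.na(bins)
    bb <- bins[ok]
    s_by_bin <- rowsum(as.vector(s)[ok], bb)
    m_by_bin <- rowsum(as.vector(m)[ok], bb)
    at <- as.integer(rownames(s_by_bin))
    num[at] <- num[at] + s_by_bin[, 1L]
    cnt[at] <- cnt[at] + m_by_bin[, 1L]
    denom <- denom + sum(dvx[v]^2 + dvy[v]^2)
    denom_n <- denom_n + nv
  }
  if (denom_n < 2L || denom <= denom_n * 1e-24) {
    return(structure(list(r_um = c(0, (edges[-1L] + edges[-length(edges)]) / 2),
                          c_r = rep(NA_real_, n_bins + 1L),
                          counts = cnt, xi_v_um = NA_real_,
                          status = "insufficient_data",
                          below_resolution = NA),
                     class = "correlation_profile"))
  }
  c_r <- ifelse(cnt > 0, (num / cnt) / (denom / denom_n), NA_real_)
  centers <- c(0, (edges[-1L] + edges[-length(edges)]) / 2)
  nonempty <- sum(cnt > 0)
  if (nonempty < min_bin_fraction * (n_bins + 1L)) {
    status <- "insufficient_data"
    xi <- NA_real_
    below <- NA
  } else {
    target <- exp(-1)
    obs <- which(!is.na(c_r))
    xi <- NA_real_
    status <- "no_crossing"
    below <- FALSE
    for (ii in seq_along(obs)[-1L]) {
      i0 <- obs[ii - 1L]; i1 <- obs[ii]
      if (c_r[i0] >= target && c_r[i1] < target) {
        xi <- centers[i0] + (centers[i1] - centers[i0]) *
          (c_r[i0] - target) / (c_r[i0] - c_r[i1])
        status <- "ok"
        below <- centers[i1] <= spacing * 1.5
        break
      }
    }
  }
  structure(list(r_um = centers, c_r = as.numeric(c_r),
                 counts = as.numeric(cnt), xi_v_um = xi, status = status,
                 below_resolution = below),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("correlation_profile: %d bins, xi_v = %s um (%s)\n",
              length(x$r_um),
              if (is.na(x$xi_v_um)) "NA" else sprintf("%.3g", x$xi_v_um),
              x$status))
  invisible(x)
}

#' Strain-rate decomposition of a velocity field
#'
#' Estimates the velocity gradient at each node by local least squares over
#' the valid nodes of its 3x3 neighbourhood, symmetrizes it, and splits the
#' 2-D strain-rate tensor E into its isotropic part (dilation rate,
#' `iso = tr(E) / 2`) and the magnitude of its traceless (deviatoric) part.
#' The default deviatoric magnitude is the Frobenius norm
#' `||E - iso * I||_F`; the maximum-shear convention (largest eigenvalue of
#' the traceless part, Frobenius / sqrt(2)) is available via `convention`.
#' Nodes whose neighbourhood has fewer than 6 valid nodes are flagged
#' invalid.
#'
#' @param field A `velocity_field`.
#' @param convention `"frobenius"` (default) or `"max_shear"`.
#' @return List of class `strain_rate_field`: `isotropic` and `deviatoric`
#'   matrices (1/h), the symmetric-gradient components `exx`, `exy`, `eyy`,
#'   `valid`, plus grid geometry.
#' @export
strain_rate <- function(field, convention = c("frobenius", "max_shear")) {
  convention <- match.arg(convention)
  nr <- nrow(field$vx); nc <- ncol(field$vx)
  if (nr < 3L || nc < 3L) {
    stop_epijam("strain_rate needs at least a 3x3 grid",
                class = "epijam_empty_input")
  }
  h <- field$spacing_um
  iso <- matrix(NA_real_, nr, nc)
  dev <- matrix(NA_real_, nr, nc)
  exx <- matrix(NA_real_, nr, nc)
  exy <- matrix(NA_real_, nr, nc)
  eyy <- matrix(NA_real_, nr, nc)
  ok <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- max(1L, i - 1L):min(nr, i + 1L)
      jj <- max(1L, j - 1L):min(nc, j + 1L)
      sub_v <- field$valid[ii, jj]
      if (sum(sub_v) < 6L) next
      # local coordinates in um; x along columns, y along rows (y-up grid)
      xs <- h * (rep(jj, each = length(ii)) - j)
      ys <- h * (rep(ii, times = length(jj)) - i)
      w <- as.vector(sub_v)
      X <- cbind(1, xs, ys)[w, , drop = FALSE]
      if (qr(X)$rank < 3L) next
      vxs <- as.vector(field$vx[ii, jj])[w]
      vys <- as.vector(field$vy[ii, jj])[w]
      bx <- qr.solve(X, vxs)
      by <- qr.solve(X, vys)
      G <- matrix(c(bx[2L], bx[3L], by[2L], by[3L]), 2L, 2L, byrow = TRUE)
      E <- (G + t(G)) / 2
      tr2 <- (E[1L, 1L] + E[2L, 2L]) / 2
      D <- E - diag(tr2, 2L)
      fro <- sqrt(sum(D^2))
      iso[i, j] <- tr2
      dev[i, j] <- if (convention == "frobenius") fro else fro / sqrt(2)
      exx[i, j] <- E[1L, 1L]
      exy[i, j] <- E[1L, 2L]
      eyy[i, j] <- E[2L, 2L]
      ok[i, j] <- TRUE
    }
  }
  structure(list(isotropic = iso, deviatoric = dev,
                 exx = exx, exy = exy, eyy = eyy, valid = ok,
                 spacing_um = h, origin_um = field$origin_um,
                 time_h = field$time_h, convention = convention),
            class = "strain_rate_field")
}
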
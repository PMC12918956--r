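#' Particle image velocimetry on an image pair
#'
#' Single-pass FFT cross-correlation PIV. Each interrogation window of
#' `frame_a` is correlated with the same window of `frame_b` after mean
#' subtraction; the correlation peak gives the integer displacement and a
#' 3-point Gaussian fit refines it to subpixel precision (parabolic fallback
#' where the Gaussian fit is undefined). Windows whose peak-to-second-peak
#' ratio falls below `peak_ratio_min` are flagged invalid, as are windows
#' with negligible texture. Displacements are converted to micrometres per
#' hour; the returned field is in physical y-up coordinates (a displacement
#' toward larger row indices, i.e. down the image, is a negative `vy`).
#'
#' @param frame_a,frame_b Numeric matrices (grayscale images, image row
#'   convention), same shape.
#' @param window_px Interrogation window side (>= 16, power of two
#'   recommended).
#' @param overlap Fraction of window overlap in `[0, 1)`.
#' @param dt_h Time between frames (hours).
#' @param um_per_px Pixel size (micrometres).
#' @param peak_ratio_min Validity threshold on first/second correlation peak.
#' @return A [velocity_field()]; attributes `dx_px`, `dy_px` hold the raw
#'   pixel-space displacement matrices (image convention) for diagnostics.
#' @export
piv <- function(frame_a, frame_b, window_px = 32L, overlap = 0.5,
                dt_h = 1, um_per_px = 1, peak_ratio_min = 1.5) {
  if (!all(dim(frame_a) == dim(frame_b))) {
    stop_epijam("frame shapes differ", class = "epijam_shape_mismatch")
  }
  if (window_px < 16L) {
    stop_epijam("window must be >= 16 px", class = "epijam_invalid_config")
  }
  if (window_px > min(dim(frame_a))) {
    stop_epijam("window larger than image", class = "epijam_invalid_config")
  }
  stopifnot(overlap >= 0, overlap < 1)
  step <- max(1L, as.integer(round(window_px * (1 - overlap))))
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  r0 <- seq(1L, nr - window_px + 1L, by = step)
  c0 <- seq(1L, nc - window_px + 1L, by = step)
  dx <- matrix(NA_real_, length(r0), length(c0))
  dy <- matrix(NA_real_, length(r0), length(c0))
  ok <- matrix(FALSE, length(r0), length(c0))
  w <- window_px
  half <- w %/% 2L
  search <- w %/% 4L               # displacements beyond w/4 are not trusted
  pad_n <- 2L * w
  lag <- (-search):search
  pad_idx <- (lag %% pad_n) + 1L
  overlap_n <- outer(w - abs(lag), w - abs(lag))
  subpx <- function(cm1, c0v, cp1) {
    if (cm1 > 0 && c0v > 0 && cp1 > 0 && (cm1 != c0v || cp1 != c0v)) {
      den <- 2 * log(cm1) - 4 * log(c0v) + 2 * log(cp1)
      if (den != 0) return((log(cm1) - log(cp1)) / den)
    }
    den <- 2 * (cm1 - 2 * c0v + cp1)
    if (den != 0) (cm1 - cp1) / den else 0
  }
  for (ri in seq_along(r0)) {
    for (ci in seq_along(c0)) {
      a <- frame_a[r0[ri]:(r0[ri] + w - 1L), c0[ci]:(c0[ci] + w - 1L)]
      b <- frame_b[r0[ri]:(r0[ri] + w - 1L), c0[ci]:(c0[ci] + w - 1L)]
      a <- a - mean(a); b <- b - mean(b)
      if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) next
      # zero-padded linear cross-covariance, normalized by the number of
      # overlapping pixels at each lag (removes the circular-wrap artifact
      # and the triangular bias toward zero lag)
      pa <- matrix(0, pad_n, pad_n); pb <- matrix(0, pad_n, pad_n)
      pa[seq_len(w), seq_len(w)] <- a
      pb[seq_len(w), seq_len(w)] <- b
      s <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb),
                         inverse = TRUE)) / (pad_n * pad_n)
      cc <- s[pad_idx, pad_idx] / overlap_n
      pk <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
      # peak-to-second-peak validation on the search region, excluding the
      # main lobe (radius 3) around the first peak
      masked <- cc
      mi <- max(1L, pk[1L] - 3L):min(nrow(cc), pk[1L] + 3L)
      mj <- max(1L, pk[2L] - 3L):min(ncol(cc), pk[2L] + 3L)
      masked[mi, mj] <- -Inf
      second <- max(masked)
      if (!(second > 0) || max(cc) / second >= peak_ratio_min) {
        di <- lag[pk[1L]]
        dj <- lag[pk[2L]]
        ddi <- if (pk[1L] > 1L && pk[1L] < nrow(cc)) {
          subpx(cc[pk[1L] - 1L, pk[2L]], cc[pk[1L], pk[2L]],
                cc[pk[1L] + 1L, pk[2L]])
        } else 0
        ddj <- if (pk[2L] > 1L && pk[2L] < ncol(cc)) {
          subpx(cc[pk[1L], pk[2L] - 1L], cc[pk[1L], pk[2L]],
                cc[pk[1L], pk[2L] + 1L])
        } else 0
        dy[ri, ci] <- di + ddi  # rows: image y-down
        dx[ri, ci] <- dj + ddj
        ok[ri, ci] <- TRUE
      }
    }
  }
  centers_c <- c0 + half - 0.5          # px, image convention
  centers_r <- r0 + half - 0.5
  # physical grid: x increases with column, y-up; flip rows so that row 1 of
  # the field is the bottom of the image
  flip <- rev(seq_along(r0))
  vx <- dx[flip, , drop = FALSE] * um_per_px / dt_h
  vy <- -dy[flip, , drop = FALSE] * um_per_px / dt_h
  valid <- ok[flip, , drop = FALSE]
  origin <- c(centers_c[1L] * um_per_px,
              (nr - centers_r[length(centers_r)]) * um_per_px)
  fld <- velocity_field(vx, vy, spacing_um = step * um_per_px,
                        origin_um = origin, valid = valid)
  attr(fld, "dx_px") <- dx
  attr(fld, "dy_px") <- dy
  attr(fld, "valid_px") <- ok
  fld
}

#' Render a phantom image pair with a known displacement field
#'
#' Builds a textured grayscale image and warps it by a prescribed
#' displacement field (pixel units, image convention) to produce a second
#' frame, giving PIV a ground truth. The second image samples the first at
#' `x - d(x)` by bilinear interpolation on a periodically extended texture,
#' so a constant displacement is an exact shift.
#'
#' @param n_px Image side in pixels.
#' @param dx_px,dy_px Displacement field: scalars or matrices of the image
#'   size (columns / rows respectively; `dy` positive = down the image).
#' @param texture_seed Seed for the random texture.
#' @param texture_scale_px Gaussian smoothing scale of the texture.
#' @param noise_sd Additive Gaussian noise SD on both frames (0 = none).
#' @param window_px PIV window intended for analysis; displacements larger
#'   than a quarter window are refused.
#' @return List `frame_a`, `frame_b`, `dx_px`, `dy_px` (full-size matrices).
#' @export
render_phantom_pair <- function(n_px = 256L, dx_px = 0, dy_px = 0,
                                texture_seed = 1L, texture_scale_px = 1.5,
                                noise_sd = 0, window_px = 32L) {
  if (length(dx_px) == 1L) dx_px <- matrix(dx_px, n_px, n_px)
  if (length(dy_px) == 1L) dy_px <- matrix(dy_px, n_px, n_px)
  stopifnot(all(dim(dx_px) == c(n_px, n_px)),
            all(dim(dy_px) == c(n_px, n_px)))
  if (max(abs(dx_px), abs(dy_px)) > window_px / 4) {
    stop_epijam("displacement exceeds a quarter of the PIV window; ",
                "increase window_px or reduce the displacement",
                class = "epijam_displacement_too_large")
  }
  with_seed(texture_seed, {
    tex <- matrix(stats::rnorm(n_px * n_px), n_px, n_px)
    tex <- gaussian_blur(tex, texture_scale_px, periodic = TRUE)
    tex <- (tex - min(tex)) / (max(tex) - min(tex))
    # sample frame_b at (r - dy, c - dx), periodic bilinear
    rr <- matrix(rep(seq_len(n_px), n_px), n_px, n_px)
    cc <- matrix(rep(seq_len(n_px), each = n_px), n_px, n_px)
    sr <- rr - dy_px
    sc <- cc - dx_px
    fb <- bilinear_periodic(tex, sr, sc)
    fa <- tex
    if (noise_sd > 0) {
      fa <- fa + matrix(stats::rnorm(n_px * n_px, 0, noise_sd), n_px, n_px)
      fb <- fb + matrix(stats::rnorm(n_px * n_px, 0, noise_sd), n_px, n_px)
    }
    list(frame_a = fa, frame_b = fb, dx_px = dx_px, dy_px = dy_px)
  })
}

# Periodic bilinear interpolation of matrix `img` at fractional (row, col).
bilinear_periodic <- function(img, r, c) {
  n <- nrow(img); m <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  wrapn <- function(i, n) ((i - 1L) %% n) + 1L
  i0 <- wrapn(r0, n); i1 <- wrapn(r0 + 1L, n)
  j0 <- wrapn(c0, m); j1 <- wrapn(c0 + 1L, m)
  idx <- function(i, j) img[cbind(as.vector(i), as.vector(j))]
  out <- idx(i0, j0) * (1 - fr) * (1 - fc) +
         idx(i1, j0) * fr * (1 - fc) +
         idx(i0, j1) * (1 - fr) * fc +
         idx(i1, j1) * fr * fc
  matrix(out, n, m)
}

# Separable Gaussian blur; periodic wraps the kernel, otherwise renormalized
# at the borders.
gaussian_blur <- function(img, sigma, periodic = FALSE) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  n <- nrow(img); m <- ncol(img)
  conv1 <- function(x, n_len) {
    # x: matrix, convolve along rows (dimension 1) for each column
    if (periodic) {
      K <- matrix(0, n_len, n_len)
      for (o in -half:half) {
        K[cbind(seq_len(n_len), ((seq_len(n_len) - 1L + o) %% n_len) + 1L)] <-
          K[cbind(seq_len(n_len), ((seq_len(n_len) - 1L + o) %% n_len) + 1L)] +
          k[o + half + 1L]
      }
      K %*% x
    } else {
      pad <- rbind(matrix(0, half, ncol(x)), x, matrix(0, half, ncol(x)))
      wts <- rbind(matrix(0, half, ncol(x)), matrix(1, n_len, ncol(x)),
                   matrix(0, half, ncol(x)))
      num <- stats::filter(pad, k, sides = 2)
      den <- stats::filter(wts, k, sides = 2)
      (num / den)[half + seq_len(n_len), , drop = FALSE]
    }
  }
  out <- conv1(img, n)
  t(conv1(t(out), m))
}
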
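#' Four-parameter logistic (Hill) curve
#'
#' `y(t) = bottom + (top - bottom) / (1 + (ec50 / t)^hill)` for `t > 0`.
#' The half-maximal time `ec50` is reported in hours; the name `logec50` is
#' kept for the fitted parameter because marker transitions are conventionally
#' summarized by their "LogEC50" even when the axis is time. At `t = ec50` the
#' noiseless value is exactly `(bottom + top) / 2`; the curve is monotone
#' between `bottom` and `top` for `hill > 0`.
#'
#' @param t Times (hours, > 0).
#' @param bottom,top Asymptotes.
#' @param ec50 Half-maximal time (hours).
#' @param hill Dimensionless Hill slope (non-zero).
#' @return Numeric vector of curve values.
#' @export
sigmoid_4pl <- function(t, bottom, top, ec50, hill) {
  stopifnot(all(t > 0), ec50 > 0, hill != 0)
  bottom + (top - bottom) / (1 + exp(hill * (log(ec50) - log(t))))
}

#' Generate a noisy sigmoidal marker time course
#'
#' Samples the four-parameter logistic at the given times and adds i.i.d.
#' Gaussian noise, reproducibly under `seed`. Mirrors the sigmoidal rise of
#' junction maturation and cytoplasmic marker ratios during epithelial
#' crowding.
#'
#' @param times Times in hours (sorted, > 0).
#' @param bottom,top,ec50,hill True curve parameters (see [sigmoid_4pl()]).
#' @param noise_sigma Noise SD in value units.
#' @param seed Integer seed.
#' @return Data frame `time_h`, `value` of class `sigmoid_series` with the
#'   true parameters stored in attribute `true_params`.
#' @export
generate_sigmoid_series <- function(times, bottom = 1, top = 3, ec50 = 90,
                                    hill = 8, noise_sigma = 0, seed = 1L) {
  stopifnot(!is.unsorted(times), all(times > 0), hill != 0)
  mu <- sigmoid_4pl(times, bottom, top, ec50, hill)
  vals <- if (noise_sigma > 0) {
    with_seed(seed, mu + stats::rnorm(length(times), 0, noise_sigma))
  } else mu
  structure(data.frame(time_h = times, value = vals),
            class = c("sigmoid_series", "data.frame"),
            true_params = list(bottom = bottom, top = top, ec50 = ec50,
                               hill = hill, noise_sigma = noise_sigma,
                               seed = seed))
}

#' Generate a velocity field with an imposed correlation length
#'
#' Draws each velocity component as a stationary Gaussian random field on a
#' periodic grid whose spatial autocorrelation is `exp(-r / xi)` (circulant
#' embedding: the target covariance is diagonalized by the FFT; small
#' negative spectral weights are clipped). Used to validate the correlation
#' length estimator against a known `xi`.
#'
#' @param n_nodes Grid side (nodes).
#' @param spacing_um Node spacing (micrometres).
#' @param xi_um Imposed correlation length (micrometres).
#' @param sigma RMS amplitude per component (micrometres/hour).
#' @param seed Integer seed.
#' @return A [velocity_field()].
#' @export
synth_correlated_field <- function(n_nodes = 32L, spacing_um = 10,
                                   xi_um = 40, sigma = 5, seed = 1L) {
  stopifnot(n_nodes >= 8L, xi_um > 0)
  n <- n_nodes
  L <- n * spacing_um
  d1 <- spacing_um * pmin(0:(n - 1L), n - (0:(n - 1L)))  # torus distance
  r <- sqrt(outer(d1^2, d1^2, "+"))
  covm <- exp(-r / xi_um)
  lam <- Re(stats::fft(covm))
  lam[lam < 0] <- 0
  with_seed(seed, {
    draw <- function() {
      z <- matrix(stats::rnorm(n * n), n, n) +
        1i * matrix(stats::rnorm(n * n), n, n)
      f <- Re(stats::fft(sqrt(lam) * z, inverse = TRUE)) / n
      f / stats::sd(as.vector(f)) * sigma
    }
    vx <- draw()
    vy <- draw()
    velocity_field(vx, vy, spacing_um = spacing_um)
  })
}
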
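#' Rigid-pack scaling null prediction for the T1 rate
#'
#' In the rigid-pack picture of collective motion, cells translate in
#' coherent clusters of size `L_c` and neighbor exchanges happen only at
#' cluster interfaces. The fraction of interface cells then scales as
#' `f_int ~ 1/L_c ~ 1/V_rms`, while the relative speed of neighbouring
#' clusters scales as `V_rel ~ V_rms`, so the T1 rate
#' `R_T1 ~ f_int * V_rel` is independent of `V_rms`. The proportionality
#' constants are fixed by a single calibration pair `(V_rms, R_T1)`; the
#' testable content is the *constancy* of the prediction, which this
#' function realizes exactly: the predicted rate equals the calibration rate
#' at every grid point, and rescaling the V_rms grid leaves it unchanged.
#'
#' @param vrms_grid Strictly positive V_rms values (micrometres/hour).
#' @param calibration Length-2 numeric: a `(V_rms, R_T1)` pair.
#' @return List of class `null_model_prediction`: `vrms_grid`, `f_int`,
#'   `v_rel_um_h`, `predicted_rate` (constant vector).
#' @export
rigid_pack_prediction <- function(vrms_grid, calibration) {
  stopifnot(length(calibration) == 2L)
  if (any(vrms_grid <= 0) || calibration[1L] <= 0) {
    stop_epijam("V_rms values must be strictly positive",
                class = "epijam_invalid_config")
  }
  c2 <- 1                                   # V_rel = c2 * V_rms
  c1 <- calibration[2L] / (c2 * 1)          # so c1 * c2 = calibrated rate
  f_int <- pmin(1, c1 / vrms_grid)
  structure(list(vrms_grid = vrms_grid, f_int = f_int,
                 v_rel_um_h = c2 * vrms_grid,
                 predicted_rate = rep(c1 * c2, length(vrms_grid)),
                 calibration = calibration),
            class = "null_model_prediction")
}

#' Test the dependence of the T1 rate on tissue motility
#'
#' Ordinary least-squares regression of `R_T1` on `V_rms` over time-aligned
#' paired observations, with a seeded pairs bootstrap: a percentile CI for
#' the slope and a studentized (percentile-t) two-sided p-value against zero
#' slope using heteroskedasticity-robust standard errors (rate bins are
#' Poisson-ish and heteroscedastic, so resampling pairs is preferred over
#' parametric OLS errors, and studentizing keeps the test near nominal size
#' at a few dozen pairs). The rigid-pack null predicts slope 0; a fluid
#' tissue predicts a positive slope. When the residuals are identically zero
#' the relation is exact and the parametric limit (p = 0, or 1 for a zero
#' slope) is reported instead of the bootstrap floor.
#'
#' @param pairs Data frame with columns `vrms` and `rate` (one row per time
#'   bin per movie).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed for the resampling.
#' @param conf Confidence level for the slope CI.
#' @return List of class `rate_speed_relation`: `slope`, `intercept`,
#'   `ci` (length 2), `p_value`, `n_pairs`, `status` (`"ok"` or
#'   `"degenerate"`), `boot_slopes`.
#' @export
rate_speed_test <- function(pairs, n_boot = 2000L, seed = 1L, conf = 0.95) {
  stopifnot(all(c("vrms", "rate") %in% names(pairs)))
  pairs <- pairs[is.finite(pairs$vrms) & is.finite(pairs$rate), ]
  n <- nrow(pairs)
  if (n < 5L) {
    stop_epijam("need at least 5 (V_rms, R_T1) pairs, got ", n,
                class = "epijam_empty_input")
  }
  if (stats::var(pairs$vrms) <= (1e-10 * mean(abs(pairs$vrms)))^2) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          ci = c(NA_real_, NA_real_), p_value = NA_real_,
                          n_pairs = n, status = "degenerate",
                          boot_slopes = numeric(0)),
                     class = "rate_speed_relation"))
  }
  x <- pairs$vrms; y <- pairs$rate
  # slope + heteroskedasticity-robust (HC1) standard error
  slope_se <- function(xs, ys) {
    dx <- xs - mean(xs)
    sxx <- sum(dx^2)
    b <- sum(dx * ys) / sxx
    e <- ys - (mean(ys) - b * mean(xs)) - b * xs
    m <- length(xs)
    c(b, sqrt(sum(dx^2 * e^2) / sxx^2 * m / (m - 2)))
  }
  bs <- slope_se(x, y)
  b <- bs[1L]
  a <- mean(y) - b * mean(x)
  resid <- y - (a + b * x)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[idx]) == 0) return(c(NA_real_, NA_real_))
      b2 <- slope_se(x[idx], y[idx])
      c(b2[1L], if (b2[2L] > 0) (b2[1L] - b) / b2[2L] else NA_real_)
    }, numeric(2L))
  })
  slopes <- boot[1L, ][is.finite(boot[1L, ])]
  tstar <- boot[2L, ][is.finite(boot[2L, ])]
  alpha <- 1 - conf
  ci <- stats::quantile(slopes, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  if (sum(resid^2) < 1e-28 * max(1, sum(y^2)) || bs[2L] == 0 ||
      !length(tstar)) {
    # exact linear relation: parametric limit
    p <- if (b == 0) 1 else 0
  } else {
    # studentized (percentile-t) pairs bootstrap, two-sided
    t_obs <- b / bs[2L]
    p <- (sum(abs(tstar) >= abs(t_obs)) + 1) / (length(tstar) + 1)
  }
  structure(list(slope = b, intercept = a, se_robust = bs[2L], ci = ci,
                 p_value = p, n_pairs = n, status = "ok",
                 boot_slopes = slopes),
            class = "rate_speed_relation")
}

#' @export
print.rate_speed_relation <- function(x, ...) {
  if (x$status == "degenerate") {
    cat("rate_speed_relation: degenerate V_rms variance; test undefined\n")
  } else {
    cat(sprintf("rate_speed_relation: slope %.4g [%.4g, %.4g], p = %.3g, n = %d\n",
                x$slope, x$ci[1L], x$ci[2L], x$p_value, x$n_pairs))
  }
  invisible(x)
}

#' Fit a four-parameter logistic to a marker time course
#'
#' Seeded multi-start nonlinear least squares (Levenberg-Marquardt) of the
#' [sigmoid_4pl()] model. The half-maximal time is optimized on the log
#' scale, which makes the fit exactly equivariant under rescaling of the
#' time axis; starting values are taken from the data (value range for the
#' asymptotes, time quantiles for `ec50`, a small grid for `hill`). Returns
#' the best converged fit or a flagged failure.
#'
#' @param series A `sigmoid_series` or any data frame with `time_h`,
#'   `value`.
#' @param hill_starts Grid of Hill-slope starting values.
#' @param ec50_quantiles Time quantiles used as `ec50` starts.
#' @return List of class `sigmoid_fit`: `bottom`, `top`, `logec50_h`,
#'   `hill`, `residual_sd`, `converged`, `extrapolated` (EC50 outside the
#'   observed time range), `n_points`.
#' @export
fit_sigmoid <- function(series, hill_starts = c(1, 2, 4, 8, 16),
                        ec50_quantiles = c(0.25, 0.5, 0.75)) {
  stopifnot(all(c("time_h", "value") %in% names(series)))
  t <- series$time_h; y <- series$value
  if (length(t) < 6L) {
    stop_epijam("need at least 6 points for a 4PL fit",
                class = "epijam_empty_input")
  }
  if (any(t <= 0)) {
    stop_epijam("4PL fit requires strictly positive times",
                class = "epijam_invalid_config")
  }
  if (stats::sd(y) == 0) {
    stop_epijam("constant series: 4PL fit is undefined",
                class = "epijam_degenerate_series")
  }
  lt <- log(t)
  model <- function(p) p[1L] + (p[2L] - p[1L]) / (1 + exp(p[4L] * (p[3L] - lt)))
  best <- NULL
  rng <- range(y)
  increasing <- stats::cor(t, y) >= 0
  for (hq in hill_starts) {
    for (q in ec50_quantiles) {
      start <- list(bottom = if (increasing) rng[1L] else rng[2L],
                    top = if (increasing) rng[2L] else rng[1L],
                    lec = as.numeric(stats::quantile(lt, q)),
                    hill = hq)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + exp(hill * (lec - lt))),
          start = start,
          control = minpack.lm::nls.lm.control(maxiter = 200L),
          data = data.frame(y = y, lt = lt)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || ss < best$ss - 1e-12 * max(1, best$ss)) {
        best <- list(fit = fit, ss = ss)
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(bottom = NA_real_, top = NA_real_,
                          logec50_h = NA_real_, hill = NA_real_,
                          residual_sd = NA_real_, converged = FALSE,
                          extrapolated = NA, n_points = length(t)),
                     class = "sigmoid_fit"))
  }
  cf <- stats::coef(best$fit)
  ec50 <- exp(unname(cf["lec"]))
  structure(list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                 logec50_h = ec50, hill = unname(cf["hill"]),
                 residual_sd = sqrt(best$ss / max(1L, length(t) - 4L)),
                 converged = TRUE,
                 extrapolated = ec50 < min(t) || ec50 > max(t),
                 n_points = length(t)),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("sigmoid_fit: no start converged\n")
  } else {
    cat(sprintf("sigmoid_fit: bottom %.4g, top %.4g, LogEC50 %.4g h, hill %.4g (resid SD %.3g)%s\n",
                x$bottom, x$top, x$logec50_h, x$hill, x$residual_sd,
                if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  }
  invisible(x)
}

#' Motility-onset change-point estimation
#'
#' Fits a continuous two-segment piecewise-linear model to a V_rms time
#' course by exhaustive grid search of the breakpoint over interior observed
#' times, and estimates a confidence interval for the breakpoint by a seeded
#' residual bootstrap. A change point is only declared when the two-segment
#' fit improves on the single straight line (partial F-test); otherwise the
#' series is flagged as having no detectable onset. The estimate is
#' invariant under adding a constant to the series.
#'
#' @param time_h,value The series (>= 10 points).
#' @param n_boot Residual-bootstrap replicates for the CI.
#' @param seed Integer seed.
#' @param margin Number of points excluded at each end of the breakpoint
#'   grid.
#' @param alpha Significance level of the improvement F-test.
#' @return List of class `change_point`: `onset_h`, `slope_pre`,
#'   `slope_post`, `ci_h`, `status` (`"ok"`, `"no_change_point"`,
#'   `"boundary"`), `p_improvement`.
#' @export
detect_onset <- function(time_h, value, n_boot = 500L, seed = 1L,
                         margin = 3L, alpha = 0.05) {
  stopifnot(length(time_h) == length(value))
  n <- length(time_h)
  if (n < 10L) {
    stop_epijam("need at least 10 points for onset detection",
                class = "epijam_empty_input")
  }
  ord <- order(time_h)
  t <- time_h[ord]; y <- value[ord]
  fit_at <- function(tau, yy) {
    X <- cbind(1, t - tau, pmax(t - tau, 0))
    qr_x <- qr(X)
    beta <- qr.coef(qr_x, yy)
    beta[is.na(beta)] <- 0
    res <- yy - X %*% beta
    list(beta = beta, sse = sum(res^2))
  }
  grid <- t[(margin + 1L):(n - margin)]
  grid <- unique(grid)
  best_tau <- function(yy) {
    sses <- vapply(grid, function(tau) fit_at(tau, yy)$sse, numeric(1L))
    grid[which.min(sses)]
  }
  tau <- best_tau(y)
  fb <- fit_at(tau, y)
  # single-line reference
  X1 <- cbind(1, t)
  res1 <- y - X1 %*% qr.coef(qr(X1), y)
  sse1 <- sum(res1^2)
  df2 <- n - 4L  # intercept, two slopes, breakpoint
  if (fb$sse <= 0 && sse1 <= 0) {
    p_imp <- 1
  } else if (fb$sse == 0) {
    p_imp <- 0
  } else {
    f_stat <- ((sse1 - fb$sse) / 2) / (fb$sse / df2)
    p_imp <- stats::pf(f_stat, 2, df2, lower.tail = FALSE)
  }
  slope_pre <- unname(fb$beta[2L])
  slope_post <- unname(fb$beta[2L] + fb$beta[3L])
  if (p_imp > alpha) {
    return(structure(list(onset_h = NA_real_, slope_pre = slope_pre,
                          slope_post = slope_post,
                          ci_h = c(NA_real_, NA_real_),
                          status = "no_change_point", p_improvement = p_imp),
                     class = "change_point"))
  }
  status <- if (tau == grid[1L] || tau == grid[length(grid)]) {
    "boundary"
  } else "ok"
  yhat <- y - (y - cbind(1, t - tau, pmax(t - tau, 0)) %*% fit_at(tau, y)$beta)
  resid <- as.vector(y - yhat)
  ci <- with_seed(seed, {
    taus <- vapply(seq_len(n_boot), function(i) {
      yb <- as.vector(yhat) + sample(resid, n, replace = TRUE)
      best_tau(yb)
    }, numeric(1L))
    stats::quantile(taus, c(0.025, 0.975), names = FALSE)
  })
  structure(list(onset_h = tau, slope_pre = slope_pre,
                 slope_post = slope_post, ci_h = ci, status = status,
                 p_improvement = p_imp),
            class = "change_point")
}

#' @export
print.change_point <- function(x, ...) {
  if (x$status == "no_change_point") {
    cat("change_point: no detectable onset (p =", signif(x$p_improvement, 3),
        ")\n")
  } else {
    cat(sprintf("change_point: onset %.3g h [%.3g, %.3g] (%s), slopes %.3g -> %.3g\n",
                x$onset_h, x$ci_h[1L], x$ci_h[2L], x$status, x$slope_pre,
                x$slope_post))
  }
  invisible(x)
}
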
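#' Fit the power law tau ~ q^-n
#'
#' Ordinary least squares of log tau on log q over the pairs inside
#' `q_range`. For translational diffusion probed at wave vector q, tau is the
#' time to cover a distance ~ 2 pi / q, so MSD ~ t^(2/n) and the
#' sub-diffusion exponent is beta = 2/n (n = 2 is Fickian; n > 2 signals
#' sub-diffusion).
#'
#' @param taus data.frame with columns `q` (inverse Angstrom) and `tau` (ps),
#'   e.g. the output of [fit_cole_cole_all()]
#' @param q_range optional c(lo, hi) restricting the fit; default all pairs
#' @return an object of class `scaling_result`: list with `n`, `beta` = 2/n,
#'   `q_range`, `n_se` (standard error of n), `r_squared`, `n_points`
#' @examples
#' fit_power_law_tau_q(data.frame(q = c(0.5, 1, 2), tau = 4 / c(0.5, 1, 2)^2))
#' @export
fit_power_law_tau_q <- function(taus, q_range = NULL) {
  .assert(is.data.frame(taus) && all(c("q", "tau") %in% names(taus)),
          "taus must be a data.frame with columns q and tau")
  keep <- rep(TRUE, nrow(taus))
  if (!is.null(q_range))
    keep <- taus$q >= q_range[1] & taus$q <= q_range[2]
  q <- taus$q[keep]; tau <- taus$tau[keep]
  .assert(all(q > 0) && all(tau > 0), "q and tau must be positive",
          "hydrosub_domain_error")
  .assert(length(q) >= 3, "need at least 3 (q, tau) pairs in range",
          "hydrosub_data_error")
  fit <- stats::lm(log(tau) ~ log(q))
  sm <- .quiet_perfect_fit(summary(fit))
  n <- -unname(stats::coef(fit)[2])
  .assert(n > 0, "fitted exponent n must be positive (tau must fall with q)",
          "hydrosub_fit_error")
  structure(list(n = n, beta = 2 / n,
                 q_range = if (is.null(q_range)) range(q) else q_range,
                 n_se = unname(sm$coefficients[2, 2]),
                 r_squared = sm$r.squared, n_points = length(q)),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf(
    "<scaling_result> n = %.3f +/- %.3f (R^2 = %.4f, %d points, q in [%g, %g]) -> beta = 2/n = %.3f\n",
    x$n, x$n_se, x$r_squared, x$n_points, x$q_range[1], x$q_range[2],
    x$beta))
  invisible(x)
}

#' Sub-diffusion exponent from the q-scaling exponent
#'
#' @param n power-law exponent in tau ~ q^-n, > 0
#' @return beta = 2 / n
#' @export
beta_from_n <- function(n) {
  .assert(all(n > 0), "n must be > 0", "hydrosub_domain_error")
  2 / n
}

#' Mean-squared displacement of a trajectory
#'
#' For a uniformly sampled trajectory, averages |r(t0 + lag) - r(t0)|^2 over
#' all particles and over time origins t0 stepped by `origin_stride` (origins
#' are subsampled beyond `max_origins` per lag to bound cost). For a
#' non-uniform (e.g. log-spaced) grid, the ensemble MSD from the first frame
#' is returned, which is the natural quantity for aging random walks.
#'
#' @param traj a [trajectory]
#' @param lags integer frame offsets to evaluate (uniform grids only);
#'   default: every offset up to 50 frames, then log-spaced
#' @param origin_stride origin subsampling step in frames
#' @param max_origins cap on the number of origins per lag
#' @return an object of class `msd_curve`: data.frame with columns `lag`
#'   (ps), `msd` (Angstrom^2) and `n_origins`; includes the lag-0 row
#' @export
compute_msd <- function(traj, lags = NULL, origin_stride = 1L,
                        max_origins = 10000L) {
  .assert(inherits(traj, "trajectory"), "traj must be a trajectory")
  nt <- length(traj$times)
  .assert(nt >= 2, "need at least 2 frames", "hydrosub_data_error")
  dt <- diff(traj$times)
  uniform <- diff(range(dt)) <= 1e-9 * mean(dt)

  if (!uniform) {
    d <- traj$coords[-1, , , drop = FALSE]
    o <- traj$coords[rep(1L, nt - 1L), , , drop = FALSE]
    msd <- apply((d - o)^2, 1, sum) / dim(traj$coords)[2]
    out <- data.frame(lag = c(0, traj$times[-1] - traj$times[1]),
                      msd = c(0, msd),
                      n_origins = 1L)
    class(out) <- c("msd_curve", "data.frame")
    return(out)
  }

  if (is.null(lags)) {
    lags <- unique(c(seq_len(min(50L, nt - 1L)),
                     round(logspace(1, nt - 1L, 64))))
    lags <- sort(lags[lags >= 1 & lags <= nt - 1L])
  }
  .assert(all(lags >= 1) && all(lags <= nt - 1L),
          "lag exceeds trajectory span", "hydrosub_data_error")
  np <- dim(traj$coords)[2]
  step <- mean(dt)
  rows <- lapply(lags, function(k) {
    origins <- seq.int(1L, nt - k, by = origin_stride)
    if (length(origins) > max_origins)
      origins <- origins[round(seq(1, length(origins),
                                   length.out = max_origins))]
    d <- traj$coords[origins + k, , , drop = FALSE] -
      traj$coords[origins, , , drop = FALSE]
    data.frame(lag = k * step, msd = sum(d^2) / (length(origins) * np),
               n_origins = length(origins))
  })
  out <- rbind(data.frame(lag = 0, msd = 0, n_origins = nt),
               do.call(rbind, rows))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the MSD power-law exponent
#'
#' Least squares of log MSD on log lag restricted to a time window; the slope
#' is the anomalous diffusion exponent beta in MSD ~ t^beta (beta = 1 is
#' Brownian, beta < 1 sub-diffusive).
#'
#' @param msd an `msd_curve` (or data.frame with columns lag, msd)
#' @param window c(t_lo, t_hi) fit window in ps; default 5-1000 ps
#' @return fitted exponent beta (numeric scalar) with attributes `se` and
#'   `n_points`
#' @export
fit_msd_exponent <- function(msd, window = c(5, 1000)) {
  .assert(is.data.frame(msd) && all(c("lag", "msd") %in% names(msd)),
          "msd must have columns lag and msd")
  keep <- msd$lag >= window[1] & msd$lag <= window[2] & msd$lag > 0 &
    msd$msd > 0
  .assert(sum(keep) >= 3, "need at least 3 positive MSD points in window",
          "hydrosub_data_error")
  fit <- stats::lm(log(msd$msd[keep]) ~ log(msd$lag[keep]))
  beta <- unname(stats::coef(fit)[2])
  attr(beta, "se") <- unname(
    .quiet_perfect_fit(summary(fit))$coefficients[2, 2])
  attr(beta, "n_points") <- sum(keep)
  beta
}

#' Average the Cole-Cole heterogeneity parameter over a q band
#'
#' Unweighted mean of alpha over converged fits with q inside `q_range`
#' (default the 0.7-1.5 inverse-Angstrom band over which spectra probe
#' single-molecule translation).
#'
#' @param fits data.frame with columns q, alpha and (optionally) converged,
#'   e.g. from [fit_cole_cole_all()]
#' @param q_range c(lo, hi) in inverse Angstrom, inclusive
#' @return mean alpha (scalar)
#' @export
average_alpha <- function(fits, q_range = c(0.7, 1.5)) {
  .assert(is.data.frame(fits) && all(c("q", "alpha") %in% names(fits)),
          "fits must have columns q and alpha")
  conv <- if ("converged" %in% names(fits)) fits$converged else TRUE
  keep <- conv & fits$q >= q_range[1] & fits$q <= q_range[2]
  .assert(any(keep), "no converged fits inside q_range",
          "hydrosub_data_error")
  mean(fits$alpha[keep])
}

#' Bulk-like water fraction at a hydration level
#'
#' The first two hydration layers bind about 1.2 g water per gram of protein;
#' water beyond that behaves bulk-like. At hydration level h (g water / g
#' protein) the bulk-like fraction is max(0, (h - bound_water) / h).
#'
#' @param h hydration level in g water per g protein, > 0
#' @param bound_water bound (non-bulk-like) water in g/g, >= 0
#' @return fraction in \[0, 1)
#' @examples
#' bulk_like_fraction(2.0)   # 0.40
#' bulk_like_fraction(4.0)   # 0.70
#' @export
bulk_like_fraction <- function(h, bound_water = 1.2) {
  .assert(all(h > 0), "hydration level h must be > 0",
          "hydrosub_domain_error")
  .assert(bound_water >= 0, "bound_water must be >= 0",
          "hydrosub_domain_error")
  pmax(0, (h - bound_water) / h)
}
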
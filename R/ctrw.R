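#' Draw waiting times from a waiting-time model
#'
#' Exponential and Pareto draws use the inverse CDF; the Pareto density is
#' psi(t) = beta t_min^beta t^-(1+beta) on \[t_min, Inf). Empirical models
#' pick a bin with probability proportional to its mass and draw log-uniform
#' within the bin (bins are log-spaced, so this avoids mass pile-up at bin
#' edges).
#'
#' @param model a [waiting_model]
#' @param n number of draws
#' @return waiting times in ps
#' @export
sample_waiting_time <- function(model, n = 1L) {
  .assert(inherits(model, "waiting_model"), "model must be a waiting_model",
          "hydrosub_domain_error")
  switch(model$kind,
    exponential = stats::rexp(n, rate = 1 / model$mean),
    pareto = model$t_min * stats::runif(n)^(-1 / model$tail_exponent),
    empirical = {
      d <- model$distribution
      k <- length(d$mass)
      bin <- sample.int(k, n, replace = TRUE, prob = d$mass)
      lo <- d$edges[bin]; hi <- d$edges[bin + 1L]
      exp(stats::runif(n, log(lo), log(hi)))
    })
}

#' Simulate the coarse-grained random-jump (RJ) model
#'
#' A particle performs a one-dimensional random jump of constant length l0,
#' going forwards or backwards with equal probability, with the residence
#' time between adjacent sites drawn from the waiting-time model (for an
#' empirical model, from an extracted P(tau_res)). Time is event-driven: the
#' position is held between jumps and sampled on the observation grid. The
#' ensemble MSD over the observation times is fitted for the sub-diffusion
#' exponent beta on `msd_window`.
#'
#' @param model a [waiting_model]
#' @param step_length jump length l0 in Angstrom
#' @param n_particles number of walkers
#' @param t_max simulated time span in ps
#' @param seed integer seed
#' @param obs_times observation grid; default [default_observation_times()]
#' @param msd_window c(t_lo, t_hi) in ps for the beta fit
#' @return an object of class `rj_result`: list with `msd` (an `msd_curve`),
#'   `beta`, `n_jumps` (summary of jumps per particle), `degenerate` (TRUE
#'   when no particle jumped within `t_max`), and the configuration
#' @export
simulate_rj <- function(model, step_length = 3.5, n_particles = 1000L,
                        t_max = 2000, seed = 1L, obs_times = NULL,
                        msd_window = c(5, 1000)) {
  if (is.null(obs_times)) obs_times <- default_observation_times(t_max)
  traj <- gen_ctrw_trajectories(model, step_length = step_length,
                                n_particles = n_particles, t_max = t_max,
                                dims = 1L, seed = seed,
                                obs_times = obs_times, store_events = TRUE)
  events <- attr(traj, "events")
  n_jumps <- vapply(events, function(e) length(e$times), integer(1))
  degenerate <- all(n_jumps == 0L)
  msd <- compute_msd_ensemble(traj)
  beta <- if (degenerate) NA_real_ else
    tryCatch(as.numeric(fit_msd_exponent(msd, msd_window)),
             error = function(e) NA_real_)
  structure(list(msd = msd, beta = beta,
                 n_jumps = summary(n_jumps), degenerate = degenerate,
                 model = model, step_length = step_length,
                 n_particles = n_particles, t_max = t_max, seed = seed,
                 msd_window = msd_window),
            class = "rj_result")
}

#' @export
print.rj_result <- function(x, ...) {
  cat(sprintf(
    "<rj_result> %d walkers, l0 = %g Angstrom, t_max = %g ps: beta = %.3f%s\n",
    x$n_particles, x$step_length, x$t_max, x$beta,
    if (x$degenerate) " (DEGENERATE: no jumps)" else ""))
  invisible(x)
}

#' Ensemble MSD from the first frame
#'
#' MSD(t) = < |r(t) - r(0)|^2 > over particles, evaluated at every
#' observation time. This is the quantity the RJ model predicts; unlike the
#' origin-averaged MSD it is well defined for aging (heavy-tailed) walks.
#'
#' @param traj a [trajectory]
#' @return an `msd_curve` data.frame (lag ps, msd Angstrom^2, n_origins = 1)
#' @export
compute_msd_ensemble <- function(traj) {
  .assert(inherits(traj, "trajectory"), "traj must be a trajectory")
  nt <- length(traj$times)
  np <- dim(traj$coords)[2]
  o <- traj$coords[rep(1L, nt), , , drop = FALSE]
  msd <- apply((traj$coords - o)^2, 1, sum) / np
  out <- data.frame(lag = traj$times - traj$times[1], msd = msd,
                    n_origins = 1L)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Sub-diffusion exponent across a series of waiting-time models
#'
#' Runs [simulate_rj()] once per model with a shared configuration (same
#' seed, walker count, step length and window) and tabulates the fitted
#' betas in input order. Heavier-tailed waiting-time distributions yield
#' smaller beta.
#'
#' @param models list of [waiting_model]s (length >= 2)
#' @param ... shared configuration passed to [simulate_rj()]
#' @return data.frame with columns `model` (description) and `beta`
#' @export
beta_vs_distribution <- function(models, ...) {
  .assert(is.list(models) && length(models) >= 1,
          "models must be a non-empty list")
  rows <- lapply(models, function(m) {
    res <- simulate_rj(m, ...)
    data.frame(model = utils::capture.output(print(m)), beta = res$beta)
  })
  do.call(rbind, rows)
}
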
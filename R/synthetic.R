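#' Specification of synthetic Cole-Cole spectra
#'
#' Declares the ground truth for a synthetic susceptibility (or raw
#' structure-factor) dataset: one Cole-Cole triple (tau, alpha, chi0) per wave
#' vector, a common frequency grid, and a multiplicative noise level.
#'
#' @param q_values wave vectors in inverse Angstrom, > 0
#' @param tau relaxation times in ps (> 0), recycled to `length(q_values)`
#' @param alpha shape parameters in \[0, 1), recycled likewise
#' @param chi0 amplitudes (> 0), recycled likewise
#' @param frequencies frequency grid in THz, strictly increasing, > 0
#' @param noise_level relative Gaussian noise fraction, >= 0
#' @param temperature temperature in K (used for the Bose factor when
#'   `output_kind = "structure_factor"`)
#' @param output_kind `"susceptibility"` or `"structure_factor"`
#' @param seed integer seed for the noise draw
#' @return an object of class `spectra_spec`
#' @export
spectra_spec <- function(q_values, tau, alpha, chi0, frequencies,
                         noise_level = 0, temperature = 280,
                         output_kind = c("susceptibility", "structure_factor"),
                         seed = 1L) {
  output_kind <- match.arg(output_kind)
  n <- length(q_values)
  .assert(n >= 1 && all(q_values > 0), "need q values > 0",
          "hydrosub_param_error")
  tau <- rep_len(as.numeric(tau), n)
  alpha <- rep_len(as.numeric(alpha), n)
  chi0 <- rep_len(as.numeric(chi0), n)
  .assert(all(tau > 0), "all tau must be > 0 ps", "hydrosub_param_error")
  .assert(all(alpha >= 0 & alpha < 1), "all alpha must lie in [0, 1)",
          "hydrosub_param_error")
  .assert(all(chi0 > 0), "all chi0 must be > 0", "hydrosub_param_error")
  .assert(all(frequencies > 0) && all(diff(frequencies) > 0),
          "frequency grid must be positive and strictly increasing",
          "hydrosub_grid_error")
  .assert(noise_level >= 0, "noise_level must be >= 0",
          "hydrosub_param_error")
  .assert(temperature > 0, "temperature must be > 0 K",
          "hydrosub_param_error")
  structure(list(q_values = as.numeric(q_values), tau = tau, alpha = alpha,
                 chi0 = chi0, frequencies = as.numeric(frequencies),
                 noise_level = noise_level, temperature = temperature,
                 output_kind = output_kind, seed = as.integer(seed)),
            class = "spectra_spec")
}

#' Spectra spec for a target sub-diffusion exponent
#'
#' Convenience constructor emulating a system whose relaxation-time scaling
#' encodes a chosen sub-diffusion exponent beta*: tau(q) = tau0 * q^(-2/beta*)
#' so that a power-law fit of tau against q recovers n = 2/beta*. The
#' Cole-Cole width is tied to the heterogeneity as alpha = 1 - beta*, making
#' heavier mobility tails (smaller beta*) broader spectra.
#'
#' @param beta_star target sub-diffusion exponent in (0, 1]
#' @param q_values wave vectors (inverse Angstrom)
#' @param tau0 relaxation time at q = 1 (ps)
#' @param chi0 amplitude
#' @param frequencies frequency grid (THz); default spans the relaxation peaks
#' @inheritParams spectra_spec
#' @return a [spectra_spec]
#' @export
subdiffusion_spectra_spec <- function(beta_star,
                                      q_values = seq(0.7, 1.5, by = 0.2),
                                      tau0 = 10, chi0 = 1,
                                      frequencies = NULL, noise_level = 0,
                                      temperature = 280, seed = 1L) {
  .assert(beta_star > 0 && beta_star <= 1, "beta_star must lie in (0, 1]",
          "hydrosub_param_error")
  tau <- tau0 * q_values^(-2 / beta_star)
  if (is.null(frequencies)) {
    nu_peaks <- peak_frequency(tau)
    frequencies <- logspace(min(nu_peaks) / 300, max(nu_peaks) * 300, 200)
  }
  spectra_spec(q_values, tau = tau, alpha = 1 - beta_star, chi0 = chi0,
               frequencies = frequencies, noise_level = noise_level,
               temperature = temperature, seed = seed)
}

#' Generate synthetic Cole-Cole spectra
#'
#' Evaluates the Cole-Cole function at each (q, nu) cell from the spec's
#' per-q triples, applies multiplicative relative Gaussian noise
#' (1 + noise_level * eps), truncated at zero so intensities stay
#' non-negative, and - for structure-factor output - multiplies by the Bose
#' factor so that [to_susceptibility()] inverts the operation exactly. The
#' stored error matrix is noise_level times the noiseless model, i.e. the
#' known one-sigma scale of the applied noise.
#'
#' @param spec a [spectra_spec]
#' @return a [spectrum_grid] with the spec's ground truth attached as
#'   attribute `"truth"` (data.frame q, tau, alpha, chi0)
#' @export
gen_cole_cole_spectra <- function(spec) {
  .assert(inherits(spec, "spectra_spec"), "spec must be a spectra_spec")
  nq <- length(spec$q_values); nf <- length(spec$frequencies)
  clean <- t(vapply(seq_len(nq), function(i)
    cole_cole(spec$frequencies, spec$tau[i], spec$alpha[i], spec$chi0[i]),
    numeric(nf)))
  intensity <- clean
  errors <- NULL
  if (spec$noise_level > 0) {
    eps <- .with_seed(spec$seed, matrix(stats::rnorm(nq * nf), nq, nf))
    intensity <- pmax(clean * (1 + spec$noise_level * eps), 0)
    errors <- spec$noise_level * clean
  }
  if (spec$output_kind == "structure_factor") {
    nb <- matrix(bose_factor(spec$frequencies, spec$temperature),
                 nq, nf, byrow = TRUE)
    intensity <- intensity * nb
    if (!is.null(errors)) errors <- errors * nb
  }
  g <- spectrum_grid(spec$q_values, spec$frequencies, intensity,
                     errors = errors, temperature = spec$temperature,
                     kind = spec$output_kind)
  attr(g, "truth") <- data.frame(q = spec$q_values, tau = spec$tau,
                                 alpha = spec$alpha, chi0 = spec$chi0)
  g
}

#' Waiting-time model for random-jump dynamics
#'
#' Describes the residence-time distribution between jumps: exponential
#' (Poissonian, normal diffusion), Pareto with tail exponent beta in (0, 1]
#' (heavy-tailed, sub-diffusion with MSD ~ t^beta), or an empirical log-binned
#' distribution such as one produced by [residence_distribution()].
#'
#' @param kind `"exponential"`, `"pareto"` or `"empirical"`
#' @param mean mean waiting time in ps (exponential)
#' @param tail_exponent Pareto tail exponent beta in (0, 1]
#' @param t_min Pareto lower cutoff in ps, > 0
#' @param distribution a `residence_distribution` (empirical)
#' @return an object of class `waiting_model`
#' @examples
#' waiting_model("exponential", mean = 5)
#' waiting_model("pareto", tail_exponent = 0.5, t_min = 1)
#' @export
waiting_model <- function(kind = c("exponential", "pareto", "empirical"),
                          mean = NULL, tail_exponent = NULL, t_min = NULL,
                          distribution = NULL) {
  kind <- match.arg(kind)
  m <- switch(kind,
    exponential = {
      .assert(!is.null(mean) && mean > 0, "exponential mean must be > 0 ps",
              "hydrosub_param_error")
      list(kind = kind, mean = mean)
    },
    pareto = {
      .assert(!is.null(t_min) && t_min > 0, "pareto t_min must be > 0 ps",
              "hydrosub_param_error")
      .assert(!is.null(tail_exponent) && tail_exponent > 0 &&
                tail_exponent <= 1,
              "pareto tail_exponent must lie in (0, 1]",
              "hydrosub_param_error")
      list(kind = kind, tail_exponent = tail_exponent, t_min = t_min)
    },
    empirical = {
      .assert(inherits(distribution, "residence_distribution"),
              "empirical model needs a residence_distribution",
              "hydrosub_param_error")
      list(kind = kind, distribution = distribution)
    })
  structure(m, class = "waiting_model")
}

#' @export
print.waiting_model <- function(x, ...) {
  desc <- switch(x$kind,
    exponential = sprintf("exponential(mean = %g ps)", x$mean),
    pareto = sprintf("pareto(beta = %g, t_min = %g ps)", x$tail_exponent,
                     x$t_min),
    empirical = sprintf("empirical(%d bins)", length(x$distribution$mass)))
  cat("<waiting_model>", desc, "\n")
  invisible(x)
}

#' Trajectory container
#'
#' Time-ordered particle coordinates on a shared observation-time grid.
#'
#' @param times observation times in ps, strictly increasing
#' @param coords numeric array `[n_times, n_particles, n_dims]` in Angstrom
#'   (a matrix is accepted for one particle or one dimension)
#' @return an object of class `trajectory`
#' @export
trajectory <- function(times, coords) {
  if (length(dim(coords)) == 2L)
    coords <- array(coords, c(nrow(coords), ncol(coords), 1L))
  .assert(length(dim(coords)) == 3L, "coords must be [time, particle, dim]")
  .assert(dim(coords)[1] == length(times),
          "first coords dimension must match times")
  .assert(all(diff(times) > 0), "times must be strictly increasing")
  structure(list(times = as.numeric(times), coords = coords),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<trajectory> %d frames x %d particles x %dD, t = %g .. %g ps\n",
              d[1], d[2], d[3], min(x$times), max(x$times)))
  invisible(x)
}

#' Default observation-time grid for jump trajectories
#'
#' Log-spaced times from 1 ps to `t_max` (64 points) merged with a uniform
#' fine grid over the first 10 ps, so MSD fits can span decades while early
#' times stay resolved. Always starts at 0.
#'
#' @param t_max trajectory length in ps
#' @param n_log number of log-spaced points
#' @return strictly increasing times in ps, starting at 0
#' @export
default_observation_times <- function(t_max, n_log = 64) {
  .assert(t_max > 0, "t_max must be > 0 ps")
  fine <- seq(0, min(10, t_max), by = 0.25)
  lg <- if (t_max > 1) logspace(1, t_max, n_log) else numeric(0)
  sort(unique(signif(c(fine, lg), 10)))
}

# Draw enough waiting times from `model` to pass t_max; returns the jump
# times (cumulative sums) <= t_max.
.jump_times <- function(model, t_max) {
  mean_wait <- switch(model$kind,
    exponential = model$mean,
    pareto = if (model$tail_exponent > 1) {
      model$t_min * model$tail_exponent / (model$tail_exponent - 1)
    } else model$t_min * 5,  # heavy tail: mean infinite, any guess works
    empirical = sum(model$distribution$mass *
                      sqrt(model$distribution$edges[-1] *
                             utils::head(model$distribution$edges, -1))))
  n_guess <- max(16L, ceiling(1.2 * t_max / mean_wait))
  tj <- cumsum(sample_waiting_time(model, n_guess))
  while (tj[length(tj)] <= t_max) {
    tj <- c(tj, tj[length(tj)] +
              cumsum(sample_waiting_time(model, n_guess)))
  }
  tj[tj <= t_max]
}

#' Generate continuous-time random-walk trajectories
#'
#' Each particle performs jumps of fixed length `step_length` along a
#' uniformly chosen axis direction (one of the 2 * `dims` lattice directions),
#' separated by waiting times drawn independently from `model`
#' (wait-then-jump: the position is held constant between jumps). Positions
#' are reported on the observation grid by holding the position after the
#' last jump at or before each observation time.
#'
#' @param model a [waiting_model]
#' @param step_length jump length l0 in Angstrom, > 0
#' @param n_particles number of independent walkers, >= 1
#' @param t_max trajectory length in ps, > 0
#' @param dims 1 or 3 spatial dimensions
#' @param seed integer seed
#' @param obs_times observation grid (ps); default
#'   [default_observation_times()]
#' @param store_events if TRUE, attach the per-particle jump event log
#'   (times and displacement vectors) as attribute `"events"`
#' @return a [trajectory]
#' @export
gen_ctrw_trajectories <- function(model, step_length, n_particles, t_max,
                                  dims = 1L, seed = 1L, obs_times = NULL,
                                  store_events = FALSE) {
  .assert(inherits(model, "waiting_model"), "model must be a waiting_model")
  .assert(step_length > 0, "step_length must be > 0 Angstrom",
          "hydrosub_param_error")
  .assert(n_particles >= 1, "need n_particles >= 1", "hydrosub_param_error")
  .assert(t_max > 0, "t_max must be > 0 ps", "hydrosub_param_error")
  .assert(dims %in% c(1L, 3L), "dims must be 1 or 3", "hydrosub_param_error")
  if (is.null(obs_times)) obs_times <- default_observation_times(t_max)
  .assert(all(obs_times >= 0) && all(obs_times <= t_max) &&
            all(diff(obs_times) > 0),
          "obs_times must be increasing within [0, t_max]")

  coords <- array(0, c(length(obs_times), n_particles, dims))
  events <- if (store_events) vector("list", n_particles)
  .with_seed(seed, {
    for (p in seq_len(n_particles)) {
      tj <- .jump_times(model, t_max)
      nj <- length(tj)
      if (nj) {
        axis <- sample.int(dims, nj, replace = TRUE)
        sgn <- sample(c(-1, 1), nj, replace = TRUE)
        steps <- matrix(0, nj, dims)
        steps[cbind(seq_len(nj), axis)] <- sgn * step_length
        pos <- apply(steps, 2, cumsum)
        if (nj == 1L) pos <- matrix(pos, 1L)
        idx <- findInterval(obs_times, tj)
        pos0 <- rbind(rep(0, dims), pos)
        coords[, p, ] <- pos0[idx + 1L, ]
        if (store_events) events[[p]] <- list(times = tj, steps = steps)
      } else if (store_events) {
        events[[p]] <- list(times = numeric(0),
                            steps = matrix(0, 0, dims))
      }
    }
  })
  tr <- trajectory(obs_times, coords)
  if (store_events) attr(tr, "events") <- events
  tr
}

#' Generate layer-dependent trajectories above a planar surface
#'
#' Emulates hydration-layer-dependent mobility: particles move in the 3-D
#' half-space z >= 0 with fixed-length lattice jumps, but the waiting-time
#' model for the next jump is selected by the particle's current hydration
#' layer, `floor(z / layer_thickness) + 1` (particles beyond the last listed
#' layer use the final model, representing bulk). The surface at z = 0 is
#' reflecting.
#'
#' @param layer_models list of [waiting_model]s, one per layer, nearest
#'   surface first; the last entry applies to all deeper layers
#' @param layer_thickness layer thickness in Angstrom (3.5 Angstrom is the
#'   first coordination-shell radius of water)
#' @param step_length jump length in Angstrom
#' @param n_particles number of walkers
#' @param t_max trajectory length in ps
#' @param seed integer seed
#' @param obs_times observation grid; default [default_observation_times()]
#' @param z_init starting heights (Angstrom): scalar or vector recycled over
#'   particles; default uniform over the modelled layers
#' @return a [trajectory] with 3 dimensions (x, y, z)
#' @export
gen_layered_trajectories <- function(layer_models, layer_thickness = 3.5,
                                     step_length = 3.5, n_particles, t_max,
                                     seed = 1L, obs_times = NULL,
                                     z_init = NULL) {
  .assert(is.list(layer_models) && length(layer_models) >= 1,
          "need at least one layer model", "hydrosub_config_error")
  lapply(layer_models, function(m)
    .assert(inherits(m, "waiting_model"), "layer models must be waiting_model",
            "hydrosub_config_error"))
  .assert(layer_thickness > 0, "layer_thickness must be > 0 Angstrom",
          "hydrosub_param_error")
  .assert(step_length > 0, "step_length must be > 0", "hydrosub_param_error")
  if (is.null(obs_times)) obs_times <- default_observation_times(t_max)
  n_layers <- length(layer_models)

  coords <- array(0, c(length(obs_times), n_particles, 3L))
  .with_seed(seed, {
    z0 <- if (is.null(z_init)) {
      stats::runif(n_particles, 0, n_layers * layer_thickness)
    } else rep_len(z_init, n_particles)
    .assert(all(z0 >= 0), "starting heights must be >= 0",
            "hydrosub_geometry_error")
    for (p in seq_len(n_particles)) {
      pos <- c(0, 0, z0[p])
      t_now <- 0
      oi <- 1L
      n_obs <- length(obs_times)
      repeat {
        layer <- min(floor(pos[3] / layer_thickness) + 1L, n_layers)
        wait <- sample_waiting_time(layer_models[[layer]], 1L)
        t_next <- t_now + wait
        while (oi <= n_obs && obs_times[oi] < t_next) {
          coords[oi, p, ] <- pos
          oi <- oi + 1L
        }
        if (t_next > t_max || oi > n_obs) break
        ax <- sample.int(3L, 1L)
        pos[ax] <- pos[ax] + sample(c(-1, 1), 1L) * step_length
        if (pos[3] < 0) pos[3] <- -pos[3]  # reflecting surface
        t_now <- t_next
      }
      while (oi <= n_obs) {
        coords[oi, p, ] <- pos
        oi <- oi + 1L
      }
    }
  })
  trajectory(obs_times, coords)
}

#' Write a trajectory as delimited text
#'
#' Long format, tab separated, columns time (ps), particle_id, x, y, z
#' (Angstrom; unused dimensions written as 0).
#'
#' @param traj a [trajectory]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  .assert(inherits(traj, "trajectory"), "traj must be a trajectory")
  d <- dim(traj$coords)
  get_dim <- function(k) if (k <= d[3]) as.vector(traj$coords[, , k]) else 0
  df <- data.frame(time = rep(traj$times, times = d[2]),
                   particle_id = rep(seq_len(d[2]), each = d[1]),
                   x = get_dim(1), y = get_dim(2), z = get_dim(3))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory from delimited text
#'
#' @param path file written by [write_trajectory()]
#' @param dims number of spatial dimensions to keep (trailing all-zero
#'   columns are dropped when NULL)
#' @return a [trajectory]
#' @export
read_trajectory <- function(path, dims = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  times <- sort(unique(df$time))
  ids <- sort(unique(df$particle_id))
  if (is.null(dims)) {
    dims <- 3L
    if (all(df$z == 0)) dims <- 2L
    if (dims == 2L && all(df$y == 0)) dims <- 1L
  }
  coords <- array(0, c(length(times), length(ids), dims))
  ti <- match(df$time, times); pi <- match(df$particle_id, ids)
  cols <- c("x", "y", "z")[seq_len(dims)]
  for (k in seq_len(dims)) coords[cbind(ti, pi, k)] <- df[[cols[k]]]
  trajectory(times, coords)
}
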
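# Independent brute-force oracles used to cross-check the implementation.

# Naive frame-by-frame sequential first-passage scan. Same convention as
# residence_times (trailing interval censored) but written as a direct scan
# with no chunking or vectorisation.
oracle_residence <- function(traj, threshold) {
  nt <- length(traj$times)
  np <- dim(traj$coords)[2]
  samples <- numeric(0)
  censored <- 0L
  for (p in seq_len(np)) {
    ref <- 1L
    found_end <- FALSE
    while (!found_end) {
      hit <- NA_integer_
      j <- ref + 1L
      while (j <= nt) {
        disp2 <- sum((traj$coords[j, p, ] - traj$coords[ref, p, ])^2)
        if (disp2 >= threshold^2) { hit <- j; break }
        j <- j + 1L
      }
      if (is.na(hit)) {
        censored <- censored + 1L
        found_end <- TRUE
      } else {
        samples <- c(samples, traj$times[hit] - traj$times[ref])
        ref <- hit
        if (ref >= nt) { censored <- censored + 1L; found_end <- TRUE }
      }
    }
  }
  list(samples = samples, censored = censored)
}

# Double loop over every origin/lag pair on a uniform grid.
oracle_msd <- function(traj, lags, origin_stride = 1L) {
  nt <- length(traj$times)
  np <- dim(traj$coords)[2]
  dt <- traj$times[2] - traj$times[1]
  vapply(lags, function(k) {
    origins <- seq.int(1L, nt - k, by = origin_stride)
    total <- 0
    for (o in origins) {
      for (p in seq_len(np)) {
        total <- total + sum((traj$coords[o + k, p, ] -
                                traj$coords[o, p, ])^2)
      }
    }
    total / (length(origins) * np)
  }, numeric(1))
}

# Exact outcome distribution of a 1-D random jump with two equally likely
# deterministic waiting times, observed at time t_obs: enumerates every wait
# sequence prefix that crosses t_obs and convolves with the binomial sign
# distribution. Returns P(position = l0 * j) indexed by displacement j.
oracle_rj_pmf <- function(wait_values, t_obs, l0 = 1) {
  pmf_jumps <- new.env(parent = emptyenv())
  add <- function(n, p) {
    key <- as.character(n)
    prev <- if (!is.null(pmf_jumps[[key]])) pmf_jumps[[key]] else 0
    pmf_jumps[[key]] <- prev + p
  }
  recurse <- function(t_now, n_jumps, prob) {
    # next wait: if every continuation exceeds t_obs the count is final
    if (t_now + min(wait_values) > t_obs) {
      add(n_jumps, prob)
      return(invisible(NULL))
    }
    for (w in wait_values) {
      if (t_now + w > t_obs) add(n_jumps, prob / length(wait_values))
      else recurse(t_now + w, n_jumps + 1L, prob / length(wait_values))
    }
  }
  recurse(0, 0L, 1)
  counts <- sort(as.integer(ls(pmf_jumps)))
  pos_pmf <- new.env(parent = emptyenv())
  for (n in counts) {
    pn <- pmf_jumps[[as.character(n)]]
    for (k in 0:n) {  # k positive steps out of n
      x <- 2L * k - n
      key <- as.character(x)
      prev <- if (!is.null(pos_pmf[[key]])) pos_pmf[[key]] else 0
      pos_pmf[[key]] <- prev + pn * stats::dbinom(k, n, 0.5)
    }
  }
  xs <- sort(as.integer(ls(pos_pmf)))
  stats::setNames(vapply(as.character(xs), function(k) pos_pmf[[k]],
                         numeric(1)), xs * l0)
}

# Random lattice-walk trajectory on a uniform grid (for oracle comparisons).
make_lattice_traj <- function(n_frames, n_particles, dims = 1L, step = 1,
                              dt = 1, seed = 1L) {
  set.seed(seed)
  coords <- array(0, c(n_frames, n_particles, dims))
  for (p in seq_len(n_particles)) {
    ax <- sample.int(dims, n_frames - 1L, replace = TRUE)
    sg <- sample(c(-1, 1), n_frames - 1L, replace = TRUE)
    steps <- matrix(0, n_frames - 1L, dims)
    steps[cbind(seq_len(n_frames - 1L), ax)] <- sg * step
    coords[, p, ] <- rbind(rep(0, dims), apply(steps, 2, cumsum))
  }
  trajectory(dt * (seq_len(n_frames) - 1) + dt, coords)
}

# Narrow-bin empirical waiting model whose draws are (numerically) the
# given support values with the given masses.
point_mass_model <- function(values, masses = NULL) {
  if (is.null(masses)) masses <- rep(1 / length(values), length(values))
  eps <- 1e-9
  edges <- as.vector(rbind(values * (1 - eps), values * (1 + eps)))
  mass <- numeric(2 * length(values) - 1)
  mass[seq(1, by = 2, length.out = length(values))] <- masses
  dist <- structure(list(edges = edges, mass = mass, n = NA_integer_),
                    class = "residence_distribution")
  waiting_model("empirical", distribution = dist)
}
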
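#' Extract residence times by sequential first passage
#'
#' The residence time tau_res of a particle is the time it needs to move a
#' threshold distance (3.5 Angstrom by default, the radius of water's first
#' coordination shell) from a reference position. The scan is sequential: the
#' reference starts at the first frame; when the Euclidean displacement from
#' the reference first reaches the threshold, the elapsed time is recorded as
#' one sample, the reference resets to the current position, and the scan
#' continues. The final incomplete interval is counted as censored and
#' excluded from the samples.
#'
#' @param traj a [trajectory]
#' @param threshold displacement threshold in Angstrom, > 0
#' @param layers optional integer matrix `[n_frames, n_particles]` of layer
#'   labels (e.g. from [assign_layers()]); each sample is then labelled with
#'   the layer at its interval's starting frame
#' @return an object of class `residence_set`: list with `samples` (ps),
#'   `censored_count`, `threshold` and optional `layer` labels per sample
#' @export
residence_times <- function(traj, threshold = 3.5, layers = NULL) {
  .assert(inherits(traj, "trajectory"), "traj must be a trajectory")
  .assert(threshold > 0, "threshold must be > 0 Angstrom",
          "hydrosub_domain_error")
  nt <- length(traj$times)
  .assert(nt >= 2, "single-frame trajectory has no residence intervals",
          "hydrosub_data_error")
  np <- dim(traj$coords)[2]
  if (!is.null(layers))
    .assert(all(dim(layers) == c(nt, np)),
            "layers must be a [n_frames, n_particles] matrix")
  thr2 <- threshold^2
  samples <- vector("list", np)
  labels <- vector("list", np)
  censored <- 0L
  chunk <- 64L  # scan ahead in blocks; passages are usually local in time
  for (p in seq_len(np)) {
    pos <- matrix(traj$coords[, p, ], nrow = nt)
    nd <- ncol(pos)
    ref <- 1L
    s <- numeric(0)
    l <- integer(0)
    repeat {
      if (ref >= nt) { censored <- censored + 1L; break }
      j <- NA_integer_
      from <- ref + 1L
      while (from <= nt) {
        to <- min(from + chunk - 1L, nt)
        d2 <- rowSums((pos[from:to, , drop = FALSE] -
                         matrix(pos[ref, ], to - from + 1L, nd,
                                byrow = TRUE))^2)
        hit <- which(d2 >= thr2)
        if (length(hit)) { j <- from + hit[1] - 1L; break }
        from <- to + 1L
      }
      if (is.na(j)) { censored <- censored + 1L; break }
      s <- c(s, traj$times[j] - traj$times[ref])
      if (!is.null(layers)) l <- c(l, layers[ref, p])
      ref <- j
    }
    samples[[p]] <- s
    labels[[p]] <- l
  }
  structure(list(samples = unlist(samples), censored_count = censored,
                 threshold = threshold,
                 layer = if (!is.null(layers)) unlist(labels)),
            class = "residence_set")
}

#' @export
print.residence_set <- function(x, ...) {
  cat(sprintf(
    "<residence_set> %d samples (threshold %g Angstrom), %d censored\n",
    length(x$samples), x$threshold, x$censored_count))
  invisible(x)
}

#' Log-binned residence-time distribution
#'
#' Probability mass function of residence times on logarithmically spaced
#' bins spanning the sample range.
#'
#' @param rts a `residence_set` (or numeric vector of residence times, ps)
#' @param bins_per_decade number of bins per factor of 10 in time
#' @return an object of class `residence_distribution`: list with `edges`
#'   (ps, strictly increasing), `mass` (sums to 1) and `n` (sample count)
#' @export
residence_distribution <- function(rts, bins_per_decade = 10) {
  x <- if (inherits(rts, "residence_set")) rts$samples else as.numeric(rts)
  .assert(length(x) >= 1, "no residence samples", "hydrosub_data_error")
  .assert(all(x > 0), "residence times must be positive")
  lo <- min(x); hi <- max(x)
  if (hi / lo < 1 + 1e-12) {
    half <- 0.5 / bins_per_decade
    edges <- lo * 10^c(-half, half)
    mass <- 1
  } else {
    n_bins <- max(1L, ceiling(log10(hi / lo) * bins_per_decade))
    edges <- 10^seq(log10(lo), log10(hi), length.out = n_bins + 1L)
    edges[1] <- edges[1] * (1 - 1e-12)
    edges[length(edges)] <- edges[length(edges)] * (1 + 1e-12)
    counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                       nbins = n_bins)
    mass <- counts / length(x)
  }
  structure(list(edges = edges, mass = mass, n = length(x)),
            class = "residence_distribution")
}

#' @export
print.residence_distribution <- function(x, ...) {
  cat(sprintf(
    "<residence_distribution> %d bins over [%.3g, %.3g] ps, n = %d\n",
    length(x$mass), min(x$edges), max(x$edges), x$n))
  invisible(x)
}

#' Mean and squared deviation of residence times
#'
#' The second central moment <(tau_res - <tau_res>)^2> (population
#' normalisation, divisor N) quantifies the width of the mobility
#' distribution: it grows by orders of magnitude as hydration water becomes
#' more heterogeneous.
#'
#' @param rts a `residence_set` or numeric vector (ps)
#' @return list with `mean` (ps) and `squared_deviation` (ps^2)
#' @export
second_moment <- function(rts) {
  x <- if (inherits(rts, "residence_set")) rts$samples else as.numeric(rts)
  .assert(length(x) >= 2, "need at least 2 residence samples",
          "hydrosub_data_error")
  m <- mean(x)
  list(mean = m, squared_deviation = mean((x - m)^2))
}

#' Assign hydration-layer labels above a planar surface
#'
#' Layers of thickness `layer_thickness` are indexed outward from the surface
#' at z = 0: layer index = floor(z / layer_thickness) + 1, so z in
#' \[0, 3.5) Angstrom is layer 1, \[3.5, 7) is layer 2, and so on.
#'
#' @param traj a 3-D [trajectory] whose last coordinate is the height above
#'   the surface
#' @param layer_thickness layer thickness in Angstrom, > 0
#' @return integer matrix `[n_frames, n_particles]` of layer indices
#' @export
assign_layers <- function(traj, layer_thickness = 3.5) {
  .assert(inherits(traj, "trajectory"), "traj must be a trajectory")
  .assert(layer_thickness > 0, "layer_thickness must be > 0",
          "hydrosub_domain_error")
  nd <- dim(traj$coords)[3]
  z <- traj$coords[, , nd]
  z <- matrix(z, nrow = length(traj$times))
  .assert(all(z >= 0), "coordinates below the surface (z < 0)",
          "hydrosub_geometry_error")
  matrix(as.integer(floor(z / layer_thickness)) + 1L, nrow = nrow(z))
}

#' Residence-time distributions resolved by hydration layer
#'
#' Residence intervals are grouped by the layer of their starting frame; one
#' log-binned distribution is returned per layer that completed at least one
#' interval (empty layers are omitted).
#'
#' @inheritParams residence_times
#' @inheritParams assign_layers
#' @inheritParams residence_distribution
#' @return named list mapping layer index to [residence_distribution()]
#' @export
layer_residence_distributions <- function(traj, threshold = 3.5,
                                          layer_thickness = 3.5,
                                          bins_per_decade = 10) {
  layers <- assign_layers(traj, layer_thickness)
  rts <- residence_times(traj, threshold, layers = layers)
  if (!length(rts$samples)) return(list())
  split_samples <- split(rts$samples, rts$layer)
  lapply(split_samples, residence_distribution,
         bins_per_decade = bins_per_decade)
}

#' Write a residence distribution as delimited text
#'
#' Columns bin_lo, bin_hi (ps) and mass; tab separated.
#'
#' @param dist a `residence_distribution`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_residence_distribution <- function(dist, path) {
  .assert(inherits(dist, "residence_distribution"),
          "dist must be a residence_distribution")
  k <- length(dist$mass)
  df <- data.frame(bin_lo = dist$edges[seq_len(k)],
                   bin_hi = dist$edges[seq_len(k) + 1L],
                   mass = dist$mass)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a residence distribution from delimited text
#'
#' @param path file written by [write_residence_distribution()]
#' @param n sample count to record (the file stores only masses)
#' @return a `residence_distribution`
#' @export
read_residence_distribution <- function(path, n = NA_integer_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(edges = c(df$bin_lo, df$bin_hi[nrow(df)]),
                 mass = df$mass, n = n),
            class = "residence_distribution")
}
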
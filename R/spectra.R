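#' Spectrum grid container
#'
#' Holds quasi-elastic neutron intensities on a (q, frequency) grid, either as
#' the raw dynamic structure factor S(q, nu) or as the imaginary susceptibility
#' chi''(q, nu).
#'
#' @param q_values wave vectors in inverse Angstrom, all > 0
#' @param frequencies frequency grid in THz, strictly increasing, all > 0
#' @param intensity numeric matrix with `length(q_values)` rows and
#'   `length(frequencies)` columns
#' @param errors optional matrix of one-sigma uncertainties, same shape
#' @param temperature sample temperature in K, > 0
#' @param kind `"structure_factor"` or `"susceptibility"`
#' @return an object of class `spectrum_grid`
#' @examples
#' g <- spectrum_grid(1, c(0.1, 1), matrix(c(1, 2), 1), temperature = 280,
#'                    kind = "susceptibility")
#' @export
spectrum_grid <- function(q_values, frequencies, intensity, errors = NULL,
                          temperature = 280, kind = c("susceptibility",
                                                      "structure_factor")) {
  kind <- match.arg(kind)
  q_values <- as.numeric(q_values)
  frequencies <- as.numeric(frequencies)
  intensity <- as.matrix(intensity)
  .assert(all(is.finite(q_values)) && all(q_values > 0),
          "q values must be positive and finite")
  .assert(all(is.finite(frequencies)) && all(frequencies > 0),
          "frequencies must be positive (THz)", "hydrosub_grid_error")
  .assert(all(diff(frequencies) > 0),
          "frequencies must be strictly increasing", "hydrosub_grid_error")
  .assert(nrow(intensity) == length(q_values) &&
            ncol(intensity) == length(frequencies),
          "intensity matrix must be length(q) x length(frequencies)",
          "hydrosub_grid_error")
  .assert(temperature > 0, "temperature must be > 0 K")
  if (kind == "structure_factor") {
    .assert(all(intensity >= 0), "structure factor intensities must be >= 0",
            "hydrosub_grid_error")
  }
  if (!is.null(errors)) {
    errors <- as.matrix(errors)
    .assert(all(dim(errors) == dim(intensity)),
            "error matrix shape must match intensity", "hydrosub_grid_error")
  }
  structure(list(q_values = q_values, frequencies = frequencies,
                 intensity = intensity, errors = errors,
                 temperature = temperature, kind = kind),
            class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("<spectrum_grid> %s, %d q x %d frequencies, T = %g K\n",
              x$kind, length(x$q_values), length(x$frequencies),
              x$temperature))
  cat(sprintf("  q: %g .. %g 1/Ang;  nu: %g .. %g THz\n",
              min(x$q_values), max(x$q_values),
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Bose occupation factor
#'
#' Thermal occupation n_B(nu) = 1 / (exp(h nu / k_B T) - 1) with h in
#' micro-eV per THz and k_B in micro-eV per K, so that a frequency in THz and
#' a temperature in K can be combined directly.
#'
#' @param frequency frequency in THz, > 0 (vectorised)
#' @param temperature temperature in K, > 0
#' @return dimensionless occupation number
#' @examples
#' bose_factor(1, 280)    # ~ 5.8e3: classical regime, h nu << k_B T
#' @export
bose_factor <- function(frequency, temperature) {
  .assert(all(frequency > 0), "frequency must be > 0 THz",
          "hydrosub_domain_error")
  .assert(temperature > 0, "temperature must be > 0 K",
          "hydrosub_domain_error")
  x <- .PLANCK_UEV_PER_THZ * frequency / (.KB_UEV_PER_K * temperature)
  1 / expm1(x)
}

#' Convert a structure-factor grid to susceptibility
#'
#' chi''(q, nu) = S(q, nu) / n_B(nu): relaxation processes hidden under the
#' thermal occupation become peaks at nu_peak = 1 / (2 pi tau). Errors are
#' scaled by the same per-frequency factor.
#'
#' @param grid a [spectrum_grid] of kind `"structure_factor"`
#' @return a [spectrum_grid] of kind `"susceptibility"`
#' @export
to_susceptibility <- function(grid) {
  .assert(inherits(grid, "spectrum_grid"), "grid must be a spectrum_grid")
  .assert(grid$kind == "structure_factor",
          "grid is already a susceptibility", "hydrosub_state_error")
  nb <- bose_factor(grid$frequencies, grid$temperature)
  scale <- matrix(1 / nb, nrow = length(grid$q_values),
                  ncol = length(grid$frequencies), byrow = TRUE)
  spectrum_grid(grid$q_values, grid$frequencies, grid$intensity * scale,
                errors = if (!is.null(grid$errors)) grid$errors * scale,
                temperature = grid$temperature, kind = "susceptibility")
}

#' Convert a susceptibility grid back to a structure factor
#'
#' Inverse of [to_susceptibility()]: multiplies each cell by the Bose factor.
#'
#' @param grid a [spectrum_grid] of kind `"susceptibility"`
#' @return a [spectrum_grid] of kind `"structure_factor"`
#' @export
to_structure_factor <- function(grid) {
  .assert(inherits(grid, "spectrum_grid"), "grid must be a spectrum_grid")
  .assert(grid$kind == "susceptibility",
          "grid is already a structure factor", "hydrosub_state_error")
  nb <- bose_factor(grid$frequencies, grid$temperature)
  scale <- matrix(nb, nrow = length(grid$q_values),
                  ncol = length(grid$frequencies), byrow = TRUE)
  spectrum_grid(grid$q_values, grid$frequencies, grid$intensity * scale,
                errors = if (!is.null(grid$errors)) grid$errors * scale,
                temperature = grid$temperature, kind = "structure_factor")
}

#' Cole-Cole susceptibility function
#'
#' The symmetric broadened relaxation spectrum
#' \deqn{\chi''(\nu) = \chi_0 \frac{(2\pi\nu\tau)^{1-\alpha}\cos(\pi\alpha/2)}
#'   {1 + 2(2\pi\nu\tau)^{1-\alpha}\sin(\pi\alpha/2) +
#'    (2\pi\nu\tau)^{2(1-\alpha)}}.}
#' `alpha = 0` recovers the single-timescale Debye form; larger `alpha` means a
#' broader underlying distribution of relaxation times. The peak sits at
#' nu = 1 / (2 pi tau) for every `alpha`.
#'
#' @param frequency frequency in THz, > 0 (vectorised)
#' @param tau relaxation time in ps, > 0
#' @param alpha shape (heterogeneity) parameter in \[0, 1)
#' @param chi0 amplitude, > 0
#' @return susceptibility values, same length as `frequency`
#' @examples
#' cole_cole(1 / (2 * pi), tau = 1, alpha = 0, chi0 = 1)   # Debye peak: 0.5
#' @export
cole_cole <- function(frequency, tau, alpha, chi0) {
  .assert(all(frequency > 0), "frequency must be > 0 THz",
          "hydrosub_domain_error")
  .assert(tau > 0, "tau must be > 0 ps", "hydrosub_domain_error")
  .assert(alpha >= 0 && alpha < 1, "alpha must lie in [0, 1)",
          "hydrosub_domain_error")
  .assert(chi0 > 0, "chi0 must be > 0", "hydrosub_domain_error")
  x <- (2 * pi * frequency * tau)^(1 - alpha)
  s <- sin(pi * alpha / 2)
  chi0 * x * cos(pi * alpha / 2) / (1 + 2 * x * s + x^2)
}

#' Peak frequency of a relaxation process
#'
#' @param tau relaxation time in ps, > 0
#' @return peak frequency in THz, 1 / (2 pi tau)
#' @export
peak_frequency <- function(tau) {
  .assert(all(tau > 0), "tau must be > 0 ps", "hydrosub_domain_error")
  1 / (2 * pi * tau)
}

#' Convert an energy-transfer axis (micro-eV) to frequency (THz)
#'
#' Backscattering spectrometers report energy transfer E in micro-eV; the
#' relaxation model lives in frequency. E = h nu with h = 4.135668 ueV/THz.
#'
#' @param energy_ueV energy transfer in micro-eV
#' @return frequency in THz
#' @export
energy_to_frequency <- function(energy_ueV) {
  energy_ueV / .PLANCK_UEV_PER_THZ
}

# Residual vector for the Cole-Cole fit, in the sqrt-weighted metric.
.cc_resid <- function(par, nu, y, sw) {
  model <- {
    x <- (2 * pi * nu * exp(par[1]))^(1 - par[2])
    s <- sin(pi * par[2] / 2)
    exp(par[3]) * x * cos(pi * par[2] / 2) / (1 + 2 * x * s + x^2)
  }
  sw * (model - y)
}

#' Fit the Cole-Cole function to one q slice of a susceptibility grid
#'
#' Weighted least squares of the Cole-Cole form against the spectrum at one
#' wave vector. Weights are 1/error^2 where an error matrix is present,
#' otherwise uniform in log-frequency so linearly spaced grids do not
#' over-weight the high-frequency wing. Optimisation is bounded
#' Levenberg-Marquardt in (log tau, alpha, log chi0) with bounds
#' tau in \[1e-3, 1e6\] ps and alpha in \[0, 0.99\], started from
#' tau0 = 1/(2 pi nu_argmax), alpha0 = 0.2, chi0 = 2 x peak height, with
#' fallback starts alpha0 = 0.05 and 0.5 if the first start fails.
#'
#' @param grid a [spectrum_grid] of kind `"susceptibility"`
#' @param q_index row index of the q slice to fit
#' @param window optional c(lo, hi) frequency window (THz) restricting the fit
#' @param rel_tol relative residual norm above which the fit is flagged
#'   non-converged
#' @return an object of class `cole_cole_params`: list with `q`, `tau` (ps),
#'   `alpha`, `chi0`, `resid` (relative residual norm), `converged`,
#'   `interior_peak`, and `cov` (parameter covariance of (tau, alpha, chi0),
#'   or NULL if unavailable)
#' @seealso [fit_cole_cole_all()] to fit every q slice
#' @export
fit_cole_cole <- function(grid, q_index, window = NULL, rel_tol = 0.25) {
  .assert(inherits(grid, "spectrum_grid"), "grid must be a spectrum_grid")
  .assert(grid$kind == "susceptibility",
          "fit requires a susceptibility grid; call to_susceptibility first",
          "hydrosub_state_error")
  .assert(q_index >= 1 && q_index <= length(grid$q_values),
          "q_index out of range")
  nu <- grid$frequencies
  y <- grid$intensity[q_index, ]
  err <- if (!is.null(grid$errors)) grid$errors[q_index, ]
  if (!is.null(window)) {
    keep <- nu >= window[1] & nu <= window[2]
    nu <- nu[keep]; y <- y[keep]
    if (!is.null(err)) err <- err[keep]
  }
  .assert(length(nu) >= 8, "need at least 8 frequency points to fit",
          "hydrosub_data_error")
  .assert(any(y != 0), "all-zero spectrum slice", "hydrosub_data_error")

  w <- if (!is.null(err) && all(err > 0)) 1 / err^2 else .dlog_weights(nu)
  sw <- sqrt(w)
  imax <- which.max(y)
  interior_peak <- imax > 1 && imax < length(y)

  lower <- c(log(1e-3), 0, -700)
  upper <- c(log(1e6), 0.99, 700)
  tau0 <- 1 / (2 * pi * nu[imax])
  chi00 <- 2 * max(y)
  yn2 <- sum(w * y^2)

  best <- NULL
  for (alpha0 in c(0.2, 0.05, 0.5)) {
    start <- pmin(pmax(c(log(tau0), alpha0, log(chi00)), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = .cc_resid, nu = nu, y = y, sw = sw,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (fit$info %in% 1:3 && sqrt(fit$deviance / yn2) <= rel_tol) break
  }
  .assert(!is.null(best), "Cole-Cole fit failed at every start",
          "hydrosub_fit_error")

  par <- best$par
  tau <- exp(par[1]); alpha <- par[2]; chi0 <- exp(par[3])
  resid <- sqrt(best$deviance / yn2)
  at_bound <- par[1] <= lower[1] + 1e-9 || par[1] >= upper[1] - 1e-9 ||
    alpha >= upper[2] - 1e-9
  converged <- (best$info %in% 1:3) && resid <= rel_tol && !at_bound &&
    interior_peak

  cov <- tryCatch({
    ct <- best$deviance / max(1, length(y) - 3) * solve(best$hessian)
    # delta method from (log tau, alpha, log chi0) to (tau, alpha, chi0)
    jac <- diag(c(tau, 1, chi0))
    v <- jac %*% ct %*% t(jac)
    dimnames(v) <- list(c("tau", "alpha", "chi0"), c("tau", "alpha", "chi0"))
    v
  }, error = function(e) NULL)

  structure(list(q = grid$q_values[q_index], tau = tau, alpha = alpha,
                 chi0 = chi0, resid = resid, converged = converged,
                 interior_peak = interior_peak, cov = cov),
            class = "cole_cole_params")
}

#' @export
print.cole_cole_params <- function(x, ...) {
  cat(sprintf(
    "<cole_cole_params> q = %.3g 1/Ang: tau = %.4g ps, alpha = %.4g, chi0 = %.4g (resid %.3g, %s)\n",
    x$q, x$tau, x$alpha, x$chi0, x$resid,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit the Cole-Cole function to every q slice
#'
#' @inheritParams fit_cole_cole
#' @param ... passed to [fit_cole_cole()]
#' @return data.frame with columns q, tau, alpha, chi0, resid, converged
#' @export
fit_cole_cole_all <- function(grid, ...) {
  fits <- lapply(seq_along(grid$q_values), function(i)
    fit_cole_cole(grid, i, ...))
  do.call(rbind, lapply(fits, function(f)
    data.frame(q = f$q, tau = f$tau, alpha = f$alpha, chi0 = f$chi0,
               resid = f$resid, converged = f$converged)))
}

#' Write a spectrum grid as delimited text
#'
#' Long format with header `q, frequency, intensity, error` (tab separated);
#' temperature and kind are kept in `#`-prefixed metadata lines.
#'
#' @param grid a [spectrum_grid]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_spectra <- function(grid, path) {
  .assert(inherits(grid, "spectrum_grid"), "grid must be a spectrum_grid")
  nq <- length(grid$q_values); nf <- length(grid$frequencies)
  df <- data.frame(q = rep(grid$q_values, each = nf),
                   frequency = rep(grid$frequencies, times = nq),
                   intensity = as.vector(t(grid$intensity)),
                   error = if (!is.null(grid$errors))
                     as.vector(t(grid$errors)) else NA_real_)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# temperature_K: %.10g", grid$temperature),
               sprintf("# kind: %s", grid$kind)), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum grid from delimited text
#'
#' @param path file written by [write_spectra()] (or any delimited table with
#'   columns q, frequency, intensity and optional error)
#' @param temperature,kind overrides for files lacking the metadata lines
#' @return a [spectrum_grid]
#' @export
read_spectra <- function(path, temperature = NULL, kind = NULL) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(m)) trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  if (is.null(temperature)) {
    temperature <- as.numeric(get_meta("temperature_K"))
    .assert(length(temperature) == 1 && is.finite(temperature),
            "temperature missing from file; pass temperature=")
  }
  if (is.null(kind)) {
    kind <- get_meta("kind")
    .assert(!is.null(kind), "kind missing from file; pass kind=")
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t")
  q_values <- sort(unique(df$q))
  frequencies <- sort(unique(df$frequency))
  idx <- cbind(match(df$q, q_values), match(df$frequency, frequencies))
  intensity <- matrix(NA_real_, length(q_values), length(frequencies))
  intensity[idx] <- df$intensity
  errors <- NULL
  if ("error" %in% names(df) && !all(is.na(df$error))) {
    errors <- matrix(NA_real_, length(q_values), length(frequencies))
    errors[idx] <- df$error
  }
  spectrum_grid(q_values, frequencies, intensity, errors = errors,
                temperature = temperature, kind = kind)
}
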
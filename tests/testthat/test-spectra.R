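test_that("Bose factor matches closed-form values and limits", {
  # h nu / kB T = 4.135668 / 24128.5 at 1 THz, 280 K -> n_B ~ 1/x - 1/2
  expect_equal(bose_factor(1, 280), 5833.7, tolerance = 1e-3)
  # quantum limit: occupation vanishes when h nu >> kB T
  expect_lt(bose_factor(1e5, 280), 1e-6)
  # classical limit: n_B * (h nu / kB T) -> 1 as nu -> 0
  x <- 4.135668 * 1e-8 / (86.17333 * 280)
  expect_equal(bose_factor(1e-8, 280) * x, 1, tolerance = 1e-7)
  expect_error(bose_factor(-1, 280), class = "hydrosub_domain_error")
  expect_error(bose_factor(1, 0), class = "hydrosub_domain_error")
})

test_that("Cole-Cole function reproduces closed-form peak values", {
  nu_pk <- 1 / (2 * pi)
  # Debye peak value chi0 / 2
  expect_equal(cole_cole(nu_pk, tau = 1, alpha = 0, chi0 = 1), 0.5)
  # alpha = 0.5: cos(pi/4) / (2 (1 + sin(pi/4)))
  expect_equal(cole_cole(nu_pk, tau = 1, alpha = 0.5, chi0 = 1),
               cos(pi / 4) / (2 * (1 + sin(pi / 4))))
  expect_equal(cole_cole(nu_pk, tau = 1, alpha = 0.5, chi0 = 1), 0.20711,
               tolerance = 1e-4)
  expect_error(cole_cole(1, tau = 1, alpha = 1, chi0 = 1),
               class = "hydrosub_domain_error")
})

test_that("Cole-Cole is symmetric in log-frequency about the peak", {
  set.seed(1)
  for (i in 1:20) {
    tau <- 10^runif(1, -2, 3)
    alpha <- runif(1, 0, 0.95)
    chi0 <- 10^runif(1, -2, 2)
    r <- 10^runif(1, 0.1, 2)
    nu_pk <- 1 / (2 * pi * tau)
    expect_equal(cole_cole(nu_pk * r, tau, alpha, chi0),
                 cole_cole(nu_pk / r, tau, alpha, chi0), tolerance = 1e-12)
  }
})

test_that("Cole-Cole is non-negative, vanishes at both frequency limits, and narrows as alpha drops", {
  nu <- logspace(1e-8, 1e8, 200)
  vals <- cole_cole(nu, tau = 5, alpha = 0.3, chi0 = 2)
  expect_true(all(vals >= 0))
  # wings decay as x^(1-alpha) and x^-(1-alpha)
  expect_lt(vals[1], 1e-4)
  expect_lt(vals[length(nu)], 1e-4)
  # peak amplitude chi0 cos(pi a/2) / (2 (1 + sin(pi a/2))) decreases in alpha
  alphas <- seq(0, 0.9, by = 0.1)
  peaks <- vapply(alphas, function(a)
    cole_cole(1 / (2 * pi * 5), tau = 5, alpha = a, chi0 = 2), numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("peak location is 1/(2 pi tau) independent of alpha (grid argmax)", {
  expect_equal(peak_frequency(10), 0.015915, tolerance = 1e-4)
  expect_equal(peak_frequency(1 / (2 * pi)), 1)
  for (alpha in c(0, 0.2, 0.5)) {
    tau <- 10
    nu <- logspace(1e-5, 10, 20000)
    vals <- cole_cole(nu, tau, alpha, 1)
    nu_argmax <- nu[which.max(vals)]
    # within one grid spacing (log step ~ 7e-4)
    expect_equal(log(nu_argmax), log(peak_frequency(tau)), tolerance = 1e-3)
  }
  expect_error(peak_frequency(0), class = "hydrosub_domain_error")
})

test_that("susceptibility conversion divides by the Bose factor and inverts", {
  g <- spectrum_grid(1, c(0.5, 1, 2, 4), matrix(1, 1, 4), temperature = 280,
                     kind = "structure_factor")
  chi <- to_susceptibility(g)
  expect_equal(chi$kind, "susceptibility")
  # constant S -> chi'' = 1/n_B, strictly increasing in frequency
  expect_true(all(diff(chi$intensity[1, ]) > 0))
  expect_equal(chi$intensity[1, ],
               1 / bose_factor(g$frequencies, 280))
  # round trip restores the original grid
  back <- to_structure_factor(chi)
  expect_equal(back$intensity, g$intensity, tolerance = 1e-14)
  expect_error(to_susceptibility(chi), class = "hydrosub_state_error")
  expect_error(to_structure_factor(g), class = "hydrosub_state_error")
})

test_that("structure-factor output of the generator converts back to exact Cole-Cole values", {
  spec <- spectra_spec(c(0.8, 1.2), tau = c(5, 2), alpha = c(0.1, 0.3),
                       chi0 = c(1, 2), frequencies = logspace(1e-4, 5, 60),
                       noise_level = 0, output_kind = "structure_factor")
  chi <- to_susceptibility(gen_cole_cole_spectra(spec))
  for (i in 1:2) {
    expect_equal(chi$intensity[i, ],
                 cole_cole(spec$frequencies, spec$tau[i], spec$alpha[i],
                           spec$chi0[i]),
                 tolerance = 1e-12)
  }
})

test_that("noiseless Cole-Cole fits recover the generating parameters", {
  cases <- list(c(tau = 10, alpha = 0.2, chi0 = 1),
                c(tau = 0.5, alpha = 0.45, chi0 = 3),
                c(tau = 100, alpha = 0.05, chi0 = 0.2))
  for (cs in cases) {
    spec <- spectra_spec(1, tau = cs["tau"], alpha = cs["alpha"],
                         chi0 = cs["chi0"],
                         frequencies = logspace(peak_frequency(cs["tau"]) / 200,
                                                peak_frequency(cs["tau"]) * 200,
                                                200))
    fit <- fit_cole_cole(gen_cole_cole_spectra(spec), 1)
    expect_true(fit$converged)
    expect_equal(fit$tau, unname(cs["tau"]), tolerance = 1e-3)
    expect_equal(fit$alpha, unname(cs["alpha"]), tolerance = 1e-3)
    expect_equal(fit$chi0, unname(cs["chi0"]), tolerance = 1e-3)
  }
})

test_that("a noiseless Debye spectrum is recognised as alpha ~ 0", {
  spec <- spectra_spec(1, tau = 10, alpha = 0, chi0 = 1,
                       frequencies = logspace(1e-5, 10, 200))
  fit <- fit_cole_cole(gen_cole_cole_spectra(spec), 1)
  expect_lt(fit$alpha, 0.01)
})

test_that("fitting is scale-equivariant in the amplitude", {
  spec <- spectra_spec(1, tau = 3, alpha = 0.25, chi0 = 1,
                       frequencies = logspace(1e-4, 10, 150))
  g <- gen_cole_cole_spectra(spec)
  f1 <- fit_cole_cole(g, 1)
  g2 <- spectrum_grid(g$q_values, g$frequencies, g$intensity * 7.5,
                      temperature = g$temperature, kind = g$kind)
  f2 <- fit_cole_cole(g2, 1)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-6)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-6)
  expect_equal(f2$chi0, 7.5 * f1$chi0, tolerance = 1e-6)
})

test_that("tau is recovered to a few percent under 5% noise (replicate study)", {
  errs <- vapply(1:50, function(s) {
    spec <- spectra_spec(1, tau = 10, alpha = 0.2, chi0 = 1,
                         frequencies = logspace(1e-5, 10, 200),
                         noise_level = 0.05, seed = s)
    fit <- fit_cole_cole(gen_cole_cole_spectra(spec), 1)
    abs(fit$tau / 10 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("degenerate spectra are rejected with data errors", {
  g <- spectrum_grid(1, logspace(0.1, 1, 5), matrix(1, 1, 5),
                     kind = "susceptibility")
  expect_error(fit_cole_cole(g, 1), class = "hydrosub_data_error")
  g0 <- spectrum_grid(1, logspace(0.1, 1, 20), matrix(0, 1, 20),
                      kind = "susceptibility")
  expect_error(fit_cole_cole(g0, 1), class = "hydrosub_data_error")
})

test_that("spectra survive a write/read round trip", {
  spec <- spectra_spec(c(0.7, 1.1), tau = c(8, 4), alpha = 0.2, chi0 = 1,
                       frequencies = logspace(1e-3, 2, 40),
                       noise_level = 0.05, seed = 3)
  g <- gen_cole_cole_spectra(spec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectra(g, path)
  g2 <- read_spectra(path)
  expect_equal(g2$q_values, g$q_values)
  expect_equal(g2$frequencies, g$frequencies, tolerance = 1e-12)
  expect_equal(g2$intensity, g$intensity, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(g2$errors, g$errors, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g2$temperature, g$temperature)
  expect_equal(g2$kind, g$kind)
})

test_that("energy transfer in micro-eV converts to THz through h", {
  expect_equal(energy_to_frequency(4.135668), 1)
})
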
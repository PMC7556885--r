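test_that("first passage of uniform motion gives the closed-form residence time", {
  # v = 0.35 A/ps against a 3.5 A threshold: one sample every 10 ps
  t <- seq(0, 100, 0.1)
  tr <- trajectory(t + 0.1, array(0.35 * t, c(length(t), 1, 1)))
  rts <- residence_times(tr, threshold = 3.5)
  # one frame of quantisation slack per passage
  expect_true(length(rts$samples) %in% c(9L, 10L))
  expect_true(all(abs(rts$samples - 10) <= 0.1 + 1e-9))
})

test_that("a static particle yields no samples and one censored interval", {
  tr <- trajectory(1:50, array(1.25, c(50, 1, 3)))
  rts <- residence_times(tr, 3.5)
  expect_length(rts$samples, 0)
  expect_equal(rts$censored_count, 1)
  expect_error(residence_times(trajectory(1, array(0, c(1, 1, 1))), 3.5),
               class = "hydrosub_data_error")
})

test_that("residence extraction equals the brute-force first-passage scan", {
  for (cfg in list(list(dims = 1L, frames = 400, np = 40, step = 1),
                   list(dims = 3L, frames = 300, np = 30, step = 1.2),
                   list(dims = 1L, frames = 1000, np = 100, step = 2))) {
    tr <- make_lattice_traj(cfg$frames, cfg$np, dims = cfg$dims,
                            step = cfg$step, seed = cfg$frames + cfg$np)
    got <- residence_times(tr, 3.5)
    want <- oracle_residence(tr, 3.5)
    expect_identical(got$samples, want$samples)
    expect_identical(got$censored_count, want$censored)
  }
})

test_that("completed residence intervals never exceed the trajectory span", {
  model <- waiting_model("pareto", tail_exponent = 0.7, t_min = 0.3)
  tr <- gen_ctrw_trajectories(model, 1.2, 60, 150, dims = 3, seed = 14,
                              obs_times = seq(0, 150, 0.5))
  rts <- residence_times(tr, 3.5)
  # per construction samples are global, so check the global bound per batch
  expect_true(all(rts$samples <= 150))
  expect_true(all(rts$samples > 0))
})

test_that("log-binned distributions are proper probability mass functions", {
  set.seed(3)
  x <- rexp(5000, 1 / 10)
  d <- residence_distribution(x)
  expect_lt(abs(sum(d$mass) - 1), 1e-12)
  expect_true(all(diff(d$edges) > 0))
  # identical samples collapse to one occupied bin of mass 1
  d1 <- residence_distribution(rep(4.2, 25))
  expect_equal(sum(d1$mass), 1)
  expect_equal(sum(d1$mass > 0), 1)
  expect_error(residence_distribution(numeric(0)),
               class = "hydrosub_data_error")
})

test_that("exponential samples fill log bins per the analytic CDF", {
  set.seed(8)
  m <- 10
  x <- rexp(1e5, 1 / m)
  d <- residence_distribution(x)
  k <- length(d$mass)
  p_true <- pexp(d$edges[-1], 1 / m) - pexp(d$edges[-(k + 1)], 1 / m)
  p_true <- p_true / sum(p_true)  # condition on the observed range
  sigma <- sqrt(p_true * (1 - p_true) / length(x))
  expect_true(all(abs(d$mass - p_true) <= 3 * sigma + 1e-4))
})

test_that("heavy-tail samples show the psi(t) ~ t^-(1+beta) log-log slope", {
  set.seed(9)
  beta <- 0.5
  x <- 1 * runif(2e5)^(-1 / beta)  # pareto t_min = 1
  d <- residence_distribution(x, bins_per_decade = 6)
  k <- length(d$mass)
  centers <- sqrt(d$edges[-1] * d$edges[-(k + 1)])
  dens <- d$mass / diff(d$edges)
  # tail: decades above t_min with enough counts to be stable
  keep <- centers > 10 & centers < 1e4 & d$mass * d$n > 50
  fit <- lm(log(dens[keep]) ~ log(centers[keep]))
  expect_equal(unname(coef(fit)[2]), -1.5, tolerance = 0.1 / 1.5)
})

test_that("second moments match hand computation and exponential theory", {
  expect_equal(second_moment(c(1, 3)), list(mean = 2, squared_deviation = 1))
  expect_equal(second_moment(rep(7, 5))$squared_deviation, 0)
  set.seed(11)
  m <- 4
  x <- rexp(1e5, 1 / m)
  mom <- second_moment(x)
  expect_equal(mom$squared_deviation, m^2, tolerance = 0.03)
  expect_error(second_moment(5), class = "hydrosub_data_error")
})

test_that("hydration layers are indexed outward in 3.5 A shells", {
  z <- c(1.0, 4.0, 8.0)
  tr <- trajectory(1:3, array(c(rep(0, 6), z), c(3, 1, 3)))
  layers <- assign_layers(tr)
  expect_equal(as.vector(layers), c(1L, 2L, 3L))
  tr_neg <- trajectory(1:2, array(c(0, 0, 0, 0, 1, -1), c(2, 1, 3)))
  expect_error(assign_layers(tr_neg), class = "hydrosub_geometry_error")
})

test_that("per-layer distributions separate slow-surface from fast-bulk water", {
  models <- list(waiting_model("exponential", mean = 15),
                 waiting_model("exponential", mean = 1))
  tr <- gen_layered_trajectories(models, layer_thickness = 3.5,
                                 step_length = 1.5, n_particles = 250,
                                 t_max = 400, seed = 6,
                                 obs_times = seq(0, 400, 0.5))
  lrd <- layer_residence_distributions(tr)
  expect_true(all(c("1", "3") %in% names(lrd)))
  bin_mean <- function(d) {
    k <- length(d$mass)
    sum(d$mass * sqrt(d$edges[-1] * d$edges[-(k + 1)]))
  }
  expect_gt(bin_mean(lrd[["1"]]), bin_mean(lrd[["3"]]))
})

test_that("particles confined to the first layer populate only layer 1", {
  # small in-plane drift keeps z within [0, 3.5)
  t <- 1:60
  coords <- array(0, c(60, 2, 3))
  coords[, , 1] <- outer(0.5 * t, c(1, -1))
  coords[, , 3] <- 1.0
  lrd <- layer_residence_distributions(trajectory(t, coords))
  expect_equal(names(lrd), "1")
})

test_that("resampling an extracted distribution reproduces the mean (closure loop)", {
  model <- waiting_model("exponential", mean = 8)
  obs <- seq(0, 1000, 0.25)
  tr <- gen_ctrw_trajectories(model, step_length = 3.5, n_particles = 300,
                              t_max = 1000, dims = 1, seed = 9,
                              obs_times = obs)
  rts <- residence_times(tr, 3.5)
  d <- residence_distribution(rts)
  walk <- gen_ctrw_trajectories(waiting_model("empirical", distribution = d),
                                step_length = 3.5, n_particles = 300,
                                t_max = 1000, dims = 1, seed = 10,
                                obs_times = obs)
  rts2 <- residence_times(walk, 3.5)
  expect_equal(mean(rts2$samples), mean(rts$samples), tolerance = 0.05)
})

test_that("wider relative residence spread means smaller RJ beta (rank order)", {
  models <- list(exp1 = waiting_model("exponential", mean = 1),
                 p09 = waiting_model("pareto", tail_exponent = 0.9,
                                     t_min = 0.05),
                 p07 = waiting_model("pareto", tail_exponent = 0.7,
                                     t_min = 0.05),
                 p05 = waiting_model("pareto", tail_exponent = 0.5,
                                     t_min = 0.05))
  widths <- numeric(length(models))
  betas <- numeric(length(models))
  for (i in seq_along(models)) {
    x <- hydrosub:::.with_seed(50 + i, sample_waiting_time(models[[i]], 2e4))
    mom <- second_moment(x)
    widths[i] <- mom$squared_deviation / mom$mean^2
    rj <- simulate_rj(waiting_model("empirical",
                                    distribution = residence_distribution(x)),
                      step_length = 3.5, n_particles = 2000, t_max = 2000,
                      seed = 60 + i)
    betas[i] <- rj$beta
  }
  expect_true(all(diff(widths) > 0))  # series ordered by tail weight
  expect_equal(cor(widths, betas, method = "spearman"), -1)
})
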
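#' @keywords internal
.config_defaults <- function() {
  list(temperature = 280, q_range = c(0.7, 1.5), msd_window = c(5, 1000),
       displacement_threshold = 3.5, layer_thickness = 3.5,
       bound_water = 1.2, hydration_levels = numeric(0),
       stages = c("generate", "to_chi", "fit_cc", "scale", "residence",
                  "rjsim"),
       outdir = "hydrosub_out", quiet = FALSE)
}

.known_config_keys <- function() {
  c(names(.config_defaults()), "seed", "spectra", "trajectories", "rj")
}

.stochastic_stages <- c("generate", "rjsim")

#' Validate a pipeline configuration
#'
#' Parses structured text (YAML) into a typed, defaulted run configuration.
#' Unknown keys are rejected; a seed is mandatory whenever a stochastic stage
#' (generation or RJ simulation) is enabled. Defaults: temperature 280 K,
#' q band 0.7-1.5 inverse Angstrom, MSD window 5-1000 ps, displacement and
#' layer thresholds 3.5 Angstrom, bound water 1.2 g/g.
#'
#' @param config a file path to a YAML config, a YAML string, or a list
#' @return an object of class `run_config`
#' @seealso [run_all()], [serialize_config()]
#' @export
validate_config <- function(config) {
  raw <- if (is.list(config)) {
    config
  } else if (length(config) == 1 && !grepl("\n", config) &&
             file.exists(config)) {
    yaml::read_yaml(config)
  } else {
    yaml::yaml.load(paste(config, collapse = "\n"))
  }
  .assert(is.list(raw), "config must parse to a mapping",
          "hydrosub_parse_error")
  unknown <- setdiff(names(raw), .known_config_keys())
  .assert(length(unknown) == 0,
          paste("unknown config keys:", paste(unknown, collapse = ", ")),
          "hydrosub_validation_error")
  cfg <- utils::modifyList(.config_defaults(), raw)

  num <- function(x, name, len = 1, positive = TRUE) {
    v <- suppressWarnings(as.numeric(x))
    .assert(length(v) == len && all(is.finite(v)),
            sprintf("config field '%s' must be %d finite number(s)", name,
                    len), "hydrosub_parse_error")
    if (positive) .assert(all(v > 0), sprintf("'%s' must be > 0", name),
                          "hydrosub_validation_error")
    v
  }
  cfg$temperature <- num(cfg$temperature, "temperature")
  cfg$q_range <- num(cfg$q_range, "q_range", 2)
  cfg$msd_window <- num(cfg$msd_window, "msd_window", 2)
  cfg$displacement_threshold <- num(cfg$displacement_threshold,
                                    "displacement_threshold")
  cfg$layer_thickness <- num(cfg$layer_thickness, "layer_thickness")
  cfg$bound_water <- num(cfg$bound_water, "bound_water", positive = FALSE)
  .assert(cfg$bound_water >= 0, "bound_water must be >= 0",
          "hydrosub_validation_error")
  if (length(cfg$hydration_levels))
    cfg$hydration_levels <- num(cfg$hydration_levels, "hydration_levels",
                                length(cfg$hydration_levels))
  .assert(diff(cfg$q_range) > 0 && diff(cfg$msd_window) > 0,
          "q_range and msd_window must be increasing pairs",
          "hydrosub_validation_error")
  cfg$stages <- as.character(unlist(cfg$stages))
  bad <- setdiff(cfg$stages, .config_defaults()$stages)
  .assert(length(bad) == 0,
          paste("unknown stages:", paste(bad, collapse = ", ")),
          "hydrosub_validation_error")
  if (any(cfg$stages %in% .stochastic_stages)) {
    .assert(!is.null(cfg$seed),
            "seed is required when a stochastic stage is enabled",
            "hydrosub_validation_error")
    cfg$seed <- as.integer(num(cfg$seed, "seed", positive = FALSE))
  }
  if (!is.null(cfg$spectra) && !is.null(cfg$spectra$alpha)) {
    a <- as.numeric(cfg$spectra$alpha)
    .assert(all(a >= 0 & a < 1), "spectra alpha must lie in [0, 1)",
            "hydrosub_validation_error")
  }
  for (key in c("spectra", "trajectories")) {
    p <- cfg[[key]]$path
    if (!is.null(p))
      .assert(file.exists(p), sprintf("%s path does not exist: %s", key, p),
              "hydrosub_validation_error")
  }
  structure(cfg, class = "run_config")
}

#' Serialise a run configuration back to YAML
#'
#' @param config a `run_config`
#' @return a YAML string; `validate_config(serialize_config(x))` is
#'   idempotent
#' @export
serialize_config <- function(config) {
  .assert(inherits(config, "run_config"), "config must be a run_config")
  yaml::as.yaml(unclass(config))
}

.log_stage <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[hydrosub] %s: %s", stage, sprintf(...)))
}

.build_waiting_model <- function(spec) {
  waiting_model(kind = spec$kind, mean = spec$mean,
                tail_exponent = spec$tail_exponent, t_min = spec$t_min)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order: generate (synthetic
#' spectra and/or trajectories), to_chi (Bose-factor conversion), fit_cc
#' (per-q Cole-Cole fits), scale (tau ~ q^-n, beta = 2/n, alpha averaged over
#' the q band, bulk-like fractions), residence (first-passage residence
#' times, distribution, moments, per-layer tables for 3-D trajectories), and
#' rjsim (random-jump simulation driven by the extracted residence-time
#' distribution, or by a configured parametric model). All artifacts are
#' written under `config$outdir`, together with a single JSON report.
#'
#' @param config a `run_config` from [validate_config()] (or anything it
#'   accepts)
#' @return the report, invisibly, as a list (also written to
#'   `outdir/report.json`); `$status` records per-stage "ok" / "failed" /
#'   "skipped"
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  quiet <- isTRUE(config$quiet)
  stages <- config$stages
  status <- stats::setNames(rep("skipped", length(stages)), stages)
  report <- list()
  env <- new.env(parent = emptyenv())

  run_stage <- function(name, deps_ok, fun) {
    if (!(name %in% stages)) return(invisible(NULL))
    if (!deps_ok) {
      status[[name]] <<- "skipped"
      .log_stage(quiet, name, "skipped (unmet dependency)")
      return(invisible(NULL))
    }
    out <- tryCatch({
      fun()
      status[[name]] <<- "ok"
    }, error = function(e) {
      status[[name]] <<- "failed"
      report$errors[[name]] <<- conditionMessage(e)
      .log_stage(quiet, name, "FAILED: %s", conditionMessage(e))
    })
    invisible(out)
  }

  # -- generate ------------------------------------------------------------
  run_stage("generate", TRUE, function() {
    if (!is.null(config$spectra) && is.null(config$spectra$path)) {
      sp <- config$spectra
      spec <- if (!is.null(sp$beta_star)) {
        subdiffusion_spectra_spec(
          beta_star = sp$beta_star,
          q_values = if (!is.null(sp$q_values)) as.numeric(sp$q_values)
            else seq(0.7, 1.5, by = 0.2),
          tau0 = sp$tau0 %||% 10, chi0 = sp$chi0 %||% 1,
          noise_level = sp$noise_level %||% 0,
          temperature = config$temperature, seed = config$seed)
      } else {
        freqs <- if (!is.null(sp$frequencies))
          as.numeric(sp$frequencies)
        else logspace(sp$freq_min %||% 1e-4, sp$freq_max %||% 10,
                      sp$n_freq %||% 200)
        spectra_spec(as.numeric(sp$q_values), as.numeric(sp$tau),
                     as.numeric(sp$alpha), as.numeric(sp$chi0 %||% 1),
                     frequencies = freqs,
                     noise_level = sp$noise_level %||% 0,
                     temperature = config$temperature,
                     output_kind = sp$kind %||% "susceptibility",
                     seed = config$seed)
      }
      env$spectra <- gen_cole_cole_spectra(spec)
      env$truth <- attr(env$spectra, "truth")
      write_spectra(env$spectra, file.path(config$outdir, "spectra.tsv"))
      .log_stage(quiet, "generate", "spectra: %d q x %d frequencies",
                 length(env$spectra$q_values),
                 length(env$spectra$frequencies))
    }
    if (!is.null(config$trajectories) &&
        is.null(config$trajectories$path)) {
      tr <- config$trajectories
      model <- .build_waiting_model(tr$model)
      env$traj <- gen_ctrw_trajectories(
        model, step_length = tr$step_length %||% 3.5,
        n_particles = tr$n_particles %||% 1000L,
        t_max = tr$t_max %||% 2000, dims = tr$dims %||% 1L,
        seed = config$seed)
      write_trajectory(env$traj,
                       file.path(config$outdir, "trajectories.tsv"))
      .log_stage(quiet, "generate", "trajectories: %d particles, t_max %g ps",
                 dim(env$traj$coords)[2], tr$t_max %||% 2000)
    }
  })

  # external inputs
  if (!is.null(config$spectra$path) && is.null(env$spectra))
    env$spectra <- read_spectra(config$spectra$path,
                                temperature = config$temperature,
                                kind = config$spectra$kind)
  if (!is.null(config$trajectories$path) && is.null(env$traj))
    env$traj <- read_trajectory(config$trajectories$path)

  # -- to_chi --------------------------------------------------------------
  run_stage("to_chi", !is.null(env$spectra), function() {
    if (env$spectra$kind == "structure_factor") {
      env$spectra <- to_susceptibility(env$spectra)
      write_spectra(env$spectra,
                    file.path(config$outdir, "susceptibility.tsv"))
    }
    .log_stage(quiet, "to_chi", "kind = %s", env$spectra$kind)
  })

  # -- fit_cc --------------------------------------------------------------
  run_stage("fit_cc", !is.null(env$spectra) &&
              identical(env$spectra$kind, "susceptibility"), function() {
    env$cc <- fit_cole_cole_all(env$spectra)
    utils::write.table(env$cc,
                       file.path(config$outdir, "cole_cole_fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$cole_cole <<- env$cc
    .log_stage(quiet, "fit_cc", "%d q slices fitted, %d converged",
               nrow(env$cc), sum(env$cc$converged))
  })

  # -- scale ---------------------------------------------------------------
  run_stage("scale", !is.null(env$cc), function() {
    sc <- fit_power_law_tau_q(env$cc, q_range = NULL)
    ab <- tryCatch(average_alpha(env$cc, config$q_range),
                   error = function(e) NA_real_)
    report$scaling <<- list(n = sc$n, beta = sc$beta, n_se = sc$n_se,
                            r_squared = sc$r_squared,
                            alpha_bar = ab, q_band = config$q_range)
    if (length(config$hydration_levels))
      report$bulk_like <<- data.frame(
        h = config$hydration_levels,
        fraction = bulk_like_fraction(config$hydration_levels,
                                      config$bound_water))
    .log_stage(quiet, "scale", "n = %.3f, beta = %.3f, alpha_bar = %.3f",
               sc$n, sc$beta, ab)
  })

  # -- residence -----------------------------------------------------------
  run_stage("residence", !is.null(env$traj), function() {
    rts <- residence_times(env$traj, config$displacement_threshold)
    env$rdist <- residence_distribution(rts)
    mom <- second_moment(rts)
    write_residence_distribution(env$rdist,
                                 file.path(config$outdir,
                                           "residence_distribution.tsv"))
    report$residence <<- list(
      n_samples = length(rts$samples), censored = rts$censored_count,
      mean = mom$mean, squared_deviation = mom$squared_deviation,
      relative_width = mom$squared_deviation / mom$mean^2)
    if (dim(env$traj$coords)[3] == 3L &&
        all(env$traj$coords[, , 3] >= 0)) {
      lrd <- layer_residence_distributions(env$traj,
                                           config$displacement_threshold,
                                           config$layer_thickness)
      report$residence$layers <<- lapply(lrd, function(d)
        list(n = d$n, edges = d$edges, mass = d$mass))
    }
    .log_stage(quiet, "residence", "%d samples, mean %.3g ps",
               length(rts$samples), mom$mean)
  })

  # -- rjsim ---------------------------------------------------------------
  rj_cfg <- config$rj
  rj_model_available <- !is.null(rj_cfg$model) ||
    ("residence" %in% stages && !is.null(env$traj))
  run_stage("rjsim", rj_model_available, function() {
    model <- if (!is.null(rj_cfg$model)) {
      .build_waiting_model(rj_cfg$model)
    } else {
      .assert(!is.null(env$rdist),
              "rjsim needs a residence distribution or a configured model",
              "hydrosub_config_error")
      waiting_model("empirical", distribution = env$rdist)
    }
    res <- simulate_rj(model,
                       step_length = rj_cfg$step_length %||% 3.5,
                       n_particles = rj_cfg$n_particles %||% 1000L,
                       t_max = rj_cfg$t_max %||% 2000,
                       seed = config$seed,
                       msd_window = config$msd_window)
    utils::write.table(res$msd, file.path(config$outdir, "rj_msd.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$rj <<- list(beta = res$beta, degenerate = res$degenerate,
                       model = utils::capture.output(print(model)))
    .log_stage(quiet, "rjsim", "beta = %.3f", res$beta)
  })

  # -- report --------------------------------------------------------------
  if (!is.null(env$truth)) report$ground_truth <- env$truth
  cfg_yaml <- serialize_config(config)
  cfg_path <- file.path(config$outdir, "config.yaml")
  writeLines(cfg_yaml, cfg_path)
  report$provenance <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("hydrosub")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  report$status <- as.list(status)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  if (any(status == "failed"))
    warning("one or more pipeline stages failed; see report$errors")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
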
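#' Default pipeline configuration
#'
#' Single nested configuration consumed by [run_pipeline()] and
#' [pipeline_manifest()]. Defaults are the full study protocol:
#' 200-point Sobol training design over the 14-parameter box, 5-fold
#' cross-validation, Saltelli sensitivity analysis, C fixed at 1.7 kPa
#' after ranking, history-matching waves with 100 000-point test sets
#' and the 3.5 -> 3.0 threshold schedule, and ensemble MCMC with 18
#' walkers of 100 000 steps (burn-in 10 000, thinning 10). `quick = TRUE`
#' scales every budget down to desk scale for smoke runs.
#'
#' @param seed master seed; every random draw in the pipeline derives
#'   from it
#' @param quick use reduced budgets
#' @return nested list of class `pipeline_config`
#' @export
default_config <- function(seed = 1L, quick = FALSE) {
  cfg <- list(
    seed = as.integer(seed),
    anatomy = list(V_ED = 90, A_MV = 8),
    noise = list(level = "baseline"),
    design = list(n_train = 200, mode = "14"),
    emulation = list(cv_folds = 5, n_restarts = 5, maxit = 60),
    gsa = list(N = 1024, C_fixed = 1.7),
    hm = list(n_test = 100000, n_simul_wave1 = 200, n_simul = 100,
              threshold_start = 3.5, threshold_step = 0.5,
              threshold_floor = 3.0, convergence_tol = 0.01,
              max_waves = 10),
    mcmc = list(n_walkers = 18, n_steps = 100000, burn_in = 10000,
                thin = 10, a = 2, max_extensions = 3),
    stats = list(n_patients = 10)
  )
  if (quick) {
    cfg$design$n_train <- 150
    cfg$emulation$n_restarts <- 2
    cfg$emulation$maxit <- 40
    cfg$gsa$N <- 128
    cfg$hm$n_test <- 4000
    cfg$hm$n_simul_wave1 <- 100
    cfg$hm$n_simul <- 40
    cfg$hm$max_waves <- 3
    cfg$mcmc$n_steps <- 2000
    cfg$mcmc$burn_in <- 400
    cfg$mcmc$max_extensions <- 0
  }
  cfg$quick <- quick
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of a [default_config()]-style configuration, with
#' validation of range ordering and budget positivity.
#'
#' @param path YAML file path
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname read_config
#' @param config a `pipeline_config`
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

validate_config <- function(cfg) {
  need <- c("seed", "anatomy", "design", "emulation", "gsa", "hm", "mcmc")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config missing blocks: ", paste(miss, collapse = ", "))
  with(cfg$hm, stopifnot(threshold_floor <= threshold_start,
                         n_test > 0, n_simul > 0, convergence_tol > 0))
  with(cfg$mcmc, stopifnot(n_walkers >= 2, n_steps > burn_in, thin >= 1))
  stopifnot(cfg$design$n_train >= 10 * nrow(param_ranges(cfg$design$mode)))
  invisible(TRUE)
}

#' Manifest of a configured pipeline run
#'
#' The stage schedule and every budget and seed a run would use, as a
#' flat named list — the record asserted by protocol-fidelity checks and
#' written alongside artifacts to enable exact re-runs.
#'
#' @param config a `pipeline_config`
#' @return named list
#' @export
pipeline_manifest <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  thresholds <- vapply(seq_len(config$hm$max_waves), function(w)
    max(config$hm$threshold_start - (w - 1) * config$hm$threshold_step,
        config$hm$threshold_floor), numeric(1))
  list(
    stages = c("design", "simulate", "emulate_cv", "gsa", "fix_C",
               "re_emulate", "hm_waves", "mcmc", "map_neighbour", "stats"),
    seed = config$seed,
    design_n_train = config$design$n_train,
    design_mode = config$design$mode,
    cv_folds = config$emulation$cv_folds,
    gsa_N = config$gsa$N,
    C_fixed = config$gsa$C_fixed,
    hm_n_test = config$hm$n_test,
    hm_n_simul_wave1 = config$hm$n_simul_wave1,
    hm_n_simul = config$hm$n_simul,
    hm_threshold_schedule = thresholds,
    hm_convergence_tol = config$hm$convergence_tol,
    mcmc_n_walkers = config$mcmc$n_walkers,
    mcmc_n_steps = config$mcmc$n_steps,
    mcmc_burn_in = config$mcmc$burn_in,
    mcmc_thin = config$mcmc$thin,
    quick = isTRUE(config$quick))
}

#' Write / read pipeline tables
#'
#' Lossless CSV round-trip for rectangular artifacts (designs, feature
#' matrices, wave records, posterior samples), with a typed metadata
#' header carried in `#` comment lines, and JSON for nested records
#' (observations, manifests). Numbers are written with full precision
#' and parsed with the C locale decimal point.
#'
#' @param x data.frame or matrix to write
#' @param path file path
#' @param meta optional named list of scalar metadata
#' @return `read_table_csv` returns the data.frame with a `meta`
#'   attribute
#' @export
write_table_csv <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta))
    writeLines(paste0("# ", names(meta), ": ",
                      vapply(meta, format, character(1))), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# ", lines)
  meta <- NULL
  if (any(hdr)) {
    kv <- sub("^# ", "", lines[hdr])
    keys <- sub(":.*$", "", kv)
    vals <- sub("^[^:]*: ?", "", kv)
    meta <- stats::setNames(as.list(vals), keys)
  }
  body <- lines[!hdr]
  if (!length(body) || !nzchar(body[1]))
    stop("malformed table file: no header row in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Observations JSON round-trip
#'
#' @param obs an [observations()] object
#' @param path JSON file path
#' @return `read_observations` returns the [observations()] object
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "la_observations"))
  jsonlite::write_json(list(mu = as.list(obs$mu),
                            sigma = as.list(obs$sigma),
                            provenance = obs$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  observations(unlist(x$mu), unlist(x$sigma), provenance = x$provenance)
}

#' Run the full calibration pipeline
#'
#' Executes the stage chain in order — 14-parameter Sobol design,
#' simulation, per-feature emulation with cross-validation, global
#' sensitivity analysis and parameter ranking, fixing C_region,
#' history-matching waves in the 9-parameter space, ensemble MCMC, MAP
#' and nearest simulated neighbour, and the synthetic-cohort
#' mixed-effects analysis — writing each stage's artifacts and a
#' manifest into `outdir`. Any stage failure halts with the stage name.
#'
#' @param config a `pipeline_config`
#' @param outdir artifact directory (created if needed)
#' @return invisibly, a list with the in-memory stage results
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("lascal_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- pipeline_manifest(config)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  anatomy <- default_anatomy(V_ED = config$anatomy$V_ED,
                             A_MV = config$anatomy$A_MV)
  grid <- time_grid()
  seed <- config$seed

  r14 <- param_ranges(config$design$mode)
  X <- stage("design", sobol_design(r14, config$design$n_train))
  write_table_csv(X, file.path(outdir, "design.csv"),
                  meta = list(stage = "design", seed = seed))
  Y <- stage("simulate", run_design(X, anatomy, grid))
  write_table_csv(Y, file.path(outdir, "features.csv"),
                  meta = list(stage = "simulate", units = "ml|mm"))

  eb <- feature_emulator_basis(anatomy)
  cv <- stage("emulate_cv", {
    lapply(seq_len(ncol(Y)), function(j)
      cross_validate(X, Y[, j], k = config$emulation$cv_folds,
                     seed = seed, ranges = r14,
                     n_restarts = min(config$emulation$n_restarts, 3),
                     maxit = config$emulation$maxit,
                     extra_basis = eb, output_transform = "log"))
  })
  names(cv) <- colnames(Y)
  cv_tab <- data.frame(feature = names(cv),
                       mean_R2 = vapply(cv, `[[`, numeric(1), "mean_R2"),
                       mean_ISE = vapply(cv, `[[`, numeric(1), "mean_ISE"))
  write_table_csv(cv_tab, file.path(outdir, "cv_report.csv"))

  emus14 <- stage("emulate", fit_emulators(
    X, Y, ranges = r14, n_restarts = config$emulation$n_restarts,
    seed = seed, maxit = config$emulation$maxit,
    extra_basis = eb, output_transform = "log"))
  gsa <- stage("gsa", gsa_emulators(emus14, r14, N = config$gsa$N))
  write_table_csv(gsa$ranking, file.path(outdir, "gsa_ranking.csv"))

  # fix C_region and calibrate in the 9-parameter space
  obs <- stage("observations", make_verification_observations(
    noise_level = config$noise$level, seed = seed, anatomy = anatomy,
    grid = grid))
  write_observations(obs, file.path(outdir, "observations.json"))

  hm_cfg <- hm_config(n_test = config$hm$n_test,
                      n_simul_wave1 = config$hm$n_simul_wave1,
                      n_simul = config$hm$n_simul,
                      threshold_start = config$hm$threshold_start,
                      threshold_step = config$hm$threshold_step,
                      threshold_floor = config$hm$threshold_floor,
                      convergence_tol = config$hm$convergence_tol,
                      max_waves = config$hm$max_waves, seed = seed)
  cal <- stage("hm_mcmc", calibrate(
    obs, param_ranges("9"), hm_cfg,
    n_walkers = config$mcmc$n_walkers, n_steps = config$mcmc$n_steps,
    burn_in = config$mcmc$burn_in, thin = config$mcmc$thin,
    max_extensions = config$mcmc$max_extensions, anatomy = anatomy,
    grid = grid, seed = seed))
  waves_tab <- do.call(rbind, lapply(cal$hm$waves, as.data.frame))
  write_table_csv(waves_tab, file.path(outdir, "hm_waves.csv"))
  write_table_csv(cal$posterior$samples,
                  file.path(outdir, "posterior_samples.csv"),
                  meta = list(stage = "mcmc", seed = seed))
  ci <- credible_summaries(cal$posterior)
  jsonlite::write_json(list(
    map = as.list(cal$map_neighbour$map),
    neighbour = as.list(cal$map_neighbour$neighbour),
    intervals = ci$intervals,
    acceptance = cal$posterior$accept_rate,
    tau = cal$posterior$tau, rhat = cal$posterior$rhat),
    file.path(outdir, "posterior_summary.json"),
    auto_unbox = TRUE, digits = NA)

  cohort <- stage("stats", make_cohort(config$stats$n_patients,
                                       seed = seed))
  lmm <- fit_lmm(cohort, covariate = "alpha")
  write_table_csv(lmm$coefficients, file.path(outdir, "lmm_alpha.csv"))
  reg <- matrix(cohort$d_ES, ncol = 5, byrow = TRUE,
                dimnames = list(NULL, la_regions()))
  tt <- paired_t_bonferroni(reg)
  write_table_csv(as.data.frame(tt$p_adjusted),
                  file.path(outdir, "paired_t_adjusted.csv"))

  invisible(list(design = X, features = Y, cv = cv, gsa = gsa,
                 obs = obs, calibration = cal, cohort = cohort,
                 lmm = lmm, paired_t = tt, outdir = outdir,
                 manifest = manifest))
}
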
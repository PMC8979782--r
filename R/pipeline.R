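#' Read the three claims tables from a directory
#'
#' Expects `patients.csv`, `dispensings.csv`, `episodes.csv` with ISO-8601
#' dates, as written by the `simulate` stage or supplied by the user.
#'
#' @param dir directory containing the tables.
#' @return list `patients`, `dispensings`, `episodes` with Date columns parsed.
#' @export
read_claims <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  patients <- rd("patients.csv")
  for (v in c("date_of_birth", "death_date", "rac_entry_date",
              "full_entitlement_start"))
    patients[[v]] <- as.Date(patients[[v]])
  dispensings <- rd("dispensings.csv")
  dispensings$supply_date <- as.Date(dispensings$supply_date)
  dispensings$strength_mg <- as.character(dispensings$strength_mg)
  episodes <- rd("episodes.csv")
  episodes$admission_date <- as.Date(episodes$admission_date)
  list(patients = patients, dispensings = dispensings, episodes = episodes)
}

# stage manifest: config snapshot + input hashes + seed + versions.
write_manifest <- function(out_dir, stage, inputs, config_snapshot, seed) {
  hashes <- list()
  if (length(inputs)) {
    hashes <- as.list(tools::md5sum(inputs))
    names(hashes) <- basename(names(hashes))
  }
  manifest <- list(stage = stage, seed = seed,
                   package_version = as.character(utils::packageVersion("wceclaims")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   inputs = hashes, config = config_snapshot)
  jsonlite::write_json(manifest, file.path(out_dir, paste0("manifest-", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
}

serialize_fit <- function(fit, path) {
  jsonlite::write_json(list(
    model = fit$model, ties = fit$ties,
    basis = if (!is.null(fit$basis))
      list(window = fit$basis$window, n_knots = fit$basis$n_knots,
           constrained = fit$basis$constrained),
    theta = as.list(fit$theta), beta = as.list(fit$beta),
    vcov = fit$vcov, loglik = fit$loglik, bic = fit$bic,
    n_events = fit$n_events, converged = fit$converged
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
}

#' Load a serialized fit for prediction
#'
#' Rebuilds a prediction-capable fit object (coefficients, covariance, spline
#' basis) from the JSON written by the `fit-wce` / `fit-ncc` stages.
#'
#' @param path path to a fit JSON artifact.
#' @return a `wce_fit`-like object usable with [weight_function_ci()],
#'   [pattern_hr()] and [hr_surface()].
#' @export
load_fit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- if (!is.null(j$basis))
    spline_basis(j$basis$window, j$basis$n_knots, isTRUE(j$basis$constrained))
  theta <- unlist(j$theta); beta <- unlist(j$beta)
  vcov <- as.matrix(j$vcov)
  nm <- c(names(theta), names(beta))
  dimnames(vcov) <- list(nm, nm)
  structure(list(theta = theta, beta = beta, coef = c(theta, beta),
                 vcov = vcov, loglik = j$loglik, bic = j$bic,
                 n_events = j$n_events, basis = basis, ties = j$ties,
                 converged = j$converged, model = j$model),
            class = "wce_fit")
}

#' Pipeline configuration
#'
#' Assembles the settings of a full pipeline run. All fields have working
#' defaults; a YAML file with the same field names can be loaded with
#' [read_pipeline_config()].
#'
#' @param sim a [sim_config()] (used by the `simulate` stage).
#' @param claims a [claims_config()].
#' @param candidates candidate basis grid for `fit-wce` (data.frame with
#'   `window`, `knots`, `constrained`).
#' @param ncc list: `n_controls`, `age_caliper`, `entry_caliper`, `seed`,
#'   `window` (basis window for the NCC fit), `knots`, `constrained`.
#' @param heatmap list: `doses`, `durations`, `stop_durations`, `stop_lags` —
#'   the prediction grids of the `report` stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            claims = sim$claims,
                            candidates = NULL,
                            ncc = list(n_controls = 2, age_caliper = 2,
                                       entry_caliper = 30, seed = 1L,
                                       window = 75, knots = 1,
                                       constrained = FALSE),
                            heatmap = list(doses = 1:4, durations = 2:75,
                                           stop_durations = c(2, 7, 30),
                                           stop_lags = 1:75)) {
  # default grid: windows x knots 1..3, unconstrained and constrained
  if (is.null(candidates))
    candidates <- expand.grid(window = c(30, 60, 75, 90, 180), knots = 1:3,
                              constrained = c(FALSE, TRUE),
                              KEEP.OUT.ATTRS = FALSE)
  structure(list(sim = sim, claims = claims, candidates = candidates,
                 ncc = ncc, heatmap = heatmap), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `sim` (fields of [sim_config()] other than
#' `claims` and `true_weights`; `true_weight_scale` scales the default truth),
#' `claims` (fields of [claims_config()]), `candidates` (list of
#' `window`/`knots`/`constrained`), `ncc`, `heatmap`. Missing keys fall back
#' to package defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  claims_args <- y$claims %||% list()
  for (v in c("study_start", "study_end"))
    if (!is.null(claims_args[[v]])) claims_args[[v]] <- as.Date(claims_args[[v]])
  claims <- do.call(claims_config, claims_args)
  sim_args <- y$sim %||% list()
  scale <- sim_args$true_weight_scale %||% 1
  sim_args$true_weight_scale <- NULL
  sim_args$claims <- claims
  sim_args$true_weights <- default_true_weights(scale)
  if (!is.null(sim_args$true_covariate_effects))
    sim_args$true_covariate_effects <- unlist(sim_args$true_covariate_effects)
  if (!is.null(sim_args$comorbidity_prev))
    sim_args$comorbidity_prev <- unlist(sim_args$comorbidity_prev)
  sim <- do.call(sim_config, sim_args)
  args <- list(sim = sim, claims = claims)
  if (!is.null(y$candidates))
    args$candidates <- do.call(rbind, lapply(y$candidates, as.data.frame))
  if (!is.null(y$ncc)) args$ncc <- utils::modifyList(
    pipeline_config(sim = sim)$ncc, y$ncc)
  if (!is.null(y$heatmap)) args$heatmap <- lapply(y$heatmap, unlist)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one pipeline stage
#'
#' Stages: `simulate` (claims tables + truth from the simulator),
#' `build-cohort` (eligibility cascade, cohort, counting process, exclusion
#' ledger), `fit-wce` (BIC selection over the candidate grid; best fit
#' serialized), `fit-ncc` (matched sets + conditional logistic WCE fit),
#' `predict` (weight function and HR surface from a fit JSON), `report`
#' (weight-function bands, dose-duration HR grid, past-use HR curves,
#' covariate HR table). Each stage writes its artifacts plus a manifest with
#' input hashes, config snapshot and seed into `out_dir`; no stage mutates
#' upstream artifacts. Stages expect their upstream artifacts in `out_dir`.
#'
#' @param command stage name.
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created if missing).
#' @param seed integer seed for the stages that draw (simulate, fit-ncc);
#'   overrides the seeds in `config`.
#' @return invisibly, the paths of the artifacts written.
#' @export
run_pipeline <- function(command = c("simulate", "build-cohort", "fit-wce",
                                     "fit-ncc", "predict", "report"),
                         config = pipeline_config(), out_dir = ".",
                         seed = NULL) {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  need <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p))
      stop("stage-order error: missing upstream artifact ", f, call. = FALSE)
    p
  }
  wcsv <- function(x, f) {
    p <- file.path(out_dir, f)
    utils::write.csv(x, p, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }

  if (command == "simulate") {
    sim_cfg <- config$sim
    if (!is.null(seed)) sim_cfg$seed <- as.integer(seed)
    out <- simulate_population(sim_cfg)
    wcsv(out$patients, "patients.csv")
    wcsv(out$dispensings, "dispensings.csv")
    wcsv(out$episodes, "episodes.csv")
    truth <- list(weights = if (!is.null(out$truth$weights)) list(
      window = out$truth$weights$basis$window,
      n_knots = out$truth$weights$basis$n_knots,
      constrained = out$truth$weights$basis$constrained,
      theta = as.list(out$truth$weights$theta)),
      per_patient = out$truth$per_patient)
    if (sim_cfg$n_patients <= 200) truth$hazard <- out$truth$hazard
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_manifest(out_dir, "simulate", character(0),
                   list(n_patients = sim_cfg$n_patients,
                        study_start = format(config$claims$study_start),
                        study_end = format(config$claims$study_end)),
                   sim_cfg$seed)
  } else if (command == "build-cohort") {
    ins <- c(need("patients.csv"), need("dispensings.csv"), need("episodes.csv"))
    tabs <- read_claims(out_dir)
    cohort <- build_cohort(tabs$patients, tabs$dispensings, tabs$episodes,
                           config$claims)
    wcsv(cohort$members, "cohort.csv")
    wcsv(cohort$exclusions, "exclusions.csv")
    wcsv(build_counting_process(cohort), "counting_process.csv")
    wcsv(series_to_long(cohort$exposure), "exposure_days.csv")
    write_manifest(out_dir, "build-cohort", ins,
                   list(study_start = format(config$claims$study_start),
                        study_end = format(config$claims$study_end)), NA)
  } else if (command == "fit-wce") {
    ins <- c(need("patients.csv"), need("dispensings.csv"), need("episodes.csv"))
    tabs <- read_claims(out_dir)
    cohort <- build_cohort(tabs$patients, tabs$dispensings, tabs$episodes,
                           config$claims)
    sel <- select_model(cohort, config$candidates)
    wcsv(sel$table, "model_selection.csv")
    serialize_fit(sel$fits[[1]], file.path(out_dir, "fit_wce.json"))
    paths <- c(paths, file.path(out_dir, "fit_wce.json"))
    write_manifest(out_dir, "fit-wce", ins,
                   list(candidates = nrow(config$candidates)), NA)
  } else if (command == "fit-ncc") {
    ins <- c(need("patients.csv"), need("dispensings.csv"), need("episodes.csv"))
    tabs <- read_claims(out_dir)
    cohort <- build_cohort(tabs$patients, tabs$dispensings, tabs$episodes,
                           config$claims)
    ncc_seed <- if (!is.null(seed)) as.integer(seed) else config$ncc$seed
    sets <- sample_risk_sets(cohort, seed = ncc_seed,
                             n_controls = config$ncc$n_controls,
                             age_caliper = config$ncc$age_caliper,
                             entry_caliper = config$ncc$entry_caliper)
    wcsv(sets$sets, "ncc_sets.csv")
    fit <- fit_wce_clogit(sets, cohort, tabs$dispensings,
                          spline_basis(config$ncc$window, config$ncc$knots,
                                       isTRUE(config$ncc$constrained)))
    serialize_fit(fit, file.path(out_dir, "fit_ncc.json"))
    paths <- c(paths, file.path(out_dir, "fit_ncc.json"))
    write_manifest(out_dir, "fit-ncc", ins,
                   list(n_controls = config$ncc$n_controls), ncc_seed)
  } else if (command == "predict" || command == "report") {
    fp <- need("fit_wce.json")
    fit <- load_fit(fp)
    wcsv(weight_function_ci(fit), "weight_function.csv")
    hm <- config$heatmap
    wcsv(hr_surface(fit, hm$doses, hm$durations, stop_lags = 0),
         "hr_current_use.csv")
    wcsv(hr_surface(fit, hm$doses, hm$stop_durations, stop_lags = hm$stop_lags),
         "hr_past_use.csv")
    if (command == "report") {
      wcsv(covariate_table(fit), "covariate_hr.csv")
      if (file.exists(file.path(out_dir, "fit_ncc.json"))) {
        nfit <- load_fit(file.path(out_dir, "fit_ncc.json"))
        wcsv(weight_function_ci(nfit), "weight_function_ncc.csv")
      }
    }
    write_manifest(out_dir, command, fp, list(), NA)
  }
  invisible(paths)
}
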
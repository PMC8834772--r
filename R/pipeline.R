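#' Configure an end-to-end projection run
#'
#' @param outcomes subset of \code{c("incidence", "mortality")}.
#' @param scenarios named list of [scenario_config()] per outcome (the
#'   bundled Catalonia-like pair by default), or \code{NULL} when reading
#'   from files.
#' @param counts_paths,population_paths named per-outcome CSV paths (used
#'   when \code{scenarios} is \code{NULL}); counts cover observed years,
#'   population covers observed plus projection years.
#' @param observed_years,projection_years year ranges; defaults follow the
#'   scenario configs. An empty \code{projection_years} yields an
#'   observed-only report (no projections, no decomposition).
#' @param reference_years the two burden-table years (default 2015, 2030).
#' @param truncate_from reporting/modelling age cut-off (default 45).
#' @param standard a [standard_population()] (ESP 2013 by default).
#' @param sampler,prior passed to [apc_spec()].
#' @param seed master seed; per-outcome fit seeds are derived from it.
#' @param outdir output directory for the report bundle.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(outcomes = c("incidence", "mortality"),
                       scenarios = NULL, counts_paths = NULL,
                       population_paths = NULL,
                       observed_years = NULL, projection_years = NULL,
                       reference_years = c(2015L, 2030L),
                       truncate_from = 45,
                       standard = standard_population(),
                       sampler = list(), prior = list(),
                       seed = 1L, outdir = tempfile("apcrun")) {
  outcomes <- match.arg(outcomes, c("incidence", "mortality"),
                        several.ok = TRUE)
  if (is.null(scenarios) && is.null(counts_paths)) {
    scenarios <- lapply(stats::setNames(nm = outcomes), function(o) {
      catalonia_like_scenario(o, seed = seed * 10L + match(o, outcomes))
    })
  }
  structure(list(outcomes = outcomes, scenarios = scenarios,
                 counts_paths = counts_paths,
                 population_paths = population_paths,
                 observed_years = observed_years,
                 projection_years = projection_years,
                 reference_years = as.integer(reference_years),
                 truncate_from = truncate_from, standard = standard,
                 sampler = sampler, prior = prior,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Run the full burden-projection pipeline
#'
#' For each outcome: load or simulate the count/population tables, fit the
#' Bayesian APC model, project counts and ASRs with 95% prediction
#' intervals, compute AAPCs over the observed and projected spans, extract
#' cohort and period relative-risk curves, build a burden table at the
#' reference years (aggregated to 10-year reporting bands), and decompose
#' the net change in cases between the reference years into risk, ageing
#' and size components. All stage outputs are written as CSV under
#' \code{config$outdir} together with a JSON manifest (config digest, seed,
#' package version); rounded display tables always have a full-precision
#' companion. Any stage failure aborts the run with the stage named and
#' removes partial outputs. Runs are deterministic given the config and
#' seed.
#'
#' @param config a [run_config()].
#' @return (invisibly) a named list of per-outcome results plus the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  results <- tryCatch({
    res <- lapply(stats::setNames(nm = config$outcomes), function(oc) {
      run_outcome(config, oc, function(s) stage <<- paste0(oc, "/", s))
    })
    stage <- "manifest"
    manifest <- list(
      outcomes = config$outcomes,
      reference_years = config$reference_years,
      truncate_from = config$truncate_from,
      seed = config$seed,
      source = if (is.null(config$scenarios)) "files" else "scenario",
      package_version = as.character(utils::packageVersion("apcburden")))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
               file.path(config$outdir, "manifest.json"))
    res
  }, error = function(e) {
    unlink(config$outdir, recursive = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(c(results, list(outdir = config$outdir)))
}

run_outcome <- function(config, outcome, set_stage) {
  log_stage <- function(s) {
    set_stage(s)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), outcome, s))
  }
  od <- function(...) file.path(config$outdir, paste0(outcome, "_", ...))

  log_stage("data")
  if (!is.null(config$scenarios)) {
    scen <- config$scenarios[[outcome]]
    tr <- generate_truth(scen)
    population <- tr$population
    obs_years <- scen$years[scen$years <= scen$observed_through]
    proj_years <- scen$years[scen$years > scen$observed_through]
    counts <- sample_counts(tr, years = obs_years, outcome = outcome)
  } else {
    counts <- read_table(config$counts_paths[[outcome]], "counts",
                         outcome = outcome)
    population <- read_table(config$population_paths[[outcome]], "population")
    obs_years <- counts$years
    proj_years <- setdiff(population$years, obs_years)
  }
  if (!is.null(config$observed_years)) obs_years <- config$observed_years
  if (!is.null(config$projection_years)) proj_years <- config$projection_years
  projecting <- length(proj_years) > 0
  write_table(counts, od("counts_observed.csv"))
  write_table(population, od("population.csv"))

  log_stage("fit")
  spec <- apc_spec(projection_years = proj_years, prior = config$prior,
                   sampler = config$sampler,
                   seed = config$seed + 131L * match(outcome, config$outcomes))
  fit <- fit_apc(counts, population, spec)

  log_stage("project")
  projections <- NULL
  if (projecting) {
    projections <- project_counts(fit)
    utils::write.csv(projections, od("projected_counts.csv"), row.names = FALSE)
  }

  log_stage("rates")
  series <- asr_series(fit, config$standard, config$truncate_from)
  utils::write.csv(series, od("asr_series.csv"), row.names = FALSE)
  aapcs <- data.frame(
    span = c("observed", if (projecting) "projected"),
    from = c(min(obs_years), if (projecting) max(obs_years) + 1L),
    to = c(max(obs_years), if (projecting) max(proj_years)))
  aapcs$aapc_endpoint <- mapply(function(f, t) {
    aapc(series, f, t, "endpoint_geometric")
  }, aapcs$from, aapcs$to)
  aapcs$aapc_loglinear <- mapply(function(f, t) {
    aapc(series, f, t, "loglinear_regression")
  }, aapcs$from, aapcs$to)
  utils::write.csv(aapcs, od("aapc.csv"), row.names = FALSE)

  log_stage("effects")
  for (ax in c("cohort", "period")) {
    utils::write.csv(extract_relative_effects(fit, ax),
                     od("effects_", ax, ".csv"), row.names = FALSE)
  }

  burden <- decomp <- NULL
  ref <- config$reference_years
  if (all(ref %in% fit$design$years_all)) {
    log_stage("burden")
    # model-based expected counts at the reference years (fitted values for
    # years inside the observed range, projections beyond it)
    med_rates <- fitted_rate_matrix(fit)
    ref_counts <- count_table(
      counts$bands, ref[1]:ref[2],
      round(med_rates[, as.character(ref[1]:ref[2]), drop = FALSE] *
              population$values[, match(ref[1]:ref[2], population$years)]),
      outcome = outcome)
    report_bands <- reporting_bands(counts$bands)
    ref_rep <- aggregate_bands(ref_counts, report_bands)
    asr_ref <- stats::setNames(series$asr[match(ref, series$year)],
                               as.character(ref))
    burden <- burden_table(ref_rep, asr_ref, ref)
    utils::write.csv(burden, od("burden_full_precision.csv"), row.names = FALSE)
    utils::write.csv(format_burden_table(burden), od("burden.csv"),
                     row.names = FALSE)

    log_stage("decomposition")
    decomp <- decompose_net_change(
      1e5 * med_rates[, as.character(ref[1])],
      population$values[, match(ref[1], population$years)],
      1e5 * med_rates[, as.character(ref[2])],
      population$values[, match(ref[2], population$years)])
    utils::write.csv(data.frame(
      cases_baseline = decomp$cases_baseline, cases_final = decomp$cases_final,
      net_change_pct = decomp$net_change_pct, aging_pct = decomp$aging_pct,
      risk_pct = decomp$risk_pct, size_pct = decomp$size_pct),
      od("decomposition.csv"), row.names = FALSE)
  }

  list(fit = fit, projections = projections, asr = series, aapc = aapcs,
       burden = burden, decomposition = decomp)
}

# Posterior-median rate matrix (per person-year) over bands x all years.
fitted_rate_matrix <- function(fit) {
  med <- apply(fit$lambda, 2, stats::median)
  out <- matrix(NA_real_, nrow(fit$design$bands), length(fit$design$years_all),
                dimnames = list(fit$design$bands$label, fit$design$years_all))
  out[cbind(fit$cells$a, match(fit$cells$year, fit$design$years_all))] <- med
  out
}

# Default 10-year reporting bands for a 5-year modelling grid starting at
# the truncation age: 45-54, 55-64, 65-74, 75+.
reporting_bands <- function(bands) {
  lo <- min(bands$lower)
  tops <- seq(lo, max(bands$lower) - 10, by = 10)
  c(paste0(tops[-length(tops)], "-", tops[-length(tops)] + 9),
    paste0(tops[length(tops)], "+"))
}

#' Trend projection for the youngest reporting band
#'
#' The under-45 band is excluded from APC modelling (event rates there are
#' very low) but still appears in burden reports. This projects its counts
#' by a year-only log-linear Poisson trend (no age or cohort structure) and
#' returns the reference-year entries to merge into a burden table.
#'
#' @param counts_u45 a [count_table()] with the single young band over the
#'   observed years.
#' @param reference_years years at which fitted/projected counts are needed.
#' @return data.frame: year, N (expected counts from the trend model).
#' @export
report_under45 <- function(counts_u45, reference_years) {
  stopifnot(inherits(counts_u45, "count_table"), nrow(counts_u45$bands) == 1)
  y <- as.numeric(counts_u45$values[1, ])
  if (all(y == 0)) stop("all-zero observed series", call. = FALSE)
  df <- data.frame(year = counts_u45$years, y = y)
  fit <- stats::glm(y ~ year, family = stats::poisson(), data = df)
  data.frame(year = as.integer(reference_years),
             N = as.numeric(stats::predict(
               fit, newdata = data.frame(year = reference_years),
               type = "response")))
}
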
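# Shared fixtures, built in code.

# Small scenario for fast model tests: 5 bands, 12 observed + 3 projected
# years, large enough person-years that fits are well informed.
small_scenario <- function(period_drift = -0.015, cohort_drift = -0.04,
                           cohort_bump = NULL, py = 3e5, seed = 7L) {
  scenario_config(
    age_bands = c("45-49", "50-54", "55-59", "60-64", "65+"),
    years = 2000:2014, observed_through = 2011,
    age_curve = log(c(10, 15, 20, 25, 28) / 1e5),
    period_drift = period_drift, cohort_drift = cohort_drift,
    cohort_bump = cohort_bump,
    base_population = rep(py, 5),
    population_growth = 1.003, aging_shift = 0.002, seed = seed)
}

# Sampler settings for unit tests, where speed matters more than the
# convergence flag (fits are short; warnings are suppressed explicitly
# where the flag is not the property under test).
fast_sampler <- list(chains = 2L, adapt = 300L, burnin = 300L,
                     iter = 1500L, thin = 1L)

fit_scenario <- function(scen, sampler = fast_sampler, seed = 11L,
                         outcome = "incidence") {
  tr <- generate_truth(scen)
  obs <- scen$years[scen$years <= scen$observed_through]
  proj <- scen$years[scen$years > scen$observed_through]
  counts <- sample_counts(tr, years = obs, outcome = outcome)
  fit <- suppressWarnings(fit_apc(counts, tr$population,
                                  apc_spec(projection_years = proj,
                                           sampler = sampler, seed = seed)))
  list(truth = tr, counts = counts, fit = fit)
}

# Coverage of truth coordinates by central 95% posterior intervals.
ci_coverage <- function(draws, truth, sel = seq_along(truth)) {
  lo <- apply(draws, 2, stats::quantile, 0.025)
  hi <- apply(draws, 2, stats::quantile, 0.975)
  mean(truth[sel] >= lo[sel] & truth[sel] <= hi[sel])
}
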
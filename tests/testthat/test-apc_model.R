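make_design <- function(bands, years_obs, years_proj = integer(0)) {
  nb <- length(bands)
  counts <- count_table(bands, years_obs, matrix(1L, nb, length(years_obs)))
  pop <- population_table(bands, c(years_obs, years_proj),
                          matrix(1e5, nb, length(years_obs) + length(years_proj)))
  build_design(counts, pop, apc_spec(projection_years = years_proj))
}

test_that("cohort bucketing follows the midpoint rule and is contiguous", {
  d <- make_design(c("45-49", "50-54", "55-59"), 1995:2005)
  # band [45,50) has midpoint 47; year 2000 -> birth 1953 -> bucket 1950-1954
  cell <- d$cells[d$cells$band == "45-49" & d$cells$year == 2000, ]
  expect_equal(d$cohort_labels[cell$c], "1950-1954")
  # one band up, five years later: same diagonal, same cohort
  cell2 <- d$cells[d$cells$band == "50-54" & d$cells$year == 2005, ]
  expect_equal(cell2$c, cell$c)
  # full lattice: bucket indices contiguous and every cell assigned once
  expect_equal(sort(unique(d$cells$c)), seq_along(d$cohorts))
  expect_equal(diff(d$cohorts), rep(5L, length(d$cohorts) - 1))
  expect_equal(nrow(d$cells),
               3 * length(d$years_all))

  # degenerate lattice: one band, one year, one cohort
  d1 <- make_design("45-49", 2000)
  expect_equal(length(d1$cohorts), 1L)
})

test_that("design rejects mismatched grids and detached projection ranges", {
  counts <- count_table(c("45-49", "50-54"), 2000:2009, matrix(1L, 2, 10))
  pop_other <- population_table(c("50-54", "55-59"), 2000:2009,
                                matrix(1e4, 2, 10))
  expect_error(build_design(counts, pop_other, apc_spec()), "same age bands")
  pop <- population_table(c("45-49", "50-54"), 2000:2009, matrix(1e4, 2, 10))
  expect_error(build_design(counts, pop, apc_spec(projection_years = 2012:2013)),
               "immediately after")
  expect_error(build_design(counts, pop, apc_spec(projection_years = 2010:2012)),
               "must cover")
})

test_that("identification is invariant to pre-constraint level shifts", {
  d <- make_design(c("45-49", "50-54", "55-59"), 1995:2006, 2007:2009)
  set.seed(5)
  mu <- 0.3
  alpha <- rnorm(3); beta <- rnorm(length(d$years_all)); gamma <- rnorm(length(d$cohorts))
  a <- apcburden:::apc_identify(mu, alpha, beta, gamma, d)
  b <- apcburden:::apc_identify(mu - 0.7, alpha, beta + 0.7, gamma, d)
  expect_equal(a$alpha, b$alpha, tolerance = 1e-12)
  expect_equal(a$beta, b$beta, tolerance = 1e-12)
  expect_equal(a$gamma, b$gamma, tolerance = 1e-12)
  expect_equal(a$mu, b$mu, tolerance = 1e-12)
  # centring conventions hold exactly
  expect_equal(mean(a$alpha), 0, tolerance = 1e-12)
  expect_equal(mean(a$beta[, seq_along(d$years_obs)]), 0, tolerance = 1e-12)
  expect_equal(mean(a$gamma[, d$cohorts_obs]), 0, tolerance = 1e-12)
  bc <- d$cohorts + 2
  x <- bc[d$cohorts_obs] - mean(bc[d$cohorts_obs])
  expect_equal(sum(a$gamma[, d$cohorts_obs] * x), 0, tolerance = 1e-10)
})

test_that("fits are reproducible draw-for-draw under a fixed seed", {
  scen <- small_scenario()
  r1 <- fit_scenario(scen, seed = 3L)
  r2 <- fit_scenario(scen, seed = 3L)
  expect_identical(r1$counts$values, r2$counts$values)
  expect_identical(r1$fit$ypred, r2$fit$ypred)
  expect_identical(r1$fit$mu, r2$fit$mu)
})

test_that("degenerate inputs are rejected", {
  scen <- small_scenario()
  tr <- generate_truth(scen)
  obs <- 2000:2011
  counts <- sample_counts(tr, years = obs)
  zero <- count_table(counts$bands, obs, matrix(0L, 5, 12))
  expect_error(fit_apc(zero, tr$population, apc_spec(projection_years = 2012:2014)),
               "all counts are zero")
  short <- count_table(counts$bands, 2000:2005, counts$values[, 1:6])
  expect_error(fit_apc(short, tr$population, apc_spec()), "8 observed years")
})

test_that("flat-rate data yields near-zero centred effects", {
  # constant-rate surface with large person-years: the flat-surface limit
  scen <- small_scenario(period_drift = 0, cohort_drift = 0, py = 2e6)
  scen$age_curve[] <- log(25 / 1e5)
  r <- fit_scenario(scen, seed = 21L)
  id <- r$fit$identified
  d <- r$fit$design
  med <- function(m, sel) apply(m[, sel, drop = FALSE], 2, median)
  expect_lt(max(abs(med(id$alpha, seq_len(5)))), 0.05)
  expect_lt(max(abs(med(id$beta, seq_along(d$years_obs)))), 0.05)
  expect_lt(max(abs(med(id$gamma, d$cohorts_obs))), 0.05)
})

test_that("age-only model matches the analytic per-band rate estimate", {
  # with period and cohort clamped to zero, posterior median rates should
  # agree with events/person-years pooled per band
  bands <- c("45-49", "50-54", "55-59")
  years <- 2000:2007
  pop <- population_table(bands, years, matrix(5e5, 3, 8))
  rate <- c(10, 20, 30) / 1e5
  counts <- sample_counts(matrix(rate, 3, 8), pop, seed = 17L)
  fit <- suppressWarnings(fit_apc(counts, pop,
    apc_spec(components = "age", sampler = fast_sampler, seed = 2L)))
  med <- apply(fit$lambda, 2, median)
  mle <- rowSums(counts$values) / rowSums(pop$values)
  for (a in 1:3) {
    cells_a <- which(fit$cells$a == a)
    expect_equal(mean(med[cells_a]), unname(mle[a]), tolerance = 0.03)
  }
})

test_that("relative-effect curves are normalised and validated", {
  scen <- small_scenario()
  r <- fit_scenario(scen, seed = 13L)
  for (ax in c("cohort", "period")) {
    ec <- extract_relative_effects(r$fit, ax)
    expect_true(all(ec$relative_risk > 0))
    expect_true(all(ec$lower95 <= ec$relative_risk &
                      ec$relative_risk <= ec$upper95))
    # geometric mean of the median curve over observed labels is 1
    expect_equal(mean(log(ec$relative_risk[ec$observed])), 0,
                 tolerance = 1e-6)
  }
  expect_error(extract_relative_effects(r$fit, "age"), "arg")
})

test_that("projection intervals are ordered and scale with exposure", {
  scen <- small_scenario()
  r <- fit_scenario(scen, seed = 19L)
  proj <- project_counts(r$fit)
  expect_true(all(proj$lower >= 0))
  expect_true(all(proj$lower <= proj$median & proj$median <= proj$upper))
  expect_setequal(unique(proj$year), 2012:2014)

  # zero person-years force zero counts (Poisson(0))
  z <- matrix(0, 5, 2, dimnames = list(NULL, 2013:2014))
  pz <- project_counts(r$fit, z)
  expect_true(all(pz$median == 0 & pz$upper == 0))

  # doubling person-years doubles posterior-predictive means (rates fixed)
  fut <- r$truth$population$values[, as.character(2012:2014)]
  m1 <- project_counts(r$fit, fut)$mean
  m2 <- project_counts(r$fit, 2 * fut)$mean
  expect_equal(m2 / m1, rep(2, length(m1)), tolerance = 0.06)

  expect_error(project_counts(r$fit, matrix(1, 5, 1,
    dimnames = list(NULL, 2050))), "outside the model horizon")
})

test_that("non-convergence is flagged, not silently ignored", {
  # split-Rhat separates chains stuck at different levels ...
  stuck <- c(rnorm(200, 0), rnorm(200, 3))
  expect_gt(apcburden:::split_rhat(stuck, nchain = 2, niter = 200), 1.01)
  # ... and is ~1 for well-mixed chains
  set.seed(8)
  mixed <- rnorm(400)
  expect_lt(apcburden:::split_rhat(mixed, nchain = 2, niter = 200), 1.05)
  # a fit carries the flag and the per-quantity statistics
  scen <- small_scenario()
  r <- fit_scenario(scen, seed = 23L)
  expect_type(r$fit$diagnostics$converged, "logical")
  expect_true(all(is.finite(r$fit$diagnostics$rhat)))
  expect_equal(r$fit$diagnostics$converged,
               max(r$fit$diagnostics$rhat) <= 1.01)
})

test_that("centred-effect RMSE shrinks as person-years grow", {
  rmse_at <- function(py, seed) {
    scen <- small_scenario(py = py, seed = seed)
    r <- fit_scenario(scen, seed = seed)
    id <- r$fit$identified
    tr <- r$truth$truth
    d <- r$fit$design
    med <- function(m) apply(m, 2, median)
    sel_p <- seq_along(d$years_obs)
    err <- c(med(id$alpha) - tr$alpha,
             med(id$beta)[sel_p] - tr$beta[sel_p],
             med(id$gamma)[d$cohorts_obs] - tr$gamma[d$cohorts_obs])
    sqrt(mean(err^2))
  }
  r <- vapply(c(1e4, 1e5, 1e6), rmse_at, numeric(1), seed = 29L)
  expect_true(r[2] < r[1])
  expect_true(r[3] < r[2])
})
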
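#' Specify an age-period-cohort model run
#'
#' Collects everything that determines an APC fit besides the data: the
#' projection horizon, the prior scales of the random-walk innovation
#' standard deviations, the MCMC settings, and the seed. Periods are annual;
#' cohorts live on a 5-year grid derived from the band midpoints (see
#' [build_design()]).
#'
#' The model is \eqn{y_{ap} \sim Poisson(n_{ap}\lambda_{ap})} with
#' \eqn{\log\lambda_{ap} = \mu + \alpha_a + \beta_p + \gamma_{c(a,p)}}:
#' a second-order random walk on the age effects \eqn{\alpha} (smooth age
#' curve), a first-order random walk with drift on the period effects
#' \eqn{\beta} (the drift carries the calendar trend into the projection
#' years), and a driftless first-order random walk on the cohort effects
#' \eqn{\gamma}. Innovation standard deviations get half-normal priors.
#'
#' @param projection_years integer vector of years to project (must start
#'   immediately after the observed years end); may be empty.
#' @param prior named list of half-normal scales: \code{sd_age} (RW2
#'   innovation across adjacent 5-year bands), \code{sd_period} (annual RW1
#'   innovation), \code{sd_cohort} (RW1 innovation per 5-year cohort step),
#'   \code{sd_drift} (normal prior SD of the annual period drift) and
#'   \code{sd_intercept} (normal prior SD of \eqn{\mu}).
#' @param sampler named list: \code{chains}, \code{adapt}, \code{burnin},
#'   \code{iter} (posterior iterations per chain), \code{thin}.
#' @param seed integer seed controlling the JAGS chains and the posterior
#'   predictive draws; fixed seed gives draw-for-draw reproducibility.
#' @param components which effects enter the linear predictor; dropping
#'   \code{"period"}/\code{"cohort"} fits reduced models (used e.g. to check
#'   the age-only model against the analytic per-band rate estimate).
#' @return an object of class \code{apc_spec}.
#' @export
apc_spec <- function(projection_years = integer(0),
                     prior = list(),
                     sampler = list(),
                     seed = 1L,
                     components = c("age", "period", "cohort")) {
  prior_def <- list(sd_age = 1, sd_period = 0.05, sd_cohort = 0.2,
                    sd_drift = 1, sd_intercept = 10)
  sampler_def <- list(chains = 2L, adapt = 2000L, burnin = 3000L,
                      iter = 60000L, thin = 30L)
  prior <- utils::modifyList(prior_def, prior)
  sampler <- utils::modifyList(sampler_def, sampler)
  stopifnot(all(unlist(prior) > 0), sampler$chains >= 1, sampler$iter >= 1)
  components <- match.arg(components, c("age", "period", "cohort"),
                          several.ok = TRUE)
  structure(list(projection_years = as.integer(projection_years),
                 prior = prior, sampler = sampler, seed = as.integer(seed),
                 components = components),
            class = "apc_spec")
}

#' Index maps for the APC lattice
#'
#' Maps every (band, year) cell to age index \code{a}, period index \code{p}
#' and cohort index \code{c}. Periods are annual over the observed plus
#' projected years. Birth cohorts are bucketed on a 5-year grid: the birth
#' year of a cell is the calendar year minus the band's midpoint age
#' (floored, so band [45,50) has midpoint 47), and the bucket is the
#' enclosing \code{[5k, 5k+5)} interval of birth years. Two cells one band
#' up and five years later land in the same bucket by construction. The
#' bucket sequence over the full lattice must be contiguous.
#'
#' @param counts a [count_table()] over the observed years.
#' @param population a [population_table()] on the same bands, covering the
#'   observed and (when projecting) the projection years.
#' @param spec an [apc_spec()].
#' @return a list with the band table, year/cohort axes, per-cell index
#'   data.frame \code{cells} (columns band, year, a, p, c, observed), and
#'   the observed/projected masks used by the identification convention.
#' @export
build_design <- function(counts, population, spec) {
  stopifnot(inherits(counts, "count_table"),
            inherits(population, "population_table"),
            inherits(spec, "apc_spec"))
  if (!identical(counts$bands$label, population$bands$label)) {
    stop("counts and population must share the same age bands", call. = FALSE)
  }
  years_obs <- counts$years
  years_proj <- spec$projection_years
  if (length(years_proj) > 0 && years_proj[1] != max(years_obs) + 1L) {
    stop("projection years must start immediately after the observed years",
         call. = FALSE)
  }
  years_all <- c(years_obs, years_proj)
  if (!all(years_all %in% population$years)) {
    stop("population table must cover all observed and projection years",
         call. = FALSE)
  }
  bands <- counts$bands
  mid <- band_midpoint(bands)
  grid <- expand.grid(a = seq_len(nrow(bands)), p = seq_along(years_all))
  birth <- years_all[grid$p] - mid[grid$a]
  bucket <- 5L * (birth %/% 5L)
  buckets <- sort(unique(bucket))
  if (length(buckets) > 1 && any(diff(buckets) != 5L)) {
    stop("cohort buckets are not contiguous on the 5-year grid", call. = FALSE)
  }
  cells <- data.frame(
    band = bands$label[grid$a],
    year = years_all[grid$p],
    a = grid$a, p = grid$p,
    c = match(bucket, buckets),
    cohort = bucket,
    observed = years_all[grid$p] %in% years_obs)
  list(bands = bands, midpoints = mid,
       years_obs = years_obs, years_proj = years_proj, years_all = years_all,
       cohorts = buckets,
       cohort_labels = paste0(buckets, "-", buckets + 4L),
       cohorts_obs = sort(unique(cells$c[cells$observed])),
       cells = cells)
}

# Identification convention shared by the fitter and the truth generator.
#
# The APC linear predictor is invariant under adding t*(age midpoint) to
# alpha, subtracting t*year from beta and adding t*(birth year) to gamma.
# The convention fixes that direction by forcing the OLS slope of gamma
# (over the cohorts appearing in observed cells, per birth year) to zero,
# re-allocating it to the period axis, and then centring alpha, beta and
# gamma to mean zero over their observed index sets, with the constants
# absorbed into mu. On the bucketed cohort grid the slope transfer is exact
# up to the bucket rounding residual; predictions always use raw draws.
#
# mu, alpha, beta, gamma may be vectors/matrices with draws in rows.
apc_identify <- function(mu, alpha, beta, gamma, design) {
  alpha <- rbind(alpha); beta <- rbind(beta); gamma <- rbind(gamma)
  mu <- as.numeric(mu)
  bc <- design$cohorts + 2          # bucket midpoint birth year
  obs_c <- design$cohorts_obs
  obs_p <- seq_along(design$years_obs)
  mid <- design$midpoints
  # per-draw OLS slope of gamma on birth year over observed cohorts
  x <- bc[obs_c] - mean(bc[obs_c])
  s <- as.numeric(gamma[, obs_c, drop = FALSE] %*% x) / sum(x^2)
  gamma <- gamma - outer(s, bc - mean(bc[obs_c]))
  beta <- beta + outer(s, design$years_all - mean(design$years_obs))
  alpha <- alpha - outer(s, mid - mean(mid))
  am <- rowMeans(alpha)
  bm <- rowMeans(beta[, obs_p, drop = FALSE])
  gm <- rowMeans(gamma[, obs_c, drop = FALSE])
  list(mu = mu + am + bm + gm,
       alpha = alpha - am, beta = beta - bm, gamma = gamma - gm,
       net_drift = s)
}
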
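#' Fit a Bayesian autoregressive age-period-cohort model
#'
#' Fits the Poisson APC model described in [apc_spec()] by MCMC (JAGS),
#' with the period and cohort random walks extended over the projection
#' years: future period and cohort effects are sampled from their
#' autoregressive prior dynamics (drift plus innovation noise) conditional
#' on the posterior, which is what produces prediction intervals that widen
#' with the projection horizon. Posterior-predictive counts are drawn as
#' Poisson around each draw's rate surface times the person-years.
#'
#' Convergence is assessed by rank-normalised split-\eqn{\widehat{R}} on the
#' hyperparameters, the drift, and a spread of fitted cell log-rates (which
#' are identifiable; the raw effect levels are not). A fit with
#' \eqn{\widehat{R} > 1.01} is flagged with a warning and
#' \code{converged = FALSE}, never silently ignored.
#'
#' @param counts a [count_table()] over the observed years (at least 3
#'   bands and 8 years; not all zero).
#' @param population a [population_table()] on the same bands covering
#'   observed plus projection years.
#' @param spec an [apc_spec()].
#' @return an object of class \code{apc_posterior}: raw and identified
#'   effect draws, hyperparameter draws, rate draws \eqn{\lambda} and
#'   posterior-predictive count draws over bands x (observed + projected)
#'   years, the design, and diagnostics.
#' @export
fit_apc <- function(counts, population, spec = apc_spec()) {
  design <- build_design(counts, population, spec)
  obs <- design$cells[design$cells$observed, ]
  if (nrow(design$bands) < 3) stop("need at least 3 age bands", call. = FALSE)
  if (length(design$years_obs) < 8) {
    stop("need at least 8 observed years", call. = FALSE)
  }
  y <- counts$values[cbind(obs$a, match(obs$year, counts$years))]
  n <- population$values[cbind(obs$a, match(obs$year, population$years))]
  if (all(y == 0)) stop("degenerate data: all counts are zero", call. = FALSE)

  A <- nrow(design$bands)
  P <- length(design$years_all)
  C <- length(design$cohorts)
  use <- c(age = "age" %in% spec$components,
           period = "period" %in% spec$components,
           cohort = "cohort" %in% spec$components)
  model_txt <- jags_apc_model(A, P, C, use)
  dat <- list(y = as.numeric(y), logn = log(n), N = length(y),
              a = obs$a, p = obs$p, cc = obs$c,
              A = A, P = P, C = C,
              sd_age = spec$prior$sd_age,
              sd_period = spec$prior$sd_period,
              sd_cohort = spec$prior$sd_cohort,
              sd_drift = spec$prior$sd_drift,
              sd_mu = spec$prior$sd_intercept)
  drop <- c(if (!use["age"]) "sd_age",
            if (!use["period"]) c("sd_period", "sd_drift"),
            if (!use["cohort"]) "sd_cohort",
            if (!use["age"]) c("A", "a"), if (!use["period"]) c("P", "p"),
            if (!use["cohort"]) c("C", "cc"))
  dat <- dat[setdiff(names(dat), drop)]
  monitors <- c("mu",
                if (use["age"]) "alpha", if (use["period"]) c("beta", "drift"),
                if (use["cohort"]) "gamma",
                if (use["age"]) "sigma.alpha", if (use["period"]) "sigma.beta",
                if (use["cohort"]) "sigma.gamma")
  inits <- lapply(seq_len(spec$sampler$chains), function(ch) {
    list(mu = log(sum(y) / sum(n)),
         .RNG.name = "base::Wichmann-Hill",
         .RNG.seed = spec$seed * 100L + ch)
  })
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(model_txt), data = dat,
                          inits = inits, n.chains = spec$sampler$chains,
                          n.adapt = spec$sampler$adapt, quiet = TRUE)
  if (spec$sampler$burnin > 0) {
    stats::update(jm, spec$sampler$burnin, progress.bar = "none")
  }
  sam <- rjags::coda.samples(jm, monitors, n.iter = spec$sampler$iter,
                             thin = spec$sampler$thin, progress.bar = "none")
  draws <- do.call(rbind, lapply(sam, as.matrix))
  nchain <- length(sam)
  niter <- nrow(draws) / nchain

  pick <- function(stub, k) {
    if (k == 1 && stub %in% colnames(draws)) return(draws[, stub, drop = FALSE])
    draws[, paste0(stub, "[", seq_len(k), "]"), drop = FALSE]
  }
  mu_d <- as.numeric(draws[, "mu"])
  D <- length(mu_d)
  alpha_d <- if (use["age"]) pick("alpha", A) else matrix(0, D, A)
  beta_d <- if (use["period"]) pick("beta", P) else matrix(0, D, P)
  gamma_d <- if (use["cohort"]) pick("gamma", C) else matrix(0, D, C)

  # rate surface per draw over the full lattice (raw, identifiable)
  cells <- design$cells
  eta <- matrix(mu_d, D, nrow(cells)) +
    alpha_d[, cells$a, drop = FALSE] +
    beta_d[, cells$p, drop = FALSE] +
    gamma_d[, cells$c, drop = FALSE]
  lambda <- exp(eta)

  # posterior-predictive counts, seeded independently of the chains
  n_all <- population$values[cbind(cells$a, match(cells$year, population$years))]
  ypred <- with_seed(spec$seed + 7654321L, {
    matrix(stats::rpois(D * nrow(cells), lambda * rep(n_all, each = D)),
           D, nrow(cells))
  })

  ident <- apc_identify(mu_d, alpha_d, beta_d, gamma_d, design)

  hyper <- draws[, intersect(c("sigma.alpha", "sigma.beta", "sigma.gamma",
                               "drift"), colnames(draws)), drop = FALSE]
  # diagnostics target identifiable quantities: the canonicalised effects,
  # the innovation SDs and a spread of fitted cell log-rates; raw effect
  # levels and the raw drift lie along the APC non-identified directions
  diag_cells <- unique(round(seq(1, sum(cells$observed), length.out = 25)))
  diag_mat <- cbind(
    hyper[, setdiff(colnames(hyper), "drift"), drop = FALSE],
    if (use["age"]) ident$alpha,
    if (use["period"]) ident$beta,
    if (use["cohort"]) ident$gamma,
    eta[, which(cells$observed)[diag_cells], drop = FALSE])
  colnames(diag_mat) <- c(
    setdiff(colnames(hyper), "drift"),
    if (use["age"]) paste0("alpha", seq_len(A)),
    if (use["period"]) paste0("beta", seq_len(P)),
    if (use["cohort"]) paste0("gamma", seq_len(C)),
    paste0("lograte", diag_cells))
  rhat <- apply(diag_mat, 2, split_rhat, nchain = nchain, niter = niter)
  ess <- tryCatch(
    apply(diag_mat, 2, function(v) {
      coda::effectiveSize(coda::mcmc(v))
    }), error = function(e) rep(NA_real_, ncol(diag_mat)))
  converged <- all(is.finite(rhat)) && max(rhat) <= 1.01
  if (!converged) {
    warning("APC fit flagged for non-convergence: max split-Rhat = ",
            round(max(rhat, na.rm = TRUE), 3), call. = FALSE)
  }

  structure(list(
    design = design, spec = spec, outcome = counts$outcome,
    mu = mu_d, alpha = alpha_d, beta = beta_d, gamma = gamma_d,
    identified = ident, hyper = hyper,
    lambda = lambda, ypred = ypred, cells = cells,
    person_years = n_all,
    diagnostics = list(rhat = rhat, ess = ess, converged = converged),
    n_chains = nchain), class = "apc_posterior")
}

#' @export
print.apc_posterior <- function(x, ...) {
  cat(sprintf("<apc_posterior> %d draws (%d chains), %d bands x %d years (%d projected)\n",
              length(x$mu), x$n_chains, nrow(x$design$bands),
              length(x$design$years_all), length(x$design$years_proj)))
  cat(sprintf("max split-Rhat %.3f (%s)\n", max(x$diagnostics$rhat),
              if (x$diagnostics$converged) "converged" else "FLAGGED"))
  invisible(x)
}

# JAGS model text for the (possibly reduced) APC model.
jags_apc_model <- function(A, P, C, use) {
  lp <- c("mu",
          if (use["age"]) "alpha[a[i]]",
          if (use["period"]) "beta[p[i]]",
          if (use["cohort"]) "gamma[cc[i]]")
  paste0("model {\n",
  "  for (i in 1:N) {\n",
  "    y[i] ~ dpois(m[i])\n",
  "    log(m[i]) <- logn[i] + ", paste(lp, collapse = " + "), "\n",
  "  }\n",
  "  mu ~ dnorm(0, pow(sd_mu, -2))\n",
  if (use["age"]) paste0(
  "  alpha[1] ~ dnorm(0, 0.01)\n",
  "  alpha[2] ~ dnorm(alpha[1], 0.01)\n",
  "  for (j in 3:A) { alpha[j] ~ dnorm(2*alpha[j-1] - alpha[j-2], tau.alpha) }\n",
  "  sigma.alpha ~ dnorm(0, pow(sd_age, -2)) T(0,)\n",
  "  tau.alpha <- pow(sigma.alpha, -2)\n") else "",
  if (use["period"]) paste0(
  "  beta[1] ~ dnorm(0, 0.01)\n",
  "  for (t in 2:P) { beta[t] ~ dnorm(beta[t-1] + drift, tau.beta) }\n",
  "  drift ~ dnorm(0, pow(sd_drift, -2))\n",
  "  sigma.beta ~ dnorm(0, pow(sd_period, -2)) T(0,)\n",
  "  tau.beta <- pow(sigma.beta, -2)\n") else "",
  if (use["cohort"]) paste0(
  "  gamma[1] ~ dnorm(0, 0.01)\n",
  "  for (k in 2:C) { gamma[k] ~ dnorm(gamma[k-1], tau.gamma) }\n",
  "  sigma.gamma ~ dnorm(0, pow(sd_cohort, -2)) T(0,)\n",
  "  tau.gamma <- pow(sigma.gamma, -2)\n") else "",
  "}\n")
}

# Rank-normalised split-Rhat (Vehtari et al. style) for a single chain-
# stacked vector. Splits each chain in half.
split_rhat <- function(v, nchain, niter) {
  half <- floor(niter / 2)
  if (half < 2) return(NA_real_)
  chains <- matrix(v, nrow = niter)[seq_len(2 * half), , drop = FALSE]
  splits <- cbind(chains[seq_len(half), , drop = FALSE],
                  chains[half + seq_len(half), , drop = FALSE])
  z <- stats::qnorm((rank(splits) - 0.375) / (length(splits) + 0.25))
  z <- matrix(z, nrow = half)
  m <- ncol(z); nn <- nrow(z)
  mu_j <- colMeans(z); s2_j <- apply(z, 2, stats::var)
  B <- nn * stats::var(mu_j)
  W <- mean(s2_j)
  if (W == 0) return(1)
  sqrt((nn - 1) / nn + B / (W * nn))
}

# Evaluate a block with a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' Summarise projected counts with prediction intervals
#'
#' Posterior-predictive medians and central intervals of counts for the
#' years covered by \code{population_future}, obtained by Poisson sampling
#' around each draw's rate surface times the supplied person-years. Passing
#' the person-years used at fit time reproduces the fit's own predictive
#' summary; passing an alternative future population rescales the expected
#' counts while leaving the rates untouched.
#'
#' @param posterior an [fit_apc()] result.
#' @param population_future a [population_table()] on the model's bands, or
#'   a bare numeric matrix (bands x years, year-named columns; zeros
#'   allowed) covering a subset of the model's years. Defaults to the
#'   projection years of the fit with the fit's person-years.
#' @param level central interval probability.
#' @return data.frame with columns band, year, median, lower, upper, mean.
#' @export
project_counts <- function(posterior, population_future = NULL, level = 0.95) {
  stopifnot(inherits(posterior, "apc_posterior"))
  design <- posterior$design
  if (is.null(population_future)) {
    yrs <- design$years_proj
    if (length(yrs) == 0) stop("fit has no projection years", call. = FALSE)
    sel <- posterior$cells$year %in% yrs
    n <- posterior$person_years[sel]
  } else {
    pv <- if (inherits(population_future, "population_table")) {
      population_future$values
    } else {
      as.matrix(population_future)
    }
    if (any(pv < 0) || any(!is.finite(pv))) {
      stop("person-years must be finite and non-negative", call. = FALSE)
    }
    yrs <- as.integer(colnames(pv))
    if (nrow(pv) != nrow(design$bands)) {
      stop("future population must have one row per model band", call. = FALSE)
    }
    if (any(is.na(yrs)) || !all(yrs %in% design$years_all)) {
      stop("future population years missing or outside the model horizon",
           call. = FALSE)
    }
    sel <- posterior$cells$year %in% yrs
    n <- pv[cbind(posterior$cells$a[sel], match(posterior$cells$year[sel], yrs))]
  }
  lam <- posterior$lambda[, sel, drop = FALSE]
  D <- nrow(lam)
  yp <- with_seed(posterior$spec$seed + 999331L, {
    matrix(stats::rpois(length(lam), lam * rep(n, each = D)), D, ncol(lam))
  })
  qs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  qmat <- apply(yp, 2, stats::quantile, probs = qs, names = FALSE)
  out <- data.frame(band = posterior$cells$band[sel],
                    year = posterior$cells$year[sel],
                    median = qmat[2, ], lower = qmat[1, ], upper = qmat[3, ],
                    mean = colMeans(yp))
  out[order(out$year, match(out$band, design$bands$label)), , drop = FALSE]
}

#' Relative-risk curves by cohort or period
#'
#' Exponentiated centred effects: the risk of each birth cohort (or period)
#' relative to the average across the observed cohorts (periods), as
#' posterior medians with 95% intervals. The median curve is normalised so
#' its geometric mean over the observed labels is exactly 1.
#'
#' @param posterior an [fit_apc()] result.
#' @param axis \code{"cohort"} or \code{"period"}.
#' @param level central interval probability.
#' @return data.frame of class \code{effect_curve}: label (cohort bucket
#'   start-end or calendar year), relative_risk, lower95, upper95, observed.
#' @export
extract_relative_effects <- function(posterior, axis = c("cohort", "period"),
                                     level = 0.95) {
  stopifnot(inherits(posterior, "apc_posterior"))
  axis <- match.arg(axis)
  design <- posterior$design
  if (axis == "cohort") {
    eff <- posterior$identified$gamma
    labels <- design$cohort_labels
    obs <- seq_len(ncol(eff)) %in% design$cohorts_obs
  } else {
    eff <- posterior$identified$beta
    labels <- as.character(design$years_all)
    obs <- design$years_all %in% design$years_obs
  }
  qs <- c(0.5, (1 - level) / 2, 1 - (1 - level) / 2)
  qmat <- apply(eff, 2, stats::quantile, probs = qs, names = FALSE)
  shift <- mean(qmat[1, obs])  # exact geometric-mean-1 normalisation
  out <- data.frame(label = labels,
                    relative_risk = exp(qmat[1, ] - shift),
                    lower95 = exp(qmat[2, ] - shift),
                    upper95 = exp(qmat[3, ] - shift),
                    observed = obs)
  class(out) <- c("effect_curve", "data.frame")
  attr(out, "axis") <- axis
  out
}
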
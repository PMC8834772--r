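#' Standard populations for age standardisation
#'
#' Loads one of the bundled European Standard Population weight sets: the
#' 2013 revision (default) or the 1976 revision, in 5-year bands from
#' \code{"<5"} to \code{"85+"}, each summing to 100,000. A custom standard
#' can be built by passing any band/weight CSV with columns
#' \code{age_band,weight}.
#'
#' @param version \code{"esp2013"} or \code{"esp1976"}, or a path to a
#'   custom CSV.
#' @return an object of class \code{standard_population}: a data.frame of
#'   bands with a \code{weight} column.
#' @export
standard_population <- function(version = c("esp2013", "esp1976")) {
  path <- if (file.exists(version[1])) {
    version[1]
  } else {
    version <- match.arg(version)
    system.file("extdata", paste0(version, ".csv"), package = "apcburden",
                mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bands <- validate_bands(parse_age_bands(df$age_band))
  if (any(df$weight <= 0)) stop("standard weights must be positive", call. = FALSE)
  out <- cbind(bands, weight = as.numeric(df$weight))
  class(out) <- c("standard_population", "data.frame")
  out
}

# Map standard-population weights onto a (possibly coarser) band grid,
# restricted to bands with lower >= truncate_from. Each table band must be
# exactly covered by standard bands.
standard_weights_for <- function(bands, standard, truncate_from = 0) {
  keep <- which(bands$lower >= truncate_from)
  if (length(keep) == 0) {
    stop("age truncation at ", truncate_from, " leaves no bands", call. = FALSE)
  }
  w <- vapply(keep, function(i) {
    lo <- bands$lower[i]
    up <- bands$upper[i]
    inside <- if (is.na(up)) {
      standard$lower >= lo
    } else {
      standard$lower >= lo &
        (!is.na(standard$upper) & standard$upper <= up)
    }
    if (!any(inside)) {
      stop("standard population does not cover band '", bands$label[i], "'",
           call. = FALSE)
    }
    covered <- standard[inside, , drop = FALSE]
    span_ok <- covered$lower[1] == lo &&
      (is.na(up) || (!is.na(covered$upper[nrow(covered)]) &&
                       covered$upper[nrow(covered)] == up) ||
         identical(covered$upper[nrow(covered)], up))
    if (!span_ok) {
      stop("standard population bands do not tile band '", bands$label[i],
           "'", call. = FALSE)
    }
    sum(covered$weight)
  }, numeric(1))
  list(index = keep, weights = w / sum(w))
}

#' Expected counts from rates and a target population
#'
#' The registry-transfer step: applies age-specific rates (per 100,000
#' person-years) observed in registry areas to the person-years of a target
#' population, yielding expected case counts per cell, rounded to the
#' nearest integer so they can enter Poisson modelling downstream.
#'
#' @param registry_rates numeric matrix of rates per 100,000 (bands x
#'   years), or a vector recycled across the population's years.
#' @param target_population a [population_table()].
#' @param outcome outcome tag for the resulting [count_table()].
#' @return a [count_table()] on the population's grid.
#' @export
estimate_counts_from_rates <- function(registry_rates, target_population,
                                       outcome = NA_character_) {
  stopifnot(inherits(target_population, "population_table"))
  nb <- nrow(target_population$bands)
  ny <- length(target_population$years)
  r <- if (is.matrix(registry_rates)) registry_rates
       else matrix(registry_rates, nb, ny)
  if (nrow(r) != nb || ncol(r) != ny) {
    stop("rate grid does not match the target population grid", call. = FALSE)
  }
  counts <- round(r * target_population$values / 1e5)
  count_table(target_population$bands, target_population$years, counts,
              outcome = outcome)
}

#' Age-specific rates per 100,000
#'
#' @param counts a [count_table()].
#' @param population a matching [population_table()].
#' @return numeric matrix (bands x years) of rates per 100,000 person-years.
#' @export
age_specific_rates <- function(counts, population) {
  stopifnot(inherits(counts, "count_table"),
            inherits(population, "population_table"))
  if (!identical(counts$bands$label, population$bands$label) ||
      !identical(counts$years, population$years)) {
    stop("counts and population grids differ", call. = FALSE)
  }
  1e5 * counts$values / population$values
}

#' Truncated age-standardised rates
#'
#' Computes per-year ASRs: the weighted mean of age-specific rates using
#' standard-population weights renormalised over the included bands
#' (\code{lower >= truncate_from}), per 100,000 person-years. With
#' renormalised weights a constant-rate surface standardises to exactly
#' that constant for any standard.
#'
#' @param counts a [count_table()].
#' @param population a matching [population_table()].
#' @param standard a [standard_population()].
#' @param truncate_from include only bands starting at this age (default
#'   45, the usual cut-off for ovarian-cancer reporting in older women).
#' @return a data.frame of class \code{rate_series}: year, asr.
#' @export
asr <- function(counts, population, standard = standard_population(),
                truncate_from = 45) {
  rates <- age_specific_rates(counts, population)
  sw <- standard_weights_for(counts$bands, standard, truncate_from)
  series <- as.numeric(sw$weights %*% rates[sw$index, , drop = FALSE])
  rate_series(counts$years, series, truncation = truncate_from)
}

rate_series <- function(years, asr, lower95 = NA_real_, upper95 = NA_real_,
                        truncation = NA) {
  out <- data.frame(year = as.integer(years), asr = asr,
                    lower95 = lower95, upper95 = upper95)
  class(out) <- c("rate_series", "data.frame")
  attr(out, "truncation") <- truncation
  out
}

#' Posterior ASR series with prediction intervals
#'
#' Standardises each posterior draw's rate surface, giving per-year ASR
#' medians with central 95% intervals over the observed and projected
#' years.
#'
#' @param posterior an [fit_apc()] result.
#' @inheritParams asr
#' @param level central interval probability.
#' @return a \code{rate_series} with interval columns filled.
#' @export
asr_series <- function(posterior, standard = standard_population(),
                       truncate_from = 45, level = 0.95) {
  stopifnot(inherits(posterior, "apc_posterior"))
  design <- posterior$design
  sw <- standard_weights_for(design$bands, standard, truncate_from)
  years <- design$years_all
  qs <- c(0.5, (1 - level) / 2, 1 - (1 - level) / 2)
  res <- vapply(seq_along(years), function(j) {
    sel <- which(posterior$cells$year == years[j])
    sel <- sel[match(sw$index, posterior$cells$a[sel])]
    draws <- 1e5 * (posterior$lambda[, sel, drop = FALSE] %*% sw$weights)
    stats::quantile(draws, probs = qs, names = FALSE)
  }, numeric(3))
  rate_series(years, res[1, ], res[2, ], res[3, ], truncation = truncate_from)
}

#' Annual average percent change of a rate series
#'
#' Two estimators: \code{endpoint_geometric} uses only the two endpoint
#' rates, \code{100((r_to/r_from)^{1/(to-from)} - 1)};
#' \code{loglinear_regression} is \code{100(exp(b) - 1)} with \code{b} the
#' OLS slope of log rate on year over \code{[from_year, to_year]}. The two
#' agree exactly on an exactly exponential series.
#'
#' @param series a \code{rate_series} (or data.frame with year and asr).
#' @param from_year,to_year endpoints (years present in the series).
#' @param method estimator.
#' @return percent per year (scalar).
#' @export
aapc <- function(series, from_year, to_year,
                 method = c("endpoint_geometric", "loglinear_regression")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(series), all(c("year", "asr") %in% names(series)))
  if (!all(c(from_year, to_year) %in% series$year)) {
    stop("from_year and to_year must both be present in the series", call. = FALSE)
  }
  if (to_year <= from_year) stop("to_year must exceed from_year", call. = FALSE)
  if (method == "endpoint_geometric") {
    r0 <- series$asr[series$year == from_year]
    r1 <- series$asr[series$year == to_year]
    if (r0 <= 0 || r1 <= 0) {
      stop("endpoint rates must be positive for the geometric AAPC", call. = FALSE)
    }
    100 * ((r1 / r0)^(1 / (to_year - from_year)) - 1)
  } else {
    sub <- series[series$year >= from_year & series$year <= to_year, ]
    if (any(sub$asr <= 0)) {
      stop("all rates must be positive for the log-linear AAPC", call. = FALSE)
    }
    b <- stats::coef(stats::lm(log(asr) ~ year, data = sub))[["year"]]
    100 * (exp(b) - 1)
  }
}

#' Burden table for two reference years
#'
#' Builds the standard burden layout: per reporting band the number of
#' events N and the row percentage (100 N_band / N_total), the yearly
#' total, the net change in totals between the two reference years, and
#' the ASR of each year. Values are returned at full precision; the
#' conventional display rounding is N to integers, percentages to 1 d.p.,
#' net change to 2 d.p. and ASR to 1 d.p. (see [format_burden_table()]).
#'
#' @param counts a [count_table()] on reporting bands containing both
#'   reference years (other years are ignored), or a numeric matrix with
#'   band-label rownames and year colnames holding just the reference
#'   years (a count table's annual grid is not required when only the two
#'   compared years are known, as in a published burden table).
#' @param asr_values named numeric vector of ASRs, names = reference years
#'   (optional).
#' @param reference_years the two years compared (default the range of
#'   \code{names(asr_values)} or the table's first/last year).
#' @return data.frame of class \code{burden_table}: one row per reference
#'   year with N and pct per band, total, net_change_pct (second row), asr.
#' @export
burden_table <- function(counts, asr_values = NULL, reference_years = NULL) {
  if (inherits(counts, "count_table")) {
    vals <- counts$values
    bands <- counts$bands
  } else {
    vals <- as.matrix(counts)
    bands <- validate_bands(parse_age_bands(rownames(vals)))
  }
  years <- as.integer(colnames(vals))
  if (is.null(reference_years)) {
    reference_years <- if (!is.null(asr_values)) {
      as.integer(names(asr_values))
    } else {
      range(years)
    }
  }
  stopifnot(length(reference_years) == 2)
  if (!all(reference_years %in% years)) {
    stop("reference years not present in the count table", call. = FALSE)
  }
  v <- vals[, as.character(reference_years), drop = FALSE]
  totals <- colSums(v)
  if (any(totals == 0)) stop("zero total events in a reference year", call. = FALSE)
  pct <- sweep(v, 2, totals, "/") * 100
  out <- data.frame(year = reference_years, total = totals,
                    net_change_pct = c(NA_real_,
                                       net_change_pct(totals[1], totals[2])),
                    asr = if (is.null(asr_values)) NA_real_
                          else as.numeric(asr_values[as.character(reference_years)]),
                    row.names = NULL)
  for (i in seq_len(nrow(bands))) {
    out[[paste0("N_", bands$label[i])]] <- v[i, ]
    out[[paste0("pct_", bands$label[i])]] <- pct[i, ]
  }
  class(out) <- c("burden_table", "data.frame")
  out
}

#' Round a burden table to display precision
#'
#' @param tab a [burden_table()].
#' @return data.frame with N as integers, percentages at 1 d.p., net change
#'   at 2 d.p., ASR at 1 d.p.
#' @export
format_burden_table <- function(tab) {
  stopifnot(inherits(tab, "burden_table"))
  out <- as.data.frame(tab)
  for (nm in names(out)) {
    if (startsWith(nm, "N_") || nm == "total") out[[nm]] <- round(out[[nm]])
    if (startsWith(nm, "pct_") || nm == "asr") out[[nm]] <- round(out[[nm]], 1)
    if (nm == "net_change_pct") out[[nm]] <- round(out[[nm]], 2)
  }
  out
}
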
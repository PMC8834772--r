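#' Registry tables of counts and person-years
#'
#' The two core containers mirror how population-based cancer registries
#' publish data: a matrix over age bands (rows) and consecutive calendar
#' years (columns). A `count_table` holds non-negative integer event counts
#' (incident cases or deaths); a `population_table` holds strictly positive
#' person-years at risk. A paired count and population table must share the
#' same band/year grid.
#'
#' @param bands character vector of band labels (see [parse_age_bands()]) or
#'   a data.frame as returned by it.
#' @param years integer vector of consecutive calendar years.
#' @param values numeric matrix, \code{length(bands)} rows by
#'   \code{length(years)} columns.
#' @param outcome for counts, one of \code{"incidence"} or
#'   \code{"mortality"} (or \code{NA} when not applicable).
#' @return An object of class \code{count_table} or \code{population_table}
#'   (both inherit from \code{registry_table}): a list with elements
#'   \code{bands}, \code{years}, \code{values} and, for counts,
#'   \code{outcome}.
#' @examples
#' count_table(c("45-49", "50-54"), 2000:2002,
#'             matrix(5, 2, 3), outcome = "incidence")
#' @export
count_table <- function(bands, years, values, outcome = NA_character_) {
  tab <- new_registry_table(bands, years, values, kind = "counts")
  v <- tab$values
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, ]
    stop("negative count at (", tab$bands$label[bad[1]], ", ",
         tab$years[bad[2]], ")", call. = FALSE)
  }
  if (any(v != round(v))) {
    bad <- which(v != round(v), arr.ind = TRUE)[1, ]
    stop("non-integer count at (", tab$bands$label[bad[1]], ", ",
         tab$years[bad[2]], ")", call. = FALSE)
  }
  if (!is.na(outcome) && !outcome %in% c("incidence", "mortality")) {
    stop("outcome must be 'incidence' or 'mortality'", call. = FALSE)
  }
  tab$outcome <- outcome
  class(tab) <- c("count_table", "registry_table")
  tab
}

#' @rdname count_table
#' @export
population_table <- function(bands, years, values) {
  tab <- new_registry_table(bands, years, values, kind = "population")
  if (any(tab$values <= 0)) {
    bad <- which(tab$values <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive person-years at (", tab$bands$label[bad[1]], ", ",
         tab$years[bad[2]], ")", call. = FALSE)
  }
  class(tab) <- c("population_table", "registry_table")
  tab
}

new_registry_table <- function(bands, years, values, kind) {
  if (is.character(bands)) bands <- parse_age_bands(bands)
  bands <- validate_bands(bands)
  years <- as.integer(years)
  if (length(years) == 0) stop("table has no years", call. = FALSE)
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("years must be consecutive annual values", call. = FALSE)
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"  # uniform storage so round trips compare identical
  if (nrow(values) != nrow(bands) || ncol(values) != length(years)) {
    stop("values must be a ", nrow(bands), " x ", length(years),
         " matrix (bands x years)", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("missing or non-finite cells", call. = FALSE)
  dimnames(values) <- list(bands$label, years)
  list(bands = bands, years = years, values = values)
}

#' @export
print.registry_table <- function(x, ...) {
  kind <- if (inherits(x, "count_table")) "count_table" else "population_table"
  cat(sprintf("<%s> %d bands (%s .. %s) x %d years (%d-%d)\n", kind,
              nrow(x$bands), x$bands$label[1], x$bands$label[nrow(x$bands)],
              length(x$years), min(x$years), max(x$years)))
  if (inherits(x, "count_table") && !is.na(x$outcome)) {
    cat("outcome:", x$outcome, "\n")
  }
  print(x$values, ...)
  invisible(x)
}

#' Read a registry table from CSV
#'
#' Two dialects are accepted. Long format has a header
#' \code{age_band,year,value} with one row per cell. Wide format has a first
#' column \code{age_band} and one column per calendar year. The file must
#' define a complete band-by-year grid: missing cells, duplicate
#' \code{(band, year)} keys, negative values, and (for counts) non-integer
#' values are rejected with the offending key named, rather than silently
#' reindexed.
#'
#' @param path file path to a CSV.
#' @param schema \code{"counts"} or \code{"population"}.
#' @param outcome optional outcome tag for count tables.
#' @return a [count_table()] or [population_table()].
#' @export
read_table <- function(path, schema = c("counts", "population"),
                       outcome = NA_character_) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- trimws(tolower(names(df)))
  if (identical(nm[seq_len(min(3, length(nm)))], c("age_band", "year", "value"))) {
    long <- data.frame(age_band = trimws(as.character(df[[1]])),
                       year = as.integer(df[[2]]),
                       value = as.numeric(df[[3]]))
  } else if (nm[1] == "age_band") {
    yrs <- suppressWarnings(as.integer(names(df)[-1]))
    if (any(is.na(yrs))) {
      stop("wide CSV column headers after 'age_band' must be years", call. = FALSE)
    }
    long <- data.frame(
      age_band = rep(trimws(as.character(df[[1]])), times = length(yrs)),
      year = rep(yrs, each = nrow(df)),
      value = as.numeric(unlist(df[-1], use.names = FALSE)))
  } else {
    stop("unrecognised CSV layout: expected long 'age_band,year,value' or ",
         "wide with first column 'age_band'", call. = FALSE)
  }
  key <- paste(long$age_band, long$year, sep = "|")
  if (anyDuplicated(key)) {
    d <- long[duplicated(key), ][1, ]
    stop("duplicate cell for (", d$age_band, ", ", d$year, ")", call. = FALSE)
  }
  if (any(is.na(long$value))) {
    m <- long[is.na(long$value), ][1, ]
    stop("missing value at (", m$age_band, ", ", m$year, ")", call. = FALSE)
  }
  bands <- validate_bands(parse_age_bands(unique(long$age_band))[
    order(parse_age_bands(unique(long$age_band))$lower), , drop = FALSE])
  years <- sort(unique(long$year))
  values <- matrix(NA_real_, nrow(bands), length(years),
                   dimnames = list(bands$label, years))
  values[cbind(match(long$age_band, bands$label),
               match(long$year, years))] <- long$value
  if (any(is.na(values))) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("missing cell for (", bands$label[bad[1]], ", ",
         years[bad[2]], ")", call. = FALSE)
  }
  if (schema == "counts") count_table(bands, years, values, outcome = outcome)
  else population_table(bands, years, values)
}

#' Write a registry table to CSV
#'
#' Emits the long-format dialect accepted by [read_table()] (columns
#' \code{age_band,year,value}), preserving band labels verbatim so that
#' \code{read_table(write_table(x))} reproduces \code{x} exactly.
#'
#' @param table a [count_table()] or [population_table()].
#' @param path output file path.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "registry_table"))
  if (length(table$years) == 0) stop("table has no years", call. = FALSE)
  long <- data.frame(
    age_band = rep(table$bands$label, times = length(table$years)),
    year = rep(table$years, each = nrow(table$bands)),
    value = as.vector(table$values))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate age bands
#'
#' Collapses a table onto coarser bands, e.g. the 5-year modelling bands
#' onto the 10-year reporting bands used in burden tables. Every target band
#' must be the union of consecutive source bands; values are summed, so the
#' per-year grand total is conserved exactly.
#'
#' @param table a [count_table()] or [population_table()].
#' @param target_bands character labels or a parsed band data.frame.
#' @return a table of the same class on the target bands.
#' @examples
#' x <- count_table(c("45-49", "50-54"), 2000, matrix(c(10, 5), 2, 1))
#' aggregate_bands(x, "45-54")$values
#' @export
aggregate_bands <- function(table, target_bands) {
  stopifnot(inherits(table, "registry_table"))
  if (is.character(target_bands)) target_bands <- parse_age_bands(target_bands)
  target_bands <- validate_bands(target_bands)
  src <- table$bands
  out <- matrix(0, nrow(target_bands), length(table$years))
  for (i in seq_len(nrow(target_bands))) {
    lo <- target_bands$lower[i]
    up <- target_bands$upper[i]
    j0 <- which(src$lower == lo)
    jn <- if (is.na(up)) which(is.na(src$upper)) else which(src$upper == up)
    if (length(j0) != 1 || length(jn) != 1 || jn < j0) {
      stop("target band '", target_bands$label[i],
           "' is not a union of consecutive source bands", call. = FALSE)
    }
    out[i, ] <- colSums(table$values[j0:jn, , drop = FALSE])
  }
  if (inherits(table, "count_table")) {
    count_table(target_bands, table$years, out, outcome = table$outcome)
  } else {
    population_table(target_bands, table$years, out)
  }
}
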
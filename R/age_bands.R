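#' Parse age-band labels
#'
#' Age bands are half-open intervals \code{[lower, upper)} in integer years.
#' Three label forms are accepted: \code{"<L"} (everything below L, i.e.
#' \code{[0, L)}), \code{"L-U"} (the 5- or 10-year demographic convention,
#' \code{"45-49"} meaning \code{[45, 50)}), and \code{"L+"} (open-ended top
#' band \code{[L, Inf)}). Any other label is rejected.
#'
#' @param labels character vector of band labels.
#' @return A data.frame with columns \code{label}, \code{lower} (inclusive)
#'   and \code{upper} (exclusive; \code{NA} for an open-ended band).
#' @examples
#' parse_age_bands(c("<45", "45-49", "85+"))
#' @export
parse_age_bands <- function(labels) {
  labels <- trimws(as.character(labels))
  lower <- upper <- rep(NA_real_, length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (grepl("^<[0-9]+$", lab)) {
      lower[i] <- 0
      upper[i] <- as.numeric(sub("^<", "", lab))
    } else if (grepl("^[0-9]+-[0-9]+$", lab)) {
      parts <- as.numeric(strsplit(lab, "-", fixed = TRUE)[[1]])
      lower[i] <- parts[1]
      upper[i] <- parts[2] + 1  # "45-49" is [45, 50)
    } else if (grepl("^[0-9]+\\+$", lab)) {
      lower[i] <- as.numeric(sub("\\+$", "", lab))
      upper[i] <- NA_real_
    } else {
      stop("unparseable age-band label: '", lab,
           "' (expected '<L', 'L-U' or 'L+')", call. = FALSE)
    }
    if (!is.na(upper[i]) && lower[i] >= upper[i]) {
      stop("age band '", lab, "' has lower >= upper", call. = FALSE)
    }
  }
  data.frame(label = labels, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

#' Build labels from band bounds
#'
#' Inverse of [parse_age_bands()]: \code{[45, 50)} becomes \code{"45-49"},
#' \code{[0, 45)} becomes \code{"<45"}, an unbounded band becomes
#' \code{"85+"}.
#'
#' @param lower,upper numeric vectors of band bounds (upper exclusive,
#'   \code{NA} for open-ended).
#' @return character vector of labels.
#' @export
age_band_labels <- function(lower, upper) {
  ifelse(is.na(upper), paste0(lower, "+"),
         ifelse(lower == 0, paste0("<", upper),
                paste0(lower, "-", upper - 1)))
}

# Validate a parsed band table: sorted, non-overlapping, contiguous; only the
# last band may be open-ended.
validate_bands <- function(bands) {
  if (nrow(bands) == 0) stop("no age bands", call. = FALSE)
  if (is.unsorted(bands$lower, strictly = TRUE)) {
    stop("age bands must be sorted ascending by lower bound", call. = FALSE)
  }
  open <- which(is.na(bands$upper))
  if (length(open) > 1 || (length(open) == 1 && open != nrow(bands))) {
    stop("only the last age band may be open-ended", call. = FALSE)
  }
  if (nrow(bands) > 1) {
    up <- bands$upper[-nrow(bands)]
    lo <- bands$lower[-1]
    bad <- which(is.na(up) | up != lo)
    if (length(bad)) {
      stop("age bands not contiguous between '", bands$label[bad[1]],
           "' and '", bands$label[bad[1] + 1], "'", call. = FALSE)
    }
  }
  bands
}

# Midpoint age used to assign birth cohorts: floor of the interval midpoint.
# Open-ended bands are treated as one 5-year step wide for this purpose,
# so "85+" gets midpoint 87 just as "85-89" would.
band_midpoint <- function(bands, open_width = 5) {
  upper <- ifelse(is.na(bands$upper), bands$lower + open_width, bands$upper)
  floor((bands$lower + upper) / 2)
}
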
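#' Net change in case counts between two periods
#'
#' @param cases_baseline,cases_final event totals in the two periods
#'   (baseline must be positive).
#' @return percent change, \code{100 (final - baseline) / baseline}.
#' @examples
#' net_change_pct(445, 348)  # -21.80 at 2 d.p.
#' @export
net_change_pct <- function(cases_baseline, cases_final) {
  if (cases_baseline <= 0) stop("baseline cases must be positive", call. = FALSE)
  100 * (cases_final - cases_baseline) / cases_baseline
}

#' Bashir-Esteve decomposition of the net change in cases
#'
#' Partitions the net change (NC) in expected case counts between a
#' baseline and a final period into three additive components: change in
#' population size (S|A), change in population age structure / ageing (A),
#' and change in age-specific risk (R|A), with risk and size conditioned on
#' the structural change. The counterfactual ladder applies size first,
#' then structure, then risk:
#' \deqn{C_1 = \sum_a r_{1a} N_{1a} / 10^5}
#' \deqn{C_{size} = \sum_a r_{1a} (T_2 N_{1a} / T_1) / 10^5}
#' \deqn{C_{struct} = \sum_a r_{1a} N_{2a} / 10^5}
#' \deqn{C_2 = \sum_a r_{2a} N_{2a} / 10^5}
#' with \eqn{T} the total person-years. All components are expressed as a
#' percentage of baseline cases \eqn{C_1}, so
#' \code{NC = aging + risk + size} holds exactly by construction.
#'
#' @param rates_baseline,rates_final age-specific rates per 100,000
#'   person-years (one value per band).
#' @param pop_baseline,pop_final person-years per band.
#' @return object of class \code{net_change_decomposition}: the baseline
#'   and final expected cases, the three percentage components, the net
#'   change, and the intermediate counterfactual case counts.
#' @examples
#' # rates halved, population unchanged: all change is risk
#' d <- decompose_net_change(c(10, 20), c(1e5, 1e5), c(5, 10), c(1e5, 1e5))
#' round(c(d$net_change_pct, d$risk_pct), 10)
#' @export
decompose_net_change <- function(rates_baseline, pop_baseline,
                                 rates_final, pop_final) {
  k <- length(rates_baseline)
  if (length(pop_baseline) != k || length(rates_final) != k ||
      length(pop_final) != k) {
    stop("all four vectors must be on the same band grid", call. = FALSE)
  }
  if (any(pop_baseline <= 0) || any(pop_final <= 0)) {
    stop("person-years must be positive", call. = FALSE)
  }
  t1 <- sum(pop_baseline); t2 <- sum(pop_final)
  c1 <- sum(rates_baseline * pop_baseline) / 1e5
  if (c1 <= 0) stop("baseline expected cases must be positive", call. = FALSE)
  c_size <- sum(rates_baseline * (t2 * pop_baseline / t1)) / 1e5
  c_struct <- sum(rates_baseline * pop_final) / 1e5
  c2 <- sum(rates_final * pop_final) / 1e5
  structure(list(
    cases_baseline = c1, cases_final = c2,
    net_change_pct = 100 * (c2 - c1) / c1,
    size_pct = 100 * (c_size - c1) / c1,
    aging_pct = 100 * (c_struct - c_size) / c1,
    risk_pct = 100 * (c2 - c_struct) / c1,
    counterfactual_cases = c(baseline = c1, size = c_size,
                             structure = c_struct, final = c2)),
    class = "net_change_decomposition")
}

#' @export
print.net_change_decomposition <- function(x, ...) {
  cat(sprintf("Net change: %.2f%% (cases %.1f -> %.1f)\n",
              x$net_change_pct, x$cases_baseline, x$cases_final))
  cat(sprintf("  risk (R|A): %+.2f%%  aging (A): %+.2f%%  size (S|A): %+.2f%%\n",
              x$risk_pct, x$aging_pct, x$size_pct))
  invisible(x)
}
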
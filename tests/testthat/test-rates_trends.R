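test_that("rate-to-count transfer matches the elementwise definition", {
  pop <- population_table("45-49", 2000, matrix(1e6, 1, 1))
  expect_equal(unname(estimate_counts_from_rates(10, pop)$values[1, 1]), 100)
  expect_true(all(estimate_counts_from_rates(0, pop)$values == 0))

  set.seed(41)
  bands <- c("45-49", "50-54", "55-59")
  popm <- matrix(runif(12, 5e4, 5e5), 3, 4)
  rates <- matrix(runif(12, 5, 50), 3, 4)
  pop <- population_table(bands, 2000:2003, popm)
  got <- estimate_counts_from_rates(rates, pop)$values
  oracle <- matrix(0, 3, 4)
  for (i in 1:3) for (j in 1:4) oracle[i, j] <- round(rates[i, j] * popm[i, j] / 1e5)
  expect_equal(unname(got), oracle)
  expect_error(estimate_counts_from_rates(matrix(1, 2, 4), pop),
               "does not match")
})

test_that("age-specific rates invert counts exactly", {
  counts <- count_table("45-49", 2000, matrix(50, 1, 1))
  pop <- population_table("45-49", 2000, matrix(2.5e5, 1, 1))
  r <- age_specific_rates(counts, pop)
  expect_equal(unname(r[1, 1]), 20)
  expect_equal(r * pop$values / 1e5, counts$values)
  zero <- count_table("45-49", 2000, matrix(0, 1, 1))
  expect_equal(unname(age_specific_rates(zero, pop)[1, 1]), 0)
})

test_that("bundled standard populations load with full weight", {
  for (v in c("esp2013", "esp1976")) {
    std <- standard_population(v)
    expect_equal(sum(std$weight), 1e5)
    expect_equal(std$label[nrow(std)], "85+")
  }
})

test_that("ASR equals the constant for constant-rate surfaces, any standard", {
  bands <- c("45-49", "50-54", "55-59", "60-64", "65-69", "70-74",
             "75-79", "80-84", "85+")
  pop <- population_table(bands, 2000:2002,
                          matrix(seq(2e5, 1e5, length.out = 9), 9, 3))
  r <- 17.3
  counts_v <- r * pop$values / 1e5
  counts <- count_table(bands, 2000:2002, round(counts_v))
  # use the exact-rate path: constant rates via a synthetic exact table
  set.seed(3)
  for (v in c("esp2013", "esp1976")) {
    std <- standard_population(v)
    exact_counts <- count_table(bands, 2000:2002,
                                matrix(173, 9, 3))
    exact_pop <- population_table(bands, 2000:2002, matrix(1e6, 9, 3))
    s <- asr(exact_counts, exact_pop, std, truncate_from = 45)
    expect_equal(s$asr, rep(17.3, 3), tolerance = 1e-12)
  }
})

test_that("ASR is the renormalised standard-weighted mean of rates", {
  # two bands, rates 10 and 30, equal weights -> 20
  counts <- count_table(c("45-49", "50-54"), 2000, matrix(c(10, 30), 2, 1))
  pop <- population_table(c("45-49", "50-54"), 2000, matrix(1e5, 2, 1))
  std <- counts$bands; std$weight <- c(1, 1)
  class(std) <- c("standard_population", "data.frame")
  expect_equal(asr(counts, pop, std, truncate_from = 45)$asr, 20)

  # random 9-band instance against an independent dot-product oracle
  set.seed(47)
  bands <- c("45-49", "50-54", "55-59", "60-64", "65-69", "70-74",
             "75-79", "80-84", "85+")
  popm <- matrix(runif(9, 5e4, 3e5), 9, 1)
  cm <- matrix(rpois(9, 60), 9, 1)
  counts <- count_table(bands, 2010, cm)
  pop <- population_table(bands, 2010, popm)
  esp <- standard_population("esp2013")
  got <- asr(counts, pop, esp, truncate_from = 45)$asr
  w <- esp$weight[match(bands, esp$label)]
  oracle <- sum((w / sum(w)) * (1e5 * cm / popm))
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_error(asr(counts, pop, esp, truncate_from = 99), "leaves no bands")
})

test_that("AAPC estimators agree with closed forms", {
  # constant series: no trend under either method
  flat <- data.frame(year = 2000:2010, asr = 12)
  expect_equal(aapc(flat, 2000, 2010, "endpoint_geometric"), 0)
  expect_equal(aapc(flat, 2000, 2010, "loglinear_regression"), 0,
               tolerance = 1e-10)

  # exact exponential decline: both methods return 100(e^b - 1)
  yrs <- 2000:2015
  expo <- data.frame(year = yrs, asr = 20 * exp(-0.02 * (yrs - 2000)))
  want <- 100 * (exp(-0.02) - 1)
  expect_equal(aapc(expo, 2000, 2015, "endpoint_geometric"), want,
               tolerance = 1e-10)
  expect_equal(aapc(expo, 2000, 2015, "loglinear_regression"), want,
               tolerance = 1e-10)

  bad <- data.frame(year = 2000:2001, asr = c(0, 5))
  expect_error(aapc(bad, 2000, 2001, "endpoint_geometric"), "positive")
  expect_error(aapc(flat, 1990, 2010), "present in the series")
})

test_that("burden tables carry N, row percentages, totals and net change", {
  m <- matrix(c(48, 80, 110, 92, 115,
                34, 55, 78, 89, 92), ncol = 2,
              dimnames = list(c("<45", "45-54", "55-64", "65-74", "75+"),
                              c(2015, 2030)))
  tab <- burden_table(m, asr_values = c("2015" = 22.4, "2030" = 14.8))
  expect_equal(tab$total, c(445, 348))
  expect_equal(tab$net_change_pct[2], -21.7977528, tolerance = 1e-6)
  expect_equal(round(tab$`pct_<45`[1], 1), 10.8)
  # row percentages sum to 100 exactly pre-rounding
  pct_cols <- grep("^pct_", names(tab), value = TRUE)
  expect_equal(rowSums(tab[, pct_cols]), c(100, 100), tolerance = 1e-10)
  # display rounding: 1 d.p. percentages, 2 d.p. net change
  fmt <- format_burden_table(tab)
  expect_equal(fmt$net_change_pct[2], -21.80)
  expect_equal(fmt$asr, c(22.4, 14.8))

  zero <- matrix(0, 1, 2, dimnames = list("45-54", c(2015, 2030)))
  expect_error(burden_table(zero, reference_years = c(2015, 2030)),
               "zero total")
})
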
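survey <- dgrp_line_genotypes()

test_that("allele weights follow the half-weight heterozygote convention", {
  dd <- survey[survey$group == "dirty_dozen", ]
  dist <- allele_distribution(dd)
  expect_equal(dist[["opa31"]], 5)
  expect_equal(dist[["opa33a"]], 3)
  expect_equal(dist[["opa32"]], 2)
  expect_equal(dist[["opa35a1"]], 1)
  expect_equal(dist[["opa23"]], 1)
  het <- data.frame(line_id = "x", haplotype1 = "opa31", haplotype2 = "opa32")
  expect_equal(as.vector(allele_distribution(het)), c(0.5, 0.5))
  expect_length(allele_distribution(survey[0, ]), 0L)
})

test_that("allele weights sum to the line count for every survey group", {
  for (g in unique(survey$group)) {
    sub <- survey[survey$group == g, ]
    expect_equal(sum(allele_distribution(sub)), nrow(sub), label = g)
  }
})

test_that("non-wild-type fractions match the published group statistics", {
  rr <- survey[survey$group == "radiation_resistant", ]
  expect_equal(percent1(nonwildtype_fraction(rr)), 58.3)
  rs <- survey[survey$group == "radiation_sensitive", ]
  expect_equal(percent1(nonwildtype_fraction(rs)), 31.8)
  k <- survey[survey$group == "in3rk", ]
  expect_equal(percent1(nonwildtype_fraction(k)), 100)
  wt <- data.frame(haplotype1 = rep("opa31", 4))
  expect_equal(nonwildtype_fraction(wt), 0)
  # complement: wild-type weight fraction + non-wild-type fraction = 1
  w <- allele_distribution(rr)
  expect_equal(nonwildtype_fraction(rr) + w[["opa31"]] / nrow(rr), 1)
})

test_that("mean absolute deviation weights het haplotypes by half", {
  rr <- survey[survey$group == "radiation_resistant", ]
  expect_equal(round_half_away(mean_abs_deviation(rr), 1), 1.8)
  rs <- survey[survey$group == "radiation_sensitive", ]
  expect_equal(round_half_away(mean_abs_deviation(rs), 1), 0.6)
  k <- survey[survey$group == "in3rk", ]
  expect_equal(round_half_away(mean_abs_deviation(k), 1), 3.7)
  wt <- data.frame(haplotype1 = rep("opa31", 4))
  expect_equal(mean_abs_deviation(wt), 0)
  # zero iff every haplotype has the reference length
  one_off <- data.frame(haplotype1 = c("opa31", "opa32"))
  expect_gt(mean_abs_deviation(one_off), 0)
})

test_that("sex ratio reproduces the stock measurement", {
  expect_equal(round_half_away(sex_ratio(144, 124), 1), 53.7)
  expect_equal(sex_ratio(1, 1), 50)
  expect_equal(sex_ratio(0, 10), 0)
  expect_error(sex_ratio(0, 0), class = "notchopa_undefined_rate")
})

test_that("X-linked Hardy-Weinberg expectations use the published rounding", {
  hw <- xlinked_hw_expected(39, 53.7, 0.5)
  expect_equal(hw$n_female, 21)
  expect_equal(hw$n_male, 18)
  expect_equal(unname(hw$expected_rounded),
               c(14, 14, 11))
  expect_equal(unname(hw$expected), c(14.25, 14.25, 10.5))
  # fixed allele: everything in one class
  fix <- xlinked_hw_expected(25, 40, 1.0)
  expect_equal(unname(fix$expected), c(25, 0, 0))
  even <- xlinked_hw_expected(100, 50, 0.5)
  expect_equal(unname(even$expected), c(37.5, 37.5, 25))
})

test_that("raw expected counts sum to n for randomized parameters", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(1:500, 1)
    pf <- stats::runif(1, 0, 100)
    p <- stats::runif(1)
    hw <- xlinked_hw_expected(n, pf, p)
    expect_equal(sum(hw$expected), n)
    expect_true(all(hw$expected >= 0))
  }
  expect_error(xlinked_hw_expected(10, 50, 1.2),
               class = "notchopa_domain_error")
})

test_that("the goodness-of-fit statistic matches direct arithmetic and chisq.test", {
  hw <- xlinked_hw_expected(39, 53.7, 0.5)
  obs <- c(A_only = 13, B_only = 14, het_female = 12)
  fit <- goodness_of_fit(obs, hw$expected)
  hand <- (13 - 14.25)^2 / 14.25 + (14 - 14.25)^2 / 14.25 +
    (12 - 10.5)^2 / 10.5
  expect_equal(fit$statistic, hand)
  expect_equal(fit$df, 2L)
  ref <- suppressWarnings(stats::chisq.test(obs, p = hw$expected / 39))
  expect_equal(fit$statistic, unname(ref$statistic))
  expect_equal(fit$p_value, unname(ref$p.value))
  expect_equal(goodness_of_fit(hw$expected, hw$expected)$statistic, 0)
  expect_error(goodness_of_fit(c(a = 1), c(b = 1)),
               class = "notchopa_domain_error")
  expect_error(goodness_of_fit(c(a = 1, b = 2), c(a = 1, b = 0)),
               class = "notchopa_domain_error")
})

test_that("population summaries write bar-plot-ready TSVs", {
  dir <- withr::local_tempdir()
  write_population_tsv(survey, dir)
  dist <- read.delim(file.path(dir, "distribution.tsv"))
  expect_true(all(c("allele", "length", "weight") %in% names(dist)))
  stats_df <- read.delim(file.path(dir, "group_stats.tsv"))
  expect_equal(
    stats_df$pct_nonwildtype[stats_df$group == "radiation_resistant"], 58.3)
  expect_equal(
    stats_df$mean_abs_deviation[stats_df$group == "radiation_resistant"], 1.8)
})
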
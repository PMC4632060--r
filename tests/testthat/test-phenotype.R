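test_that("observation categories map to the published scores", {
  expect_equal(score_observation("NORMAL"), 1.0)
  expect_equal(score_observation("MISSING"), 0.0)
  expect_equal(score_observation("ECTOPIC_NEAR", "aDC"), 2.0)
  expect_equal(score_observation("SPLIT", "pSC"), 2.0)
  expect_equal(score_observation("SLENDER"), 0.5)
  expect_equal(score_observation("SLENDER", fraction = 0.75), 0.75)
  expect_equal(score_observation("SHARED_MID", "aDC"), 1.5)
  expect_equal(score_observation("SHARED_MID", "pSC"), 1.5)
  expect_equal(score_observation("SOCKET_PLUS_ECTOPIC"), -1.0)
  expect_equal(score_observation("DOUBLE_EMPTY_SOCKET"), -2.0)
  expect_error(score_observation("SHARED_MID", "uHU"),
               class = "notchopa_domain_error")
  expect_error(score_observation("SLENDER", fraction = 1.2),
               class = "notchopa_domain_error")
})

test_that("the rarer defect class is masked within each group", {
  g <- data.frame(genotype = "g", sex = "F", position = "aDC",
                  score = c(rep(2, 5), rep(0, 2), rep(1, 43)))
  m <- mask_rarer_defect(g)
  expect_equal(sum(m$score == 0), 0)
  expect_equal(sum(m$masked), 2)
  expect_equal(sum(m$score == 2), 5)

  nomask <- data.frame(genotype = "g", sex = "F", position = "aDC",
                       score = c(rep(2, 3), rep(1, 47)))
  expect_false(any(mask_rarer_defect(nomask)$masked))

  tie <- data.frame(genotype = "g", sex = "F", position = "aDC",
                    score = c(2, 2, 0, 0, 1))
  mt <- mask_rarer_defect(tie)
  expect_equal(sum(mt$score == 2), 2)   # ectopic kept on ties
  expect_equal(sum(mt$score == 0), 0)
})

test_that("no group retains both defect classes after masking", {
  set.seed(9)
  obs <- expand.grid(genotype = c("a", "b"), sex = c("F", "M"),
                     position = bristle_positions(),
                     rep = 1:30, stringsAsFactors = FALSE)
  obs$score <- sample(c(0, 0.5, 1, 1.5, 2, -1), nrow(obs), replace = TRUE,
                      prob = c(.1, .05, .7, .05, .08, .02))
  m <- mask_rarer_defect(obs)
  key <- paste(m$genotype, m$sex, m$position)
  for (k in unique(key)) {
    s <- m$score[key == k]
    expect_false(any(s > 1) && any(s < 1), label = k)
  }
})

test_that("cohort frequencies average masked scores per cell", {
  allnorm <- data.frame(genotype = "wt", sex = "F",
                        position = rep(bristle_positions(), 4), score = 1)
  cf <- cohort_frequencies(allnorm)
  expect_true(all(cf$mean_score == 1))
  one_ect <- data.frame(genotype = "v", sex = "M", position = "pDC",
                        score = c(rep(1, 9), 2))
  cf2 <- cohort_frequencies(one_ect)
  expect_equal(cf2$mean_score, 1.1)
  expect_equal(cf2$n, 10)
  expect_equal(cf2$n_ectopic, 1)
})

test_that("ectopic rates count flies and grow monotonically", {
  base <- data.frame(fly_id = rep(sprintf("f%02d", 1:100), each = 2),
                     position = rep(c("aDC", "uHU"), 100), score = 1)
  expect_equal(ectopic_rate(base), 0)
  withect <- base
  withect$score[withect$fly_id %in% sprintf("f%02d", 1:8) &
                  withect$position == "aDC"] <- 2
  expect_equal(ectopic_rate(withect), 0.08)
  # ectopics at non-listed positions do not count
  withect$score[withect$position == "uHU"] <- 2
  expect_equal(ectopic_rate(withect), 0.08)
  more <- withect
  more$score[more$fly_id == "f09" & more$position == "aDC"] <- 2
  expect_gte(ectopic_rate(more), ectopic_rate(withect))
  allect <- base; allect$score <- 2
  expect_equal(ectopic_rate(allect), 1)
})

test_that("embryonic failure is a guarded fraction", {
  expect_equal(embryonic_failure(27, 100), 0.27)
  expect_equal(embryonic_failure(0, 500), 0)
  expect_equal(embryonic_failure(500, 500), 1)
  expect_error(embryonic_failure(1, 0), class = "notchopa_undefined_rate")
  expect_error(embryonic_failure(6, 5), class = "notchopa_domain_error")
})

test_that("fecundity summary reproduces the published means", {
  fec <- dgrp_fecundity()
  s <- fecundity_summary(fec$eggs)
  expect_equal(s$mean_display, 1465)
  expect_equal(s$mean_percent_of_max, 64.3)
  expect_equal(s$percent_of_max[fec$line_id == "RAL-237"], 100)
  expect_equal(s$percent_of_max[fec$line_id == "RAL-646"], 63.1)
  expect_equal(fecundity_summary(2276)$percent_of_max, 100)
  expect_error(fecundity_summary(c(0, 0)), class = "notchopa_undefined_rate")
  expect_error(fecundity_summary(numeric(0)), class = "notchopa_empty_input")
})
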
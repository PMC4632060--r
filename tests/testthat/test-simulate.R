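reg <- default_registry()

test_that("clone sequences are flanks plus codons", {
  anchors <- default_anchors()
  expect_equal(nchar(build_sequence(registry_get(reg, "opa31"), anchors)), 113)
  expect_equal(nchar(build_sequence(registry_get(reg, "opa23"), anchors)), 89)
  expect_error(build_sequence(allele_record("opa31", pq_config(13, TRUE, 17))),
               class = "notchopa_domain_error")
})

test_that("zero rates leave clones untouched; forced contraction gives opa30L", {
  opa31 <- registry_get(reg, "opa31")
  set.seed(1)
  for (i in 1:20) {
    m <- mutate_clone(opa31, list(contraction = 0, expansion = 0))
    expect_equal(m$class, "ORIGINAL")
    expect_identical(m$allele$codons, opa31$codons)
  }
  set.seed(1)
  forced <- mutate_clone(opa31, list(contraction = 1, expansion = 0))
  expect_equal(forced$class, "SLIPPAGE_CONTRACTION")
  # the longest glutamine run of the default pattern is the left CAG run
  expect_equal(forced$allele$name, "opa30L")
  expect_equal(pq_string(forced$allele$config), "Q12HQ17")
})

test_that("heterozygous clone draws are balanced and contamination bounds hold", {
  geno <- list(registry_get(reg, "opa31"), registry_get(reg, "opa32"))
  set.seed(2)
  clones <- simulate_individual(geno, 10000,
                                list(contraction = 0, expansion = 0,
                                     intraculture = 0, interculture = 0))
  frac31 <- mean(clones$allele == "opa31")
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(frac31 - 0.5), 4 * se)
  # full contamination replaces every clone from the pool
  pool <- list(registry_get(reg, "opa33a"))
  set.seed(3)
  cont <- simulate_individual(list(registry_get(reg, "opa31")), 50,
                              list(intraculture = 0, interculture = 1),
                              interculture_pool = pool)
  expect_true(all(cont$allele == "opa33a"))
  expect_true(all(cont$true_class == "CONTAMINANT_INTERCULTURE"))
  expect_error(
    simulate_individual(geno, 5, list(intraculture = 0.5)),
    class = "notchopa_config_error")
})

test_that("identical seeds reproduce studies byte for byte", {
  cfg <- sim_config(individuals_per_line = 3L, seed = 99L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth_clones, b$truth_clones)
  c <- simulate_study(sim_config(individuals_per_line = 3L, seed = 100L))
  expect_false(identical(a$sequences, c$sequences))
})

test_that("study structure respects X-linkage and truth covers every clone", {
  cfg <- sim_config(lines = list(poly = list(alleles = c("opa31", "opa32"))),
                    individuals_per_line = 30L, seed = 4L)
  st <- simulate_study(cfg)
  expect_setequal(names(st$sequences), st$samples$clone_id)
  expect_setequal(names(st$sequences), st$truth_clones$clone_id)
  expect_equal(anyDuplicated(st$truth_clones$clone_id), 0L)
  ti <- st$truth_individuals
  males <- ti[ti$sex == "M", ]
  expect_true(all(is.na(males$allele2)))  # hemizygous
  expect_true(any(ti$sex == "F"))
  counts <- table(st$samples$individual_id)
  expect_true(all(counts >= 5 & counts <= 13))
})

test_that("an empty study yields empty outputs", {
  st <- simulate_study(sim_config(individuals_per_line = 0L, seed = 1L))
  expect_length(st$sequences, 0L)
  expect_equal(nrow(st$samples), 0L)
  expect_equal(nrow(st$truth_individuals), 0L)
})

test_that("study files round-trip through disk", {
  dir <- withr::local_tempdir()
  st <- simulate_study(sim_config(individuals_per_line = 2L, seed = 7L))
  write_simulated_study(st, dir)
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "clones.fasta"))
  expect_equal(length(seqs), length(st$sequences))
  expect_equal(as.character(seqs[[1]]), unname(st$sequences[[1]]))
  samples <- read.delim(file.path(dir, "samples.tsv"))
  expect_equal(nrow(samples), nrow(st$samples))
  expect_true(file.exists(file.path(dir, "config.yml")))
})

test_that("bristle and embryo simulators hit their generating probabilities", {
  probs <- data.frame(position = "pDC", sex = "F",
                      p_ectopic = 0.1, p_missing = 0)
  set.seed(6)
  obs <- simulate_bristles(probs, n_flies = 400, sexes = "F")
  pdc <- obs[obs$position == "pDC", ]
  rate <- mean(pdc$category == "ECTOPIC_NEAR")
  se <- sqrt(0.1 * 0.9 / nrow(pdc))
  expect_lt(abs(rate - 0.1), 3 * se)
  expect_true(all(obs$category[obs$position != "pDC"] == "NORMAL"))
  none <- simulate_bristles(probs[0, ], n_flies = 3)
  expect_true(all(none$category == "NORMAL"))

  expect_equal(simulate_embryo_assay(0, 500)$unhatched, 0)
  expect_equal(simulate_embryo_assay(1, 500)$unhatched, 500)
  set.seed(8)
  draw <- simulate_embryo_assay(0.27, 10000)
  se <- sqrt(0.27 * 0.73 / 10000)
  expect_lt(abs(draw$unhatched / draw$total - 0.27), 3 * se)
})
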
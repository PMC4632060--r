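reg <- default_registry()
key_of <- function(nm) third_positions(registry_get(reg, nm)$codons)
slip_key <- function(parent, nm) third_positions(slip_variant(reg, parent, nm)$codons)

k31 <- key_of("opa31"); k32 <- key_of("opa32"); k23 <- key_of("opa23")
k30L <- slip_key("opa31", "opa30L")
k31L <- slip_key("opa32", "opa31L")

test_that("tallies count clones deterministically and reject empty input", {
  clones <- data.frame(
    third_position_string = c(rep(k31, 8), k30L),
    pq_string = NA_character_, stringsAsFactors = FALSE)
  t1 <- tally_clones(clones)
  expect_equal(sum(t1$count), 9L)
  expect_equal(t1$count, c(8L, 1L))
  expect_equal(t1$key[1], k31)
  expect_error(tally_clones(clones[0, ]), class = "notchopa_empty_input")
  # same pQ, different third positions tally separately
  a2 <- third_positions(registry_get(reg, "opa35a2")$codons)
  a1 <- third_positions(registry_get(reg, "opa35a1")$codons)
  t2 <- tally_clones(data.frame(third_position_string = c(a1, a1, a2),
                                pq_string = NA_character_))
  expect_equal(nrow(t2), 2L)
})

test_that("calling is invariant to clone input order", {
  set.seed(7)
  clones <- data.frame(
    third_position_string = c(rep(k31, 6), rep(k32, 5), k30L),
    pq_string = NA_character_, stringsAsFactors = FALSE)
  base <- call_individual(tally_clones(clones))
  for (i in 1:5) {
    shuffled <- clones[sample.int(nrow(clones)), , drop = FALSE]
    alt <- call_individual(tally_clones(shuffled))
    expect_equal(alt$zygosity, base$zygosity)
    expect_equal(alt$clones, base$clones)
  }
})

test_that("minor clones are explained as slippage, contaminant, or ambiguous", {
  # a singleton contraction rides along a dominant allele
  c1 <- call_individual(setNames(c(8, 1), c(k31, k30L)))
  expect_equal(c1$zygosity, "single")
  expect_equal(c1$alleles$name, "opa31")
  expect_equal(c1$clones$class[c1$clones$key == k30L], "SLIPPAGE_CONTRACTION")
  expect_equal(c1$clones$side[c1$clones$key == k30L], "L")

  # heterozygote with a stutter product of the second allele
  c2 <- call_individual(setNames(c(5, 4, 1), c(k31, k32, k31L)))
  expect_equal(c2$zygosity, "heterozygous")
  expect_setequal(c2$alleles$name, c("opa31", "opa32"))
  expect_equal(c2$clones$class[c2$clones$key == k31L], "SLIPPAGE_CONTRACTION")
  expect_equal(c2$clones$parent[c2$clones$key == k31L], k32)

  # a foreign clone in a homozygous line is an interculture contaminant
  c3 <- call_individual(setNames(c(8, 1), c(k23, k31)),
                        foreign_alleles = c("opa31", "opa32"))
  expect_equal(c3$zygosity, "single")
  expect_equal(c3$alleles$name, "opa23")
  expect_equal(c3$clones$class[c3$clones$key == k31],
               "CONTAMINANT_INTERCULTURE")
})

test_that("the singleton-contaminant rule needs eight clones", {
  k33a <- key_of("opa33a")  # unrelated to opa23 by slippage, not foreign
  below <- call_individual(setNames(c(6, 1), c(k23, k33a)))
  expect_equal(below$clones$class[below$clones$key == k33a], "AMBIGUOUS")
  above <- call_individual(setNames(c(8, 1), c(k23, k33a)))
  expect_equal(above$clones$class[above$clones$key == k33a],
               "CONTAMINANT_INTRACULTURE")
})

test_that("support-qualified stutter and foreign alleles are demoted", {
  # two identical contraction clones among ten do not make a heterozygote
  c1 <- call_individual(setNames(c(8, 2), c(k31, k30L)))
  expect_equal(c1$zygosity, "single")
  expect_equal(c1$clones$class[c1$clones$key == k30L], "SLIPPAGE_CONTRACTION")
  # a true het partner at ~50% stays above the stutter ceiling
  c2 <- call_individual(setNames(c(5, 4), c(k31, k32)))
  expect_equal(c2$zygosity, "heterozygous")
  # two foreign clones do not make a heterozygote either
  c3 <- call_individual(setNames(c(8, 2), c(k23, k31)),
                        foreign_alleles = c("opa31", "opa32"))
  expect_equal(c3$zygosity, "single")
  expect_equal(c3$alleles$name, "opa23")
})

test_that("degenerate tallies give ambiguous calls, not errors", {
  spread <- call_individual(setNames(rep(1, 6), c(
    k31, k32, k23, key_of("opa33a"), key_of("opa34"), key_of("opa33b"))))
  expect_equal(spread$zygosity, "ambiguous")
  expect_false(is.na(spread$diagnostic))
  expect_warning(call_individual(setNames(2, k31)), "clones")
})

test_that("every clone receives exactly one class and counts partition", {
  set.seed(11)
  pool <- c(k31, k32, k23, k30L, k31L, key_of("opa33a"))
  for (rep in 1:25) {
    counts <- table(sample(pool, sample(3:13, 1), replace = TRUE))
    call <- suppressWarnings(
      call_individual(setNames(as.integer(counts), names(counts)),
                      foreign_alleles = c("opa33a")))
    expect_equal(sum(call$clones$count), sum(counts))
    expect_false(any(is.na(call$clones$class)))
    expect_true(all(call$clones$class %in% c(
      "ORIGINAL", "SLIPPAGE_CONTRACTION", "SLIPPAGE_EXPANSION",
      "CONTAMINANT_INTRACULTURE", "CONTAMINANT_INTERCULTURE", "AMBIGUOUS")))
    if (call$zygosity == "heterozygous") expect_equal(nrow(call$alleles), 2L)
  }
})

test_that("the sequential caller agrees with the enumeration oracle", {
  set.seed(23)
  params <- genotype_params()
  foreign <- list(registry_get(reg, "opa33a"))
  pool <- c(k31, k32, k23, k30L, k31L, slip_key("opa31", "opa29L"),
            key_of("opa33a"))
  for (rep in 1:60) {
    draw <- sample(pool, sample(4:13, 1), replace = TRUE,
                   prob = c(8, 6, 4, 1, 1, 1, 1))
    counts <- table(draw)
    counts <- setNames(as.integer(counts), names(counts))
    call <- suppressWarnings(
      call_individual(counts, params, foreign_alleles = list(foreign[[1]])))
    want <- oracle_call(counts, params, foreign)
    expect_equal(sort(call$alleles$key), want$candidates)
    expect_equal(call$zygosity, want$zygosity)
    got <- setNames(call$clones$class, call$clones$key)
    expect_equal(got[names(want$classes)], want$classes[names(want$classes)],
                 ignore_attr = TRUE)
  }
})

test_that("line calls union individual alleles and flag conflicts", {
  ind <- function(counts, foreign = NULL)
    call_individual(counts, foreign_alleles = foreign)
  hets <- replicate(3, ind(setNames(c(5, 5), c(k31, k32))), simplify = FALSE)
  singles31 <- replicate(2, ind(setNames(10, k31)), simplify = FALSE)
  singles32 <- replicate(2, ind(setNames(10, k32)), simplify = FALSE)
  line <- call_line(c(hets, singles31, singles32), "RAL-sim")
  expect_true(line$het)
  expect_setequal(line$haplotypes, c("opa31", "opa32"))
  expect_true(line$conflict)  # conflicting single-allele calls are flagged
  solo <- call_line(singles31, "mono")
  expect_false(solo$het)
  expect_equal(solo$haplotypes, "opa31")
})

test_that("error rates keep numerators and denominators", {
  call <- call_individual(setNames(c(20, 1), c(k31, k30L)))
  er <- estimate_error_rates(call$clones)
  expect_equal(er$contraction$numerator, 1L)
  expect_equal(er$contraction$denominator, 21L)
  expect_equal(percent1(er$contraction$rate), 4.8)
  clean <- call_individual(setNames(100, k31))
  er0 <- estimate_error_rates(clean$clones)
  expect_equal(er0$contraction$rate, 0)
  expect_equal(er0$expansion$rate, 0)
  expect_equal(er0$original$rate, 1)
  expect_error(estimate_error_rates(data.frame(class = character(0))),
               class = "notchopa_undefined_rate")
})
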
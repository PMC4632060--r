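# Population summaries and X-linked Hardy-Weinberg expectations.
#
# Line-level summaries follow the conventions of the genotyping survey:
# a homozygous (or hemizygous) line contributes weight 1 to its allele, each
# haplotype of a segregating line contributes 0.5, and repeat-length
# deviation is measured as |length - 31| residues from the wild-type opa31.

.name_length <- function(name) {
  len <- suppressWarnings(as.integer(sub("^opa(\\d+).*$", "\\1", name)))
  if (any(is.na(len)))
    stop_notchopa(sprintf("cannot read a repeat length from allele name '%s'",
                          name[is.na(len)][1]), "notchopa_domain_error")
  len
}

.as_line_df <- function(lines) {
  if (is.data.frame(lines)) {
    stopifnot(all(c("haplotype1") %in% names(lines)))
    if (is.null(lines$haplotype2)) lines$haplotype2 <- NA_character_
    return(lines)
  }
  # list of opa_line_genotype
  do.call(rbind, lapply(lines, function(l)
    data.frame(line_id = l$line_id, haplotype1 = l$haplotypes[1],
               haplotype2 = if (length(l$haplotypes) >= 2L) l$haplotypes[2]
               else NA_character_, stringsAsFactors = FALSE)))
}

#' Allele weights across lines
#'
#' Each homozygous line contributes weight 1 to its allele; each haplotype of
#' a heterozygous (segregating) line contributes 0.5.  Weights therefore sum
#' to the number of lines.
#'
#' @param lines data.frame with columns `haplotype1` and optionally
#'   `haplotype2` (`NA` for homozygous lines), or a list of
#'   [call_line()] results.
#' @return named numeric vector of weights, ordered by repeat length then
#'   name.
#' @export
allele_distribution <- function(lines) {
  lines <- .as_line_df(lines)
  if (is.null(lines) || nrow(lines) == 0L) return(stats::setNames(numeric(0), character(0)))
  het <- !is.na(lines$haplotype2)
  w <- c(stats::setNames(ifelse(het, 0.5, 1), lines$haplotype1),
         stats::setNames(rep(0.5, sum(het)), lines$haplotype2[het]))
  out <- tapply(w, names(w), sum)
  out <- out[order(.name_length(names(out)), names(out))]
  stats::setNames(as.vector(out), names(out))
}

#' Fraction of haplotype weight that is not wild type
#'
#' @param lines as in [allele_distribution()].
#' @param wildtype wild-type allele name.
#' @return fraction in \[0, 1\]: (total weight - wild-type weight) / lines.
#' @export
nonwildtype_fraction <- function(lines, wildtype = "opa31") {
  lines <- .as_line_df(lines)
  if (is.null(lines) || nrow(lines) == 0L)
    stop_notchopa("no lines: fraction undefined", "notchopa_undefined_rate")
  dist <- allele_distribution(lines)
  wt <- if (wildtype %in% names(dist)) dist[[wildtype]] else 0
  (sum(dist) - wt) / nrow(lines)
}

#' Mean absolute repeat-length deviation from wild type
#'
#' Per line, the mean of |length - reference| over its haplotypes (so each
#' haplotype of a heterozygous line is weighted 0.5); then averaged over
#' lines.
#'
#' @param lines as in [allele_distribution()].
#' @param reference_length wild-type repeat length in residues.
#' @return mean deviation in amino acids.
#' @export
mean_abs_deviation <- function(lines, reference_length = 31) {
  lines <- .as_line_df(lines)
  if (is.null(lines) || nrow(lines) == 0L)
    stop_notchopa("no lines: deviation undefined", "notchopa_undefined_rate")
  dev <- vapply(seq_len(nrow(lines)), function(i) {
    haps <- c(lines$haplotype1[i], lines$haplotype2[i])
    haps <- haps[!is.na(haps)]
    mean(abs(.name_length(haps) - reference_length))
  }, 0)
  mean(dev)
}

#' Percent female from sex counts
#'
#' @param n_female,n_male counts.
#' @return percent female (0-100).
#' @export
sex_ratio <- function(n_female, n_male) {
  if (n_female + n_male <= 0)
    stop_notchopa("no individuals: sex ratio undefined", "notchopa_undefined_rate")
  100 * n_female / (n_female + n_male)
}

#' X-linked Hardy-Weinberg expected genotype counts
#'
#' At an X-linked biallelic locus, males are hemizygous, so the expected
#' counts among `n` individuals with female fraction `f` and allele
#' frequency `p` are: A-only = M p + F p^2, B-only = M (1-p) + F (1-p)^2,
#' heterozygous (females only) = F 2p(1-p), with F the female count and
#' M = n - F.  The female count is rounded to an integer before the
#' expectations are computed, and the reported counts are additionally
#' rounded half away from zero -- the rounding order under which the
#' published 14/14/11 expectation for 39 individuals at 53.7% female and
#' p = 0.5 is reproduced.
#'
#' @param n number of individuals.
#' @param percent_female percent of females (0-100).
#' @param p frequency of allele A.
#' @return an object of class `opa_hwe`: `n`, `n_female`, `n_male`, `p`,
#'   `expected` (raw A-only/B-only/het counts, summing to `n`), and
#'   `expected_rounded`.
#' @examples
#' xlinked_hw_expected(39, 53.7, 0.5)
#' @export
xlinked_hw_expected <- function(n, percent_female, p) {
  if (p < 0 || p > 1 || percent_female < 0 || percent_female > 100)
    stop_notchopa("p must be in [0,1] and percent_female in [0,100]",
                  "notchopa_domain_error")
  f <- round_half_away(n * percent_female / 100)
  m <- n - f
  expected <- c(A_only = m * p + f * p^2,
                B_only = m * (1 - p) + f * (1 - p)^2,
                het_female = f * 2 * p * (1 - p))
  structure(list(n = n, n_female = f, n_male = m, p = p,
                 expected = expected,
                 expected_rounded = round_half_away(expected)),
            class = "opa_hwe")
}

#' @export
print.opa_hwe <- function(x, ...) {
  cat(sprintf("X-linked Hardy-Weinberg expectation: n = %d (%dF/%dM), p = %g\n",
              x$n, x$n_female, x$n_male, x$p))
  for (nm in names(x$expected))
    cat(sprintf("  %-11s %6.2f  (rounded %d)\n", nm, x$expected[[nm]],
                as.integer(x$expected_rounded[[nm]])))
  invisible(x)
}

#' Pearson goodness of fit of observed to expected counts
#'
#' Chi-square statistic sum((O-E)^2/E) with categories - 1 degrees of
#' freedom, for comparing observed genotype counts with (externally supplied)
#' Hardy-Weinberg expectations.
#'
#' @param observed,expected named or unnamed count vectors over matching
#'   categories.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
goodness_of_fit <- function(observed, expected) {
  if (length(observed) != length(expected) ||
      (!is.null(names(observed)) && !is.null(names(expected)) &&
       !setequal(names(observed), names(expected))))
    stop_notchopa("observed and expected categories do not match",
                  "notchopa_domain_error")
  if (!is.null(names(observed)) && !is.null(names(expected)))
    expected <- expected[names(observed)]
  if (any(expected <= 0))
    stop_notchopa("expected counts must be positive", "notchopa_domain_error")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Write a distribution and group-statistics summary as TSV
#'
#' @param lines as in [allele_distribution()], with optional `group` column.
#' @param dir output directory; writes `distribution.tsv` (allele weights,
#'   bar-plot ready) and, when a `group` column is present,
#'   `group_stats.tsv` (per-group non-wild-type percent and mean deviation).
#' @param wildtype,reference_length see [nonwildtype_fraction()] and
#'   [mean_abs_deviation()].
#' @return `dir`, invisibly.
#' @export
write_population_tsv <- function(lines, dir, wildtype = "opa31",
                                 reference_length = 31) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- .as_line_df(lines)
  dist <- allele_distribution(lines)
  utils::write.table(
    data.frame(allele = names(dist), length = .name_length(names(dist)),
               weight = as.vector(dist)),
    file.path(dir, "distribution.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(lines$group)) {
    stats_df <- do.call(rbind, lapply(split(lines, lines$group), function(g)
      data.frame(group = g$group[1], n_lines = nrow(g),
                 pct_nonwildtype = percent1(nonwildtype_fraction(g, wildtype)),
                 mean_abs_deviation =
                   round_half_away(mean_abs_deviation(g, reference_length), 1),
                 stringsAsFactors = FALSE)))
    utils::write.table(stats_df, file.path(dir, "group_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
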
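# Published survey tables used as computable inputs.
#
# These are the printed line-genotype, fecundity and QC clone tallies from
# the Sanger genotyping survey of the Notch opa repeats in the DGRP (RAL)
# lines, transcribed as in-code data so the summary statistics can be
# recomputed from scratch.

#' Line genotypes from the DGRP opa genotyping survey
#'
#' One row per line per survey group.  Groups: `dirty_dozen` (lines with
#' ambiguous short-read assemblies), `radiation_resistant` (top
#' radiation-resistant lines), `radiation_sensitive` (randomly chosen
#' radiation-sensitive lines), and `in3rk` (homozygotes for the Kodani 3R
#' inversion).  Segregating stocks carry both haplotypes (RAL-142
#' opa31/opa32, RAL-370 opa36/opa37); some lines appear in several groups.
#'
#' @return data.frame with columns `group`, `line_id`, `haplotype1`,
#'   `haplotype2` (`NA` for homozygous lines).
#' @export
dgrp_line_genotypes <- function() {
  g <- function(group, line_id, h1, h2 = NA_character_)
    data.frame(group = group, line_id = line_id, haplotype1 = h1,
               haplotype2 = h2, stringsAsFactors = FALSE)
  rbind(
    g("dirty_dozen", "RAL-21", "opa31"),
    g("dirty_dozen", "RAL-237", "opa35a1"),
    g("dirty_dozen", "RAL-350", "opa31"),
    g("dirty_dozen", "RAL-439", "opa31"),
    g("dirty_dozen", "RAL-440", "opa31"),
    g("dirty_dozen", "RAL-555", "opa33a"),
    g("dirty_dozen", "RAL-646", "opa23"),
    g("dirty_dozen", "RAL-776", "opa33a"),
    g("dirty_dozen", "RAL-796", "opa33a"),
    g("dirty_dozen", "RAL-801", "opa32"),
    g("dirty_dozen", "RAL-802", "opa32"),
    g("dirty_dozen", "RAL-822", "opa31"),

    g("radiation_resistant", "RAL-91", "opa31"),
    g("radiation_resistant", "RAL-69", "opa32"),
    g("radiation_resistant", "RAL-338", "opa32"),
    g("radiation_resistant", "RAL-208", "opa31"),
    g("radiation_resistant", "RAL-57", "opa33b"),
    g("radiation_resistant", "RAL-492", "opa31"),
    g("radiation_resistant", "RAL-142", "opa31", "opa32"),
    g("radiation_resistant", "RAL-879", "opa31"),
    g("radiation_resistant", "RAL-370", "opa36", "opa37"),
    g("radiation_resistant", "RAL-808", "opa31"),
    g("radiation_resistant", "RAL-237", "opa35a1"),
    g("radiation_resistant", "RAL-88", "opa37"),
    g("radiation_resistant", "RAL-405", "opa31"),
    g("radiation_resistant", "RAL-646", "opa23"),
    g("radiation_resistant", "RAL-801", "opa32"),
    g("radiation_resistant", "RAL-105", "opa33b"),
    g("radiation_resistant", "RAL-776", "opa33a"),
    g("radiation_resistant", "RAL-195", "opa31"),

    g("radiation_sensitive", "RAL-21", "opa31"),
    g("radiation_sensitive", "RAL-350", "opa31"),
    g("radiation_sensitive", "RAL-365", "opa31"),
    g("radiation_sensitive", "RAL-439", "opa31"),
    g("radiation_sensitive", "RAL-440", "opa31"),
    g("radiation_sensitive", "RAL-555", "opa33a"),
    g("radiation_sensitive", "RAL-712", "opa31"),
    g("radiation_sensitive", "RAL-796", "opa33a"),
    g("radiation_sensitive", "RAL-802", "opa32"),
    g("radiation_sensitive", "RAL-820", "opa34"),
    g("radiation_sensitive", "RAL-822", "opa31"),
    g("radiation_sensitive", "RAL-832", "opa31"),
    g("radiation_sensitive", "RAL-837", "opa31"),
    g("radiation_sensitive", "RAL-852", "opa35a2"),
    g("radiation_sensitive", "RAL-859", "opa32"),
    g("radiation_sensitive", "RAL-861", "opa32"),
    g("radiation_sensitive", "RAL-882", "opa31"),
    g("radiation_sensitive", "RAL-887", "opa31"),
    g("radiation_sensitive", "RAL-890", "opa31"),
    g("radiation_sensitive", "RAL-897", "opa31"),
    g("radiation_sensitive", "RAL-908", "opa31"),
    g("radiation_sensitive", "RAL-911", "opa31"),

    g("in3rk", "RAL-100", "opa32"),
    g("in3rk", "RAL-105", "opa33b"),
    g("in3rk", "RAL-646", "opa23")
  )
}

#' Fecundity counts for the lines with the shortest and longest opa variants
#'
#' Eggs laid in a 28-hr period at 25 degrees.
#'
#' @return data.frame with columns `line_id`, `genotype`, `eggs`.
#' @export
dgrp_fecundity <- function() {
  data.frame(
    line_id = c("RAL-646", "RAL-021", "RAL-439", "RAL-440", "RAL-822", "RAL-237"),
    genotype = c("opa23", "opa31", "opa31", "opa31", "opa31", "opa35"),
    eggs = c(1436L, 1196L, 1699L, 742L, 1438L, 2276L),
    stringsAsFactors = FALSE
  )
}

#' Look up a slippage variant of a registry allele
#'
#' Convenience accessor: enumerates [slippage_neighbors()] of `parent` and
#' returns the derivative with the requested name (e.g. `"opa30L"` from
#' `"opa31"`).
#'
#' @param registry an [allele_registry()].
#' @param parent parent allele name.
#' @param name derivative name (`"opa{N}{L|R}"`).
#' @return an [allele_record()].
#' @export
slip_variant <- function(registry, parent, name) {
  nb <- slippage_neighbors(registry_get(registry, parent),
                           ancestral_his_index = registry$ancestral_his_index)
  for (rec in nb) if (rec$name == name) return(rec)
  stop_notchopa(sprintf("'%s' is not a slippage neighbor of '%s'", name, parent),
                "notchopa_domain_error")
}

#' Clone tallies of the four genotyping QC experiments
#'
#' The quality-control clone sets from the genotyping survey, reconstructed
#' from their published tallies with registry (placeholder) codon strings:
#'
#' * `pcr_error`: 21 clones re-amplified from a single opa31 template; one
#'   opa30L contraction (PCR error rate 1/21).
#' * `somatic`: 218 clones of the endogenous locus of an opa31 stock; 205
#'   original and 13 contractions.  (The published per-class tally
#'   enumerates 12 of the 13 variants implied by the totals; the
#'   unenumerated clone is assigned here to the dominant opa30L class.)
#' * `intraculture`: 360 pooled clones from 39 individuals of a stock
#'   segregating opa31/opa32 in equal amounts; 21 contractions and one
#'   two-clone opa33L expansion.
#' * `interculture`: 358 pooled clones from 38 individuals of the opa23
#'   stock; 12 opa22L contractions plus 13 clones matching the foreign
#'   opa31/opa32 cultures handled the same day (`foreign` lists them).
#'
#' @return named list; each element has `tally` (named clone counts keyed by
#'   third-position codon string) and `foreign` (foreign allele names or
#'   `NULL`).
#' @export
qc_reference_clone_sets <- function() {
  reg <- default_registry()
  key <- function(rec) third_positions(rec$codons)
  opa31 <- registry_get(reg, "opa31")
  opa32 <- registry_get(reg, "opa32")
  opa23 <- registry_get(reg, "opa23")
  k31 <- key(opa31); k32 <- key(opa32); k23 <- key(opa23)
  k30L <- key(slip_variant(reg, "opa31", "opa30L"))
  k29L <- key(slip_variant(reg, "opa31", "opa29L"))
  k28L <- key(slip_variant(reg, "opa31", "opa28L"))
  k30R <- key(slip_variant(reg, "opa31", "opa30R"))
  k31L <- key(slip_variant(reg, "opa32", "opa31L"))
  k33L <- key(slip_variant(reg, "opa32", "opa33L"))
  k22L <- key(slip_variant(reg, "opa23", "opa22L"))
  list(
    pcr_error = list(
      tally = stats::setNames(c(20, 1), c(k31, k30L)),
      foreign = NULL),
    somatic = list(
      tally = stats::setNames(c(205, 10, 1, 2), c(k31, k30L, k29L, k30R)),
      foreign = NULL),
    intraculture = list(
      tally = stats::setNames(c(169, 168, 10, 10, 1, 2),
                              c(k31, k32, k30L, k31L, k28L, k33L)),
      foreign = NULL),
    interculture = list(
      tally = stats::setNames(c(333, 12, 6, 7), c(k23, k22L, k31, k32)),
      foreign = c("opa31", "opa32"))
  )
}
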
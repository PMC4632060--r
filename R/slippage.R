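# PCR slippage (stutter) model for the opa repeats.
#
# Replication slippage within a run of identical glutamine codons produces
# single- (occasionally multi-) codon contractions and, rarely, expansions.
# Derivatives are named "opa{N}{L|R}" by the side of the histidine on which
# the run lies; the observed extremes are a 4-codon contraction (opa27R from
# opa31) and a 2-codon expansion, which set the default reachability limits.

#' Maximal runs of identical glutamine codons
#'
#' @param codons codon string (any form accepted by [as_codons()]).
#' @return data.frame with columns `start`, `end`, `length`, `codon`, one row
#'   per maximal run of identical CAA or CAG codons (1-based, inclusive).
#' @export
codon_runs <- function(codons) {
  codons <- as_codons(codons)
  r <- rle(codons)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values %in% c("CAA", "CAG")
  data.frame(start = start[keep], end = end[keep],
             length = r$lengths[keep], codon = r$values[keep],
             stringsAsFactors = FALSE)
}

.his_index <- function(codons) {
  his <- which(codons %in% c("CAC", "CAT"))
  if (length(his) == 0L) NA_integer_ else his[1]
}

.run_side <- function(run_start, his_index, ancestral_his_index) {
  ref <- if (is.na(his_index)) ancestral_his_index else his_index
  if (run_start <= ref) "L" else "R"
}

#' Enumerate slippage derivatives of an allele
#'
#' Each derivative removes (1..`max_del`) or inserts (1..`max_ins`) codons
#' within one run of >= 2 identical glutamine codons; a deletion leaves at
#' least one codon of the run.  Derivatives are named `"opa{N}{L|R}"` with L
#' for changes left of the histidine and R for changes right of it; for
#' histidine-less parents the side is taken from the position the histidine
#' occupies in the ancestral wild-type pattern (`ancestral_his_index`).
#'
#' @param parent an [allele_record()] with a codon string.
#' @param max_del maximum codons deleted per event (default 4, the observed
#'   extreme).
#' @param max_ins maximum codons inserted per event (default 2).
#' @param ancestral_his_index see [allele_registry()].
#' @return list of derived [allele_record()]s (deduplicated by codon string);
#'   empty when the parent has no eligible run.
#' @export
slippage_neighbors <- function(parent, max_del = 4L, max_ins = 2L,
                               ancestral_his_index = 14L) {
  if (is.null(parent$codons))
    stop_notchopa("parent allele has no codon string", "notchopa_domain_error")
  codons <- parent$codons
  his <- .his_index(codons)
  runs <- codon_runs(codons)
  runs <- runs[runs$length >= 2L, , drop = FALSE]
  out <- list()
  seen <- character(0)
  add <- function(new_codons, side, steps) {
    key <- paste(third_positions(new_codons), side, sep = "|")
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    config <- classify_codons(new_codons)
    name <- sprintf("opa%d%s", total_residues(config), side)
    out[[length(out) + 1L]] <<- allele_record(
      name, config, new_codons,
      derived_from = list(parent = parent$name, side = side, steps = steps))
  }
  for (i in seq_len(nrow(runs))) {
    side <- .run_side(runs$start[i], his, ancestral_his_index)
    for (k in seq_len(max_del)) {
      if (k > runs$length[i] - 1L) break
      add(codons[-(runs$start[i]:(runs$start[i] + k - 1L))], side, -k)
    }
    for (k in seq_len(max_ins)) {
      ins <- rep(runs$codon[i], k)
      add(append(codons, ins, after = runs$start[i]), side, k)
    }
  }
  out
}

#' Test whether one allele is a slippage derivative of another
#'
#' True iff the child configuration is reachable from the parent by a length
#' change confined to one side of the histidine, within the deletion and
#' insertion limits.  Alleles that gain or lose the histidine are never
#' slippage derivatives (glutamine-run slippage cannot create or remove the
#' CAY codon).
#'
#' @param child,parent [allele_record()]s (codon strings not required).
#' @param max_del,max_ins reachability limits, as in [slippage_neighbors()].
#' @return list with elements `is_derivative` (flag), `side` (`"L"`, `"R"` or
#'   `NA`), and `steps` (positive count, or `NA`).
#' @examples
#' reg <- default_registry()
#' opa30L <- allele_record("opa30L", pq_config(12, TRUE, 17))
#' is_slippage_derivative(opa30L, registry_get(reg, "opa31"))
#' @export
is_slippage_derivative <- function(child, parent, max_del = 4L, max_ins = 2L) {
  no <- list(is_derivative = FALSE, side = NA_character_, steps = NA_integer_)
  cc <- child$config; pc <- parent$config
  if (cc$has_his != pc$has_his) return(no)
  within <- function(d) d != 0L && d >= -max_del && d <= max_ins
  if (!cc$has_his) {
    d <- cc$left_q - pc$left_q
    if (!within(d)) return(no)
    # side for uninterrupted tracts follows the ancestral wild-type layout,
    # under which the slippage-prone CAG run lies left of the histidine
    return(list(is_derivative = TRUE, side = "L", steps = abs(d)))
  }
  dl <- cc$left_q - pc$left_q
  dr <- cc$right_q - pc$right_q
  if (dl != 0L && dr == 0L && within(dl))
    list(is_derivative = TRUE, side = "L", steps = abs(dl))
  else if (dr != 0L && dl == 0L && within(dr))
    list(is_derivative = TRUE, side = "R", steps = abs(dr))
  else
    no
}
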
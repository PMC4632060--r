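# Shared fixtures and an independent calling oracle.

# codon vector for (l, H?, r) built directly, without default_codons()
build_cax <- function(left_q, has_his = FALSE, right_q = 0L) {
  c(rep("CAG", left_q), if (has_his) "CAT", rep("CAG", right_q))
}

# Independent oracle for call_individual: enumerates candidate subsets and
# classification assignments instead of running the sequential procedure.
# An allele is "explainable" by a set S if it is a slippage derivative of a
# better-supported member (below the stutter ceiling) or foreign-listed
# while S keeps a non-foreign member.  The oracle returns the maximal
# support-qualified subset with nothing explainable, plus the rule-priority
# class of every allele outside it.
oracle_call <- function(counts, params = genotype_params(),
                        foreign_records = list()) {
  keys <- names(counts)
  total <- sum(counts)
  recs <- lapply(keys, function(k) {
    codons <- notchopa::as_codons(k)
    list(name = k, config = classify_codons(codons), codons = codons)
  })
  names(recs) <- keys
  is_foreign <- vapply(keys, function(k) {
    any(vapply(foreign_records, function(f) {
      pq_string(f$config) == pq_string(recs[[k]]$config) &&
        (is.null(f$codons) || identical(f$codons, recs[[k]]$codons))
    }, TRUE))
  }, TRUE)
  support <- keys[counts >= params$het_min_support &
                    counts / total >= params$het_min_frac]
  slip_of <- function(b, a) is_slippage_derivative(recs[[b]], recs[[a]],
                                                   params$max_del,
                                                   params$max_ins)$is_derivative
  explainable <- function(b, S) {
    slip <- any(vapply(S, function(a)
      counts[[a]] > counts[[b]] && slip_of(b, a), TRUE)) &&
      counts[[b]] / total <= params$slip_max_frac
    contam <- is_foreign[[b]] && any(!is_foreign[S])
    slip || contam
  }
  S <- support
  repeat {
    drop <- Filter(function(b) explainable(b, setdiff(S, b)), S)
    if (length(drop) == 0L) break
    # drop the weakest explainable allele first
    S <- setdiff(S, drop[[which.min(counts[drop])]])
  }
  classify <- function(b) {
    slip_parent <- Filter(function(a) slip_of(b, a), S)
    if (length(slip_parent) > 0L) {
      shorter <- total_residues(recs[[b]]$config) <
        total_residues(recs[[slip_parent[[1]]]]$config)
      if (shorter) "SLIPPAGE_CONTRACTION" else "SLIPPAGE_EXPANSION"
    } else if (is_foreign[[b]]) "CONTAMINANT_INTERCULTURE"
    else if (counts[[b]] == 1L &&
             total >= params$singleton_contaminant_min_clones)
      "CONTAMINANT_INTRACULTURE"
    else "AMBIGUOUS"
  }
  cls <- vapply(keys, function(k)
    if (k %in% S) "ORIGINAL" else classify(k), "")
  zyg <- if (length(S) == 1L) "single"
  else if (length(S) == 2L) "heterozygous" else "ambiguous"
  list(candidates = sort(S), classes = cls, zygosity = zyg)
}
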
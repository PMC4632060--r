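# Anchor-based extraction of the CAX repeat run from clone sequences.
#
# Repeat alignments need flanking non-repetitive "anchor" sequence to start
# and end in the right place, so the locus is located by matching a left and
# a right anchor (allowing a few substitutions, no indels -- Sanger clone
# flanks are high quality) on both strands and taking the in-frame CAX codon
# run between them.

#' Anchor configuration for repeat extraction
#'
#' @param left_anchor,right_anchor non-repetitive nucleotide flanks bounding
#'   the repeat run.
#' @param max_mismatch substitutions tolerated per anchor (no indels).
#' @return an object of class `anchor_config`.
#' @export
anchor_config <- function(left_anchor, right_anchor, max_mismatch = 1L) {
  left_anchor <- toupper(left_anchor)
  right_anchor <- toupper(right_anchor)
  if (!nzchar(left_anchor) || !nzchar(right_anchor))
    stop_notchopa("anchors must be non-empty", "notchopa_domain_error")
  has_cax_run <- function(a) {
    # an in-frame run of >= 2 CAX codons in any of the three frames
    grepl("(CA[AGCT]){2}", a)
  }
  if (has_cax_run(left_anchor) || has_cax_run(right_anchor))
    stop_notchopa("anchors must not contain an in-frame CAX run of length >= 2",
                  "notchopa_domain_error")
  structure(list(left_anchor = left_anchor, right_anchor = right_anchor,
                 max_mismatch = as.integer(max_mismatch)),
            class = "anchor_config")
}

#' Default anchors used by the synthetic clone generator
#'
#' Synthetic placeholders (the true genomic flanks are not shipped); any
#' 10-bp non-CAX flanks satisfying [anchor_config()] work.
#'
#' @param max_mismatch substitutions tolerated per anchor.
#' @return an [anchor_config()].
#' @export
default_anchors <- function(max_mismatch = 1L) {
  anchor_config("ATGTCGCCTA", "TGACCGTTAG", max_mismatch)
}

.match_anchor <- function(subject, anchor, max_mismatch) {
  m <- Biostrings::matchPattern(anchor, subject,
                                max.mismatch = max_mismatch,
                                with.indels = FALSE)
  data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m))
}

.extract_one_strand <- function(seq_string, anchors) {
  subject <- Biostrings::DNAString(seq_string)
  left <- .match_anchor(subject, anchors$left_anchor, anchors$max_mismatch)
  right <- .match_anchor(subject, anchors$right_anchor, anchors$max_mismatch)
  loci <- list()
  for (le in left$end) for (rs in right$start) {
    width <- rs - le - 1L
    if (width < 3L || width %% 3L != 0L) next
    inner <- substr(seq_string, le + 1L, rs - 1L)
    codons <- substring(inner, seq(1L, nchar(inner), 3L),
                        seq(3L, nchar(inner), 3L))
    config <- tryCatch(classify_codons(codons), error = function(e) e)
    loci[[length(loci) + 1L]] <- list(start0 = le, end0 = rs - 1L,
                                      codons = codons, config = config)
  }
  loci
}

#' Locate and extract the CAX repeat run from a sequence
#'
#' Searches both strands for the anchor pair and returns the in-frame CAX
#' codon run between the matches.  The extraction refuses to guess: several
#' candidate loci raise an ambiguity error listing all of them, and a
#' non-CAX codon between matched anchors raises a malformed-repeat error.
#'
#' @param sequence nucleotide string (or `DNAString`).
#' @param anchors an [anchor_config()].
#' @param seq_id identifier carried into the result.
#' @return an object of class `repeat_locus`: list with `seq_id`, `strand`
#'   (`"+"`/`"-"`), `start`/`end` (0-based half-open, on the searched
#'   strand), `codons`, `config` and `n_codons`.
#' @export
locate_and_extract <- function(sequence, anchors, seq_id = NA_character_) {
  stopifnot(inherits(anchors, "anchor_config"))
  seq_string <- toupper(as.character(sequence))
  if (nchar(seq_string) <
      nchar(anchors$left_anchor) + nchar(anchors$right_anchor) + 3L)
    stop_notchopa("sequence too short to contain anchors and a repeat run",
                  "notchopa_no_locus")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_string)))
  hits <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq_string else rc
    for (locus in .extract_one_strand(s, anchors)) {
      locus$strand <- strand
      hits[[length(hits) + 1L]] <- locus
    }
  }
  if (length(hits) == 0L)
    stop_notchopa("anchor pair not found on either strand", "notchopa_no_locus")
  if (length(hits) > 1L)
    stop_notchopa(sprintf("ambiguous extraction: %d candidate loci (%s)",
                          length(hits),
                          paste(vapply(hits, function(h)
                            sprintf("%s:%d-%d", h$strand, h$start0, h$end0), ""),
                            collapse = ", ")),
                  "notchopa_ambiguous_locus")
  hit <- hits[[1]]
  if (inherits(hit$config, "error")) stop(hit$config)
  structure(list(seq_id = seq_id, strand = hit$strand,
                 start = hit$start0, end = hit$end0,
                 codons = hit$codons, config = hit$config,
                 n_codons = length(hit$codons)),
            class = "repeat_locus")
}

#' @export
print.repeat_locus <- function(x, ...) {
  cat(sprintf("repeat locus %s [%s:%d-%d): %d CAX codons, %s\n",
              x$seq_id, x$strand, x$start, x$end, x$n_codons,
              pq_string(x$config)))
  invisible(x)
}

#' Extract repeat runs from a FASTA file or sequence set
#'
#' @param fasta path to a FASTA file, a named character vector of sequences,
#'   or a `DNAStringSet`.
#' @param anchors an [anchor_config()].
#' @return data.frame with one row per sequence: `sequence_id`, `strand`,
#'   `start`, `end`, `n_codons`, `pq_string`, `third_position_string`, and
#'   `error` (`NA` on success; extraction failures are reported per sequence
#'   rather than aborting the run).
#' @export
extract_repeats <- function(fasta, anchors) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    Biostrings::readDNAStringSet(fasta)
  else fasta
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    res <- tryCatch(
      locate_and_extract(as.character(seqs[[i]]), anchors, seq_id = ids[i]),
      notchopa_error = function(e) e)
    if (inherits(res, "error"))
      data.frame(sequence_id = ids[i], strand = NA_character_,
                 start = NA_integer_, end = NA_integer_,
                 n_codons = NA_integer_, pq_string = NA_character_,
                 third_position_string = NA_character_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(sequence_id = ids[i], strand = res$strand,
                 start = res$start, end = res$end, n_codons = res$n_codons,
                 pq_string = pq_string(res$config),
                 third_position_string = third_positions(res$codons),
                 error = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an extraction table as TSV
#' @param extraction data.frame from [extract_repeats()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_extraction_tsv <- function(extraction, path) {
  utils::write.table(extraction, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Minimum read length spanning a repeat run
#'
#' A read must cover the full repeat plus anchor sequence on both sides:
#' `3 * n_codons + 2 * anchor_per_side` base pairs.  The wild-type 31-codon
#' run with 10-bp anchors needs reads longer than 140 bp, which is why
#' short-read assemblies fail at this locus.
#'
#' @param n_codons repeat length in codons.
#' @param anchor_per_side anchor bases required on each side.
#' @return required bases (bp).
#' @examples
#' min_spanning_read_length(40, 10)  # 140
#' @export
min_spanning_read_length <- function(n_codons, anchor_per_side) {
  if (any(n_codons < 0) || any(anchor_per_side < 0))
    stop_notchopa("arguments must be non-negative", "notchopa_domain_error")
  3 * n_codons + 2 * anchor_per_side
}

#' Can a read span a repeat run?
#'
#' Strict inequality: a read exactly as long as the required span is not
#' sufficient (a 75-nt read cannot span 23 codons with 3-bp anchors, which
#' needs exactly 75 bases).
#'
#' @param read_len read length (bp).
#' @inheritParams min_spanning_read_length
#' @return logical.
#' @export
can_span <- function(read_len, n_codons, anchor_per_side) {
  read_len > min_spanning_read_length(n_codons, anchor_per_side)
}
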
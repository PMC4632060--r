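# pQ configurations and CAX codon strings.
#
# The opa repeats of Notch are a run of 5'-CAX codons: CAA/CAG (CAR) encode
# glutamine, CAC/CAT (CAY) encode histidine.  A configuration is two pQ
# tracts separated by at most one histidine, written Q{l}HQ{r} (or Q{l} for
# an uninterrupted tract).  Codon strings are carried in "third position"
# compact form: one of A/G/C/T per codon.

.Q_THIRD <- c("A", "G")   # CAA, CAG -> glutamine
.H_THIRD <- c("C", "T")   # CAC, CAT -> histidine

#' Construct a pQ configuration
#'
#' @param left_q number of glutamine codons before the histidine (the whole
#'   tract when there is no histidine).
#' @param has_his whether the single interrupting histidine is present.
#' @param right_q number of glutamine codons after the histidine; must be 0
#'   when `has_his` is `FALSE`.
#' @return an object of class `pq_config` with fields `left_q`, `has_his`,
#'   `right_q`.
#' @examples
#' pq_config(13, TRUE, 17)   # the wild-type Q13HQ17 configuration
#' pq_config(23)             # the uninterrupted Q23 configuration
#' @export
pq_config <- function(left_q, has_his = FALSE, right_q = 0L) {
  left_q <- as.integer(left_q)
  right_q <- as.integer(right_q)
  if (is.na(left_q) || is.na(right_q) || left_q < 0L || right_q < 0L)
    stop_notchopa("tract lengths must be non-negative integers", "notchopa_domain_error")
  if (!has_his && right_q != 0L)
    stop_notchopa("right_q must be 0 when there is no histidine", "notchopa_domain_error")
  structure(list(left_q = left_q, has_his = isTRUE(has_his), right_q = right_q),
            class = "pq_config")
}

#' Total residue count of a pQ configuration
#' @param config a [pq_config()].
#' @return integer: left + right glutamines plus one for the histidine.
#' @export
total_residues <- function(config) {
  stopifnot(inherits(config, "pq_config"))
  config$left_q + config$right_q + as.integer(config$has_his)
}

#' Render a pQ configuration as a string
#' @param config a [pq_config()].
#' @return `"Q{l}HQ{r}"`, or `"Q{l}"` for an uninterrupted tract.
#' @export
pq_string <- function(config) {
  stopifnot(inherits(config, "pq_config"))
  if (config$has_his)
    sprintf("Q%dHQ%d", config$left_q, config$right_q)
  else
    sprintf("Q%d", config$left_q)
}

#' @export
format.pq_config <- function(x, ...) pq_string(x)

#' @export
print.pq_config <- function(x, ...) {
  cat(sprintf("pQ configuration %s (%d residues)\n", pq_string(x), total_residues(x)))
  invisible(x)
}

#' @export
as.character.pq_config <- function(x, ...) pq_string(x)

pq_equal <- function(a, b) {
  a$left_q == b$left_q && a$has_his == b$has_his && a$right_q == b$right_q
}

# ---- codon strings -----------------------------------------------------

#' Split a CAX nucleotide run into codons
#'
#' @param x either a nucleotide string whose length is a multiple of 3, a
#'   character vector of three-letter codons, or a compact third-position
#'   string (one of A/G/C/T per codon).
#' @return character vector of codons (`"CAA"`, `"CAG"`, `"CAC"`, `"CAT"`).
#' @export
as_codons <- function(x) {
  x <- toupper(as.character(x))
  if (length(x) == 1L && nzchar(x) && !grepl("[^AGCT]", x)) {
    if (!grepl("CA", x, fixed = TRUE)) {
      # compact third-position form
      x <- paste0("CA", strsplit(x, "")[[1]])
    } else {
      if (nchar(x) %% 3L != 0L)
        stop_notchopa("nucleotide run length is not a multiple of 3",
                      "notchopa_malformed_repeat")
      x <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
    }
  }
  if (length(x) == 0L || identical(x, ""))
    stop_notchopa("empty codon input", "notchopa_empty_input")
  x
}

#' Compact third-position form of a codon string
#' @param codons codon vector or string accepted by [as_codons()].
#' @return single string of third positions, e.g. `"GGGT..."`.
#' @export
third_positions <- function(codons) {
  codons <- as_codons(codons)
  paste(substring(codons, 3L, 3L), collapse = "")
}

#' Classify a CAX codon run into a pQ configuration
#'
#' Validates that every codon is a 5'-CAX codon with at most one histidine
#' codon (CAC/CAT), and returns the left-tract / histidine / right-tract
#' layout.
#'
#' @param codons codon vector, nucleotide run, or compact third-position
#'   string (see [as_codons()]).
#' @return a [pq_config()].
#' @examples
#' classify_codons(c(rep("CAG", 13), "CAT", rep("CAG", 17)))  # Q13HQ17
#' classify_codons(strrep("G", 23))                           # Q23
#' @export
classify_codons <- function(codons) {
  codons <- as_codons(codons)
  bad <- !(codons %in% c("CAA", "CAG", "CAC", "CAT"))
  if (any(bad))
    stop_notchopa(sprintf("non-CAX codon in repeat run: %s", codons[bad][1]),
                  "notchopa_malformed_repeat")
  his <- which(codons %in% c("CAC", "CAT"))
  if (length(his) > 1L)
    stop_notchopa("more than one histidine codon in repeat run",
                  "notchopa_malformed_repeat")
  if (length(his) == 0L)
    pq_config(length(codons), FALSE, 0L)
  else
    pq_config(his - 1L, TRUE, length(codons) - his)
}

#' Build a default codon string for a pQ configuration
#'
#' Used for registry placeholder sequences: the left tract ends in a 7-codon
#' CAG run (the slippage hotspot, so simulated contractions are predominantly
#' left-side), the right tract breaks CAG runs with CAA so no run reaches 7,
#' and the histidine is CAT.
#'
#' @param config a [pq_config()].
#' @return character vector of codons.
#' @export
default_codons <- function(config) {
  stopifnot(inherits(config, "pq_config"))
  left_third <- function(n) {
    if (n <= 7L) strrep("G", n)
    else paste0(strrep("A", n - 7L), strrep("G", 7L))
  }
  right_third <- function(n) {
    out <- character(0)
    while (n > 6L) {
      out <- c(out, "GGGGGA")
      n <- n - 6L
    }
    paste(c(out, strrep("G", n)), collapse = "")
  }
  third <- if (config$has_his) {
    paste0(left_third(config$left_q), "T", right_third(config$right_q))
  } else if (config$left_q > 13L) {
    # uninterrupted tracts keep the wild-type left-arm layout (CAG hotspot
    # run ending at codon 13) so slippage in them is labelled left-side,
    # matching the observed opa22L-type contractions of opa23
    paste0(left_third(13L), right_third(config$left_q - 13L))
  } else {
    left_third(config$left_q)
  }
  as_codons(third)
}
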
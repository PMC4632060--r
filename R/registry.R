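# The allele registry: named opa alleles and the naming policy.
#
# Naming convention for opa alleles of Notch:
#   * base name "opa{N}" where N is the total residue count of the pQ-H-pQ
#     region (opa31 = Q13HQ17);
#   * a lowercase letter suffix (a, b, ...) separates same-length alleles
#     whose histidine sits at a different position (opa33a = Q14HQ18,
#     opa33b = Q15HQ17); an unlettered name occupies "a";
#   * a numeric suffix on the letter (a1, a2, ...) separates alleles with the
#     identical pQ configuration but different codon strings, i.e.
#     independent indel histories (opa35a1 / opa35a2, both Q13HQ21);
#   * "*n" tags mark synonymous single-substitution variants and are stored
#     as opaque registry tags;
#   * "L"/"R" suffixes mark slippage derivatives on the left/right side of
#     the histidine (opa30L = Q12HQ17 from opa31).

#' Construct an allele record
#'
#' @param name registry name, e.g. `"opa31"`, `"opa33b"`, `"opa35a1"`.
#' @param config a [pq_config()].
#' @param codons codon string (any form accepted by [as_codons()]) or `NULL`
#'   for phenotype-only records.
#' @param synonymous_suffix optional `"*n"` tag.
#' @param derived_from optional list(parent=, side=, steps=) for slippage
#'   variants.
#' @param notes free-text notes.
#' @return an object of class `allele_record`.
#' @export
allele_record <- function(name, config, codons = NULL, synonymous_suffix = NULL,
                          derived_from = NULL, notes = "") {
  stopifnot(inherits(config, "pq_config"))
  base_len <- as.integer(sub("^opa(\\d+).*$", "\\1", name))
  if (!is.na(base_len) && base_len != total_residues(config))
    stop_notchopa(sprintf("name '%s' does not match configuration %s (%d residues)",
                          name, pq_string(config), total_residues(config)),
                  "notchopa_registry_integrity")
  if (!is.null(codons)) {
    codons <- as_codons(codons)
    if (length(codons) != total_residues(config) ||
        !pq_equal(classify_codons(codons), config))
      stop_notchopa(sprintf("codon string of '%s' does not encode %s",
                            name, pq_string(config)),
                    "notchopa_registry_integrity")
  }
  structure(list(name = name, config = config, codons = codons,
                 synonymous_suffix = synonymous_suffix,
                 derived_from = derived_from, notes = notes),
            class = "allele_record")
}

#' @export
print.allele_record <- function(x, ...) {
  cat(sprintf("%s  %s (%d residues)%s\n", x$name, pq_string(x$config),
              total_residues(x$config),
              if (is.null(x$codons)) "  [no codon string]" else ""))
  if (!is.null(x$codons))
    cat("  third positions: ", third_positions(x$codons), "\n", sep = "")
  invisible(x)
}

#' Create an allele registry
#'
#' The registry is environment-backed so that [resolve_name()] can add newly
#' minted names in place.
#'
#' @param records list of [allele_record()]s.
#' @param ancestral_his_index 1-based codon position the histidine occupies in
#'   the ancestral wild-type pattern; used to assign an L/R side to slippage
#'   in histidine-less alleles (the wild type carries 13 left glutamines, so
#'   the histidine is codon 14).
#' @return an object of class `allele_registry`.
#' @export
allele_registry <- function(records = list(), ancestral_his_index = 14L) {
  env <- new.env(parent = emptyenv())
  env$records <- list()
  env$ancestral_his_index <- as.integer(ancestral_his_index)
  reg <- structure(env, class = "allele_registry")
  for (rec in records) registry_add(reg, rec)
  reg
}

#' Add a record to a registry
#' @param registry an [allele_registry()].
#' @param record an [allele_record()].
#' @return the registry, invisibly.
#' @export
registry_add <- function(registry, record) {
  stopifnot(inherits(registry, "allele_registry"), inherits(record, "allele_record"))
  if (record$name %in% names(registry$records))
    stop_notchopa(sprintf("duplicate allele name '%s'", record$name),
                  "notchopa_registry_integrity")
  registry$records[[record$name]] <- record
  invisible(registry)
}

#' Look up an allele by name
#' @param registry an [allele_registry()].
#' @param name allele name.
#' @return the [allele_record()], or an error if absent.
#' @export
registry_get <- function(registry, name) {
  rec <- registry$records[[name]]
  if (is.null(rec))
    stop_notchopa(sprintf("allele '%s' is not in the registry", name),
                  "notchopa_registry_integrity")
  rec
}

#' @export
#' @rdname registry_get
registry_names <- function(registry) names(registry$records)

#' @export
print.allele_registry <- function(x, ...) {
  cat(sprintf("allele registry: %d alleles\n", length(x$records)))
  for (rec in x$records)
    cat(sprintf("  %-10s %s\n", rec$name, pq_string(rec$config)))
  invisible(x)
}

#' Default allele registry
#'
#' The alleles genotyped in the RAL (DGRP) survey plus the Canton-S wild
#' type.  pQ configurations are as published; the codon strings are synthetic
#' placeholders built by [default_codons()] (the published third-position
#' strings are not machine-readable), with opa35a2 differing from opa35a1 by
#' a CAG/CAA swap so the two nucleotide-level alleles stay distinguishable.
#'
#' @return an [allele_registry()].
#' @export
default_registry <- function() {
  spec <- list(
    opa23  = pq_config(23L),
    opa31  = pq_config(13L, TRUE, 17L),
    opa32  = pq_config(13L, TRUE, 18L),
    opa33a = pq_config(14L, TRUE, 18L),
    opa33b = pq_config(15L, TRUE, 17L),
    opa34  = pq_config(16L, TRUE, 17L),
    opa35a1 = pq_config(13L, TRUE, 21L),
    opa35a2 = pq_config(13L, TRUE, 21L),
    opa36  = pq_config(13L, TRUE, 22L),
    opa37  = pq_config(13L, TRUE, 23L)
  )
  recs <- lapply(names(spec), function(nm) {
    codons <- default_codons(spec[[nm]])
    if (nm == "opa35a2") {
      # independent indel history placeholder: first right-tract codon CAA
      his <- which(codons %in% c("CAC", "CAT"))
      codons[his + 1L] <- "CAA"
    }
    allele_record(nm, spec[[nm]], codons,
                  notes = "synthetic placeholder codon string")
  })
  allele_registry(recs)
}

.parse_pq_string <- function(s) {
  m <- regmatches(s, regexec("^Q(\\d+)(?:HQ(\\d+))?$", s))[[1]]
  if (length(m) == 0L)
    stop_notchopa(sprintf("cannot parse pQ string '%s'", s),
                  "notchopa_registry_integrity")
  if (m[3] == "")
    pq_config(as.integer(m[2]))
  else
    pq_config(as.integer(m[2]), TRUE, as.integer(m[3]))
}

#' Read / write an allele registry as TSV
#'
#' Columns: `name`, `pq_string`, `third_position_string`, `his_index`,
#' `notes`.  The round trip is lossless.
#'
#' @param path file path.
#' @param registry an [allele_registry()].
#' @return `read_allele_registry()` returns an [allele_registry()];
#'   `write_allele_registry()` returns `path` invisibly.
#' @export
read_allele_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  recs <- lapply(seq_len(nrow(df)), function(i) {
    config <- .parse_pq_string(df$pq_string[i])
    codons <- if (!is.na(df$third_position_string[i]) &&
                  nzchar(df$third_position_string[i]))
      as_codons(df$third_position_string[i]) else NULL
    allele_record(df$name[i], config, codons,
                  notes = if ("notes" %in% names(df) && !is.na(df$notes[i]))
                    df$notes[i] else "")
  })
  allele_registry(recs)
}

#' @rdname read_allele_registry
#' @export
write_allele_registry <- function(registry, path) {
  recs <- registry$records
  df <- data.frame(
    name = vapply(recs, `[[`, "", "name"),
    pq_string = vapply(recs, function(r) pq_string(r$config), ""),
    third_position_string = vapply(recs, function(r)
      if (is.null(r$codons)) "" else third_positions(r$codons), ""),
    his_index = vapply(recs, function(r)
      if (r$config$has_his) r$config$left_q + 1L else NA_integer_, 1L),
    notes = vapply(recs, `[[`, "", "notes"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.parse_name <- function(name) {
  m <- regmatches(name, regexec("^opa(\\d+)([a-z]?)(\\d*)$", name))[[1]]
  if (length(m) == 0L) return(NULL)
  list(len = as.integer(m[2]),
       letter = if (m[3] == "") NA_character_ else m[3],
       number = if (m[4] == "") NA_integer_ else as.integer(m[4]))
}

#' Resolve (or mint) the registry name for a pQ configuration
#'
#' Returns the existing name on an exact match.  Otherwise a new name is
#' minted and added to the registry: `"opa{total}"` when the length is free;
#' the next free letter suffix when the length is taken by a different
#' histidine position; the next numeric suffix when the pQ configuration
#' matches an existing allele but the codon string differs.
#'
#' @param config a [pq_config()].
#' @param codons optional codon string; when supplied, nucleotide-level
#'   identity is required for an exact match.
#' @param registry an [allele_registry()]; minted names are added to it.
#' @return the allele name (character).
#' @export
resolve_name <- function(config, codons = NULL, registry) {
  stopifnot(inherits(config, "pq_config"), inherits(registry, "allele_registry"))
  if (!is.null(codons)) codons <- as_codons(codons)
  recs <- registry$records
  same_pq <- recs[vapply(recs, function(r) pq_equal(r$config, config), TRUE)]
  if (length(same_pq) > 0L) {
    if (is.null(codons)) return(same_pq[[1]]$name)
    for (r in same_pq) {
      if (is.null(r$codons) || identical(r$codons, codons)) return(r$name)
    }
    # identical pQ, different codon string: next numeric suffix in the family
    first <- .parse_name(same_pq[[1]]$name)
    letter <- if (!is.null(first) && !is.na(first$letter)) first$letter else "a"
    nums <- vapply(same_pq, function(r) {
      p <- .parse_name(r$name)
      if (is.null(p)) 1L else if (is.na(p$number)) 1L else p$number
    }, 1L)
    name <- sprintf("opa%d%s%d", total_residues(config), letter, max(nums) + 1L)
  } else {
    len <- total_residues(config)
    same_len <- recs[vapply(recs, function(r)
      total_residues(r$config) == len, TRUE)]
    if (length(same_len) == 0L) {
      name <- sprintf("opa%d", len)
    } else {
      used <- vapply(same_len, function(r) {
        p <- .parse_name(r$name)
        if (is.null(p) || is.na(p$letter)) "a" else p$letter
      }, "")
      free <- setdiff(letters, used)
      if (length(free) == 0L)
        stop_notchopa("letter suffixes exhausted", "notchopa_registry_integrity")
      name <- sprintf("opa%d%s", len, free[1])
    }
  }
  registry_add(registry, allele_record(name, config, codons))
  name
}

#' Distinct pQ isoforms encoded by a set of alleles
#'
#' Alleles differing only at the nucleotide level collapse to one isoform.
#'
#' @param alleles list of [allele_record()]s, or a character vector of names
#'   looked up in `registry`.
#' @param registry registry used when `alleles` is a character vector.
#' @return character vector of unique pQ strings.
#' @examples
#' reg <- default_registry()
#' length(distinct_isoforms(registry_names(reg), reg))  # 9
#' @export
distinct_isoforms <- function(alleles, registry = NULL) {
  if (is.character(alleles)) {
    stopifnot(!is.null(registry))
    alleles <- lapply(alleles, function(nm) registry_get(registry, nm))
  }
  unique(vapply(alleles, function(r) pq_string(r$config), ""))
}
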
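# Rule-based genotype calling from Sanger clone libraries.
#
# A genotype is called per individual from the tally of its sequenced
# clones.  Minor clones are explained, in order of biological precedence, as
# PCR slippage artifacts of a supported allele, as interculture contaminants
# (clones matching a known foreign stock), or as intraculture contaminants
# (a singleton minor allele among eight or more clones, the bottle-mate
# rule); anything left is ambiguous.

#' Genotype-calling parameters
#'
#' @param min_clones clones below which a call is flagged low-coverage
#'   (warning only).
#' @param het_min_support minimum clones for an allele to support
#'   heterozygosity.
#' @param het_min_frac minimum clone fraction for the same.
#' @param slip_max_frac ceiling fraction below which a support-qualified
#'   allele can still be demoted as a slippage artifact of a better-supported
#'   allele.  Stutter runs at ~5-6% per clone while a true heterozygous
#'   allele is drawn at ~50%, so 0.30 separates the two regimes at typical
#'   clone counts.
#' @param singleton_contaminant_min_clones minimum total clones for the
#'   singleton-contaminant (bottle-mate) rule to apply.
#' @param max_del,max_ins slippage reachability limits
#'   (see [is_slippage_derivative()]).
#' @return an object of class `genotype_params`.
#' @export
genotype_params <- function(min_clones = 5L, het_min_support = 2L,
                            het_min_frac = 0.2, slip_max_frac = 0.3,
                            singleton_contaminant_min_clones = 8L,
                            max_del = 4L, max_ins = 2L) {
  p <- list(min_clones = as.integer(min_clones),
            het_min_support = as.integer(het_min_support),
            het_min_frac = het_min_frac, slip_max_frac = slip_max_frac,
            singleton_contaminant_min_clones =
              as.integer(singleton_contaminant_min_clones),
            max_del = as.integer(max_del), max_ins = as.integer(max_ins))
  if (any(unlist(p) <= 0))
    stop_notchopa("all thresholds must be positive", "notchopa_domain_error")
  structure(p, class = "genotype_params")
}

.clone_key <- function(third, pq) {
  ifelse(!is.na(third) & nzchar(third), third, pq)
}

.key_to_record <- function(key, name = NA_character_) {
  if (grepl("^Q", key)) {
    config <- .parse_pq_string(key)
    codons <- NULL
  } else {
    codons <- as_codons(key)
    config <- classify_codons(codons)
  }
  list(name = name, config = config, codons = codons)
}

#' Tally clones by allele
#'
#' Clones are keyed by codon string (third-position form) so that alleles
#' identical at the pQ level but different at the nucleotide level are
#' tallied separately; clones without sequence fall back to the pQ string.
#'
#' @param clones data.frame with columns `third_position_string` (may be
#'   `NA`) and/or `pq_string`, one row per clone.
#' @return data.frame of class `opa_tally`: `key`, `pq_string`, `count`,
#'   ordered by descending count then key.
#' @export
tally_clones <- function(clones) {
  if (is.null(clones) || nrow(clones) == 0L)
    stop_notchopa("no clones to tally", "notchopa_empty_input")
  third <- clones$third_position_string %||% rep(NA_character_, nrow(clones))
  pq <- clones$pq_string %||% vapply(third, function(t)
    pq_string(classify_codons(t)), "")
  key <- .clone_key(third, pq)
  agg <- as.data.frame(table(key = key), stringsAsFactors = FALSE)
  names(agg)[2] <- "count"
  agg$pq_string <- vapply(agg$key, function(k)
    pq_string(.key_to_record(k)$config), "")
  agg <- agg[order(-agg$count, agg$key), c("key", "pq_string", "count")]
  rownames(agg) <- NULL
  class(agg) <- c("opa_tally", "data.frame")
  agg
}

.as_tally <- function(x) {
  if (inherits(x, "opa_tally")) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    # named counts keyed by third-position or pQ string
    df <- data.frame(key = names(x), count = as.integer(x),
                     stringsAsFactors = FALSE)
    df$pq_string <- vapply(df$key, function(k)
      pq_string(.key_to_record(k)$config), "")
    df <- df[order(-df$count, df$key), c("key", "pq_string", "count")]
    rownames(df) <- NULL
    class(df) <- c("opa_tally", "data.frame")
    return(df)
  }
  tally_clones(x)
}

.foreign_records <- function(foreign_alleles, registry) {
  if (is.null(foreign_alleles)) return(list())
  if (is.character(foreign_alleles))
    lapply(foreign_alleles, function(nm) registry_get(registry, nm))
  else foreign_alleles
}

.matches_foreign <- function(rec, foreign) {
  for (f in foreign) {
    if (!pq_equal(rec$config, f$config)) next
    if (is.null(rec$codons) || is.null(f$codons) ||
        identical(rec$codons, f$codons))
      return(TRUE)
  }
  FALSE
}

#' Call the genotype of one individual from its clone tally
#'
#' The procedure: (1) alleles meeting the heterozygosity support thresholds
#' are provisional candidates; (2) a candidate is demoted when it is a
#' slippage derivative of a better-supported candidate and sits below the
#' stutter ceiling, or when it matches a known foreign allele while a
#' non-foreign candidate exists; (3) every remaining minor allele is
#' classified as `SLIPPAGE_CONTRACTION`/`SLIPPAGE_EXPANSION` if it is a
#' slippage derivative of a surviving candidate, else
#' `CONTAMINANT_INTERCULTURE` if it matches a foreign allele, else
#' `CONTAMINANT_INTRACULTURE` if it is a singleton among at least
#' `singleton_contaminant_min_clones` clones, else `AMBIGUOUS`; (4) zygosity
#' is heterozygous with exactly two surviving candidates, single-allele
#' (hemizygous/homozygous) with one, ambiguous otherwise.
#'
#' @param tally an `opa_tally` (or clone data.frame, or named count vector).
#' @param params a [genotype_params()].
#' @param foreign_alleles optional character vector of registry names (or
#'   list of [allele_record()]s) known to belong to other cultures.
#' @param registry registry used to name called alleles (a fresh
#'   [default_registry()] if not supplied; unknown alleles are minted into
#'   it).
#' @param individual_id identifier carried into the call.
#' @return an object of class `opa_genotype`: list with `individual_id`,
#'   `zygosity` (`"single"`, `"heterozygous"`, `"ambiguous"`), `alleles`
#'   (data.frame name/key/count of called alleles), `clones` (per-allele
#'   classification table), `n_clones`, and `diagnostic`.
#' @export
call_individual <- function(tally, params = genotype_params(),
                            foreign_alleles = NULL, registry = NULL,
                            individual_id = NA_character_) {
  tally <- .as_tally(tally)
  if (is.null(registry)) registry <- default_registry()
  foreign <- .foreign_records(foreign_alleles, registry)
  total <- sum(tally$count)
  if (total < params$min_clones)
    warning(sprintf("individual %s: only %d clones (min_clones = %d)",
                    individual_id, total, params$min_clones), call. = FALSE)
  recs <- lapply(tally$key, .key_to_record)
  n <- nrow(tally)
  is_cand <- tally$count >= params$het_min_support &
    tally$count / total >= params$het_min_frac
  class <- rep(NA_character_, n)
  parent <- rep(NA_character_, n)
  side <- rep(NA_character_, n)
  slip_class <- function(i, j) {
    d <- is_slippage_derivative(recs[[i]], recs[[j]],
                                params$max_del, params$max_ins)
    if (!d$is_derivative) return(NULL)
    list(class = if (total_residues(recs[[i]]$config) <
                     total_residues(recs[[j]]$config))
      "SLIPPAGE_CONTRACTION" else "SLIPPAGE_EXPANSION",
      side = d$side)
  }
  # (2) iteratively demote support-qualified artifacts, weakest first: an
  # allele is explainable as stutter when a better-supported candidate can
  # produce it by slippage and it sits below the stutter ceiling, or as an
  # interculture contaminant when it is foreign-listed and a non-foreign
  # candidate remains
  is_foreign <- vapply(recs, .matches_foreign, TRUE, foreign = foreign)
  repeat {
    expl <- vapply(seq_len(n), function(i) {
      if (!is_cand[i]) return(FALSE)
      slip <- tally$count[i] / total <= params$slip_max_frac &&
        any(vapply(which(is_cand), function(j)
          tally$count[j] > tally$count[i] && !is.null(slip_class(i, j)),
          TRUE))
      slip || (is_foreign[i] && any(is_cand & !is_foreign))
    }, TRUE)
    if (!any(expl)) break
    weakest <- which(expl)[which.min(tally$count[expl])]
    is_cand[weakest] <- FALSE
  }
  # (3) classify minor alleles against the surviving candidates; parents are
  # scanned in tally order (descending count, then key), so ties break
  # toward the higher-count parent, then alphabetically
  for (i in which(!is_cand)) {
    done <- FALSE
    for (j in which(is_cand)) {
      s <- slip_class(i, j)
      if (!is.null(s)) {
        class[i] <- s$class; parent[i] <- tally$key[j]; side[i] <- s$side
        done <- TRUE
        break
      }
    }
    if (done) next
    if (is_foreign[i]) {
      class[i] <- "CONTAMINANT_INTERCULTURE"
    } else if (tally$count[i] == 1L &&
               total >= params$singleton_contaminant_min_clones) {
      class[i] <- "CONTAMINANT_INTRACULTURE"
    } else {
      class[i] <- "AMBIGUOUS"
    }
  }
  class[is_cand] <- "ORIGINAL"
  # display names: candidates through the registry, artifacts by their
  # slippage name opa{N}{L|R}
  name <- vapply(seq_len(n), function(i) {
    if (!is.na(side[i]))
      sprintf("opa%d%s", total_residues(recs[[i]]$config), side[i])
    else
      resolve_name(recs[[i]]$config, recs[[i]]$codons, registry)
  }, "")
  clones <- data.frame(key = tally$key, name = name,
                       pq_string = tally$pq_string, count = tally$count,
                       class = class, parent = parent, side = side,
                       stringsAsFactors = FALSE)
  n_cand <- sum(is_cand)
  zygosity <- if (n_cand == 1L) "single"
  else if (n_cand == 2L) "heterozygous"
  else "ambiguous"
  diagnostic <- if (n_cand == 0L)
    "no allele meets the heterozygosity support thresholds"
  else if (n_cand > 2L)
    sprintf("%d alleles meet the support thresholds", n_cand)
  else NA_character_
  structure(list(individual_id = individual_id, zygosity = zygosity,
                 alleles = clones[is_cand, c("name", "key", "count")],
                 clones = clones, n_clones = total, diagnostic = diagnostic),
            class = "opa_genotype")
}

#' @export
print.opa_genotype <- function(x, ...) {
  al <- paste(sprintf("%s (%d)", x$alleles$name, x$alleles$count),
              collapse = " / ")
  cat(sprintf("individual %s: %s%s  [%d clones]\n", x$individual_id,
              x$zygosity, if (nzchar(al)) paste0(" ", al) else "", x$n_clones))
  minor <- x$clones[x$clones$class != "ORIGINAL", , drop = FALSE]
  for (i in seq_len(nrow(minor)))
    cat(sprintf("  minor %s x%d: %s\n", minor$name[i], minor$count[i],
                minor$class[i]))
  if (!is.na(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' Call a line genotype from its individual calls
#'
#' The line allele set is the union of called alleles across individuals; the
#' line is flagged heterozygous (segregating) when two or more alleles are
#' seen.  Conflicting single-allele calls are flagged, not fatal.
#'
#' @param calls list of [call_individual()] results.
#' @param line_id identifier.
#' @return an object of class `opa_line_genotype`: `line_id`, `haplotypes`
#'   (character), `het` flag, `n_individuals`, `support` (clones per allele),
#'   `conflict` flag.
#' @export
call_line <- function(calls, line_id = NA_character_) {
  stopifnot(length(calls) >= 1L)
  al <- do.call(rbind, lapply(calls, `[[`, "alleles"))
  support <- tapply(al$count, al$name, sum)
  haplotypes <- names(sort(support, decreasing = TRUE))
  singles <- unlist(lapply(calls, function(c)
    if (c$zygosity == "single") c$alleles$name else NULL))
  conflict <- length(unique(singles)) > 1L
  structure(list(line_id = line_id, haplotypes = haplotypes,
                 het = length(haplotypes) >= 2L,
                 n_individuals = length(calls),
                 support = as.vector(support[haplotypes]),
                 conflict = conflict),
            class = "opa_line_genotype")
}

#' @export
print.opa_line_genotype <- function(x, ...) {
  cat(sprintf("line %s: %s%s  [%d individuals]\n", x$line_id,
              paste(x$haplotypes, collapse = "/"),
              if (x$het) " (segregating)" else "", x$n_individuals))
  if (x$conflict)
    cat("  note: conflicting single-allele calls across individuals\n")
  invisible(x)
}

#' Estimate clone-level error rates from classified clones
#'
#' Each rate is a class count over the total clone count; the
#' original-genotype fraction is additionally reported after removing
#' interculture contaminants from the denominator (the convention used when
#' summarizing a contaminated culture).
#'
#' @param clones data.frame with a `class` column (one row per clone, or with
#'   a `count` column of per-allele tallies), e.g. the `clones` element of an
#'   [call_individual()] result or rows bound across individuals.
#' @return an object of class `opa_error_rates`: each rate keeps its
#'   numerator and denominator; `print()` shows one-decimal percents rounded
#'   half away from zero.
#' @export
estimate_error_rates <- function(clones) {
  if (is.null(clones$class))
    stop_notchopa("clones must carry a 'class' column", "notchopa_domain_error")
  count <- clones$count %||% rep(1L, nrow(clones))
  total <- sum(count)
  if (total == 0L)
    stop_notchopa("zero clones: rates undefined", "notchopa_undefined_rate")
  n_of <- function(cls) sum(count[clones$class %in% cls])
  n_inter <- n_of("CONTAMINANT_INTERCULTURE")
  rate <- function(num, den) list(numerator = num, denominator = den,
                                  rate = if (den > 0) num / den else NA_real_)
  structure(list(
    contraction = rate(n_of("SLIPPAGE_CONTRACTION"), total),
    expansion = rate(n_of("SLIPPAGE_EXPANSION"), total),
    intraculture = rate(n_of("CONTAMINANT_INTRACULTURE"), total),
    interculture = rate(n_inter, total),
    original = rate(n_of("ORIGINAL"), total),
    original_excl_interculture = rate(n_of("ORIGINAL"), total - n_inter),
    ambiguous = rate(n_of("AMBIGUOUS"), total),
    n_clones = total
  ), class = "opa_error_rates")
}

#' @export
print.opa_error_rates <- function(x, ...) {
  cat(sprintf("clone error rates (%d clones):\n", x$n_clones))
  show <- function(label, r) {
    if (is.na(r$rate)) return(invisible(NULL))
    cat(sprintf("  %-28s %5.1f%%  (%d/%d)\n", label, percent1(r$rate),
                r$numerator, r$denominator))
  }
  show("original genotype", x$original)
  show("original (excl. intercult.)", x$original_excl_interculture)
  show("slippage contraction", x$contraction)
  show("slippage expansion", x$expansion)
  show("intraculture contamination", x$intraculture)
  show("interculture contamination", x$interculture)
  show("ambiguous", x$ambiguous)
  invisible(x)
}

#' Call genotypes for a whole clone-library study
#'
#' Joins an extraction table to a sample sheet, calls every individual, then
#' every line, and estimates study-wide error rates from the pooled clone
#' classifications.
#'
#' @param extraction data.frame from [extract_repeats()] (columns
#'   `sequence_id`, `pq_string`, `third_position_string`; rows with a
#'   non-`NA` `error` are dropped with a message).
#' @param samples sample sheet data.frame: `clone_id`, `line_id`,
#'   `individual_id`, `sex`.
#' @param params a [genotype_params()].
#' @param foreign_alleles see [call_individual()].
#' @param registry naming registry (fresh [default_registry()] by default).
#' @return an object of class `opa_genotypes`: `individuals` (named list of
#'   `opa_genotype`), `lines` (named list of `opa_line_genotype`),
#'   `clone_classes` (pooled per-allele classification table with
#'   `individual_id`/`line_id`), and `error_rates`.
#' @export
call_genotypes <- function(extraction, samples, params = genotype_params(),
                           foreign_alleles = NULL, registry = NULL) {
  if (is.null(registry)) registry <- default_registry()
  if (!is.null(extraction$error)) {
    bad <- !is.na(extraction$error)
    if (any(bad)) {
      message(sum(bad), " clone(s) failed extraction and were dropped")
      extraction <- extraction[!bad, , drop = FALSE]
    }
  }
  df <- merge(extraction, samples, by.x = "sequence_id", by.y = "clone_id")
  calls <- list()
  classes <- list()
  for (ind in unique(df$individual_id)) {
    sub <- df[df$individual_id == ind, , drop = FALSE]
    call <- call_individual(tally_clones(sub), params,
                            foreign_alleles = foreign_alleles,
                            registry = registry, individual_id = ind)
    calls[[as.character(ind)]] <- call
    cl <- call$clones
    cl$individual_id <- ind
    cl$line_id <- sub$line_id[1]
    classes[[length(classes) + 1L]] <- cl
  }
  clone_classes <- do.call(rbind, classes)
  lines <- list()
  for (ln in unique(df$line_id)) {
    ids <- unique(df$individual_id[df$line_id == ln])
    lines[[as.character(ln)]] <- call_line(calls[as.character(ids)],
                                           line_id = ln)
  }
  structure(list(individuals = calls, lines = lines,
                 clone_classes = clone_classes,
                 error_rates = estimate_error_rates(clone_classes)),
            class = "opa_genotypes")
}

#' @export
print.opa_genotypes <- function(x, ...) {
  cat(sprintf("opa genotype calls: %d individuals in %d lines\n",
              length(x$individuals), length(x$lines)))
  for (l in x$lines) print(l)
  invisible(x)
}

#' @export
summary.opa_genotypes <- function(object, ...) {
  zyg <- table(vapply(object$individuals, `[[`, "", "zygosity"))
  cat("zygosity:", paste(names(zyg), zyg, sep = "=", collapse = ", "), "\n")
  print(object$error_rates)
  invisible(object)
}

#' Write genotype-call tables as TSV
#'
#' @param genotypes an [call_genotypes()] result.
#' @param dir output directory; writes `genotypes.tsv` (per individual),
#'   `lines.tsv`, and `clone_classes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_genotype_tsv <- function(genotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ind <- do.call(rbind, lapply(genotypes$individuals, function(c)
    data.frame(individual_id = c$individual_id, zygosity = c$zygosity,
               alleles = paste(c$alleles$name, collapse = "/"),
               support = paste(c$alleles$count, collapse = "/"),
               n_clones = c$n_clones, stringsAsFactors = FALSE)))
  lns <- do.call(rbind, lapply(genotypes$lines, function(l)
    data.frame(line_id = l$line_id,
               haplotypes = paste(l$haplotypes, collapse = "/"),
               het = l$het, n_individuals = l$n_individuals,
               stringsAsFactors = FALSE)))
  utils::write.table(ind, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(lns, file.path(dir, "lines.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(genotypes$clone_classes,
                     file.path(dir, "clone_classes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
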
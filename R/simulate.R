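# Seeded synthetic Sanger clone libraries and phenotype tables.
#
# The generator emulates the structure of the genotyping study: inbred lines
# on the X (males hemizygous), 5-13 clones sequenced per individual, with
# per-clone PCR slippage (contraction ~5%, expansion ~0.6%) and
# contamination from bottle mates (intraculture, ~5.7%) or from foreign
# cultures handled alongside (interculture, ~3.6%).  Ground truth is
# recorded for every clone so the calling pipeline can be validated end to
# end.

#' Simulation configuration
#'
#' @param lines named list: line id -> list with `alleles` (1-2 registry
#'   names) and optional `freqs` (allele frequencies, default equal).  The
#'   default is four homozygous lines carrying opa31, opa32, opa33a and
#'   opa23.
#' @param individuals_per_line individuals sampled per line.
#' @param fraction_female probability an individual is female (default the
#'   observed 53.7%).
#' @param clones_range inclusive range clones-per-individual are drawn
#'   uniformly from; give a single value for a fixed count.
#' @param rates per-clone probabilities: `contraction`, `expansion`,
#'   `intraculture`, `interculture`.
#' @param foreign_pool registry names of foreign-culture alleles feeding
#'   interculture contamination.
#' @param anchors an [anchor_config()] providing the flanks of the emitted
#'   sequences.
#' @param registry an [allele_registry()].
#' @param seed integer seed governing all draws (stream order: lines ->
#'   individuals -> clones).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(lines = NULL, individuals_per_line = 10L,
                       fraction_female = 0.537, clones_range = c(5L, 13L),
                       rates = list(contraction = 0.05, expansion = 0.006,
                                    intraculture = 0.057, interculture = 0.036),
                       foreign_pool = c("opa35a1", "opa34"),
                       anchors = default_anchors(), registry = default_registry(),
                       seed = 1L) {
  if (is.null(lines))
    lines <- list(simA = list(alleles = "opa31"),
                  simB = list(alleles = "opa32"),
                  simC = list(alleles = "opa33a"),
                  simD = list(alleles = "opa23"))
  for (l in lines) stopifnot(length(l$alleles) %in% 1:2)
  r <- unlist(rates)
  if (any(r < 0 | r > 1))
    stop_notchopa("rates must be probabilities", "notchopa_domain_error")
  if (length(clones_range) == 1L) clones_range <- rep(clones_range, 2L)
  if (clones_range[1] < 1L)
    stop_notchopa("clone counts must be >= 1", "notchopa_domain_error")
  for (nm in unlist(lapply(lines, `[[`, "alleles")))
    registry_get(registry, nm)  # errors on unresolvable names
  structure(list(lines = lines,
                 individuals_per_line = as.integer(individuals_per_line),
                 fraction_female = fraction_female,
                 clones_range = as.integer(clones_range),
                 rates = as.list(r), foreign_pool = foreign_pool,
                 anchors = anchors, registry = registry,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build the nucleotide sequence of a clone
#'
#' @param allele an [allele_record()] with a codon string.
#' @param anchors an [anchor_config()] (its anchors are the flanks).
#' @return nucleotide string: left flank + codons + right flank.
#' @export
build_sequence <- function(allele, anchors = default_anchors()) {
  if (is.null(allele$codons))
    stop_notchopa(sprintf("allele '%s' has no codon string", allele$name),
                  "notchopa_domain_error")
  paste0(anchors$left_anchor, paste(allele$codons, collapse = ""),
         anchors$right_anchor)
}

#' Apply per-clone PCR slippage to an allele
#'
#' With probability `rates$contraction` one codon is deleted from the
#' longest run of identical glutamine codons (ties broken at random); with
#' probability `rates$expansion` one codon is inserted there instead;
#' otherwise the clone is unchanged.  Derived alleles are named
#' `opa{N}{L|R}` by the side of the histidine the run lies on.
#'
#' @param allele an [allele_record()] with a codon string.
#' @param rates list with `contraction` and `expansion` probabilities.
#' @param ancestral_his_index see [allele_registry()].
#' @return list with `allele` (possibly derived record) and `class`
#'   (`"ORIGINAL"`, `"SLIPPAGE_CONTRACTION"` or `"SLIPPAGE_EXPANSION"`).
#' @export
mutate_clone <- function(allele, rates, ancestral_his_index = 14L) {
  u <- stats::runif(1)
  p_con <- rates$contraction %||% 0
  p_exp <- rates$expansion %||% 0
  event <- if (u < p_con) "SLIPPAGE_CONTRACTION"
  else if (u < p_con + p_exp) "SLIPPAGE_EXPANSION"
  else "ORIGINAL"
  if (event == "ORIGINAL")
    return(list(allele = allele, class = "ORIGINAL"))
  runs <- codon_runs(allele$codons)
  runs <- runs[runs$length >= 2L, , drop = FALSE]
  if (nrow(runs) == 0L)
    return(list(allele = allele, class = "ORIGINAL"))
  longest <- which(runs$length == max(runs$length))
  i <- if (length(longest) > 1L) sample(longest, 1L) else longest
  his <- .his_index(allele$codons)
  side <- .run_side(runs$start[i], his, ancestral_his_index)
  codons <- if (event == "SLIPPAGE_CONTRACTION")
    allele$codons[-runs$start[i]]
  else
    append(allele$codons, runs$codon[i], after = runs$start[i])
  config <- classify_codons(codons)
  rec <- allele_record(sprintf("opa%d%s", total_residues(config), side),
                       config, codons,
                       derived_from = list(parent = allele$name, side = side,
                                           steps = if (event == "SLIPPAGE_CONTRACTION") -1L else 1L))
  list(allele = rec, class = event)
}

#' Simulate the clone library of one individual
#'
#' Each clone is drawn from the individual's allele(s) (heterozygotes
#' 50/50), passed through [mutate_clone()], then replaced by a random
#' contaminant-pool allele with the contamination probabilities.
#'
#' @param genotype list of 1-2 [allele_record()]s.
#' @param n_clones clones to emit.
#' @param rates see [sim_config()].
#' @param intraculture_pool,interculture_pool lists of [allele_record()]s
#'   contaminant clones are drawn from; a pool may be empty only if its rate
#'   is zero.
#' @param ancestral_his_index see [allele_registry()].
#' @return data.frame with one row per clone: `allele`, `pq_string`,
#'   `third_position_string`, `true_class`, `true_source`.
#' @export
simulate_individual <- function(genotype, n_clones, rates,
                                intraculture_pool = list(),
                                interculture_pool = list(),
                                ancestral_his_index = 14L) {
  stopifnot(length(genotype) %in% 1:2)
  p_intra <- rates$intraculture %||% 0
  p_inter <- rates$interculture %||% 0
  if (p_intra > 0 && length(intraculture_pool) == 0L)
    stop_notchopa("intraculture rate > 0 but pool is empty", "notchopa_config_error")
  if (p_inter > 0 && length(interculture_pool) == 0L)
    stop_notchopa("interculture rate > 0 but pool is empty", "notchopa_config_error")
  rows <- lapply(seq_len(n_clones), function(i) {
    src <- genotype[[sample.int(length(genotype), 1L)]]
    m <- mutate_clone(src, rates, ancestral_his_index)
    allele <- m$allele; class <- m$class; source <- src$name
    u <- stats::runif(1)
    if (u < p_intra) {
      allele <- intraculture_pool[[sample.int(length(intraculture_pool), 1L)]]
      class <- "CONTAMINANT_INTRACULTURE"; source <- allele$name
    } else if (u < p_intra + p_inter) {
      allele <- interculture_pool[[sample.int(length(interculture_pool), 1L)]]
      class <- "CONTAMINANT_INTERCULTURE"; source <- allele$name
    }
    data.frame(allele = allele$name, pq_string = pq_string(allele$config),
               third_position_string = third_positions(allele$codons),
               true_class = class, true_source = source,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a whole clone-library study
#'
#' Emits clone sequences, a sample sheet and ground truth for every line and
#' individual in the configuration.  Sexes are assigned by
#' `fraction_female`; X-linkage is respected (males carry one allele,
#' females two draws from the line's allele frequencies).  Intraculture
#' contaminants are drawn from the line's own allele set (bottle mates);
#' interculture contaminants from the foreign pool.  Identical seeds produce
#' identical output.
#'
#' @param config a [sim_config()].
#' @return an object of class `opa_sim_study`: `sequences` (named character
#'   vector clone_id -> nucleotide sequence), `samples` (sample-sheet
#'   data.frame `clone_id`/`line_id`/`individual_id`/`sex`), `truth_clones`
#'   (`clone_id`, `allele`, `true_class`, `true_source`),
#'   `truth_individuals` (`individual_id`, `line_id`, `sex`, `allele1`,
#'   `allele2`), and `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  reg <- config$registry
  ahi <- reg$ancestral_his_index
  inter_pool <- lapply(config$foreign_pool, function(nm) registry_get(reg, nm))
  sequences <- character(0)
  samples <- list(); truth_clones <- list(); truth_ind <- list()
  for (line_id in names(config$lines)) {
    spec <- config$lines[[line_id]]
    alleles <- lapply(spec$alleles, function(nm) registry_get(reg, nm))
    freqs <- spec$freqs %||% rep(1 / length(alleles), length(alleles))
    intra_pool <- alleles
    for (k in seq_len(config$individuals_per_line)) {
      ind_id <- sprintf("%s_i%02d", line_id, k)
      sex <- if (stats::runif(1) < config$fraction_female) "F" else "M"
      geno_idx <- if (sex == "M") sample.int(length(alleles), 1L, prob = freqs)
      else sample.int(length(alleles), 2L, replace = TRUE, prob = freqs)
      geno <- unique(alleles[geno_idx])
      n_clones <- if (config$clones_range[1] == config$clones_range[2])
        config$clones_range[1]
      else sample(seq.int(config$clones_range[1], config$clones_range[2]), 1L)
      clones <- simulate_individual(geno, n_clones, config$rates,
                                    intraculture_pool = intra_pool,
                                    interculture_pool = inter_pool,
                                    ancestral_his_index = ahi)
      ids <- sprintf("%s_c%02d", ind_id, seq_len(nrow(clones)))
      recs <- Map(function(third, nm) {
        codons <- as_codons(third)
        allele_record(nm, classify_codons(codons), codons)
      }, clones$third_position_string, clones$allele)
      seqs <- vapply(recs, build_sequence, "", anchors = config$anchors)
      sequences <- c(sequences, stats::setNames(seqs, ids))
      samples[[length(samples) + 1L]] <-
        data.frame(clone_id = ids, line_id = line_id, individual_id = ind_id,
                   sex = sex, stringsAsFactors = FALSE)
      truth_clones[[length(truth_clones) + 1L]] <-
        data.frame(clone_id = ids, allele = clones$allele,
                   true_class = clones$true_class,
                   true_source = clones$true_source, stringsAsFactors = FALSE)
      truth_ind[[length(truth_ind) + 1L]] <-
        data.frame(individual_id = ind_id, line_id = line_id, sex = sex,
                   allele1 = geno[[1]]$name,
                   allele2 = if (length(geno) == 2L) geno[[2]]$name
                   else NA_character_, stringsAsFactors = FALSE)
    }
  }
  empty <- function(...) data.frame(..., stringsAsFactors = FALSE)[0, , drop = FALSE]
  structure(list(
    sequences = sequences,
    samples = if (length(samples)) do.call(rbind, samples)
    else empty(clone_id = "", line_id = "", individual_id = "", sex = ""),
    truth_clones = if (length(truth_clones)) do.call(rbind, truth_clones)
    else empty(clone_id = "", allele = "", true_class = "", true_source = ""),
    truth_individuals = if (length(truth_ind)) do.call(rbind, truth_ind)
    else empty(individual_id = "", line_id = "", sex = "", allele1 = "",
               allele2 = ""),
    config = config
  ), class = "opa_sim_study")
}

#' @export
print.opa_sim_study <- function(x, ...) {
  cat(sprintf("simulated clone study: %d clones, %d individuals, %d lines\n",
              length(x$sequences), nrow(x$truth_individuals),
              length(x$config$lines)))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' @param study an [simulate_study()] result.
#' @param dir output directory; writes `clones.fasta`, `samples.tsv`,
#'   `truth_clones.tsv`, `truth_individuals.tsv` and `config.yml` (a
#'   key-value echo of the generating configuration).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(study$sequences)
  Biostrings::writeXStringSet(seqs, file.path(dir, "clones.fasta"))
  utils::write.table(study$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth_clones, file.path(dir, "truth_clones.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth_individuals,
                     file.path(dir, "truth_individuals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- study$config
  lines <- c(
    sprintf("seed: %d", cfg$seed),
    sprintf("individuals_per_line: %d", cfg$individuals_per_line),
    sprintf("fraction_female: %g", cfg$fraction_female),
    sprintf("clones_range: [%d, %d]", cfg$clones_range[1], cfg$clones_range[2]),
    vapply(names(cfg$rates), function(r)
      sprintf("rate_%s: %g", r, cfg$rates[[r]]), ""),
    sprintf("foreign_pool: [%s]", paste(cfg$foreign_pool, collapse = ", ")),
    vapply(names(cfg$lines), function(l)
      sprintf("line_%s: [%s]", l, paste(cfg$lines[[l]]$alleles, collapse = ", ")),
      "")
  )
  writeLines(lines, file.path(dir, "config.yml"))
  invisible(dir)
}

#' Simulate bristle observations
#'
#' Per hemi-notum categorical draws: each position is ectopic with its
#' per-position/sex probability, missing with its probability, normal
#' otherwise.
#'
#' @param defect_probs data.frame with columns `position`, `sex`,
#'   `p_ectopic`, `p_missing` (positions/sexes absent from the table get
#'   probability 0).
#' @param n_flies flies per sex.
#' @param genotype genotype label carried into the table.
#' @param sexes sexes to simulate.
#' @return observation data.frame: `fly_id`, `sex`, `genotype`, `side`,
#'   `position`, `category`.
#' @export
simulate_bristles <- function(defect_probs, n_flies, genotype = "sim",
                              sexes = c("F", "M")) {
  if (any(defect_probs$p_ectopic < 0 | defect_probs$p_ectopic > 1) ||
      any(defect_probs$p_missing < 0 | defect_probs$p_missing > 1))
    stop_notchopa("probabilities must be in [0,1]", "notchopa_domain_error")
  grid <- expand.grid(position = bristle_positions(), side = c("L", "R"),
                      fly = seq_len(n_flies), sex = sexes,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  idx <- match(paste(grid$position, grid$sex),
               paste(defect_probs$position, defect_probs$sex))
  p_e <- ifelse(is.na(idx), 0, defect_probs$p_ectopic[idx])
  p_m <- ifelse(is.na(idx), 0, defect_probs$p_missing[idx])
  u <- stats::runif(nrow(grid))
  data.frame(
    fly_id = sprintf("%s_%s%04d", genotype, grid$sex, grid$fly),
    sex = grid$sex, genotype = genotype, side = grid$side,
    position = grid$position,
    category = ifelse(u < p_e, "ECTOPIC_NEAR",
                      ifelse(u < p_e + p_m, "MISSING", "NORMAL")),
    stringsAsFactors = FALSE)
}

#' Simulate an embryonic hatch assay
#'
#' @param p_fail probability an embryo fails to hatch.
#' @param n_embryos embryos laid.
#' @return list with `unhatched` and `total`.
#' @export
simulate_embryo_assay <- function(p_fail, n_embryos) {
  if (p_fail < 0 || p_fail > 1)
    stop_notchopa("p_fail must be in [0,1]", "notchopa_domain_error")
  list(unhatched = stats::rbinom(1, n_embryos, p_fail), total = n_embryos)
}
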
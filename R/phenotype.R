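# Macrochaete scoring and viability/fecundity summaries.
#
# The adult hemi-notum carries 13 stereotyped macrochaete positions.  Each
# position on each hemi-notum receives a numeric score: 1.0 normal, 0.0
# missing, 2.0 ectopic or split, fractional for slender bristles, 1.5 to
# each member of a DC/SC pair sharing a mid-positioned bristle, -1.0 for an
# empty socket plus a nearby ectopic, -2.0 for two empty sockets replacing
# one bristle.  Within a genotype x sex x position group only the more
# frequent defect class (ectopic or missing) is scored; the rarer class is
# masked to 1.0 so opposite defects cannot cancel in the mean.

#' The 13 macrochaete positions of the hemi-notum
#'
#' Upper/lower humeral, presutural, anterior/posterior notopleural,
#' supra-alar, postalar, dorsocentral and scutellar positions.
#'
#' @return character vector of position labels.
#' @export
bristle_positions <- function() {
  c("uHU", "lHU", "PS", "aNP", "pNP", "aSA", "pSA", "aPA", "pPA",
    "aDC", "pDC", "aSC", "pSC")
}

.paired_positions <- c("aDC", "pDC", "aSC", "pSC")

.bristle_categories <- c("NORMAL", "MISSING", "ECTOPIC_NEAR", "SPLIT",
                         "SLENDER", "SHARED_MID", "SOCKET_PLUS_ECTOPIC",
                         "DOUBLE_EMPTY_SOCKET")

#' Score one bristle observation
#'
#' @param category one of `NORMAL`, `MISSING`, `ECTOPIC_NEAR`, `SPLIT`,
#'   `SLENDER`, `SHARED_MID`, `SOCKET_PLUS_ECTOPIC`, `DOUBLE_EMPTY_SOCKET`.
#' @param position position label; required to validate `SHARED_MID`, which
#'   only occurs at the paired dorsocentral/scutellar positions.
#' @param fraction score for `SLENDER` bristles, in (0, 1); defaults to 0.5
#'   when not recorded.
#' @return numeric score.
#' @export
score_observation <- function(category, position = NA_character_,
                              fraction = NA_real_) {
  category <- match.arg(category, .bristle_categories)
  if (category == "SHARED_MID" && !(position %in% .paired_positions))
    stop_notchopa(sprintf(
      "SHARED_MID is only valid at the paired DC/SC positions, not '%s'",
      position), "notchopa_domain_error")
  if (category == "SLENDER") {
    if (is.na(fraction)) fraction <- 0.5
    if (fraction <= 0 || fraction >= 1)
      stop_notchopa("SLENDER fraction must be in (0, 1)", "notchopa_domain_error")
    return(fraction)
  }
  switch(category,
         NORMAL = 1.0, MISSING = 0.0, ECTOPIC_NEAR = 2.0, SPLIT = 2.0,
         SHARED_MID = 1.5, SOCKET_PLUS_ECTOPIC = -1.0,
         DOUBLE_EMPTY_SOCKET = -2.0)
}

#' Score a table of bristle observations
#'
#' @param obs data.frame with columns `position`, `category`, and optionally
#'   `fraction` plus any identifier columns (`fly_id`, `sex`, `genotype`,
#'   `side`).
#' @return `obs` with a `score` column appended.
#' @export
score_observations <- function(obs) {
  frac <- obs$fraction %||% rep(NA_real_, nrow(obs))
  obs$score <- vapply(seq_len(nrow(obs)), function(i)
    score_observation(obs$category[i], obs$position[i], frac[i]), 0)
  obs
}

#' Mask the rarer defect class within each scoring group
#'
#' Within each genotype x sex x position group, if both ectopic-type scores
#' (> 1) and missing-type scores (< 1) occur, every score of the less
#' frequent class is replaced by 1.0.  Ties keep the ectopic class (the
#' missing-type scores are masked).
#'
#' @param scores data.frame with columns `score` and the grouping columns.
#' @param group_by grouping columns (default genotype, sex, position;
#'   columns absent from `scores` are ignored).
#' @return `scores` with `score` masked and a logical `masked` column.
#' @export
mask_rarer_defect <- function(scores,
                              group_by = c("genotype", "sex", "position")) {
  group_by <- intersect(group_by, names(scores))
  key <- if (length(group_by) == 0L) rep("all", nrow(scores))
  else do.call(paste, c(scores[group_by], sep = "\r"))
  scores$masked <- FALSE
  for (k in unique(key)) {
    idx <- which(key == k)
    ect <- scores$score[idx] > 1
    mis <- scores$score[idx] < 1
    if (any(ect) && any(mis)) {
      drop <- if (sum(ect) >= sum(mis)) mis else ect
      scores$score[idx[drop]] <- 1.0
      scores$masked[idx[drop]] <- TRUE
    }
  }
  scores
}

#' Cohort mean-score frequencies per position
#'
#' Mean (masked) score per genotype x sex x position, with hemi-nota counts
#' and defect tallies retained.  Empty cells are omitted, not zero-filled.
#'
#' @param scores data.frame with `score` and grouping columns `genotype`,
#'   `sex`, `position` (whichever are present are used).
#' @return data.frame with columns the grouping columns, `mean_score`, `n`,
#'   `n_ectopic`, `n_missing`.
#' @export
cohort_frequencies <- function(scores) {
  group_by <- intersect(c("genotype", "sex", "position"), names(scores))
  stopifnot(length(group_by) > 0L, nrow(scores) > 0L)
  split_idx <- split(seq_len(nrow(scores)),
                     scores[group_by], drop = TRUE, sep = "\r")
  rows <- lapply(split_idx, function(idx) {
    out <- scores[idx[1], group_by, drop = FALSE]
    out$mean_score <- mean(scores$score[idx])
    out$n <- length(idx)
    out$n_ectopic <- sum(scores$score[idx] > 1)
    out$n_missing <- sum(scores$score[idx] < 1)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of flies with an ectopic bristle
#'
#' A fly counts as ectopic when any of its scores exceeds 1.0 at the listed
#' positions (the duplication-prone dorsocentral, scutellar and posterior
#' postalar positions by default).
#'
#' @param scores data.frame with `fly_id`, `position`, `score`.
#' @param positions positions considered.
#' @return fraction of flies in \[0, 1\].
#' @export
ectopic_rate <- function(scores,
                         positions = c("aDC", "pDC", "aSC", "pSC", "pPA")) {
  stopifnot(nrow(scores) > 0L)
  hit <- tapply(scores$score > 1 & scores$position %in% positions,
                scores$fly_id, any)
  mean(hit)
}

#' Fraction of embryos failing to hatch
#'
#' @param unhatched,total embryo counts.
#' @return fraction in \[0, 1\].
#' @export
embryonic_failure <- function(unhatched, total) {
  if (total <= 0)
    stop_notchopa("no embryos: failure rate undefined", "notchopa_undefined_rate")
  if (unhatched > total)
    stop_notchopa("unhatched exceeds total", "notchopa_domain_error")
  unhatched / total
}

#' Fecundity summary across lines
#'
#' @param eggs egg counts, one per line; optionally named by line.
#' @return list with `mean` (unrounded), `mean_display` (integer, half away
#'   from zero), `max`, `percent_of_max` (per line, of the maximum count),
#'   and `mean_percent_of_max` (computed from the unrounded mean).
#' @export
fecundity_summary <- function(eggs) {
  if (length(eggs) == 0L)
    stop_notchopa("no egg counts", "notchopa_empty_input")
  mx <- max(eggs)
  if (mx <= 0)
    stop_notchopa("maximum egg count is zero: percent-of-max undefined",
                  "notchopa_undefined_rate")
  m <- mean(eggs)
  list(mean = m, mean_display = round_half_away(m), max = mx,
       percent_of_max = round_half_away(100 * eggs / mx, 1),
       mean_percent_of_max = round_half_away(100 * m / mx, 1))
}
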
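# ---------------------------------------------------------------------------
# Derived features: reference-tissue ratios, the quantified visual score and
# the five-condition multifactorial score.
# ---------------------------------------------------------------------------

RATIO_FEATURES <- c("primary", "liver", "brainstem", "lung")
ALL_FEATURES <- c("suvmax", RATIO_FEATURES)

#' Cut-offs for the multifactorial score conditions
#'
#' Defaults are the cut-offs derived from the reference cohort: SUVmax
#' 5.495 and node-to-reference ratios 0.457 (primary), 1.374 (liver), 0.749
#' (brainstem), 4.593 (contralateral lung). All five conditions are
#' evaluated with an inclusive `>=`.
#'
#' @param suvmax,primary,liver,brainstem,lung Strictly positive cut-offs.
#' @return A named numeric vector of class `score_thresholds`.
#' @export
score_thresholds <- function(suvmax = 5.495, primary = 0.457, liver = 1.374,
                             brainstem = 0.749, lung = 4.593) {
  th <- c(suvmax = suvmax, primary = primary, liver = liver,
          brainstem = brainstem, lung = lung)
  if (any(!is.finite(th)) || any(th <= 0))
    stop("all score thresholds must be strictly positive", call. = FALSE)
  structure(th, class = "score_thresholds")
}

#' Node-to-reference SUV ratios
#'
#' The four quotients of the node's SUVmax to the reference SUVmax of the
#' primary tumour, liver, brainstem and contralateral lung, unrounded.
#'
#' @param node_suvmax Node SUVmax (scalar or vector).
#' @param primary_suvmax,liver_suvmax,brainstem_suvmax,lung_suvmax Reference
#'   SUVmax values (recycled against `node_suvmax`).
#' @return Data frame with columns `primary`, `liver`, `brainstem`, `lung`.
#' @export
compute_ratios <- function(node_suvmax, primary_suvmax, liver_suvmax,
                           brainstem_suvmax, lung_suvmax) {
  refs <- list(primary = primary_suvmax, liver = liver_suvmax,
               brainstem = brainstem_suvmax, lung = lung_suvmax)
  if (any(!is.finite(node_suvmax)) || any(node_suvmax <= 0))
    stop("node_suvmax must be strictly positive and finite", call. = FALSE)
  for (organ in names(refs)) {
    r <- refs[[organ]]
    if (any(!is.finite(r)) || any(r <= 0))
      stop("reference uptake for '", organ,
           "' must be strictly positive and finite", call. = FALSE)
  }
  data.frame(primary = node_suvmax / primary_suvmax,
             liver = node_suvmax / liver_suvmax,
             brainstem = node_suvmax / brainstem_suvmax,
             lung = node_suvmax / lung_suvmax)
}

#' Quantified visual score (1-3)
#'
#' Quantitative translation of the visual reading score: score 1 if the
#' node's maximum uptake is at most the liver's; score 2 if above the liver
#' but at most the primary tumour's; score 3 if above the primary. The
#' conditions are evaluated in this order, so when a patient's primary
#' uptake is below the liver's a node with `liver >= ln > primary` still
#' receives score 1 (first matching rule wins); such inversions are
#' reported via a warning because the ordering is then ambiguous.
#'
#' @param ln_suvmax Node SUVmax (vectorised).
#' @param liver_suvmax,primary_suvmax Reference SUVmax (recycled).
#' @return Integer vector of scores in 1..3.
#' @export
visual_score <- function(ln_suvmax, liver_suvmax, primary_suvmax) {
  n <- max(length(ln_suvmax), length(liver_suvmax), length(primary_suvmax))
  ln <- rep_len(ln_suvmax, n)
  liv <- rep_len(liver_suvmax, n)
  pri <- rep_len(primary_suvmax, n)
  if (any(!is.finite(c(ln, liv, pri))) || any(c(ln, liv, pri) <= 0))
    stop("all uptake values must be strictly positive and finite", call. = FALSE)
  if (any(pri < liv))
    warning("primary uptake below liver uptake for ", sum(pri < liv),
            " node(s); visual score rules applied in listed order",
            call. = FALSE)
  ifelse(ln <= liv, 1L, ifelse(ln <= pri, 2L, 3L))
}

#' Multifactorial malignancy score (0-5)
#'
#' One point per fulfilled condition, all inclusive: (I) SUVmax >= 5.495,
#' (II) node/primary >= 0.457, (III) node/liver >= 1.374, (IV)
#' node/brainstem >= 0.749, (V) node/lung >= 4.593 (defaults; see
#' [score_thresholds()]).
#'
#' @param node_suvmax Node SUVmax (vectorised).
#' @param ratios Data frame from [compute_ratios()] (columns `primary`,
#'   `liver`, `brainstem`, `lung`).
#' @param thresholds A [score_thresholds()] vector.
#' @return Data frame with integer column `score` and logical columns
#'   `cond_suvmax`, `cond_primary`, `cond_liver`, `cond_brainstem`,
#'   `cond_lung`.
#' @export
multifactorial_score <- function(node_suvmax, ratios,
                                 thresholds = score_thresholds()) {
  stopifnot(all(RATIO_FEATURES %in% names(ratios)))
  flags <- data.frame(
    cond_suvmax = node_suvmax >= thresholds[["suvmax"]],
    cond_primary = ratios$primary >= thresholds[["primary"]],
    cond_liver = ratios$liver >= thresholds[["liver"]],
    cond_brainstem = ratios$brainstem >= thresholds[["brainstem"]],
    cond_lung = ratios$lung >= thresholds[["lung"]])
  cbind(score = as.integer(rowSums(flags)), flags)
}

#' Dichotomise a score
#'
#' Positive (malignant call) iff `score >= cutoff`. The default cut-off of 3
#' ("higher than two") is the optimum found on the reference cohort for both
#' the visual and the multifactorial score.
#'
#' @param score Integer score vector.
#' @param cutoff Integer cut-off within the score's range.
#' @param max_score Largest attainable score (5 for the multifactorial
#'   score, 3 for the visual score).
#' @return Character vector `"positive"`/`"negative"`.
#' @export
classify_score <- function(score, cutoff = 3L, max_score = 5L) {
  if (!is.finite(cutoff) || cutoff != round(cutoff) || cutoff < 1 ||
      cutoff > max_score)
    stop("cutoff must be an integer in 1..", max_score, call. = FALSE)
  if (any(score < 0 | score > max_score))
    stop("score outside 0..", max_score, call. = FALSE)
  ifelse(score >= cutoff, "positive", "negative")
}

# Per-node feature table for a cohort: suvmax + four ratios + both scores.
cohort_features <- function(cohort, thresholds = score_thresholds()) {
  flat <- as.data.frame(cohort)
  ratios <- compute_ratios(flat$suvmax, flat$primary_suvmax, flat$liver_suvmax,
                           flat$brainstem_suvmax, flat$lung_suvmax)
  ms <- multifactorial_score(flat$suvmax, ratios, thresholds)
  vs <- suppressWarnings(
    visual_score(flat$suvmax, flat$liver_suvmax, flat$primary_suvmax))
  data.frame(patient_id = flat$patient_id, node_id = flat$node_id,
             histology = flat$histology, suvmax = flat$suvmax,
             ratio_primary = ratios$primary, ratio_liver = ratios$liver,
             ratio_brainstem = ratios$brainstem, ratio_lung = ratios$lung,
             visual_score = vs, multi_score = ms$score,
             multi_flags = apply(ms[RATIO_FLAG_COLS], 1L,
                                 function(f) paste(as.integer(f), collapse = "")))
}

RATIO_FLAG_COLS <- c("cond_suvmax", "cond_primary", "cond_liver",
                     "cond_brainstem", "cond_lung")

#' Append derived feature columns to a cohort table
#'
#' Adds `ratio_primary`, `ratio_liver`, `ratio_brainstem`, `ratio_lung`,
#' `visual_score`, `multi_score` and `multi_flags` (conditions I-V as a
#' 5-character 0/1 string) to the flat cohort data frame.
#'
#' @param cohort An `ln_cohort`.
#' @param thresholds A [score_thresholds()] vector.
#' @return Data frame: the [cohort_columns()] schema plus the feature
#'   columns.
#' @export
score_cohort <- function(cohort, thresholds = score_thresholds()) {
  flat <- as.data.frame(cohort)
  feats <- cohort_features(cohort, thresholds)
  cbind(flat, feats[setdiff(names(feats),
                            c("patient_id", "node_id", "histology", "suvmax"))])
}
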
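# ---------------------------------------------------------------------------
# ln_staging(): the end-to-end analysis as a fitted-model object.
# ---------------------------------------------------------------------------

#' Fit the quantitative lymph-node staging analysis to a cohort
#'
#' Runs the complete node-level analysis: computes the four node-to-reference
#' SUV ratios, builds ROC curves and AUCs (with confidence intervals) for
#' SUVmax and each ratio, fixes or re-derives the per-feature cut-offs,
#' tabulates the 2x2 cross table and operating characteristics at each
#' cut-off, and evaluates the quantified visual score and the five-condition
#' multifactorial score the same way. Nodes are treated as independent
#' observations (no within-patient clustering adjustment), mirroring the
#' per-node cross-table design.
#'
#' Two cut-off modes make the two-stage construction explicit:
#' `cutoff_mode = "fixed"` applies the supplied `thresholds` (defaulting to
#' the reference cohort's published cut-offs) both for the per-feature
#' dichotomisation and as the multifactorial score conditions;
#' `cutoff_mode = "derive"` re-derives every cut-off from this cohort's own
#' ROC curve by the minimum-distance-to-(0,1) criterion and feeds the
#' derived values into the score.
#'
#' @param cohort An `ln_cohort` (see [read_cohort()], [simulate_cohort()]).
#' @param features Features to analyse: subset of `"suvmax"`, `"primary"`,
#'   `"liver"`, `"brainstem"`, `"lung"`.
#' @param cutoff_mode `"fixed"` (use `thresholds`) or `"derive"`
#'   (minimum-distance optimum on this cohort).
#' @param thresholds A [score_thresholds()] vector (used directly in fixed
#'   mode; ignored for features in derive mode).
#' @param score_cutoff,visual_cutoff Integer positivity cut-offs for the
#'   multifactorial (0--5) and visual (1--3) scores; default 3 ("higher
#'   than two").
#' @param ci_method AUC confidence-interval method, `"delong"` or
#'   `"hanley"`.
#' @param conf_level Confidence level for AUC intervals.
#' @return An object of class `ln_staging` with components `features` (per
#'   feature: `cutoff`, `roc`, `auc`, `table`, `metrics`), `scores` (same
#'   for `visual` and `multiscore`, plus the per-node score vectors),
#'   `node_features` (per-node feature table), `cohort_summary`, `caveats`
#'   and `config`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_patients = 40, seed = 7))
#' fit <- ln_staging(cohort)
#' summary(fit)
#' @export
ln_staging <- function(cohort,
                       features = ALL_FEATURES,
                       cutoff_mode = c("fixed", "derive"),
                       thresholds = score_thresholds(),
                       score_cutoff = 3L, visual_cutoff = 3L,
                       ci_method = c("delong", "hanley"),
                       conf_level = 0.95) {
  stopifnot(inherits(cohort, "ln_cohort"))
  cutoff_mode <- match.arg(cutoff_mode)
  ci_method <- match.arg(ci_method)
  features <- match.arg(features, ALL_FEATURES, several.ok = TRUE)
  if (length(features) == 0L) stop("feature list must be non-empty", call. = FALSE)

  flat <- as.data.frame(cohort)
  labels <- flat$histology
  if (length(unique(labels)) < 2L)
    stop("both histology classes must be present in the cohort", call. = FALSE)

  ratios <- compute_ratios(flat$suvmax, flat$primary_suvmax, flat$liver_suvmax,
                           flat$brainstem_suvmax, flat$lung_suvmax)
  feature_values <- cbind(suvmax = flat$suvmax, ratios)

  analyse_values <- function(values, cutoff) {
    roc <- roc_curve(values, labels)
    if (is.null(cutoff)) {
      opt <- optimal_cutoff(roc)
      cutoff <- opt$threshold
    }
    tab <- build_contingency(values, labels, cutoff)
    list(cutoff = cutoff, roc = roc,
         auc = roc_auc(values, labels, method = ci_method,
                       conf_level = conf_level),
         table = tab, metrics = metrics_from_contingency(tab),
         p_value = compare_groups(values[labels == "benign"],
                                  values[labels == "malignant"]))
  }

  feats <- list()
  for (f in features) {
    fixed <- if (cutoff_mode == "fixed") thresholds[[f]] else NULL
    feats[[f]] <- analyse_values(feature_values[[f]], fixed)
  }

  # thresholds feeding the score: fixed ones, or this cohort's derived ones
  score_th <- thresholds
  if (cutoff_mode == "derive") {
    for (f in ALL_FEATURES) {
      score_th[[f]] <- if (!is.null(feats[[f]])) feats[[f]]$cutoff
        else optimal_cutoff(roc_curve(feature_values[[f]], labels))$threshold
    }
  }

  ms <- multifactorial_score(flat$suvmax, ratios, score_th)
  vs <- suppressWarnings(
    visual_score(flat$suvmax, flat$liver_suvmax, flat$primary_suvmax))
  analyse_score <- function(score, cutoff, max_score) {
    roc <- roc_curve(score, labels)
    tab <- build_contingency(score, labels, cutoff)
    list(cutoff = cutoff, roc = roc,
         auc = roc_auc(score, labels, method = ci_method,
                       conf_level = conf_level),
         table = tab, metrics = metrics_from_contingency(tab),
         max_score = max_score)
  }
  scores <- list(visual = c(analyse_score(vs, visual_cutoff, 3L),
                            list(values = vs)),
                 multiscore = c(analyse_score(ms$score, score_cutoff, 5L),
                                list(values = ms$score)))

  n_mal <- sum(labels == "malignant")
  caveats <- character(0)
  if (any(flat$primary_suvmax < flat$liver_suvmax))
    caveats <- c(caveats, paste0(
      "primary uptake below liver uptake for some patients; ",
      "visual score rules applied in listed order"))

  structure(list(
    features = feats,
    scores = scores,
    score_thresholds = score_th,
    node_features = cbind(flat[c("patient_id", "node_id", "histology")],
                          feature_values,
                          visual_score = vs, multi_score = ms$score),
    cohort_summary = list(
      n_patients = nrow(cohort$patients),
      n_nodes = nrow(flat),
      n_malignant = n_mal,
      prevalence = n_mal / nrow(flat),
      station_counts = table(factor(flat$station, levels = VALID_STATIONS))),
    caveats = caveats,
    config = list(features = features, cutoff_mode = cutoff_mode,
                  score_cutoff = score_cutoff, visual_cutoff = visual_cutoff,
                  ci_method = ci_method, conf_level = conf_level)),
    class = "ln_staging")
}

#' @export
print.ln_staging <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("Quantitative lymph-node staging analysis (%s cut-offs)\n",
              x$config$cutoff_mode))
  cat(sprintf("Cohort: %d nodes in %d patients, %d malignant (%.1f%%)\n",
              cs$n_nodes, cs$n_patients, cs$n_malignant, 100 * cs$prevalence))
  print(summary(x))
  invisible(x)
}

#' Tabulate a fitted staging analysis
#'
#' One row per feature and score: cut-off, AUC with confidence interval and
#' the five operating characteristics (percentages, rounded half-up to two
#' decimals).
#'
#' @param object An `ln_staging` fit.
#' @param ... Unused.
#' @return Data frame with columns `feature`, `cutoff`, `auc`, `ci_low`,
#'   `ci_high`, `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
summary.ln_staging <- function(object, ...) {
  row <- function(name, res) {
    data.frame(feature = name, cutoff = res$cutoff, auc = res$auc$auc,
               ci_low = res$auc$ci_low, ci_high = res$auc$ci_high,
               sensitivity = res$metrics$pct$sensitivity,
               specificity = res$metrics$pct$specificity,
               ppv = res$metrics$pct$ppv, npv = res$metrics$pct$npv,
               accuracy = res$metrics$pct$accuracy)
  }
  out <- do.call(rbind, c(
    lapply(names(object$features),
           function(f) row(f, object$features[[f]])),
    lapply(names(object$scores),
           function(s) row(s, object$scores[[s]]))))
  rownames(out) <- NULL
  out
}

#' @export
coef.ln_staging <- function(object, ...) {
  vapply(object$features, function(f) f$cutoff, numeric(1))
}

#' Classify new nodes with a fitted staging analysis
#'
#' Applies the fit's cut-offs (per-feature and score) to new node data.
#'
#' @param object An `ln_staging` fit.
#' @param newdata An `ln_cohort` or a flat data frame with at least the
#'   columns `suvmax`, `primary_suvmax`, `liver_suvmax`, `brainstem_suvmax`,
#'   `lung_suvmax`.
#' @param type `"class"` (per-feature and per-score positive/negative
#'   calls), `"score"` (visual and multifactorial scores) or `"features"`
#'   (SUVmax and the four ratios).
#' @param ... Unused.
#' @return Data frame with one row per node.
#' @export
predict.ln_staging <- function(object, newdata,
                               type = c("class", "score", "features"), ...) {
  type <- match.arg(type)
  flat <- if (inherits(newdata, "ln_cohort")) as.data.frame(newdata)
    else as.data.frame(newdata)
  ratios <- compute_ratios(flat$suvmax, flat$primary_suvmax, flat$liver_suvmax,
                           flat$brainstem_suvmax, flat$lung_suvmax)
  vals <- cbind(suvmax = flat$suvmax, ratios)
  if (type == "features") return(vals)
  th <- object$score_thresholds
  ms <- multifactorial_score(flat$suvmax, ratios, th)
  vs <- suppressWarnings(
    visual_score(flat$suvmax, flat$liver_suvmax, flat$primary_suvmax))
  if (type == "score")
    return(data.frame(visual_score = vs, multi_score = ms$score))
  out <- data.frame(row.names = seq_len(nrow(flat)))
  for (f in names(object$features)) {
    out[[f]] <- ifelse(vals[[f]] >= object$features[[f]]$cutoff,
                       "positive", "negative")
  }
  out$visual <- classify_score(vs, object$config$visual_cutoff, 3L)
  out$multiscore <- classify_score(ms$score, object$config$score_cutoff, 5L)
  out
}

#' Plot ROC curves of a fitted staging analysis
#'
#' Overlays the empirical ROC curves of the analysed features (and,
#' optionally, scores) in 1 - specificity / sensitivity space and marks each
#' feature's operating point at its cut-off.
#'
#' @param x An `ln_staging` fit.
#' @param which Names of features/scores to draw; default all features.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ln_staging <- function(x, which = names(x$features), ...) {
  all_res <- c(x$features, x$scores)
  which <- intersect(which, names(all_res))
  if (length(which) == 0L) stop("nothing to plot", call. = FALSE)
  cols <- grDevices::hcl.colors(max(3L, length(which)), "Dark 2")
  graphics::plot(c(0, 1), c(0, 1), type = "n",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = "ROC curves", ...)
  graphics::abline(0, 1, col = "grey70", lty = 2)
  for (i in seq_along(which)) {
    res <- all_res[[which[i]]]
    o <- order(1 - res$roc$specificity, res$roc$sensitivity)
    graphics::lines((1 - res$roc$specificity)[o], res$roc$sensitivity[o],
                    col = cols[i], lwd = 2)
    graphics::points(1 - res$metrics$raw$specificity,
                     res$metrics$raw$sensitivity, col = cols[i], pch = 19)
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.2f)", which,
                                    vapply(all_res[which],
                                           function(r) r$auc$auc, numeric(1))),
                   col = cols[seq_along(which)], lwd = 2, bty = "n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Reproduction of the bundled reference tables
# ---------------------------------------------------------------------------

#' Recompute the reference cohort's performance tables
#'
#' Applies [metrics_from_contingency()] to each of the five bundled 2x2
#' cross tables of the 101-node reference cohort and compares the
#' recomputed operating characteristics side by side with the originally
#' published values. Cells where the recomputation disagrees with the
#' published figure beyond printing precision are flagged as caveats rather
#' than matched: the reference publication's SUVmax sensitivity (89.67 vs
#' recomputed 26/29 = 89.66) and lymph-node/lung accuracy (81.89 vs
#' recomputed 82/101 = 81.19) are known inconsistencies of the original
#' tables.
#'
#' @return An `ln_table_report`: list with `comparison` (data frame: one
#'   row per feature and metric, recomputed vs published), `tables` (the
#'   cross tables), `metrics` (recomputed `performance_metrics`) and
#'   `caveats`.
#' @export
reproduce_tables <- function() {
  tabs <- reference_cross_tables()
  pub <- reference_data()$published_metrics
  metric_names <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  rows <- list(); caveats <- character(0)
  metrics <- lapply(tabs, metrics_from_contingency)
  for (f in names(tabs)) {
    for (m in metric_names) {
      recomputed <- metrics[[f]]$pct[[m]]
      published <- pub[[f]][[m]]
      agree <- abs(recomputed - published) < 0.005
      if (!agree)
        caveats <- c(caveats, sprintf(
          "%s %s: published %.2f%% but recomputed %.2f%% from the cross table; reporting the recomputed value",
          f, m, published, recomputed))
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, metric = m, recomputed = recomputed,
                   published = published, agree = agree)
    }
  }
  structure(list(comparison = do.call(rbind, rows), tables = tabs,
                 metrics = metrics, caveats = caveats),
            class = "ln_table_report")
}

#' @export
print.ln_table_report <- function(x, ...) {
  cat("Recomputed reference-cohort performance (vs published):\n")
  wide <- stats::reshape(x$comparison[c("feature", "metric", "recomputed")],
                         idvar = "feature", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("^recomputed\\.", "", names(wide))
  print(wide, row.names = FALSE)
  if (length(x$caveats)) {
    cat("Caveats:\n")
    for (cv in x$caveats) cat("  -", cv, "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Report serialization
# ---------------------------------------------------------------------------

report_list <- function(fit) {
  res_to_list <- function(res) {
    list(cutoff = res$cutoff,
         auc = res$auc[c("auc", "ci_low", "ci_high", "se", "level", "method")],
         table = res$table[c("tn", "fp", "fn", "tp")],
         metrics = list(raw = res$metrics$raw, pct = res$metrics$pct),
         p_value = res$p_value)
  }
  list(features = lapply(fit$features, res_to_list),
       scores = lapply(fit$scores, function(s) res_to_list(s)),
       score_thresholds = as.list(unclass(fit$score_thresholds)),
       cohort_summary = list(
         n_patients = fit$cohort_summary$n_patients,
         n_nodes = fit$cohort_summary$n_nodes,
         n_malignant = fit$cohort_summary$n_malignant,
         prevalence = fit$cohort_summary$prevalence,
         station_counts = as.list(fit$cohort_summary$station_counts)),
       caveats = as.list(fit$caveats),
       config = fit$config)
}

#' Write / read an analysis report as JSON
#'
#' Numbers are serialized at full double precision, so a written report
#' reloads with every value bit-identical.
#'
#' @param fit An `ln_staging` fit.
#' @param path Output JSON path.
#' @return `write_report`: `path` invisibly; `read_report`: the report as a
#'   nested list.
#' @export
write_report <- function(fit, path) {
  stopifnot(inherits(fit, "ln_staging"))
  jsonlite::write_json(report_list(fit), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Flatten a fit to a performance-table CSV
#'
#' Writes the [summary.ln_staging()] table (one row per feature/score with
#' cut-off, AUC, CI and the five metrics) as CSV.
#'
#' @param fit An `ln_staging` fit.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_performance_csv <- function(fit, path) {
  utils::write.csv(summary(fit), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
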
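# ---------------------------------------------------------------------------
# ROC analysis and diagnostic performance.
#
# Orientation: higher feature value => more likely malignant; a node is test
# positive iff value >= threshold (inclusive), consistently with the score
# conditions. The empirical curve carries one operating point per distinct
# observed value plus the two degenerate endpoints.
# ---------------------------------------------------------------------------

check_two_classes <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both histology classes must be present", call. = FALSE)
  labels
}

#' Empirical ROC curve
#'
#' @param values Numeric per-node feature values (finite).
#' @param labels `"benign"`/`"malignant"` per node; both classes must be
#'   present.
#' @return An `roc_curve` object: data frame with columns `threshold`
#'   (increasing; `-Inf` and `Inf` are the all-positive/all-negative
#'   endpoints), `sensitivity` and `specificity`, plus attributes `values`
#'   and `labels`.
#' @export
roc_curve <- function(values, labels) {
  labels <- check_two_classes(labels)
  if (length(values) != length(labels))
    stop("values and labels must have the same length", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite feature value", call. = FALSE)
  mal <- labels == "malignant"
  n_mal <- sum(mal); n_ben <- sum(!mal)
  thr <- c(sort(unique(values)), Inf)
  sens <- vapply(thr, function(t) sum(mal & values >= t) / n_mal, numeric(1))
  spec <- vapply(thr, function(t) sum(!mal & values < t) / n_ben, numeric(1))
  curve <- data.frame(threshold = c(-Inf, thr),
                      sensitivity = c(1, sens), specificity = c(0, spec))
  structure(curve, class = c("roc_curve", "data.frame"),
            values = values, labels = labels)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d operating points (%d malignant / %d benign)\n",
              nrow(x), sum(attr(x, "labels") == "malignant"),
              sum(attr(x, "labels") == "benign")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Area under the ROC curve with confidence interval
#'
#' The point estimate is the trapezoidal area under the empirical ROC
#' curve, identical to the pairwise concordance probability with ties
#' counted 1/2. The confidence interval uses DeLong's variance estimate by
#' default; `method = "hanley"` gives the Hanley-McNeil approximation.
#' Intervals are clipped to [0, 1].
#'
#' @param values,labels As in [roc_curve()].
#' @param method CI method, `"delong"` (default) or `"hanley"`.
#' @param conf_level Confidence level, default 0.95.
#' @return An `auc_estimate` object: list with `auc`, `ci_low`, `ci_high`,
#'   `se`, `level`, `method`.
#' @export
roc_auc <- function(values, labels, method = c("delong", "hanley"),
                    conf_level = 0.95) {
  method <- match.arg(method)
  labels <- check_two_classes(labels)
  if (any(!is.finite(values))) stop("non-finite feature value", call. = FALSE)
  x <- values[labels == "malignant"]   # cases
  y <- values[labels == "benign"]      # controls
  m <- length(x); n <- length(y)
  # placement values: P(case i outranks a random control), ties = 1/2
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n,
                numeric(1))
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                numeric(1))
  auc <- mean(v10)
  se <- if (method == "delong") {
    s10 <- if (m > 1) stats::var(v10) else 0
    s01 <- if (n > 1) stats::var(v01) else 0
    sqrt(s10 / m + s01 / n)
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    sqrt((auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
            (n - 1) * (q2 - auc^2)) / (m * n))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc = auc, ci_low = max(0, auc - z * se),
                 ci_high = min(1, auc + z * se), se = se,
                 level = conf_level, method = method),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f, %s)\n", x$auc, 100 * x$level,
              x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Optimal cut-off by minimum distance to the (0, 1) corner
#'
#' Selects the operating point of the ROC curve minimising
#' `d = sqrt((1 - sensitivity)^2 + (1 - specificity)^2)`. Ties are broken
#' in favour of higher specificity, then lower threshold. The degenerate
#' endpoints compete like any other point (they can only win on a
#' degenerate curve, which is an error).
#'
#' @param curve An [roc_curve()].
#' @return A `cutoff_result` object: list with `threshold`, `d`,
#'   `sensitivity`, `specificity`.
#' @export
optimal_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  finite <- is.finite(curve$threshold)
  if (!any(finite))
    stop("degenerate ROC curve: no non-degenerate operating point", call. = FALSE)
  cand <- curve[finite, , drop = FALSE]
  d <- sqrt((1 - cand$sensitivity)^2 + (1 - cand$specificity)^2)
  ord <- order(d, -cand$specificity, cand$threshold)
  best <- ord[1]
  structure(list(threshold = cand$threshold[best], d = d[best],
                 sensitivity = cand$sensitivity[best],
                 specificity = cand$specificity[best]),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Optimal cut-off %.4g (d = %.4f): sensitivity %.1f%%, specificity %.1f%%\n",
              x$threshold, x$d, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

# round half up (away from zero), as used for percentage reporting
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Diagnostic performance metrics from a 2x2 table
#'
#' Standard operating characteristics: sensitivity `tp/(tp+fn)`,
#' specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`, NPV `tn/(tn+fn)`, accuracy
#' `(tp+tn)/n`. Raw fractions are retained unrounded; the `*_pct` fields
#' are percentages rounded half-up to two decimals for reporting. A metric
#' whose denominator is zero is returned as `NA` (undefined), never as 0.
#'
#' @param tab A [contingency()] table.
#' @return A `performance_metrics` object: list with `raw` (fractions) and
#'   `pct` (rounded percentages), each with elements `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, plus the source `table`.
#' @export
metrics_from_contingency <- function(tab) {
  stopifnot(inherits(tab, "contingency"))
  n <- tab$tn + tab$fp + tab$fn + tab$tp
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  raw <- list(sensitivity = safe_div(tab$tp, tab$tp + tab$fn),
              specificity = safe_div(tab$tn, tab$tn + tab$fp),
              ppv = safe_div(tab$tp, tab$tp + tab$fp),
              npv = safe_div(tab$tn, tab$tn + tab$fn),
              accuracy = (tab$tp + tab$tn) / n)
  pct <- lapply(raw, function(v) if (is.na(v)) NA_real_ else round_half_up(100 * v, 2))
  structure(list(raw = raw, pct = pct, table = tab),
            class = "performance_metrics")
}

#' @export
print.performance_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf("sens %s  spec %s  PPV %s  NPV %s  acc %s\n",
              fmt(x$pct$sensitivity), fmt(x$pct$specificity), fmt(x$pct$ppv),
              fmt(x$pct$npv), fmt(x$pct$accuracy)))
  invisible(x)
}

#' Two-group comparison of a feature between histology classes
#'
#' Two-sided Mann-Whitney U test (normal approximation with continuity
#' correction, tie-corrected), matching the nonparametric
#' median-and-range presentation of the class summaries.
#'
#' @param benign_values,malignant_values Numeric vectors, each nonempty.
#' @return Two-sided p-value.
#' @export
compare_groups <- function(benign_values, malignant_values) {
  if (length(benign_values) == 0L || length(malignant_values) == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  stats::wilcox.test(malignant_values, benign_values, exact = FALSE,
                     correct = TRUE)$p.value
}
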
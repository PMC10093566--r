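test_that("ROC curves include endpoints and behave on separable/tied input", {
  curve <- roc_curve(c(1, 2, 3, 4), c("benign", "benign", "malignant", "malignant"))
  expect_true(any(curve$sensitivity == 1 & curve$specificity == 0))
  expect_true(any(curve$sensitivity == 0 & curve$specificity == 1))
  at3 <- curve[curve$threshold == 3, ]
  expect_equal(at3$sensitivity, 1)
  expect_equal(at3$specificity, 1)
  expect_true(all(diff(curve$sensitivity) <= 0))

  tied <- roc_curve(rep(2, 6), rep(c("benign", "malignant"), 3))
  expect_true(all((tied$sensitivity %in% c(0, 1)) &
                  (tied$specificity %in% c(0, 1))))
  expect_error(roc_curve(1:3, rep("benign", 3)), "both")
})

test_that("every ROC operating point matches a brute-force contingency", {
  rc <- random_cohort_values(50, seed = 101)
  curve <- roc_curve(rc$values, rc$labels)
  for (row in seq_len(nrow(curve))) {
    t <- curve$threshold[row]
    if (!is.finite(t)) next
    cells <- oracle_contingency(rc$values, rc$labels, t)
    expect_equal(curve$sensitivity[row], cells["tp"] / (cells["tp"] + cells["fn"]),
                 ignore_attr = TRUE)
    expect_equal(curve$specificity[row], cells["tn"] / (cells["tn"] + cells["fp"]),
                 ignore_attr = TRUE)
  }
})

test_that("trapezoid AUC equals pairwise concordance and handles ties as 1/2", {
  expect_equal(roc_auc(c(1, 2, 8, 9), c("benign", "benign", "malignant",
                                        "malignant"))$auc, 1.0)
  expect_equal(roc_auc(rep(3, 8), rep(c("benign", "malignant"), 4))$auc, 0.5)

  for (seed in 1:10) {
    rc <- random_cohort_values(30, seed = 200 + seed)
    est <- roc_auc(rc$values, rc$labels)
    expect_equal(est$auc, oracle_auc(rc$values, rc$labels), tolerance = 1e-12)
  }
})

test_that("AUC orientation flip is complementary", {
  for (seed in 1:5) {
    rc <- random_cohort_values(35, seed = 300 + seed)
    a1 <- roc_auc(rc$values, rc$labels)$auc
    a2 <- roc_auc(-rc$values, rc$labels)$auc
    expect_equal(a1 + a2, 1, tolerance = 1e-12)
  }
})

test_that("DeLong and Hanley-McNeil intervals bracket the estimate sensibly", {
  rc <- random_cohort_values(60, seed = 7)
  for (m in c("delong", "hanley")) {
    est <- roc_auc(rc$values, rc$labels, method = m)
    expect_lte(est$ci_low, est$auc)
    expect_gte(est$ci_high, est$auc)
    expect_gte(est$ci_low, 0)
    expect_lte(est$ci_high, 1)
    expect_equal(est$level, 0.95)
  }
})

test_that("AUC and DeLong CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    rc <- random_cohort_values(45, seed = 400 + seed)
    est <- roc_auc(rc$values, rc$labels, method = "delong")
    ref <- pROC::roc(response = rc$labels, predictor = rc$values,
                     levels = c("benign", "malignant"), direction = "<",
                     quiet = TRUE)
    expect_equal(est$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_equal(c(est$ci_low, est$ci_high), pmin(1, pmax(0, ci[c(1, 3)])),
                 tolerance = 1e-9)
  }
})

test_that("optimal cut-off minimises distance to (0,1) with the stated tie-break", {
  # perfect separation: d = 0 at the separating threshold
  curve <- roc_curve(c(1, 2, 8, 9), c("benign", "benign", "malignant",
                                      "malignant"))
  opt <- optimal_cutoff(curve)
  expect_equal(opt$d, 0)
  expect_equal(opt$threshold, 8)

  # symmetric tie between (sens .9, spec .8) at t = 2 and (sens .8, spec .9)
  # at t = 3: the higher-specificity point wins
  vals <- c(rep(1, 8), 2, 3,            # benign
            1, 2, rep(3, 8))            # malignant
  labs <- rep(c("benign", "malignant"), each = 10)
  curve2 <- roc_curve(vals, labs)
  p2 <- curve2[curve2$threshold == 2, ]
  p3 <- curve2[curve2$threshold == 3, ]
  expect_equal(c(p2$sensitivity, p2$specificity), c(0.9, 0.8))
  expect_equal(c(p3$sensitivity, p3$specificity), c(0.8, 0.9))
  opt2 <- optimal_cutoff(curve2)
  expect_equal(opt2$threshold, 3)
  expect_equal(opt2$specificity, 0.9)

  expect_error(optimal_cutoff(structure(
    data.frame(threshold = c(-Inf, Inf), sensitivity = c(1, 0),
               specificity = c(0, 1)), class = c("roc_curve", "data.frame"))),
    "degenerate")
})

test_that("optimal cut-off equals exhaustive minimisation on random cohorts", {
  for (seed in 1:20) {
    rc <- random_cohort_values(50, seed = 500 + seed)
    got <- optimal_cutoff(roc_curve(rc$values, rc$labels))
    want <- oracle_optimal_cutoff(rc$values, rc$labels)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$d, want$d, tolerance = 1e-12)
    expect_equal(got$d,
                 sqrt((1 - got$sensitivity)^2 + (1 - got$specificity)^2))
  }
})

test_that("performance metrics reproduce the reference-table rows", {
  m <- metrics_from_contingency(contingency(tn = 64, fp = 8, fn = 3, tp = 26))
  expect_equal(m$pct$specificity, 88.89)
  expect_equal(m$pct$ppv, 76.47)
  expect_equal(m$pct$npv, 95.52)
  expect_equal(m$pct$accuracy, 89.11)
  expect_equal(m$pct$sensitivity, 89.66)  # 26/29, two decimals half-up

  m2 <- metrics_from_contingency(contingency(tn = 53, fp = 19, fn = 0, tp = 29))
  expect_equal(m2$pct$sensitivity, 100)
  expect_equal(m2$pct$npv, 100)
  expect_equal(m2$pct$specificity, 73.61)

  m3 <- metrics_from_contingency(contingency(tn = 1, fp = 0, fn = 0, tp = 1))
  expect_true(all(unlist(m3$pct) == 100))
})

test_that("undefined metrics are NA, never zero", {
  m <- metrics_from_contingency(contingency(tn = 3, fp = 0, fn = 2, tp = 0))
  expect_true(is.na(m$raw$ppv))
  expect_true(is.na(m$pct$ppv))
  expect_false(is.na(m$raw$specificity))
})

test_that("ROC points recompute through build_contingency + metrics", {
  rc <- random_cohort_values(40, seed = 8)
  curve <- roc_curve(rc$values, rc$labels)
  for (t in curve$threshold[is.finite(curve$threshold)]) {
    m <- metrics_from_contingency(build_contingency(rc$values, rc$labels, t))
    row <- curve[curve$threshold == t, ]
    expect_equal(row$sensitivity, m$raw$sensitivity)
    expect_equal(row$specificity, m$raw$specificity)
  }
})

test_that("group comparison is a two-sided Mann-Whitney test", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_lt(compare_groups(rnorm(20), rnorm(20) + 10), 0.001)
  expect_error(compare_groups(numeric(0), 1:3), "nonempty")
})

test_that("calibrated groups separate significantly at the reference sizes", {
  cs <- reference_class_summaries()
  db <- class_distribution(cs$benign$suvmax$median, cs$benign$suvmax$low,
                           cs$benign$suvmax$high)
  dm <- class_distribution(cs$malignant$suvmax$median, cs$malignant$suvmax$low,
                           cs$malignant$suvmax$high)
  hits <- 0L
  for (seed in 1:40) {
    set.seed(900 + seed)
    p <- compare_groups(draw_class_distribution(72, db),
                        draw_class_distribution(29, dm))
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})
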
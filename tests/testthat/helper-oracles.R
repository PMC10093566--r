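# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the implementation they check.

oracle_contingency <- function(values, labels, cutoff) {
  tn <- fp <- fn <- tp <- 0L
  for (i in seq_along(values)) {
    pos <- values[i] >= cutoff
    mal <- labels[i] == "malignant"
    if (mal && pos) tp <- tp + 1L
    if (mal && !pos) fn <- fn + 1L
    if (!mal && pos) fp <- fp + 1L
    if (!mal && !pos) tn <- tn + 1L
  }
  c(tn = tn, fp = fp, fn = fn, tp = tp)
}

# pairwise concordance over all malignant x benign pairs, ties counted 1/2
oracle_auc <- function(values, labels) {
  x <- values[labels == "malignant"]
  y <- values[labels == "benign"]
  total <- 0
  for (xi in x) for (yj in y) {
    total <- total + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  total / (length(x) * length(y))
}

# exhaustive minimisation of d over all distinct thresholds, with the same
# tie-break (higher specificity, then lower threshold)
oracle_optimal_cutoff <- function(values, labels) {
  best <- NULL
  for (t in sort(unique(values))) {
    cells <- oracle_contingency(values, labels, t)
    sens <- cells["tp"] / (cells["tp"] + cells["fn"])
    spec <- cells["tn"] / (cells["tn"] + cells["fp"])
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    cand <- list(threshold = t, d = unname(d), sensitivity = unname(sens),
                 specificity = unname(spec))
    if (is.null(best) || d < best$d - 1e-15 ||
        (abs(d - best$d) <= 1e-15 && spec > best$specificity + 1e-15)) {
      best <- cand
    }
  }
  best
}

# exhaustive voxel-by-voxel sphere membership
oracle_voi_voxels <- function(volume, voi) {
  dm <- dim(volume$values); sp <- volume$spacing_mm
  out <- NULL
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    center <- c((i - 1) * sp[1], (j - 1) * sp[2], (k - 1) * sp[3])
    if (sqrt(sum((center - voi$center_mm)^2)) <= voi$diameter_mm / 2)
      out <- rbind(out, c(i = i, j = j, k = k))
  }
  out
}

# double loop over candidate centers and averaging-sphere members
oracle_suv_peak <- function(volume, voi, sphere_volume_ml = 1.0) {
  centers <- oracle_voi_voxels(volume, voi)
  dm <- dim(volume$values); sp <- volume$spacing_mm
  r <- (3 * sphere_volume_ml * 1000 / (4 * pi))^(1 / 3)
  best <- -Inf
  for (c_row in seq_len(nrow(centers))) {
    cc <- (centers[c_row, ] - 1) * sp
    vals <- c()
    for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
      pos <- c((i - 1) * sp[1], (j - 1) * sp[2], (k - 1) * sp[3])
      if (sqrt(sum((pos - cc)^2)) <= r) vals <- c(vals, volume$values[i, j, k])
    }
    best <- max(best, mean(vals))
  }
  best
}

# small hand-buildable cohort data frame in the flat schema
demo_flat <- function() {
  path <- system.file("extdata", "demo_cohort.csv", package = "petln")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

random_cohort_values <- function(n, seed) {
  set.seed(seed)
  labels <- c("benign", "malignant",
              sample(c("benign", "malignant"), n - 2L, replace = TRUE))
  values <- round(stats::rlnorm(n, log(4), 0.8), sample(0:3, 1L))
  list(values = values, labels = labels)
}
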
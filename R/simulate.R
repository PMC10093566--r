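# ---------------------------------------------------------------------------
# Calibrated synthetic cohort generator.
#
# Per-class feature distributions are truncated log-normals calibrated to the
# reference cohort's class-conditional medians and ranges. Patient-level
# reference uptakes are shared by all of a patient's nodes; because node
# classes are drawn independently within a patient, sharing references mixes
# the class-conditional ratio distributions. The generator pre-compensates
# this mixing bias analytically (see simulate_cohort) so that class-wise
# sample medians of SUVmax and of every ratio recover their calibration
# targets at large n.
# ---------------------------------------------------------------------------

# central interval of the untruncated log-normal that the range should span
RANGE_COVERAGE <- 0.995

#' Calibrate a truncated log-normal to a median and range
#'
#' The log-normal location is set so the distribution's median equals
#' `median`; the scale is set so the central 99.5\% interval of the
#' untruncated distribution spans `[low, high]`; sampling then truncates to
#' `[low, high]` by rejection.
#'
#' @param median Target median (must lie strictly inside the range).
#' @param low,high Range bounds, `0 < low < high`.
#' @return A `class_distribution` object: list with `median`, `low`,
#'   `high`, `meanlog`, `sdlog`.
#' @export
class_distribution <- function(median, low, high) {
  if (!(is.finite(median) && is.finite(low) && is.finite(high)))
    stop("median and range must be finite", call. = FALSE)
  if (!(0 < low && low < median && median < high))
    stop(sprintf("infeasible targets: need 0 < low < median < high, got %g (%g-%g)",
                 median, low, high), call. = FALSE)
  z <- stats::qnorm(1 - (1 - RANGE_COVERAGE) / 2)
  structure(list(median = median, low = low, high = high,
                 meanlog = log(median),
                 sdlog = (log(high) - log(low)) / (2 * z)),
            class = "class_distribution")
}

# mean of log X for the truncated log-normal (truncated-normal mean in log space)
truncated_log_mean <- function(dist, meanlog = dist$meanlog) {
  a <- (log(dist$low) - meanlog) / dist$sdlog
  b <- (log(dist$high) - meanlog) / dist$sdlog
  meanlog + dist$sdlog * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Draw from a calibrated class distribution
#'
#' @param n Number of draws.
#' @param dist A [class_distribution()].
#' @param shift_log Optional additive shift of the whole distribution in log
#'   space (location and truncation bounds move together, so the achieved
#'   shift of the log-mean is exactly `shift_log`); used by the generator's
#'   reference-consistency compensation.
#' @return Numeric vector of length `n`, all values within the (possibly
#'   shifted) truncation range.
#' @export
draw_class_distribution <- function(n, dist, shift_log = 0) {
  stopifnot(inherits(dist, "class_distribution"))
  out <- numeric(0)
  meanlog <- dist$meanlog + shift_log
  lo <- dist$low * exp(shift_log)
  hi <- dist$high * exp(shift_log)
  while (length(out) < n) {
    cand <- stats::rlnorm(max(16L, 2L * (n - length(out))), meanlog, dist$sdlog)
    out <- c(out, cand[cand >= lo & cand <= hi])
  }
  out[seq_len(n)]
}

#' Specification of a synthetic staging cohort
#'
#' Defaults reproduce the structure of the reference cohort: node-level
#' malignancy prevalence 28.7\%, 1--6 nodes per patient with median 3,
#' nodal stations with the observed station frequencies, patient covariates
#' uniform inside the inclusion windows (fasting glucose <= 8.3 mmol/L,
#' uptake time 46--68 min, injected activity 226--245 MBq), and per-class
#' feature distributions calibrated to the reference class summaries.
#'
#' @param n_patients Number of patients to generate.
#' @param malignancy_prevalence Per-node probability of malignant histology.
#' @param nodes_per_patient_prob Probability vector over 1..6 nodes per
#'   patient; the default has median 3 and mean 3.28.
#' @param class_summaries Per-class median/range targets as returned by
#'   [reference_class_summaries()].
#' @param seed Integer seed; `simulate_cohort()` uses it for every draw.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 37L,
                        malignancy_prevalence = 0.287,
                        nodes_per_patient_prob = c(0.12, 0.20, 0.26, 0.20, 0.14, 0.08),
                        class_summaries = reference_class_summaries(),
                        seed = 1L) {
  if (n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (!(malignancy_prevalence > 0 && malignancy_prevalence < 1))
    stop("malignancy_prevalence must be in (0, 1)", call. = FALSE)
  if (length(nodes_per_patient_prob) != 6L || any(nodes_per_patient_prob < 0) ||
      sum(nodes_per_patient_prob) <= 0)
    stop("nodes_per_patient_prob must be 6 nonnegative weights", call. = FALSE)
  nodes_per_patient_prob <- nodes_per_patient_prob / sum(nodes_per_patient_prob)
  dists <- lapply(class_summaries, function(cls) {
    lapply(cls, function(f) class_distribution(f$median, f$low, f$high))
  })
  cs <- reference_data()$cohort_structure
  structure(list(n_patients = as.integer(n_patients),
                 malignancy_prevalence = malignancy_prevalence,
                 nodes_per_patient_prob = nodes_per_patient_prob,
                 distributions = dists,
                 stations = cs$stations,
                 station_prob = cs$station_counts / sum(cs$station_counts),
                 glucose_range = c(3.9, cs$glucose_max_mmol_per_l),
                 uptake_time_range = cs$uptake_time_min_range,
                 activity_range = cs$activity_mbq_range,
                 weight_range = c(55, 95),
                 age_range = cs$age_range,
                 male_fraction = cs$male_fraction,
                 subtype_prob = unlist(cs$histology_subtype_counts) /
                   sum(unlist(cs$histology_subtype_counts)),
                 suvmean_frac = c(0.55, 0.85),
                 suvpeak_frac = c(0.80, 0.98),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Reference-consistency compensation. Sharing one reference per patient
# rigidly ties the class contrast of the final log ratios to the class
# contrast of log SUVmax; whenever the calibration targets imply a different
# contrast for a ratio (excess D = d_mu_r[o] - d_mu_S, with d_mu_* the
# malignant-minus-benign differences of the truncated distributions'
# log-means), the shared reference must itself correlate with the patient's
# class composition. The generator induces exactly the required correlation
# by shifting the latent ratio draws that feed the implied references: for a
# node of class c in an n-node patient the per-organ log shift is
#   benign:    -(n-1) *  p      * D[o]
#   malignant: +(n-1) * (1 - p) * D[o]
# (p = malignancy prevalence). Because each draw enters the patient
# reference with weight 1/n, these shifts cancel the class-mixing bias of
# the final class-conditional log-ratio means exactly, for every n.
ratio_log_shifts <- function(spec) {
  d <- spec$distributions
  d_mu_s <- truncated_log_mean(d$malignant$suvmax) -
    truncated_log_mean(d$benign$suvmax)
  shifts <- list(benign = numeric(0), malignant = numeric(0))
  for (organ in RATIO_FEATURES) {
    d_mu_r <- truncated_log_mean(d$malignant[[organ]]) -
      truncated_log_mean(d$benign[[organ]])
    excess <- d_mu_r - d_mu_s
    shifts$benign[organ] <- -spec$malignancy_prevalence * excess
    shifts$malignant[organ] <- (1 - spec$malignancy_prevalence) * excess
  }
  shifts
}

#' Generate a synthetic staging cohort
#'
#' For every patient: covariates are drawn uniformly inside their inclusion
#' windows; the node count comes from the 1--6 distribution; each node's
#' class is an independent Bernoulli draw at the malignancy prevalence; node
#' SUVmax and four target node-to-reference ratios are drawn from the
#' class-conditional calibrated distributions; the patient's shared
#' reference uptakes are the geometric means of the per-node implied
#' references (`suvmax / target ratio`), after which the ratios actually
#' carried by the cohort are recomputed against the shared references
#' (reference-consistency step, with analytic pre-compensation of the
#' class-mixing bias; see the package vignette). SUVmean and SUVpeak are
#' fixture conventions: uniform fractions 0.55--0.85 and 0.80--0.98 of
#' SUVmax.
#'
#' Regenerating with the same spec and seed is bit-identical.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return An `ln_cohort` with attributes `spec`, `seed` and `latent` (the
#'   per-node latent draws: class, raw SUVmax, target ratios).
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  shifts <- ratio_log_shifts(spec)
  d <- spec$distributions
  runif1 <- function(range) stats::runif(1, range[1], range[2])
  rows <- vector("list", spec$n_patients)
  latent <- vector("list", spec$n_patients)

  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%04d", p)
    n_nodes <- sample.int(6L, 1L, prob = spec$nodes_per_patient_prob)
    glucose <- runif1(spec$glucose_range)
    uptake <- runif1(spec$uptake_time_range)
    activity <- runif1(spec$activity_range)
    weight <- runif1(spec$weight_range)
    age <- sample(seq(spec$age_range[1], spec$age_range[2]), 1L)
    sex <- if (stats::runif(1) < spec$male_fraction) "m" else "f"
    subtype <- sample(names(spec$subtype_prob), 1L, prob = spec$subtype_prob)

    cls <- ifelse(stats::runif(n_nodes) < spec$malignancy_prevalence,
                  "malignant", "benign")
    suv <- numeric(n_nodes)
    target_ratio <- matrix(NA_real_, n_nodes, length(RATIO_FEATURES),
                           dimnames = list(NULL, RATIO_FEATURES))
    for (j in seq_len(n_nodes)) {
      suv[j] <- draw_class_distribution(1L, d[[cls[j]]]$suvmax)
      for (organ in RATIO_FEATURES) {
        target_ratio[j, organ] <- draw_class_distribution(
          1L, d[[cls[j]]][[organ]],
          shift_log = (n_nodes - 1) * shifts[[cls[j]]][organ])
      }
    }
    # shared references: geometric mean of per-node implied references
    refs <- exp(colMeans(log(suv / target_ratio)))
    station <- sample(spec$stations, n_nodes, replace = TRUE,
                      prob = spec$station_prob)
    size_meanlog <- ifelse(cls == "malignant", log(15), log(10))
    short_axis <- stats::rlnorm(n_nodes, size_meanlog, 0.45)
    suvmean <- suv * stats::runif(n_nodes, spec$suvmean_frac[1], spec$suvmean_frac[2])
    suvpeak <- suv * stats::runif(n_nodes, spec$suvpeak_frac[1], spec$suvpeak_frac[2])

    rows[[p]] <- data.frame(
      patient_id = pid,
      node_id = sprintf("%s_N%d", pid, seq_len(n_nodes)),
      station = station,
      short_axis_mm = round(short_axis, 1),
      suvmax = suv, suvmean = suvmean, suvpeak = suvpeak,
      histology = cls,
      primary_suvmax = refs[["primary"]], liver_suvmax = refs[["liver"]],
      brainstem_suvmax = refs[["brainstem"]], lung_suvmax = refs[["lung"]],
      glucose_mmol_per_l = glucose, uptake_time_min = uptake,
      injected_activity_mbq = activity, body_weight_kg = weight,
      age_years = age, sex = sex, histology_subtype = subtype,
      stringsAsFactors = FALSE)
    latent[[p]] <- data.frame(node_id = rows[[p]]$node_id, class = cls,
                              suvmax_draw = suv, target_ratio,
                              stringsAsFactors = FALSE)
  }

  cohort <- ln_cohort(do.call(rbind, rows))
  attr(cohort, "spec") <- spec
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "latent") <- do.call(rbind, latent)
  cohort
}
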
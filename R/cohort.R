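# ---------------------------------------------------------------------------
# Cohort data model: flat per-node tables with patient-level fields repeated.
# ---------------------------------------------------------------------------

#' Column names of the flat cohort CSV schema
#'
#' One row per lymph node; patient-level fields are repeated on every row of
#' that patient. All SUVs are body-weight-normalised standardized uptake
#' values; reference uptakes are the SUVmax of the primary tumour, a 5 cm
#' liver VOI, a 2 cm brainstem VOI and a 5 cm VOI in the contralateral
#' (non-tumour) lung.
#'
#' @return Character vector of mandatory column names, in canonical order.
#' @export
cohort_columns <- function() {
  c("patient_id", "node_id", "station", "short_axis_mm",
    "suvmax", "suvmean", "suvpeak", "histology",
    "primary_suvmax", "liver_suvmax", "brainstem_suvmax", "lung_suvmax",
    "glucose_mmol_per_l", "uptake_time_min", "injected_activity_mbq",
    "body_weight_kg", "age_years", "sex", "histology_subtype")
}

PATIENT_COLUMNS <- c("patient_id", "primary_suvmax", "liver_suvmax",
                     "brainstem_suvmax", "lung_suvmax", "glucose_mmol_per_l",
                     "uptake_time_min", "injected_activity_mbq",
                     "body_weight_kg", "age_years", "sex", "histology_subtype")

NODE_COLUMNS <- c("patient_id", "node_id", "station", "short_axis_mm",
                  "suvmax", "suvmean", "suvpeak", "histology")

VALID_STATIONS <- c(2L, 4L, 5L, 6L, 7L, 10L, 11L, 12L)
GLUCOSE_MAX <- 8.3
UPTAKE_WINDOW <- c(45, 70)
MAX_NODES_PER_PATIENT <- 6L

#' Construct a validated lymph-node cohort
#'
#' Builds an `ln_cohort` object from a flat data frame in the
#' [cohort_columns()] schema, enforcing the study's inclusion criteria and
#' per-node consistency rules. Violations are reported with the offending
#' row index and field.
#'
#' Enforced invariants: fasting glucose <= 8.3 mmol/L; uptake time within
#' 45--70 min; positive activity, weight and SUVs; `suvmean <= suvmax` and
#' `suvpeak <= suvmax`; station one of 2/4/5/6/7/10/11/12; histology
#' benign/malignant; patient-level fields constant within a patient; 1--6
#' nodes per patient.
#'
#' @param data Data frame with the columns of [cohort_columns()].
#' @return An object of class `ln_cohort`: a list with elements `patients`
#'   (one row per patient) and `nodes` (one row per node).
#' @export
ln_cohort <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(data))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- data[cohort_columns()]
  problems <- character(0)
  note <- function(row, field, msg) {
    problems <<- c(problems, sprintf("row %d [%s]: %s", row, field, msg))
  }

  num_fields <- c("short_axis_mm", "suvmax", "suvmean", "suvpeak",
                  "primary_suvmax", "liver_suvmax", "brainstem_suvmax",
                  "lung_suvmax", "glucose_mmol_per_l", "uptake_time_min",
                  "injected_activity_mbq", "body_weight_kg", "age_years")
  for (f in num_fields) {
    v <- suppressWarnings(as.numeric(data[[f]]))
    bad <- which(is.na(v) | !is.finite(v))
    for (r in bad) note(r, f, sprintf("non-numeric value '%s'", data[[f]][r]))
    data[[f]] <- v
  }
  for (f in c("patient_id", "node_id", "histology", "sex", "histology_subtype")) {
    data[[f]] <- as.character(data[[f]])
  }
  data$station <- suppressWarnings(as.integer(data$station))

  ok <- function(v) !is.na(v) & is.finite(v)
  for (r in seq_len(nrow(data))) {
    d <- data[r, ]
    if (!nzchar(d$patient_id) || is.na(d$patient_id)) note(r, "patient_id", "empty")
    if (!nzchar(d$node_id) || is.na(d$node_id)) note(r, "node_id", "empty")
    if (is.na(d$station) || !(d$station %in% VALID_STATIONS))
      note(r, "station", sprintf("'%s' not a valid nodal station (%s)",
                                 d$station, paste(VALID_STATIONS, collapse = "/")))
    if (ok(d$short_axis_mm) && d$short_axis_mm < 0)
      note(r, "short_axis_mm", "must be >= 0")
    for (f in c("suvmax", "suvmean", "suvpeak", "primary_suvmax",
                "liver_suvmax", "brainstem_suvmax", "lung_suvmax")) {
      if (ok(d[[f]]) && d[[f]] <= 0) note(r, f, "must be > 0")
    }
    if (ok(d$suvmean) && ok(d$suvmax) && d$suvmean > d$suvmax + 1e-12)
      note(r, "suvmean", "suvmean must not exceed suvmax")
    if (ok(d$suvpeak) && ok(d$suvmax) && d$suvpeak > d$suvmax + 1e-12)
      note(r, "suvpeak", "suvpeak must not exceed suvmax")
    if (!(d$histology %in% c("benign", "malignant")))
      note(r, "histology", sprintf("'%s' not benign/malignant", d$histology))
    if (ok(d$glucose_mmol_per_l) && d$glucose_mmol_per_l > GLUCOSE_MAX)
      note(r, "glucose_mmol_per_l",
           sprintf("%.2f violates the inclusion criterion <= %.1f mmol/L",
                   d$glucose_mmol_per_l, GLUCOSE_MAX))
    if (ok(d$uptake_time_min) &&
        (d$uptake_time_min < UPTAKE_WINDOW[1] || d$uptake_time_min > UPTAKE_WINDOW[2]))
      note(r, "uptake_time_min",
           sprintf("%.1f outside the inclusion window %g-%g min",
                   d$uptake_time_min, UPTAKE_WINDOW[1], UPTAKE_WINDOW[2]))
    if (ok(d$injected_activity_mbq) && d$injected_activity_mbq <= 0)
      note(r, "injected_activity_mbq", "must be > 0")
    if (ok(d$body_weight_kg) && d$body_weight_kg <= 0)
      note(r, "body_weight_kg", "must be > 0")
    if (!(d$sex %in% c("f", "m"))) note(r, "sex", sprintf("'%s' not f/m", d$sex))
    if (!(d$histology_subtype %in% c("AC", "SCC", "SCLC", "NSCLC_NOS")))
      note(r, "histology_subtype", sprintf("unknown subtype '%s'", d$histology_subtype))
  }

  # patient-level consistency and node counts
  if (length(problems) == 0L) {
    if (anyDuplicated(data$node_id)) {
      dup <- data$node_id[duplicated(data$node_id)]
      problems <- c(problems, sprintf("duplicated node_id: %s",
                                      paste(unique(dup), collapse = ", ")))
    }
    for (pid in unique(data$patient_id)) {
      idx <- which(data$patient_id == pid)
      if (length(idx) > MAX_NODES_PER_PATIENT)
        problems <- c(problems,
                      sprintf("patient %s has %d nodes (max %d)", pid,
                              length(idx), MAX_NODES_PER_PATIENT))
      for (f in setdiff(PATIENT_COLUMNS, "patient_id")) {
        if (length(unique(data[[f]][idx])) > 1L)
          problems <- c(problems,
                        sprintf("patient %s: inconsistent patient-level field '%s'",
                                pid, f))
      }
    }
  }

  if (length(problems) > 0L) {
    stop("invalid cohort (", length(problems), " problem(s)):\n  ",
         paste(utils::head(problems, 20L), collapse = "\n  "), call. = FALSE)
  }

  patients <- data[!duplicated(data$patient_id), PATIENT_COLUMNS]
  rownames(patients) <- NULL
  nodes <- data[NODE_COLUMNS]
  rownames(nodes) <- NULL
  structure(list(patients = patients, nodes = nodes), class = "ln_cohort")
}

#' @export
print.ln_cohort <- function(x, ...) {
  n_mal <- sum(x$nodes$histology == "malignant")
  cat(sprintf("Lymph-node cohort: %d patients, %d nodes (%d malignant, %.1f%%)\n",
              nrow(x$patients), nrow(x$nodes), n_mal,
              100 * n_mal / nrow(x$nodes)))
  tab <- table(factor(x$nodes$station, levels = VALID_STATIONS))
  cat("Stations:", paste(sprintf("%s(n=%d)", names(tab), as.integer(tab)),
                         collapse = " "), "\n")
  invisible(x)
}

#' Flatten a cohort to the canonical one-row-per-node data frame
#'
#' @param x An `ln_cohort`.
#' @param ... Unused.
#' @return Data frame in the [cohort_columns()] schema.
#' @export
as.data.frame.ln_cohort <- function(x, ...) {
  m <- match(x$nodes$patient_id, x$patients$patient_id)
  flat <- cbind(x$nodes,
                x$patients[m, setdiff(PATIENT_COLUMNS, "patient_id"),
                           drop = FALSE])
  flat <- flat[cohort_columns()]
  rownames(flat) <- NULL
  flat
}

#' Read a cohort CSV
#'
#' Comma-separated, UTF-8, header row mandatory, decimal point. The file is
#' validated on load; rows violating the cohort invariants abort the read
#' with row-indexed diagnostics.
#'
#' @param path Path to a CSV file in the [cohort_columns()] schema.
#' @return An `ln_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  ln_cohort(data)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` reproduces
#' `x` field for field.
#'
#' @param cohort An `ln_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ln_cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Contingency tables
# ---------------------------------------------------------------------------

#' Build a 2x2 contingency table from a continuous feature and histology
#'
#' Test positivity is `value >= cutoff` (inclusive), matching the score
#' conditions used throughout the package; the reference standard is the
#' histology label.
#'
#' @param values Numeric vector of per-node feature values.
#' @param labels Character/factor vector of `"benign"`/`"malignant"`, same
#'   length as `values`.
#' @param cutoff Positivity threshold (inclusive).
#' @return A `contingency` object: list with integer cells `tn`, `fp`,
#'   `fn`, `tp`.
#' @examples
#' build_contingency(c(5.495, 5.494), c("malignant", "benign"), 5.495)
#' @export
build_contingency <- function(values, labels, cutoff) {
  labels <- as.character(labels)
  if (length(values) != length(labels))
    stop("values and labels must have the same length", call. = FALSE)
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite feature value", call. = FALSE)
  if (!all(labels %in% c("benign", "malignant")))
    stop("labels must be 'benign' or 'malignant'", call. = FALSE)
  if (!is.finite(cutoff)) stop("cutoff must be finite", call. = FALSE)
  pos <- values >= cutoff
  mal <- labels == "malignant"
  contingency(tn = sum(!mal & !pos), fp = sum(!mal & pos),
              fn = sum(mal & !pos), tp = sum(mal & pos))
}

#' Construct a contingency table from its four cells
#'
#' @param tn,fp,fn,tp Nonnegative integer cell counts (true negative, false
#'   positive, false negative, true positive).
#' @return A `contingency` object.
#' @export
contingency <- function(tn, fp, fn, tp) {
  cells <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be nonnegative integers", call. = FALSE)
  if (sum(cells) < 1) stop("contingency table must contain at least one count",
                           call. = FALSE)
  cells <- as.integer(round(cells))
  structure(list(tn = cells[1], fp = cells[2], fn = cells[3], tp = cells[4]),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), nrow = 2, byrow = TRUE,
              dimnames = list(c("histo neg", "histo pos"),
                              c("test neg", "test pos")))
  print(m)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Bundled reference results (the 101-node staging cohort)
# ---------------------------------------------------------------------------

reference_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "reference_tables.json", package = "petln",
                          mustWork = TRUE)
      cache <<- jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cache
  }
})

#' Reference cross tables of the 101-node staging cohort
#'
#' The five 2x2 cross tables (histology versus PET positivity at the
#' published cut-offs) for SUVmax and the four reference-tissue ratios, as
#' observed in the prospective 101-node cohort bundled with the package.
#' Every table has class margins 29 malignant / 72 benign.
#'
#' @return Named list of [contingency()] objects, keyed `suvmax`,
#'   `primary`, `liver`, `brainstem`, `lung`.
#' @export
reference_cross_tables <- function() {
  ct <- reference_data()$cross_tables
  lapply(ct, function(t) contingency(tn = t$tn, fp = t$fp, fn = t$fn, tp = t$tp))
}

#' Class-conditional feature summaries of the reference cohort
#'
#' Median and range of SUVmax and of the four ratios, separately for benign
#' and malignant nodes; these summaries calibrate the synthetic cohort
#' generator.
#'
#' @return Nested list: `$benign` / `$malignant`, each a list per feature
#'   with elements `median`, `low`, `high`.
#' @export
reference_class_summaries <- function() {
  reference_data()$class_summaries
}

#' Published performance metrics of the reference cohort
#'
#' The per-feature cut-offs, AUCs with 95\% confidence intervals, and the
#' five operating characteristics as originally reported, used by
#' [reproduce_tables()] for side-by-side comparison with the package's own
#' recomputation.
#'
#' @return List with elements `cutoffs`, `published_metrics`,
#'   `score_cutoffs`, `cohort_structure`.
#' @export
reference_results <- function() {
  d <- reference_data()
  d[c("cutoffs", "published_metrics", "score_cutoffs", "cohort_structure")]
}
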
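{
  "description": "Reference results from the prospective 101-node thoracic lymph-node staging cohort bundled with petln: per-feature 2x2 cross tables (histology vs PET positivity at the published cut-offs), the published performance metrics, the score cut-offs, and the class-conditional feature summaries (median and range) used to calibrate the synthetic cohort generator.",
  "n_nodes": 101,
  "n_malignant": 29,
  "n_benign": 72,
  "cutoffs": {
    "suvmax": 5.495,
    "primary": 0.457,
    "liver": 1.374,
    "brainstem": 0.749,
    "lung": 4.593
  },
  "cross_tables": {
    "suvmax": {"tn": 64, "fp": 8, "fn": 3, "tp": 26},
    "primary": {"tn": 58, "fp": 14, "fn": 6, "tp": 23},
    "liver": {"tn": 59, "fp": 13, "fn": 3, "tp": 26},
    "brainstem": {"tn": 56, "fp": 16, "fn": 5, "tp": 24},
    "lung": {"tn": 53, "fp": 19, "fn": 0, "tp": 29}
  },
  "published_metrics": {
    "suvmax": {"sensitivity": 89.67, "specificity": 88.89, "ppv": 76.47, "npv": 95.52, "accuracy": 89.11, "auc": 0.92, "ci_low": 0.85, "ci_high": 0.98},
    "primary": {"sensitivity": 79.31, "specificity": 80.56, "ppv": 62.16, "npv": 90.63, "accuracy": 80.20, "auc": 0.86, "ci_low": 0.78, "ci_high": 0.94},
    "liver": {"sensitivity": 89.66, "specificity": 81.94, "ppv": 66.67, "npv": 95.16, "accuracy": 84.16, "auc": 0.91, "ci_low": 0.85, "ci_high": 0.98},
    "brainstem": {"sensitivity": 82.76, "specificity": 77.78, "ppv": 60.00, "npv": 91.80, "accuracy": 79.21, "auc": 0.88, "ci_low": 0.81, "ci_high": 0.95},
    "lung": {"sensitivity": 100.00, "specificity": 73.61, "ppv": 60.42, "npv": 100.00, "accuracy": 81.89, "auc": 0.94, "ci_low": 0.89, "ci_high": 0.98},
    "visual": {"sensitivity": 34.48, "specificity": 95.83, "ppv": 76.92, "npv": 78.41, "accuracy": 78.22, "auc": 0.81, "ci_low": 0.72, "ci_high": 0.89},
    "multiscore": {"sensitivity": 89.66, "specificity": 86.11, "ppv": 72.22, "npv": 95.38, "accuracy": 87.13, "auc": 0.93, "ci_low": 0.88, "ci_high": 0.98}
  },
  "score_cutoffs": {"visual": 3, "multiscore": 3},
  "class_summaries": {
    "benign": {
      "suvmax": {"median": 3.45, "low": 1.14, "high": 19.00},
      "primary": {"median": 0.22, "low": 0.06, "high": 1.27},
      "liver": {"median": 0.92, "low": 0.28, "high": 4.42},
      "brainstem": {"median": 0.52, "low": 0.14, "high": 3.88},
      "lung": {"median": 3.47, "low": 1.08, "high": 19.00}
    },
    "malignant": {
      "suvmax": {"median": 11.00, "low": 2.35, "high": 35.55},
      "primary": {"median": 0.75, "low": 0.13, "high": 2.42},
      "liver": {"median": 3.18, "low": 0.63, "high": 11.19},
      "brainstem": {"median": 1.63, "low": 0.51, "high": 8.46},
      "lung": {"median": 14.67, "low": 4.60, "high": 50.61}
    }
  },
  "cohort_structure": {
    "malignancy_prevalence": 0.287,
    "nodes_per_patient_range": [1, 6],
    "nodes_per_patient_median": 3,
    "stations": [2, 4, 5, 6, 7, 10, 11, 12],
    "station_counts": [6, 21, 8, 3, 27, 18, 16, 2],
    "glucose_max_mmol_per_l": 8.3,
    "uptake_time_min_range": [46, 68],
    "activity_mbq_range": [226, 245],
    "age_range": [52, 83],
    "male_fraction": 0.6486,
    "histology_subtype_counts": {"AC": 19, "SCC": 16, "SCLC": 1, "NSCLC_NOS": 1}
  }
}
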
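---
title: "Quantitative PET lymph-node staging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative PET lymph-node staging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petln)
```

## The problem and the model

Pre-operative N-staging of lung cancer hinges on deciding, node by node,
whether a hilar or mediastinal lymph node is malignant. Visual FDG-PET/CT
reading does this well but is subjective; `petln` implements the
quantitative alternative: treat each node's uptake — SUVmax and its ratios
to reference tissues — as a continuous diagnostic test against the
histologic reference standard, and report the whole apparatus of
diagnostic-accuracy statistics for it.

The analysis is deliberately simple and fully specified:

1. **Features.** Per node: SUVmax and the four ratios of node SUVmax to the
   SUVmax of the primary tumour, liver (5 cm VOI), brainstem (2 cm VOI) and
   contralateral non-tumour lung (5 cm VOI). Ratios to the liver and lung
   are intended to cancel inter-patient differences in glucose metabolism
   and inflammatory lung background; the ratio to the primary cancels
   histology-subtype differences in avidity.
2. **Scores.** A quantified visual score (1–3, ordered comparisons against
   liver then primary) and a multifactorial score (0–5) counting how many
   of five thresholded conditions a node meets. Both are dichotomised at
   score ≥ 3.
3. **Performance.** Empirical ROC curves (positivity: value ≥ threshold),
   trapezoidal AUC (equal to the tie-corrected concordance probability),
   confidence intervals, optimal cut-offs by minimum Euclidean distance to
   the (0, 1) corner, and the five 2×2 operating characteristics.

The key modelling assumption throughout is **node-level independence**:
nodes are analysed as independent observations even when several come from
one patient, matching the per-node cross-table design of the reference
cohort. No clustering correction is applied; AUC confidence intervals are
therefore slightly anticonservative when within-patient correlation is
present.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| score thresholds | 5.495 / 0.457 / 1.374 / 0.749 / 4.593 | SUV, ratios | the five score conditions; overridable, or re-derivable from data |
| score cut-off | 3 | points | positivity of visual and multifactorial scores |
| CI method | DeLong | — | AUC interval; Hanley–McNeil available |
| confidence level | 0.95 | — | AUC intervals |
| half-life | 109.77 | min | F-18 decay correction in SUV normalisation |
| SUVpeak sphere | 1.0 | mL | averaging sphere (diameter ≈ 12.4 mm) |
| voxel spacing | 1.5 × 1.5 × 5.0 | mm | default synthetic grid |

Thresholds are data, not constants: `ln_staging(..., cutoff_mode =
"derive")` re-derives all five from the cohort at hand and feeds the
derived values into the multifactorial score, making the two-stage
construction (derive cut-offs, then use them as score conditions) explicit.

## Numerical and procedural choices

- **Inclusive positivity.** Every comparison against a threshold uses ≥,
  uniformly: score conditions, contingency building, ROC thresholds. A node
  exactly at a cut-off is positive.
- **Optimal cut-off tie-break.** When two operating points have equal
  distance $d$, the higher-specificity point wins, then the lower
  threshold. The reference procedure is silent here; this rule is the
  package's own and is applied deterministically.
- **AUC ties.** Tied case/control values count 1/2 in the concordance;
  the trapezoid under the empirical curve equals this by construction, and
  the test suite asserts the identity against an $O(n^2)$ pairwise oracle.
- **DeLong default.** The reference analysis does not name its CI method;
  the package defaults to DeLong's nonparametric variance (the de-facto
  standard) and offers Hanley–McNeil because legacy software commonly used
  it. The method used is recorded in every report.
- **Group comparison.** Class summaries are medians with ranges, so the
  two-group test is the two-sided Mann–Whitney U (normal approximation,
  continuity- and tie-corrected); identical groups give p = 1.
- **Rounding.** Percentages are reported rounded half-up to two decimals;
  all raw fractions are retained and used for computation. The recomputed
  reference table therefore shows 89.66% where 26/29 was originally
  printed as 89.67%, and 81.19% where 82/101 was printed as 81.89% — both
  flagged as caveats rather than matched.
- **Degenerate visual ordering.** If a patient's primary uptake is below
  the liver's, the visual-score rules are applied in their listed order
  (first match wins), so such a node gets score 1; the case is warned
  about because the ordering is then ambiguous.
- **SUVpeak.** Never formally defined in the reference procedure; the
  package uses the EANM-style convention: candidate centers at voxel
  centers inside the VOI, mean over a 1.0 mL sphere, sphere clipped at the
  volume boundary but allowed to extend beyond the VOI.
- **Voxel membership.** Center-in-sphere, no partial-volume weighting —
  simple, orientation-invariant and exactly reproducible by a brute-force
  oracle. Physical coordinates put the origin at the center of the first
  voxel, axes (x, y, z) with the given spacing; NIfTI affines are not
  interpreted beyond the voxel spacing.
- **Undefined metrics.** A metric with a zero denominator (e.g. PPV with
  no positive calls) is `NA`, never 0.

## The synthetic cohort generator

No per-node raw data are published for the reference cohort, so the
generator emulates its *printed* statistical structure:

- node-level malignancy prevalence 28.7%, nodes per patient on 1–6 with
  median 3 (default pmf 0.12/0.20/0.26/0.20/0.14/0.08, mean 3.28, chosen
  once as a realistic shape consistent with the printed median and range);
- per-class SUVmax and ratio distributions as **truncated log-normals**:
  location = log median, scale such that the central 99.5% interval of the
  untruncated distribution spans the printed range, truncation to the
  range by rejection. Log-normals were chosen because all class summaries
  are positive and right-skewed medians-with-ranges; the true family is
  unknown;
- patient covariates uniform inside the inclusion windows (fasting glucose
  3.9–8.3 mmol/L, uptake time 46–68 min, injected activity 226–245 MBq),
  ages 52–83, 65% male, subtype frequencies as observed;
- SUVmean = SUVmax × U(0.55, 0.85) and SUVpeak = SUVmax × U(0.80, 0.98):
  fixture conventions enforcing the partial-volume ordering, not estimates.

### The reference-consistency step

References (liver, brainstem, lung, primary SUVmax) are drawn **once per
patient** and shared by all of that patient's nodes, while node classes
are independent Bernoulli draws. This creates a structural tension: with a
truly class-independent shared reference, the class contrast of the log
ratios is forced to equal the class contrast of log SUVmax, but the
calibration targets imply a *larger* contrast for the lung ratio
(3.47 → 14.67, versus SUVmax 3.45 → 11.00). The data thus demand that the
lung background correlate negatively with the patient's nodal involvement.

The generator induces exactly the required correlation. Per node it draws
SUVmax and four target ratios from the class-conditional distributions,
sets the patient's references to the geometric means of the implied
per-node references (SUVmax / target ratio), and recomputes the final
ratios against the shared references. Averaging across nodes of mixed
class would bias the class-conditional log-ratio means by
$\frac{n-1}{n}\,w_c\,(\Delta\mu_{r,o} - \Delta\mu_S)$ (with $n$ the
patient's node count, $w_c$ the opposite-class probability and
$\Delta\mu$ the malignant–benign differences of the truncated
distributions' log-means). Because each latent draw enters the patient
reference with weight $1/n$, shifting the latent ratio draws of benign
nodes by $-(n-1)\,p\,(\Delta\mu_{r,o}-\Delta\mu_S)$ and of malignant nodes
by $+(n-1)(1-p)(\Delta\mu_{r,o}-\Delta\mu_S)$ (shifting location and
truncation bounds together) cancels this bias exactly, for every $n$. The
correction is analytic — computed from the calibrated distributions, the
node-count distribution and the prevalence — and contains no fitted
constants.

At ~1,300 generated nodes the class-conditional sample medians of SUVmax
and of all four ratios land within a few percent of their targets, the
malignant fraction within about one point of 28.7%, and end-to-end AUCs
fall in roughly 0.94–0.98 — above the 0.86–0.94 reported for the real
cohort, as expected: the generator draws classes from cleanly separated
parametric families and omits the biological overlap that produces real
false calls (inflammatory nodes with SUVmax ~10, lepidic adenocarcinoma
metastases with SUVmax ~3.5). Passing calibration tests therefore shows
the pipeline is correct and the generator faithful to the printed
summaries — not that real-world accuracy would be this high.

What the generator does **not** model: within-patient correlation of node
classes, station-specific malignancy rates, scanner noise and
reconstruction effects, harmonisation differences between sites, and the
joint dependence between SUVmax and each ratio beyond what the
reference-sharing construction induces (the true joint law is unknowable
from printed marginals).

## Determinism

One integer seed drives every draw in `simulate_cohort()`; the global RNG
state is saved and restored, and identical spec + seed regenerates a
bit-identical cohort. Analysis (`ln_staging()`) is fully deterministic
given a cohort; reports serialize numbers at 17 significant digits so a
written report reloads value-exact.

## Problem sizes in the test suite

The suite checks the ROC machinery against brute-force oracles on 100
random cohorts of up to 60 nodes, the SUV metrics against exhaustive-loop
references on 50 random phantoms of up to 10×10×7 voxels, and generator
calibration on one 400-patient (~1,300-node) cohort — sizes chosen so the
oracles remain exhaustive (the point of an oracle) while the stochastic
checks have enough data that a 10% median tolerance is a real constraint.

## Known limitations

- Node-level independence ignores within-patient clustering; inference is
  per-node, not per-patient.
- The reference VOI convention follows the bundled ratio definitions
  (SUVmax of the reference VOI); sites using liver SUVmean will obtain
  shifted liver ratios and should re-derive cut-offs.
- The visual-score translation has known poor sensitivity at cut-off ≥ 3
  (its third level requires the node to outshine the primary tumour); it
  is included for completeness, not recommendation.
- Cut-offs bundled with the package come from a single-scanner cohort;
  `cutoff_mode = "derive"` exists precisely because they are unlikely to
  transfer unchanged to other devices or reconstruction protocols.
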
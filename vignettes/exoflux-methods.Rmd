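---
title: "Methods: serum exo-metabolome footprinting of transporter mutants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum exo-metabolome footprinting of transporter mutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A large fraction of bacterial membrane transporters — in *E. coli*, on
the order of a quarter of them — have no experimentally assigned
substrate. One way to find candidate substrates without prior
knowledge is metabolic footprinting: incubate cells briefly in a
chemically rich, physiologically plausible medium (human serum), and
watch which extracellular compounds fall (uptake) or rise (excretion)
in untargeted LC-MS peak-area time courses. Contrasting a wild type
(WT) with paired knockout (KO) and overexpression (OE) mutants of a
single transporter gene then attributes those movements to the
transporter: if overexpression speeds a compound's disappearance from
the medium and knockout slows it, the compound is a candidate uptake
substrate; the mirror pattern implies export. When both genotypes of
the pair tell the same story the call is *converged* — a dual
validation — and ranked above calls supported by one genotype alone.

`exoflux` implements this pipeline end to end on peak-area tables:
drift correction, QC filtering, deduplication, identification
confidence levels, import/export calling, mutant-vs-WT differential
selection, and KO/OE direction inference — plus a simulator that
generates the full experimental design with known ground truth.

## The experimental design the simulator emulates

Each simulated run contains, per strain, three technical replicates at
0, 5, 15 and 30 minutes of serum incubation; triplicate serum-only
control wells (no cells) at every time point, which expose compounds
that degrade or appear in serum by themselves; and pooled-QC
injections interleaved through the run (one every ten analytical
injections, plus one at each end). Compounds belong to one of five
kinetic classes:

* **IMPORTED** — expectation `baseline * exp(-r_s t)`; first-order
  depletion is the natural form for uptake from a large medium
  reservoir.
* **EXPORTED** — expectation `baseline * (1 + r_s t)`. The published
  time-course figures show near-linear accumulation over 30 min, and
  no functional form is stated, so linear kinetics are the default;
  a saturating alternative (exponential approach with a 15-minute
  time constant) is available via `export_kinetics = "saturating"`.
  This is an assumption of the simulator, not a claim about the
  biology.
* **SERUM_DEGRADING / SERUM_APPEARING** — the same decay/growth laws,
  but applied in *every* well including the cell-free controls.
* **INERT** — flat.

The strain-specific rate `r_s` multiplies the WT rate by `oe_factor`
(default 3) in the overexpression mutant of the compound's affected
gene, by `ko_factor` (default 0.3) in its knockout, and by 0 in the
serum-only control. The residual knockout activity reflects
transporter redundancy: deleting one transporter rarely abolishes
transport of its substrate, because paralogues with overlapping
specificity remain.

Defaults that are not fixed by the study design were chosen once as
values a metabolomics practitioner would call realistic and are not
tuned: replicate noise is multiplicative lognormal with a 10% CV
(peak areas are positive and heteroscedastic; mean-one lognormal
factors make the empirical replicate CV converge to the configured
value); WT import rates are drawn uniformly from 0.03–0.08 per minute
(30-minute survival fractions of roughly 0.09–0.41); export rates from
0.05–0.2 per minute (30-minute accumulation of 2.5–7-fold); baselines
log-uniform over 10^4–10^6; instrument drift is a smooth monotone
half-cosine over injection order spanning `1 ± drift_amplitude`
(default 10%; the drift-correction evaluations use 30%). Drift
multiplies every injection — QC and analytical alike — since that is
what instrument drift is physically and what QC-based correction
presumes. All randomness flows from a single integer seed, and the
same seed reproduces a run exactly.

What the simulator deliberately does **not** emulate: m/z and
chromatographic structure (isotopes, adducts, coeluting features),
missingness mechanisms, batch boundaries, non-monotone drift, and
correlated biological (pleiotropic) responses across compounds.
Passing the recovery tests therefore shows that the decision rules
recover the kinetic structure they were designed for at realistic
noise — not that real serum data are this clean. In particular, real
mutant contrasts suffer pleiotropy and tentative annotation, which no
synthetic benchmark can certify away.

## Preprocessing

**Drift correction (QC-RLSC).** Per feature, a LOESS curve (degree 1,
span 0.75) is fit to the pooled-QC intensities against injection
order, and every sample is divided by the fitted curve normalised to
the median QC intensity. The median, rather than the mean, anchors the
corrected scale robustly. Features with fewer than `min_qc_count = 5`
non-missing QC values, or with a non-finite/non-positive fitted curve,
pass through unchanged and are flagged rather than silently dropped.
The span can instead be selected automatically per feature by
corrected AIC (`loess_span = "aicc"`), using the smoother's trace as
the effective number of parameters; the fixed span is the default for
reproducibility. Samples outside the QC-covered injection range use
the boundary value of the curve. Degree 1 is deliberate: with as few
as five QC points a quadratic local fit is underdetermined, and the
drift being corrected is monotone.

**QC CV and deduplication.** The reproducibility filter is the percent
coefficient of variation over QC injections, computed *after*
correction (the order is not fixed by the source workflow; a
`qc_cv_raw` column preserves the before value). Features at CV ≤ 30%
enter uniqueness clustering: greedy grouping within 5 ppm neutral mass
and 0.1 min retention time, processed in descending median QC
intensity with lexicographic feature-id tie-break, so the result is
deterministic and independent of input row order. The tolerances are
package defaults — the workflow this implements filtered on "exact
mass and retention time" without stating tolerances.

**Log2 transform.** Statistical testing happens on log2 intensities.
Zeros and missing cells are imputed with half the feature's minimum
positive value first (zeros are treated as measurements below the
effective detection limit, not as absences); features with no positive
value at all are dropped. Both events are logged.

## Identification confidence levels

Evidence exported from spectral-library matching maps to the standard
1–5 confidence scale, best evidence first: an mzVault match score
strictly exceeding 70 gives level 1; an mzCloud score strictly
exceeding 70, level 2; a "Full match" annotation source, level 3; a
molecular formula, level 4; a confirmed molecular weight, level 5.
"Exceeding 70" is implemented as a strict inequality, and the ordering
is best-evidence-wins, the convention of this reporting scale. Summary
percentages are rounded half-up to integers, except that a nonzero
share that would round to 0% is reported with one decimal — the rule
that reproduces mixed cells like 39% next to 0.2% in the published
overview table.

## Import/export calling

A compound is called transported in a strain when at least one of
three criteria fires on the replicate-level time course:

1. linear regression of intensity on time with adjusted R² > 0.7;
2. exponential regression (`A e^{kt}`, fit by least squares on log
   intensities) with adjusted R² > 0.7, the R² computed on the
   original intensity scale from back-transformed fits with p = 2;
3. greater than 3-fold change between 0 and 15 min *and* greater than
   5-fold change between 0 and 30 min, both in the same direction,
   using replicate means and bidirectional ratios.

Fits use all replicate-level points (n = 12 at the full design) rather
than time-point means, which keeps the degrees of freedom honest;
"over the first 15 min" is read as the 0→15 contrast. Direction is
IMPORT when the 30-minute mean lies below the 0-minute mean, EXPORT
otherwise. Two flags accompany each call instead of silent filtering:
`serum_control_also_called` marks compounds whose serum-only control
wells satisfy the same rule in the same direction (serum-intrinsic
degradation or appearance, not transport), and `noisy` marks replicate
CV above 50% at any time point — a programmatic stand-in for the
manual triage of noisy curves that an analyst would otherwise do.
Downstream inference excludes serum-flagged compounds by default.

## Differential transport and direction inference

Two criteria compare each compound in a mutant against WT, and a
compound is selected when either fires:

* **Criterion A** — at 5, 15 or 30 min, a ≥ 2-fold change of the
  replicate mean relative to WT with *no overlap* between the two
  strains' replicate ranges (min–max; the strictest natural reading of
  "without any overlap").
* **Criterion B** — Welch's unequal-variance t-test on log2 values at
  each of the three time points, firing when the smallest p-value is
  below 0.01. The source workflow does not state which values its
  p < 0.01 test compared; per-time Welch on log2 values is the
  default, and a pooled-across-times variant sits behind
  `pooled = TRUE`. No multiple-testing correction is applied in
  selection, mirroring the raw-threshold workflow.

A calibration caveat worth knowing: with three replicates per group,
Welch's test is conservative — its true size at the 0.01 threshold is
about 0.0056 per test (Monte-Carlo), so the per-compound null firing
rate across three time points is about 0.017, below the nominal
`1 − 0.99³ ≈ 0.030`. The paired t-test used for volcano statistics
(t30 vs t0, paired by replicate) is essentially exact at the 0.05
level. Degenerate inputs are defined rather than erroring: identical
pairs give p = 1; zero-variance groups with different means give p = 0
and are the limit case of complete separation.

For each selected call the mutant's net relative change of the
replicate means over 0→30 min is compared with WT's: a
mutant depleting more than a depleting WT is `FASTER_DEPLETION`, less
is `SLOWER_DEPLETION`, with accumulation analogues; a flat WT defers
to the sign of the mutant's own change. No second effect-size
threshold is applied beyond selection itself — the source narrative
compares curves qualitatively after selection, and the package follows
that. The KO/OE merge is genotype-asymmetric by construction: OE
evidence implies a direction only through *enhanced* function
(faster depletion → uptake, faster accumulation → export), KO evidence
only through *impaired* function (slower depletion → uptake, slower
accumulation → export). Matching directions from both genotypes give
`UPTAKE_CONVERGED`/`EXPORT_CONVERGED`; one consistent item gives a
`*_SINGLE` verdict; sign patterns inconsistent with the simple
transporter model (e.g. faster depletion in both genotypes) give
`AMBIGUOUS`. The rank converged > single > ambiguous encodes dual
validation without inventing a numeric confidence score. Shared-and-
unique candidate sets across mutants are summarised as exclusive
(UpSet-style) intersection counts, which partition the union.

## Problem sizes and evaluation choices

The packaged evaluations run at sizes chosen to make Monte-Carlo
statements stable while staying desk-sized: the default simulated
design uses 100 compounds (12 imported, 12 exported, 6 + 6
serum-intrinsic, 64 inert) over two KO/OE transporter pairs; null
calibrations use 8,000–10,000 simulated inert compounds; recovery
statistics average 12–20 independent seeds. The acceptance script
(`scripts/acceptance.R`) recomputes every reported quantity from
scratch at run time from its `--seed`.

## Known limitations

* The simulator's kinetic forms (exponential uptake, linear export)
  are assumptions; sensitivity to them can be probed via
  `export_kinetics` but is not exhaustively mapped.
* Effects are encoded one-gene-per-compound; pleiotropy, compensating
  regulation and shared substrates across transporters are absent,
  and they are the dominant ambiguity in real contrasts.
* Deduplication tolerances and the CV-after-correction ordering are
  package choices where the source workflow is silent; both are
  switchable.
* Identification levels consume exported library scores; no spectral
  matching happens in the package, so level assignments are only as
  good as the upstream evidence.
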
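---
title: "Modelling and analysing 13C tracing of the TCA cycle in kidney tumours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing 13C tracing of the TCA cycle in kidney tumours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcatrace)
```

## The problem

Intraoperative infusion of ¹³C-labelled nutrients ([U-¹³C]glucose,
[1,2-¹³C]acetate, [U-¹³C]glutamine) followed by mass-spectrometric analysis
of resected tissue reveals how tumours and adjacent kidney use circulating
fuels. The observables are mass isotopologue distributions (MIDs: the
fractions of each metabolite carrying 0, 1, ..., C heavy carbons) and, for
glutamate, positional isotopomers (which carbons are labelled). Interpreting
them requires (i) a mechanistic model of how label propagates through the
TCA cycle, (ii) correction of raw spectra for naturally occurring heavy
isotopes, (iii) summary metrics with missing-value discipline, and (iv)
statistics that respect the nested fragment-within-patient design. This
package implements all four, together with a metabolomics QC pipeline,
gene-set survival scoring, and generators for synthetic cohorts so that
every stage is testable without patient data.

## The label-propagation model

### State space

Each metabolite pool with $C$ carbons is represented by a probability
vector over its $2^C$ binary carbon-labelling patterns (at most 64 states,
for citrate). This keeps the model exact: MIDs are pattern-count marginals
(`positional_to_mid()`), and positional species such as [4,5-¹³C]glutamate
are single coordinates of the state vector. We deliberately model discrete
*turns* rather than continuous-time fluxes: the questions the metrics
answer ("does label survive into a second turn?", "which route formed this
citrate?") are naturally posed per turn, and the discrete model is exact at
desk scale. Absolute flux estimation (¹³C-MFA), isotopically non-stationary
fitting and compartmentation are out of scope.

### Atom maps

A single numbering convention is fixed throughout (any convention works as
long as the observable anchors hold):

* citrate carbons 1–4 are the oxaloacetate carbons, 5–6 the acetyl
  carboxyl and methyl carbons;
* isocitrate dehydrogenase releases OAA C4; α-KG dehydrogenase releases
  α-KG C1 (OAA C1) — both first-turn CO₂ losses are OAA-derived;
* consequently the two acetyl carbons land on α-KG/glutamate carbons 4 and
  5, so first-turn metabolism of [1,2-¹³C]acetyl-CoA yields
  [4,5-¹³C]glutamate exclusively — the positional anchor;
* succinate and fumarate are symmetric; their distributions are averaged
  with the carbon reversal (exact 50/50 scrambling);
* pyruvate enters either through PDH (acetyl-CoA from pyruvate C2–C3, C1
  lost) or through carboxylation (OAA from pyruvate C1–C3 plus an
  unlabelled CO₂ carbon), so glucose can label first-turn citrate beyond
  m+2 when carboxylation is active;
* the reductive branch runs α-KG backwards: citrate gains one unlabelled
  CO₂-derived carbon, and cleavage returns a two-carbon acetyl unit and
  OAA → malate. Fully labelled α-KG gives citrate m+5 and malate m+3, the
  signature of reductive glutamine metabolism.

The tests verify every anchor by exhaustive enumeration over the pattern
space.

### Turn structure and parameters

A turn runs α-KG → succinate → fumarate → malate → OAA → citrate → α-KG.
The OAA inflow is a mixture controlled by `pc_fraction` (pyruvate
carboxylation), `anaplerosis_unlabelled` (unlabelled anaplerotic sources)
and `turnover`, the per-turn probability that malate-derived carbon
re-enters condensation. `turnover` is the knob behind multi-turn markers:
at `turnover = 0` no citrate m+4 can ever form from acetate, and the
citrate m+4/m+2 ratio is non-decreasing in `turnover` (a property test).
Entry pools are held constant at the tracer enrichment, emulating a
continuous infusion at steady plasma enrichment. Defaults: acetyl-CoA
enrichment 0.22 and glutamine-derived α-KG enrichment 0.32, mid-range of
the 20–25% acetyl-CoA and 30–35% glutamine m+5 plasma enrichments typical
of such infusions; `n_turns = 8`, by which point states are essentially
converged for `turnover < 1`.

Two modelling choices the data do not constrain were fixed once:
glutamate↔α-KG exchange defaults to full per-turn equilibration
(`glu_exchange = 1`), and a single `dilution` knob applies the same
unlabelled exchange to every pool (per-pool differences are not
identifiable from the observables we target). The reductive branch is
applied as a terminal mixing fraction of the citrate and malate pools
(`reductive_fraction`), not iterated — it is used as a route signature,
not a kinetic model. The glutamine entry is modelled as direct α-KG-pool
replacement at the stated enrichment.

## Natural-abundance correction

The measured spectrum of a derivatized fragment convolves the tracer MID
with the natural-isotope envelope of every other atom (backbone-adjacent
plus derivatization atoms — TBDMS groups contribute substantial C and Si)
and the residual ¹³C binomial of the unlabelled backbone carbons. The
forward model is a lower-triangular correction matrix; inversion uses
nonnegative least squares rather than direct matrix inversion because the
latter can return negative fractions on noisy spectra. Clamping events are
reported. The kernel is truncated to the instrument's m+0..m+C window and
renormalized, with the truncated mass reported. The round trip
`correct_mid(convolve_mid(x))` recovers `x` to well below 1e-8 (property
test over random MIDs with TBDMS-scale formulas). Isotope abundances
default to standard IUPAC values and are overridable, since correction
should match the instrument's reference table.

## Labelling metrics

All metrics operate on corrected MIDs: total labelling `1 − m+0`;
isotopologue ratios (citrate m+2/pyruvate m+3 for PDH contribution,
citrate m+4/m+2 for two-turn retention, citrate m+5 and malate m+3 for the
reductive route); plasma-normalized labelling; the [4,5-¹³C]glutamate
fraction of total glutamate labelling; and the respiratory control ratio
(state III / state IV oxygen consumption). Undefined ratios (zero
denominators, fully unlabelled glutamate) return reason-coded missing
values rather than raising, so cohort tables stay rectangular. The
[4,5-¹³C] fraction uses `1 − P(unlabelled)` as its denominator; for
positional data this coincides with the sum over labelled species.

```{r example}
kid <- simulate_tca(tracer_spec("acetate"), kidney_params())
tum <- simulate_tca(tracer_spec("acetate"), tumour_params())
c(kidney = kid$mids$citrate[5] / kid$mids$citrate[3],
  tumour = tum$mids$citrate[5] / tum$mids$citrate[3])
c(kidney = as.numeric(glu45_fraction(kid$states$glutamate)),
  tumour = as.numeric(glu45_fraction(tum$states$glutamate)))
```

A slow-turning, reductive-leaning parameter set reproduces all qualitative
directions observed in clear-cell tumours relative to kidney: lower
citrate m+2/pyruvate m+3, lower total labelling, lower citrate m+4/m+2,
higher [4,5-¹³C]glutamate fraction, higher citrate m+5.

## The QC pipeline

Stage order is fixed: per-feature signal-to-noise (QC median / blank
median) filtering → run-order trend test on QC injections (Spearman, BH
adjusted) → LOESS drift correction applied only to features with a
significant trend → total-ion-count normalization over a stable feature
subset → log₁₀ transformation → ionization-mode deduplication keeping the
higher-S/N measurement. Design decisions where the procedure leaves
freedom:

* thresholds default to common practice values (S/N ≥ 3, BH α = 0.05,
  LOESS span 0.75, stable subset CV ≤ 0.2 and S/N ≥ 10) and are all
  configurable;
* the trend statistic is Spearman's rank correlation (robust to monotone
  nonlinearity);
* "within the interquartile range" restricts the QC points entering the
  significance test to those inside the feature's QC IQR, guarding
  against single outlier injections;
* the LOESS is fitted on QC samples only (standard QC-based correction
  practice) and held flat beyond the QC-covered run-order range;
* zeros are imputed with half the feature's smallest positive value
  before the log; ties in the mode dedup keep positive mode. Every clamp,
  imputation, skip and tie-break is logged in the stage reports.

Cross-study comparison min-normalizes, log₁₀-transforms, computes Cohen's
d between tumour and normal, and correlates effect sizes over matched
HMDB identifiers.

## Scores and survival

The OxPhos score is the first principal component of log₂-transformed,
mean-centred, z-scaled expression of the gene set (KEGG oxidative
phosphorylation plus the PDH complex genes), sign-oriented to correlate
positively with mean set expression — without that convention "high
OxPhos" is ambiguous. Stratification supports a median split (ties at the
cut go to "low", deterministically) and a 30/70 quantile rule leaving the
middle 40% unlabelled, with optional grade/stage subcohort filters.
Kaplan–Meier curves and log-rank tests are delegated to the `survival`
package; the tests check them against a hand-computed product-limit table
and an exhaustive 252-assignment permutation oracle.

The nested fragment-within-patient comparison treats the patient as the
experimental unit: a two-level nested ANOVA of class against
between-patient variation, computed on equally weighted patient means. In
the balanced case this is algebraically the pooled-variance t-test on
patient means (verified in the tests); pooling fragments directly would
pseudoreplicate. A patient contributing fragments to both tissue classes
is split into two independent units — no pairing is assumed.

## Synthetic cohorts

The generators define the study conditions under which the pipeline is
validated:

* **Tracing cohorts**: per-patient parameters are log-normal
  perturbations (SD 0.25, a moderate interpatient variability) of the
  class prior; the default contrast is kidney-like (`turnover` 0.9, PDH
  fraction 0.75, reductive fraction 0.05) versus tumour-like (`turnover`
  0.45, PDH fraction 0.35, reductive fraction 0.3), 10 patients per class
  with 3 fragments each. Fragment-level measurement noise is Dirichlet
  with concentration κ = 500 (about 2% SD on major fractions), which
  preserves the simplex constraint by construction; Gaussian noise plus
  renormalization would not.
* **Feature tables**: log-normal intensities over a 150-injection batch
  with QC injections every fifth run (30 QCs), blanks at 1% of signal,
  QC replicate CV 5%, and optional multiplicative linear run-order drift.
  The QC density matters: the IQR-restricted Spearman test needs enough
  central QC points for drift at factor 2 to be detectable in essentially
  every replicate.
* **Survival cohorts**: a latent per-sample activity shifts the set genes
  and multiplies an exponential hazard by `exp(beta * z)`, with
  independent exponential censoring calibrated to the requested rate.

All generators are pure functions of their specification and seed. They
emulate the statistical structure the analyses assume — compositional
noise, hierarchical variance, drift, score-dependent hazard — but not
real-data features such as correlated metabolite panels, heteroscedastic
peak integration, batch effects across days, or non-proportional hazards;
passing tests demonstrate correctness of the computations under the
modelled structure, not robustness to everything real instruments do.

## Problem sizes and numerical choices

The validation suite uses desk-scale problem sizes chosen to make the
checks sharp but quick: exhaustive enumeration for every atom-map anchor;
100 random MIDs for the correction round trip (tolerance 1e-8); 10-point
parameter grids for monotonicity; 100 seeded cohorts (10+10 patients × 3
fragments) for the nested-detection rate; 200 seeded feature tables for
drift power; 2 000 replicates for log-rank type-I calibration. Probability
vectors are validated to 1e-9 after every operation; renormalization
tolerances at read time are 1e-6. Correction matrices are rejected when
their reciprocal condition number falls below 1e-12.

## Known limitations

The simulator is a single-compartment, discrete-turn model: it cannot
separate cytosolic from mitochondrial pools, estimate absolute fluxes, or
model CO₂ refixation beyond the reductive carboxylation carbon. The QC
pipeline assumes one batch per run (apply it per batch otherwise). The
survival analysis assumes proportional hazards in the synthetic
calibration and does not model competing risks.
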
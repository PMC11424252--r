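# tcatrace

Analysis toolkit for ¹³C-infusion tracing studies of kidney tumours and
adjacent kidney, for researchers working with stable-isotope tracing,
LC/GC-MS metabolomics and tumour expression/survival data.

Infusing patients with [U-¹³C]glucose, [1,2-¹³C]acetate or
[U-¹³C]glutamine during surgery and measuring mass isotopologue
distributions (MIDs, the fractions m+0..m+C of each metabolite carrying
0..C heavy carbons) in resected tissue reveals how tumours use circulating
fuels. `tcatrace` provides the computational core such a study needs:

* **An exact TCA-cycle label simulator** — each metabolite pool is a
  probability vector over its 2^C carbon-labelling patterns, propagated
  through discrete cycle turns with standard citrate-synthase/IDH/α-KGDH
  atom maps, symmetric-intermediate scrambling, pyruvate-carboxylase and
  anaplerotic entry, and a reductive-carboxylation branch. It reproduces
  the canonical signatures: first-turn acetate gives citrate m+2 and
  [4,5-¹³C]glutamate only; label retention into a second turn yields
  citrate m+4; oxidative glutamine gives m+4 intermediates; reductive
  glutamine gives citrate m+5 and malate m+3.
* **Natural-abundance correction** — forward convolution of tracer MIDs
  with the isotope envelope of derivatized fragments (TBDMS-scale
  formulas) and nonnegative-least-squares inversion of measured spectra,
  with an exact round trip.
* **Labelling metrics** — total labelling (1 − m+0), isotopologue ratios
  (citrate m+2/pyruvate m+3, citrate m+4/m+2, citrate m+5, malate m+3),
  plasma normalization, the [4,5-¹³C]glutamate fraction, respiratory
  control ratios; reason-coded missing values instead of exceptions.
* **A metabolomics QC pipeline** — signal-to-noise filtering, BH-adjusted
  run-order trend tests on QC injections, conditional LOESS drift
  correction, TIC normalization over a stable feature subset, log₁₀
  transformation, ionization-mode deduplication, and cross-study Cohen's
  d concordance.
* **Scores and survival** — gene-set PC1 scoring (KEGG OxPhos + PDH
  complex style sets), median and 30/70 stratification with grade/stage
  filters, Kaplan–Meier estimation, log-rank tests, nested
  fragment-within-patient comparisons, BH adjustment, Tukey/Dunnett
  ANOVA wrappers.
* **Synthetic cohort generators** — tracing cohorts with patient-level
  parameter variation and Dirichlet compositional noise, drifting feature
  tables with QC/blank structure, and expression/survival cohorts with a
  score-dependent hazard, so the whole pipeline is testable without
  patient data.

## Worked example

```r
library(tcatrace)

# mechanistic contrast: oxidative kidney vs slow-turning, reductive tumour
kid <- simulate_tca(tracer_spec("acetate"), kidney_params())
tum <- simulate_tca(tracer_spec("acetate"), tumour_params())
c(kidney = kid$mids$citrate[5] / kid$mids$citrate[3],
  tumour = tum$mids$citrate[5] / tum$mids$citrate[3])
#>     kidney     tumour
#> 0.10442132 0.05085172
```

Citrate m+4/m+2 — the fraction of label that survived into a second cycle
turn — is roughly halved under tumour-like parameters (low `turnover`),
mirroring the reduced two-turn retention seen in clear-cell tumours.

```r
# a full synthetic study: 10+10 patients x 3 fragments, Dirichlet noise
co <- generate_tracing_cohort(cohort_spec(), seed = 1)
m  <- fragment_metrics(co)
sub <- m[m$metric == "cit_m2_over_pyr_m3" & is.finite(m$value), ]
nc  <- nested_comparison(sub$value, sub$patient, sub$tissue)
round(unlist(nc$class_means), 3); signif(nc$p, 3)
#> adjacent_kidney           ccRCC
#>           0.982           0.445
#> [1] 3.64e-08
```

The nested test (patients as units, fragments nested within patients)
detects the lower tumour citrate m+2/pyruvate m+3 ratio — the PDH
contribution of glucose — without pseudoreplicating fragments.

```r
# natural-abundance round trip on a derivatized citrate fragment
f <- tbdms_formula("citrate")
x <- c(0.55, 0.05, 0.25, 0.05, 0.05, 0.03, 0.02)
max(abs(correct_mid(convolve_mid(x, f), f) - x))
#> [1] 2.220446e-16
```

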
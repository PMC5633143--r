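---
title: "Targeted 1H NMR metabolomics with PLS-DA VIP selection and data fusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted 1H NMR metabolomics with PLS-DA VIP selection and data fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrfusion)
```

## The problem this package addresses

`nmrfusion` re-implements, as a tested and reusable pipeline, a targeted
proton-NMR metabolomics analysis of a three-diet porcine atherosclerosis
cohort: 28 animals split into a balanced-diet group (BDG, n = 11), an
unbalanced Western-diet group (UDG, n = 9) and a regression group (RG, n = 8,
nine months of Western diet followed by three months of balanced diet), with
paired serum, urine and skeletal-muscle-tissue spectra plus a clinical
covariate table. Because no raw spectra from the original cohort are publicly
deposited, the package is built around a synthetic-cohort generator whose
defaults are calibrated to the published group statistics; every analysis
stage is then exercised as a recovery problem — the pipeline must read back
out of simulated spectra what the generator put in.

The analysis chain is:

1. **Spectral preprocessing** — chemical-shift referencing to a compartment
   anchor (alpha-glucose at 5.225 ppm for serum, TSP at 0.000 ppm for urine
   and tissue), segment-wise integer peak alignment against the median
   spectrum (icoshift-style), and probabilistic quotient normalization (PQN).
2. **Targeted quantification** — trapezoidal integration of fixed,
   non-overlapping ppm windows: 27 serum, 19 urine, 26 tissue metabolites.
3. **Univariate statistics** — left-to-right percentage differences (PD),
   signed relative standard deviations (RSD) and pooled-variance Student t
   tests for the three ordered comparisons BDG vs RG, RG vs UDG, BDG vs UDG.
4. **Chemometrics** — PLS-DA (NIPALS, class coded 0/1), 7-fold
   cross-validation, VIP scores with jackknife confidence intervals, the
   iterative VIP >= 0.8 selection loop, and ROC/AUC computed from the
   cross-validated predictions (Y-predcv).
5. **Fusion** — inner-join of the serum (`_S`), urine (`_U`), tissue (`_T`)
   and clinical (unsuffixed) blocks into one matrix per paired animal.

## The generative model

### Concentrations

For metabolite $m$ in group $g$, latent concentrations are log-normal with
arithmetic mean $\mu_{mg} = \beta_m \cdot k_{mg}$ and coefficient of variation
$c_{mg} = |RSD_{mg}|/100$, where $\beta_m$ is a base level (1 arbitrary unit by
default) and $k_{mg}$ a group multiplier. The published tables report PD
values computed left to right,

$$PD = 100\,\frac{\bar{x}_\text{left} - \bar{x}_\text{right}}{\bar{x}_\text{left}},$$

so with the BDG multiplier anchored at 1 the calibration inverts the two
BDG-anchored columns: $k_{m,RG} = 1 - PD(\mathrm{BDG\,vs\,RG})/100$ and
$k_{m,UDG} = 1 - PD(\mathrm{BDG\,vs\,UDG})/100$. The three printed pairwise
PDs are mutually inconsistent at the last printed digit (serum leucine implies
UDG/BDG = 1.196 through RG but 1.202 directly), so the direct columns win and
the RG-vs-UDG column is never used for calibration; this minimizes propagated
rounding. Metabolites absent from the published tables are null (multiplier 1
in every group) with a default within-group RSD of 15%, a typical biological
CV for targeted NMR integrals.

Three printed values cannot be represented by a positive-valued generator:
the tissue valine RSD of -6032.5% and isoleucine RSDs down to -656.7% (both
reflecting near-zero or negative means of baseline-corrected integrals), and
the tissue isoleucine PD of 151 (which implies a negative RG mean). RSD
magnitudes are capped at 200%, multipliers implied below zero are clamped at
0.05, the affected metabolites are flagged in the cohort manifest, and both
are excluded from recovery targets. The urine table prints identical RSDs for
the BDG and RG columns; they are used as printed and flagged.

### Spectra

Each spectrum is a sum of unit-area Lorentzian singlets (one per metabolite,
full width at half maximum 0.004 ppm by default, about 2.4 Hz at 600.58 MHz),
so the window integral is proportional to concentration:

$$I(\delta) = d_i \sum_m c_{mi}\,
  \frac{\gamma/\pi}{(\delta - \delta_m - j_{mi})^2 + \gamma^2}
  + \text{anchor} + \varepsilon(\delta).$$

* $d_i$ — per-sample log-normal dilution factor (mean 1; CV 15% for serum and
  urine, 5% for tissue extracts). This exercises PQN without overwhelming it.
* $j_{mi}$ — per-metabolite, per-sample chemical-shift jitter, Gaussian with
  sd 0.002 ppm (about 2.7 points on the default grid), the positional
  uncertainty the alignment step must undo.
* An integer global referencing error per sample (sd 3 points) that the
  anchor-referencing step must undo; the anchor resonance mimics an internal
  standard — fixed amplitude, no jitter, not scaled by dilution.
* $\varepsilon$ — Gaussian instrument noise, default sd 1% of the height of a
  unit-concentration peak, so integral RSDs are dominated by biological CV.
* The default axis is $2^{14}$ points over -1..11 ppm — the acquired 64k/20
  ppm grid scaled down for desk-scale runtimes; full resolution is reachable
  through `sim_params()`. Lorentzians are evaluated within 0.75 ppm of their
  center (neglected tail mass < 0.2%, identical for all samples, so it cancels
  in every ratio the pipeline reports).
* Peak positions follow the study's figure legends where printed (the urine
  unknowns at 2.3, 5.23, 6.91, 7.02, 7.22 and 8.22 ppm; the anchors); all
  other shifts are HMDB-typical values, nudged where needed so that windows
  within a compartment never overlap. One singlet per metabolite.

Clinical covariates (body weight, three subcutaneous-fat depths, TG, TC,
HDL-C, LDL-C, glucose, insulin — ten end-of-study variables) are Gaussian
per group with the published means and SDs, truncated at zero. Start-of-study
columns are out of scope. Insulin units are used as printed.

### What the generator does not emulate

No pulse-sequence physics (relaxation, J-coupling, multiplets, water
suppression residuals), no baseline or phase distortions, no longitudinal
design, no correlation structure between metabolites beyond the shared
dilution factor. Passing recovery tests therefore shows that the analysis
chain is faithful to this idealized forward model — not that it would be
unbiased on spectra with crowded multiplets or baseline artifacts.

## Preprocessing choices

* **Referencing** translates whole spectra by integer points so the maximum
  within anchor ± 0.1 ppm sits at the nominal anchor.
* **Alignment** is integer-shift-per-segment against the point-wise median
  spectrum, two passes (the target is recomputed once), segments cut at the
  midpoints between library windows, default maximum shift 10 points (reduced
  automatically on coarser grids so every segment stays wider than
  `2*max_shift + 1`). Vacated points replicate the segment edge value, so no
  signal crosses segment borders. Correlation-optimized warping is not
  implemented: a single well-defined algorithm is preferable, and integer
  shifts are adequate for singlet libraries.
* **PQN** uses the point-wise median spectrum of the compartment's cohort as
  reference (a control-group reference can be supplied); quotients are taken
  over points where the reference exceeds `median + 5 * mad`, excluding the
  residual water region (4.7–5.1 ppm) and the anchor window, and the
  per-sample factor is the median quotient. Exclusions are standard practice;
  the source study does not state its own.
* Phasing and baseline correction are out of scope — the generator emits
  phased, baseline-free spectra.

## Statistical and chemometric choices

* **PD denominator**: the published convention is only "left to right"; both
  \((A-B)/A\) and \((A-B)/B\) reproduce the printed chains to within rounding.
  The left-anchored form is fixed by decree and used consistently in both the
  generator calibration and the analysis, which makes recovery
  self-consistent.
* **t test**: classical pooled-variance, two-sided, flag at p < 0.05, no
  multiple-testing correction (matching the source analysis); a Welch switch
  exists. Zero pooled variance with equal means returns t = 0, p = 1.
* **PLS-DA**: NIPALS with the class coded {0, 1} and centered, X autoscaled
  (unit SD scaling includes mean-centering, as in the SIMCA lineage the
  study used). Components whose score variance vanishes truncate the model.
* **Cross-validation**: 7 folds, deterministic round-robin in sample order
  (venetian blinds); a seeded stratified alternative exists. Scaling is refit
  inside every training fold. $Q^2 = 1 - PRESS/SS_{tot}$ about the
  full-sample mean.
* **Component count**: chosen by forward search — add components while $Q^2$
  improves by more than 0.01, capped at `min(5, n - 2, p)`; a fixed count can
  be configured.
* **VIP and jackknife**: $VIP_j = \sqrt{p \sum_a SS_a w_{aj}^2 / \sum_a
  SS_a}$ with unit-norm weight vectors, so $\sum_j VIP_j^2 = p$ identically.
  The jackknife recomputes VIP on each leave-one-fold-out submodel;
  $SE_j = \sqrt{\frac{k-1}{k} \sum_i (VIP_{ij} - \overline{VIP}_{j})^2}$ and
  the CI uses the t quantile with $k - 1$ degrees of freedom at level 0.95.
  The exact formula used by the original commercial software is not public;
  this standard jackknife is fixed by decree and recorded in reports.
* **Selection loop**: a variable is dropped when its VIP falls below 0.8 *or*
  its CI overlaps zero — the published goal ("variables exceeding 0.8 and
  without overlapping 0") forces the OR-drop reading. The loop stops when all
  survivors pass, or when a guard fires: fewer than two variables would
  remain, or 25 iterations. Retained sets shrink strictly, so termination is
  guaranteed.
* **ROC/AUC**: threshold sweep over the cross-validated predictions of the
  final model, trapezoidal AUC (identical to the Mann–Whitney statistic with
  half credit for ties), sensitivity/specificity also reported at the 0.5
  cutoff of the 0/1 coding scale.

## Known limitations worth stating plainly

* **Post-selection optimism.** The procedure evaluates the ROC on
  cross-validated predictions of the *final, re-built* model — after the VIP
  loop has already seen all samples. On all-null synthetic cohorts the fused
  selected-model CV-AUC has a median near 0.9, while the selection-free
  cross-validated model is correctly at chance level. The package reproduces
  the published procedure faithfully and its test suite asserts both facts;
  interpret reported AUCs accordingly.
* **PQN attenuates group contrasts.** When several metabolites in a
  compartment shift in the same direction, the median quotient absorbs part
  of the group effect into the "dilution" factor. End-to-end recovery of
  printed PDs is therefore biased a few percent toward zero (about 2 PD
  points for serum acetone, about 6 for urine N-phenylacetylglutamine, where
  9 of 19 metabolites fall in UDG). This is a property of PQN itself, not of
  the implementation: recovery from raw integrals divided by the true
  dilution factors is unbiased.
* **Estimator biases at small n.** The sample RSD of a log-normal with
  CV 15.3% has expectation about 14.9 at n = 11; recovered mean RSDs sit
  slightly below the printed values for this reason alone.
* Negative printed RSDs cannot be reproduced by a positive-valued generator
  (see above); tissue valine and isoleucine are excluded from recovery
  claims.

## Problem sizes used by the test suite

Unit tests run on a $2^{12}$-point axis with proportionally reduced alignment
shift bounds; recovery and discrimination checks use the default $2^{14}$-point
axis with 200 replicate cohorts for the univariate recovery means and 50
replicate cohorts for the fused-model AUC study, and 100 replicates for the
selection-power study (2 informative variables at Cohen's d = 2 plus 8 null
variables, n = 20). The same computations, from scratch, are what
`scripts/acceptance.R` reports.

## A short example

```{r example, eval = FALSE}
co <- generate_cohort(seed = 1)
lib <- metabolite_library("serum")
pp <- preprocess_spectra(co$spectra$serum, lib)
ft <- integrate_windows(pp$spectra, lib)
head(build_univariate_report(ft)[, c("metabolite", "pd_bdg_udg", "p_bdg_udg")])

fts <- lapply(c(serum = "serum", urine = "urine", tissue = "tissue"),
              function(comp) {
                l <- metabolite_library(comp)
                integrate_windows(preprocess_spectra(co$spectra[[comp]], l)$spectra, l)
              })
fused <- fuse(fts$serum, fts$urine, fts$tissue, co$clinical)
run_comparison(fused, "BDG", "UDG")
```
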
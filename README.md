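# nmrfusion

Targeted ¹H NMR metabolomics of a three-diet porcine atherosclerosis cohort,
rebuilt as a tested R pipeline: synthetic spectral cohorts with known ground
truth, spectral preprocessing (anchor referencing, icoshift-style segment
alignment, probabilistic quotient normalization), targeted window
quantification, the study's univariate statistics (percentage difference,
relative standard deviation, Student t test), NIPALS PLS-DA with iterative
VIP variable selection and jackknife confidence intervals, cross-validated
ROC/AUC evaluation, and multi-block fusion of serum + urine + tissue +
clinical data.

The package is aimed at metabolomics practitioners who want a transparent,
scriptable implementation of this analysis style — and at anyone who wants to
probe its statistical behavior (recovery bias, post-selection optimism) on
simulated cohorts where the truth is known.

## The cohort and the model

Three diet groups of pigs: balanced diet (BDG, n = 11), Western unbalanced
diet (UDG, n = 9) and a regression group (RG, n = 8; Western diet later
replaced by a balanced one), with paired serum, urine and muscle-tissue
spectra (27/19/26 targeted metabolites) and ten clinical covariates. Because
the original raw spectra are not deposited, cohorts are simulated: metabolite
concentrations are log-normal with group mean multipliers calibrated by
inverting the published percentage differences,

    PD = 100 · (mean_left − mean_right) / mean_left     (left to right)

with the BDG mean anchored at 1, and within-group CVs set to the published
relative standard deviations. Spectra are sums of unit-area Lorentzian
singlets with per-sample dilution, chemical-shift jitter, referencing error
and instrument noise.

Group separation is modeled with PLS-DA (class coded 0/1, NIPALS), 7-fold
cross-validation, and variable importance in projection,

    VIP_j = sqrt( p · Σ_a SS_a w_aj² / Σ_a SS_a ),   Σ_j VIP_j² = p,

with jackknife confidence intervals over leave-one-fold-out submodels.
Variables with VIP < 0.8 or a CI overlapping 0 are removed and the model is
re-built until all survivors pass. ROC/AUC is computed from the final model's
7-fold cross-validated predictions.

## Worked example

```r
library(nmrfusion)

co  <- generate_cohort(seed = 1)                  # 28 animals, 3 compartments
lib <- metabolite_library("serum")
pp  <- preprocess_spectra(co$spectra$serum, lib)  # reference, align, PQN
ft  <- integrate_windows(pp$spectra, lib)         # 28 x 27 feature table
rep_ <- build_univariate_report(ft)
rep_[rep_$metabolite %in% c("Leucine", "Valine", "Acetone", "Betaine"),
     c("metabolite", "pd_bdg_rg", "pd_rg_udg", "pd_bdg_udg", "p_bdg_udg", "rsd_bdg")]
#>    metabolite pd_bdg_rg pd_rg_udg pd_bdg_udg p_bdg_udg rsd_bdg
#> 4     Leucine     -5.24     -9.42      -15.2  8.63e-05    5.19
#> 5      Valine    -16.89      4.56      -11.6  2.51e-02   11.40
#> 13    Acetone    -56.33     17.97      -28.2  4.55e-02   16.60
#> 21    Betaine     -8.91     31.07       24.9  8.82e-04   13.72
```

Each row is one metabolite: the three percentage differences over the ordered
group comparisons (negative PD means the right-hand group is higher), the
t-test p value for BDG vs UDG, and the within-BDG relative standard deviation
in percent. Values vary cohort to cohort; their means across many simulated
cohorts recover the calibrated effects up to the PQN attenuation discussed in
the vignette.

Fusing all blocks and running the BDG-vs-UDG comparison:

```r
fts <- lapply(c(serum = "serum", urine = "urine", tissue = "tissue"),
              function(comp) {
                l <- metabolite_library(comp)
                integrate_windows(preprocess_spectra(co$spectra[[comp]], l)$spectra, l)
              })
fused <- fuse(fts$serum, fts$urine, fts$tissue, co$clinical)  # 82 variables
run_comparison(fused, "BDG", "UDG")
#> BDG vs UDG: AUC = 1.000, Q2 = 0.897, 23 variable(s) retained
```

The retained set mixes serum (`_S`), urine (`_U`), tissue (`_T`) and clinical
variables, and the cross-validated AUC of the final model is 1 — the fused
blocks separate the two diets completely on this cohort.

An end-to-end run over all three comparisons and all blocks, with reports
written to disk:

```r
run_study(default_config(seed = 1), outdir = "out")
```

or from a shell, `Rscript inst/scripts/run_study.R --seed 1 --outdir out`.

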
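# hepkin — dual-input compartment modelling of dynamic FDG PET in the liver

`hepkin` is an R package for kinetic analysis of short-protocol dynamic
¹⁸F-FDG PET of the liver with dual blood input (hepatic artery + portal
vein). It is aimed at researchers in quantitative PET who want to simulate,
fit and compare liver compartment models — including voxelwise parametric
imaging — without access to clinical scan data: a synthetic-data module
emulates the whole acquisition.

## The models

The tracer supply to the liver is the mixture
`C_B(t) = HPI·A(t) + (1−HPI)·P(t)`, where `A`/`P` are arterial and
portal-venous input curves and `HPI` is the hepatic artery perfusion index
(HCC lesions are predominantly artery-fed). Tissue kinetics follow the
linear compartmental system `dC/dt = M C + K1 C_B e1`, measured as
`C_T = αᵀC + Vb C_B`:

- **3C model** (two-tissue): free FDG `C_E` and FDG6P `C_M`, rates
  `K1, k2, k3, k4`, plus `HPI` and `Vb` — 6 parameters.
- **4C model**: adds an endoplasmic-reticulum FDG6P pool `C_R` with entry
  rate `k5` (G6PT) and return `k6` (G6Pase), plus the interstitial volume
  `Vi` and ER-to-cytosol volume ratio `v` — 9 parameters.

Fitting is weighted nonlinear least squares
(`WRSS(θ) = Σ wᵢ (cᵢ − C_T(tᵢ;θ))²`) with bounded multistart
Levenberg–Marquardt; models are compared with the least-squares AIC
`N·ln(WRSS/N) + 2P`. Cohort tools provide group summaries, paired t tests,
Mann–Whitney ROC/AUC per marker, a multiparameter (logistic-combination)
ROC, and AUC-ranked marker lists. `fit_voxelwise()` produces `K1`, `k3`,
`k5` and `HPI` parametric maps from 4-D images (NIfTI in/out).

The methods vignette (`vignettes/liver-kinetics.Rmd`) documents the
numerical scheme (exact matrix-exponential propagation validated against a
stiff ODE solver), the noise model, and a structural identifiability
analysis of the 9-parameter 4C model that explains what single-TAC fits
can and cannot recover.

## Worked example

Simulate a study-sized cohort (28 HCC lesions, 24 background-liver ROIs,
5% frame noise), fit every TAC and rank the markers:

```r
library(hepkin)

spec <- cohort_spec(n_hcc = 28, n_liver = 24, noise = 0.05, seed = 11)
coh  <- gen_cohort(spec)
tab  <- fit_cohort(coh$tacs, coh$arterial, coh$portal, model = "3C",
                   cfg = fit_config(n_starts = 5, max_iter = 200, tol = 1e-8),
                   reweight = TRUE)
tab$group <- coh$truth$group

rank_markers(tab, c("K1", "k2", "k3", "k4", "HPI", "Vb"), tab$group,
             positive = "HCC")
#>   marker       auc flipped
#> 6     Vb 0.8444940   FALSE
#> 5    HPI 0.6927083   FALSE
#> 4     k4 0.6607143    TRUE
#> 1     K1 0.5565476    TRUE
#> 3     k3 0.5424107   FALSE
#> 2     k2 0.5193452    TRUE

multiparametric_roc(tab, c("HPI", "Vb", "k3"), tab$group, positive = "HCC")
#> <roc_result> AUC 0.891 (28 pos / 24 neg)
```

The ranked table reports each marker's area under the ROC curve for
discriminating HCC from background liver on this synthetic cohort
(`flipped = TRUE` marks markers that run *lower* in HCC, such as `k4`
here); the multiparameter ROC combines standardised markers with an
in-sample logistic score — 0.891 for the HPI + Vb + k3 combination,
exceeding every single marker.

A noiseless single-TAC fit recovers the generating 3C parameters exactly:

```r
inputs <- gen_inputs(seed = 1)
truth  <- default_group_params("3C", "HCC")$mean
x   <- simulate_tac(truth, inputs$arterial, inputs$portal,
                    default_schedule(include_static = TRUE))
fit <- fit_tac(x, inputs$arterial, inputs$portal, model = "3C",
               cfg = fit_config(include_static_frame = TRUE))
fit
#> <kinetic_fit 3C> WRSS 3.988e-24, AIC -952.1, converged TRUE (start 17)
#> <kinetic_params 3C> K1=1.302, k2=1.435, k3=0.047, k4=0.026, HPI=0.652, Vb=0.208
```

## Command-line interface

A thin wrapper is installed at `system.file("cli", "hepkin", package =
"hepkin")` with subcommands `simulate`, `fit` (with `--compare` for the
3C-vs-4C AIC comparison), `roc`, `parimg` and `fixtures`; every run writes
a provenance JSON. See `?hepkin_cli`.

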
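# dcetk — quantitative DCE-MRI pharmacokinetics in R

`dcetk` quantifies subtle blood–brain-barrier leakage from dynamic
contrast-enhanced (DCE) MRI. It implements the full measurement chain for a
dual-flip-angle spoiled gradient-echo (SPGR) brain protocol, twice: the
conventional pipeline (variable flip-angle T1 mapping → signal-to-
concentration conversion → vascular input function → voxelwise
tracer-kinetic fitting) and a direct-inference route in which a dual-pathway
dilated convolutional network maps the raw signal-time series straight to
parameter maps, trained with a joint parameter + kinetic-model-consistency
loss. A seeded digital reference object (brain phantom) generator and an
agreement-metric stack (nRMSE, SSIM, Bland–Altman limits, Lin's concordance,
paired Wilcoxon tissue statistics) make the whole chain testable at desk
scale. It is intended for researchers developing or validating quantitative
DCE methods in the low-permeability regime (Ktrans ~ 10⁻³ min⁻¹).

## Models

Signal and concentration are linked by the steady-state SPGR equation with a
baseline offset,

    S(t) = M₀ sinα (1 − e^−(K+L)) / (1 − cosα e^−(K+L)) + [S(0) − SPGR(Ct = 0)],
    K = TR/T₁₀,  L = r₁ Ct(t) TR,

inverted in closed form for Ct(t); T₁₀ comes from the two-point variable
flip-angle estimate on the 2°/12° pre-contrast pair. Tissue kinetics follow
the Patlak model

    Ct(t) = vp Cp(t) + Ktrans ∫₀ᵗ Cp(τ) dτ

(linear least squares, one QR per volume) or the extended Tofts model

    Ct(t) = vp Cp(t) + Ktrans ∫₀ᵗ Cp(τ) e^−kep(t−τ) dτ

(bounded L-BFGS NLS, ≤ 30 iterations, Patlak-informed warm start). The
network alternative is trained to minimize

    L = ‖θ − θ̂‖² + ‖Ct(t) − f_tk(θ̂)‖²

over 24×24 signal patches and needs no input function at prediction time.

## A worked example

Simulate one phantom subject, fit it voxelwise, and summarize:

```r
library(dcetk)

spec <- phantom_spec(shape = c(64, 64, 4), n_subjects = 1,
                     sigma = 0.02, seed = 7)
ds <- simulate_dataset(spec, 1)
conc <- signal_to_concentration(ds$signal_noisy, ds$sb, ds$relax,
                                ds$spec$params)$conc
fit <- fit_volume(conc, ds$cp, model = "patlak", mask = ds$brain)
fit
#> Voxelwise patlak fit: 9740 voxels in mask, 100.0% valid
#>      ktrans          vp 
#> 0.001171724 0.011919242 
cor(fit$maps$ktrans[ds$brain], ds$truth$ktrans[ds$brain])
#> [1] 0.9622472
```

The printed coefficients are the median fitted Ktrans (min⁻¹) and plasma
volume fraction over the masked voxels — white-matter-dominated medians a
little above the NAWM generating means (Ktrans 10⁻³ min⁻¹, vp 0.01), as
expected with lesions in the mix; the correlation is the voxelwise agreement
between fitted and generating Ktrans at 2% signal noise. `predict(fit)`
returns the fitted concentration curves, `residuals(fit, conc)` the misfit.

The same stack drives a command-line interface
(`inst/cli/dcetk`): `simulate`, `t1map`, `conc`, `fit`, `train`, `predict`,
`evaluate`, each writing a JSON manifest with the configuration hash and
input checksums. `predict` takes weights and a 4D NIfTI only — by design
there is no input-function flag.

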
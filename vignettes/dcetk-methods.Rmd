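---
title: "Quantitative DCE-MRI with dcetk: models, fitting, and direct inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative DCE-MRI with dcetk: models, fitting, and direct inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcetk)
```

## The measurement problem

Dynamic contrast-enhanced (DCE) MRI tracks a gadolinium bolus through serial
T1-weighted imaging. In brain studies of subtle blood-brain-barrier (BBB)
leakage — small vessel disease, lacunar stroke, white-matter hyperintensities —
the volume transfer constant Ktrans is of order 10^-3 min^-1, so the
enhancement of interest is a few percent of baseline signal, comparable to the
acquisition noise. `dcetk` implements the complete quantification stack for a
dual-flip-angle spoiled gradient-echo (SPGR) protocol, a conventional
voxelwise tracer-kinetic fitting route, a convolutional network that infers
parameter maps directly from the signal-time series, and a seeded digital
reference object (phantom) that makes the whole stack testable against known
ground truth.

The default acquisition constants describe a 1.5 T brain protocol: TR =
8.24 ms, pre-contrast flip angles 2 and 12 degrees, 21 frames (one
pre-contrast baseline + 20 post-injection dynamics) at 73 s spacing, contrast
relaxivity r1 = 4.2 s^-1 mM^-1, hematocrit 0.45. All of these live in one
`acq_params()` object consumed by every transform.

## Signal model

The steady-state SPGR magnitude at flip angle $\alpha$ is

$$S = M_0 \sin\alpha\,\frac{1 - e^{-(K+L)}}{1 - \cos\alpha\, e^{-(K+L)}},
\qquad K = T_R / T_{10},\quad L = r_1\, C_t(t)\, T_R .$$

Internally TR and T10 are seconds and Ct is mM, so $L$ is dimensionless;
kinetic rates are converted to min^-1 only at the kinetics boundary.

*T1 mapping.* `compute_t10()` uses the two-point variable flip-angle closed
form on the signal ratio $S_R = S_a/S_b$. Voxels where the log argument is
non-positive (background, non-physical ratios, the infinite-T10 limit) are
flagged invalid and carried as `NA` plus an explicit mask — every downstream
operation consumes the mask rather than guessing at sentinels. `compute_m0()`
inverts the steady-state magnitude at the higher flip angle.

*Dynamic forward model and inversion.* The dynamic model is the
baseline-offset form: the SPGR term at Ct(t) plus the constant
$S(0) - \mathrm{SPGR}(C_t{=}0)$, anchored to the measured baseline frame, so
that $C_t = 0$ reproduces $S(0)$ exactly. Its inversion is algebraically
exact; the round trip is tested to 1e-10 relative over Ct in [0, 2] mM and
T10 in [0.3, 3] s. Frames whose signal falls outside the invertible range
(beyond the saturation asymptote) are masked per frame. Negative
concentrations produced by noise are *retained*, not clipped, so that
least-squares fitting sees unbiased noise; clipping is available as an option
and off by default.

The time origin is a convention the protocol itself does not pin down: the
single baseline frame sits at t = 0, which doubles as the quadrature anchor
with Cp(0) = 0, and post-injection frames follow at 73 s multiples.

## Tracer-kinetic models and fitting

Two nested models link tissue concentration to the plasma input function
Cp(t):

$$\text{Patlak:}\quad C_t(t) = v_p C_p(t) + K^{trans}\!\int_0^t C_p(\tau)\,d\tau$$

$$\text{eTofts:}\quad C_t(t) = v_p C_p(t) + K^{trans}\!\int_0^t
C_p(\tau)\, e^{-k_{ep}(t-\tau)}\,d\tau$$

Both integrals use cumulative trapezoid quadrature on the native 73 s frame
grid, built from one shared lower-triangular weight matrix, so the nesting
identity eTofts(kep = 0) = Patlak holds to machine precision rather than to a
quadrature tolerance. On this coarse clinical grid the trapezoid error is
O(dt^2) — about 1.5e-3 mM for a smooth bolus — and halving the frame interval
shrinks it fourfold; the tests assert the convergence order directly. The
eTofts model is parameterized as (Ktrans, kep, vp); ve = Ktrans/kep is derived
output. The baseline frame anchors the quadrature but is excluded from fit
residuals.

The vascular input function is measured in a venous voxel neighborhood (3x3
in-plane average, which reduces the VIF noise sd threefold), treated as whole
blood, and converted to plasma via Cp = Cb/(1 - Hct). No arteriovenous delay
correction is applied: at 73 s sampling the delay is negligible. The
whole-blood/plasma distinction matters quantitatively — skipping the Hct
correction scales every Ktrans and vp by (1 - Hct).

*Patlak fitting* is ordinary least squares on the design [Cp(t), AUC(t)]
solved by QR; one factorization serves an entire volume because the design is
shared across voxels. Estimates are returned raw (possibly negative);
non-negativity clipping is a config option, off by default, so that the noise
distribution of the estimator stays symmetric.

*eTofts fitting* minimizes the residual sum of squares under box bounds
(Ktrans in [0, 0.1] min^-1, kep in [0, 10] min^-1, vp in [0, 1] — the
low-permeability brain regime) with L-BFGS-B, analytic gradients, and a
30-iteration cap. Two implementation details matter at these magnitudes.
First, the default convergence factor of R's `optim` (factr = 1e7) stops the
solver when the objective changes by ~2e-9 relative — but a noiseless SSE at
these concentration scales is ~1e-10, so the solver must be run at
factr = 1e3. Second, the default start is warm: Ktrans and vp are seeded from
the closed-form Patlak fit of the same curve (the kep -> 0 nested model) and
kep from mid-range. With both in place the fit recovers a 5x5x5 noiseless
grid spanning Ktrans in [1e-3, 1e-2] min^-1, kep in [0.05, 1] min^-1, vp in
[0.005, 0.05] to within 1% at every grid point inside the iteration budget.
A cold explicit start remains available through `init=`. Non-convergence is
reported, never raised: the best iterate comes back with a flag.

## Direct inference network

The network maps a 24 x 24 x T signal patch (frames stacked as channels) to a
24 x 24 x n parameter patch, n = 2 (Patlak) or 3 (eTofts). The first layer
filters each frame independently with a 4 x 4 kernel and aggregates frames
through a learned 1 x 1 combination into 32 maps — the stated first-layer
semantics are ambiguous between this depthwise reading and a full 3D filter;
the depthwise + learned aggregation reading is implemented and recorded here
as the point most open to an alternative. Two parallel pathways follow: a
local pathway of three standard 4 x 4 convolutions and a global pathway of
three dilated 4 x 4 convolutions (dilation 2, 4, 8). The local depth is not
stated numerically anywhere; three layers mirror the dilated pathway and make
the concatenation symmetric. The concatenated 64-channel feature map passes
through a 64-filter 4 x 4 convolution and three per-voxel 1 x 1 layers (256,
128, n). Zero padding keeps every layer at 24 x 24; a rectifier follows every
layer except the output.

*Loss.* Training minimizes a two-term objective per voxel:
parameter fidelity $\lVert\theta - \tilde\theta\rVert^2$ plus model
consistency $\lVert C_t(t) - f_{tk}(\tilde\theta)\rVert^2$, where $f_{tk}$ is
the (differentiable, trapezoid-quadrature) kinetic forward model driven by
the *training* subject's plasma curve. Both terms are normalized per element;
the consistency weight λ defaults to 1. Because Ktrans (~1e-3) and vp (~1e-2)
live an order of magnitude apart, the parameter channels are standardized by
their training-set standard deviation inside the parameter term (default on;
raw mode reproduces the plain two-term sum). The implementation goes one step
further and has the network regress the standardized channels directly,
de-standardizing at the output boundary — an exact reparameterization of the
same objective that keeps the output layer O(1); without it, adaptively
rescaling a He-initialized output down three orders of magnitude consumes
hundreds of epochs. At prediction time no input function is consumed at all:
the trained weights plus the 4D signal series are the entire input.

*Training protocol.* Adam (lr 1e-3, per-update decay lr/(1 + 1e-4 t) — the
decay is interpreted as learning-rate decay, not weight decay), mini-batches
of patches, an 80/20 train/validation split, early stopping after 15 epochs
without validation improvement, weights restored from the best validation
epoch, and every random draw (split, shuffling, initialization) flowing from
one seed. Inputs are scaled by each subject's mean in-brain baseline
intensity (config `normalize_input`, default `baseline_mean`; `none`
reproduces raw intensities), with the test subject's scale recomputed from
its own baseline — it is a property of the signal, not an auxiliary input.
On top of the per-subject scale, the trainer z-scores each input channel
with training-set statistics (stored in the model and re-applied at
prediction): baseline-scaled signals sit near 1.0 with only few-percent
fluctuations, and He-initialized rectifier stacks train poorly on inputs
with a large common offset.
Patches are extracted on a stride-6 lattice; at prediction time each slice is
tiled the same way (plus edge-anchored tiles when the extent is not
lattice-aligned) and the overlapping predictions — 16 per interior voxel —
are averaged over the count actually covering each voxel.

*Numerical engine.* Activations are (pixels x batch) x channels matrices;
each convolution is an im2col expansion plus one BLAS GEMM, with the fused
forward/backward pass compiled (Rcpp/RcppArmadillo) in single precision, the
customary arithmetic for training convolutional networks. Weights, the
optimizer state, and the loss are double precision in R. A per-layer
double-precision implementation of the same layers is kept and serves as the
independent numerical oracle in the test suite; the fused engine agrees with
it to ~1e-5 (outputs) and ~1e-4 (gradients) relative, which is the expected
single-precision rounding scale. Training is bit-reproducible for a fixed
seed on a fixed BLAS.

## The digital reference object

The phantom emulates the study acquisition geometry per subject: an
elliptical brain cross-section containing normal-appearing white matter
(NAWM), a deep-gray-matter (DGM) core, a periventricular WMH ring segment, a
seeded recent-stroke-lesion (RSL) blob, and a posterior-midline vessel
rectangle spanning all slices (>= 3 voxels wide so the 3x3 VIF patch fits,
sized to stay >= 1% of in-brain area). Ground-truth parameters are drawn per
voxel from tissue-conditional truncated normals; the default means encode the
subtle-BBB-leak regime — Ktrans (min^-1): NAWM 1e-3, WMH 2e-3, DGM 1.5e-3,
RSL 5e-3, vessel 0; vp: 0.01 / 0.015 / 0.03 / 0.02 / 0.6; relative spread
10%; kep = Ktrans/0.2 for eTofts phantoms; T10 0.6 s (white matter), 1.0 s
(gray matter and lesion), 1.4 s (blood). These are generator defaults chosen
to match the order of magnitude reported for stroke-lesion voxels, not claims
about any cohort.

The plasma input function is a causal biexponential bolus
$C_p(t) = D\,(a_1 e^{-m_1 t} + a_2 e^{-m_2 t})$ for t > 0 with defaults
a1 = 4.5 mM, m1 = 0.6 min^-1, a2 = 1.2 mM, m2 = 0.05 min^-1 — a ~3.3 mM
first-frame peak decaying to a ~1 mM tail on the 73 s grid, the shape family
observed in venous sinus measurements, with per-subject lognormal jitter
(sd 0.15) on the peak and tail amplitudes so that subjects share the
time-to-peak but not the magnitude. Signal noise is additive zero-mean
Gaussian, independent per voxel and frame, with sd expressed as a fraction of
the mean in-brain baseline signal (default 2%); Gaussian rather than Rician
because at the simulated SNR the Rician floor is negligible and Gaussian
noise keeps the SPGR inversion unbiased, which the estimator tests rely on.
The same noise is applied to the stored pre-contrast flip-angle pair so the
conventional pipeline can be exercised end to end, T1 mapping included.

Every dataset stores each intermediate (labels, truth maps, input function,
noiseless concentration, noiseless and noisy signal, relaxation maps), making
each pipeline stage testable against its own oracle, and is a pure function
of the spec including its seed.

What the phantom deliberately does *not* model: anatomically realistic
geometry, motion and registration artifacts, B1/flip-angle error, Rician
noise, bolus-arrival delays, and protocol variation across subjects. Passing
tests on this phantom therefore demonstrate numerical and statistical
correctness of the estimators under the stated noise model — not robustness
to the full messiness of clinical data.

## Evaluation conventions

Because map-similarity numbers depend on unstated conventions, both are
pinned and reported: nRMSE is RMSE divided by the *reference range* within
the mask, and SSIM is the Gaussian-weighted form (11 x 11 window, sigma 1.5,
K1 = 0.01, K2 = 0.03, data range taken from the reference within the mask,
window-radius border cropped before averaging) — verified to 1e-12 against an
independent reference implementation. One caution discovered while testing:
for maps with near-zero local means, SSIM of a sign-flipped image against the
original is *positive* (the luminance and structure factors are both
negative), so anti-correlation only drives SSIM negative when fluctuations
anti-correlate about a common mean level.

Bland-Altman reports the mean difference and 1.96-sd limits of agreement;
Lin's concordance correlation coefficient is
$2\,\mathrm{cov}(x,y) / (\sigma_x^2 + \sigma_y^2 + (\bar x - \bar y)^2)$.
Tissue-wise comparisons summarize one value per subject per tissue (the
median) and pair the two methods across subjects with the Wilcoxon
signed-rank test — the pairing unit is the subject, two-sided by default, raw
p-values without multiplicity correction; identical paired samples return
p = 1 by convention. Curve-fit quality is reported per slice (nRMSE over the
slice-frame stack, SSIM averaged over frames) and aggregated as mean ± sd
across slices.

## The scaled validation study

The package's end-to-end check trains the Patlak-flavor network on a seeded
six-subject phantom (64 x 64 x 4 slices, 2% baseline noise) in
leave-one-subject-out style and evaluates the held-out subject. Problem
sizes are chosen so the whole study runs on a single desktop core: stride-6
patch extraction gives 196 patches per subject, 980 for five training
subjects, split 80/20; training uses mini-batches of 64 patches for up to 35
epochs. On the held-out subject the network's Ktrans map is compared with the
ground truth (voxelwise Pearson r) and with the *conventional pipeline run on
the same noisy acquisition* — VFA T1 mapping from the noisy flip-angle pair,
SPGR inversion, vessel-patch VIF with hematocrit correction, voxelwise Patlak
OLS. That arm is the honest comparator: handing the fit the true relaxation
maps and the true plasma curve would grant it oracle inputs that no real
pipeline has, and the direct-inference route exists precisely to absorb the
error of those intermediate steps. Median absolute Ktrans error is the
robustness metric; within-tissue parameter spread (10% relative, i.i.d.
across voxels) is irreducible for a spatial-context regressor, so the
network's error floor is set by that spread while the conventional fit's is
set by noise propagated through the pipeline.

## Known limitations

* The network engine is compiled for the published topology (two depth-3
  pathways, three head layers); channel widths, kernel, dilations and patch
  size are configurable, the pathway structure is not.
* eTofts-flavor network training is supported but markedly slower than
  Patlak (the consistency term requires per-voxel exponential-kernel
  convolutions under varying kep).
* Single-precision training means run-to-run reproducibility is tied to the
  BLAS build; results are bit-identical for a fixed environment and seed.
* The CLI reads whole volumes into memory; it is sized for research volumes,
  not streaming clinical archives.
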
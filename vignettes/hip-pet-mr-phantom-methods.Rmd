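---
title: "Methods: phantom-validated quantification of [18F]-NaF PET/MR of the hip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated quantification of [18F]-NaF PET/MR of the hip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipoa)
```

# What this package computes

Hybrid [18F]-sodium-fluoride PET/MR of the hip yields, per subject, a dynamic
PET series (bone perfusion/mineralization), T1rho- and T2-weighted MR stacks
(cartilage composition), morphologic lesion grades, and the femur geometry.
`hipoa` implements the quantification chain that turns these into scalar
biomarkers — SUV, the Patlak influx constant Kpat, cartilage T1rho/T2, shape
mode scores, lesion totals — plus the statistics that relate them. Because no
patient data are distributed, every stage is validated against a digital hip
phantom whose ground truth (kinetic parameters, relaxation times, shape modes,
planted correlations, rater disagreement) is known exactly.

# The phantom

`phantom_spec()` builds a voxelized hip (default 32 x 32 x 20 voxels of 2 mm)
with five disjoint regions: femur, acetabulum, femoral and acetabular
cartilage shells, and a femoral-artery column. Defaults are the study
conditions throughout the tests:

* Dynamic protocol: 12 frames of 10 s, 6 of 30 s, 10 of 4 min — 28 frames,
  45 min (`make_frame_schedule()`).
* Influx constants of realistic magnitude: acetabulum 0.015 1/min, femur
  0.007 1/min, VB 0.05; cartilage an order of magnitude lower.
* Relaxation times: cartilage T1rho 36.44 ms and T2 33.57 ms (population-mean
  magnitudes for hip cartilage), bone 25/20 ms, blood long (150 ms), S0 = 100
  arbitrary units; preparation schedules TSL 0/15/30/45 ms and
  TE 0/10.4/20.8/41.6 ms.
* Subject covariates: 70 kg, 250 MBq, age 55, HOOS-type pain score.

The arterial input is a tri-exponential bolus
\(P(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t} - (A_1+A_2) e^{-\lambda_0 t}\)
with \(\lambda_0\) larger than both decay rates, so \(P(0) = 0\), a single
early peak (about 0.6 min with the defaults) and monotone decay. The form was
chosen because it integrates in closed form — `aif_integral()` and
`aif_double_integral()` — which gives machine-precision oracles for frame
averaging and the Patlak abscissa.

Tissue curves come in two modes. `patlak_exact` constructs
\(ROI(t) = K_{pat}\int_0^t P + V_B P(t)\) identically, the reference signal
for testing the graphical analysis; when built against a *sampled* input
function it uses the same trapezoidal running integral as the analysis code,
so parameter recovery is an algebraic identity rather than a numerical
approximation. `compartment` integrates the irreversible two-tissue system
\(\dot C_1 = K_1 P - (k_2+k_3)C_1,\ \dot C_2 = k_3 C_1\) (deSolve, with an
extra cumulative state so frame averages come from the antiderivative), whose
Patlak slope approaches \(K_{pat} = K_1 k_3/(k_2+k_3)\) after equilibration.

Rendered frames hold the *interval average* of the region TAC (what a scanner
reports), not a midpoint sample; midpoint sampling is available as an option.
PET noise is pseudo-Poisson — zero-mean Gaussian with standard deviation
`pet_noise * sqrt(signal / duration_min)`, so short early frames are noisier —
with the default scale 0.17 chosen to give late-frame voxel TACs a
coefficient of variation around 5%, a conventional reconstruction-domain
level. MR noise is additive Gaussian (default sigma 2 on S0 = 100, i.e. 2%).
True sinogram-domain noise, point-spread, attenuation and scatter are out of
scope; what passing tests show is therefore correctness and noise-robustness
of the estimators, not scanner realism.

Every stochastic operation takes an explicit seed and restores the caller's
RNG state; renders are bit-identical under a fixed seed.

# PET kinetics

SUV is the 1 g/mL-convention normalization
`activity [kBq/mL] x weight [kg] / dose [MBq]` (`compute_suv()`), applied to
the duration-weighted mean of the late frames (`static_uptake()`, default
30-45 min window).

The input function is the mean arterial TAC: over a supplied artery mask, or
automatically (`extract_aif()`): candidate voxels must peak within the first
2 min and decline by at least 50% by scan end; the top 20 by early peak are
reduced to their largest 6-connected component and averaged. The heuristic is
a documented stand-in — the clinical isolation algorithm is not specified in
the literature this follows — and on the phantom it selects only true artery
voxels.

`patlak_transform()` maps the data to normalized time,
\(x = \int_0^t P/P(t)\), \(y = ROI/P\), with a trapezoidal running integral
over the sample times, P taken as 0 at t = 0, and points with
\(P < 10^{-6}\max P\) dropped (guards the division at t = 0).
`patlak_fit()` runs unweighted OLS on points at or beyond the equilibration
cutoff t* (default 15 min; frame-duration weights optional). Numerical
behaviour worth knowing: on the standard grid the trapezoid carries a
bolus-onset error of a few percent at the very first mid-times, falling below
0.5% beyond ~5 min and ~0.3% in the fit window; the resulting bias on Kpat
from rendered images is ~0.3-0.4%, well inside the 2% band the compartment
recovery is held to. Voxelwise fits (`patlak_voxelwise()`) share the abscissa
across voxels and solve the per-voxel OLS in closed form; they are restricted
to bone masks by default for cost. Decay correction is assumed already
applied to the input activity, as scanners convention; it is documented, not
performed.

# Relaxometry

`fit_monoexp()` fits \(S(\tau) = S_0 e^{-\tau/T}\) per voxel: log-linear
initialization on the positive samples, then damped Gauss-Newton
(Levenberg-Marquardt) refinement. The solver is vectorized across voxels —
each iteration solves the per-voxel 2x2 normal equations with individual
damping factors — because a 10^4-voxel slice would otherwise cost 10^4
optimizer calls; on single curves it matches `minpack.lm::nlsLM` to solver
tolerance (tested). Bounds T in (1, 300) ms cover the physiologic
cartilage/bone range and stop runaway fits on flat signals. A voxel is
invalid if it has fewer than two positive samples, hits a bound, or fits with
R^2 < 0.5; invalid voxels are flagged, never silently zeroed, and ROI
summaries (`roi_relaxation()`) average valid voxels only and report the valid
fraction. The model has no constant offset (no noise floor term): with the
additive-Gaussian phantom noise the estimator is unbiased to well under 2% at
2% noise, which is what the tests hold it to; on magnitude images with
Rician noise a floor term would be the first extension.

# Spatial normalization

`resample_to_grid()` is standard affine-to-affine regridding (trilinear for
intensities, nearest for labels, out-of-field zero-filled and counted; RAS+
affines, 0-based voxel indices, mm units).

`register_nonrigid()` estimates a smooth displacement field (reference
coordinates to subject coordinates) by free-form deformation: displacements
on a coarse control lattice (default spacing 3 voxels), interpolated
trilinearly to the voxel grid, matched by mean squared error with a
first-difference roughness penalty (weight 0.01), optimized coarse-to-fine
over a 3-level pyramid. No installed R package provides volumetric nonrigid
registration, so the optimizer is part of the package: Barzilai-Borwein
gradient descent with an Armijo backtracking line search and analytic
gradients. Two numerical choices matter. First, the moving image is sampled
with *edge-clamped* interpolation: zero-filling outside the volume makes the
cost discontinuous whenever content touches a face, which silently defeats
any line search. Second, a strong-Wolfe quasi-Newton search (optim's
L-BFGS-B) fails on the trilinear objective because its derivative has kinks
at integer sample positions; sufficient-decrease backtracking is robust to
them. The whole module has no random initialization and is deterministic.
On the phantom, a planted smooth warp of 3-voxel amplitude is recovered with
bone-label Dice ~0.96 (unregistered 0.89) and a mean field error just under
one voxel; accuracy is symmetric under input swap to < 0.001 Dice.

`propagate_masks()` warps labels nearest-neighbour and can refine each bone
label against the intensity image with a piecewise-constant (Chan-Vese-style)
boundary evolution: boundary voxels exchange with background when that lowers
\((I-\mu_{in})^2 - (I-\mu_{out})^2\) plus a curvature penalty, for at most N
sweeps; fragments disconnected from the main component are reverted, which
preserves label topology. The outside mean is global over background — a
band-local mean stalls inside wide objects where the local band has no
contrast.

# Shape model

`align_surfaces()` is generalized Procrustes with translation and rotation
only; the Kabsch rotation is constrained to det(R) = +1, so reflections are
never introduced. Scale is deliberately retained: the shape features of
interest include head size and shaft thickness, which similarity scaling
would remove. `fit_pca()` eigendecomposes the sample covariance of the
flattened point vectors (via SVD); variance fractions are eigenvalues over
the total, scores are centered projections, and signs are fixed so each
mode's largest-magnitude loading is positive. `reconstruct()` produces
mean + sum(score_j sqrt(lambda_j) mode_j) for SD-unit scores, the convention
for mean +/- 2 SD mode visualizations. Establishing point correspondence from
raw masks is out of scope; the phantom provides it, and real use would derive
it from the spatial module's propagated atlas labels.

The planted femur modes (trochanter prominence, head size, shaft thickness,
neck-shaft angle, cam bump, osteophyte bump) are analytic displacement fields
on a parametric template — capped-cylinder shaft, cylindrical neck at 130
degrees, spherical head, trochanter bump — with each point labelled by part so
geometric probes (head radius, shaft thickness, neck-shaft angle, trochanter
prominence; `femur_probes()`) can label recovered modes
(`mode_feature_report()`). One construction detail is load-bearing: the raw
anatomical fields are projected orthogonal to the similarity-group generators
(global translations and infinitesimal rotations) before orthonormalization.
Without that projection, Procrustes alignment absorbs part of each planted
mode and the recovered PCA subspace is tens of degrees away from the planted
one; with it, recovery is exact to ~0.01 degrees at zero noise. For the same
reason the subspace-stability test specifies measurement noise at the *shape*
level (noise totalling 10% of the smallest mode SD in shape-vector norm):
per-coordinate noise of that nominal size across all 3N coordinates adds an
isotropic variance floor of order sigma^2·3N/n that visibly rotates any
estimated subspace — a property of PCA, not of this implementation.

# Scoring and agreement

Cartilage lesions are graded 0-2 and bone-marrow-edema-like lesions 0-3 in
the ten standard subregions (AA, FA, AP, FP, ASL, ASM, FL, FSL, FSM, FI);
totals range 0-20 and 0-30. Grading from images is a human task and out of
scope — the module encodes the scheme, totals, and validation (the 0.5/1.5 cm
BME size thresholds are documentation constants). `rater_agreement()` pools
per-cell grades and computes unweighted Cohen's kappa
\((p_o - p_e)/(1 - p_e)\) with marginal-product chance agreement; linear
weights are available for the ordinal scales, and each score type is assessed
separately by default with a pooled option. When both raters are constant and
identical, p_e = 1 and kappa is reported as undefined with 100% agreement.
The phantom's two-rater simulator gives rater B a fixed per-cell departure
probability, so expected raw agreement is known exactly (93% at the default).

# Statistics

`pearson()` returns the sample r with the two-sided p from
\(t = r\sqrt{(n-2)/(1-r^2)}\); `partial_pearson()` implements
covariate correction as the correlation of OLS residuals, on n - 2 - c
degrees of freedom — the standard reading of "corrected for", and one that can
flip signs. `paired_region_test()` is a paired two-sided t-test (Wilcoxon
signed-rank optional for small samples); an exactly constant difference
vector is flagged degenerate instead of producing an unstable t statistic.
`association_screen()` batches pairs with per-pair covariate sets and applies
no multiplicity correction by default, matching exploratory small-cohort
practice; Benjamini-Hochberg is available behind a flag and labelled as such.

# Problem sizes and determinism

The validation suite runs on deliberately small instances: a 32 x 32 x 20
phantom, 10^4-voxel relaxometry slabs, 50-subject shape cohorts (~680 points
per surface), 500-replicate correlation simulations. These sizes were chosen
so the entire suite and the acceptance script each complete in a couple of
minutes on one CPU while leaving every statistical check comfortably powered.
`run_pipeline()` is a pure function of (config, seed): the manifest records a
config hash and the MD5 of every output file, volumes are written as
uncompressed NIfTI so bytes depend only on data, and reruns are bit-identical
— tested, and reported by the acceptance script.

# Known limitations

* No scanner physics: noise enters in image space; attenuation, scatter,
  point-spread, and Dixon fat-water imaging are not modelled.
* The artery-isolation heuristic and the registration algorithm are
  documented stand-ins for unspecified clinical components; contracts, not
  re-implementations.
* Mono-exponential relaxometry without a noise floor; biased under strong
  Rician noise.
* The femur template is a parametric proxy, not anatomy; probes are exact on
  it but approximate on real bones.
* Correspondence across surfaces is assumed given.
* Reported patient-cohort values (SUV/Kpat means, correlation r's, variance
  percentages) are cohort-specific and are *not* reproduced — the phantom
  plants effects of the same magnitude and the package checks recovery.
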
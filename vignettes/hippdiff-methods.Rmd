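---
title: "Models and methods behind hippdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hippdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hippdiff` simulates and analyses multi-shell diffusion MRI (dMRI) studies of
age-related hippocampal gray-matter microstructure. This vignette is the
package's own account of the science it implements: the signal models and
their assumptions, the geometry and statistics, the design of the synthetic
study generator, the numerical choices, and the limitations a user should
know about. Everything quantitative asserted here is computed by the test
suite or by `scripts/acceptance.R`; nothing is quoted from elsewhere.

## The problem

Hippocampal development during late childhood and adolescence is thought to
be microstructural — growth and pruning of neurites, changes in soma
characteristics — rather than macrostructural (volume, thickness). Diffusion
MRI can separate these contributions, but only through biophysical models
fitted voxel-wise to multi-shell acquisitions, followed by surface-based
anatomical localisation and cohort-level statistics. Real paediatric data of
this kind are access-restricted, so the package ships a fully synthetic study
generator whose outputs exercise every stage of the analysis: acquisition
scheme, cohort, anatomy, ground-truth microstructure with age and sex
structure, and noisy signals.

## Acquisition scheme

The default protocol has six shells, b = 0 (14 volumes), 0.5 (30), 1.2 (30),
2.4 (60), 4.0 (60) and 6.0 (60) ms/µm², with near-uniform directions from a
Fibonacci sphere lattice. Pulse timings are not part of the emulated
protocol's public description; the defaults δ = 7 ms, Δ = 24 ms are typical
of strong-gradient systems capable of b = 6 ms/µm², and both are
configurable. Absolute soma-radius values depend on this timing choice; all
comparisons within a simulated study are unaffected.

## Signal models

**Diffusion tensor (DTI).** `S = S0 exp(−⟨B, D⟩_F)` with `B = b g gᵀ` the
b-matrix of a volume. Fitted by weighted linear least squares on
log-signals (weights = squared signals) using the b ≤ 1.2 ms/µm² shells
only, where the single-tensor approximation is defensible. Mean diffusivity
is the eigenvalue mean; fractional anisotropy the normalised eigenvalue
standard deviation; negative eigenvalues are clamped to zero and flagged.

**Watson-dispersed stick + zeppelin + CSF (NODDI).**
`S = (1 − f_iso)(f_in S_in + (1 − f_in) S_en) + f_iso S_iso`, with the
intraneurite compartment a stick of diffusivity 1.7 µm²/ms dispersed by a
Watson distribution of concentration κ about a mean orientation µ, the
extraneurite compartment a zeppelin with the standard tortuosity constraint
`d_perp = d_par (1 − f_in)` (the tortuosity constraint is the convention of
the model family, adopted here and stated explicitly because it is a
modelling assumption, not a fitted quantity), and CSF an isotropic ball at
3.0 µm²/ms. The orientation dispersion index is `ODI = (2/π) atan(1/κ)`.

The Watson average of a stick, `E[exp(−c (g·n)²)]`, is a spherical integral
of `exp(nᵀ Q n)` with the rank-2 form `Q = κ µµᵀ − c g gᵀ`. We reduce it
exactly to one dimension: with eigenvalues `(λ₊, λ₋, 0)` of `Q` obtained in
closed form from the 2×2 block in span{µ, g}, the integral becomes a
Gauss–Legendre quadrature in cos θ with a Bessel-I₀ azimuthal kernel
(order 64 by default, 48 inside the fitter). The reduction is exact; only
the 1-D quadrature is approximate, and it is cross-checked in the tests
against Monte-Carlo spherical sampling and against the closed-form powder
stick at κ = 0. κ = ∞ switches to the coherent-stick expression.

**Soma and neurite density (SANDI).** The direction-averaged (powder)
signal `S̄(b) = (1 − f_ec)(f_in S̄_in + (1 − f_in) S̄_is) + f_ec S̄_ec`, with
the powder stick `S̄_in = √(π/(4 b d_in)) erf(√(b d_in))`, an isotropic
extracellular ball, and an impermeable sphere of radius `r_s` under the
Gaussian phase distribution (GPD) approximation with intra-soma diffusivity
fixed at 3.0 µm²/ms. The GPD series runs over stationary points of the
first-order spherical Bessel function (30 terms by default, with a
truncation check). Derived maps: `fneurite = (1 − f_ec) f_in`,
`fsoma = (1 − f_ec)(1 − f_in)`, `fextracellular = f_ec`, and `Rsoma = r_s`;
the three fractions sum to 1 by construction.

**Fitting.** NODDI and SANDI are inverted by bounded multi-start
Levenberg–Marquardt (5 Latin-hypercube starts plus one moment-based start by
default; bounds: fractions [0,1], r_s [1,12] µm, diffusivities
[0.1,3] µm²/ms). The reference implementations of SANDI use machine-learning
regression; bounded NLLS estimates the same quantities and is far easier to
verify against the forward model, which is why it is used here — absolute
agreement with learned fitters is not claimed. The orientation µ is fixed to
the DTI principal eigenvector (or supplied externally) rather than fitted
jointly; this decouples orientation from magnitude fitting. Because the
inversions have multiple basins, further deterministic start batches are
launched until the best fit reaches the data's expected noise floor
(estimated from replicate scatter; effectively zero for noiseless data).
Ties are broken by start index; every fit is deterministic given
(inputs, seed).

A note on conditioning: with five nonzero shells and five free parameters,
the SANDI inversion is exactly determined, and two consequences follow.
First, it is globally non-unique outside an identifiable domain: for large
somas (r_s above roughly 8 µm at the default pulse timings) or
extracellular-dominated voxels, a second parameter vector reproduces all
five shell means to machine precision — the tests freeze one such duplicate
pair — so no estimator can recover the generating parameters there, and
recovery claims are made over the study-conditions domain (f_ec 0.22–0.48,
fsoma 0.35–0.48, r_s 6–8 µm, d_in 1.4–2.0, d_ec 0.8–1.2 µm²/ms), where the
fitter's measured noiseless recovery rate is >99%. Second, the
`fsoma`/`Rsoma` pair is weakly identified even inside that domain — noise
moves the two estimates along a soft trade-off ridge (smaller somas resemble
fewer somas). Measured consequence: with parcels of only a few dozen voxels,
an injected `Rsoma` age decline leaks a spurious positive `fsoma` age trend;
with realistic parcel sizes (a few hundred voxels at 2 mm resolution) the
leak is negligible. The end-to-end tests therefore use parcels of ~190
voxels per hemisphere.

## Synthetic study generator

The generator's defaults are the study conditions every downstream test
assumes: 88 participants aged 8–19 years (42 male), both hemispheres, ages
uniform by default with an optional right-skewed mode that oversamples the
8–12 year range. Ground-truth effects are injected per subfield directly on
the *reported* signal fractions — the extracellular fraction declines at
−0.008/year, the soma fraction is exactly flat, hence the neurite fraction
rises at +0.008/year; soma radius declines at −0.06 µm/year in Sub and CA1
only; orientation dispersion has no age trend; a +0.0025/year sex-by-age
interaction sits on the extracellular fraction. Intercepts vary across
subfields (f_ec 0.32–0.38, ODI 0.5, r_s 7 µm, d_in 1.7, d_ec 1.0 µm²/ms).
Ages are centred at the cohort mid-point (13.5 y) so intercepts are
mid-cohort parcel means. Values are clipped to physical bounds with the clip
count logged; the default effect sizes never clip. Through the compartment
mix these choices also imply a declining mean diffusivity (the extracellular
compartment is the most diffusive), without any explicit MD effect.

Parametrising the derived fractions directly (rather than the raw stick
fraction of the cellular signal) keeps all three injected fraction trends
exactly linear in age; the raw intraneurite fraction follows as
`f_in = fneurite / (1 − f_ec)`.

The domain is a topologically correct curved slab, not hippocampal anatomy:
a box in the AP/PD index plane whose mid-surface undulates along IO, with
analytic "true" coordinates retained so Laplace solutions and surface
placement can be tested against exact answers. Subfield labels are equal
proximal-distal bands (Sub, CA1, CA2, CA3, DG/CA4) and long-axis labels
equal anterior-posterior bands; the histology-atlas boundaries of real
pipelines are out of scope. Orientation fields are coherent along a chosen
anatomical axis. Noise is Rician by default (magnitude MRI), with
`sigma = S0/snr` defined at b = 0, plus Gaussian and noiseless modes used by
oracle tests; the closed-form Rician mean is verified against sampled
magnitudes. T2 differences between compartments are ignored — fractions are
signal fractions, not volume fractions — and no scanner artefacts (motion,
eddy, Gibbs) are simulated.

Ground-truth residuals can be drawn per voxel (default) or per parcel
(`residual_scope = "parcel"`): the latter is the reduced-scale stand-in for
between-participant biological variability used on small test domains, where
per-voxel residuals would be averaged away by parcel means while inflating
simulation cost.

What passing tests do and do not show: the generator produces on-model
signals — compartment mixtures exactly obeying the fitted forward models on
a geometrically idealised domain. Passing recovery and sign tests
demonstrates the pipeline's correctness and statistical calibration, not
robustness to off-model tissue (exchange, fibre crossings, T2 effects,
partial volume) or to real anatomical variability.

## Geometry

Laplace coordinate fields ψ_AP, ψ_PD, ψ_IO solve ∇²ψ = 0 on the gray-matter
mask with ψ = 0/1 on per-axis source/sink boundary layers and zero-flux
conditions on other mask walls. The 7-point discrete Laplacian is solved
directly (sparse Cholesky) rather than by relaxation: exact to solver
precision with no iteration-count tuning; the residual max-norm is checked
against the same 1e-6 tolerance a relaxation scheme would use. On a
rectangular slab the solution equals the analytic linear ramp to better than
1e-5 and satisfies the discrete maximum principle.

Gradient fields use central differences (one-sided at mask edges, flagged
where undefined). The primary diffusion orientation is an externally
supplied peak field or, by default, the DTI principal eigenvector —
spherical-deconvolution peak estimation is a cited external method, not
reimplemented here. The three cosine-similarity maps are the absolute
normalised inner products between the primary orientation and each axis
gradient: 0 = orthogonal, 1 = parallel (antiparallel vectors also give 1).

The midthickness surface is a regular unfolded grid (121 × 60 = 7260
vertices by default; the real convention uses 7262, and exact vertex-count
matching is not a goal) mapped to native space by walking the IO streamline
(RK4 through the normalised gradient, step 0.25 voxel) to the ψ_IO = 0.5
level and then refining all three coordinates jointly with a damped
quasi-Newton iteration on the interpolated fields. Volume sampling uses the
enclosing voxel, no interpolation. Thickness is the IO streamline arc length
(plus one voxel for the two half-voxel caps beyond the boundary-layer
centres); gyrification is native vertex area over area-matched unfolded
vertex area, so a distortion-free mapping gives exactly 1; subfield volume
is voxel count times voxel volume, and subfield volumes sum exactly to the
GM volume. Voxel indices are 0-based with native coordinates at voxel
centres, `(index + 0.5) × voxel size` mm.

## Statistics

Parcel-level: metrics are sampled to the surface, averaged within subfield
or long-axis parcels per participant and hemisphere, and hemispheres are
averaged within participants unless the hemisphere-by-age interaction is
significant (the averaging function refuses, per metric, unless forced).
Age associations use two-sided Pearson correlation with a significance
ladder whose minimum alpha 0.01 is the Bonferroni per-test level for five
subfield tests at family-wise 0.05; 0.005 and 0.0005 are also annotated. The
ladder is metadata — raw p-values are always emitted.

Interaction tests are nested-model F-tests,
`F = ((SSE_red − SSE_full)/Δdf) / (SSE_full/df_full)`, with treatment coding
and alphabetical reference levels, for the three families age:sex,
age:hemisphere and age:parcel; the shared design
`value ~ age + parcel + sex + age:parcel + sex:parcel (+ age:sex)`
reproduces F(1,424)/F(4,424) shapes at n = 88 and 5 parcels.
Benjamini–Hochberg correction is applied within each declared metric family.

Vertex-level: per vertex, `value ~ age + sex + age:sex` across participants,
extracting `t = β_age/SE(β_age)` (complete cases per vertex; exact fits and
zero-variance vertices masked). Age-contrast maps are summarised by their
absolute Pearson correlation with the contrived positional AP and PD
gradient maps (the unfolded coordinates themselves) and by the mean |t|.

Spin test: the correlation between two surface maps is tested against a
null built from random rigid transformations of one map on the unfolded
rectangular grid — toroidal translations plus optional axis flips — which
preserve spatial autocorrelation; the exact transform family of
published hippocampal spin tests is not reproduced (it is not fully
specified by their descriptions), and the toroidal family is a documented
stand-in. Two-sided p with the finite-sample correction
`p = (1 + #{|R_null| ≥ |R_obs|}) / (n_perm + 1)` guarantees p > 0; the
default is 2500 permutations. The reference battery correlates each
age-contrast map with each reference map and applies Benjamini–Hochberg
across the whole matrix. The shipped reference maps are *synthetic*
Gaussian random fields with controlled smoothness, clearly named stand-ins
for quantitative-R1, Bielschowsky, Merker, SV2A, calretinin, calbindin and
parvalbumin maps; they reproduce smoothness only, and any conforming
user-supplied maps can be substituted.

## Numerical choices and problem sizes

* Watson integrals: Gauss–Legendre order 64 (48 in the fitter); κ capped at
  64 (ODI ≥ 0.01); κ = ∞ handled analytically.
* GPD series: 30 terms, truncation warning at 1e-7 on the log-signal.
  The GPD approximation itself degrades at strong diffusion weighting for
  large spheres: against a timestep-converged random-walk simulation it
  agrees to <0.3% for qR ≲ 1.7 (e.g. r_s = 3 µm at b = 6, 8 µm at b = 0.5)
  but overestimates the signal by ~20% at r_s = 8 µm, b = 4 ms/µm²
  (qR ≈ 3.4). This is a known limitation of the approximation, inherited by
  everything built on it; the tests pin both the validity regime and the
  breakdown.
* Optimisation: bounded Levenberg–Marquardt, ftol 1e-15, 200 iterations,
  Latin-hypercube starts plus a moment-based start; further deterministic
  start batches are launched (up to 6) until the best fit reaches the data's
  expected noise floor, estimated from within-shell direction scatter
  (SANDI) or b = 0 replicate scatter (NODDI); ties by first index.
* Laplace: direct sparse Cholesky, residual max-norm ≤ 1e-6.
* Degenerate inputs are errors or flags, never silent: empty shells,
  sub-6-direction shells, non-positive signals, all-zero tensors (FA = 0 by
  convention), zero-norm peaks, constant t-maps, zero-variance correlations.
* Test problem sizes (chosen so the full suite runs on one CPU in tens of
  minutes): recovery at 500 voxels per model; bias/RMSE ladders at 150
  voxels per snr; calibration at 1000 null simulations (F and t) and 500
  spin replicates at 199 permutations; end-to-end sign recovery at 20
  replicates of an 88-participant cohort with parcel-scope fits on a
  ~1000-voxel domain; the spin-test self-correlation check runs at the full
  2500 permutations. The demo pipeline profile is 12 participants, a
  20×14×9 grid, 200 permutations.

## Known limitations

* The generator is on-model by construction; it cannot expose model
  misspecification.
* Fractions are signal fractions: compartment T2 differences are not
  modelled.
* The GPD sphere signal is biased at high qR (above).
* The 5-shell SANDI inversion is non-unique outside its identifiable
  domain, and the `fsoma`/`Rsoma` trade-off makes those two estimates
  mutually contaminating at low effective SNR (above).
* The spin-test null is a toroidal-shift family on the unfolded grid, a
  stand-in for published hippocampal spin-test mechanics.
* Macrostructure on the shared synthetic domain varies between participants
  only through an injected nuisance jitter (no age effect), mirroring a null
  macrostructural finding by construction.
* Surfaces are exchanged as TSV rather than GIFTI.
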
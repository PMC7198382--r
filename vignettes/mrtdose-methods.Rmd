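---
title: "Methods: dosimetry and damage-imaging models in mrtdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetry and damage-imaging models in mrtdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtdose)
```

`mrtdose` implements the computational chain used in preclinical studies
of Lu-177 radiopharmaceutical therapy (e.g. somatostatin-receptor
targeted Lu-177-DOTATATE) in which DNA double-strand-break damage,
reported by gamma-H2AX, is read out alongside physical dosimetry. This
vignette documents the models, their assumptions, the tunable parameters,
and the design decisions taken where the underlying experimental reports
leave the method open.

## Nuclear data

Decay data for Lu-177 (beta emitter, T~1/2~ = 159.5 h, gammas at 113 and
208 keV) and In-111 (electron capture, T~1/2~ = 67.3 h, gammas at 171 and
245 keV) ship as plain-text CSV tables with `# source=` provenance
headers. The Lu-177 beta spectrum is computed once (see
`data-raw/make_nuclide_tables.R`) from the published branch endpoints and
intensities with the allowed-shape Fermi theory using the relativistic
point-charge Fermi function; the resulting mean beta energy (0.1343 MeV)
agrees with the ICRP-107 value (0.1336 MeV) to 0.5%. Conversion-electron
and Auger lines are an approximate compilation; the total electron energy
per decay (0.1477 MeV) matches the reference 0.1473 MeV. Invariants —
spectrum normalisation, non-negative yields, and consistency of the mean
electron energy with its components — are enforced by tests.

## Cellular dosimetry

The cell is modelled as two concentric spheres (nucleus radius $r_N$,
cell radius $r_C$) with the membrane as a thin source shell (default
0.01 µm) at the cell surface. Cellular S values
$S(N \leftarrow \mathrm{source})$, the nucleus dose per unit cumulated
activity in a source compartment, are computed by Monte Carlo: source
positions uniform in the compartment, emission energies drawn from the
electron mixture, isotropic directions, and straight-line
continuous-slowing-down (CSDA) transport on a NIST-ESTAR range table.
The energy deposited along the chord through the nucleus is the
difference of residual energies at entry and exit.

Approximations, in decreasing order of importance:

* **Straight-line CSDA transport** — no multiple scattering or delta
  rays. Justified because cell dimensions (µm) are far below the Lu-177
  beta range (up to ~1.8 mm); the dominant uncertainty is the chord
  geometry, not the track structure.
* **Photons ignored at the cellular scale** — the photon absorbed
  fraction for keV gammas in a 10-µm sphere is below 1e-3, standard
  practice in cellular MIRD dosimetry.
* **Equilibrium cross-dose** — cells irradiated in suspension receive a
  cross-dose from medium and neighbour activity computed as the
  charged-particle-equilibrium dose: time-integrated activity
  concentration × mean electron energy per decay / density, minus the
  own-cell term already counted exactly through the S values. An
  explicit pairwise cell lattice is not modelled.

A note on the published beta range: the "1.7 mm average" sometimes
quoted for Lu-177 corresponds to the *maximum* (endpoint) CSDA range in
water; the range of the mean-energy electron (134 keV) is about 0.24 mm.
The package documents both and adopts neither as "the" range; all
transport uses the full spectrum.

The Monte-Carlo estimator is validated against an independent
deterministic triple-quadrature oracle (source radius × direction cosine
× emission energy) with its own geometry arithmetic; agreement is
required within 3 Monte-Carlo standard errors plus a 2% quadrature
allowance. Reciprocity ($m_T S(T\leftarrow S) \approx m_S S(S\leftarrow
T)$) holds to ~5%; it is approximate because electron transport is not
symmetric under source/target exchange at these energies.

Default geometry is $r_N = 5$ µm, $r_C = 10$ µm. The originating
experiments derived per-cell-line geometries from confocal microscopy but
did not print them, so the defaults here are explicit, configurable
placeholders — results that depend on them should be treated as
scenario-conditional.

## Clonogenic survival

Survival follows the linear-quadratic model
$SF(D) = \exp(-\alpha D - \beta D^2)$. The fit is weighted least squares
on $\ln SF$ with inverse-variance weights from the binomial counting
error, under the constraint $\alpha, \beta \ge 0$ (active-set reduction;
the fitting method is a package choice, as the source experiments do not
state theirs). D90, the dose at which survival has dropped 10-fold,
solves $\alpha D + \beta D^2 = \ln 10$ and is evaluated in the
cancellation-free form $2\ln 10 / (\alpha + \sqrt{\alpha^2 + 4\beta\ln
10})$. Zero-colony wells receive a 0.5-colony continuity correction with
a warning. EBRT-vs-MRT comparison uses an F test of curve coincidence
(pooled vs separate weighted fits) plus a pointwise predicted-difference
band. Dose-rate effects (Lea–Catcheside) are out of scope.

## gamma-H2AX focus quantification

Nuclei are segmented from the nucleus channel by Otsu thresholding, hole
filling, connected components, and distance-transform seeded splitting of
touching objects. Focus detection is multiscale Laplacian-of-Gaussian
blob detection (scales 1–2.8 px by default) restricted to nucleus masks,
with per-scale thresholds at `k_sigma` (default 4) robust noise SDs of
the filtered response — thresholds are relative, so counts are invariant
to global intensity rescaling.

Counting by LoG maxima alone undercounts densely damaged nuclei, where
foci lie closer than the optical resolution. `detect_foci()` therefore
runs a CLEAN-style fit-and-subtract refinement per nucleus: Gaussian
amplitudes at the detected positions are fitted jointly by ridge-
stabilised linear least squares (template width estimated image-wide from
isolated blobs), the model is subtracted, residual peaks above a stricter
threshold are added, and the set is re-fitted with backward elimination
of components below 3 noise SDs. On synthetic truth this keeps recall
and precision above 0.9 and the mean count within 10% of the generating
mean up to ~80 foci per nucleus; beyond that, counts degrade gracefully
(the hard resolution limit of merged spots).

Pan-nuclear staining (late-stage apoptosis) is flagged and excluded from
counts. The criterion requires both a large bright area fraction (default
0.5 of the nucleus above the focus-intensity threshold) *and* uniformity
(median elevation above background exceeding 3× the nucleus-internal
MAD). The uniformity conjunct is a deliberate extension of a pure
area-fraction rule: nuclei with dozens of overlapping foci can exceed any
area threshold, but their punctate texture has high internal contrast,
while true pan-nuclear staining is flat.

Group summaries use Welch t tests (two groups) or Welch ANOVA with
comparisons against control. Exact Dunnett critical values need the
multivariate t distribution, which is not available in this dependency
set; the package substitutes Holm-adjusted Welch t tests against the
control — conservative, and flagged in the output as an approximation.

## Tumor dosimetry

Tumor time–activity curves are fitted with a mono-exponential
$A(t) = A_0 e^{-\lambda_{\mathrm{eff}} t}$ on the washout phase (samples
at and after the maximum; uptake peaks at ~1 h in the emulated
experiments). The biological half-life follows from
$1/T_{\mathrm{eff}} = 1/T_{\mathrm{phys}} + 1/T_{\mathrm{bio}}$.
Cumulated activity is the trapezoid over observed samples plus an
analytic exponential tail. Absorbed dose uses the sphere model
re-implemented as Monte Carlo: the electron absorbed fraction
$\varphi_e(R)$ from the same CSDA transport applied to a uniform sphere
(validated against a deterministic radial-quadrature oracle and the
equilibrium limit $D \to \tilde{A}\Delta_e/\rho$), with density 1.03
g/mL for soft (lymphoid-like) tissue. A crude photon self-dose term
(mean-chord $\mu_{en}$ approximation) exists but is off by default;
electrons dominate at mouse-tumor scale. Dose is integrated to 72 h by
default in the CLI, matching how the emulated study reports it, with
`t_end_h` exposed.

Two estimator choices deserve a note. First, activity quantification
noise is multiplicative, so `fit_monoexp(..., error_model = "lognormal")`
fits by OLS on log activity — the maximum-likelihood estimator under
that noise model; the default remains original-scale `nls`. Second, when
a cohort of curves is summarised, the package reports the half-life of
the *mean clearance constant*, $\ln 2 / \bar{\lambda}$ (for a balanced
design this equals the pooled common-$\lambda$ fit). The arithmetic mean
of per-animal half-lives is systematically high — $1/\hat\lambda$ is
convex, so at a per-animal $\hat\lambda$ CV of ~12% (four samples, 10%
noise) the mean half-life is inflated by ~1.6% — whereas clearance
rates average linearly.

Percent-injected-dose conversions use the injected activity without
decay correction; this convention is not stated in the source reports
and is therefore configurable and logged prominently here.

## Dual-isotope quantification

Two-window In-111/Lu-177 quantification is standards-based: a 2×2
sensitivity/crosstalk matrix $M$ (counts per MBq, window × isotope) is
estimated by least squares from a phantom ladder spanning pure In to pure
Lu, and samples are unmixed as $A = M^{-1}c$ with Poisson error
propagation ($\mathrm{cov}(A) = M^{-1}\mathrm{diag}(c)M^{-T}$) and
clip-to-zero (flagged) for negative estimates. The scanner itself —
pinhole geometry, scatter, attenuation — is deliberately not modelled;
the linear window-count response mirrors how quantification against
known-activity standards works in practice.

## Spatial dose–damage correlation

Co-registered activity/damage map pairs (autoradiography vs gamma-H2AX
immunofluorescence; or Lu-177 vs In-111 SPECT) are analysed
pixel-by-pixel: integer-translation registration by masked
cross-correlation, edge erosion (default 3 px) to omit section-edge
staining artefacts, 2-D histogram, OLS regression, and a Wald–Wolfowitz
runs test on residual signs ordered by the predictor as the linearity
check (exact combinatorial null for n ≤ 20, normal approximation with
continuity correction otherwise; the reported p is left-tailed — too few
runs indicate systematic curvature). Voxel-binned analysis partitions
voxels into equal-width half-open bins of the activity map and reports
the largest lower sub-range whose linear fit passes the runs test — the
operational definition of "linear up to" a saturation point.

## The synthetic world

Every generator default encodes a reported condition of the emulated
study; none is tuned to test outcomes:

| Generator | Stated condition encoded |
|---|---|
| `gen_uptake_timecourse()` | 57 mBq/cell at 2 h; 13% cytoplasm; <0.1% nucleus; 6–9 mBq/cell nonspecific band |
| `gen_survival_data()` | binomial colonies from LQ truth; D90 plausibility band 5.3–9.5 Gy |
| `gen_micrographs()` | focus counts NB(67, 18) at 1 h post 6 Gy; 42±14 vs 15±9.7 at 72 h; sigma 2 px spots, SNR ≥ 5 |
| `gen_tac_cohort()` | T_bio 65.2 h ⇒ T_eff 46.3 h; 36 %ID/mL at 24 h; 177 mm³ tumors; 20 MBq injected |
| `gen_phantom_series()` | In:Lu ladder 1:0→0:1, 10–20% crosstalk, ≥1e4 counts/tube |
| `gen_tumor_maps()` | heterogeneous uptake; damage linear up to 20 (%ID/g-like) then plateau |

Choices the reports do not fix, made once and kept: focus positions use
a hard-core (sequential-inhibition) process with minimum separation 2
sigma — distinct chromatin domains of ~0.5 µm at the emulated pixel
scale do not overlap; per-animal biological half-lives are lognormal
with CV 0.25, chosen so the cohort T_eff SD (~8 h) matches the reported
inter-animal spread; uptake saturates with a 0.5 h half-time (dynamic
imaging in the emulated study peaks at 60 min); negative-binomial counts
reflect the reported overdispersion (SD > sqrt(mean)).

What a green test does *not* establish: the generators draw Gaussian
spots on elliptical nuclei with stationary noise — real micrographs have
uneven illumination, autofluorescence and 3-D defocus; the TAC model is
a single exponential — real curves have perfusion components; phantom
counts are ideal Poisson — real reconstructions have correlated noise.
Detector and fitter performance on these synthetic worlds bounds, but
does not guarantee, performance on real data.

## Numerical choices

* CSDA ranges interpolate log-log between ESTAR anchors; below the
  10 keV anchor the first segment's power law is extrapolated (affects
  only the last ~2 µm of track).
* The LoG kernels are scale-normalised ($\sigma^2\nabla^2 G$) and
  DC-free; blob candidates are strict 8-neighbourhood maxima.
* Half-open bins `[lo, hi)` with a right-closed top bin; 0-based pixel
  coordinates in all outputs.
* Monte-Carlo reproducibility: every stochastic routine takes `rng_seed`
  and restores the caller's RNG state.
* Image files: the offline toolchain has no TIFF codec, so maps and
  micrographs travel as plain-text CSV matrices (`write_map()` /
  `read_map()`), lossless for the data the package produces.

## Known limitations

* No electron track-structure (nanodosimetric) detail; no photon
  transport beyond the crude sphere term.
* Cellular geometries are study-specific inputs; shipped defaults are
  placeholders.
* The exact Dunnett procedure is approximated (see above).
* Deformable registration, stain normalisation and 3-D confocal stacks
  are out of scope; registration is integer-pixel translation only.
* The mean tumor absorbed dose of the emulated study (12.9 ± 3.4 Gy)
  depends on unpublished per-animal curves; the package checks only that
  an end-to-end synthetic cohort lands at the same order of magnitude.
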
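---
title: "Methods: average glandular dose estimation and model comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: average glandular dose estimation and model comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammodose)
```

## The dosimetric problem

Average glandular dose (AGD) — the mean absorbed dose to the radiosensitive
glandular tissue of the compressed breast — is the reference patient-dose
quantity in mammography. It cannot be measured: it is inferred from a
measurable entrance quantity through Monte-Carlo-derived conversion factors
that depend on compressed breast thickness, beam quality (half-value layer,
HVL) and, most sensitively, on the breast's glandularity (the glandular
fraction of breast mass). Because glandularity is not directly observable
either, every dosimetry protocol embeds a *model* of it, and the choice of
model moves reported doses by amounts that matter for dose registries and
diagnostic reference levels.

`mammodose` implements three glandularity routes through the dose
calculation and the analyses needed to compare them on a cohort:

1. **Population model (Dance formalism).**
   $\mathrm{AGD} = K \cdot g(T, \mathrm{HVL}) \cdot c(G, T, \mathrm{HVL})
   \cdot s(\mathrm{anode/filter})$, where $K$ is the incident air kerma
   (IAK, mGy, no backscatter), $g$ converts kerma to dose for a 50%
   glandular breast, $c$ corrects for glandularity $G$ differing from 50%
   ($c(50\%) = 1$ by definition; $c < 1$ for denser breasts) and $s$
   corrects the spectrum relative to Mo/Mo. $G$ comes from a population
   table indexed by age group and thickness.
2. **Equipment (Wu) formalism.** $\mathrm{AGD} = X_{ESE} \cdot
   \mathrm{DgN}$, entrance skin exposure times a normalized glandular dose
   coefficient. Clinical systems estimate the breast density in the
   *densest region* of a pre-exposure image, so their effective
   glandularity is roughly twice the whole-breast value except at the
   extremes. The package defaults to *pass-through* of the
   equipment-reported dose — which is what a retrospective header analysis
   observes — and offers a compute mode for synthetic cohorts.
3. **Personalized (volumetric) model.** The same Dance formalism, but with
   $G$ measured from the projection image: per-pixel dense-tissue
   thickness $h_d = \ln(P/P_\mathrm{fat}) / (\mu_\mathrm{fat} -
   \mu_\mathrm{dense})$, integrated to a volumetric breast density (VBD)
   and converted to percent by weight (GPW).

The three estimates and their pairwise ratios are computed per exposure by
`compute_agd_table()`; `summarize_ratios()`, `density_categories()`,
`fit_glandularity_regression()` and `ratio_covariate_correlation()`
reproduce the comparison analyses.

## Conversion-factor tables and interpolation

The shipped tables (`load_factor_tables("paper-default")`) transcribe the
published grids: $g$ and $c$ at thickness 20–110 mm × HVL {0.3, 0.5, 0.8}
mm Al, the 50–64-year population glandularity column, and fourteen
thickness-class reference points (seven classes × two age groups) carrying
paired Dance/personalized glandularities and c-values at the
bin-representative HVLs 0.380–0.459 mm Al. The original parametrization
behind those numbers is not published; the package substitutes
interpolation over the printed nodes, with a loader (long-form CSV with
explicit axis columns) that accepts fuller user tables.

* **g**: bilinear in (thickness, HVL); exact at nodes; queries outside the
  stated validity range (2–11 cm, 0.3–0.8 mm Al) are errors, never
  extrapolations.
* **c**: the table is organized as *stations* — per-(thickness, HVL)
  piecewise-linear curves in glandularity. Each printed node is kept
  exactly; curves are anchored at the definitional $c(50\%) = 1$ where no
  printed 50% node exists, and extended to glandularity 0 and 100 with
  their end-segment slopes so every query in $[0, 100]$ is inside the node
  span (the 40 mm station, whose only printed node sits at 50%, borrows
  its slope from the neighbouring thickness stations). Between stations the
  value is bilinear across the rectangular grid; the thickness-class
  reference stations sit off that grid and take precedence on an exact
  (thickness, HVL) match, which keeps every printed c-value exactly
  reproducible at the cost of a sub-0.2% discontinuity in an
  $\varepsilon$-neighbourhood of those fourteen points. Interpolated
  values are bounded by their bracketing nodes and strictly decreasing in
  glandularity by construction.
* **s**: exact lookup; Mo/Mo = 1 is definitional and validated at load.
  The transcribed reference grids include no s values, so the defaults
  (Mo/Rh 1.017, Rh/Rh 1.061, Rh/Al 1.044, W/Rh 1.042, W/Ag 1.042) are
  taken from the published s-factor literature of the Dance formalism.
* **Population glandularity**: the 50–64-year column is printed in full;
  the 40–49-year values are only printed at the seven class-representative
  thicknesses, which are themselves unprinted. The package recovers those
  thicknesses (23.18, 32.55, 44.18, 53.25, 62.22, 75.6, 95 mm) by
  inverting the 50–64 column at the older group's class glandularities —
  the unique choice that makes the two printed blocks mutually consistent.
  Ages below 40 use the 40–49 table and 65+ the 50–64 table (the
  neighbour-substitution rule); the age-group policy is configurable.
* **DgN**: the true equipment polynomials are proprietary; compute-mode
  Wu doses default to a *Dance-equivalent* DgN ($g \cdot c \cdot s$ per
  unit IAK, evaluated at the densest-region glandularity) and are labelled
  approximate. Any user table or function can be plugged in, with its own
  exposure unit convention.

## Image-based density estimation

The two-tissue inversion is exact on its own forward model, which the
phantom generator (`synth_phantom()`) implements: rectangular or
semicircular breast footprints, rectangular dense inserts, exponential
attenuation with defaults $\mu_\mathrm{fat} = 0.057$,
$\mu_\mathrm{dense} = 0.082\,\mathrm{mm}^{-1}$ (representative effective
values near 20 keV), and multiplicative Gaussian noise. Negative dense
thicknesses (noise pushing $P$ above $P_\mathrm{fat}$) are clamped to zero
and thicknesses above the recorded breast thickness clamped down; both are
counted and reported. The VBD→GPW conversion removes a 5 mm subcutaneous
adipose layer per side (matching the population model's 0.5 cm surface
layer assumption), optionally erodes the mask edge, and converts volume to
mass fractions with $\rho_\mathrm{fat} = 0.93$,
$\rho_\mathrm{dense} = 1.04$ g/cm³ — the vendor's exact conversion is
unpublished, so these parameters are exposed and documented as a stand-in.

What the phantom suite does *not* emulate: scatter, beam hardening,
anti-scatter grids, detector glare, paddle tilt, the uncompressed breast
edge's thickness roll-off, and real segmentation (the proprietary
phase-congruency boundary finding is replaced by known masks or
thresholding). Passing phantom tests therefore demonstrate correctness of
the *inversion and bookkeeping*, not clinical fidelity on real mammograms.
A 15% recorded-thickness error changes VBD on the default slab phantom by
about $-13\%$ of its value (≈1–2 percentage points), consistent in
direction and order of magnitude with published sensitivity analyses.

## The synthetic cohort generator

No patient data accompany the package; `generate_cohort()` draws exposure
records whose marginal structure matches the study population the
comparison analyses assume:

* **n = 3050**; CC/MLO alternating.
* **Age**: truncated normal on [18, 80]; parent parameters (59.85, 13.72)
  solved so the *realized* mean/SD equal the reported 57.9 ± 11.9 years.
* **Thickness**: truncated normal (57, 13.5) on [20, 110] mm, rounded to
  integer mm; chosen to reproduce the reported thickness-class occupancy
  322/1464/1135/129 (20–40/41–60/61–80/>80 mm) to within a few percent.
* **HVL**: the class-representative values 0.380/0.397/0.414/0.430/0.459
  mm Al by thickness class, plus N(0, 0.006) jitter.
* **Glandularity (personalized)**: linear plane in age and thickness with
  normal residual, clipped to [0, 100]. The plane is specified on the
  *observable* scale: the defaults are the reported regression
  coefficients (59.6, −0.332 %/y, −0.431 %/mm). Because clipping at 0
  attenuates a refit, the generator draws from a latent plane inflated by
  fixed factors (latent 64.16, −0.3681, −0.4856, residual SD 9.52),
  pre-computed once on a 2-million-record calibration so that
  large-sample OLS on the clipped output recovers the stated observable
  coefficients with $R^2 \approx 0.39$ (the reported $R^2$, which also
  pins the residual SD — the one free parameter). These constants are
  frozen, stored with every cohort, and are not per-seed tuning knobs.
* **IAK**: lognormal with an AEC-like exponential thickness term
  (median 1.5 mGy at 50 mm, doubling per ≈20 mm).
* **Equipment dose**: generated through the Wu pathway — the equipment's
  own glandularity estimate (latent truth + N(0, 3) noise) is doubled and
  capped at 100% (the densest-region heuristic) and multiplied into the
  Dance-equivalent DgN.
* **Anode/filter**: Mo/Mo below 35 mm, Mo/Rh to 55 mm, Rh/Rh above.

All randomness flows from a single seed through named substreams, so
adding a field never perturbs existing draws, and every latent truth is
returned in a sidecar. Known fidelity limits: age and thickness are drawn
independently (the real correlation is unknown), the glandularity model is
exactly linear where real involution saturates, and equipment doses come
from the approximate DgN fallback. Consequently cohort-dependent published
numbers (class mean ratios such as 0.83/0.88/1.02, Pearson correlations,
the 68.6% personalized-glandularity maximum) are *not* assertion targets;
the suite asserts the structural facts instead — exact factor
reproduction, dose linearity, ratio-closure, and the qualitative trend
that the Dance/personalized ratio is below 1 for 20–40 mm breasts and
approaches 1 above 80 mm.

## Worked example

```{r example, eval = FALSE}
ft <- load_factor_tables("paper-default")
cohort <- generate_cohort(cohort_params(), seed = 1)
agd <- compute_agd_table(cohort$records, ft)
summarize_ratios(agd, "ratio_dance_volpara")
fit_glandularity_regression(cohort$records)
```

On seed 1 this reports class means of the Dance/personalized ratio rising
from 0.88 (20–40 mm) through 0.93 and 0.97 to 0.99 (>80 mm), and the
OLS refit returns (59.8, −0.327, −0.440) with $R^2 = 0.40$ — inside three
reported standard errors of the generating coefficients.

## Numerical choices and degenerate inputs

Fractional thicknesses are rounded to integer mm before thickness-class
assignment (matching the integer class labels; R's round-half-even applies
at exact .5 ties); sub-20 mm records join the 20–40 mm class with a
warning. Ratio summaries use the sample (n−1) SD. Density categories use
glandularity quartile bins with boundary values in the lower bin and 0 in
category 1. A constant-glandularity regression input returns zero slopes
with $R^2$ defined as 0; collinear designs are a named singularity error.
Zero-variance correlation inputs are errors, not NaNs. Factor queries
outside the validity ranges are errors naming the offending axis. The
problem sizes used by the test suite (cohorts of 10³–10⁴, phantoms up to
400 × 400 pixels at 0.1 mm) keep the full run within seconds while leaving
discretization error well below the asserted tolerances.

## DICOM reading

`read_dicom_headers()` is a deliberately minimal explicit-VR little-endian
header parser (no R DICOM reader is a package dependency and pixel data is
never touched): it extracts thickness, age (falling back to birth/study
dates), HVL, anode/filter (normalizing DICOM material names), entrance
dose, organ dose (dGy → mGy) and the density fields through a configurable
tag map, because private density tag addresses vary by equipment software
version. Files it cannot parse are skipped with a logged reason.
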
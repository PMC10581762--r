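---
title: "Visual-field geometry and phylogenetic comparative methods in owlfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Visual-field geometry and phylogenetic comparative methods in owlfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owlfield)
library(dplyr)
```

owlfield analyses the configuration of avian binocular visual fields — how
wide the region seen by both eyes is, where it sits relative to the bill,
and what shape it traces across elevations — and relates that configuration
to ecology (diet, foraging habitat, allometry) while accounting for shared
ancestry among species. This vignette is the package's methodological
account: the models, the conventions and tunable parameters, the numerical
choices, and what the synthetic data generator does and does not emulate.

## From perimeter readings to field profiles

A visual-field perimeter locates the margin of each eye's retinal
projection at known angles around the head, at 10° steps of elevation.
Internally azimuth is signed, positive toward the bird's right, zero in the
median sagittal plane; elevation is zero at the horizontal through the
eyes, positive upward. Margins are read from the apparatus centre at finite
radius, but the visual field is defined for a viewpoint at infinity, so
each margin is corrected to the direction *from the eye itself*: with the
head centre at the origin, forward along +y, the eye at `(±s/2, 0)` (eye
separation `s`) and the ophthalmoscope at `(r sinθ, r cosθ)` (apparatus
radius `r`), the corrected azimuth is `θ′ = atan2(r sinθ ∓ s/2, r cosθ)`.
This is the exact 2-D geometry, applied to the horizontal component at each
elevation; it reduces to the identity as `r → ∞` or `s → 0`. Both `r` and
`s` are required inputs (they are properties of the apparatus and the
individual bird, not constants of the method).

At each elevation the binocular width is the overlap of the two medial
margins, `max(0, left − right)`. The clamp stores no negative "gap", but
the signed difference remains recoverable from the margins and is used
where it matters (see vertical extent). The cyclopean field is the union of
the two monocular fields and the blind sector its complement to 360°;
`field_components()` computes the union independently so the
inclusion–exclusion identity is a checkable property rather than a
definition.

Elevations blocked by the bill holder get the arithmetic mean of the
nearest measured widths above and below (`interpolate_blocked()`); measured
rows are never modified. Profiles truncated at the bottom of the
measurement range are closed by extending the trend of the last two
measured widths linearly down to zero (`estimate_lower_bounds()`), with the
added rows flagged. A non-decreasing trend cannot terminate; the profile is
then closed one grid step below, with a warning, rather than silently.

### Summary statistics and their conventions

Three scalars summarise a profile: the maximum binocular overlap, the
elevation at which it occurs (reported as the magnitude of its offset from
the eye–bill-tip projection, an input angle), and the vertical extent of
the binocular field. Two conventions are worth stating:

* **Ties in the maximum** are broken toward the lowest elevation. Owl
  bill-tip projections point downward, so the lowest tied elevation is the
  reference-consistent choice, and it makes the statistic deterministic.
* **Vertical extent** is the distance between the lower and upper limits of
  positive binocular width. Where the *signed* width (left minus right
  margin) changes sign between adjacent grid rows, the limit is the
  linearly interpolated zero crossing — a grid-resolution-independent
  definition; where the profile simply ends with positive width (a
  truncated measurement), the end row is the limit. Zero-width rows beyond
  the limits therefore never change the extent.

Species values are arithmetic means of the per-individual summary
statistics (1–3 individuals per species), not means of raw margins.

## Outline shape: elliptic Fourier analysis

The binocular field outline is projected on a Cartesian plane — x the
half-width on either side of the median plane, y the elevation — traversed
up the right limb and down the left, and closed. Shape is quantified by the
elliptic Fourier transform in the Kuhl–Giardina formulation: the closed
curve, parameterized by arc length `t ∈ [0, T)`, is decomposed as

$$x(t) = a_0 + \sum_{n=1}^{N} a_n \cos\tfrac{2\pi n t}{T} + b_n \sin\tfrac{2\pi n t}{T},
\qquad y(t) \text{ likewise with } c_n, d_n,$$

with coefficients computed as the exact integrals for the piecewise-linear
curve. Outlines are standardized first (`resample_outline()`): the
traversal restarts at the topmost vertex (ties toward smallest x), and `k`
points are placed at equal arc-length spacing. This removes the
parameterization phase without touching orientation.

Normalization removes translation (the `a_0`-type terms are set aside) and
scale (all coefficients are divided by the semi-major axis of the
first-harmonic ellipse, computed as the largest singular value of the 2×2
first-harmonic matrix). **Rotation alignment is off by default**: the full
definition of shape is invariant under rotation, but a visual field's
elevation axis is anatomically meaningful and the Cartesian projection
preserves it; aligning every outline to its first ellipse would erase
up/down structure. A `rotate = TRUE` flag provides the standard
first-ellipse alignment for users who want strict rotation invariance.

One approximation should be understood: because the parameterization is
arc length, even a perfect ellipse has non-sinusoidal coordinate functions
(the curve moves at unit speed, not at uniform angle). Its first-harmonic
ellipse therefore only approximates the true semi-axes (within about 9% at
2:1 aspect) and higher harmonics are small but not zero. The package's
tests assert these properties at honest 10% bounds; for a circle, where
arc-length and angle parameterizations coincide, the first harmonic is
exact and higher harmonics vanish to machine precision.

The number of harmonics is chosen by cumulative harmonic power,
`power(n) = (a_n² + b_n² + c_n² + d_n²)/2`, with a default threshold of
0.99, the smallest count whose cumulative fraction reaches the threshold
across all outlines being retained. `reconstruction_error()` reports the
distance-based criterion (mean point distance to the best available
reconstruction, non-increasing in `n` by Parseval's relation) for visual
inspection. Principal components are computed on the covariance (not
correlation) of the coefficient matrix — coefficients share a unit after
normalization — with zero-variance columns (entries fixed by normalization
or by bilateral symmetry of the outlines) dropped with a warning.
`shape_at_pc()` reconstructs outlines along a component for
interpretation.

## Phylogenetic comparative machinery

Trees are `ape::phylo` objects; `phylo_vcv()` gives the Brownian-motion
covariance `C` (shared root-to-node path lengths). Pagel's lambda scales
the off-diagonal of `C`, leaving the diagonal alone: λ = 1 is Brownian
motion, λ = 0 a star phylogeny.

`pgls_fit()` estimates regression coefficients by generalized least
squares with error covariance `σ²·C_λ`. The likelihood is full Gaussian
maximum likelihood with `σ²` profiled analytically; λ is profiled on
`[0, 1]` with a 101-point grid pre-scan followed by a bounded
one-dimensional optimizer around the best grid point, so boundary optima
(λ ≈ 0 or ≈ 1, common in practice) are found reliably and local optima are
avoided. Conventions, stated so numbers are comparable across software:

* λ is restricted to `[0, 1]`; boundary estimates are reported as reached
  bounds (`phylo_signal_lambda()` flags them).
* AIC counts the regression coefficients plus `σ²` plus λ —
  `AIC = −2·logLik + 2(p + 2)`.
* Coefficient standard errors use the unbiased residual variance
  `RSS/(n − p)`; t statistics are referred to `t(n − p)`.
* Unused factor levels are dropped before the design matrix is built, and
  rank is checked on column-normalized designs so covariates on very
  different scales (body mass in grams next to 0/1 dummies) cannot mask
  collinearity.
* Categorical coding: treatment contrasts with diet baseline
  `invertebrate` and habitat baseline `dense` (`prepare_traits()`).

`phylostep()` performs bidirectional stepwise selection from the
intercept-only model, accepting the single add/drop move with the lowest
AIC until no move improves it, and returns the accepted-move trace so the
monotone AIC decrease can be audited. On four or fewer candidates,
`pgls_all_subsets()` provides the exhaustive certificate; the tests require
the two to agree.

`phylo_anova()` tests a whole grouping factor: the observed statistic is
the ordinary one-way ANOVA F on the raw tip values (the tree plays no role
in F itself), and the null distribution comes from Brownian simulations on
the tree with rate and grand mean estimated from the data by ML, each
simulated dataset re-scored with the same labels. The p-value
`(#{F_sim ≥ F_obs} + 1)/(n_sims + 1)` has resolution `1/(n_sims + 1)`;
`n_sims` defaults to 1000 and the seed is mandatory. Because F is
location-scale invariant, the calibration depends only on the tree's
correlation structure; the type-I error at α = 0.05 is verified to sit in
[0.03, 0.07] on a 23-species tree in the acceptance tests. Degenerate
inputs follow explicit conventions: zero between-group variation gives
F = 0; a trait constant on the tree short-circuits the simulation (p = 1,
with a warning).

`asr_bm()` gives maximum-likelihood (GLS) ancestral states under Brownian
motion via the conditional expectation given the tips; the root estimate
coincides with the intercept-only GLS mean, an identity the tests check
numerically. `mcc_tree()` summarises a tree sample by the
maximum-clade-credibility criterion — each tree scored by the sum of log
sample frequencies of its clades, the best tree returned with node heights
replaced by each clade's mean height across the trees containing it (edges
clamped at zero where the averages are locally inconsistent).

## The synthetic study generator

`sim_config()` + `simulate_study()` generate a full synthetic study:
a pure-birth (Yule) tree conditioned on the species count; diet and
habitat labels by seeded draw; three species traits as
`y = Xβ + ε, ε ~ MVN(0, σ²·C_λ)` with the tree covariance scaled to unit
height so `sd` is the tip-level standard deviation in degrees; and, per
species and individual, perimeter records built by inverse construction —
a tent-shaped signed-width function whose derived maximum, peak elevation
and vertical extent equal the table's values plus seeded individual noise,
mapped back into the apparatus frame (finite radius, finite eye
separation) so the correction pipeline is genuinely exercised. One blocked
elevation per individual (on a linear limb, where the neighbour-mean rule
is exact) exercises interpolation. Each stage draws from its own seed
stream derived from the master seed, so stages can be regenerated
independently.

Defaults are the study conditions the analyses assume: 23 species, 1–3
individuals, 2° individual noise, overlap intercept 52.6° with diet
(vertebrate) −3.6°, habitat −5.0°/−9.8° and λ ≈ 0; vertical extent
intercept 97° with diet −9.7°, habitat −3.0°/−9.1° and λ = 0.97; bill-tip
offset 34.3° with no ecological effects. Residual tip standard deviations
(2.5°, 8°, 6°) were chosen once to be commensurate with the reported
standard errors at 23 species; diet and habitat frequencies (65%
vertebrate; 35/40/25% dense/semi-open/open) reflect a realistic owl
assemblage. Body mass (log-normal around 500 g) and eye axial length
(shallow allometric scaling) carry *no* effect on the visual-field traits:
they are the candidates model selection should reject.

What the generator does not emulate: measurement error in the margins
themselves (noise enters at the level of the summary-defining widths),
asymmetric or non-tent profile shapes, eye movements, facial-disc feather
boundaries, and any raptor-specific anatomy. Passing tests therefore
demonstrate that the estimators recover what the generative model puts in
— identifiability, calibration and correctness of the machinery — not that
real owl fields satisfy the tent-shaped idealisation.

## Problem sizes and runtime choices

The test suite fixes every random seed and uses sizes chosen to make
statistical assertions sharp while keeping the suite fast: 1000 synthetic
profiles for the geometry conservation checks; 4096-point outlines where
machine-precision harmonic statements are made; 200 replicates on a
100-tip tree for λ and β recovery (bias within two Monte-Carlo standard
errors); 500 replicates × 999 simulations on a 23-tip tree for ANOVA
calibration; 100 five-tip samples against the brute-force MCC oracle; and
five seeded 23-species studies for the stepwise-vs-exhaustive certificate.

## Known limitations

* λ is estimated, not tested; no likelihood-ratio intervals are reported.
* No measurement-error (within-species variance) model in the PGLS stage;
  species means are treated as known, as in the analyses this package
  implements.
* The MCC tree uses mean clade heights, which can be locally inconsistent
  for rarely co-occurring clades; affected edges are clamped at zero.
* Outline analysis assumes bilaterally symmetric binocular fields (the
  construction enforces symmetry about the median plane).
* No multiple-testing correction is applied anywhere; every p-value is
  reported with its test and simulation count.
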
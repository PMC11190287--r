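---
title: "Quantifying crystallographic texture in biomineral EBSD maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying crystallographic texture in biomineral EBSD maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conotex)
```

## The scientific problem

Enamel-like biominerals such as conodont crown tissue are polycrystalline
apatite. Because apatite is stiffest along its crystallographic c-axis, the
degree to which the c-axes co-align with the direction of biting stress is a
mechanical adaptation that an organism can control during biomineralization.
EBSD maps record one crystal orientation per pixel; `conotex` turns such maps
into scalar measures of that control and provides the statistical machinery
to compare them across taxa, together with a Raman screen for diagenetic
overprint.

## Orientations, symmetry and misorientation

Orientations are stored as unit quaternions and exchanged with files as Bunge
Z-X-Z Euler angles (degrees in files, radians internally) — the convention of
the CTF and ANG formats the package reads. Crystal symmetry is the set of 12
proper rotations of point group 622: EBSD cannot distinguish
inversion-related orientations, so the hexagonal Laue class is fully
represented by its proper rotations, and no improper operations ever enter
the quaternion algebra. The quaternion sign ambiguity is resolved by keeping
the scalar part non-negative.

The misorientation between two orientations is the smallest rotation angle
relating them after applying the symmetry group to both sides. By conjugation
invariance of the rotation angle the double minimum collapses to a single
sweep over the 12 group elements, which is what the compiled kernel
evaluates; the test suite checks it against the exhaustive 12 x 12 product
oracle to 1e-9 degrees. For this symmetry the largest attainable
misorientation is about 93.84 degrees, which the random-pair reference
reproduces empirically.

Default lattice parameters are fluorapatite (a = 9.37 A, c = 6.88 A). They
only enter through Miller-Bravais direction conversion and can be overridden
in `crystal_symmetry()` when a refinement provides other values.

## The ODF and the Texture Index

The orientation distribution function (ODF) assigns to each orientation g the
volume fraction of material at that orientation, normalized so that the
integral over the orientation space (with normalized Haar measure) is 1; a
random texture has f = 1 everywhere. `build_odf()` estimates f by kernel
density with the de la Vallee Poussin kernel

psi(omega) = C(kappa) cos^(2 kappa)(omega / 2),

symmetrized over the crystal group. The *halfwidth* parameter is interpreted
as the half width at half maximum of the kernel as a function of
misorientation angle — the convention of the established texture toolboxes —
so kappa solves cos^(2 kappa)(h/2) = 1/2; for the 4 degree default,
kappa is about 569. C(kappa) = sqrt(pi) Gamma(kappa + 2) / Gamma(kappa + 1/2)
normalizes the kernel to unit mass; the tests confirm this constant against
direct 1-d quadrature.

The Texture Index is TI = integral of f(g)^2 over orientation space: 1 for a
uniform texture, growing as orientations concentrate. Three independent
routes are implemented:

* **grid** — deterministic quadrature on an equal-volume SO(3) grid built as
  the Hopf-fibration product of a Fibonacci sphere lattice (images of the
  crystal z-axis) and a uniform circle of spin angles. The default
  resolution is half the kernel halfwidth (clamped to 1-5 degrees). Because
  the symmetrized ODF is integrated over the full space, no fundamental-zone
  boundary weights are needed — the integral is identical. The product
  structure also gives an exact analytic neighbor search (a z-band of sphere
  indices, then one circular spin window per sphere point), so evaluation
  scales with the kernel support rather than the grid size.
* **series** — the closed-form route: the kernel's character (Chebyshev)
  coefficients are known in closed form from the cosine moments of
  cos^(2 kappa), the self-convolution follows as T-hat_l = c_l^2 / (2l + 1),
  and TI is the double sum of T over all symmetrized component pairs. This
  is exact up to series truncation (coefficients below 1e-10 are dropped)
  and is the default for up to 5000 components.
* **mc** — Monte-Carlo integration, either over Haar samples or, for sharp
  textures where Haar sampling is hopelessly high-variance, by importance
  sampling from the ODF itself (then TI = E_f[f]). This route exists as an
  independent oracle; the acceptance suite requires 2% agreement with the
  quadrature routes.

A practical note on finite samples: the TI of a kernel estimate from n
discrete orientations has expectation 1 + (TI_single - 1)/n under a uniform
truth, where TI_single is the single-kernel TI (about 710 at 4 degrees under
hexagonal symmetry). This inflation, not an implementation artifact, is why
TI falls with the number of orientations in a region — the effect the
area-subsampling experiment quantifies.

## Pole figures, MUD and pfJ

The pole density of a direction family (e.g. `<0001>` or `<11-20>`) is a
spherical kernel density of all symmetry-equivalent specimen-frame
directions, antipodally symmetrized because diffraction cannot sign a
direction, and normalized to multiples of uniform density (MUD). Only
crystal symmetry is applied; specimen symmetry is triclinic, matching
asymmetric observed pole figures. The spherical kernel is the sphere
analogue of the dlVP kernel with the same halfwidth convention. Quadrature
uses a Fibonacci (spiral) equal-area lattice of 10,000 nodes (about 2 degree
spacing); pfJ is the mean squared MUD over that lattice, the pole-figure
analogue of TI, and is at least 1 by the Cauchy-Schwarz inequality.
Upper-hemisphere stereographic export and plotting are provided for display.

## M-index

The M-index compares the distribution of misorientation angles between
uncorrelated orientation pairs with the random (Mackenzie-type) reference
for the symmetry: M = 1/2 * sum of absolute bin differences, i.e. the
discrete total-variation distance, 0 for a random fabric and approaching 1
for a single crystal. Pairs are drawn from pixels, not reconstructed grains,
because the analyses this package supports apply no grain reconstruction;
the pair count is capped (default 1e5) for tractability and 1 degree bins
follow the convention of the M-index literature. The reference is estimated
once per symmetry by seeded Monte Carlo (1e6 draws) and cached — one
implementation path for any symmetry group rather than a hexagonal-only
closed form; its repeatability (total-variation distance below 0.005
between independent runs) is tested.

## Grain reconstruction as a caveat, not a result

`reconstruct_grains()` performs the standard threshold segmentation: flood
fill over 4-connected indexed pixels joining neighbors whose misorientation
is below the threshold, then discarding grains smaller than 2 pixels and
labelling again. A sweep over 1-17 degrees in steps of 4 is provided, and
each sweep row reports the fraction of grain-boundary interfaces that sit
against a non-indexed pixel. On synthetic maps whose masked pixels follow
patch borders — the situation in beam-sensitive bioapatite — that fraction
is large, demonstrating why inferred grain size distributions would mostly
reflect the pattern of missing data. The package deliberately stops there:
grain sizes are not offered as biological results. Mean grain orientations
use the quaternion eigenvector barycenter after moving members into the
symmetry branch of the grain seed. Non-indexed pixels can be filled from
adjacent grains by repeated one-pixel dilation (so enclosed holes fill
completely); indexed pixels are never modified.

## Subsampling and group statistics

`subsample_squares()` draws axis-aligned squares at seeded uniform positions
(overlap allowed — nothing in the sampling design forbids it), rejects
squares with fewer than 100 indexed pixels, and computes TI, M-index and
optionally pfJ per square. `ti_area_correlation()` is Pearson's correlation
of TI against area with its two-sided t-test; `area_sensitivity()` reports
the slope of each index against log area relative to the index mean, which
is how the package states that the M-index is less area-sensitive than TI.

Between-group comparison uses the tie-corrected Kruskal-Wallis test
(chi-squared approximation, k - 1 degrees of freedom) and pairwise Wilcoxon
rank-sum tests. The Bonferroni divisor defaults to 6 — the number of
samples, reproducing the published convention, giving a per-comparison level
of 0.83% and a 99.17% Hodges-Lehmann confidence interval at alpha = 0.05 —
although 6 groups form 15 pairs; the divisor is an argument because dividing
by the number of pairs is equally defensible, and the choice is left to the
analyst.

## Raman screen

The v1-phosphate band of apatite near 964 cm^-1 is fitted with a classic
pseudo-Voigt: shared center and width for the Gaussian and Lorentzian parts,
a mixing fraction eta in [0, 1], and a *linear* baseline (one extra
parameter buys tolerance of fluorescence slope). The fit window defaults to
940-985 cm^-1 around the band and is configurable. Initialization is
deterministic — argmax for the center, half-maximum crossings for the width,
window-edge regression for the baseline — and optimization uses
Levenberg-Marquardt with box constraints, so a fit is a pure function of the
data. A center within 5% of the window edge raises a warning flag. The
exact parameterization of the proprietary software used in the original
acquisitions is unpublished, so agreement with externally fitted values is
expected at the ~0.1 cm^-1 level, not bit-exact.

Cross-dataset comparison uses ranged major axis (model II) regression of
FWHM over PCMI — appropriate because both band parameters carry measurement
error: both variables are scaled by their ranges, the major-axis slope of
the rescaled scatter is taken in closed form and back-transformed. Slope and
intercept differences between datasets are judged by seeded case-resampling
bootstrap (2000 resamples, percentile intervals).

## The synthetic generator

`generate_map()` emulates the texture archetypes seen in conodont crown
tissue: c-axes concentrated near the functional (X) axis with a
taxon-dependent angular spread; rotation about the c-axis drawn from a
uniform girdle over the 60 degree hexagonal period, a wrapped-normal
dispersed model, or a wrapped-normal mixture (including the three-cluster
case); spatially coherent elongated patches from an anisotropic Voronoi
tessellation whose long axes need not follow the c-axis; and a masked
non-indexed fraction placed at random or along patch borders, spanning the
13-43% range typical of beam-sensitive bioapatite. The c-axis spread is a
rotationally symmetric angular-Gaussian (half-normal angle about a uniform
perpendicular axis), an adequate stand-in for a Fisher-type spread at the
small dispersions used. Every generator is a pure function of (recipe,
seed), and ground truth (patch ids, per-patch orientations) travels with the
map.

The default six-step schedule (`default_taxon_schedule()`) moves from a wide
girdle (c dispersion 24 degrees), through a tighter girdle, a three-cluster
a-axis model, and progressively tighter dispersed models down to 3 degrees,
with within-patch noise and non-indexed fraction shrinking in parallel —
monotonically increasing biomineralization control by construction. What
passing the ordering test shows is that the pipeline *recovers* a known
ordering; it does not show that real inter-taxon differences have any
particular effect size. Likewise the generator does not emulate appositional
growth banding, diffraction artifacts, or spatially varying indexing
quality, so tests on it cannot rule out biases those features might cause in
real data.

## Numerical choices and problem sizes

* Kernel evaluations are truncated where the kernel falls below 1e-6 of its
  peak; the quadrature mass of any ODF is verified to be 1 within 0.5%.
* The kernel lookup table used on the quadrature grid has relative
  interpolation error ~1e-5, far below the 2% oracle tolerances.
* Ties in grain-fill votes go to the smallest grain id; labelling is
  deterministic in raster order.
* Degenerate inputs error loudly: empty ODFs, all-identical group values,
  zero-range regressions, windows outside the spectral range.
* The test and acceptance runs use maps of 72 x 72 to 96 x 96 pixels,
  subsampling schedules of five square sizes times 50 squares, 1e4-1e6
  Monte-Carlo draws, and 10-seed property repetitions — sizes chosen so the
  statistical bounds in the tests (for example, total-variation distances
  and KDE inflation limits) have comfortable margins.

## Known limitations

Square grids only (hexagonal acquisition grids are rejected explicitly);
binary vendor formats are out of scope; no harmonic ODF expansion or
texture-component fitting; no correlated (neighbor-pair) misorientation
statistics; no mixed-effects or spatially correlated inference on the
subsampling results — squares may overlap and are treated as exchangeable,
which the analyst should keep in mind when interpreting p-values.
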
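# conotex

Quantitative crystallographic-texture analysis for biomineral EBSD data,
with a companion Raman diagenesis screen. The package was built for the kind
of question asked about the dental tissues of conodonts — the earliest
skeletonized vertebrates: *how much control did the organism exert over the
orientations of the apatite crystals in its teeth?* Apatite is stiffest
along its crystallographic c-axis, so alignment of c-axes with the biting
(occlusal) axis is a mechanical adaptation, and the sharpness of the
orientation distribution is a proxy for biomineralization control.

It is aimed at palaeontologists and biomineralization researchers who have
per-pixel orientation maps (Oxford CTF or EDAX ANG text exports) and want
reproducible scalar texture measures and the statistics to compare them.

## What it computes

The orientation distribution function (ODF) is estimated from the measured
orientations g_i by kernel density on the rotation space with the
de la Vallée Poussin kernel (halfwidth 4° by default), symmetrized over the
12 proper rotations of the hexagonal point group 622:

  f(g) = (1/N) Σ_i ψ_κ(ω(g, g_i)),  ψ_κ(ω) = C(κ) cos^2κ(ω/2),  ∮ f dg = 1

From f the package derives

* **Texture Index** — TI = ∮ f(g)² dg; 1 for a random fabric, larger the
  sharper the texture (deterministic SO(3) quadrature, a closed-form kernel
  series, and a Monte-Carlo oracle, mutually validated);
* **M-index** — half the integrated absolute difference between the
  uncorrelated misorientation-angle distribution and the random
  (Mackenzie-type) reference for the symmetry;
* **pole figures / MUD and pfJ** — spherical kernel densities of `<0001>`
  and `<11-20>` in multiples of uniform density, and the pole-figure texture
  index (the TI analogue per crystal axis);
* **grain reconstruction sweeps** (1–17° thresholds) that quantify how far
  inferred grain boundaries simply trace non-indexed pixels;
* **area-subsampling statistics** — random squares per map, Pearson
  correlation of TI with area, area-sensitivity of each index,
  Kruskal-Wallis and pairwise Wilcoxon tests with Bonferroni correction;
* **Raman ν₁-PO₄³⁻ band fits** — pseudo-Voigt center (PCMI) and width
  (FWHM) with a linear baseline, plus ranged major axis (model II)
  regression of FWHM over PCMI and bootstrap slope comparisons across
  datasets;
* **synthetic EBSD maps and Raman spectra** with known ground truth
  (girdle / dispersed / clustered rotation about the c-axis, elongated
  orientation patches, masked non-indexed pixels), so the whole pipeline is
  testable without any instrument data.

## Worked example

```r
library(conotex)

# a synthetic map emulating a well-ordered crown tissue: c-axes within ~6°
# of the occlusal axis, dispersed rotation about c, 25% non-indexed pixels
rec <- texture_recipe(c_dispersion = 6, a_model = a_dispersed(6),
                      unindexed_fraction = 0.25)
map <- generate_map(rec, 72, 72, seed = 42)
map
#> <ebsd_map> 72 x 72 px, step 1 um, indexed 75.0% (1 phase)

texture_summary(map, seed = 1)
#>      n area_um2      ti m_index  pfj_c  pfj_a max_mud
#> 1 3888     5184 136.894   0.912 62.431 13.066 134.805

# TI falls as the sampled area grows (finite-sample KDE inflation):
ss <- subsample_squares(map, sizes = c(12, 24, 48), n_per_size = 20, seed = 2)
ti_area_correlation(ss)
#> $rho        -0.525561
#> $p_value     1.618557e-05
#> $n           60

# Raman v1 band at signal-to-noise 50:
sp <- generate_raman(964.0, 4.5, 0.5, snr = 50, seed = 3)
fit_v1_band(sp)
#> <raman_fit> PCMI 964.01 cm-1, FWHM 4.41 cm-1, eta 0.48, residual RMS 19.4
```

A `texture_summary()` row reads: 3888 indexed orientations over 5184 µm²
gave a Texture Index of ~137 (a strongly ordered fabric; a random one gives
1), an M-index of 0.91 (1 would be a single crystal), and much sharper
c-axis than a-axis pole figures — the signature of c-axes locked to the
functional axis with residual rotation about them. Real maps enter the same
functions through `read_ctf()` / `read_ang()` followed by `crop_map()` and
`merge_phases()`.

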
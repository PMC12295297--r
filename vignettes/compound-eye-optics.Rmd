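---
title: "Modelling apposition compound-eye optics from ommatidial morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling apposition compound-eye optics from ommatidial morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ommatidia)
library(dplyr)
```

## The model

An apposition compound eye images through hundreds of independent optical
units (ommatidia). Each unit stacks a biconvex corneal lens over a
crystalline cone and a fused light-guiding rhabdom; its performance is
governed by a handful of measurable lengths: the facet (aperture) diameter
$D$, the corneal radii of curvature $r_1$ (outer) and $r_2$ (inner), the
corneal thickness $t$, and the rhabdom's distal diameter $d$ and length $l$.

The corneal lens is treated as a thick lens. With refractive indices
$n_0$ (air), $n_c$ (cornea) and $n_k$ (crystalline cone), the two surfaces
contribute powers

$$P_1 = \frac{n_c - n_0}{r_1}, \qquad P_2 = \frac{n_k - n_c}{-r_2},$$

both radii entered positive as measured (the biconvex sign convention is
embedded in the $P_2$ formula), and the thickness contributes the
neutralizing term

$$P_3 = -\frac{t}{n_c}\,P_1 P_2, \qquad P_l = P_1 + P_2 + P_3 .$$

From the total power follow the object- and image-side focal lengths
$f = n_0 / P_l$ and $f' = n_k / P_l$ (so $f'/f = n_k/n_0$ exactly), the
F-number $F = f/D$, the small-angle acceptance angle of the rhabdom
$\Delta\rho_{rh} = d/f$, the diffraction (Airy disk) half-width
$\Delta\rho_1 = \lambda/D$, and the white-light optical sensitivity with
self-screening absorption

$$S_w = \left(\frac{\pi}{4}\right)^2 D^2 \left(\frac{d}{f}\right)^2
        \frac{k\,l}{2.3 + k\,l},$$

where $k$ is the rhabdom absorption coefficient and the constant
$2.3 = \ln 10$ converts the decadic self-screening optical density to
natural units. Finally the rhabdom is analysed as a step-index waveguide
with

$$V = \frac{\pi d}{\lambda}\sqrt{n_{rh}^2 - n_{su}^2},$$

whose value against the mode cutoffs $2.405, 3.832, 5.136, 6.380$ (first
zeros of the relevant Bessel functions; the fundamental mode has no cutoff)
determines how many guided light modes the rhabdom supports — a proxy for
how effectively short-wavelength light is retained, relevant for an insect
whose genome-predicted photoreceptors peak in the UV, blue and green.

All angles use the small-angle ratio (not the arctangent) with the
conversion factor $180/\pi$, matching the convention of the comparative
literature at these magnitudes (a few degrees to ~20 degrees).

## Default constants and where they come from

The morphometric source tables print no refractive indices, wavelength or
absorption coefficient, so the package's defaults are calibrated: they are
the unique round-value constants under which the shipped morphometry
reproduces the published derived optics, and they coincide with the values
used by the comparative method for miniature hymenopteran eyes.

| constant | default | role |
|---|---|---|
| `n_outside` | 1.000 | object medium (air) |
| `n_cornea`  | 1.452 | corneal lens |
| `n_cone`    | 1.348 | crystalline cone (image medium) |
| `n_rhabdom` | 1.363 | rhabdom core (literature-standard) |
| `n_surround`| 1.339 | cytoplasm around the rhabdom |
| `wavelength_um` | 0.5 | mid-visible design wavelength, µm |
| `absorption_per_um` | 0.007 | natural rhabdom absorption, µm⁻¹ |

Every value is overridable via `optical_constants()` or a YAML/JSON config
(`read_optical_constants()`). The calibrated status of these defaults is a
real caveat: agreement with the published table validates internal
consistency, not an independent measurement of the indices.

## Printed-precision versus full-precision reporting

Published comparative tables round aggressively, and the rounding is part
of the chain: a total power of 0.0726 µm⁻¹ prints as 0.073, and the printed
focal length 13.7 µm is $1/0.073$, not the unrounded $1/0.0726\ldots =
13.77$. `eye_summary()` therefore exposes both modes:

* `printed_precision` (default): $P_l$ is rounded to three decimals
  *before* the focal lengths are derived; the printed $f$ then feeds the
  acceptance angle, F-number and sensitivity; every output is rounded to
  its report precision (powers 3 decimals; lengths, angles, F-number 1
  decimal; sensitivity 2 decimals) with half-away-from-zero rounding
  (`round_half_away()`), the convention the printed values follow
  (18.466 → 18.5, −0.0029 → −0.003).
* `full_precision`: the unrounded chain, used by the Monte-Carlo
  propagation and any downstream numerical work.

```{r}
m <- eye_morphometry(load_fixture("table1"))
s <- suppressWarnings(eye_summary(m))
tidy(s)
```

### The F-number caveat

For the three comparison wasp species, $F = f/D$ reproduces the published
F-numbers (0.8, 1.4, 1.3). For the focal fig wasp it does not: $13.7/11.8 =
1.16$ against a published 1.1 that was obtained with a revised formulation
whose definition is not part of the public record. The package deliberately
does not guess at that formulation: `eye_summary()` always computes $f/D$
and raises a classed warning (`ommatidia_warning_f_number`) so the
discrepancy is surfaced, never silently absorbed.
`compare_computed_published()` confirms the F-number is the only row on
which the computed and transcribed columns disagree.

## Fixtures and the measurement-table format

Two fixtures ship with the package (`load_fixture()`): the full
morphometric table of the female *Ceratosolen gravelyi* compound eye
(26 parameters with mean, sd, n, range) and the four-species comparative
optics table (*C. gravelyi*, *Megaphragma mymaripenne*, *Trichogramma
evanescens*, *Anaphes flavipes*), extended with each comparison species'
published facet diameter, which the optics table itself does not repeat.
Two transcription choices are worth recording: the source prints a single
ocellus row with two means (median 35.0, lateral 33.2 µm) over one shared
range and no per-type sd — the fixture stores two parameters with the
shared range and a missing sd; and the facet-diameter range follows the
table (9.3–13.7 µm) where the prose says 9.3–13.5.

Measurement tables are plain CSV (`species, parameter, unit, n, mean, sd,
min, max`; tab-delimited accepted on read), with missing cells as empty
strings — never 0, which is a legal-looking length. Parameter names follow
the published row labels, lower-cased; labels that the source reuses across
structural elements ("length", "distal diameter") are prefixed with their
element ("rhabdom length", "cone length") so the flat schema stays
unambiguous. Lengths are µm throughout except two fields the source prints
in nm (microvillus diameter, basal-matrix thickness), converted to µm in
the typed record with the original unit preserved for display. Unknown
parameter names are kept as a pass-through map and reported in a warning,
so partially vocabulary-conformant tables degrade loudly but gracefully.

## The synthetic eye

The facet map of the real eye was measured from tilted SEM replicas and
analysed with unpublished code, so the package ships a generator that
stands in for that stage and gives the regional statistics something
truthful to recover.

`generate_facet_lattice()` places facets on a spherical cap by a
golden-angle spiral followed by one local-repulsion relaxation pass (only
pairs closer than the mean nearest-neighbour spacing push apart). This is
deterministic, nearly hexagonal (interior facets overwhelmingly have 5–7
neighbours), and needs no physics engine. The cap half-angle is derived
from the facet count, base diameter and eye radius assuming hexagonal
packing with a 15% spacing margin — the margin standing in for the
interommatidial space of a real cornea — and is then enlarged by a few
percent, deterministically, until the minimum spacing clears 0.96× the
base diameter, so baseline-sized facets never touch.

Diameters follow a bilinear gradient. In cap-centred coordinates (azimuth
anterior-positive, elevation dorsal-positive), the anteroventral and
posteroventral pole directions are the unit diagonals $(1,-1)/\sqrt2$ and
$(-1,-1)/\sqrt2$; with $u, v$ the positive parts of a facet's normalized
projections onto them,

$$d_i = \text{base} + \text{excess}\cdot u_i - \text{deficit}\cdot v_i
        + \varepsilon_i,\qquad \varepsilon_i \sim N(0, \sigma^2),$$

clipped to the configured envelope and, as a hard guarantee, to 1.05× the
facet's nearest-neighbour distance — which enforces the non-overlap
invariant (no two centres closer than 0.95× their mean diameter along the
eye surface) pairwise. Bilateral asymmetry is a deterministic count offset
(right minus left), plus a seed-derived rotation of the right eye's spiral,
since the source attributes the asymmetry to spatial constraints without
offering a mechanism one could simulate.

The default demo configuration (also shipped as
`inst/extdata/demo_gradient.yaml`) uses the measured conditions: base
diameter 11.8 µm, envelope 9.3–13.7 µm, 247 facets per left eye with +12 on
the right (the measured per-individual counts are left 248/247/228, right
262/263/256), eye radius 90.4 µm. The gradient amplitudes (+1.0 µm
anteroventral, −1.5 µm posteroventral) and noise sd (0.3 µm) are not
printed anywhere; they were chosen once as the mildest values a
morphologist would call a visible regional gradient inside the measured
envelope (the published facet sd is 0.7 µm overall, part of which is the
regional trend itself), and they are not tuned thereafter.

The region partition is a declared convention, not a reconstruction: cap
quadrants by the signs of azimuth and elevation, a central disk (inner 30%
of the cap angle) and a dorsal-rim annulus (outer 10%). The real eye's
region boundaries are unpublished; any statistics tied to this partition
are statements about the convention.

```{r}
spec <- read_gradient_spec(
  system.file("extdata", "demo_gradient.yaml", package = "ommatidia")
)
lat <- generate_facet_lattice(spec, R_eye = 90.4)
glance(facet_region_stats(lat))
```

What the generator does *not* emulate: pentagonal and strongly curved
marginal facets, the dorsal-rim specialisation, local lattice defects, and
any developmental mechanism. Tests that pass on these lattices certify the
analysis pipeline (placement, partition, summary statistics, gradient
recovery), not fidelity to real SEM maps.

## Uncertainty propagation

The source reports point estimates only. `propagate_uncertainty()` adds a
Monte-Carlo view: the six optical-core fields are drawn as independent
zero-truncated normals from their published mean ± sd (no covariances are
published, so independence is an explicit assumption that likely overstates
the spread of ratio quantities), and each draw is pushed through the same
vectorized full-precision chain that `eye_summary()` uses — so with all sds
at zero the output collapses *exactly*, not approximately, to the
deterministic summary. Draws violating model preconditions are rejected and
resampled (at the published spreads the rejection rate is zero); sampling is
exact inverse-CDF, so runs are bit-reproducible per seed.

```{r}
pu <- propagate_uncertainty(load_fixture("table1"), n_draws = 2000, seed = 7)
pu |> select(label, mean, sd, q2.5, q97.5, deterministic)
```

With the published spreads and 2000 draws the Monte-Carlo mean of $f$ sits
within 2% of the deterministic 13.77 µm; the nonlinearity of $1/P_l$
introduces only a small positive-skew bias at these coefficient of
variations.

## Numerical choices, sizes and limitations

* Rounding is half-away-from-zero everywhere a printed value is produced;
  base R's round-half-to-even would disagree on exact halves.
* Degenerate optics fail loudly: an index-matched lens yields all-zero
  powers and a classed domain error at the focal length, not `Inf`.
* Acceptance angles outside the small-angle regime ($d \ge f$) warn rather
  than error: the formula is still the published convention there
  (the 22.2° comparison value is itself well beyond "small").
* The mode-order table is capped at five orders (cutoff 6.380); rhabdoms
  in this size class sit far below that.
* Problem sizes: test lattices use the measured ~247–259 facets per eye;
  the seeded-recovery check runs 100 lattices; Monte-Carlo checks use
  500–2000 draws. The whole suite completes in well under a minute on a
  single core.
* `tidy()`/`glance()`/`autoplot()` methods cover each result type; all
  tabular interfaces are tibbles and compose with dplyr.

The package deliberately excludes wave-optics point-spread simulation,
spectral sensitivity and opsin modelling, superposition-eye optics, and any
processing of microscope imagery.
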
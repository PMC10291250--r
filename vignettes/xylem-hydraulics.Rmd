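---
title: "Deriving and comparing xylem hydraulic traits of roots and branches"
author: "xylemhydro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and comparing xylem hydraulic traits of roots and branches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylemhydro)
```

## The scientific problem

Water moves through trees in dead xylem conduits (vessels in angiosperms,
tracheids in conifers). Because laminar flow through a capillary scales with
the fourth power of its diameter, a few wide conduits dominate the hydraulic
capacity of a cross-section, and the trade-off between wide, efficient
conduits and narrow, safer ones is central to how tree species cope with
drought. Comparative studies quantify this with a small set of traits
measured on similar-sized coarse roots and young branches:

* **CD** — conduit density, conduits per mm² of xylem;
* **F** — lumen fraction, the percentage of xylem area that is conduit lumen;
* **D_h** — the hydraulically weighted conduit diameter;
* **KS_pot** — the theoretical (Hagen–Poiseuille) conductivity per xylem
  area;
* **KS_hydr** — the conductivity actually measured gravimetrically;
* **K_L**, **HV** — conductivity per distal leaf area and the
  sapwood-to-leaf-area (Huber) ratio, which scale transport to the foliage
  it supplies;
* **WD** — wood density, dry mass per fresh volume.

This package implements the full derivation chain for these traits, the
comparative statistics used to contrast organs (coarse roots vs. 2nd-year
branches) and leaf habits (drought-deciduous vs. evergreen angiosperms), a
calibrated synthetic-study generator, and a synthetic cross-section renderer
that closes the loop on the image-analysis step. Every stage is testable
without access to field data.

## Anatomical traits from a radial sector

Conduit lumina are measured in a radial sector ("wedge") of a cross-section
with an opening angle of 20–70°, holding a few dozen conduits (the
generator emulates 57 ± 27 per sector). A `conduit_set()` holds the sector
geometry and the per-conduit lumen areas; `anatomy_traits()` derives all
five anatomy-based traits from it.

Measured lumen **areas** are converted to diameters by circle equivalence,
`d = 2\sqrt{A/\pi}`, the only diameter definition the area measurement
supports. The hydraulically weighted diameter defaults to the
conductivity-consistent convention

$$D_h = \frac{\sum d^5}{\sum d^4},$$

with the fourth-moment convention $(\sum d^4 / n)^{1/4}$ selectable via
`dh_method` — the literature uses both, and no worked number in the study
this package emulates disambiguates which was used, so the one that weights
conduits exactly as they contribute to Poiseuille flow is the default. Both
reduce to $d$ for uniform conduits and are never below the arithmetic mean.

Potential conductivity applies the Hagen–Poiseuille equation

$$K_{S,pot} = \frac{\pi \rho \sum D^4}{128\,\eta\, A_{xylem}},$$

with water density $\rho = 998.2$ kg m⁻³ and viscosity
$\eta = 1.002\times 10^{-9}$ MPa s (20 °C), diameters and areas converted
to SI internally. The reference area for anatomy-derived `KS_pot` is the
sector's woody area; it is deliberately never mixed with the flow module's
segment xylem area, which is measured with a caliper at the segment end.

```{r anatomy-example}
cs <- conduit_set("demo", organ = "root", sector_angle = 45,
                  sector_area = 5.7e5,
                  lumen_diameters = c(52, 61, 48, 70, 66, 39, 55))
anatomy_traits(cs)
```

## Empirical conductivity from flow records

Gravimetric conductivity measurements attach a segment (basal end for
branches, distal end for roots) to a tubing system under a small
hydrostatic head — 2 kPa for branches, 1 kPa for roots — and record mass
flow in g h⁻¹. `axial_conductivity()` converts a record to
$K_h = F\,l/\Delta p$ (kg m MPa⁻¹ s⁻¹). Conduits may be partly plugged by
emboli or debris in the native state, so segments are flushed repeatedly at
elevated pressure until conductivity stabilizes; `select_kmax()` takes the
first flush whose relative gain over its predecessor is below the 2 %
stability tolerance (configurable; the protocol only demands "a stable
value"), falling back to the maximum with a warning if the series never
settles. The pre-flush value is kept as a native-state diagnostic but never
enters `KS_hydr`.

The xylem area is the ellipse of the two crosswise end diameters, minus the
elliptic pith area in branches (`xylem_area()`), and
$K_{S,hydr} = K_{h,max}/A_{xylem}$. For branches with a recorded one-sided
distal leaf area, `hydraulic_traits()` also reports
$K_L = K_{h,max}/A_{leaf}$ and the Huber value $HV = A_{xylem}/A_{leaf}$.
HV is implemented in the sapwood-per-leaf-area direction, the only reading
consistent with its reported order of magnitude (10⁻⁴–10⁻³ m² m⁻²). `K_L`
is stored in SI with an optional reporting scale factor, since published
`K_L` magnitudes vary with unit conventions.

## Wood density

`segment_volume()` averages the elliptic woody areas of the two segment
ends times the length, subtracting the pith volume in branches only; stem
cores use the corer cylinder (`core_volume()`, 5 mm inner diameter).
`wood_density()` is dry mass over fresh volume, with a warning outside the
0.2–1.2 g cm⁻³ band that brackets tree wood. Inputs are assumed debarked;
that is an upstream measurement contract, not something the code can check.

## The comparative-inference layer

All inference works on tree means: replicate samples of the same tree and
organ are averaged first (`aggregate_tree_means()`) to avoid
pseudo-replication, and species means are means of tree means. The
right-skewed conductivities (`KS_hydr`, `KS_pot`, `K_L`) are log10
transformed for parametric tests.

* `habit_contrast()` and `organ_contrast()` are marginal-mean contrasts
  from one-factor linear models on species means, with fixed directions
  (deciduous − evergreen; root − branch). With a single two-level factor
  this is exactly the pooled-variance two-sample computation, which the
  test suite verifies to 10⁻¹⁰, and the residual df track the observation
  count, so a species missing one organ simply reduces df. Species means —
  not tree-level values — are the units, which is what published df of 11
  (13 angiosperm species, habit contrast) and 24 or 23 (organ contrast,
  with and without a missing root cell) imply. Organ contrasts are
  reported on the raw trait scale, matching the convention of published
  organ-contrast tables whose entries equal raw group-mean differences;
  habit contrasts for log-traits are computed and reported on the log10
  scale with a separate, clearly labeled back-transformed ratio column.
* `tukey_letters()` runs all-pairs Tukey–Kramer comparisons (studentized
  range on the pooled one-way error variance) and builds the compact
  letter display with the insert-and-absorb algorithm, so two species
  share a letter exactly when their adjusted p ≥ α. α = 0.05, with a 0.10
  "tendency" band in reported correlation flags.
* `pearson_matrix()` computes pairwise-complete Pearson correlations on
  species means with two-sided t-tests; cells with fewer than three
  complete pairs stay `NA`. No multiplicity correction is applied across
  the matrix, mirroring standard practice for these descriptive panels.
* `rb_ratio()` returns the **mean of pairwise root/branch ratios** (by
  tree for well-replicated traits, by species otherwise) — deliberately
  distinct from the ratio of group means, and sensitive to that
  distinction whenever ratios vary.
* `height_model()` fits `value ~ height + (1 | species)` by maximum
  likelihood and tests the slope with a likelihood-ratio χ²₁ test against
  the intercept-only model, falling back to pooled regression with a
  warning when the species variance collapses to zero. The LRT is used
  instead of a denominator-df approximation because it is exact about its
  null distribution asymptotically and honest about its small-sample
  anticonservatism, which the test suite measures directly (the null
  rejection rate stays near α).

`run_analyze()` chains all of this for a bundle of measurement tables and
writes the published-table layouts (contrast columns
`contrast SE df t.ratio p.value`, a species × organ wood-density table,
letters, correlations, R:B ratios, height models) with a manifest of file
digests.

## The synthetic study generator

`study_config()` + `generate_study()` emit a complete emulated campaign: 14
species (5 drought-deciduous angiosperms, 8 evergreen angiosperms, 1
gymnosperm) × 6 trees × (2 root + 3 branch) segments, plus one stem core
per tree. The generator is the package's calibration vehicle, so its
defaults are study-level constants, not knobs:

* Per species × organ the calibration table fixes (`D_h`, `CD`, σ²) of a
  lognormal conduit-diameter distribution. Lumen fraction and `KS_pot`
  follow analytically (`F = CD\,\tfrac{\pi}{4}E[d^2]`,
  `KS_pot ∝ CD\,E[d^4]`), so these three numbers per cell pin the whole
  anatomical structure. Printed species anchors (e.g. extreme conduit
  densities of 31, 236 and 947 mm⁻², lumen fractions of 6.2 and 36.8 %,
  branch D_h of 25.3 and 60 µm) are honored exactly; remaining cells were
  chosen once so the habit × organ group means reproduce the published
  group structure (deciduous/evergreen root D_h 68/58 µm, branch 45.5/34.5
  µm, root CD 80/139 mm⁻², organ contrasts of D_h ≈ 22 µm and KS_hydr ≈
  7.2, R:B of KS_hydr ≈ 5.1/5.8). Because (D_h, CD, F) jointly determine
  the lognormal spread, σ² is solved per cell rather than fixed globally;
  the resulting geometric SDs (1.09–1.45) are typical of within-sector
  diameter variation.
* Measured conductivity is constructed as `KS_hydr = r · KS_pot` with
  r = 0.25 (the empirically observed magnitude of the
  measured-to-potential ratio) and mean-one lognormal noise
  (σ_log = 0.15), inverted through the exact unit chain back to g h⁻¹
  flush records. Flush profiles rise to a plateau whose final step is
  inside the 2 % stability tolerance; the native stage is the plateau
  times a plugging factor uniform on (0.3, 1).
* One species' root flow records are discarded by default, reproducing the
  missing-cell situation a real campaign produced, so df bookkeeping is
  exercised end to end.
* Wood densities come from the per-species table (published species
  values), with a tree-level effect, sample noise, and a negative
  within-species coupling to the sample's realized lumen fraction — the
  root-level density/porosity trade-off. Across species the coupling
  emerges from the calibrated values themselves.
* Tree heights are drawn from published per-species means ± SD; leaf areas
  are set by habit-level Huber-value targets (26.4, 13.9 and
  0.696 × 10⁻⁴ m² m⁻²) with mean-one noise.
* Between-tree variance components are not published anywhere; the
  defaults (log-scale SD 0.06 on diameter scale, 0.10 on density, 0.03–
  0.04 g cm⁻³ on wood density) were chosen once as plausible magnitudes
  that give realistic within-species SEs, and are labeled as assumptions.

A single seeded RNG stream drives the whole study in a fixed traversal
order, so one integer reproduces every table bit for bit.

What the generator does **not** emulate: real micrograph texture (rays,
fibers, staining), conduit-length effects, temperature drift of viscosity,
or species-specific deviations of the measured-to-potential ratio (the
ratio r is global, whereas in real data it varies by species). Passing
calibration tests therefore demonstrates that the pipeline is unbiased and
internally consistent under the stated statistical structure — not that it
would reproduce any particular field dataset.

## Synthetic imaging round trip

`render_sector()` draws the conduits of a sector as dark non-overlapping
ellipses (aspect 1–1.3, random orientation) in a light wedge at 0.5 µm
px⁻¹ by default, placed by dart throwing with bounding-circle rejection and
anti-aliased with a one-pixel ramp. `segment_conduits()` re-measures the
image with a global Otsu threshold, connected-component labeling, an area
filter, and a centroid rule: a component belongs to the sector exactly when
its centroid lies inside the wedge. The centroid rule is the unbiased
convention for counting border-straddling conduits; the renderer keeps true
centroids inside the wedge, so recovered counts are exact and recovered CD
and D_h land well within the 5 % / 3 % round-trip bands the acceptance
suite enforces at ≤ 1 µm px⁻¹.

## Numerical choices and degenerate inputs

* All internal computation is SI (m, kg, s, MPa); µm, mm, g h⁻¹ and kPa
  exist only at the I/O boundary, and the unit audit test pins the
  conversion chain.
* Non-positive areas, diameters, heads, lengths and volumes are rejected
  with informative errors rather than propagated as NaN; a lumen total
  exceeding its sector area is treated as a measurement inconsistency.
* `select_kmax()` on a monotone-rising series returns the maximum with a
  warning rather than failing — the measurement exists, it just never
  stabilized.
* Tukey letters refuse all-identical (zero-variance) data, where the
  pooled error is undefined.
* Sector draws whose lumen total would exceed the sector area are
  rejected and redrawn (bounded attempts), and configurations whose
  implied lumen fraction reaches 100 % are rejected at construction.

## Problem sizes used by the tests

The acceptance suite runs 20 full synthetic studies (≈ 500 samples each)
for the calibration checks, 20 rendered sectors of 100–130 conduits at
1 µm px⁻¹ for the imaging round trip, 10³ conduits and 10³ flow samples
for parameter recovery, and 200 replicates of a 8-species × 4-tree design
for the mixed-model size check. These sizes give Monte-Carlo standard
errors comfortably below the tolerances they are checked against.

## Known limitations

* Conduit length and vulnerability (embolism-resistance) traits are out of
  scope; nothing here substitutes for vulnerability curves.
* The Huber value's direction and the reporting scale of K_L follow the
  magnitude-consistent reading of their definitions; both are documented
  at the function level and the SI value is always stored.
* The mixed-model p-value uses an asymptotic LRT; for very few species it
  is mildly anticonservative, which the acceptance suite quantifies rather
  than hides.
* The compact letter display depends on the pairwise decisions only; with
  heavily unbalanced designs Tukey–Kramer p-values are themselves
  approximate.
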
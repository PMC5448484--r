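---
title: "Methods: composition analysis of cell-mineralized fibrin gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition analysis of cell-mineralized fibrin gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteogel)
```

## The analysis problem

When bone-marrow stromal cells (BMSCs) are cultured inside a 3D fibrin gel
under osteogenic conditions, they secrete collagenous and non-collagenous
matrix proteins, and mineral (low-crystalline hydroxyapatite) precipitates on
that matrix. Over weeks of culture the construct changes from an almost pure
fibrin hydrogel into an organic/inorganic composite resembling immature
osteoid. Two histological readouts track this: hematoxylin/eosin (HE)
sections, in which eosin-pink marks deposited protein matrix, and von Kossa
sections, in which silver-stained brown marks mineral. A third readout, the
macroscopic shrinkage of the gel under cell traction, provides the volume
change that links section-level area measurements to construct-level volume
composition.

`osteogel` implements the full analysis chain — pixel classification,
composition algebra, contraction statistics and vesicle morphometry — and a
synthetic-phantom generator that provides every input with exact ground
truth, so the chain can be validated end to end without any real micrograph.

## Pixel classification by RGB ratios

Classification operates on raw 8-bit RGB values, per pixel, with strict
inequalities and no morphological post-processing:

* **Mineral** (von Kossa sections): `B/G < 0.85` and `R/G > 1.02`;
* **Matrix** (HE sections): `210 < R < 225`;
* **Nucleus** (either stain): `B/G > nucleus_bg_min`.

The mineral and matrix thresholds are fixed, published constants and are the
defaults of `rgb_thresholds()`. The blue/green ratio is the published
indicator for nuclei, but no threshold value was published with it;
`nucleus_bg_min` therefore defaults to 1.05 (just above the achromatic ratio
of 1, so neutral tissue never triggers it, while hematoxylin blue-purple at
typical intensities gives ratios well above 1.3) and is an explicit,
overridable parameter.

Two numerical choices deserve note:

* **G = 0 pixels.** Both ratios are undefined where the green channel is 0.
  Such pixels are classified as non-mineral and non-nucleus — the
  conservative choice, since a spurious ratio would otherwise almost always
  classify as mineral — and their count is attached to the mask and
  reported. In line profiles these positions carry `NA`.
* **Raw integers.** Ratios are evaluated on the raw 0–255 integers, with no
  smoothing: the rules are defined as pure pixel rules, and any cleanup
  (minimum object size, opening) would change the measured area fractions.
  `label_vesicles()` exposes `min_size` for contexts where filtering is
  explicitly wanted.

`area_fraction()` computes percentages over the full raster by default; an
optional ROI mask changes the denominator, because the denominator used for
the original published fractions (whole field vs gel area) is not stated and
should be the analyst's visible choice.

## From area fractions to volume composition

With `X` the mineral area percentage (von Kossa), `Y` the matrix area
percentage (HE), and the cell share fixed at `Z = 1.5` percent (cell number
saturates within the first days of culture and is then maintained), the
construct composition at a timepoint is

```
Vx = X / f,   Vy = Y / f,   Vz = Z / f,
fibrin = 100 − Vx − Vy − Vz,
f = (initial gel volume − gel volume at day 42) / 42.
```

Area fractions estimate volume fractions by the Delesse principle; `f`
rescales them to account for the traction-driven densification of the
construct. Two readings of these equations had to be fixed:

* **Units.** Taken literally, the fibrin equation multiplies `(1 − ΣV)` by
  100 while the `V`'s are already percentages. The package keeps every
  component on the percent scale and computes `fibrin = 100 − Vx − Vy − Vz`;
  this is the only reading under which the published day-42 composition
  closes (31 + 38 + 1 + 30 = 100), and it makes the closure invariant exact.
  Every accepted `composition_estimate` sums to 100 within 1e-9 by
  construction, and the pipeline re-checks this before writing any output.
* **One f for all days.** The scaling factor is anchored on the day-42
  volume and applied to every timepoint, following the definition as
  written. A per-day variant `f_d = (initial − volume_d) / d` is available
  behind `per_day_f = TRUE` (off by default) for sensitivity analysis; it
  requires per-day volumes and is a deliberate departure from the printed
  definition when used.

Infeasible inputs — `Vx + Vy + Vz > 100`, or `f ≤ 0` from a gel that did not
contract — raise errors rather than being clamped: clamping would silently
fabricate a composition. `compute_f()` itself errors only on expansion
(negative `f`) and returns 0 with a warning for a non-contracting gel, so
the failure surfaces at the composition step with a clear message.

Gel volumes come from the measured geometry: `cylinder_volume()` for the
as-cast gel (the mold is 10 mm long, 6 mm in diameter) and
`spheroid_volume()` (prolate, `π/6 · long · short²`) for the contracted
spheroidal construct.

## Gel-contraction analytics

`length_contraction()` is the percent reduction of the day-mean long-axis
length relative to the first measured day; it is invariant under uniform
rescaling of all lengths. `compare_conditions()` runs a two-sample Student
t-test (pooled variance, matching the named test; Welch via
`var_equal = FALSE`) on every shared day and flags significance at
`alpha = 0.01`, i.e. the 99% confidence level. No multiple-testing
correction is applied across days — each day is reported on its own, as in
the per-day significance stars of the original figures — and the choice is
deliberate fidelity over statistical taste.

`detect_plateau()` operationalises "no significant size change in further
culture" with consecutive-day t-tests (window 1, the simplest reading): the
plateau day is the day following the last significant pair; a series with
no significant pair plateaus at its first day; a series whose final pair is
still significant has not plateaued and returns `NA`. Zero-variance groups
are handled explicitly (equal constants → p = 1, distinct constants → p = 0)
because `t.test()` refuses essentially-constant data.

A single noisy series gives an intrinsically fuzzy plateau estimate: the
consecutive-day differences shrink exponentially, so the test loses power
gradually, and where exactly significance is lost fluctuates by one or two
sampling steps between replicate experiments. The stable summary is the
median over replicate synthetic experiments, provided by
`recover_plateau_day()` (default 15 series).

## The synthetic phantoms

The generators define the study conditions under which the package validates
itself.

**Stained sections** (`generate_stain_phantom()`). Nuclei are non-overlapping
disks; matrix forms an annular halo around each nucleus; mineral radiates
outward beyond the matrix — the radial arrangement seen around mineralizing
cells. Pixels are assigned to matrix and mineral in order of distance from
the nearest nucleus centre, so requested area fractions are realized exactly
up to rounding to a whole pixel count (well inside 0.5 percentage points for
rasters of 256×256 and above). Class colours are chosen so that, with
`noise_sd = 0`, each truth class satisfies exactly its own rule and the
fibrin background satisfies none: the paper-style thresholds constrain the
mineral, matrix and nucleus colours, while the background colorimetry is
necessarily invented (near-neutral gray with `R/G ≤ 1` for von Kossa; pale
pink with `R ≥ 235` for HE). Noise is independent per-channel Gaussian,
clipped to [0, 255] and rounded — the simplest model with a stated
parameter. Identical specs (including seed) produce bit-identical phantoms,
and generation leaves the caller's RNG state untouched.

One consequence of the strict matrix band is worth stating precisely: a
matrix pixel whose nominal red value sits mid-band (R = 217) stays inside
the open interval (210, 225) with probability ≈ 0.866 under noise of sd 5,
so the measured matrix fraction is biased low by ≈ 13% of the true fraction.
At sd = 5 a ±3 percentage-point recovery is therefore only attainable for
matrix fractions up to roughly 20%; the noisy validation phantoms use
matrix fractions of 10–15%, and the end-to-end trajectory phantoms use
`noise_sd = 2` (a well-exposed micrograph), where the band retains > 99.98%
and the bias is negligible. This is a property of the published rule itself,
not of the implementation.

**Contraction series** (`generate_contraction_series()`). Lengths follow
`plateau + (initial − plateau)·exp(−k·day)` with `k` fixed so the remaining
gap is 1% at `plateau_day` — a decay-to-plateau was described but no
functional form given, so the simplest one-parameter family is used.
Defaults: initial 10 mm (the mold length), quadruplicate measurements,
sampling every 3 days over days 0–42, and `measurement_sd = 0.025` mm.
The noise level was chosen once, by a power analysis of the plateau
detector: it is the value at which quadruplicate consecutive-day t-tests at
α = 0.01 lose significance in the neighbourhood of day 23 — i.e. the
condition under which a day-23 plateau is what the published decision rule
itself would report. Cell-laden and cell-free analogues use plateau lengths
of 1 mm and 9.3 mm, giving terminal length contractions of 90% and 7%.

**Vesicle phantoms** (`generate_vesicle_phantom()`). A circular cell of the
requested area containing circular vesicles with Gaussian radii, placed
strictly inside the cell with a 1-pixel moat between vesicles so that
8-connected labelling recovers each placed disk exactly; recorded truth
sizes are the exact pixel counts.

What the phantoms do *not* emulate: stain variability and batch effects,
chromatic aberration, section thickness and out-of-focus blur, textured or
graded staining within a class, irregular cell and deposit shapes, and
spatially correlated noise. Passing the phantom suite therefore shows that
the rules, equations and statistics are implemented correctly and are
recoverable under idealised imaging — not that the fixed thresholds
themselves generalise to arbitrary real micrographs, which is a staining-
and acquisition-dependent question.

## Vesicle morphometry

`label_vesicles()` labels connected components under 8-connectivity (the
common default for blob counting; 4-connectivity available), with labels
assigned deterministically in raster order; `min_size` defaults to 1 (no
filtering). `vesicle_stats()` computes the per-cell area ratio
`100·|vesicles ∩ cell|/|cell|` and the mean vesicle size; vesicles
straddling the cell boundary are clipped to the cell — the statistic is
defined on the single cell — with the clipped fraction reported. Zero
vesicles give an area ratio of 0 and an explicitly flagged undefined mean
rather than `NaN` arithmetic.

## The pipeline

`run_pipeline()` executes generate (or load) → segment → average → compose
in order: per day it segments `images_per_day` sections per stain (default
4, the replicate structure of a quadruplicate experiment; the original
sampling used 20 images per group), averages the per-image area fractions
within each day — areas are averaged before the composition equations are
applied, and per-image values are retained in the report — then computes
`f` and the composition trajectory, and optionally the contraction and
vesicle sections. All randomness derives from one master seed through a
deterministic sub-seed stream, so a persisted config (`write_run_config()`,
JSON or YAML) re-runs to byte-identical outputs. Degenerate inputs (zero
fractions, zero vesicles, single timepoints) produce reports with warnings,
not crashes.

## Validation problem sizes

The shipped validation suite uses: 512×512 phantoms for pixel-exact and
noisy segmentation checks (10 von Kossa + 10 HE noisy phantoms), 256×256
phantoms with 4 images per day and `noise_sd = 2` for the three-day
end-to-end trajectory (truth pattern: fibrin-rich day 28 → matrix-rich day
35 → mineral-rich day 42, with day-42 area truths X = 46.5, Y = 57 at
f = 1.5), 100 random 32×32 rasters against the per-pixel and flood-fill
oracles, 100 random (X, Y, f) triples against the brute-force equation
oracle at 1e-12, and 15 replicate contraction experiments for the plateau
median. These sizes give stable statistics while keeping the whole suite
fast.

## A worked example

```{r example}
areas <- data.frame(day = c(28, 35, 42),
                    mineral_x = c(0, 15, 46.5),
                    matrix_y = c(9, 37.5, 57))
composition_trajectory(areas, initial_volume = 64, final_volume = 1)
```

## Known limitations

* The fixed RGB thresholds encode one staining protocol and scanner; real
  deployments should inspect masks visually and may need to re-derive
  thresholds (exposed in `rgb_thresholds()`), which is stain normalisation
  territory and out of scope here.
* The day-42-anchored `f` makes early-day compositions depend on a later
  measurement; this is faithful to the definition but means a trajectory
  cannot be computed before the endpoint volume exists (use `per_day_f` for
  interim analyses, with the caveat above).
* Plateau detection inherits the power of the underlying t-test: with very
  small noise it reports `NA` (every consecutive difference significant)
  and with large noise it plateaus early. `recover_plateau_day()`
  stabilises the estimate but cannot remove this dependence.
* Vesicle analysis starts from binary masks; producing masks from raw SEM
  images (thresholding, illumination correction) is left to the caller.
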
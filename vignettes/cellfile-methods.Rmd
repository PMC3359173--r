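---
title: "Measuring cell files and locating the elongation onset: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cell files and locating the elongation onset: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellfile)
```

This vignette explains the model behind `cellfile`, the parameters that
matter, the choices made where the design was genuinely open, and what
the synthetic test suite does and does not demonstrate.

## The measurement model

A file of cells (e.g. cortical cells along a root axis) appears in a
wall-stained confocal image as a sequence of bright ridges — the shared
cell walls — crossing a darker cell interior. Along a line traced through
the file, the image intensity is therefore approximately a 1-D signal
whose peaks are wall crossings. `cellfile` reduces the 2-D problem to
exactly this 1-D signal:

1. **Spline profile.** The user's polyline is interpolated by a cubic
   spline (chord-length parameterization, natural end conditions; two
   anchors degenerate to a straight segment) and resampled at uniform arc
   length. Arc length is computed on a dense polyline evaluation of the
   spline (0.05 px parameter resolution) and inverted numerically; the
   total arc length is therefore accurate to well under 0.1 % and halving
   the sample step changes it negligibly. Intensities are sampled by
   bilinear interpolation, which preserves sub-pixel peak shape; nearest
   neighbour sampling would quantize wall positions to whole pixels.
2. **Windowed peak rule.** Sample `p_t` is a wall candidate iff its
   intensity is (a) at least the maximum of the window of `window`
   samples centred on it, excluding `p_t` itself; (b) at least
   `stringency` times the window minimum (again excluding `p_t`); and
   (c) at least `min_intensity`. Condition (b) demands that a peak
   dominates the darkest nearby interior; condition (c) exists because in
   a noisy near-black region the window minimum approaches zero and (b)
   becomes vacuous — an absolute floor is the only effective guard there.
3. **Sub-pixel walls.** Because (a) uses `>=`, a flat-topped ridge yields
   a run of adjacent candidates; each maximal run collapses to its
   intensity-weighted centroid, giving fractional-sample wall positions.
   Walls closer than `ceiling(window / 2)` samples are two shoulders of
   one ridge, so the pair merges keeping the higher peak.
4. **Cells and landmark.** Boundary positions (profile start + walls)
   give per-cell lengths. The onset of rapid elongation is the break
   point of the cell-number vs cell-length series: the interior point
   with the largest perpendicular distance to the chord joining the first
   and last points.

## Parameters

| parameter | unit | default | why |
|---|---|---|---|
| `step_px` | pixels | 1 | per-pixel scan of the profile; finer steps only oversample the bilinear interpolant |
| `window` | samples | 9 | spans a typical wall-ridge width (~1–2 µm at ~0.5 µm/px); exposed on the CLI because imagery scales differ |
| `stringency` | — | 1.5 | a wall must be 1.5× brighter than the darkest nearby interior; 1.0 disables the ratio test |
| `min_intensity` | raw units | 0 | image-dependent floor; set it just above the background noise ceiling (≈ 4–5 σ of background) |
| `include_start_as_wall` | flag | on | distances are reported from the user-placed profile start (the cortex/endodermis initial), so the start is boundary 0 |
| `mode` (landmark) | — | `cell_number` | the cumulative-length abscissa stretches the elongation end of the curve and localizes the corner less consistently; it is provided for comparison |

Windows are truncated at the profile ends rather than padded: candidates
in the first and last half-window are judged against the samples that
exist, which avoids inventing data at the boundaries.

## The break-point rule

The perpendicular distance is computed in raw data units (cell index vs
µm). Min–max normalization of both axes is available as an option but off
by default: raw units are the simplest reading consistent with computing
the distance in the data frame rather than in a display frame, and the
index is in any case invariant to adding a constant to all lengths or
scaling them all by a positive factor (the chord transforms identically).
Ties break toward the smallest index — the earliest detectable
transition — making the estimator deterministic.

The landmark's distance is anchored to the **proximal boundary** of the
break cell. Anchoring at the cell midpoint would differ by half a cell
length; the proximal boundary is reproducible and monotone in the cell
index.

## The synthetic generator

`generate_length_series()` emulates the biology the measurement targets:
`n_meristem` cells around a meristem length `L_m`, then a geometric ramp
reaching `L_m * elongation_factor` over `ramp_cells` cells, then fully
elongated cells. Defaults — `n_meristem = 30`, `L_m = 8` µm,
`elongation_factor = 15`, `ramp_cells = 6`, `noise_cv = 0.1` — describe a
typical Arabidopsis cortical file: ~8 µm meristem cells expanding ~15×,
spanning the ~10–90 µm range observed in real material. Length noise is
multiplicative lognormal with unit mean, parameterized by its coefficient
of variation: meristem cell sizes are heterogeneous but strictly
positive, which an additive Gaussian would violate.

The **true transition index is `n_meristem`** — the last meristem-length
cell, i.e. the change point just *before* elongation begins. This is the
point the chord rule finds on an idealized flat-then-rising series (the
corner is the last flat point), so noise-free recovery is exact by
construction of the estimator, not by tuning.

`render_cell_file_image()` draws walls as 1-D Gaussian ridges
(`wall_sigma_px`, default 1.5 px) in arc-length distance to the nearest
wall plane, constant across the file's width, on a zero-mean background
with additive Gaussian noise, along a straight or gently curved (circular
arc) axis. This captures what the detector actually sees — ridge-shaped
peaks over a dark interior — with exact sub-pixel ground truth. It does
**not** emulate neighbouring cell layers, "ghosting", uneven staining,
depth attenuation, or PI/GFP photophysics, so a perfect score on the
clean suite demonstrates correctness of the geometry and the detector
logic, not robustness to real-microscopy artifacts; the noisy cases probe
noise robustness only in the additive-background sense.

## Numerical choices and degenerate inputs

* Images are kept in raw integer units (8/16-bit); PNG's [0, 1] scaling
  is undone at read time. The detector is invariant to intensity scaling
  when `min_intensity` is co-scaled, so the unit convention is immaterial.
* Calibration precedence: explicit argument > TIFF resolution metadata >
  1 µm/px with a warning. Anisotropic pixel calibrations are rejected —
  one distance scale is reported along the profile.
* ImageJ `.roi` polylines use corner-origin coordinates; they are shifted
  by −0.5 px to this package's pixel-center convention on import.
* A constant profile yields no walls (no sample strictly dominates under
  `stringency > 1`). Profiles not longer than the window are an error.
* `segment_cells()` requires two boundaries; `estimate_tsz()` requires
  three cells and only warns (does not fail) when fewer than two cells
  reach ~4× the meristem length, since the user may legitimately measure
  a meristem-only file.
* A rater panel with any zero pairwise disagreement is an error: the
  Williams Index takes reciprocals. `D` is the mean absolute difference
  across images — the standard scalar-landmark disagreement. The
  jackknife CI is an optional extension, labelled as such.

## Known limitations

* **Short meristems bias the landmark.** When the flat region is short
  relative to the ramp (roughly `n_meristem` below ~2× `ramp_cells`),
  the geometric corner of the convex ramp drifts 1–2 cells past the last
  meristem cell, and truncating the profile can move it further. This is
  a property of the chord rule itself — the curve becomes too compressed
  for a well-defined corner — and is the same failure mode that makes
  profiles without at least two substantially elongated (~4×) cells
  unreliable. The package warns in that case rather than guessing.
* The detector is strictly 1-D: a wall grazed obliquely, or two files
  drifting across the profile line, will not be disentangled. The manual
  wall mechanism (`add_manual_walls()`, `--manual-walls`) is the
  escape hatch, mirroring interactive wall enhancement.
* Only single-channel planes are processed; multi-channel images require
  an explicit channel, and z-stacks are out of scope.

## Problem sizes in the test and acceptance suites

The suites run at sizes chosen to exercise every code path while staying
quick on a laptop: 1000 random 500-sample profiles for the
detector-transcription equivalence, the 6-case fixture suite (meristem
shortened to 12 cells so images stay ~1500 px wide) for image-level
recall/precision, 500 random series for break-point/exhaustive-search
equality, 200 seeded series for landmark recovery and truncation
stability (noise-free stability is checked across a grid of realistic
geometries, `n_meristem` 20–40), and 100 simulated 26-image panels for
the Williams Index. All randomness is seed-derived and reproducible.
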
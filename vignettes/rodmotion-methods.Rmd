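---
title: "rodmotion: models and measurement choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rodmotion: models and measurement choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `rodmotion`, the parameters that
matter, and the design decisions taken where the underlying measurement
procedure left room for interpretation. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## The physical model

A rod-shaped bacterium is modelled as a spherocylinder: a cylinder of
diameter $W$ capped by two hemispheres, tip-to-tip length $L$, lying on
the coverslip. Cell-wall synthesis complexes are membrane-bound emitters
that move processively around the short axis at a constant surface speed
$v$: in membrane coordinates $\theta(t) = \theta_0 + v t / r$ with
$r = W/2$, the axial coordinate unchanged. Height above the coverslip on
the cylinder flank is $z = r(1 - \cos\theta)$.

Two illumination modes are modelled. TIRF excites with an evanescent
field; rendered amplitude falls as $e^{-z/d}$ with decay depth
$d = 200$ nm. Widefield collects the full cell depth; emitters contribute
fully while $z \le 800$ nm. For *area* calculations (which need a sharp
boundary rather than a weight) the illuminated membrane is defined by a
hard cutoff $z \le d$, giving a flank band
$2 r \theta_{\max} (L - 2r)$ with $\theta_{\max} = \arccos(1 - d/r)$
plus a spherical zone $2 \pi r d$ from the two caps combined. With the
reference dimensions stored in `reference_cell_dimensions()` — wild type
$3.57 \times 1.00$ µm, the thinner and longer activated mutant
$4.09 \times 0.90$ µm — this reproduces illuminated areas of about 3.01
and 3.38 µm². Those dimensions were obtained by inverting the area model
under the constraint that the mutant is ~10 % thinner and longer than
wild type; they are the package's reference values, not fitted to any
movie.

## The synthetic-data generator

`generate_population()` places cells on a grid (tiles sized to the
longest cell plus margins, so cells can never overlap at any orientation)
and draws per-cell emitter counts from a Poisson law with mean
density × projected area. Speeds and filament lengths come from
truncated Gaussians (resampling below the bound). Rendering uses a
pixel-integrated isotropic Gaussian PSF, so a focus of flux $F$ deposits
exactly $F$ photons (to numerical precision) when far from borders;
filaments are lines of point sources at quarter-pixel midpoint spacing,
which makes the discrete sum a midpoint quadrature of the continuous
line density. Noise is per-pixel Poisson plus Gaussian read noise,
rounded to whole camera counts (integer counts also make written movies
round-trip through 16-bit TIFF exactly) and clipped at zero.

Defaults and their rationale:

| parameter | default | why |
|---|---|---|
| `pixel_size` | 65 nm | 100× objective with 6.5 µm camera pixels |
| `frame_interval`, `n_frames` | 1 s, 60 | one-minute movies at 1 s intervals |
| `tirf_depth` / `widefield_depth` | 200 / 800 nm | the two depths of field being emulated |
| `psf_sigma` | 80 nm (40 nm SIM-like) | $\approx 0.21\lambda/\mathrm{NA}$ at 515 nm, 1.45 NA; SIM ≈ 2× resolution |
| `photon_rate` | 800 photons/frame | peak-pixel SNR ≈ 8 over background, comfortably detectable |
| `background_level`, `read_noise_sd` | 10, 2 photons | typical sCMOS-scale background and read noise |

The generator emulates: circumferential motion under depth-dependent
excitation, shot/read noise, diffraction blur, sub-pixel positions,
Poisson emitter counts, and mixed two-strain fields with a cytoplasmic
red marker. It does **not** emulate photobleaching or blinking, cell
growth, vectorial/astigmatic PSFs, SIM reconstruction artefacts, bent or
tilted cells, or autofluorescence gradients. Passing tests therefore
demonstrate correctness of the measurement chain under a clean optical
model, not robustness to every artefact of real movies.

## Detection, linking and the survival filter

Spots are detected per frame by a Gaussian matched filter at the PSF
scale; local maxima are accepted when the amplitude estimate (twice the
smoothed excess over the smoothed median, which undoes the factor-of-two
loss of matched filtering) exceeds `snr_min` times the robust frame noise
(MAD). Positions are refined by an intensity-weighted centroid in a
±2σ window and duplicates within one PSF σ are merged, keeping the
brighter.

Linking is greedy mutual-nearest-neighbour between consecutive frames:
the globally closest unassigned pair within `max_link_distance` (default
250 nm ≈ 10× the per-frame motion, well under typical emitter spacing)
links first. There is no gap closing — the survival rule speaks of
*consecutive* frames — and no motion model; at the simulated densities
this simple linker is verified against ground-truth identities in the
test suite.

The survival filter keeps exactly the tracks with ≥ 5 consecutive frames
**and** ≥ 70 nm net (first-to-last) displacement. The source wording
("discarded ... if they consisted of < 5 consecutive frames and had a
minimum displacement of < 70 nm") is ambiguous about the conjunction;
discarding on *either* failure isolates directionally moving complexes,
which is the stated intent, and the literal both-fail reading remains
available (`rule = "literal"`). Net displacement is the straight-line
first-to-last distance, the natural reading of "minimum displacement".

Velocity is the absolute least-squares slope of positions projected onto
the track's principal axis versus time. A slope fit is preferred over
mean step length because localisation noise inflates step-based speeds;
the step estimator is kept as an option.

### Why the tracking default is `snr_min = 12`

Circumferential motion is foreshortened in projection: a focus at
membrane angle $\theta$ has apparent lateral speed $v\cos\theta$. Under
the exponential TIRF profile, a loose detection threshold tracks foci far
up the flank, where $\cos\theta$ is small, and biases the recovered
population mean low by 10 % or more. At the default photon budget an
amplitude cut of 12× the frame noise admits foci only up to roughly
$z \approx 120$ nm ($\theta_{\max} \approx 0.7$ rad), for which the
least-squares slope over a full transit is
$3(\sin a - a\cos a)/a^3 \approx 0.95$ of the true surface speed. This
is a geometry-derived choice, not a fitted one; `detect_spots()` itself
defaults to a looser `snr_min = 6` appropriate for plain detection.

## Filament length

Each region of interest (one filament, selected externally — mirroring
by-eye selection; there is no automatic segmentation) is processed as:
local background (median outside a dilated bright core), orientation
(principal axis of background-subtracted second moments, using only
pixels 3 MADs above background so uniform noise cannot isotropise the
moments), bicubic Catmull–Rom rotation about the intensity centroid,
a 2-pixel-wide line profile (sum of the two rows straddling the axis),
and length = longest contiguous profile run above threshold × pixel
size.

"Background + 50 %" is interpreted as background + 50 % of
(peak − background) — a half-amplitude cut, which is invariant to camera
offset and, for a box convolved with a Gaussian, crosses at the true bar
edge, keeping length bias small. The alternative reading, 1.5×
background, is implemented behind `method = "background_x1.5"`; the test
suite verifies that the ordering of two simulated populations does not
depend on the choice. The longest *contiguous* run (not the total count
of supra-threshold pixels) is used so detached noise pixels cannot extend
a filament.

Degenerate regions are flagged, never silently dropped: a region with no
dominant axis (anisotropy below 1.3) is measured unrotated and flagged;
lengths within FWHM + 2 pixels of the PSF are flagged `at_resolution`
(a sub-resolution filament reports near the PSF FWHM, not zero). These
measurements are relative, not absolute — the same caveat the original
procedure carries — which is why the generator-based calibration in the
tests reports bias against known truth explicitly.

## Membrane fraction and demultiplexing

Per cell, background-subtracted fluorescence is integrated under TIRF
and divided by the same measurement under widefield (first frame of each
mode by default; configurable). Frame background is the median outside
all cell masks. Because absolute TIRF intensity is sensitive to incident
angle and focus, strains are compared within one field and identified by
a cytoplasmic red marker: cells are split by an iterated-midpoint
threshold on mean red intensity, with a ±10 % ambiguity band to prevent
silent misassignment near the boundary, and a bimodality guard (class
means must be > 4 pooled within-class SDs apart — a single Gaussian split
at its midpoint only reaches ~2.7) that declares everything ambiguous
with a warning otherwise. Marker-swap pairs are pooled and a swap
consistency statistic reported.

## Statistics

Summaries are mean ± sample SD (n−1) with median and quartiles.
Mann–Whitney U uses the exact null distribution for tie-free samples
with $n_1 + n_2 \le 16$ and the tie-corrected normal approximation with
continuity correction otherwise; all p-values are two-sided, and no
multiple-testing correction is applied (none is applied in the original
analysis; reports note this). Histograms use half-open bins
$[kw, (k+1)w)$ anchored at zero — 5 nm/s bins for velocities, 120 nm for
lengths — so counts always sum to n.

## Problem sizes and determinism

The test suite and acceptance script run, by design, at desk scale:
velocity recovery uses ~300 emitters across 50 cells (60 frames), the
filament comparison 500 filaments per population, the ratio null 200
replicate experiments of 30 cells per strain, and the density sweep four
densities × 8 cells. These sizes give sampling errors comfortably inside
the tolerances being checked while keeping a full run in minutes. All
randomness flows from explicit integer seeds; a fixed seed reproduces
movies, truth tables and summaries bit-for-bit (RNG state is restored
after every call, so package functions never perturb a session's
random stream).

## Known limitations

- The greedy linker has no gap closing or motion model; at densities far
  above those simulated, identity swaps would rise and a LAP-style
  linker would be preferable.
- Projection foreshortening is mitigated by the detection cut, not
  corrected analytically; recovered speeds retain a small (few percent)
  downward geometric bias.
- Filament lengths are calibrated relative, not absolute; arcs are
  measured in projection.
- Channel registration is assumed perfect; bleed-through is handled only
  by the ambiguity flag, not spectral unmixing.
- Cells are straight, untilted and non-growing for the duration of a
  movie.
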
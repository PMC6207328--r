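# rodmotion

Quantitative fluorescence-imaging analysis of bacterial Rod-complex
(elongasome) dynamics, built for comparing wild-type cells with cells
carrying an activated cell-wall synthase (PBP2(L61R)).

In rod-shaped bacteria, MreB filaments and the associated RodA–PBP2
synthase move processively around the cell's short axis as they build new
cell wall. Under TIRF illumination only the bottom ~200 nm of the cell is
excited, so these complexes appear as diffraction-limited foci drifting at
tens of nm/s. This package implements the full measurement chain used to
quantify that motion, together with a synthetic-movie generator so that
every stage can be validated against known ground truth:

- **Synthetic imaging** — spherocylindrical cells on a coverslip with
  membrane-bound foci moving circumferentially (θ(t) = θ₀ + v·t/r) and
  static filaments; Gaussian PSF, exponential TIRF depth attenuation
  e^(−z/d), Poisson shot noise and Gaussian read noise; full ground-truth
  tables; multi-frame TIFF output.
- **Cell geometry** — closed-form spherocylinder areas: total
  2πr(L−2r) + 4πr², projected W(L−W) + π(W/2)², and the TIRF-illuminated
  band 2rθ_max(L−2r) + 2πrd with θ_max = arccos(1 − d/r), used to
  normalise track counts per cell.
- **Particle tracking** — matched-filter spot detection with sub-pixel
  refinement, greedy nearest-neighbour linking (no gap closing), the
  survival filter keeping tracks with ≥ 5 consecutive frames *and* ≥ 70 nm
  net displacement, principal-axis velocity fits, kymographs and
  tracks-per-µm² densities.
- **Filament length** — orientation by intensity-weighted second moments,
  bicubic rotation to a central axis, 2-pixel-wide line scan, length =
  longest contiguous run above background + 50 % of (peak − background),
  in nm.
- **Membrane fraction** — per-cell TIRF:widefield integrated-intensity
  ratios with red-marker strain demultiplexing and marker-swap pooling.
- **Statistics** — mean ± SD summaries, fixed-origin histograms (5 nm/s
  velocity bins, 120 nm length bins) and Mann–Whitney U tests (exact for
  small tie-free samples).

## Worked example

Simulate a one-minute TIRF movie of cells whose synthesis complexes move
at 22 ± 6 nm/s, then recover the speed distribution through the full
detect → link → filter → fit chain:

```r
library(rodmotion)

sim <- run_tracking_sim(n_cells = 20, emitter_density = 2.0,
                        speed_dist = c(mean = 22, sd = 6), speed_min = 5,
                        seed = 11)
s <- summarize_sample(sim$velocities)
cat(sprintf("recovered %.1f +/- %.1f nm/s (n = %d tracks)\n",
            s$mean, s$sd, s$n))
#> recovered 23.4 +/- 6.0 nm/s (n = 67 tracks)

# geometry used for per-cell normalisation
cell <- spherocylinder(3.57, 1.0)           # um
illuminated_surface_area(cell, illumination_model(0.2))
#> [1] 3.011467
```

The recovered mean sits within a few percent of the configured 22 nm/s;
the 3.01 µm² is the TIRF-illuminated membrane area of an average
wild-type cell at a 200 nm illumination depth. A YAML-configurable
end-to-end run (`run_pipeline()`) writes per-track, per-cell and
per-filament CSVs plus a machine-readable `summary.json`.

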
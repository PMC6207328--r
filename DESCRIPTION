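Package: rodmotion
Title: Quantitative Fluorescence Imaging of Bacterial Rod-Complex Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis tools for single-particle tracking of
    bacterial cell-wall synthesis machinery imaged by TIRF microscopy.
    Generates synthetic movies of spherocylindrical cells carrying
    membrane-bound fluorescent foci that move circumferentially, with full
    ground truth; detects and links foci into trajectories with the
    five-frame / 70-nm survival filter; estimates per-track velocities and
    kymograph slopes; normalises track counts by spherocylinder cell area
    including the TIRF-illuminated surface fraction; measures filament
    lengths from super-resolution snapshots by rotation, two-pixel line
    scanning and half-amplitude thresholding; computes per-cell
    TIRF:widefield membrane-fraction ratios with marker-based strain
    demultiplexing; and reports mean/SD summaries, fixed-origin histograms
    and Mann-Whitney U comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
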
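cfg_sim <- sim_snapshot_config(seed = 1)

test_that("orientation recovers bar angles and rejects isotropic spots", {
  horiz <- render_filament_snapshot(600, 0, cfg_sim, noise = FALSE,
                                    seed = 2)$image
  a <- estimate_orientation(horiz)
  expect_lt(min(a, pi - a), 0.02)
  # rendered (not resampled) 30 degree bar, against an exhaustive search
  # maximising the projected second moment
  bar30 <- render_filament_snapshot(600, pi / 6, cfg_sim, noise = FALSE,
                                    seed = 2)$image
  expect_equal(estimate_orientation(bar30), pi / 6, tolerance = 0.02)
  bg <- local_background(bar30)
  w <- pmax(bar30 - bg, 0)
  xg <- matrix(seq_len(ncol(bar30)) - 0.5, nrow(bar30), ncol(bar30),
               byrow = TRUE)
  yg <- matrix(seq_len(nrow(bar30)) - 0.5, nrow(bar30), ncol(bar30))
  cx <- sum(w * xg) / sum(w); cy <- sum(w * yg) / sum(w)
  grid <- seq(0, pi, by = 0.005)
  proj_var <- vapply(grid, function(a)
    sum(w * ((xg - cx) * cos(a) + (yg - cy) * sin(a))^2), numeric(1))
  expect_equal(estimate_orientation(bar30), grid[which.max(proj_var)],
               tolerance = 0.02)
  # a diffraction-limited spot has no axis
  spot <- matrix(10, 31, 31)
  spot <- rodmotion:::.add_gaussian(spot, 15.5 * 40.6, 15.5 * 40.6, 4000,
                                    40, 40.6)
  expect_error(estimate_orientation(spot), "degenerate")
})

test_that("rotation conserves flux and inverts cleanly", {
  img <- render_filament_snapshot(500, pi / 5, cfg_sim, noise = FALSE,
                                  jitter = FALSE, seed = 3)$image
  bg <- 10
  # identity
  expect_equal(rotate_to_axis(img, 0, background = bg), img,
               tolerance = 0.02)
  # flux conservation through an arbitrary rotation
  rot <- rotate_to_axis(img, pi / 5, background = bg)
  expect_equal(sum(rot - bg), sum(img - bg), tolerance = 0.01)
  # rotate by alpha then -alpha: original within 2% per-pixel RMS
  back <- rotate_to_axis(rotate_to_axis(img, pi / 5, background = bg),
                         -pi / 5, background = bg)
  rms <- sqrt(mean((back - img)^2))
  expect_lt(rms / max(img - bg), 0.02)
  # rotating a centred axis-aligned bar by 90 degrees is a transpose
  sq <- render_filament_snapshot(400, 0, cfg_sim, noise = FALSE,
                                 jitter = FALSE, seed = 4)$image
  r90 <- rotate_to_axis(sq, pi / 2, background = bg)
  expect_lt(max(abs(r90 - t(sq))) / max(sq - bg), 0.05)
  expect_error(rotate_to_axis(img, NA), "finite")
})

test_that("line profiles sum the two straddling rows", {
  expect_equal(line_profile(matrix(3, 10, 7)), rep(6, 7))
  m <- matrix(0, 10, 7); m[5, 4] <- 9
  prof <- line_profile(m, center_row = 5)
  expect_equal(sum(prof != 0), 1)
  expect_equal(prof[4], 9)
  # blurred bar profile matches the analytic box (*) Gaussian
  L <- 600; p <- cfg_sim$pixel_size; s <- cfg_sim$psf_sigma
  snap <- render_filament_snapshot(L, 0, cfg_sim, noise = FALSE,
                                   jitter = FALSE, seed = 1, size_px = 40)
  img <- snap$image; truth <- snap$truth
  prof <- line_profile(img - 10, center_row = truth$y_nm / p)
  # pixel-integrated analytic profile (average over 9 sub-samples per pixel)
  sub <- seq(-0.5 + 1 / 18, 0.5 - 1 / 18, length.out = 9) * p
  analytic <- vapply(seq_len(40), function(j) {
    xs <- (j - 0.5) * p - truth$x_nm + sub
    mean(pnorm((xs + L / 2) / s) - pnorm((xs - L / 2) / s))
  }, numeric(1))
  analytic <- analytic / max(analytic)
  measured <- prof / max(prof)
  core <- analytic > 0.05
  expect_lt(max(abs(measured[core] - analytic[core])), 0.02)
})

test_that("local background is robust to the filament and to noise", {
  expect_equal(local_background(matrix(7, 20, 20)), 7)
  img <- render_filament_snapshot(500, 0.4, sim_snapshot_config(
    background_level = 100), noise = FALSE, seed = 5)$image
  expect_equal(local_background(img), 100, tolerance = 0.01)
  set.seed(6)
  noisy <- matrix(rnorm(625, 100, 5), 25, 25)
  expect_lt(abs(local_background(noisy) - 100), 2)
})

test_that("thresholded run length converts to nanometres", {
  expect_equal(measure_length(c(5, 5, 5), background = 5, peak = 6,
                              pixel_size = 40.6)$length_nm, 0)
  prof <- c(rep(0, 4), rep(10, 8), rep(0, 4))
  m <- measure_length(prof, background = 0, pixel_size = 40.6)
  expect_equal(m$length_nm, 8 * 40.6)
  expect_equal(m$length_nm, 324.8)
  # detached supra-threshold pixel does not extend the run
  prof2 <- c(10, 0, rep(10, 5), 0)
  expect_equal(measure_length(prof2, background = 0,
                              pixel_size = 1)$n_pixels, 5L)
  # the 1.5 x background reading is available
  m2 <- measure_length(prof + 100, background = 100, pixel_size = 40.6,
                       method = "background_x1.5")
  expect_equal(m2$threshold, 150)
  expect_error(measure_length(c(1, 1), background = 2, peak = 1,
                              pixel_size = 1), "peak")
})

test_that("a 500 nm bar is recovered within 15% over noisy realisations", {
  meas <- vapply(1:100, function(k) {
    snap <- render_filament_snapshot(500, pi / 7, cfg_sim, seed = 100 + k)
    roi <- data.frame(x0 = 0L, y0 = 0L, x1 = ncol(snap$image),
                      y1 = nrow(snap$image))
    batch_measure(snap$image, roi, cfg_sim$pixel_size)$length_nm[1]
  }, numeric(1))
  expect_equal(mean(meas, na.rm = TRUE), 500, tolerance = 0.15)
})

test_that("measured length is monotone in true length", {
  grid <- c(200, 400, 700, 1000, 1500)
  means <- vapply(grid, function(L) {
    mean(vapply(1:30, function(k) {
      snap <- render_filament_snapshot(L, 0.3, cfg_sim, seed = 7000 + 31 * k + L)
      roi <- data.frame(x0 = 0L, y0 = 0L, x1 = ncol(snap$image),
                        y1 = nrow(snap$image))
      batch_measure(snap$image, roi, cfg_sim$pixel_size)$length_nm[1]
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("population ordering is invariant to the threshold definition", {
  a_half <- run_filament_sim(60, length_dist = c(mean = 520, sd = 190),
                             length_min = 120, seed = 21)
  b_half <- run_filament_sim(60, length_dist = c(mean = 360, sd = 130),
                             length_min = 120, seed = 22)
  a_bg <- run_filament_sim(60, length_dist = c(mean = 520, sd = 190),
                           length_min = 120, method = "background_x1.5",
                           seed = 21)
  b_bg <- run_filament_sim(60, length_dist = c(mean = 360, sd = 130),
                           length_min = 120, method = "background_x1.5",
                           seed = 22)
  ok <- function(d) d$flag %in% c("ok", "at_resolution")
  expect_gt(median(a_half$measured_nm[ok(a_half)]),
            median(b_half$measured_nm[ok(b_half)]))
  expect_gt(median(a_bg$measured_nm[ok(a_bg)]),
            median(b_bg$measured_nm[ok(b_bg)]))
})

test_that("sub-resolution filaments report near the PSF width, not zero", {
  fwhm <- 2 * sqrt(2 * log(2)) * cfg_sim$psf_sigma
  res <- vapply(1:10, function(k) {
    snap <- render_filament_snapshot(50, 0.9, cfg_sim, seed = 400 + k,
                                     size_px = 16)
    roi <- data.frame(x0 = 0L, y0 = 0L, x1 = 16L, y1 = 16L)
    m <- batch_measure(snap$image, roi, cfg_sim$pixel_size,
                       psf_fwhm_nm = fwhm)
    c(m$length_nm[1], m$flag[1] != "ok")
  }, numeric(2))
  expect_true(all(res[1, ] > 0))
  expect_equal(mean(res[1, ]), fwhm, tolerance = 0.45)
  expect_true(all(res[2, ] == 1))  # flagged, not silently reported
})

test_that("degenerate regions are flagged rather than dropped", {
  img <- matrix(10, 30, 30)
  rois <- data.frame(x0 = c(0L, 0L), y0 = c(0L, 15L),
                     x1 = c(30L, 30L), y1 = c(15L, 30L))
  out <- batch_measure(img, rois, 40.6)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$flag != "ok"))
  expect_identical(nrow(batch_measure(img, rois[0, ], 40.6)), 0L)
})
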
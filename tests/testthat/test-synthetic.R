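test_that("membrane positions map angles to the expected heights", {
  pop <- fixed_cell_population(width_um = 1.0)
  cell <- pop[[1]]
  expect_equal(membrane_position(cell, 0, 0)[, "z_nm"], c(z_nm = 0))
  expect_equal(membrane_position(cell, 0, pi)[, "z_nm"], c(z_nm = 1000))
  expect_equal(membrane_position(cell, 0, pi / 2)[, "z_nm"], c(z_nm = 500))
  # cap anchor: overhang shrinks the cross-section but keeps z finite
  cap <- membrane_position(cell, (cell$length_nm - cell$width_nm) / 2 + 300,
                           0)
  expect_gte(cap[, "z_nm"], 0)
  expect_error(membrane_position(cell, cell$length_nm, 0), "outside")
})

test_that("circumferential advance is v t / r and matches step integration", {
  em <- focus_emitters(0, 1.0, 22)
  pop <- fixed_cell_population(emitters = em)
  # static emitter
  pop0 <- fixed_cell_population(emitters = focus_emitters(0, 1.0, 0))
  expect_equal(advance_emitters(pop0, 100)[[1]]$emitters$theta0, 1.0)
  # v = 22, r = 500, t = 10 -> delta theta = 0.44
  adv <- advance_emitters(pop, 10)
  expect_equal(adv[[1]]$emitters$theta0, 1.0 + 0.44)
  # full revolution time against stepwise integration at dt = 0.01 s
  r <- 500; v <- 22
  t_rev_closed <- 2 * pi * r / v
  theta <- 0; dt <- 0.01; t <- 0
  while (theta < 2 * pi) { theta <- theta + v * dt / r; t <- t + dt }
  expect_equal(t_rev_closed, t, tolerance = 1e-3)
  expect_equal(t_rev_closed, 142.8, tolerance = 1e-3)
})

test_that("population generation honours densities and distributions", {
  # empty case
  pop <- generate_population(1, emitter_density = 0, seed = 1)
  expect_length(pop, 1)
  expect_equal(nrow(pop[[1]]$emitters), 0)
  # zero-variance speeds
  pop <- generate_population(3, emitter_density = 2,
                             speed_dist = c(mean = 22, sd = 0), seed = 2)
  speeds <- unlist(lapply(pop, function(c) c$emitters$speed_nm_s))
  expect_true(length(speeds) > 0 && all(speeds == 22))
  # Poisson sum: 100 cells of projected area 2.785 um^2 at density 1/um^2
  pop <- generate_population(100, length_dist = c(mean = 3, sd = 0),
                             width_dist = c(mean = 1, sd = 0),
                             emitter_density = 1, seed = 3)
  total <- sum(vapply(pop, function(c) nrow(c$emitters), integer(1)))
  expect_lt(abs(total - 278.5), 3 * sqrt(278.5))
  # determinism
  pop2 <- generate_population(100, length_dist = c(mean = 3, sd = 0),
                              width_dist = c(mean = 1, sd = 0),
                              emitter_density = 1, seed = 3)
  expect_identical(pop, pop2)
  expect_error(generate_population(0), "n_cells")
})

test_that("rendering conserves photons and attenuates with depth", {
  cfg <- imaging_config(seed = 1)
  # no emitters -> uniform background
  pop <- fixed_cell_population()
  fr <- render_frame(pop, 0, cfg, "tirf")
  expect_true(all(fr == cfg$background_level))
  # single focus at the bottom: flux = photon_rate
  pop <- fixed_cell_population(emitters = focus_emitters(0, 0, 0))
  fr <- render_frame(pop, 0, cfg, "tirf")
  expect_equal(sum(fr - cfg$background_level), cfg$photon_rate,
               tolerance = 1e-6)
  # z = 200 nm vs z = 0: flux ratio e^-1 (width exactly 1000 nm)
  th200 <- acos(1 - 200 / 500)
  pop2 <- fixed_cell_population(emitters = focus_emitters(0, th200, 0))
  fr2 <- render_frame(pop2, 0, cfg, "tirf")
  expect_equal(sum(fr2 - cfg$background_level) / sum(fr - cfg$background_level),
               exp(-1), tolerance = 1e-3)
  # widefield: full contribution while z <= depth
  frw <- render_frame(pop2, 0, cfg, "widefield")
  expect_equal(sum(frw - cfg$background_level), cfg$photon_rate,
               tolerance = 1e-6)
})

test_that("photon conservation holds for multi-emitter fields", {
  cfg <- imaging_config(seed = 1)
  th <- c(0, 0.4, 0.9, 1.4)
  em <- focus_emitters(c(-600, -200, 200, 600), th, 0)
  pop <- fixed_cell_population(emitters = em)
  fr <- render_frame(pop, 0, cfg, "tirf")
  r <- 500
  expected <- sum(cfg$photon_rate * exp(-r * (1 - cos(th)) / cfg$tirf_depth))
  expect_equal(sum(fr - cfg$background_level), expected, tolerance = 1e-3)
})

test_that("rendered focus amplitude strictly decreases with depth", {
  cfg <- imaging_config(seed = 1)
  fluxes <- vapply(seq(0, 2.8, by = 0.4), function(th) {
    pop <- fixed_cell_population(emitters = focus_emitters(0, th, 0))
    sum(render_frame(pop, 0, cfg, "tirf") - cfg$background_level)
  }, numeric(1))
  expect_true(all(diff(fluxes) < 0))
})

test_that("noise model is seeded, mean-preserving and clipped", {
  cfg <- imaging_config(read_noise_sd = 0, seed = 1)
  z <- matrix(0, 10, 10)
  expect_true(all(apply_noise(z, cfg) == 0))
  cfg2 <- imaging_config(seed = 1)
  big <- matrix(10000, 200, 200)
  noisy <- apply_noise(big, cfg2, seed = 4)
  expect_equal(mean(noisy), 10000, tolerance = 0.01)
  expect_identical(apply_noise(big, cfg2, seed = 9),
                   apply_noise(big, cfg2, seed = 9))
  expect_true(all(apply_noise(matrix(0.01, 50, 50), cfg2, seed = 2) >= 0))
  expect_error(apply_noise(matrix(-1, 2, 2), cfg2), "non-negative")
})

test_that("movies and ground truth are bit-reproducible under a fixed seed", {
  cfg <- imaging_config(n_frames = 5, seed = 11)
  pop <- fixed_cell_population(emitters = focus_emitters(c(-400, 300),
                                                         c(0.2, 5.8),
                                                         c(22, 28)))
  m1 <- simulate_movie(pop, cfg)
  m2 <- simulate_movie(pop, cfg)
  expect_identical(m1$frames, m2$frames)
  expect_identical(ground_truth(pop, cfg), ground_truth(pop, cfg))
})

test_that("apparent projected speed is bounded by the visibility geometry", {
  cfg <- imaging_config(n_frames = 60, seed = 1)
  pop <- fixed_cell_population(emitters = focus_emitters(0, -1.2, 22))
  gt <- ground_truth(pop, cfg)
  vis <- gt[gt$tirf_visible, ]
  steps <- sqrt(diff(vis$x_nm)^2 + diff(vis$y_nm)^2) /
           diff(vis$t_s)
  steps <- steps[diff(vis$frame) == 1]
  theta_max <- acos(1 - 2 * cfg$tirf_depth / 1000)
  expect_true(all(steps <= 22 + 1e-6))
  expect_true(all(steps >= cos(theta_max) * 22 - 1e-6))
})

test_that("movie and truth tables round-trip through disk exactly", {
  dir <- withr::local_tempdir()
  cfg <- imaging_config(n_frames = 3, seed = 5)
  pop <- fixed_cell_population(emitters = focus_emitters(0, 0.3, 22))
  mg <- simulate_movie(pop, cfg, mode = "tirf", channel = "green")
  mr <- simulate_movie(pop, cfg, mode = "widefield", channel = "red")
  truth <- ground_truth(pop, cfg)
  files <- write_outputs(list(green_tirf = mg, red_wf = mr), truth, dir)
  back <- read_movie(files[["green_tirf"]])
  expect_identical(length(back), length(mg$frames))
  expect_identical(back, mg$frames)
  expect_identical(length(read_movie(files[["red_wf"]])), 3L)
  rt <- utils::read.csv(files[["ground_truth"]])
  expect_equal(nrow(rt), nrow(truth))
  expect_equal(rt$x_nm, truth$x_nm)
  # empty truth -> header-only file
  files2 <- write_outputs(list(), truth[0, ], dir)
  expect_identical(nrow(utils::read.csv(files2[["ground_truth"]])), 0L)
  expect_error(read_movie(file.path(dir, "missing.tif")), "no such file")
})
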
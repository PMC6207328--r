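cfg_trk <- imaging_config(seed = 1)

test_that("blank frames yield almost no false detections", {
  cfg <- imaging_config(seed = 3)
  fp <- sum(vapply(1:100, function(k) {
    fr <- apply_noise(matrix(cfg$background_level, 60, 60), cfg, seed = k)
    nrow(detect_spots(fr, cfg, snr_min = 5))
  }, numeric(1)))
  expect_lt(fp / 100, 0.1)
})

test_that("a rendered focus is localised within a quarter pixel", {
  pop <- fixed_cell_population(emitters = focus_emitters(123, 0.15, 0))
  gt <- ground_truth(pop, cfg_trk)
  errs <- vapply(1:20, function(k) {
    fr <- apply_noise(render_frame(pop, 0, cfg_trk, "tirf"), cfg_trk,
                      seed = 50 + k)
    d <- detect_spots(fr, cfg_trk, snr_min = 5)
    expect_equal(nrow(d), 1L)
    sqrt((d$x_nm - gt$x_nm[1])^2 + (d$y_nm - gt$y_nm[1])^2)
  }, numeric(1))
  expect_lt(mean(errs), 0.25 * cfg_trk$pixel_size)
})

test_that("well-separated foci give exactly two detections", {
  em <- focus_emitters(c(-700, 700), 0.1, 0)  # 1400 nm apart >> 10 sd
  pop <- fixed_cell_population(emitters = em)
  fr <- apply_noise(render_frame(pop, 0, cfg_trk, "tirf"), cfg_trk, seed = 2)
  expect_equal(nrow(detect_spots(fr, cfg_trk, snr_min = 5)), 2L)
})

test_that("linking builds consecutive tracks and respects the gate", {
  # one detection per frame -> one 10-frame track
  det <- data.frame(frame = 1:10, x_nm = 100 + 20 * (1:10), y_nm = 500,
                    amplitude = 1)
  tr <- link_tracks(det)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 10L)
  # a jump beyond the gate starts a new track
  det2 <- data.frame(frame = 1:4, x_nm = c(0, 50, 1000, 1050), y_nm = 0,
                     amplitude = 1)
  tr2 <- link_tracks(det2, track_filter_config(max_link_distance = 250))
  expect_equal(length(unique(tr2$track_id)), 2L)
  # two parallel emitters far apart: no identity swaps
  det3 <- rbind(data.frame(frame = rep(1:20, 2),
                           x_nm = c(100 + 20 * (1:20), 100 + 20 * (1:20)),
                           y_nm = rep(c(200, 1800), each = 20),
                           amplitude = 1))
  tr3 <- link_tracks(det3)
  expect_equal(length(unique(tr3$track_id)), 2L)
  for (id in unique(tr3$track_id))
    expect_equal(length(unique(tr3$y_nm[tr3$track_id == id])), 1L)
  # conservation: every detection belongs to exactly one track
  expect_false(any(is.na(tr3$track_id)))
  expect_equal(nrow(tr3), 40L)
})

test_that("the survival filter matches brute-force predicate evaluation", {
  fixture <- make_track_fixture()
  kept <- filter_tracks(fixture, track_filter_config())
  expect_setequal(unique(kept$track_id), brute_force_survivors(fixture))
  # spelled-out cases: 4 frames/200 nm and 10 frames/50 nm both discarded
  t4 <- data.frame(track_id = 1, frame = 1:4, x_nm = c(0, 70, 140, 200),
                   y_nm = 0)
  expect_equal(nrow(filter_tracks(t4)), 0L)
  t10 <- data.frame(track_id = 1, frame = 1:10, x_nm = seq(0, 50, length.out = 10),
                    y_nm = 0)
  expect_equal(nrow(filter_tracks(t10)), 0L)
  # idempotence
  again <- filter_tracks(kept, track_filter_config())
  expect_equal(sort(unique(again$track_id)), sort(unique(kept$track_id)))
  # the literal both-fail reading keeps tracks that fail only one predicate
  lit <- filter_tracks(fixture, track_filter_config(), rule = "literal")
  expect_gt(length(unique(lit$track_id)), length(unique(kept$track_id)))
  # discard reasons are reported
  expect_true(sum(attr(kept, "discarded")) ==
              length(unique(fixture$track_id)) -
              length(unique(kept$track_id)))
})

test_that("velocity estimators agree with constructed motion", {
  still <- data.frame(track_id = 1, frame = 1:6, x_nm = 500, y_nm = 500)
  expect_equal(track_velocity(still), 0)
  line <- data.frame(track_id = 1, frame = 1:10, x_nm = 100 + 20 * (1:10),
                     y_nm = 50)
  expect_equal(track_velocity(line, frame_interval = 1), 20)
  expect_equal(track_velocity(line, method = "mean_step"), 20)
  diag <- data.frame(track_id = 1, frame = 1:10,
                     x_nm = 3 * (1:10), y_nm = 4 * (1:10))
  expect_equal(track_velocity(diag), 5)
  expect_error(track_velocity(line[1, , drop = FALSE]), "2 points")
})

test_that("track density divides surviving counts by footprint area", {
  cell <- spherocylinder(3, 1)
  six <- data.frame(track_id = rep(1:6, each = 2), frame = rep(1:2, 6),
                    x_nm = 0, y_nm = 0)
  expect_equal(tracks_per_area(six, 2.0), 3.0)
  expect_equal(tracks_per_area(0, cell), 0)
  expect_equal(tracks_per_area(7, cell), 7 / projected_area(cell))
  expect_error(tracks_per_area(3, 0), "positive")
})

test_that("kymographs show ridges whose slope is the speed", {
  cfg <- imaging_config(n_frames = 30, seed = 9)
  # static spot: vertical ridge, zero slope
  pop <- fixed_cell_population(emitters = focus_emitters(0, 0.05, 0))
  movie <- simulate_movie(pop, cfg)
  det <- detect_movie(movie, snr_min = 8)
  tr <- link_tracks(det)
  main_id <- names(sort(table(tr$track_id), decreasing = TRUE))[1]
  main <- tr[tr$track_id == as.integer(main_id), ]
  k <- build_kymograph(movie, main)
  expect_s3_class(k, "kymograph")
  expect_equal(ncol(k$data), length(unique(main$frame)))
  expect_lt(kymograph_slope(k), 3)
  # moving emitter: slope approximates the projected speed
  pop2 <- fixed_cell_population(emitters = focus_emitters(0, -0.6, 25))
  movie2 <- simulate_movie(pop2, cfg)
  tr2 <- link_tracks(detect_movie(movie2, snr_min = 8))
  ts2 <- track_summaries(tr2)
  main2 <- tr2[tr2$track_id == ts2$track_id[which.max(ts2$n_frames)], ]
  k2 <- build_kymograph(movie2, main2)
  v_k <- kymograph_slope(k2)
  v_t <- track_velocity(main2)
  expect_equal(v_k, v_t, tolerance = 0.15)
  expect_equal(v_k, 25, tolerance = 0.2)
  # no ridge above background -> error
  blank <- structure(list(data = matrix(10, 40, 10), pixel_size = 65,
                          frame_interval = 1, frames = 1:10),
                     class = "kymograph")
  expect_error(kymograph_slope(blank), "ridge")
})

test_that("tracking recovers emitter identity on synthetic detections", {
  sim <- run_tracking_sim(n_cells = 4, emitter_density = 1.5, seed = 31)
  # every kept track should sit close to one true emitter's path
  truth <- sim$truth
  for (id in unique(sim$tracks$track_id)) {
    tr <- sim$tracks[sim$tracks$track_id == id, ]
    errs <- vapply(seq_len(nrow(tr)), function(q) {
      cand <- truth[truth$frame == tr$frame[q], ]
      min(sqrt((cand$x_nm - tr$x_nm[q])^2 + (cand$y_nm - tr$y_nm[q])^2))
    }, numeric(1))
    expect_lt(stats::median(errs), 65)  # within one pixel of a true emitter
  }
  # and the filter applied to the linked tracks equals brute force
  linked <- link_tracks(detect_movie(simulate_movie(sim$population,
                                                    sim$config), snr_min = 12))
  expect_setequal(unique(filter_tracks(linked)$track_id),
                  brute_force_survivors(linked))
})
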
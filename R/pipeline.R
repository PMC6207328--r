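#' @name pipeline
#' @title End-to-end synthetic experiments and reporting
#'
#' @description
#' Orchestration of the full chain on synthetic data with known ground
#' truth: simulate a movie, detect and link foci, apply the survival
#' filter, estimate velocities and per-cell track densities, measure
#' filament lengths, run the ratio experiment, and write CSV/JSON reports.
NULL

#' Assign tracks to cells by footprint
#'
#' A track belongs to the cell whose spherocylinder footprint contains its
#' centroid (with a small slack for localisation error).
#'
#' @param tracks Linked detections with \code{track_id}.
#' @param cells A \code{cell_population}.
#' @param slack_nm Extra allowance beyond the cell radius.
#' @return Data frame \code{track_id}, \code{cell_id} (NA when outside all
#'   cells).
#' @export
assign_tracks_to_cells <- function(tracks, cells, slack_nm = 150) {
  ids <- unique(tracks$track_id)
  cx <- vapply(ids, function(id)
    mean(tracks$x_nm[tracks$track_id == id]), numeric(1))
  cy <- vapply(ids, function(id)
    mean(tracks$y_nm[tracks$track_id == id]), numeric(1))
  cell_id <- rep(NA_integer_, length(ids))
  for (cell in cells) {
    u <- c(cos(cell$orientation), sin(cell$orientation))
    half_cyl <- (cell$length_nm - cell$width_nm) / 2
    dx <- cx - cell$center[1]; dy <- cy - cell$center[2]
    along <- pmin(pmax(dx * u[1] + dy * u[2], -half_cyl), half_cyl)
    d <- sqrt((dx - along * u[1])^2 + (dy - along * u[2])^2)
    inside <- d <= cell$width_nm / 2 + slack_nm
    cell_id[inside & is.na(cell_id)] <- cell$cell_id
  }
  data.frame(track_id = ids, cell_id = cell_id)
}

#' Simulate and analyse a TIRF tracking experiment
#'
#' Generates a field of cells with circumferentially moving foci, renders
#' and tracks the TIRF movie, applies the survival filter and reports
#' per-track velocities and per-cell track densities next to the ground
#' truth.
#'
#' @param n_cells Number of cells.
#' @param emitter_density Emitters per um^2 projected cell area.
#' @param speed_dist Mean/sd of true circumferential speed, nm/s.
#' @param speed_min Lower truncation of the speed distribution, nm/s.
#' @param config An \code{\link{imaging_config}}.
#' @param filter A \code{\link{track_filter_config}}.
#' @param snr_min Detection threshold, see \code{\link{detect_spots}}. The
#'   default of 12 is chosen from the illumination geometry: at the
#'   simulator's default photon budget it admits foci only within roughly
#'   the bottom 120 nm of the membrane, where the apparent (projected)
#'   circumferential speed is within about 5 percent of the true surface
#'   speed; a looser cut tracks foci higher up the flank whose motion is
#'   substantially foreshortened.
#' @param length_dist,width_dist Cell dimension distributions, um.
#' @param seed Integer seed.
#' @return List with \code{population}, \code{truth}, \code{tracks}
#'   (surviving detections), \code{track_summary}, \code{velocities}
#'   (nm/s, surviving tracks), \code{densities} (per-cell data frame with
#'   \code{tracks_per_um2} and true emitter counts) and \code{config}.
#' @export
run_tracking_sim <- function(n_cells = 12, emitter_density = 2.0,
                             speed_dist = c(mean = 22, sd = 6), speed_min = 5,
                             config = imaging_config(),
                             filter = track_filter_config(), snr_min = 12,
                             length_dist = c(mean = 3.57, sd = 0.3),
                             width_dist = c(mean = 1.0, sd = 0.04),
                             seed = 1L) {
  pop <- generate_population(n_cells, length_dist = length_dist,
                             width_dist = width_dist,
                             emitter_density = emitter_density,
                             speed_dist = speed_dist, speed_min = speed_min,
                             kind = "focus", seed = seed)
  cfg <- config; cfg$seed <- as.integer(seed)
  movie <- simulate_movie(pop, cfg, mode = "tirf")
  truth <- ground_truth(pop, cfg)
  det <- detect_movie(movie, snr_min = snr_min)
  linked <- link_tracks(det, filter)
  kept <- filter_tracks(linked, filter, frame_interval = cfg$frame_interval)
  ts <- attr(kept, "track_summary")
  kept_ts <- ts[ts$kept, , drop = FALSE]
  assign <- assign_tracks_to_cells(kept, pop)
  dens <- lapply(pop, function(cell) {
    n_tr <- sum(assign$cell_id == cell$cell_id, na.rm = TRUE)
    sc <- spherocylinder(cell$length_nm / 1000, cell$width_nm / 1000)
    data.frame(cell_id = cell$cell_id,
               n_tracks = n_tr,
               area_um2 = projected_area(sc),
               tracks_per_um2 = tracks_per_area(n_tr, sc),
               n_emitters_true = nrow(cell$emitters))
  })
  list(population = pop, truth = truth, tracks = kept,
       track_summary = ts, velocities = kept_ts$velocity_nm_s,
       densities = do.call(rbind, dens), config = cfg)
}

#' Density sweep: track density versus true emitter density
#'
#' Runs \code{\link{run_tracking_sim}} at several emitter densities and
#' reports the mean measured track density at each, for checking linearity
#' of the density readout.
#'
#' @param densities Vector of emitter densities, per um^2.
#' @param n_cells Cells per density level.
#' @param ... Passed to \code{\link{run_tracking_sim}}.
#' @param seed Integer seed.
#' @return Data frame with \code{density_true}, \code{density_measured}
#'   (mean tracks/um^2) and \code{n_cells}.
#' @export
run_density_sweep <- function(densities, n_cells = 10, ..., seed = 1L) {
  out <- lapply(seq_along(densities), function(k) {
    sim <- run_tracking_sim(n_cells = n_cells,
                            emitter_density = densities[k], ...,
                            seed = seed + 1000L * k)
    data.frame(density_true = densities[k],
               density_measured = mean(sim$densities$tracks_per_um2),
               n_cells = n_cells)
  })
  do.call(rbind, out)
}

#' Simulate and measure a filament-length population
#'
#' Draws true lengths from a truncated Gaussian, renders one SIM-like
#' snapshot per filament at a random orientation and runs the full
#' measurement chain on each.
#'
#' @param n Number of filaments.
#' @param length_dist Mean/sd of true length, nm.
#' @param length_min Lower truncation, nm.
#' @param config Snapshot imaging configuration.
#' @param method Threshold rule, see \code{\link{measure_length}}.
#' @param flux_per_nm Photons per frame per nm of filament.
#' @param seed Integer seed.
#' @return Data frame with \code{true_nm}, \code{measured_nm},
#'   \code{angle}, \code{flag}.
#' @export
run_filament_sim <- function(n, length_dist = c(mean = 520, sd = 190),
                             length_min = 120,
                             config = sim_snapshot_config(),
                             method = "half_amplitude", flux_per_nm = 8,
                             seed = 1L) {
  lengths <- with_seed(seed, rtrunc_norm(n, length_dist[[1]], length_dist[[2]],
                                         lower = length_min))
  angles <- with_seed(seed + 1L, stats::runif(n, 0, pi))
  fwhm <- 2 * sqrt(2 * log(2)) * config$psf_sigma
  out <- lapply(seq_len(n), function(k) {
    snap <- render_filament_snapshot(lengths[k], angles[k], config,
                                     flux_per_nm = flux_per_nm,
                                     seed = seed + 13L * k)
    roi <- data.frame(x0 = 0L, y0 = 0L, x1 = ncol(snap$image),
                      y1 = nrow(snap$image))
    m <- batch_measure(snap$image, roi, config$pixel_size, method = method,
                       psf_fwhm_nm = fwhm)
    data.frame(true_nm = lengths[k], measured_nm = m$length_nm[1],
               angle = angles[k], flag = m$flag[1])
  })
  do.call(rbind, out)
}

#' Replicated null experiments for the TIRF:widefield ratio
#'
#' Repeats a two-strain ratio experiment with identical membrane-bound
#' fractions and reports the fraction of replicates in which the
#' between-strain Mann-Whitney test is non-significant, operationalising a
#' no-difference conclusion.
#'
#' @param n_replicates Number of replicate experiments.
#' @param n_cells Cells per strain per replicate.
#' @param membrane_fraction Common membrane-bound fraction.
#' @param alpha Significance level.
#' @param config Imaging configuration (single-frame).
#' @param seed Integer seed.
#' @return List with \code{nonsignificant_fraction}, \code{p_values},
#'   \code{alpha}.
#' @export
run_ratio_null <- function(n_replicates = 200, n_cells = 30,
                           membrane_fraction = 0.5, alpha = 0.05,
                           config = imaging_config(n_frames = 1L),
                           seed = 1L) {
  ps <- vapply(seq_len(n_replicates), function(k) {
    dat <- simulate_ratio_experiment(n_cells = n_cells,
                                     membrane_fraction = membrane_fraction,
                                     config = config, seed = seed + 37L * k)
    mann_whitney_u(dat$ratio[dat$strain == "wt"],
                   dat$ratio[dat$strain == "l61r"], mode = "normal")$p
  }, numeric(1))
  list(nonsignificant_fraction = mean(ps > alpha), p_values = ps,
       alpha = alpha)
}

#' Run the configured analysis pipeline
#'
#' Executes the stages named in the configuration (a YAML file path or an
#' equivalent nested list): \code{geometry}, \code{tracking},
#' \code{filaments}, \code{ratio}. Writes per-stage CSVs plus a
#' machine-readable \code{summary.json} and a run log into \code{out_dir},
#' and returns the summary invisibly. Identical configuration and seed give
#' an identical summary.
#'
#' @param config YAML path or nested list; recognised sections below.
#'   \describe{
#'     \item{geometry}{\code{length_um}, \code{width_um}, \code{depth_um}}
#'     \item{tracking}{\code{n_cells}, \code{emitter_density},
#'       \code{speed_mean}, \code{speed_sd}, \code{speed_min},
#'       \code{snr_min}}
#'     \item{filaments}{\code{n}, \code{mean_nm}, \code{sd_nm},
#'       \code{min_nm}}
#'     \item{ratio}{\code{n_cells}, \code{membrane_fraction}}
#'   }
#' @param out_dir Output directory.
#' @param seed Integer seed overriding \code{config$seed}.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(if (!is.null(seed)) seed else
                     if (!is.null(config$seed)) config$seed else 1L)
  summary <- list(schema_version = "1.0", seed = seed,
                  r_version = as.character(getRversion()))
  log_lines <- c(sprintf("rodmotion pipeline, seed=%d", seed),
                 sprintf("R %s", getRversion()))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (!is.null(config$geometry)) {
    g <- config$geometry
    summary$geometry <- stage("geometry", {
      cell <- spherocylinder(g$length_um, g$width_um)
      illum <- illumination_model(if (!is.null(g$depth_um)) g$depth_um else 0.2)
      list(length_um = g$length_um, width_um = g$width_um,
           depth_um = illum$depth,
           total_um2 = total_surface_area(cell),
           illuminated_um2 = illuminated_surface_area(cell, illum),
           illuminated_fraction = illuminated_fraction(cell, illum),
           projected_um2 = projected_area(cell))
    })
    log_lines <- c(log_lines, "stage geometry: ok")
  }
  if (!is.null(config$tracking)) {
    tkc <- config$tracking
    summary$tracking <- stage("tracking", {
      sim <- run_tracking_sim(
        n_cells = tkc$n_cells %||% 12,
        emitter_density = tkc$emitter_density %||% 2.0,
        speed_dist = c(mean = tkc$speed_mean %||% 22,
                       sd = tkc$speed_sd %||% 6),
        speed_min = tkc$speed_min %||% 5,
        snr_min = tkc$snr_min %||% 12, seed = seed)
      utils::write.csv(sim$track_summary,
                       file.path(out_dir, "track_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(sim$densities, file.path(out_dir, "cell_density.csv"),
                       row.names = FALSE)
      utils::write.csv(sim$tracks, file.path(out_dir, "tracks.csv"),
                       row.names = FALSE)
      vs <- summarize_sample(sim$velocities)
      list(n_tracks = vs$n, velocity_mean_nm_s = vs$mean,
           velocity_sd_nm_s = vs$sd,
           true_speed_mean_nm_s = unname(tkc$speed_mean %||% 22),
           density_mean_per_um2 = mean(sim$densities$tracks_per_um2))
    })
    log_lines <- c(log_lines, "stage tracking: ok")
  }
  if (!is.null(config$filaments)) {
    fc <- config$filaments
    summary$filaments <- stage("filaments", {
      fl <- run_filament_sim(fc$n %||% 100,
                             length_dist = c(mean = fc$mean_nm %||% 520,
                                             sd = fc$sd_nm %||% 190),
                             length_min = fc$min_nm %||% 120, seed = seed)
      utils::write.csv(fl, file.path(out_dir, "filament_lengths.csv"),
                       row.names = FALSE)
      ok <- fl$flag %in% c("ok", "at_resolution")
      ms <- summarize_sample(fl$measured_nm[ok])
      list(n = ms$n, measured_mean_nm = ms$mean, measured_sd_nm = ms$sd,
           true_mean_nm = mean(fl$true_nm))
    })
    log_lines <- c(log_lines, "stage filaments: ok")
  }
  if (!is.null(config$ratio)) {
    rc <- config$ratio
    summary$ratio <- stage("ratio", {
      dat <- simulate_ratio_experiment(
        n_cells = rc$n_cells %||% 30,
        membrane_fraction = rc$membrane_fraction %||% 0.5, seed = seed)
      utils::write.csv(dat, file.path(out_dir, "cell_ratios.csv"),
                       row.names = FALSE)
      cmp <- mann_whitney_u(dat$ratio[dat$strain == "wt"],
                            dat$ratio[dat$strain == "l61r"], mode = "normal")
      list(ratio_mean_wt = mean(dat$ratio[dat$strain == "wt"]),
           ratio_mean_l61r = mean(dat$ratio[dat$strain == "l61r"]),
           mann_whitney_p = cmp$p)
    })
    log_lines <- c(log_lines, "stage ratio: ok")
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
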
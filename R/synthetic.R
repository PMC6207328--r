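#' @name synthetic-imaging
#' @title Synthetic TIRF/widefield movie generation
#'
#' @description
#' Generates fields of non-overlapping spherocylindrical cells lying flat on
#' the coverslip, carrying membrane-bound emitters: diffraction-limited foci
#' that move circumferentially around the long axis at a constant surface
#' speed, and static filaments. Movies are rendered with a Gaussian PSF,
#' depth-dependent TIRF attenuation, Poisson shot noise and Gaussian read
#' noise, alongside a ground-truth table of true positions, depths, speeds
#' and lengths.
NULL

# truncated-normal draw by resampling; sd = 0 returns the mean
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean <= lower) stop("degenerate distribution entirely below lower bound")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw > lower])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cell population with membrane-bound emitters
#'
#' Cells are placed on a regular grid with generous margins (guaranteeing
#' non-overlap for any orientation), with dimensions drawn from Gaussian
#' distributions. Each cell receives a Poisson-distributed number of
#' emitters (mean = \code{emitter_density} x projected cell area), anchored
#' uniformly on the cylindrical flank of the membrane with uniform starting
#' circumferential angles. Speeds and filament lengths are drawn from
#' Gaussians truncated below.
#'
#' @param n_cells Number of cells.
#' @param length_dist,width_dist Mean/sd pairs (um) for cell length and
#'   width.
#' @param emitter_density Mean emitters per um^2 of projected cell area.
#' @param speed_dist Mean/sd pair (nm/s) for circumferential emitter speed.
#' @param filament_length_dist Mean/sd pair (nm) for filament arc length
#'   (used when \code{kind = "filament"}).
#' @param kind \code{"focus"} (moving spot) or \code{"filament"} (static
#'   arc).
#' @param speed_min,filament_length_min Lower truncation bounds (nm/s, nm).
#' @param margin Margin around each cell within its grid tile, nm.
#' @param orientation \code{"random"} in-plane orientation, or a fixed angle
#'   in radians.
#' @param strain_label Label stored on every cell.
#' @param has_marker Whether cells carry the cytoplasmic red marker.
#' @param seed Integer seed; fixed seed gives identical populations.
#' @return A list of cell specifications (class \code{cell_population}),
#'   each with fields \code{cell_id}, \code{center} (nm), \code{orientation},
#'   \code{length_nm}, \code{width_nm}, \code{strain_label},
#'   \code{has_marker} and an \code{emitters} data frame; the field extent
#'   in nm is stored in \code{attr(, "field_nm")}.
#' @export
generate_population <- function(n_cells,
                                length_dist = c(mean = 3.57, sd = 0.4),
                                width_dist = c(mean = 1.0, sd = 0.05),
                                emitter_density = 1.0,
                                speed_dist = c(mean = 22, sd = 6),
                                filament_length_dist = c(mean = 520, sd = 190),
                                kind = c("focus", "filament"),
                                speed_min = 0, filament_length_min = 0,
                                margin = 650, orientation = "random",
                                strain_label = "wt", has_marker = FALSE,
                                seed = 1L) {
  kind <- match.arg(kind)
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (emitter_density < 0) stop("emitter_density must be >= 0")
  if (length_dist[[1]] <= 0 || width_dist[[1]] <= 0)
    stop("cell dimension means must be positive")
  with_seed(seed, {
    lengths_um <- rtrunc_norm(n_cells, length_dist[[1]], length_dist[[2]],
                              lower = width_dist[[1]])
    widths_um <- rtrunc_norm(n_cells, width_dist[[1]], width_dist[[2]])
    widths_um <- pmin(widths_um, lengths_um)   # spherocylinder needs L >= W

    # grid placement: tile side fits the longest cell at any orientation
    tile <- max(lengths_um) * 1000 + 2 * margin
    ncol_grid <- ceiling(sqrt(n_cells))
    nrow_grid <- ceiling(n_cells / ncol_grid)
    cells <- vector("list", n_cells)
    next_emitter_id <- 1L
    for (i in seq_len(n_cells)) {
      gx <- (i - 1L) %% ncol_grid
      gy <- (i - 1L) %/% ncol_grid
      center <- c((gx + 0.5) * tile, (gy + 0.5) * tile)
      phi <- if (identical(orientation, "random"))
        stats::runif(1, 0, pi) else as.numeric(orientation)
      L_nm <- lengths_um[i] * 1000
      W_nm <- widths_um[i] * 1000
      area <- projected_area(spherocylinder(lengths_um[i], widths_um[i]))
      n_em <- stats::rpois(1, emitter_density * area)
      half_cyl <- (L_nm - W_nm) / 2
      em <- data.frame(
        emitter_id = if (n_em > 0) seq.int(next_emitter_id, length.out = n_em)
                     else integer(0),
        kind = rep(kind, n_em),
        axial_nm = stats::runif(n_em, -half_cyl, half_cyl),
        theta0 = stats::runif(n_em, 0, 2 * pi),
        speed_nm_s = if (kind == "focus")
          rtrunc_norm(n_em, speed_dist[[1]], speed_dist[[2]], speed_min)
          else rep(0, n_em),
        length_nm = if (kind == "filament")
          rtrunc_norm(n_em, filament_length_dist[[1]],
                      filament_length_dist[[2]], filament_length_min)
          else rep(0, n_em),
        intensity_scale = rep(1, n_em))
      next_emitter_id <- next_emitter_id + n_em
      cells[[i]] <- list(cell_id = i, center = center, orientation = phi,
                         length_nm = L_nm, width_nm = W_nm,
                         strain_label = strain_label, has_marker = has_marker,
                         emitters = em)
    }
    structure(cells, class = "cell_population",
              field_nm = c(ncol_grid * tile, nrow_grid * tile))
  })
}

#' Membrane surface position of an anchor
#'
#' Maps a membrane anchor (axial coordinate along the long axis, measured
#' from the cell centre, plus circumferential angle theta measured from the
#' bottom line touching the coverslip) to its lateral projection and height.
#' On the cylindrical flank the height is \eqn{z = r (1 - \cos\theta)}; on
#' the hemispherical caps the cross-section radius shrinks accordingly.
#'
#' @param cell One cell specification from
#'   \code{\link{generate_population}}.
#' @param axial_nm Axial coordinate(s), nm; |axial| up to length/2.
#' @param theta Circumferential angle(s), rad.
#' @return Matrix with columns \code{x_nm}, \code{y_nm} (lab frame
#'   projection) and \code{z_nm} (height above the coverslip).
#' @export
membrane_position <- function(cell, axial_nm, theta) {
  r <- cell$width_nm / 2
  half_cyl <- (cell$length_nm - cell$width_nm) / 2
  n <- max(length(axial_nm), length(theta))
  axial_nm <- rep_len(axial_nm, n); theta <- rep_len(theta, n)
  if (any(abs(axial_nm) > half_cyl + r + 1e-9))
    stop("anchor axial coordinate outside the cell surface")
  s <- pmax(abs(axial_nm) - half_cyl, 0)          # overhang onto a cap
  rho <- sqrt(pmax(r^2 - s^2, 0))                 # cross-section radius
  z <- r - rho * cos(theta)
  lat <- rho * sin(theta)                         # in-plane offset, perp to axis
  u <- c(cos(cell$orientation), sin(cell$orientation))
  nvec <- c(-u[2], u[1])
  cbind(x_nm = cell$center[1] + u[1] * axial_nm + nvec[1] * lat,
        y_nm = cell$center[2] + u[2] * axial_nm + nvec[2] * lat,
        z_nm = z)
}

#' Advance circumferential emitters to time t
#'
#' Pure rotation about the long axis: \eqn{\theta(t) = \theta_0 + v t / r}
#' with the axial coordinate unchanged, emulating processive circumferential
#' motion of wall-synthesis complexes.
#'
#' @param cells A \code{cell_population}.
#' @param t Time in seconds (>= 0).
#' @return The population with each focus's \code{theta0} advanced;
#'   filaments are unchanged.
#' @export
advance_emitters <- function(cells, t) {
  if (t < 0) stop("t must be >= 0")
  for (i in seq_along(cells)) {
    em <- cells[[i]]$emitters
    if (nrow(em) > 0) {
      r <- cells[[i]]$width_nm / 2
      moving <- em$kind == "focus"
      em$theta0[moving] <- em$theta0[moving] + em$speed_nm_s[moving] * t / r
      cells[[i]]$emitters <- em
    }
  }
  cells
}

# emitter angles at time t for one cell (foci rotate, filaments do not)
.emitter_theta_at <- function(cell, t) {
  em <- cell$emitters
  r <- cell$width_nm / 2
  ifelse(em$kind == "focus", em$theta0 + em$speed_nm_s * t / r, em$theta0)
}

.depth_attenuation <- function(z, config, mode) {
  if (mode == "tirf") exp(-z / config$tirf_depth)
  else as.numeric(z <= config$widefield_depth)
}

# add a pixel-integrated Gaussian of total flux `flux` at (x, y) nm
.add_gaussian <- function(img, x, y, flux, sigma, p) {
  nr <- nrow(img); nc <- ncol(img)
  j0 <- max(1L, floor((x - 6 * sigma) / p)); j1 <- min(nc, ceiling((x + 6 * sigma) / p))
  i0 <- max(1L, floor((y - 6 * sigma) / p)); i1 <- min(nr, ceiling((y + 6 * sigma) / p))
  if (j0 > j1 || i0 > i1) return(img)
  cx <- diff(stats::pnorm(((j0 - 1L):j1) * p, mean = x, sd = sigma))
  ry <- diff(stats::pnorm(((i0 - 1L):i1) * p, mean = y, sd = sigma))
  img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + flux * (ry %o% cx)
  img
}

#' Render one noise-free frame
#'
#' Each visible emitter contributes a pixel-integrated isotropic Gaussian of
#' sd \code{psf_sigma} at its projected position. In TIRF mode the amplitude
#' is attenuated by \eqn{e^{-z/d}} with the configured evanescent depth; in
#' widefield mode emitters contribute fully while \eqn{z \le} the widefield
#' depth. Filaments are rendered as dense lines of point sources (spacing
#' \code{pixel_size}/4 along the membrane arc) sharing the emitter's flux.
#' A constant \code{background_level} is added everywhere.
#'
#' @param cells A \code{cell_population}.
#' @param t Time, seconds.
#' @param config An \code{\link{imaging_config}}.
#' @param mode \code{"tirf"} or \code{"widefield"}.
#' @param field_nm Optional c(x, y) field extent override, nm.
#' @return Matrix of expected photon counts (rows = y, columns = x).
#' @export
render_frame <- function(cells, t, config, mode = c("tirf", "widefield"),
                         field_nm = NULL) {
  mode <- match.arg(mode)
  if (is.null(field_nm)) field_nm <- attr(cells, "field_nm")
  p <- config$pixel_size
  nc <- ceiling(field_nm[1] / p); nr <- ceiling(field_nm[2] / p)
  img <- matrix(0, nr, nc)
  for (cell in cells) {
    em <- cell$emitters
    if (nrow(em) == 0) next
    theta <- .emitter_theta_at(cell, t)
    for (k in seq_len(nrow(em))) {
      flux <- config$photon_rate * em$intensity_scale[k]
      if (em$kind[k] == "focus") {
        pos <- membrane_position(cell, em$axial_nm[k], theta[k])
        amp <- flux * .depth_attenuation(pos[, "z_nm"], config, mode)
        if (amp > 0)
          img <- .add_gaussian(img, pos[, "x_nm"], pos[, "y_nm"], amp,
                               config$psf_sigma, p)
      } else {
        r <- cell$width_nm / 2
        arc <- em$length_nm[k]
        npts <- max(2L, ceiling(arc / (p / 4)))
        sarc <- -arc / 2 + (seq_len(npts) - 0.5) * arc / npts
        pos <- membrane_position(cell, rep(em$axial_nm[k], npts),
                                 theta[k] + sarc / r)
        amps <- (flux / npts) * .depth_attenuation(pos[, "z_nm"], config, mode)
        for (q in which(amps > 0))
          img <- .add_gaussian(img, pos[q, "x_nm"], pos[q, "y_nm"], amps[q],
                               config$psf_sigma, p)
      }
    }
  }
  img + config$background_level
}

#' Apply shot and read noise to a frame
#'
#' Per-pixel Poisson draw with the noise-free frame as mean, plus Gaussian
#' read noise, rounded to whole camera counts and clipped at zero. Integer
#' counts make written movies round-trip through 32-bit TIFF exactly.
#'
#' @param frame Non-negative matrix of expected photon counts.
#' @param config An \code{\link{imaging_config}} (uses
#'   \code{read_noise_sd}).
#' @param seed Integer seed; defaults to the config seed. Identical
#'   seed and frame give bit-identical output.
#' @return Noisy frame, same shape.
#' @export
apply_noise <- function(frame, config, seed = config$seed) {
  if (any(frame < 0)) stop("frame must be non-negative")
  with_seed(seed, {
    noisy <- stats::rpois(length(frame), lambda = as.vector(frame))
    if (config$read_noise_sd > 0)
      noisy <- round(noisy + stats::rnorm(length(frame), 0, config$read_noise_sd))
    matrix(pmax(noisy, 0), nrow(frame), ncol(frame))
  })
}

#' Ground-truth table for a population
#'
#' One row per (emitter, frame) with true projected position, depth,
#' TIRF-visibility flag (depth within the TIRF cutoff), speed and filament
#' length.
#'
#' @param cells A \code{cell_population}.
#' @param config An \code{\link{imaging_config}}.
#' @return Data frame with columns \code{emitter_id}, \code{cell_id},
#'   \code{frame}, \code{t_s}, \code{x_nm}, \code{y_nm}, \code{z_nm},
#'   \code{tirf_visible}, \code{speed_nm_s}, \code{length_nm}.
#' @export
ground_truth <- function(cells, config) {
  rows <- list()
  for (cell in cells) {
    em <- cell$emitters
    if (nrow(em) == 0) next
    for (f in seq_len(config$n_frames)) {
      t <- (f - 1L) * config$frame_interval
      theta <- .emitter_theta_at(cell, t)
      pos <- membrane_position(cell, em$axial_nm, theta)
      rows[[length(rows) + 1L]] <- data.frame(
        emitter_id = em$emitter_id, cell_id = cell$cell_id,
        frame = f, t_s = t,
        x_nm = pos[, "x_nm"], y_nm = pos[, "y_nm"], z_nm = pos[, "z_nm"],
        tirf_visible = pos[, "z_nm"] <= config$tirf_depth,
        speed_nm_s = em$speed_nm_s, length_nm = em$length_nm)
    }
  }
  if (length(rows) == 0)
    return(data.frame(emitter_id = integer(0), cell_id = integer(0),
                      frame = integer(0), t_s = numeric(0), x_nm = numeric(0),
                      y_nm = numeric(0), z_nm = numeric(0),
                      tirf_visible = logical(0), speed_nm_s = numeric(0),
                      length_nm = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$emitter_id, out$frame), , drop = FALSE]
}

#' Simulate a full movie
#'
#' Renders all frames of a population under one illumination mode and
#' applies noise (unless \code{noise = FALSE}); frame-wise noise seeds are
#' derived deterministically from the config seed.
#'
#' @inheritParams render_frame
#' @param channel \code{"green"} or \code{"red"} (metadata only).
#' @param noise Apply shot/read noise?
#' @return A \code{movie_stack}: list with \code{frames} (list of
#'   matrices), \code{mode}, \code{channel}, \code{config}.
#' @export
simulate_movie <- function(cells, config, mode = c("tirf", "widefield"),
                           channel = "green", noise = TRUE) {
  mode <- match.arg(mode)
  frames <- vector("list", config$n_frames)
  for (f in seq_len(config$n_frames)) {
    t <- (f - 1L) * config$frame_interval
    fr <- render_frame(cells, t, config, mode)
    if (noise)
      fr <- apply_noise(fr, config,
                        seed = (config$seed %% 1000000L) + 7919L * f)
    frames[[f]] <- fr
  }
  structure(list(frames = frames, mode = mode, channel = channel,
                 config = config), class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  cat(sprintf("movie_stack: %d frame(s) of %d x %d px, mode=%s, channel=%s\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$mode, x$channel))
  invisible(x)
}

#' Binary footprint mask of a cell
#'
#' Marks pixels whose centres lie within the spherocylinder's 2-D footprint
#' (distance to the axis segment no greater than the cell radius).
#'
#' @param cell One cell specification.
#' @param config An \code{\link{imaging_config}}.
#' @param field_nm Field extent c(x, y) in nm.
#' @return Logical matrix.
#' @export
cell_footprint_mask <- function(cell, config, field_nm) {
  p <- config$pixel_size
  nc <- ceiling(field_nm[1] / p); nr <- ceiling(field_nm[2] / p)
  xc <- (seq_len(nc) - 0.5) * p
  yc <- (seq_len(nr) - 0.5) * p
  u <- c(cos(cell$orientation), sin(cell$orientation))
  half_cyl <- (cell$length_nm - cell$width_nm) / 2
  X <- matrix(xc, nr, nc, byrow = TRUE) - cell$center[1]
  Y <- matrix(yc, nr, nc) - cell$center[2]
  along <- X * u[1] + Y * u[2]
  along_cl <- pmin(pmax(along, -half_cyl), half_cyl)
  dx <- X - along_cl * u[1]
  dy <- Y - along_cl * u[2]
  matrix(sqrt(dx^2 + dy^2) <= cell$width_nm / 2, nr, nc)
}

#' Write movie stacks and ground truth to disk
#'
#' Multi-frame 16-bit TIFF per movie plus the ground-truth table as CSV.
#' Pixel values are stored as integer camera counts (0..65535), the form
#' \code{\link{apply_noise}} produces, so noisy movies round-trip exactly;
#' writing a noise-free movie quantises it to whole counts.
#'
#' @param movies Named list of \code{movie_stack} objects.
#' @param truth Ground-truth data frame (may have zero rows).
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of files written.
#' @export
write_outputs <- function(movies, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(movies)) {
    path <- file.path(dir, paste0(nm, ".tif"))
    write_movie(movies[[nm]], path)
    files[nm] <- path
  }
  tp <- file.path(dir, "ground_truth.csv")
  utils::write.csv(truth, tp, row.names = FALSE)
  files["ground_truth"] <- tp
  invisible(files)
}

#' @rdname write_outputs
#' @param movie A \code{movie_stack}.
#' @param path TIFF file path.
#' @export
write_movie <- function(movie, path) {
  scaled <- lapply(movie$frames, function(m) round(m) / 65535)
  if (any(vapply(scaled, function(m) any(m < 0 | m > 1), logical(1))))
    stop("pixel values outside the storable 16-bit range at ", path)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' Read a multi-frame TIFF written by \code{write_movie}
#'
#' @param path TIFF file path.
#' @return List of frame matrices in integer photon counts.
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  lapply(frames, function(m) round(m * 65535))
}
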
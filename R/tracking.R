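#' @name particle-tracking
#' @title Spot detection, trajectory linking, survival filtering and velocity
#'
#' @description
#' Per-frame detection of diffraction-limited foci (Gaussian matched filter,
#' SNR cut, sub-pixel centroid refinement), greedy mutual-nearest-neighbour
#' frame-to-frame linking with a distance gate and no gap closing, the
#' survival filter keeping tracks with at least 5 consecutive frames and at
#' least 70 nm net displacement, principal-axis velocity estimation,
#' kymograph construction and track density per cell area.
NULL

# separable Gaussian smoothing, replicate-padded borders
.gauss_smooth <- function(img, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px); k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  m <- img[pad_idx(nrow(img)), pad_idx(ncol(img))]
  # rows pass
  out <- matrix(0, nrow(m), ncol(img))
  for (q in seq_along(k)) out <- out + k[q] * m[, q:(q + ncol(img) - 1L)]
  out2 <- matrix(0, nrow(img), ncol(img))
  for (q in seq_along(k)) out2 <- out2 + k[q] * out[q:(q + nrow(img) - 1L), ]
  out2
}

#' Detect fluorescent foci in one frame
#'
#' Matched-filter detection: the frame is smoothed with a Gaussian of the
#' PSF sd, local maxima are found, and each candidate's amplitude is
#' estimated from the smoothed peak (corrected for the factor-of-two
#' smoothing loss). Candidates with amplitude below \code{snr_min} times the
#' robust frame noise are rejected; survivors are refined to sub-pixel
#' position by an intensity-weighted centroid and deduplicated within one
#' PSF sd.
#'
#' The default \code{snr_min = 6} keeps the false-positive rate on empty
#' frames negligible while detecting foci through most of the TIRF-lit
#' band. For velocity analysis a stricter cut is preferable (see
#' \code{\link{run_tracking_sim}}): circumferential motion is increasingly
#' foreshortened in projection as a focus climbs the membrane, so
#' restricting detection to brighter (lower) foci bounds that bias.
#'
#' @param frame 2-D intensity array.
#' @param config An \code{\link{imaging_config}} (uses pixel size and PSF
#'   sd).
#' @param snr_min Amplitude threshold in units of robust frame noise.
#' @return Data frame with \code{x_nm}, \code{y_nm}, \code{amplitude},
#'   \code{sigma_nm}; zero rows when nothing is found.
#' @export
detect_spots <- function(frame, config, snr_min = 6) {
  p <- config$pixel_size
  sigma_px <- config$psf_sigma / p
  sm <- .gauss_smooth(frame, sigma_px)
  bg <- stats::median(sm)
  noise <- stats::mad(frame)
  if (noise == 0) noise <- sqrt(max(stats::median(frame), 1))
  nr <- nrow(sm); nc <- ncol(sm)
  if (nr < 3 || nc < 3)
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      amplitude = numeric(0), sigma_nm = numeric(0)))
  ctr <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr > sm[1:(nr - 2), 2:(nc - 1)] & ctr >= sm[3:nr, 2:(nc - 1)] &
            ctr > sm[2:(nr - 1), 1:(nc - 2)] & ctr >= sm[2:(nr - 1), 3:nc] &
            ctr > sm[1:(nr - 2), 1:(nc - 2)] & ctr >= sm[3:nr, 3:nc] &
            ctr > sm[1:(nr - 2), 3:nc] & ctr >= sm[3:nr, 1:(nc - 2)]
  amp <- 2 * (ctr - bg)
  keep <- which(is_max & amp >= snr_min * noise, arr.ind = TRUE)
  if (nrow(keep) == 0)
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      amplitude = numeric(0), sigma_nm = numeric(0)))
  rows <- keep[, 1] + 1L; cols <- keep[, 2] + 1L
  w <- ceiling(2 * sigma_px)
  bg_raw <- stats::median(frame)
  res <- lapply(seq_along(rows), function(q) {
    i0 <- max(1L, rows[q] - w); i1 <- min(nr, rows[q] + w)
    j0 <- max(1L, cols[q] - w); j1 <- min(nc, cols[q] + w)
    win <- pmax(frame[i0:i1, j0:j1] - bg_raw, 0)
    s <- sum(win)
    if (s == 0) return(NULL)
    ii <- (i0:i1) - 0.5; jj <- (j0:j1) - 0.5
    cy <- sum(rowSums(win) * ii) / s
    cx <- sum(colSums(win) * jj) / s
    c(cx * p, cy * p, amp[keep[q, 1], keep[q, 2]])
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res))
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      amplitude = numeric(0), sigma_nm = numeric(0)))
  out <- data.frame(x_nm = res[, 1], y_nm = res[, 2], amplitude = res[, 3],
                    sigma_nm = config$psf_sigma)
  .merge_close_spots(out, config$psf_sigma)
}

# keep the brighter of any pair closer than one PSF sd
.merge_close_spots <- function(spots, min_sep) {
  if (nrow(spots) < 2) return(spots)
  ord <- order(-spots$amplitude)
  spots <- spots[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(spots))
  for (i in seq_len(nrow(spots) - 1)) {
    if (!keep[i]) next
    d <- sqrt((spots$x_nm[-(1:i)] - spots$x_nm[i])^2 +
              (spots$y_nm[-(1:i)] - spots$y_nm[i])^2)
    keep[which(d < min_sep) + i] <- FALSE
  }
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect foci in every frame of a movie
#'
#' @param movie A \code{movie_stack}.
#' @inheritParams detect_spots
#' @return Data frame of detections with a \code{frame} column.
#' @export
detect_movie <- function(movie, snr_min = 6) {
  out <- lapply(seq_along(movie$frames), function(f) {
    d <- detect_spots(movie$frames[[f]], movie$config, snr_min = snr_min)
    if (nrow(d) > 0) d$frame <- f
    d
  })
  out <- do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
  if (is.null(out))
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      amplitude = numeric(0), sigma_nm = numeric(0),
                      frame = integer(0)))
  rownames(out) <- NULL
  out
}

#' Track filter configuration
#'
#' Defaults implement the published survival rule: keep only trajectories
#' with at least 5 consecutive frames and at least 70 nm net displacement.
#' The linking gate defaults to 250 nm, about ten times the per-frame motion
#' at 1 s intervals and well below typical inter-emitter spacing.
#'
#' @param min_frames Minimum consecutive frames.
#' @param min_displacement Minimum net (first-to-last) displacement, nm.
#' @param max_link_distance Frame-to-frame linking gate, nm.
#' @return List of class \code{track_filter_config}.
#' @export
track_filter_config <- function(min_frames = 5L, min_displacement = 70,
                                max_link_distance = 250) {
  stopifnot(min_frames > 0, min_displacement > 0, max_link_distance > 0)
  structure(list(min_frames = as.integer(min_frames),
                 min_displacement = min_displacement,
                 max_link_distance = max_link_distance),
            class = "track_filter_config")
}

#' Link per-frame detections into trajectories
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames:
#' the globally closest unassigned pair within the distance gate is linked
#' first, then the next, and so on. Unmatched detections start new tracks;
#' there is no gap closing, so every track spans strictly consecutive
#' frames, and every detection belongs to exactly one track.
#'
#' @param detections Data frame with \code{frame}, \code{x_nm},
#'   \code{y_nm} (and any extra columns, carried through).
#' @param config A \code{\link{track_filter_config}} (uses
#'   \code{max_link_distance}).
#' @return The detections with a \code{track_id} column, ordered by track
#'   then frame.
#' @export
link_tracks <- function(detections, config = track_filter_config()) {
  if (nrow(detections) == 0) {
    detections$track_id <- integer(0)
    return(detections)
  }
  detections <- detections[order(detections$frame), , drop = FALSE]
  detections$track_id <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(detections$frame))
  idx_prev <- which(detections$frame == frames[1])
  prev_frame <- frames[1]
  detections$track_id[idx_prev] <- seq.int(next_id, length.out = length(idx_prev))
  next_id <- next_id + length(idx_prev)
  for (f in frames[-1]) {
    idx_cur <- which(detections$frame == f)
    prev_open <- if (f - prev_frame == 1) idx_prev else integer(0)
    if (length(prev_open) > 0 && length(idx_cur) > 0) {
      d <- outer(seq_along(prev_open), seq_along(idx_cur), function(a, b) {
        sqrt((detections$x_nm[prev_open[a]] - detections$x_nm[idx_cur[b]])^2 +
             (detections$y_nm[prev_open[a]] - detections$y_nm[idx_cur[b]])^2)
      })
      d[d > config$max_link_distance] <- Inf
      while (any(is.finite(d))) {
        best <- arrayInd(which.min(d), dim(d))
        a <- best[1]; b <- best[2]
        detections$track_id[idx_cur[b]] <- detections$track_id[prev_open[a]]
        d[a, ] <- Inf; d[, b] <- Inf
      }
    }
    new <- idx_cur[is.na(detections$track_id[idx_cur])]
    if (length(new) > 0) {
      detections$track_id[new] <- seq.int(next_id, length.out = length(new))
      next_id <- next_id + length(new)
    }
    idx_prev <- idx_cur
    prev_frame <- f
  }
  detections[order(detections$track_id, detections$frame), , drop = FALSE]
}

#' Per-track summaries
#'
#' @param tracks Linked detections (with \code{track_id}).
#' @param frame_interval Frame interval, s.
#' @param velocity_method \code{"fit"} (principal-axis least-squares slope)
#'   or \code{"mean_step"} (mean step length per interval).
#' @return Data frame with \code{track_id}, \code{n_frames},
#'   \code{displacement_nm} (net, first to last), \code{path_length_nm} and
#'   \code{velocity_nm_s}.
#' @export
track_summaries <- function(tracks, frame_interval = 1,
                            velocity_method = "fit") {
  ids <- unique(tracks$track_id)
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    n <- nrow(tr)
    disp <- sqrt((tr$x_nm[n] - tr$x_nm[1])^2 + (tr$y_nm[n] - tr$y_nm[1])^2)
    path <- if (n > 1) sum(sqrt(diff(tr$x_nm)^2 + diff(tr$y_nm)^2)) else 0
    vel <- if (n > 1) track_velocity(tr, frame_interval, velocity_method)
           else NA_real_
    data.frame(track_id = id, n_frames = n, displacement_nm = disp,
               path_length_nm = path, velocity_nm_s = vel)
  })
  do.call(rbind, out)
}

#' Apply the track survival filter
#'
#' Keeps exactly the tracks with at least \code{min_frames} consecutive
#' frames AND net displacement at least \code{min_displacement} (discard if
#' either fails). The literal both-fail reading (discard only tracks failing
#' both) is available via \code{rule = "literal"}.
#'
#' @param tracks Linked detections (with \code{track_id}).
#' @param config A \code{\link{track_filter_config}}.
#' @param rule \code{"keep_both"} (default) or \code{"literal"}.
#' @param frame_interval Frame interval, s (for the attached summaries).
#' @return Surviving detections; per-track summaries with \code{kept} and
#'   \code{discard_reason} are attached as \code{attr(, "track_summary")}
#'   and discard counts by reason as \code{attr(, "discarded")}.
#' @export
filter_tracks <- function(tracks, config = track_filter_config(),
                          rule = c("keep_both", "literal"),
                          frame_interval = 1) {
  rule <- match.arg(rule)
  if (nrow(tracks) == 0) return(tracks)
  ts <- track_summaries(tracks, frame_interval)
  long_enough <- ts$n_frames >= config$min_frames
  far_enough <- ts$displacement_nm >= config$min_displacement
  ts$kept <- if (rule == "keep_both") long_enough & far_enough
             else long_enough | far_enough
  ts$discard_reason <- ifelse(ts$kept, "",
    ifelse(!long_enough & !far_enough, "short_and_static",
           ifelse(!long_enough, "too_few_frames", "too_little_displacement")))
  kept_ids <- ts$track_id[ts$kept]
  out <- tracks[tracks$track_id %in% kept_ids, , drop = FALSE]
  attr(out, "track_summary") <- ts
  attr(out, "discarded") <- table(ts$discard_reason[!ts$kept])
  out
}

#' Per-track velocity
#'
#' Positions are projected onto the track's principal displacement axis and
#' the velocity is the absolute least-squares slope of projected position
#' versus time (robust to localisation noise, which inflates step-based
#' estimates). \code{method = "mean_step"} gives the mean step length per
#' frame interval instead.
#'
#' @param track Data frame of one track with \code{frame}, \code{x_nm},
#'   \code{y_nm}, at least two rows.
#' @param frame_interval Frame interval, s.
#' @param method \code{"fit"} or \code{"mean_step"}.
#' @return Velocity in nm/s (non-negative).
#' @export
track_velocity <- function(track, frame_interval = 1,
                           method = c("fit", "mean_step")) {
  method <- match.arg(method)
  n <- nrow(track)
  if (n < 2) stop("track needs at least 2 points")
  if (method == "mean_step") {
    steps <- sqrt(diff(track$x_nm)^2 + diff(track$y_nm)^2)
    return(mean(steps / (diff(track$frame) * frame_interval)))
  }
  xy <- cbind(track$x_nm - mean(track$x_nm), track$y_nm - mean(track$y_nm))
  if (all(abs(xy) < 1e-12)) return(0)
  axis <- svd(xy, nu = 0, nv = 1)$v[, 1]
  proj <- xy %*% axis
  t_s <- track$frame * frame_interval
  abs(sum((t_s - mean(t_s)) * proj) / sum((t_s - mean(t_s))^2))
}

#' Track density per cell area
#'
#' Number of surviving tracks divided by the cell's projected (footprint)
#' area, the normalisation used to compare strains with different cell
#' shapes.
#'
#' @param tracks Surviving linked detections (with \code{track_id}), or an
#'   integer track count.
#' @param cell A \code{\link{spherocylinder}}, a polygon outline (passed to
#'   \code{\link{area_from_outline}}), or a numeric area in um^2.
#' @param pixel_size Outline unit in nm when \code{cell} is a polygon.
#' @return Tracks per square micrometre.
#' @export
tracks_per_area <- function(tracks, cell, pixel_size = 1000) {
  n <- if (is.data.frame(tracks)) length(unique(tracks$track_id))
       else as.numeric(tracks)
  area <- if (inherits(cell, "spherocylinder")) projected_area(cell)
          else if (is.matrix(cell) || is.data.frame(cell))
            area_from_outline(cell, pixel_size)
          else as.numeric(cell)
  if (!is.finite(area) || area <= 0) stop("cell area must be positive")
  n / area
}

#' Build a kymograph along a track
#'
#' Intensity is sampled in every frame along the track's principal axis
#' (centred on the track centroid, extended slightly beyond the track span)
#' and summed over \code{line_width} pixels perpendicular to the line. The
#' result is a space-by-time array in which a moving focus appears as a
#' sloped ridge.
#'
#' @param movie A \code{movie_stack}.
#' @param track Data frame of one track (\code{frame}, \code{x_nm},
#'   \code{y_nm}).
#' @param line_width Width of the summed band, pixels.
#' @param margin_px Extra length beyond the track span at each end, pixels.
#' @return Object of class \code{kymograph}: list with \code{data}
#'   (space x time matrix), \code{pixel_size}, \code{frame_interval},
#'   \code{frames}.
#' @export
build_kymograph <- function(movie, track, line_width = 3L, margin_px = 6L) {
  p <- movie$config$pixel_size
  xy <- cbind(track$x_nm, track$y_nm)
  ctr <- colMeans(xy)
  dev <- sweep(xy, 2, ctr)
  axis <- if (nrow(xy) > 1 && any(abs(dev) > 1e-12))
    svd(dev, nu = 0, nv = 1)$v[, 1] else c(1, 0)
  span <- if (nrow(xy) > 1) diff(range(dev %*% axis)) else 0
  half <- span / 2 + margin_px * p
  s_nm <- seq(-half, half, by = p)
  perp <- c(-axis[2], axis[1])
  offs <- (seq_len(line_width) - (line_width + 1) / 2) * p
  frames <- sort(unique(track$frame))
  nr0 <- nrow(movie$frames[[1]]); nc0 <- ncol(movie$frames[[1]])
  kymo <- matrix(0, length(s_nm), length(frames))
  for (q in seq_along(frames)) {
    fr <- movie$frames[[frames[q]]]
    acc <- numeric(length(s_nm))
    for (o in offs) {
      xs <- (ctr[1] + s_nm * axis[1] + o * perp[1]) / p
      ys <- (ctr[2] + s_nm * axis[2] + o * perp[2]) / p
      if (any(xs < 0 | xs > nc0 | ys < 0 | ys > nr0))
        stop("kymograph line extends outside the image")
      acc <- acc + as.vector(.bilinear_sample(fr, xs, ys))
    }
    kymo[, q] <- acc
  }
  structure(list(data = kymo, pixel_size = p,
                 frame_interval = movie$config$frame_interval,
                 frames = frames), class = "kymograph")
}

#' Speed from a kymograph ridge
#'
#' Finds the per-frame peak position along the space axis (with sub-pixel
#' quadratic refinement) and fits a robust least-absolute-deviations line
#' through peak position versus time; the absolute slope is the speed.
#'
#' @param kymo A \code{\link{build_kymograph}} result.
#' @return Speed in nm/s.
#' @export
kymograph_slope <- function(kymo) {
  m <- kymo$data
  # background from the outermost space rows: the ridge, even a vertical
  # one, sits near the track centroid in the middle of the space axis
  outer_rows <- unique(c(1L, 2L, nrow(m) - 1L, nrow(m)))
  bg <- stats::median(m[outer_rows, ])
  noise <- max(stats::mad(m[outer_rows, ]), 1e-8)
  peaks <- apply(m, 2, function(col) {
    i <- which.max(col)
    if (col[i] < bg + 3 * noise) return(NA_real_)
    if (i > 1 && i < length(col)) {
      denom <- col[i - 1] - 2 * col[i] + col[i + 1]
      if (denom < 0) return(i + 0.5 * (col[i - 1] - col[i + 1]) / denom)
    }
    as.numeric(i)
  })
  ok <- !is.na(peaks)
  if (sum(ok) < 2) stop("no ridge above background in kymograph")
  t_s <- kymo$frames[ok] * kymo$frame_interval
  s_nm <- peaks[ok] * kymo$pixel_size
  fit0 <- stats::coef(stats::lm(s_nm ~ t_s))
  l1 <- function(par) sum(abs(s_nm - par[1] - par[2] * t_s))
  fit <- stats::optim(fit0, l1, method = "Nelder-Mead")$par
  unname(abs(fit[2]))
}
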
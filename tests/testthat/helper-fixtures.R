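# shared fixtures built in code

# single cell with fixed dimensions and explicit emitters; orientation 0
fixed_cell_population <- function(length_um = 3.5, width_um = 1.0,
                                  emitters = NULL, margin = 650) {
  pop <- generate_population(1, length_dist = c(mean = length_um, sd = 0),
                             width_dist = c(mean = width_um, sd = 0),
                             emitter_density = 0, orientation = 0,
                             margin = margin, seed = 1L)
  if (!is.null(emitters)) pop[[1]]$emitters <- emitters
  pop
}

focus_emitters <- function(axial_nm, theta0, speed_nm_s,
                           intensity_scale = 1) {
  n <- max(length(axial_nm), length(theta0), length(speed_nm_s))
  data.frame(emitter_id = seq_len(n), kind = "focus",
             axial_nm = rep_len(axial_nm, n), theta0 = rep_len(theta0, n),
             speed_nm_s = rep_len(speed_nm_s, n), length_nm = 0,
             intensity_scale = rep_len(intensity_scale, n))
}

# independent numeric oracle: triangulated surface quadrature of the
# spherocylinder membrane area with height z <= depth (depth = Inf gives the
# total area); patch centres decide inclusion
spherocylinder_area_quadrature <- function(L, W, depth = Inf,
                                           n_theta = 2000, n_ax = 400) {
  r <- W / 2
  # cylinder flank: z = r (1 - cos theta)
  th <- (seq_len(n_theta) - 0.5) / n_theta * 2 * pi
  dth <- 2 * pi / n_theta
  flank <- sum((r * (1 - cos(th)) <= depth)) * dth * r * (L - 2 * r)
  # two caps: sphere of radius r; z = r (1 - cos(polar)) with polar from the
  # downward vertical; area element r^2 sin(polar) dpolar dazimuth
  pol <- (seq_len(n_ax) - 0.5) / n_ax * pi
  dpol <- pi / n_ax
  ring <- 2 * pi * r^2 * sin(pol) * dpol          # full sphere rings
  caps <- sum(ring[r * (1 - cos(pol)) <= depth])  # both caps = one sphere
  flank + caps
}

# brute-force survival predicates applied straight to raw track tables
brute_force_survivors <- function(tracks, min_frames = 5,
                                  min_displacement = 70) {
  ids <- unique(tracks$track_id)
  keep <- vapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$frame), ]
    n <- nrow(tr)
    disp <- sqrt((tr$x_nm[n] - tr$x_nm[1])^2 + (tr$y_nm[n] - tr$y_nm[1])^2)
    (n >= min_frames) && (disp >= min_displacement)
  }, logical(1))
  sort(ids[keep])
}

# fixture of 20 constructed tracks covering all four (frames >=/< 5) x
# (displacement >=/< 70 nm) cells
make_track_fixture <- function() {
  specs <- expand.grid(n = c(3, 4, 6, 10, 20), far = c(TRUE, FALSE))
  rows <- list()
  for (k in seq_len(nrow(specs))) {
    for (rep in 1:2) {
      id <- (k - 1L) * 2L + rep
      n <- specs$n[k]
      disp <- if (specs$far[k]) 100 + 10 * rep else 30 + 5 * rep
      step <- disp / (n - 1)
      rows[[id]] <- data.frame(track_id = id, frame = seq_len(n),
                               x_nm = 1000 + step * (seq_len(n) - 1),
                               y_nm = 1000 + 0 * seq_len(n))
    }
  }
  do.call(rbind, rows)
}

# exhaustive-enumeration Mann-Whitney oracle (independent of the package's
# wilcox.test-based path): two-sided p over all C(n1+n2, n1) assignments
mwu_enumeration_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}
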
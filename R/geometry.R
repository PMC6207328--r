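#' Spherocylinder cell model
#'
#' Constructs the geometric model of a rod-shaped bacterium: a cylinder of
#' diameter \code{width} capped by two hemispheres, with total tip-to-tip
#' length \code{length}, resting on the coverslip.
#'
#' @param length Tip-to-tip cell length in micrometres.
#' @param width Cell diameter in micrometres.
#' @return An object of class \code{spherocylinder}.
#' @examples
#' cell <- spherocylinder(3, 1)
#' total_surface_area(cell)
#' @export
spherocylinder <- function(length, width) {
  stopifnot(is.numeric(length), is.numeric(width),
            length(length) == 1L, length(width) == 1L)
  if (!is.finite(length) || !is.finite(width) || width <= 0)
    stop("width must be finite and > 0")
  if (length < width)
    stop("length must be >= width (tip-to-tip length includes both caps)")
  structure(list(length = length, width = width), class = "spherocylinder")
}

#' @export
print.spherocylinder <- function(x, ...) {
  cat(sprintf("spherocylinder: L = %.3f um, W = %.3f um\n", x$length, x$width))
  invisible(x)
}

#' TIRF illumination model
#'
#' A hard horizontal cutoff at height \code{depth} above the coverslip:
#' membrane below the cutoff counts as illuminated.
#'
#' @param depth Evanescent-field cutoff height in micrometres
#'   (0.2 for a typical TIRF depth of 200 nm).
#' @return An object of class \code{illumination_model}.
#' @export
illumination_model <- function(depth = 0.2) {
  stopifnot(is.numeric(depth), length(depth) == 1L, is.finite(depth), depth > 0)
  structure(list(depth = depth), class = "illumination_model")
}

#' Total surface area of a spherocylinder
#'
#' Closed form: \eqn{2\pi r (L - 2r) + 4 \pi r^2} with \eqn{r = W/2}.
#'
#' @param cell A \code{\link{spherocylinder}}.
#' @return Area in square micrometres.
#' @export
total_surface_area <- function(cell) {
  stopifnot(inherits(cell, "spherocylinder"))
  r <- cell$width / 2
  2 * pi * r * (cell$length - 2 * r) + 4 * pi * r^2
}

#' TIRF-illuminated surface area of a spherocylinder
#'
#' Area of the membrane lying within \code{depth} of the coverslip: a flank
#' band on the cylinder, \eqn{2 r \theta_{max} (L - 2r)} with
#' \eqn{\theta_{max} = \arccos(1 - d/r)}, plus the spherical zone
#' \eqn{2 \pi r d} contributed jointly by the two caps. Equals the total
#' surface area once \code{depth >= width}.
#'
#' @param cell A \code{\link{spherocylinder}}.
#' @param illum An \code{\link{illumination_model}}.
#' @return Illuminated area in square micrometres.
#' @export
illuminated_surface_area <- function(cell, illum) {
  stopifnot(inherits(cell, "spherocylinder"), inherits(illum, "illumination_model"))
  d <- illum$depth
  if (d >= cell$width) return(total_surface_area(cell))
  r <- cell$width / 2
  theta_max <- acos(1 - d / r)
  band <- 2 * r * theta_max * (cell$length - 2 * r)
  caps <- 2 * pi * r * d
  band + caps
}

#' Illuminated fraction of the cell surface
#'
#' @inheritParams illuminated_surface_area
#' @return Dimensionless fraction in (0, 1].
#' @export
illuminated_fraction <- function(cell, illum) {
  illuminated_surface_area(cell, illum) / total_surface_area(cell)
}

#' Projected (footprint) area of a spherocylinder
#'
#' The 2-D footprint seen in a segmented image: a rectangle plus a disc,
#' \eqn{W (L - W) + \pi (W/2)^2}. Used to normalise track counts per cell,
#' standing in for the segmented cell area.
#'
#' @param cell A \code{\link{spherocylinder}}.
#' @return Area in square micrometres.
#' @export
projected_area <- function(cell) {
  stopifnot(inherits(cell, "spherocylinder"))
  W <- cell$width
  W * (cell$length - W) + pi * (W / 2)^2
}

#' Polygon area from a cell outline
#'
#' Shoelace area of a simple closed polygon (an externally produced cell
#' outline), converted to square micrometres.
#'
#' @param polygon Two-column matrix or data frame of vertices (x, y). The
#'   polygon is closed implicitly; a repeated final vertex is tolerated.
#' @param pixel_size Size of one outline unit in nanometres; use 1000 if the
#'   outline is already in micrometres.
#' @return Area in square micrometres.
#' @export
area_from_outline <- function(polygon, pixel_size = 1000) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L) stop("polygon must have two columns (x, y)")
  if (nrow(polygon) >= 2L && all(polygon[1, ] == polygon[nrow(polygon), ]))
    polygon <- polygon[-nrow(polygon), , drop = FALSE]
  n <- nrow(polygon)
  if (n < 3L) stop("polygon needs at least 3 distinct vertices")
  if (.polygon_self_intersects(polygon))
    stop("polygon is self-intersecting")
  x <- polygon[, 1]; y <- polygon[, 2]
  j <- c(2:n, 1L)
  area_units <- abs(sum(x * y[j] - x[j] * y)) / 2
  area_units * (pixel_size / 1000)^2
}

# Segment-pair crossing test over non-adjacent edges; O(n^2), outlines are small.
.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1L), , drop = FALSE])
  ccw <- function(ax, ay, bx, by, cx, cy) (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- ccw(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- ccw(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- ccw(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- ccw(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Reference cell dimensions for the two strains
#'
#' Mean spherocylinder dimensions (micrometres) for wild-type and activated
#' PBP2(L61R) cells used in the illuminated-area worked example. The mutant
#' is thinner and longer than wild type; with a 200 nm illumination depth
#' these dimensions give illuminated areas of about 3.01 um^2 (WT) and
#' 3.38 um^2 (L61R).
#'
#' @return Named list of two \code{\link{spherocylinder}} objects,
#'   \code{wt} and \code{l61r}.
#' @export
reference_cell_dimensions <- function() {
  list(wt   = spherocylinder(3.57, 1.00),
       l61r = spherocylinder(4.09, 0.90))
}
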
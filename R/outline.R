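#' Closed cell outline in polar form
#'
#' An outline is the sub-pixel boundary of a single cell in one frame,
#' represented in polar coordinates around its centroid. The angular origin
#' (\code{theta = 0}) points from the centroid towards the animal pole and all
#' kymograph arc-length coordinates inherit this origin. Radii are stored in
#' pixels; \code{calibration} (micrometres per pixel) converts them to
#' physical units.
#'
#' @param theta numeric vector of angles in \code{[0, 2*pi)}, strictly
#'   increasing. Angle 0 is the animal-pole direction.
#' @param r positive radii (pixels), same length as \code{theta}.
#' @param centroid numeric length-2 \code{(x, y)} centroid in pixel
#'   coordinates.
#' @param calibration micrometres per pixel.
#' @param frame_index 1-based frame number the outline belongs to.
#' @return An object of class \code{scw_outline}.
#' @export
outline <- function(theta, r, centroid, calibration = 1, frame_index = 1L) {
  stopifnot(length(theta) == length(r), length(centroid) == 2)
  if (length(theta) < 64)
    stop("outline needs at least 64 samples, got ", length(theta))
  if (any(diff(theta) <= 0) || any(theta < 0) || any(theta >= 2 * pi))
    stop("theta must be strictly increasing within [0, 2*pi)")
  if (any(!is.finite(r)) || any(r <= 0))
    stop("outline radii must be positive and finite")
  if (!is.numeric(calibration) || calibration <= 0)
    stop("calibration (um/px) must be positive")
  structure(
    list(theta = as.numeric(theta), r = as.numeric(r),
         centroid = as.numeric(centroid),
         calibration = as.numeric(calibration),
         frame_index = as.integer(frame_index)),
    class = "scw_outline")
}

#' @method print scw_outline
#' @export
print.scw_outline <- function(x, ...) {
  cat(sprintf(
    "<scw_outline> frame %d: %d samples, mean radius %.2f px (%.2f um)\n",
    x$frame_index, length(x$theta), mean(x$r), mean(x$r) * x$calibration))
  invisible(x)
}

#' Cartesian coordinates of an outline
#'
#' @param o an \code{scw_outline}.
#' @param units \code{"px"} (absolute image coordinates) or \code{"um"}
#'   (centred physical coordinates).
#' @return two-column matrix of boundary points.
#' @export
outline_xy <- function(o, units = c("px", "um")) {
  units <- match.arg(units)
  x <- o$r * cos(o$theta)
  y <- o$r * sin(o$theta)
  if (units == "px")
    cbind(x = x + o$centroid[1], y = y + o$centroid[2])
  else
    cbind(x = x * o$calibration, y = y * o$calibration)
}

#' Perimeter of an outline (micrometres)
#' @param o an \code{scw_outline}.
#' @export
outline_perimeter <- function(o) {
  xy <- outline_xy(o, "um")
  d <- diff(rbind(xy, xy[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Enclosed area of an outline (square micrometres), by the shoelace formula
#' @param o an \code{scw_outline}.
#' @export
outline_area <- function(o) {
  xy <- outline_xy(o, "um")
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Resample arbitrary (theta, r) samples (unsorted, possibly uneven) onto a
# regular grid of n angles via periodic linear interpolation.
resample_polar <- function(theta, r, n = 360L) {
  o <- order(theta)
  th <- theta[o]; rr <- r[o]
  th <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  rr <- c(rr[length(rr)], rr, rr[1])
  grid <- 2 * pi * (seq_len(n) - 1L) / n
  stats::approx(th, rr, xout = grid, rule = 2, ties = mean)$y
}

# Angle wrapped to [0, 2*pi)
wrap_angle <- function(a) a %% (2 * pi)

# Arc distance from the vegetal pole on the reference circle of radius R:
# theta = 0 is the animal pole, so the vegetal pole sits at theta = pi and
# the angular separation from it is |theta - pi| (always <= pi).
arc_from_vegetal <- function(theta, R) R * abs(wrap_angle(theta) - pi)
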
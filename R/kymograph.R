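#' Kymograph container
#'
#' A kymograph is a rectangular matrix of a quantity sampled along the cell
#' perimeter (rows; arc length in micrometres, origin at the animal pole) over
#' time (columns; seconds).
#'
#' @param values numeric matrix, one row per arc position, one column per
#'   time point.
#' @param s arc-length coordinates of the rows (micrometres).
#' @param t time coordinates of the columns (seconds).
#' @param semantics what the values are, e.g. \code{"curvature-radius"},
#'   \code{"curvature"}, \code{"fluorescence"}.
#' @param meta optional named list of extra metadata (e.g. the radius cap).
#' @return An object of class \code{scw_kymograph}.
#' @export
kymograph <- function(values, s, t, semantics = "curvature-radius",
                      meta = list()) {
  values <- as.matrix(values)
  if (nrow(values) != length(s) || ncol(values) != length(t))
    stop("kymograph dimensions do not match axis lengths")
  if (is.unsorted(s, strictly = TRUE) || is.unsorted(t, strictly = FALSE))
    stop("kymograph axes must be monotone")
  structure(list(values = values, s = as.numeric(s), t = as.numeric(t),
                 semantics = semantics, meta = meta),
            class = "scw_kymograph")
}

#' @method print scw_kymograph
#' @export
print.scw_kymograph <- function(x, ...) {
  cat(sprintf("<scw_kymograph> [%s] %d arc positions x %d time points, s in [%.1f, %.1f] um, t in [%.0f, %.0f] s\n",
              x$semantics, nrow(x$values), ncol(x$values),
              min(x$s), max(x$s), min(x$t), max(x$t)))
  invisible(x)
}

#' Add Gaussian noise to a kymograph
#'
#' Shape-preserving additive noise, used to stress-test isoline and front
#' extraction on clean simulated kymographs.
#'
#' @param kymo an \code{scw_kymograph}.
#' @param sd standard deviation of the additive Gaussian noise (same units as
#'   the kymograph values); \code{sd = 0} returns the input unchanged.
#' @param seed integer seed; the same seed reproduces the same noise.
#' @return a new \code{scw_kymograph}.
#' @export
noisy_kymograph <- function(kymo, sd, seed = 1L) {
  stopifnot(inherits(kymo, "scw_kymograph"), sd >= 0)
  if (sd == 0) return(kymo)
  set.seed(as.integer(seed))
  kymo$values <- kymo$values + matrix(stats::rnorm(length(kymo$values), 0, sd),
                                      nrow(kymo$values))
  kymo
}

#' Render a kymograph to PNG
#'
#' Pseudo-colour map: values are clipped to the central 98 percent of their
#' range and mapped linearly onto the viridis-like palette of
#' \code{\link[grDevices]{hcl.colors}} (low = dark blue, high = yellow);
#' the x axis is time (s), the y axis arc length (um) from the animal pole.
#' @param kymo an \code{scw_kymograph}.
#' @param path output PNG file.
#' @export
plot_kymograph_png <- function(kymo, path) {
  q <- stats::quantile(kymo$values, c(0.01, 0.99), na.rm = TRUE)
  v <- pmin(pmax(kymo$values, q[1]), q[2])
  grDevices::png(path, width = 640, height = 480)
  graphics::image(kymo$t, kymo$s, t(v),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "time (s)", ylab = "arc from animal pole (um)",
                  main = kymo$semantics, useRaster = TRUE)
  grDevices::dev.off()
  invisible(path)
}

#' Write a kymograph to CSV
#'
#' The first column holds the arc coordinate, remaining columns one time point
#' each (header \code{t<seconds>}).
#' @param kymo an \code{scw_kymograph}.
#' @param path output file.
#' @export
write_kymograph_csv <- function(kymo, path) {
  df <- data.frame(s_um = kymo$s, kymo$values, check.names = FALSE)
  names(df)[-1] <- sprintf("t%g", kymo$t)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
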
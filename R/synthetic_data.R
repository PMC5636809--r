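#' Parameters for a synthetic contraction-band movie
#'
#' Describes a roughly circular cell of radius \code{cell_radius} whose
#' outline is flattened by a contraction band of width \code{band_width}
#' travelling from the vegetal to the animal pole at \code{band_speed}. The
#' band is a ring perpendicular to the animal--vegetal axis, so in the imaged
#' equatorial slice it appears as two mirror-image indentations symmetric
#' about the axis. The radial deformation follows a half-sine bump, the same
#' profile the mechanical model uses for its tension band, evaluated in the
#' band-frame coordinate \code{u = (arc - speed * (t - start_time)) /
#' band_width} where \code{arc} is arc length from the vegetal pole on the
#' undeformed circle.
#'
#' @param cell_radius cell radius (um).
#' @param band_width width of the contraction band (um); the wave the model
#'   targets uses 100 um.
#' @param band_speed band speed (um/min); waves of this kind travel at around
#'   42 um/min.
#' @param band_depth fractional radial flattening at the band centre, in
#'   \code{[0, 1)}. 0 disables the band.
#' @param start_time time (s) at which the band centre crosses the vegetal
#'   pole.
#' @param frame_interval time between frames (s).
#' @param n_frames number of frames.
#' @param pixel_size um per pixel.
#' @param image_size image side length (px); the cell must fit with at least
#'   a 10 percent margin.
#' @param noise_gaussian_sd additive Gaussian read-noise sd (intensity units,
#'   images are rendered on a 0--1 scale).
#' @param noise_poisson_scale photons per intensity unit for Poisson shot
#'   noise; 0 disables shot noise.
#' @param cortical_gain intensity enrichment factor of the cortical channel
#'   inside the band.
#' @param psf_sigma isotropic Gaussian point-spread blur sd (px).
#' @param av_axis_angle image-plane angle of the animal-pole direction
#'   (radians, 0 = +x).
#' @param seed integer seed controlling all noise.
#' @return a validated parameter list of class \code{scw_band_params}.
#' @export
band_movie_params <- function(cell_radius = 85, band_width = 100,
                              band_speed = 42, band_depth = 0.1,
                              start_time = 0, frame_interval = 10,
                              n_frames = 40, pixel_size = 0.4,
                              image_size = 512, noise_gaussian_sd = 0.02,
                              noise_poisson_scale = 200, cortical_gain = 2,
                              psf_sigma = 1, av_axis_angle = 0, seed = 1L) {
  p <- list(cell_radius = cell_radius, band_width = band_width,
            band_speed = band_speed, band_depth = band_depth,
            start_time = start_time, frame_interval = frame_interval,
            n_frames = as.integer(n_frames), pixel_size = pixel_size,
            image_size = as.integer(image_size),
            noise_gaussian_sd = noise_gaussian_sd,
            noise_poisson_scale = noise_poisson_scale,
            cortical_gain = cortical_gain, psf_sigma = psf_sigma,
            av_axis_angle = av_axis_angle, seed = as.integer(seed))
  if (p$cell_radius <= 0) stop("cell_radius must be positive")
  if (p$band_width <= 0) stop("band_width must be positive")
  if (p$band_depth < 0 || p$band_depth >= 1)
    stop("band_depth must be in [0, 1)")
  if (p$frame_interval <= 0) stop("frame_interval must be positive")
  if (p$n_frames < 1) stop("need at least one frame")
  if (p$noise_gaussian_sd < 0 || p$noise_poisson_scale < 0)
    stop("noise levels must be non-negative")
  # the whole cell (diameter 2R) must fit with >= 10% margin
  if (2 * p$cell_radius * 1.1 > p$image_size * p$pixel_size)
    stop(sprintf(
      "image too small for cell: need >= %.0f px at %.2f um/px, have %d",
      ceiling(2 * p$cell_radius * 1.1 / p$pixel_size), p$pixel_size,
      p$image_size))
  class(p) <- "scw_band_params"
  p
}

# Half-sine unit bump of the band-frame coordinate: 1 at the band centre,
# 0 outside [-1/2, 1/2] (u is already normalised by band_width).
band_bump <- function(u) ifelse(abs(u) <= 0.5, cos(pi * u), 0)

#' Ground-truth outline of the synthetic cell at time t
#'
#' Radial profile \code{r(theta) = R * (1 - band_depth * g(u))} with the
#' half-sine bump \code{g} evaluated at the arc distance from the vegetal pole
#' (measured on the undeformed circle of radius R) relative to the moving
#' band centre. The curve is C1-continuous and periodic, and applies the
#' deformation symmetrically on both sides of the animal--vegetal axis.
#'
#' @param params an \code{scw_band_params}.
#' @param t time (s), non-negative times are typical but any time is valid.
#' @param n number of equal-angle samples.
#' @return an \code{scw_outline} (radii in px, centred in the image).
#' @export
true_outline <- function(params, t, n = 360L) {
  stopifnot(inherits(params, "scw_band_params"))
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  r_um <- true_radius_um(params, theta, t)
  ctr <- (params$image_size + 1) / 2
  outline(theta, r_um / params$pixel_size, centroid = c(ctr, ctr),
          calibration = params$pixel_size,
          frame_index = as.integer(round(t / params$frame_interval)) + 1L)
}

# radius (um) at body-frame angles theta (0 = animal pole) and time t (s)
true_radius_um <- function(params, theta, t) {
  R <- params$cell_radius
  arc <- arc_from_vegetal(theta, R)
  centre <- params$band_speed / 60 * (t - params$start_time)
  u <- (arc - centre) / params$band_width
  R * (1 - params$band_depth * band_bump(u))
}

#' Band centre position (arc length from the vegetal pole, um) at time t
#' @param params an \code{scw_band_params}.
#' @param t time (s).
#' @export
true_band_center <- function(params, t) {
  params$band_speed / 60 * (t - params$start_time)
}

render_frame <- function(params, t) {
  n <- params$image_size
  ctr <- (n + 1) / 2
  px <- seq_len(n)
  # image convention: img[i, j] with i = x, j = y (EBImage layout)
  dx <- (px - ctr) * params$pixel_size
  X <- matrix(dx, n, n)
  Y <- matrix(dx, n, n, byrow = TRUE)
  r_pix <- sqrt(X^2 + Y^2)
  th_img <- atan2(Y, X)
  # body-frame angle: 0 = animal pole direction
  th <- wrap_angle(th_img - params$av_axis_angle)
  r_true <- true_radius_um(params, th, t)

  dens <- matrix(0.05, n, n)
  dens[r_pix <= r_true] <- 1

  rim_half <- 1.0  # um; thin bright cortical rim
  cort <- matrix(0.05, n, n)
  rim <- abs(r_pix - r_true) <= rim_half
  arc <- arc_from_vegetal(th, params$cell_radius)
  u <- (arc - true_band_center(params, t)) / params$band_width
  gain <- 1 + (params$cortical_gain - 1) * band_bump(u)
  cort[rim] <- 0.4 * gain[rim]

  if (params$psf_sigma > 0) {
    dens <- as.matrix(EBImage::gblur(EBImage::Image(dens), params$psf_sigma))
    cort <- as.matrix(EBImage::gblur(EBImage::Image(cort), params$psf_sigma))
  }
  list(density = dens, cortical = cort)
}

apply_noise <- function(img, params) {
  if (params$noise_poisson_scale > 0)
    img <- matrix(stats::rpois(length(img),
                               pmax(img, 0) * params$noise_poisson_scale),
                  nrow(img)) / params$noise_poisson_scale
  if (params$noise_gaussian_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, params$noise_gaussian_sd),
                        nrow(img))
  img
}

#' Render a synthetic contraction-band movie with ground truth
#'
#' Produces a two-channel image stack: a transmitted-light-like density
#' channel (bright interior, dark exterior) and a cortical fluorescence
#' channel (thin bright rim, enriched by \code{cortical_gain} inside the
#' band), both blurred by a Gaussian point spread and degraded by Poisson
#' then Gaussian noise. Identical \code{(params, seed)} give bit-identical
#' output.
#'
#' @param params an \code{scw_band_params}.
#' @return list with \code{density} and \code{cortical} (lists of matrices,
#'   one per frame), \code{times} (s), and \code{ground_truth} (parameters,
#'   per-frame band centres and true outlines).
#' @export
render_movie <- function(params) {
  stopifnot(inherits(params, "scw_band_params"))
  set.seed(params$seed)
  times <- (seq_len(params$n_frames) - 1L) * params$frame_interval
  dens <- vector("list", params$n_frames)
  cort <- vector("list", params$n_frames)
  truth_outlines <- vector("list", params$n_frames)
  for (k in seq_along(times)) {
    fr <- render_frame(params, times[k])
    dens[[k]] <- apply_noise(fr$density, params)
    cort[[k]] <- apply_noise(fr$cortical, params)
    truth_outlines[[k]] <- true_outline(params, times[k])
    truth_outlines[[k]]$frame_index <- k
  }
  gt <- list(band_speed = params$band_speed, band_width = params$band_width,
             band_depth = params$band_depth, start_time = params$start_time,
             av_axis_angle = params$av_axis_angle,
             band_center = true_band_center(params, times),
             params = unclass(params), outlines = truth_outlines)
  list(density = dens, cortical = cort, times = times, ground_truth = gt)
}

#' Render a static control movie (no band)
#'
#' Same renderer with \code{band_depth = 0}: a noisy circle in every frame.
#' Used as the metaphase baseline for the wave-strength statistic.
#' @param params an \code{scw_band_params}; its \code{band_depth} is ignored.
#' @return as \code{\link{render_movie}}.
#' @export
static_control_movie <- function(params) {
  stopifnot(inherits(params, "scw_band_params"))
  params$band_depth <- 0
  render_movie(params)
}

#' Write a rendered movie to multi-page TIFF plus ground-truth JSON
#'
#' @param movie result of \code{\link{render_movie}}.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param interleave if \code{TRUE} write a single TIFF with channels
#'   interleaved (density, cortical, density, ...); otherwise one file per
#'   channel.
#' @return invisibly, the paths written.
#' @export
write_movie <- function(movie, dir, prefix = "movie", interleave = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  clamp <- function(m) pmin(pmax(m, 0), 1)
  # tiff expects [row, col] = [y, x]
  dens <- lapply(movie$density, function(m) t(clamp(m)))
  cort <- lapply(movie$cortical, function(m) t(clamp(m)))
  paths <- character(0)
  if (interleave) {
    pages <- vector("list", 2 * length(dens))
    pages[seq(1, length(pages), 2)] <- dens
    pages[seq(2, length(pages), 2)] <- cort
    p <- file.path(dir, paste0(prefix, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L)
    paths <- p
  } else {
    p1 <- file.path(dir, paste0(prefix, "_density.tif"))
    p2 <- file.path(dir, paste0(prefix, "_cortical.tif"))
    tiff::writeTIFF(dens, p1, bits.per.sample = 16L)
    tiff::writeTIFF(cort, p2, bits.per.sample = 16L)
    paths <- c(p1, p2)
  }
  gt <- movie$ground_truth
  gt$outlines <- lapply(gt$outlines, function(o)
    list(frame = o$frame_index, theta = o$theta, r_px = o$r,
         centroid = o$centroid, calibration = o$calibration))
  gt_path <- file.path(dir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(gt, gt_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, gt_path))
}

#' Read a TIFF stack as a list of matrices in the package's image convention
#' @param path TIFF file (possibly multi-page).
#' @return list of matrices indexed \code{[x, y]}.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(m) t(if (length(dim(m)) == 3) m[, , 1] else m))
}
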
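#' Smooth an outline with a periodic spline in polar coordinates
#'
#' Fits a cyclic cubic regression spline (a periodic piecewise polynomial
#' with continuous first and second derivatives) to the radius as a function
#' of angle, and evaluates it on a dense regular grid used by all downstream
#' curvature computations.
#'
#' @param o an \code{scw_outline}.
#' @param k basis dimension of the cyclic spline; the effective degrees of
#'   freedom are chosen by GCV below this ceiling. Larger k follows the
#'   outline more closely.
#' @param n_dense number of dense evaluation angles.
#' @return object of class \code{scw_smooth_outline}: dense \code{theta},
#'   \code{r} (px), \code{r_um}, residual RMS, and the source outline's
#'   centroid/calibration/frame.
#' @export
smooth_outline <- function(o, k = 40L, n_dense = 4096L) {
  stopifnot(inherits(o, "scw_outline"))
  if (length(o$theta) < 16) stop("too few outline samples to smooth (<16)")
  k <- min(as.integer(k), length(o$theta) - 2L)
  dat <- data.frame(theta = o$theta, r = o$r)
  fit <- mgcv::gam(r ~ s(theta, bs = "cc", k = k), data = dat,
                   knots = list(theta = c(0, 2 * pi)))
  th <- 2 * pi * (seq_len(n_dense) - 1L) / n_dense
  rhat <- as.numeric(mgcv::predict.gam(fit, newdata = data.frame(theta = th)))
  if (any(rhat <= 0)) stop("smoothed radius non-positive; degenerate outline")
  structure(list(theta = th, r = rhat, r_um = rhat * o$calibration,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 centroid = o$centroid, calibration = o$calibration,
                 frame_index = o$frame_index),
            class = "scw_smooth_outline")
}

# Evaluate the smoothed radius at arbitrary angles by periodic interpolation
# of the dense grid (the grid is fine enough that linear suffices).
smooth_radius_at <- function(sm, theta) {
  n <- length(sm$theta)
  th <- wrap_angle(theta)
  pos <- th / (2 * pi) * n
  i0 <- floor(pos)
  w <- pos - i0
  i1 <- (i0 %% n) + 1L
  i2 <- ((i0 + 1) %% n) + 1L
  sm$r[i1] * (1 - w) + sm$r[i2] * w
}

# Dense closed-curve geometry: equal-arc-length resampled coordinates (um,
# centred), curvature by central finite differences, cumulative arc length.
# Orientation is normalised to counter-clockwise so convex curvature is
# positive. Arc origin: the dense point at theta = 0 (animal pole).
# n_arc must stay well below the dense-theta resolution of the smoothed
# outline: resampling finer than the source polygon concentrates curvature
# at the polygon vertices and the finite differences alternate 0 / 2*kappa.
.curve_geometry <- function(sm, n_arc = 1024L) {
  n_arc <- min(n_arc, as.integer(length(sm$theta) / 4))
  x <- sm$r_um * cos(sm$theta)
  y <- sm$r_um * sin(sm$theta)
  # ensure CCW (positive signed area); theta grid is CCW by construction
  seg <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  s_cum <- c(0, cumsum(seg))
  P <- s_cum[length(s_cum)]
  # periodic resample to equal arc spacing, starting at theta = 0;
  # drop zero-length segments (duplicate points) first
  keep <- c(TRUE, seg > 1e-12)
  s_cum <- s_cum[keep]
  xc <- c(x, x[1])[keep]; yc <- c(y, y[1])[keep]
  s_new <- P * (seq_len(n_arc) - 1L) / n_arc
  xs <- stats::approx(s_cum, xc, xout = s_new, rule = 2)$y
  ys <- stats::approx(s_cum, yc, xout = s_new, rule = 2)$y
  h <- P / n_arc
  ip <- c(2:n_arc, 1L); im <- c(n_arc, 1:(n_arc - 1L))
  xp <- (xs[ip] - xs[im]) / (2 * h); yp <- (ys[ip] - ys[im]) / (2 * h)
  xpp <- (xs[ip] - 2 * xs + xs[im]) / h^2
  ypp <- (ys[ip] - 2 * ys + ys[im]) / h^2
  kappa <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  list(s = s_new, x = xs, y = ys, kappa = kappa, perimeter = P, h = h)
}

#' Turning number of a smoothed outline
#'
#' Integral of the curvature along the closed curve divided by \code{2*pi};
#' equals 1 for every simple counter-clockwise outline.
#' @param sm an \code{scw_smooth_outline}.
#' @export
turning_number <- function(sm) {
  g <- .curve_geometry(sm)
  sum(g$kappa) * g$h / (2 * pi)
}

#' Curvature-radius profile along the outline
#'
#' Divides the perimeter into segments of approximately \code{seg_len}
#' micrometres (origin at the animal pole), computes the planar curvature
#' \code{kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)} by central finite
#' differences on arc-length-resampled coordinates, and reports per-segment
#' signed radii of curvature \code{1/kappa}, capped at \code{r_max} (the
#' variance of uncapped radii diverges near inflection points).
#'
#' @param sm an \code{scw_smooth_outline}.
#' @param seg_len target segment length (um), must be < perimeter / 8.
#' @param r_max radius cap (um); default 5x the effective radius
#'   \code{perimeter / (2*pi)}. Recorded in the result.
#' @return object of class \code{scw_curvature_profile} with \code{s}
#'   (segment mid-arc positions, um), \code{radii} (um), \code{kappa} (1/um),
#'   \code{perimeter}, \code{r_max}, \code{frame_index}.
#' @export
curvature_profile <- function(sm, seg_len = 2, r_max = NULL) {
  stopifnot(inherits(sm, "scw_smooth_outline"))
  g <- .curve_geometry(sm)
  if (seg_len >= g$perimeter / 8)
    stop("seg_len must be smaller than perimeter / 8")
  if (is.null(r_max)) r_max <- 5 * g$perimeter / (2 * pi)
  n_seg <- max(8L, as.integer(round(g$perimeter / seg_len)))
  idx <- pmin(floor(g$s / g$perimeter * n_seg) + 1L, n_seg)
  kappa_seg <- as.numeric(tapply(g$kappa, idx, mean))
  radii <- ifelse(abs(kappa_seg) < 1 / r_max, sign(kappa_seg + 1e-300) * r_max,
                  1 / kappa_seg)
  radii <- pmin(pmax(radii, -r_max), r_max)
  structure(list(s = (seq_len(n_seg) - 0.5) * g$perimeter / n_seg,
                 radii = radii, kappa = kappa_seg, seg_len = seg_len,
                 perimeter = g$perimeter, r_max = r_max,
                 frame_index = sm$frame_index),
            class = "scw_curvature_profile")
}

# Resample a profile's values onto n_seg segments by arc fraction.
.resample_profile <- function(values, s, perimeter, n_out, perimeter_out) {
  frac <- s / perimeter
  frac_out <- (seq_len(n_out) - 0.5) / n_out
  f <- c(frac[length(frac)] - 1, frac, frac[1] + 1)
  v <- c(values[length(values)], values, values[1])
  stats::approx(f, v, xout = frac_out, rule = 2, ties = mean)$y
}

#' Curvature change relative to the first frame
#'
#' Subtracts the first frame's curvature (per arc-fraction-matched segment)
#' from every frame, removing uneven starting shapes.
#'
#' @param profiles list of \code{scw_curvature_profile}, one per frame.
#' @param resample if frames have different segment grids, resample onto the
#'   first frame's grid by arc fraction; if \code{FALSE}, differing grids are
#'   an error.
#' @return list of profiles whose \code{kappa} holds the curvature difference
#'   (and \code{radii} is dropped); first element is all zeros.
#' @export
relative_curvature <- function(profiles, resample = TRUE) {
  stopifnot(length(profiles) >= 2)
  ref <- profiles[[1]]
  n0 <- length(ref$kappa)
  lapply(profiles, function(p) {
    k <- p$kappa
    if (length(k) != n0 || abs(p$perimeter - ref$perimeter) > 0.05 * ref$perimeter) {
      if (!resample) stop("mismatched segment grids; set resample = TRUE")
      k <- .resample_profile(k, p$s, p$perimeter, n0, ref$perimeter)
    }
    structure(list(s = ref$s, kappa = k - ref$kappa, seg_len = ref$seg_len,
                   perimeter = ref$perimeter, r_max = ref$r_max,
                   frame_index = p$frame_index),
              class = "scw_curvature_profile")
  })
}

#' Assemble per-frame profiles into a kymograph
#'
#' @param profiles list of \code{scw_curvature_profile} (or, for intensity
#'   kymographs, lists with fields \code{s}, \code{values}, \code{perimeter}).
#' @param frame_interval time between frames (s).
#' @param what which field to use for curvature profiles: \code{"radius"},
#'   \code{"kappa"}.
#' @param t0 time of the first frame (s).
#' @return an \code{scw_kymograph} on the first frame's segment grid (other
#'   frames resampled by arc fraction).
#' @export
build_kymograph <- function(profiles, frame_interval,
                            what = c("radius", "kappa", "values"), t0 = 0) {
  what <- match.arg(what)
  pick <- function(p) switch(what, radius = p$radii, kappa = p$kappa,
                             values = p$values)
  ref <- profiles[[1]]
  n0 <- length(pick(ref))
  cols <- lapply(profiles, function(p) {
    v <- pick(p)
    if (length(v) != n0)
      v <- .resample_profile(v, p$s, p$perimeter, n0, ref$perimeter)
    v
  })
  sem <- switch(what, radius = "curvature-radius", kappa = "curvature",
                values = "fluorescence")
  meta <- list()
  if (!is.null(ref$r_max)) meta$r_max <- ref$r_max
  kymograph(do.call(cbind, cols), s = ref$s,
            t = t0 + (seq_along(profiles) - 1L) * frame_interval,
            semantics = sem, meta = meta)
}

#' Wave-strength statistic
#'
#' Variance of the (capped) curvature-radius values over all segment/frame
#' cells inside the wave window, minus the variance over an equal-length,
#' non-overlapping baseline window. Near zero for movies without a wave;
#' may be negative.
#'
#' @param kymo an \code{scw_kymograph} of curvature radii.
#' @param scw_window,baseline_window integer column (time) indices; must have
#'   equal length and not overlap.
#' @return scalar strength (um^2).
#' @export
scw_strength <- function(kymo, scw_window, baseline_window) {
  stopifnot(inherits(kymo, "scw_kymograph"))
  scw_window <- as.integer(scw_window)
  baseline_window <- as.integer(baseline_window)
  if (length(scw_window) != length(baseline_window))
    stop("wave and baseline windows must have equal length")
  if (length(intersect(scw_window, baseline_window)) > 0)
    stop("wave and baseline windows must not overlap")
  nt <- ncol(kymo$values)
  if (any(c(scw_window, baseline_window) < 1) ||
      any(c(scw_window, baseline_window) > nt))
    stop("window indices outside kymograph")
  stats::var(as.vector(kymo$values[, scw_window])) -
    stats::var(as.vector(kymo$values[, baseline_window]))
}

#' Automatic wave window: the fixed-duration window of maximal variance
#'
#' Convenience for selecting \code{scw_window}: slides a window of
#' \code{duration} seconds (default 7 min, the typical duration of the wave)
#' over the kymograph and returns the column indices maximising the variance,
#' plus an equal-length baseline window as far from it as possible.
#' @param kymo an \code{scw_kymograph}.
#' @param duration window length (s).
#' @return list with \code{scw_window}, \code{baseline_window}.
#' @export
auto_windows <- function(kymo, duration = 7 * 60) {
  dt <- if (length(kymo$t) > 1) diff(kymo$t[1:2]) else 1
  w <- max(2L, min(ncol(kymo$values) %/% 2, as.integer(round(duration / dt))))
  nt <- ncol(kymo$values)
  vs <- vapply(seq_len(nt - w + 1L), function(i)
    stats::var(as.vector(kymo$values[, i:(i + w - 1L)])), numeric(1))
  i0 <- which.max(vs)
  scw <- i0:(i0 + w - 1L)
  rest <- setdiff(seq_len(nt), scw)
  # baseline: the contiguous run of w frames in `rest` farthest from the wave
  before <- rest[rest < min(scw)]
  after <- rest[rest > max(scw)]
  base <- if (length(before) >= w) utils::head(before, w)
          else if (length(after) >= w) utils::tail(after, w)
          else stop("not enough frames outside the wave window for a baseline")
  list(scw_window = scw, baseline_window = base)
}

#' Cortical and subcortical ring intensities per curvature segment
#'
#' Builds an inward ring of depth \code{cortical_width} on the segmented
#' outline and a second ring immediately beneath it, and reports the mean
#' image intensity of each ring in the same arc-length segments used for
#' curvature, so fluorescence and curvature share coordinates.
#'
#' @param image single-channel matrix (\code{[x, y]}, same frame as outline).
#' @param sm an \code{scw_smooth_outline} for that frame.
#' @param profile the frame's \code{scw_curvature_profile} (defines the
#'   segment grid).
#' @param cortical_width depth of the cortical ring (um).
#' @param subcortical_band depth of the subcortical ring beneath it (um).
#' @return list with per-segment \code{cortical}, \code{subcortical} mean
#'   intensities, pixel counts, and the segment grid \code{s}.
#' @export
intensity_rings <- function(image, sm, profile, cortical_width = 2,
                            subcortical_band = 4) {
  stopifnot(is.matrix(image), inherits(sm, "scw_smooth_outline"))
  cal <- sm$calibration
  if ((cortical_width + subcortical_band) >= min(sm$r_um))
    stop("rings extend past the centroid")
  n1 <- nrow(image); n2 <- ncol(image)
  X <- matrix(seq_len(n1), n1, n2)
  Y <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
  th <- wrap_angle(atan2(Y - sm$centroid[2], X - sm$centroid[1]))
  r_um <- sqrt((X - sm$centroid[1])^2 + (Y - sm$centroid[2])^2) * cal
  rhat_um <- smooth_radius_at(sm, th) * cal
  depth <- rhat_um - r_um
  in_cort <- depth >= 0 & depth < cortical_width
  in_sub <- depth >= cortical_width & depth < cortical_width + subcortical_band
  # map pixel angle to arc-length segment via the dense curve geometry
  g <- .curve_geometry(sm, n_arc = 1024L)
  ang_dense <- wrap_angle(atan2(g$y, g$x))
  n_seg <- length(profile$s)
  seg_of_dense <- pmin(floor(g$s / g$perimeter * n_seg) + 1L, n_seg)
  # nearest dense angle per pixel (dense grid is equal-arc, angles monotone
  # enough on star-shaped outlines to use lookup by angular distance)
  ord <- order(ang_dense)
  lookup <- function(a) {
    i <- findInterval(a, ang_dense[ord])
    i <- pmin(pmax(i, 1L), length(ord))
    seg_of_dense[ord[i]]
  }
  res <- list(s = profile$s)
  for (ring in c("cortical", "subcortical")) {
    m <- if (ring == "cortical") in_cort else in_sub
    segs <- lookup(th[m])
    vals <- image[m]
    mu <- rep(NA_real_, n_seg); cnt <- integer(n_seg)
    agg <- tapply(vals, segs, mean)
    cts <- tapply(vals, segs, length)
    mu[as.integer(names(agg))] <- as.numeric(agg)
    cnt[as.integer(names(cts))] <- as.integer(cts)
    res[[ring]] <- mu
    res[[paste0(ring, "_n")]] <- cnt
  }
  res
}

#' Radial-deviation kymograph from an outline series
#'
#' For each frame, the smoothed radius along the perimeter minus a reference
#' radius per location, with the isotropic (mean radius) component of each
#' frame removed first so that volume-conservation breathing does not count
#' as deviation. The reference is the per-location median over frames
#' (robust while a travelling band occupies each location for only a
#' minority of frames) or the first frame. Unlike the curvature-radius
#' kymograph, the deviation of a half-sine contraction band keeps the
#' band's own half-sine shape, so the tracked ridge width reflects the band
#' width directly.
#'
#' @param outlines list of \code{scw_outline}.
#' @param frame_interval seconds between frames.
#' @param reference \code{"median"} (default) or \code{"first"}.
#' @param n_s number of arc positions.
#' @param k spline basis dimension for smoothing.
#' @return an \code{scw_kymograph} (um deviations, semantics
#'   \code{"radial-deviation"}).
#' @export
deviation_kymograph <- function(outlines, frame_interval,
                                reference = c("median", "first"),
                                n_s = 256L, k = 40L) {
  reference <- match.arg(reference)
  th <- 2 * pi * (seq_len(n_s) - 1L) / n_s
  Rmat <- vapply(outlines, function(o) {
    sm <- smooth_outline(o, k = k)
    smooth_radius_at(sm, th) * o$calibration
  }, numeric(n_s))
  Rmat <- sweep(Rmat, 2, colMeans(Rmat))  # drop isotropic breathing
  ref <- if (reference == "median") apply(Rmat, 1, stats::median)
         else Rmat[, 1]
  dev <- Rmat - ref
  # arc coordinate from the animal pole along the mean outline
  r_mean <- rowMeans(vapply(outlines, function(o) o$r * o$calibration,
                            numeric(length(outlines[[1]]$r))))
  P <- 2 * pi * mean(r_mean)
  kymograph(dev, s = P * (seq_len(n_s) - 0.5) / n_s,
            t = (seq_along(outlines) - 1L) * frame_interval,
            semantics = "radial-deviation")
}

#' Full outline-to-kymograph pipeline for a segmented movie
#'
#' Smooths each outline, computes curvature profiles, and assembles radius
#' and relative-curvature kymographs.
#'
#' @param outlines list of \code{scw_outline} (e.g. from
#'   \code{\link{segment_stack}}).
#' @param frame_interval s between frames.
#' @param seg_len segment length (um).
#' @param k spline basis dimension passed to \code{\link{smooth_outline}}.
#' @return list with \code{radius_kymo}, \code{dkappa_kymo},
#'   \code{profiles}, \code{smooth_outlines}.
#' @export
curvature_kymographs <- function(outlines, frame_interval, seg_len = 2,
                                 k = 40L) {
  sms <- lapply(outlines, smooth_outline, k = k)
  profs <- lapply(sms, curvature_profile, seg_len = seg_len)
  rel <- relative_curvature(profs)
  list(radius_kymo = build_kymograph(profs, frame_interval, "radius"),
       dkappa_kymo = build_kymograph(rel, frame_interval, "kappa"),
       profiles = profs, smooth_outlines = sms)
}
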
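#' Track a travelling band in a kymograph
#'
#' Detects, per time column, the dominant deviation from the baseline and
#' follows its position over time. The detection signal is the absolute
#' deviation of each cell from the baseline-window mean; a column counts as
#' "band detected" when its peak deviation exceeds \code{threshold_k} times
#' the baseline standard deviation. The band position is the
#' deviation-weighted centroid of the contiguous above-half-peak
#' neighbourhood of the column extremum, and the speed is the least-squares
#' slope of position versus time.
#'
#' On a full-perimeter kymograph of a wave travelling pole to pole, the band
#' appears as two mirror-image ridges (one per side of the cell). With
#' \code{fold = TRUE} the two halves are averaged and positions are reported
#' as arc length from the vegetal pole (assumed at half the perimeter from
#' the arc origin); with \code{fold = FALSE} (default) the kymograph is
#' tracked as-is.
#'
#' @param kymo an \code{scw_kymograph}.
#' @param baseline_cols columns defining the baseline (default: first 3).
#' @param threshold_k detection threshold in baseline standard deviations.
#' @param fold fold the perimeter about the vegetal pole before tracking.
#' @param edge_margin positions closer than this (um) to either end of the
#'   position axis are excluded from the speed fit (half the estimated band
#'   width if \code{NULL}), avoiding edge-truncation bias.
#' @param smooth_s running-mean window (um) applied to each column of the
#'   detection signal before peak finding. On curvature-radius kymographs the
#'   capped radii spike narrowly wherever the outline is flattest, and the
#'   spike position flickers within the band; smoothing at roughly half the
#'   band width makes the tracked peak follow the band centre. 0 disables.
#' @return an \code{scw_front_track}: \code{times}, \code{positions} (um),
#'   \code{speed_um_min}, \code{intercept}, \code{r_squared},
#'   \code{duration_s}, \code{width_um} (1.5x the median full width at half
#'   maximum, exact for a half-sine profile), \code{detected}.
#' @export
track_band <- function(kymo, baseline_cols = 1:3, threshold_k = 3,
                       fold = FALSE, edge_margin = NULL, smooth_s = 0) {
  stopifnot(inherits(kymo, "scw_kymograph"))
  V <- kymo$values
  s <- kymo$s
  base <- mean(V[, baseline_cols])
  base_sd <- stats::sd(as.vector(V[, baseline_cols]))
  D <- abs(V - base)
  if (fold) {
    P <- max(s) + (s[2] - s[1]) / 2
    p <- abs(s - P / 2)             # arc from vegetal pole
    n2 <- max(16L, length(s) %/% 2)
    binw <- (P / 2) / n2
    bin <- pmin(pmax(ceiling(p / binw), 1L), n2)
    sums <- rowsum(D, bin)
    cnt <- tabulate(bin, n2)
    Df <- matrix(0, n2, ncol(V))
    Df[as.integer(rownames(sums)), ] <- sums
    keep <- cnt > 0
    Df[keep, ] <- Df[keep, , drop = FALSE] / cnt[keep]
    D <- Df[keep, , drop = FALSE]
    s <- ((seq_len(n2) - 0.5) * binw)[keep]
  }
  if (smooth_s > 0 && length(s) > 2) {
    w_rows <- max(1L, round(smooth_s / (s[2] - s[1])))
    if (w_rows > 1L) {
      kern <- rep(1 / w_rows, w_rows)
      D <- apply(D, 2, function(col)
        stats::filter(col, kern, sides = 2) |>
          (\(x) { x[is.na(x)] <- col[is.na(x)]; x })())
      # smoothing dilutes the baseline noise scale equally
      base_sd <- base_sd / sqrt(w_rows)
    }
  }
  thr <- threshold_k * max(base_sd, 1e-12)
  nt <- ncol(D)
  pos <- rep(NA_real_, nt); fwhm <- rep(NA_real_, nt)
  for (j in seq_len(nt)) {
    col <- D[, j]
    pk <- which.max(col)
    if (col[pk] <= thr) next
    half <- col[pk] / 2
    lo <- pk; while (lo > 1 && col[lo - 1] >= half) lo <- lo - 1
    hi <- pk; while (hi < length(col) && col[hi + 1] >= half) hi <- hi + 1
    # single-pixel spikes are noise, not a band: require a spatially
    # extended ridge
    if (hi - lo + 1L < 3L) next
    w <- col[lo:hi] - half
    pos[j] <- sum(s[lo:hi] * w) / sum(w)
    fwhm[j] <- s[hi] - s[lo] + (s[2] - s[1])
  }
  det <- which(!is.na(pos))
  if (length(det) < 3L)
    stop("no travelling wave detected in kymograph")
  width_um <- 1.5 * stats::median(fwhm[det])
  margin <- if (is.null(edge_margin)) width_um / 2 else edge_margin
  fit_idx <- det[pos[det] > min(s) + margin & pos[det] < max(s) - margin]
  fit <- NULL
  if (length(fit_idx) >= 3) {
    fit <- stats::lm(pos[fit_idx] ~ kymo$t[fit_idx])
    slope <- unname(stats::coef(fit)[2]) * 60
    icpt <- unname(stats::coef(fit)[1])
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    slope <- NA_real_; icpt <- NA_real_; r2 <- NA_real_
    warning("fewer than 3 interior frames with a detected band; no speed fit")
  }
  structure(list(times = kymo$t[det], positions = pos[det],
                 speed_um_min = slope, intercept = icpt, r_squared = r2,
                 duration_s = diff(range(kymo$t[det])),
                 width_um = width_um, detected = det, folded = fold),
            class = "scw_front_track")
}

#' @method print scw_front_track
#' @export
print.scw_front_track <- function(x, ...) {
  cat(sprintf(
    "<scw_front_track> %d frames, speed %.1f um/min (R^2 %.3f), duration %.0f s, width %.0f um\n",
    length(x$times), x$speed_um_min, x$r_squared, x$duration_s, x$width_um))
  invisible(x)
}

#' Extract an intensity isoline from a kymograph
#'
#' Marching-squares contour of the kymograph at the given level; the longest
#' connected component is returned as the isoline, the remaining components
#' are kept in \code{components}.
#'
#' @param kymo an \code{scw_kymograph}.
#' @param level contour level; must lie within the value range.
#' @return an \code{scw_isoline}: \code{level}, ordered \code{s}, \code{t}
#'   points, \code{components} (list of further (s, t) paths),
#'   \code{degenerate} flag (level at the global extremum).
#' @export
extract_isoline <- function(kymo, level) {
  stopifnot(inherits(kymo, "scw_kymograph"))
  rg <- range(kymo$values)
  if (level < rg[1] || level > rg[2])
    stop(sprintf("level %g outside kymograph range [%g, %g]",
                 level, rg[1], rg[2]))
  cl <- grDevices::contourLines(kymo$s, kymo$t, kymo$values, levels = level)
  if (length(cl) == 0) {
    # level at the global extremum: report the degenerate single point
    idx <- if (abs(level - rg[2]) <= abs(level - rg[1]))
      which(kymo$values == rg[2], arr.ind = TRUE)[1, ]
    else which(kymo$values == rg[1], arr.ind = TRUE)[1, ]
    return(structure(list(level = level, s = kymo$s[idx[1]],
                          t = kymo$t[idx[2]], components = list(),
                          degenerate = TRUE), class = "scw_isoline"))
  }
  lens <- vapply(cl, function(cc) length(cc$x), integer(1))
  main <- cl[[which.max(lens)]]
  others <- lapply(cl[-which.max(lens)], function(cc)
    list(s = cc$x, t = cc$y))
  # a contour collapsed onto a single grid cell (level at an extremum)
  ds <- if (length(kymo$s) > 1) diff(kymo$s[1:2]) else 1
  dt <- if (length(kymo$t) > 1) diff(kymo$t[1:2]) else 1
  if (length(cl) == 1 && diff(range(main$x)) <= 2 * ds &&
      diff(range(main$y)) <= 2 * dt) {
    return(structure(list(level = level, s = mean(main$x), t = mean(main$y),
                          components = list(), degenerate = TRUE),
                     class = "scw_isoline"))
  }
  structure(list(level = level, s = main$x, t = main$y,
                 components = others, degenerate = FALSE),
            class = "scw_isoline")
}

# isoline position (s) as a single-valued function of time, averaging
# multiple crossings at the same time
.isoline_pos_at <- function(iso, times, tol) {
  vapply(times, function(tt) {
    sel <- abs(iso$t - tt) <= tol
    if (!any(sel)) NA_real_ else mean(iso$s[sel])
  }, numeric(1))
}

#' Offset between a concentration isoline and a tracked wave
#'
#' Compares, frame by frame, the arc position of a kymograph isoline with the
#' band position of a front track, reporting the root-mean-square offset and
#' the Pearson correlation of the two position series.
#'
#' @param iso an \code{scw_isoline} (same positional convention as the
#'   track).
#' @param front an \code{scw_front_track}.
#' @return list with \code{rms_um}, \code{pearson_r}, \code{n_frames},
#'   \code{offsets}.
#' @export
isoline_wave_overlap <- function(iso, front) {
  stopifnot(inherits(iso, "scw_isoline"), inherits(front, "scw_front_track"))
  dt <- if (length(front$times) > 1) min(diff(sort(unique(front$times)))) else 1
  ipos <- .isoline_pos_at(iso, front$times, tol = dt / 2)
  ok <- !is.na(ipos)
  if (sum(ok) < 3)
    stop("fewer than 3 frames common to isoline and track")
  off <- ipos[ok] - front$positions[ok]
  list(rms_um = sqrt(mean(off^2)),
       pearson_r = if (stats::sd(ipos[ok]) > 0 &&
                       stats::sd(front$positions[ok]) > 0)
         stats::cor(ipos[ok], front$positions[ok]) else NA_real_,
       n_frames = sum(ok), offsets = off)
}

#' Wave speed versus animal--vegetal distance
#'
#' Collects per-run (pole-to-pole distance, fitted speed) pairs and their
#' Pearson correlation, the relation used to show that the wave is guided by
#' a scalable gradient rather than travelling at a fixed speed.
#'
#' @param runs list of lists with fields \code{distance} (um, straight-line
#'   pole-to-pole) and \code{track} (an \code{scw_front_track}).
#' @return list with \code{table} (data frame distance/speed) and
#'   \code{pearson_r}.
#' @export
speed_vs_distance <- function(runs) {
  stopifnot(length(runs) >= 3)
  tab <- data.frame(
    distance_um = vapply(runs, function(r) r$distance, numeric(1)),
    speed_um_min = vapply(runs, function(r) r$track$speed_um_min, numeric(1)))
  if (stats::sd(tab$distance_um) == 0)
    stop("all distances equal; correlation undefined")
  list(table = tab, pearson_r = stats::cor(tab$distance_um, tab$speed_um_min))
}
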
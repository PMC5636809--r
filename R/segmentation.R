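#' Level-set segmentation parameters
#'
#' Settings for the Chan--Vese region-based level-set minimiser used to
#' recover the cell outline. The contract is the Chan--Vese minimiser itself;
#' the update here is a dense gradient descent with energy-monotone step
#' control (each step is accepted only if it does not increase the energy),
#' periodically re-initialising the level-set function to a signed distance
#' map.
#'
#' @param lambda_in,lambda_out region-fit weights for the inside/outside
#'   intensity misfit terms (both > 0).
#' @param smooth_weight boundary-length penalty mu; images are normalised to
#'   \code{[0, 1]} internally so this weight is scale-free.
#' @param max_iter maximum gradient-descent iterations.
#' @param tol convergence threshold: fraction of interface pixels whose sign
#'   changed in an iteration.
#' @param init initialisation: a list \code{list(type = "circle", center =
#'   NULL, radius = NULL)}, \code{list(type = "threshold")} (Otsu mask), or
#'   \code{list(type = "outline", outline = <scw_outline>)} for warm starts.
#' @param dark_object set \code{TRUE} if the cell is darker than background.
#' @param n_samples number of equal-angle samples of the returned outline.
#' @export
levelset_params <- function(lambda_in = 1, lambda_out = 1,
                            smooth_weight = 0.1, max_iter = 300L,
                            tol = 2e-3, init = list(type = "circle"),
                            dark_object = FALSE, n_samples = 360L) {
  stopifnot(lambda_in > 0, lambda_out > 0, smooth_weight >= 0,
            max_iter >= 1, tol > 0)
  structure(list(lambda_in = lambda_in, lambda_out = lambda_out,
                 smooth_weight = smooth_weight,
                 max_iter = as.integer(max_iter), tol = tol, init = init,
                 dark_object = dark_object,
                 n_samples = as.integer(n_samples)),
            class = "scw_levelset_params")
}

# smoothed Heaviside / delta with width eps (pixels)
.cv_heaviside <- function(phi, eps = 1.5) 0.5 * (1 + 2 / pi * atan(phi / eps))
.cv_delta <- function(phi, eps = 1.5) eps / (pi * (eps^2 + phi^2))

# central differences with replicated borders
.gradx <- function(m) (m[c(2:nrow(m), nrow(m)), ] - m[c(1, 1:(nrow(m) - 1)), ]) / 2
.grady <- function(m) (m[, c(2:ncol(m), ncol(m))] - m[, c(1, 1:(ncol(m) - 1))]) / 2

# curvature of the level sets of phi, div(grad phi / |grad phi|)
.cv_curvature <- function(phi) {
  gx <- .gradx(phi); gy <- .grady(phi)
  mag <- sqrt(gx^2 + gy^2 + 1e-8)
  .gradx(gx / mag) + .grady(gy / mag)
}

.cv_energy <- function(img, phi, p, eps = 1.5) {
  H <- .cv_heaviside(phi, eps)
  c1 <- sum(H * img) / max(sum(H), 1e-9)
  c2 <- sum((1 - H) * img) / max(sum(1 - H), 1e-9)
  gx <- .gradx(phi); gy <- .grady(phi)
  len <- sum(.cv_delta(phi, eps) * sqrt(gx^2 + gy^2))
  p$smooth_weight * len +
    p$lambda_in * sum(H * (img - c1)^2) +
    p$lambda_out * sum((1 - H) * (img - c2)^2)
}

.init_phi <- function(img, p) {
  n1 <- nrow(img); n2 <- ncol(img)
  init <- p$init
  type <- if (is.null(init$type)) "circle" else init$type
  if (type == "circle") {
    ctr <- if (!is.null(init$center)) init$center else c((n1 + 1) / 2, (n2 + 1) / 2)
    rad <- if (!is.null(init$radius)) init$radius else 0.35 * min(n1, n2)
    X <- matrix(seq_len(n1), n1, n2)
    Y <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
    rad - sqrt((X - ctr[1])^2 + (Y - ctr[2])^2)
  } else if (type == "threshold") {
    thr <- EBImage::otsu(EBImage::Image(img), range = range(img))
    mask <- img > thr
    .signed_distance(mask)
  } else if (type == "outline") {
    o <- init$outline
    stopifnot(inherits(o, "scw_outline"))
    X <- matrix(seq_len(n1), n1, n2)
    Y <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
    th <- wrap_angle(atan2(Y - o$centroid[2], X - o$centroid[1]))
    rr <- sqrt((X - o$centroid[1])^2 + (Y - o$centroid[2])^2)
    rhat <- resample_polar(o$theta, o$r, 720L)
    idx <- pmin(pmax(1L, as.integer(round(th / (2 * pi) * 720)) + 1L), 720L)
    matrix(rhat[idx], n1, n2) - rr
  } else stop("unknown init type: ", type)
}

.signed_distance <- function(mask) {
  m <- EBImage::Image(mask * 1)
  din <- as.matrix(EBImage::distmap(m))
  dout <- as.matrix(EBImage::distmap(1 - m))
  din - dout
}

#' Segment a single frame by Chan--Vese level-set minimisation
#'
#' Recovers a sub-pixel closed outline of the one bright (or dark) region in
#' the image. The boundary is the zero level set of the converged level-set
#' function, extracted with linear interpolation across sign changes.
#'
#' @param image single-channel 2D matrix (package convention: \code{[x, y]}).
#' @param params an \code{\link{levelset_params}}.
#' @param calibration um/px stored in the returned outline.
#' @param frame_index stored in the returned outline.
#' @param seed_point optional \code{(x, y)} point inside the object,
#'   disambiguating images containing several comparable components.
#' @return an \code{scw_outline} with attributes \code{converged},
#'   \code{iterations}, \code{energy_trace}.
#' @export
segment_frame <- function(image, params = levelset_params(), calibration = 1,
                          frame_index = 1L, seed_point = NULL) {
  stopifnot(is.matrix(image))
  p <- params
  rng <- range(image)
  if (diff(rng) < 1e-8 * max(abs(rng), 1))
    stop("segmentation failure: image has no contrast")
  img <- (image - rng[1]) / diff(rng)
  if (p$dark_object) img <- 1 - img
  phi <- .init_phi(img, p)
  phi <- pmin(pmax(phi, -6), 6)

  dt <- 1.0
  e_prev <- .cv_energy(img, phi, p)
  trace <- e_prev
  converged <- FALSE
  still <- 0L
  iter <- 0L
  reinits <- integer(0)
  while (iter < p$max_iter) {
    iter <- iter + 1L
    H <- .cv_heaviside(phi)
    c1 <- sum(H * img) / max(sum(H), 1e-9)
    c2 <- sum((1 - H) * img) / max(sum(1 - H), 1e-9)
    force <- .cv_delta(phi) *
      (p$smooth_weight * .cv_curvature(phi) -
         p$lambda_in * (img - c1)^2 + p$lambda_out * (img - c2)^2)
    fmax <- max(abs(force))
    if (fmax == 0) { converged <- TRUE; break }
    force <- force / fmax   # step size is then dt in pixels at the interface
    accepted <- FALSE
    for (k in 1:10) {
      cand <- pmin(pmax(phi + dt * force, -6), 6)
      e_new <- .cv_energy(img, cand, p)
      if (e_new <= e_prev + 1e-9 * abs(e_prev)) { accepted <- TRUE; break }
      dt <- dt / 2
    }
    if (!accepted) break
    improve <- (e_prev - e_new) / max(abs(e_prev), 1e-12)
    flips <- sum(sign(cand) != sign(phi))
    iface <- max(sum(abs(phi) < 1.5), 1)
    phi <- cand
    e_prev <- e_new
    trace <- c(trace, e_new)
    dt <- min(dt * 1.3, 1.0)
    if (iter %% 20 == 0) {
      # re-initialise to a signed distance map; the mask (and hence the
      # region terms) is unchanged but the length estimate is refreshed,
      # so the energy reference must be recomputed
      phi <- pmin(pmax(.signed_distance(phi > 0), -6), 6)
      e_prev <- .cv_energy(img, phi, p)
      reinits <- c(reinits, iter)
    }
    # converged when the energy has plateaued (no descent step achieves a
    # relative improvement above float noise for three iterations running)
    if (improve < 1e-9) still <- still + 1L else still <- 0L
    if (still >= 3L) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("Chan-Vese did not converge in %d iterations", iter))

  out <- .phi_to_outline(phi, p, calibration, frame_index, seed_point)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  attr(out, "energy_trace") <- trace
  attr(out, "reinit_iters") <- reinits
  out
}

.phi_to_outline <- function(phi, p, calibration, frame_index, seed_point) {
  cl <- grDevices::contourLines(seq_len(nrow(phi)), seq_len(ncol(phi)),
                                phi, levels = 0)
  if (length(cl) == 0)
    stop("segmentation failure: no foreground region found")
  areas <- vapply(cl, function(cc) {
    x <- cc$x; y <- cc$y; j <- c(seq_along(x)[-1], 1L)
    abs(sum(x * y[j] - x[j] * y)) / 2
  }, numeric(1))
  # interior holes show up as much smaller contours; comparable ones signal
  # genuinely ambiguous multi-object images
  big <- which(areas > 0.25 * max(areas))
  keep <- NULL
  if (length(big) > 1) {
    if (is.null(seed_point))
      stop("ambiguous segmentation: ", length(big),
           " comparable components; supply seed_point")
    d2 <- vapply(big, function(i)
      min((cl[[i]]$x - seed_point[1])^2 + (cl[[i]]$y - seed_point[2])^2),
      numeric(1))
    keep <- big[which.min(d2)]
  } else keep <- which.max(areas)
  cc <- cl[[keep]]
  if (length(cc$x) < 16 || areas[keep] < 25)
    stop("segmentation failure: foreground region too small")
  x <- cc$x; y <- cc$y
  j <- c(seq_along(x)[-1], 1L)
  a <- x * y[j] - x[j] * y
  A <- sum(a) / 2
  cx <- sum((x + x[j]) * a) / (6 * A)
  cy <- sum((y + y[j]) * a) / (6 * A)
  th <- wrap_angle(atan2(y - cy, x - cx))
  rr <- sqrt((x - cx)^2 + (y - cy)^2)
  rs <- resample_polar(th, rr, p$n_samples)
  outline(2 * pi * (seq_len(p$n_samples) - 1L) / p$n_samples, rs,
          centroid = c(cx, cy), calibration = calibration,
          frame_index = frame_index)
}

#' Segment every frame of a stack, warm-starting from the previous outline
#'
#' @param stack list of image matrices (one per frame).
#' @param params an \code{\link{levelset_params}}; frames after the first are
#'   initialised from the previous frame's outline.
#' @param calibration um/px.
#' @return list of \code{scw_outline}, with a \code{log} attribute (data frame
#'   of per-frame convergence and iteration counts).
#' @export
segment_stack <- function(stack, params = levelset_params(), calibration = 1) {
  stopifnot(length(stack) >= 1)
  outlines <- vector("list", length(stack))
  log <- data.frame(frame = seq_along(stack), converged = NA, iterations = NA)
  for (k in seq_along(stack)) {
    pk <- params
    if (k > 1) pk$init <- list(type = "outline", outline = outlines[[k - 1]])
    o <- tryCatch(
      segment_frame(stack[[k]], pk, calibration = calibration,
                    frame_index = k),
      error = function(e) stop("frame ", k, ": ", conditionMessage(e)))
    outlines[[k]] <- o
    log$converged[k] <- isTRUE(attr(o, "converged"))
    log$iterations[k] <- attr(o, "iterations")
  }
  attr(outlines, "log") <- log
  outlines
}

#' Write outlines to CSV (frame, theta, r, centroid_x, centroid_y)
#' @param outlines list of \code{scw_outline}.
#' @param path output CSV file.
#' @export
write_outlines_csv <- function(outlines, path) {
  df <- do.call(rbind, lapply(outlines, function(o)
    data.frame(frame = o$frame_index, theta = o$theta, r = o$r,
               centroid_x = o$centroid[1], centroid_y = o$centroid[2],
               calibration = o$calibration)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write QC overlay images of outlines on their frames
#'
#' One PNG per frame with the segmented outline drawn over the image.
#' @param stack list of image matrices.
#' @param outlines matching list of \code{scw_outline}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_outline_overlays <- function(stack, outlines, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_along(stack)) {
    img <- stack[[k]]
    f <- file.path(dir, sprintf("%s_%03d.png", prefix, k))
    grDevices::png(f, width = nrow(img), height = ncol(img))
    op <- graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(seq_len(nrow(img)), seq_len(ncol(img)),
                    pmin(pmax(img, 0), 1), col = grDevices::gray.colors(256),
                    axes = FALSE, xlab = "", ylab = "", useRaster = TRUE)
    xy <- outline_xy(outlines[[k]])
    graphics::lines(rbind(xy, xy[1, ]), col = "red", lwd = 1.5)
    graphics::par(op)
    grDevices::dev.off()
  }
  invisible(dir)
}

#' Read outlines written by \code{\link{write_outlines_csv}}
#' @param path CSV file.
#' @return list of \code{scw_outline}.
#' @export
read_outlines_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$frame), function(d)
    outline(d$theta, d$r, c(d$centroid_x[1], d$centroid_y[1]),
            calibration = d$calibration[1], frame_index = d$frame[1]))
}
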
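#' Parameters of the contractile-shell mechanical model
#'
#' The oocyte surface is a closed triangulated membrane whose shape at each
#' band position is the minimiser of
#' \deqn{H = \oint (2\kappa_b H^2 + \sigma(l))\, dA +
#'   \oint (K_\alpha/2\, \alpha^2 + \mu \beta)\, dA_0 +
#'   k_V/2\, (V - V_0)^2}
#' with bending stiffness \code{kappa_b}, a surface-tension band
#' \code{sigma(l)} shaped as a half-sine period of width \code{band_width}
#' along the arc length \code{l} of the axisymmetric reference contour,
#' stretch and shear moduli \code{K_alpha}, \code{mu} acting on the elastic
#' invariants \code{alpha = lambda1*lambda2 - 1} and
#' \code{beta = (lambda1 - lambda2)^2 / (2*lambda1*lambda2)} of each triangle
#' relative to the undeformed reference mesh, and an osmotic volume-restoring
#' term.
#'
#' Energies are expressed in units of \code{kappa_b}; the remaining moduli
#' are calibrated so that a 100-um band at default peak tension produces an
#' equatorial indentation of roughly ten percent of the radius, the regime
#' the model targets, with the volume held within one percent.
#'
#' @param kappa_b bending stiffness (energy units; sets the energy scale).
#' @param K_alpha stretch modulus (energy/um^2).
#' @param mu shear modulus (energy/um^2).
#' @param k_V volume stiffness (energy/um^6).
#' @param V0 target volume (um^3); \code{NULL} = reference mesh volume.
#' @param sigma_max peak band tension (energy/um^2).
#' @param band_width band width (um).
#' @param sigma_baseline resting tension outside the band.
#' @param pin_weight soft centroid-pin weight removing rigid translation.
#' @export
shell_params <- function(kappa_b = 1, K_alpha = 2.5e-3, mu = 2.5e-3,
                         k_V = 2e-8, V0 = NULL, sigma_max = 2e-3,
                         band_width = 100, sigma_baseline = 0,
                         pin_weight = 0.1) {
  p <- list(kappa_b = kappa_b, K_alpha = K_alpha, mu = mu, k_V = k_V,
            V0 = V0, sigma_max = sigma_max, band_width = band_width,
            sigma_baseline = sigma_baseline, pin_weight = pin_weight)
  mods <- unlist(p[c("kappa_b", "K_alpha", "mu", "k_V", "pin_weight")])
  if (any(mods < 0)) stop("all moduli must be non-negative")
  if (p$band_width <= 0) stop("band_width must be positive")
  class(p) <- "scw_shell_params"
  p
}

#' Triangulated sphere mesh (subdivided icosahedron)
#'
#' @param radius sphere radius (um).
#' @param n_subdiv number of 4-to-1 subdivisions of the icosahedron
#'   (vertex count \code{10 * 4^k + 2}).
#' @return an \code{scw_trimesh}: vertices \code{V} (n x 3, um), faces
#'   \code{F} (m x 3, 1-based, outward orientation), reference vertices
#'   \code{Vref} (= V), per-vertex tension \code{sigma} (zeros),
#'   \code{radius}. The animal pole is +z, the vegetal pole -z.
#' @export
make_sphere_mesh <- function(radius = 85, n_subdiv = 3L) {
  stopifnot(n_subdiv >= 0)
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  F_ <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  V <- V / sqrt(rowSums(V^2))
  for (k in seq_len(n_subdiv)) {
    nv <- nrow(V)
    e <- rbind(F_[, 1:2], F_[, 2:3], F_[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- unique(key)
    mid_id <- nv + match(key, uk)
    ue <- e[!duplicated(key), , drop = FALSE]
    mids <- (V[ue[, 1], , drop = FALSE] + V[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    V <- rbind(V, mids)
    m <- nrow(F_)
    ab <- mid_id[1:m]; bc <- mid_id[m + 1:m]; ca <- mid_id[2 * m + 1:m]
    F_ <- rbind(cbind(F_[, 1], ab, ca), cbind(F_[, 2], bc, ab),
                cbind(F_[, 3], ca, bc), cbind(ab, bc, ca))
  }
  V <- V * radius
  mesh <- structure(list(V = V, F = F_, Vref = V,
                         sigma = numeric(nrow(V)), radius = radius),
                    class = "scw_trimesh")
  if (mesh_volume(mesh) < 0) mesh$F <- mesh$F[, c(1, 3, 2)]
  mesh
}

#' Enclosed volume of a mesh (signed, positive for outward orientation)
#' @param mesh an \code{scw_trimesh}.
#' @export
mesh_volume <- function(mesh) {
  cpp_mesh_curvature(mesh$V, mesh$F)$volume
}

#' Per-vertex unsigned mean curvature (cotangent Laplacian) and areas
#' @param mesh an \code{scw_trimesh}.
#' @return list with \code{H} (1/um), \code{A} (um^2), \code{volume},
#'   \code{area}.
#' @export
mesh_curvature <- function(mesh) {
  cpp_mesh_curvature(mesh$V, mesh$F)
}

#' Euler characteristic of a mesh
#' @param mesh an \code{scw_trimesh}.
#' @export
mesh_euler <- function(mesh) {
  e <- rbind(mesh$F[, 1:2], mesh$F[, 2:3], mesh$F[, c(3, 1)])
  n_edges <- nrow(unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  nrow(mesh$V) - n_edges + nrow(mesh$F)
}

#' Banded surface-tension field on the reference contour
#'
#' The tension depends only on the arc length \code{l} from the vegetal pole
#' along the meridional contour of the undeformed (reference) surface, so the
#' band position is an external kinematic control: a half-sine bump of width
#' \code{band_width} centred at \code{band_center_arc} for the
#' \code{"band"} scenario, or a step of magnitude \code{sigma_max} behind
#' the position (on the vegetal side, already passed by the wave) for the
#' contrasting \code{"front"} scenario.
#'
#' @param mesh an \code{scw_trimesh}.
#' @param band_center_arc band centre, arc length from the vegetal pole (um).
#' @param params an \code{scw_shell_params}.
#' @param profile \code{"band"} (half-sine, the model's scenario) or
#'   \code{"front"} (step of high tension behind the front).
#' @return per-vertex tension vector.
#' @export
tension_field <- function(mesh, band_center_arc, params,
                          profile = c("band", "front")) {
  profile <- match.arg(profile)
  R <- mesh$radius
  z <- mesh$Vref[, 3]
  rr <- sqrt(rowSums(mesh$Vref^2))
  phi_veg <- acos(pmin(pmax(-z / rr, -1), 1)) # angle from the vegetal pole
  l <- R * phi_veg
  if (profile == "band") {
    u <- (l - band_center_arc) / params$band_width
    params$sigma_baseline +
      params$sigma_max * ifelse(abs(u) <= 0.5, cos(pi * u), 0)
  } else {
    params$sigma_baseline + params$sigma_max * (l < band_center_arc)
  }
}

#' Evaluate the shell energy of a mesh configuration
#'
#' @param mesh an \code{scw_trimesh}; its \code{sigma} field is used unless
#'   \code{sigma} is given.
#' @param params an \code{scw_shell_params}.
#' @param sigma optional per-vertex tension overriding \code{mesh$sigma}.
#' @return named numeric vector: \code{bending}, \code{tension},
#'   \code{stretch}, \code{shear}, \code{volume}, \code{total}, with the
#'   enclosed volume as attribute \code{enclosed_volume}.
#' @export
shell_energy <- function(mesh, params, sigma = NULL) {
  stopifnot(inherits(mesh, "scw_trimesh"), inherits(params, "scw_shell_params"))
  if (is.null(sigma)) sigma <- mesh$sigma
  V0 <- if (is.null(params$V0)) abs(cpp_mesh_curvature(mesh$Vref, mesh$F)$volume)
        else params$V0
  cpp_shell_energy(mesh$V, mesh$F, mesh$Vref, sigma, params$kappa_b,
                   params$K_alpha, params$mu, params$k_V, V0)
}

# outward-orientation / star-shape heuristic: every face normal points away
# from the centroid. Adequate for the near-axisymmetric convex-ish shapes
# this model produces; a failure indicates inversion or self-intersection.
mesh_is_valid <- function(mesh) {
  V <- mesh$V; F_ <- mesh$F
  ctr <- colMeans(V)
  a <- V[F_[, 1], ] ; b <- V[F_[, 2], ]; cc <- V[F_[, 3], ]
  nrm <- cbind((b[, 2] - a[, 2]) * (cc[, 3] - a[, 3]) -
                 (b[, 3] - a[, 3]) * (cc[, 2] - a[, 2]),
               (b[, 3] - a[, 3]) * (cc[, 1] - a[, 1]) -
                 (b[, 1] - a[, 1]) * (cc[, 3] - a[, 3]),
               (b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
                 (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1]))
  cen <- (a + b + cc) / 3
  all(rowSums(nrm * (cen - matrix(ctr, nrow(nrm), 3, byrow = TRUE))) > 0)
}

#' Relax a mesh to its steady-state (minimum-energy) shape
#'
#' Quasi-Newton (L-BFGS-B) minimisation of the shell energy over all vertex
#' positions, with a soft centroid pin removing the translational null space.
#' The shape problem is solved independently at each band position; this is
#' the single-position solver.
#'
#' @param mesh an \code{scw_trimesh} (its \code{V} is the starting point).
#' @param params an \code{scw_shell_params}.
#' @param sigma per-vertex tension (default \code{mesh$sigma}).
#' @param maxit iteration cap.
#' @param factr L-BFGS-B relative-progress stop (see \code{\link{optim}}).
#' @param fd_step finite-difference step (um) of the gradient.
#' @return the relaxed \code{scw_trimesh}, with attributes \code{energy}
#'   (component vector), \code{converged}, \code{optim_message}.
#' @export
relax_shape <- function(mesh, params, sigma = NULL, maxit = 400L,
                        factr = 1e4, fd_step = 1e-3) {
  stopifnot(inherits(mesh, "scw_trimesh"))
  if (is.null(sigma)) sigma <- mesh$sigma
  if (length(sigma) != nrow(mesh$V)) stop("sigma length != vertex count")
  V0 <- if (is.null(params$V0)) abs(cpp_mesh_curvature(mesh$Vref, mesh$F)$volume)
        else params$V0
  c0 <- colMeans(mesh$Vref)
  n <- nrow(mesh$V)
  fn <- function(par)
    cpp_shell_objective(matrix(par, n, 3), mesh$F, mesh$Vref, sigma,
                        params$kappa_b, params$K_alpha, params$mu,
                        params$k_V, V0, params$pin_weight, c0)
  gr <- function(par)
    cpp_shell_gradient(matrix(par, n, 3), mesh$F, mesh$Vref, sigma,
                       params$kappa_b, params$K_alpha, params$mu,
                       params$k_V, V0, params$pin_weight, c0, fd_step)
  e0 <- fn(as.vector(mesh$V))
  if (!is.finite(e0)) stop("non-finite starting energy")
  res <- stats::optim(as.vector(mesh$V), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = factr))
  out <- mesh
  out$V <- matrix(res$par, n, 3)
  out$sigma <- sigma
  if (res$value > e0 + 1e-9 * abs(e0))
    stop("relaxation increased the energy; diagnostic: ", res$message)
  if (!mesh_is_valid(out))
    stop("relaxed mesh failed the orientation/star-shape check ",
         "(inverted or self-intersecting surface)")
  if (res$convergence != 0)
    warning("relax_shape: iteration cap reached (", res$message, ")")
  attr(out, "energy") <- shell_energy(out, params, sigma)
  attr(out, "converged") <- res$convergence == 0
  attr(out, "optim_message") <- res$message
  out
}

#' Steady-state shapes for a sweep of band positions
#'
#' Solves the shape problem independently for each band position; each solve
#' is initialised from the previous solution (pure speed-up: the minimiser
#' does not depend on the starting point within the basin, so a reversed
#' sweep gives the same shapes).
#'
#' @param mesh starting \code{scw_trimesh} (typically a sphere).
#' @param params an \code{scw_shell_params}.
#' @param band_positions band-centre arc positions (um from the vegetal
#'   pole), ordered.
#' @param profile tension profile, see \code{\link{tension_field}}.
#' @param ... passed to \code{\link{relax_shape}}.
#' @return an \code{scw_shape_series}: \code{meshes}, \code{outlines}
#'   (meridional \code{scw_outline}s), \code{energies} (matrix),
#'   \code{band_positions}.
#' @export
sweep_band <- function(mesh, params, band_positions,
                       profile = c("band", "front"), ...) {
  profile <- match.arg(profile)
  cur <- mesh
  meshes <- vector("list", length(band_positions))
  outlines <- vector("list", length(band_positions))
  energies <- matrix(NA_real_, length(band_positions), 6,
                     dimnames = list(NULL, c("bending", "tension", "stretch",
                                             "shear", "volume", "total")))
  for (i in seq_along(band_positions)) {
    sig <- tension_field(mesh, band_positions[i], params, profile)
    cur <- tryCatch(
      relax_shape(cur, params, sigma = sig, ...),
      error = function(e) stop("band position ", band_positions[i], " (#",
                               i, "): ", conditionMessage(e)))
    meshes[[i]] <- cur
    o <- mesh_to_outline(cur)
    o$frame_index <- i
    outlines[[i]] <- o
    energies[i, ] <- as.numeric(attr(cur, "energy"))
  }
  structure(list(meshes = meshes, outlines = outlines, energies = energies,
                 band_positions = band_positions, params = params,
                 profile = profile),
            class = "scw_shape_series")
}

#' Meridional outline of a mesh
#'
#' Intersects the surface with a plane containing the symmetry (z) axis and
#' returns the section as a polar outline (theta = 0 at the animal pole, +z),
#' directly consumable by the curvature pipeline. Units are micrometres
#' (outline calibration 1).
#'
#' @param mesh an \code{scw_trimesh}.
#' @param plane_angle azimuth of the section plane (radians).
#' @param n_samples outline samples.
#' @return an \code{scw_outline}.
#' @export
mesh_to_outline <- function(mesh, plane_angle = 0, n_samples = 360L) {
  V <- mesh$V
  if (plane_angle != 0) {
    ca <- cos(-plane_angle); sa <- sin(-plane_angle)
    V <- cbind(ca * V[, 1] - sa * V[, 2], sa * V[, 1] + ca * V[, 2], V[, 3])
  }
  e <- rbind(mesh$F[, 1:2], mesh$F[, 2:3], mesh$F[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  y1 <- V[e[, 1], 2]; y2 <- V[e[, 2], 2]
  crossing <- (y1 <= 0 & y2 > 0) | (y1 > 0 & y2 <= 0)
  if (!any(crossing)) stop("empty plane intersection")
  w <- y1[crossing] / (y1[crossing] - y2[crossing])
  p1 <- V[e[crossing, 1], , drop = FALSE]
  p2 <- V[e[crossing, 2], , drop = FALSE]
  pts <- p1 + (p2 - p1) * w
  x <- pts[, 1]; z <- pts[, 3]
  cx <- mean(x); cz <- mean(z)
  th <- wrap_angle(atan2(x - cx, z - cz)) # 0 at animal pole (+z)
  rr <- sqrt((x - cx)^2 + (z - cz)^2)
  rs <- resample_polar(th, rr, n_samples)
  outline(2 * pi * (seq_len(n_samples) - 1L) / n_samples, rs,
          centroid = c(cx, cz), calibration = 1, frame_index = 1L)
}

#' Radial deviation of a shape series from its first (baseline) outline
#'
#' Per-angle radial deviation of each outline from the first one, after
#' removing the isotropic (mean-radius) component of every frame. Removing
#' the isotropic part discounts the volume-conservation bulge that spreads
#' over the whole surface while a band indents one region, isolating the
#' local deformation pattern.
#'
#' @param outlines list of \code{scw_outline} on a common angle grid (e.g.
#'   from \code{\link{sweep_band}}); the first is the baseline.
#' @return matrix (angles x frames) of deviations (um), frame 1 all zero.
#' @export
radial_deviation <- function(outlines) {
  Rmat <- vapply(outlines, function(o) o$r * o$calibration,
                 numeric(length(outlines[[1]]$r)))
  dev <- sweep(Rmat, 2, colMeans(Rmat))
  dev - dev[, 1]
}

#' Per-location persistence of the indentation
#'
#' Distinguishes a transient travelling band (each surface location indents
#' and recovers) from an accumulating front (once a location indents it stays
#' indented): for every angular location whose deviation drops below
#' \code{-threshold_frac} times the deepest indentation of the series, the
#' fraction of subsequent frames still below that threshold is computed and
#' averaged over locations.
#'
#' @param outlines as in \code{\link{radial_deviation}}; the first outline
#'   must be an undeformed baseline.
#' @param threshold_frac indentation threshold as a fraction of the deepest
#'   indentation.
#' @return mean persistence in [0, 1]; near 1 = accumulating, well below 1 =
#'   transient.
#' @export
deformation_persistence <- function(outlines, threshold_frac = 0.3) {
  dev <- radial_deviation(outlines)
  thr <- -threshold_frac * max(-dev)
  nt <- ncol(dev)
  pers <- apply(dev, 1, function(v) {
    on <- which(v < thr)
    if (length(on) == 0 || on[1] > nt - 2) return(NA_real_)
    mean(v[(on[1] + 1):nt] < thr)
  })
  mean(pers, na.rm = TRUE)
}

#' Export a mesh as an ASCII OFF file
#' @param mesh an \code{scw_trimesh}.
#' @param path output file.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$V), nrow(mesh$F)), con)
  utils::write.table(format(mesh$V, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$F - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
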
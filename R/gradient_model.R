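#' Parameters of the cdk1-cyclinB / APC reaction-diffusion model
#'
#' The model starts at nuclear envelope breakdown with cdk1-cyclinB
#' concentrated in the nuclear region and evolves two coupled fields on the
#' cell interior with zero-flux boundaries:
#' \deqn{\dot{c} = D_c \Delta c - (k_0 + k_1 \frac{a}{J^2 + c^2}) c
#'   + k_2 \Theta(R_n^2 - |x - x_n|^2)}
#' \deqn{\dot{a} = D_a \Delta a - k_3 a + k_4 \frac{a^2}{K^2 + a^2} c}
#' where \code{c} is cdk1-cyclinB, \code{a} is active APC/C and \code{Theta}
#' is the Heaviside function marking the nuclear region. APC/C is activated
#' in a slowly igniting positive feedback by cdk1-cyclinB, which realises the
#' delayed, accelerating degradation of cyclinB; the APC seed \code{APC0}
#' must be positive for the feedback to ignite at all.
#'
#' Rate values are not constrained by published tables; the defaults are
#' calibrated once so that the gradient collapses on a timescale of roughly
#' 50 minutes after nuclear envelope breakdown, and every value is exposed.
#'
#' @param D_cdk1,D_APC diffusion coefficients (um^2/s).
#' @param k0 basal cyclinB degradation (1/s).
#' @param k1 APC-mediated degradation coefficient (concentration^2/s scale
#'   set by J).
#' @param J cdk1-inhibition constant of the APC-mediated degradation term.
#' @param k2 production rate inside the nuclear region (conc/s).
#' @param k3 APC inactivation (1/s).
#' @param k4 APC activation coefficient (1/s per unit cdk1).
#' @param K APC half-activation constant.
#' @param R_nucleus nuclear radius (um).
#' @param nucleus_z signed position of the nucleus centre on the
#'   animal--vegetal axis (um; positive = animal half). \code{NULL} places it
#'   just beneath the animal pole.
#' @param APC0 initial uniform active-APC seed (> 0).
#' @param nuclear_level,cytoplasmic_level initial cdk1-cyclinB inside /
#'   outside the nucleus (a.u.).
#' @param degradation \code{"standard"} uses the APC-mediated degradation
#'   term \code{k1 * a / (J^2 + c^2) * c} of the model above;
#'   \code{"michaelis"} substitutes a Michaelis form
#'   \code{k1 * a * c / (J + c)} for sensitivity analysis only.
#' @export
gradient_params <- function(D_cdk1 = 3, D_APC = 15, k0 = 2e-4, k1 = 3e-4,
                            J = 0.3, k2 = 2e-3, k3 = 1e-3, k4 = 4.5e-3,
                            K = 0.3, R_nucleus = 35, nucleus_z = NULL,
                            APC0 = 0.02, nuclear_level = 10,
                            cytoplasmic_level = 1,
                            degradation = c("standard", "michaelis")) {
  p <- list(D_cdk1 = D_cdk1, D_APC = D_APC, k0 = k0, k1 = k1, J = J,
            k2 = k2, k3 = k3, k4 = k4, K = K, R_nucleus = R_nucleus,
            nucleus_z = nucleus_z, APC0 = APC0,
            nuclear_level = nuclear_level,
            cytoplasmic_level = cytoplasmic_level,
            degradation = match.arg(degradation))
  rates <- unlist(p[c("D_cdk1", "D_APC", "k0", "k1", "k2", "k3", "k4")])
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (p$J <= 0 || p$K <= 0) stop("J and K must be positive")
  if (p$R_nucleus <= 0) stop("R_nucleus must be positive")
  class(p) <- "scw_gradient_params"
  p
}

#' Build an axisymmetric computational domain
#'
#' The cell is an axisymmetric body around the animal--vegetal (z) axis; the
#' domain is a finite-volume grid in the meridional (z, r) half-plane with
#' cell volumes \code{2 pi r dr dz}, which makes implicit diffusion exactly
#' mass-conserving and zero-flux boundaries automatic.
#'
#' @param cell_shape \code{"sphere"}, \code{"prolate"}, \code{"oblate"} or
#'   \code{"custom"}.
#' @param radius equatorial radius (um).
#' @param av_scale semi-axis scale along z: the A--V semi-axis is
#'   \code{radius * av_scale} (> 1 for prolate, < 1 for oblate; forced to 1
#'   for \code{"sphere"}).
#' @param nz,nr grid cells along z and r.
#' @param contour for \code{"custom"}: function \code{rho(z)} giving the
#'   radial extent, plus \code{zlim} range, as a list
#'   \code{list(rho = f, zlim = c(lo, hi))}.
#' @return an \code{scw_domain}: grids \code{z}, \code{r}, spacing, logical
#'   \code{mask} (nz x nr), \code{av_distance} (um), \code{rho} contour
#'   function.
#' @export
build_domain <- function(cell_shape = c("sphere", "prolate", "oblate",
                                        "custom"),
                         radius = 85, av_scale = 1, nz = 200L, nr = 100L,
                         contour = NULL) {
  cell_shape <- match.arg(cell_shape)
  if (cell_shape == "sphere") av_scale <- 1
  if (cell_shape == "prolate" && av_scale <= 1)
    stop("prolate domain needs av_scale > 1")
  if (cell_shape == "oblate" && av_scale >= 1)
    stop("oblate domain needs av_scale < 1")
  if (cell_shape == "custom") {
    stopifnot(is.list(contour), is.function(contour$rho),
              length(contour$zlim) == 2)
    rho <- contour$rho
    zlim <- contour$zlim
  } else {
    b <- radius * av_scale
    rho <- function(z) radius * sqrt(pmax(1 - (z / b)^2, 0))
    zlim <- c(-b, b)
  }
  dz <- diff(zlim) / nz
  dr <- radius / nr
  z <- zlim[1] + (seq_len(nz) - 0.5) * dz
  r <- (seq_len(nr) - 0.5) * dr
  mask <- outer(z, r, function(zz, rr) rr <= rho(zz))
  if (!any(mask)) stop("empty domain")
  structure(list(z = z, r = r, dz = dz, dr = dr, mask = mask,
                 nz = nz, nr = nr, radius = radius,
                 av_distance = diff(zlim), rho = rho, zlim = zlim),
            class = "scw_domain")
}

# Finite-volume Laplacian machinery: index map, volumes, coupling matrix K
# with zero row sums (d(w c)/dt = D K c).
.fv_operator <- function(dom) {
  idx <- matrix(0L, dom$nz, dom$nr)
  cells <- which(dom$mask)
  idx[cells] <- seq_along(cells)
  n <- length(cells)
  zc <- ((cells - 1L) %% dom$nz) + 1L
  rc <- ((cells - 1L) %/% dom$nz) + 1L
  w <- 2 * pi * dom$r[rc] * dom$dr * dom$dz
  ii <- integer(0); jj <- integer(0); cc <- numeric(0)
  # axial neighbours (z direction): face area 2 pi r dr, distance dz
  ok <- zc < dom$nz
  nb <- idx[cbind(zc[ok] + 1L, rc[ok])]
  sel <- nb > 0L
  a <- 2 * pi * dom$r[rc[ok][sel]] * dom$dr / dom$dz
  ii <- c(ii, idx[cbind(zc[ok][sel], rc[ok][sel])]); jj <- c(jj, nb[sel])
  cc <- c(cc, a)
  # radial neighbours: face area 2 pi r_{j+1/2} dz, distance dr
  ok <- rc < dom$nr
  nb <- idx[cbind(zc[ok], rc[ok] + 1L)]
  sel <- nb > 0L
  rface <- dom$r[rc[ok][sel]] + dom$dr / 2
  a <- 2 * pi * rface * dom$dz / dom$dr
  ii <- c(ii, idx[cbind(zc[ok][sel], rc[ok][sel])]); jj <- c(jj, nb[sel])
  cc <- c(cc, a)
  K <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(cc, cc),
                            dims = c(n, n))
  K <- K - Matrix::Diagonal(n, Matrix::rowSums(K))
  list(K = K, w = w, cells = cells, zc = zc, rc = rc, n = n)
}

#' Initial condition: nuclear cdk1-cyclinB bolus plus uniform APC seed
#'
#' @param domain an \code{scw_domain}.
#' @param params an \code{scw_gradient_params}.
#' @param sources optional list of extra high-concentration regions, each
#'   \code{list(z = , R = , level = )} (on-axis spheres); by default the
#'   single nucleus from \code{params}. The nuclear production term of the
#'   dynamics always uses the primary nucleus only.
#' @return an \code{scw_gradient_field} at t = 0 with matrices \code{cdk1}
#'   and \code{apc} (NA outside the domain).
#' @export
initial_state <- function(domain, params, sources = NULL) {
  stopifnot(inherits(domain, "scw_domain"),
            inherits(params, "scw_gradient_params"))
  if (params$nuclear_level < params$cytoplasmic_level)
    stop("nuclear_level must be >= cytoplasmic_level")
  zn <- nucleus_position(domain, params)
  nuc <- list(z = zn, R = params$R_nucleus, level = params$nuclear_level)
  if (is.null(sources)) sources <- list(nuc)
  cdk1 <- matrix(NA_real_, domain$nz, domain$nr)
  apc <- matrix(NA_real_, domain$nz, domain$nr)
  cdk1[domain$mask] <- params$cytoplasmic_level
  apc[domain$mask] <- params$APC0
  Z <- matrix(domain$z, domain$nz, domain$nr)
  R <- matrix(domain$r, domain$nz, domain$nr, byrow = TRUE)
  for (srcs in sources) {
    inside <- (Z - srcs$z)^2 + R^2 <= srcs$R^2
    if (any(inside & !domain$mask))
      stop("source region extends outside the domain")
    cdk1[inside] <- srcs$level
  }
  structure(list(domain = domain, cdk1 = cdk1, apc = apc, t = 0,
                 nucleus = nuc),
            class = "scw_gradient_field")
}

# default nucleus centre: apposed to the animal cortex (z = +zmax), as the
# germinal vesicle sits against the animal pole
nucleus_position <- function(domain, params) {
  if (!is.null(params$nucleus_z)) return(params$nucleus_z)
  max(domain$zlim) - 1.05 * params$R_nucleus
}

#' Integrate the reaction-diffusion system
#'
#' Operator splitting: implicit (backward-Euler, exactly conservative)
#' finite-volume diffusion via a pre-factorised sparse Cholesky solve,
#' followed by an exponential reaction update that is exact for the linear
#' parts (so a pure \code{k0} decay matches the closed form to machine
#' precision) and unconditionally keeps concentrations non-negative.
#'
#' @param field an \code{scw_gradient_field} (t = 0 state).
#' @param params an \code{scw_gradient_params}.
#' @param dt time step (s).
#' @param T_end end time (s).
#' @param save_every store a snapshot every this many steps.
#' @return an \code{scw_gradient_series}: list of snapshot fields
#'   (\code{cdk1}, \code{apc} matrices), \code{times}, \code{domain},
#'   \code{mass} (total cdk1 per snapshot).
#' @export
run_gradient <- function(field, params, dt = 10, T_end = 3600,
                         save_every = 1L) {
  stopifnot(inherits(field, "scw_gradient_field"),
            inherits(params, "scw_gradient_params"), dt > 0)
  dom <- field$domain
  op <- .fv_operator(dom)
  W <- Matrix::Diagonal(op$n, op$w)
  sol_c <- if (params$D_cdk1 > 0)
    Matrix::Cholesky(Matrix::forceSymmetric(W - dt * params$D_cdk1 * op$K))
    else NULL
  sol_a <- if (params$D_APC > 0)
    Matrix::Cholesky(Matrix::forceSymmetric(W - dt * params$D_APC * op$K))
    else NULL
  cvec <- field$cdk1[dom$mask]
  avec <- field$apc[dom$mask]
  zn <- field$nucleus$z
  in_nuc <- (dom$z[op$zc] - zn)^2 + dom$r[op$rc]^2 <= field$nucleus$R^2
  n_steps <- ceiling(T_end / dt)
  times <- numeric(0)
  snaps <- list()
  mass <- numeric(0)
  scale0 <- max(cvec)
  push <- function(tnow, cvec, avec) {
    cm <- matrix(NA_real_, dom$nz, dom$nr); cm[dom$mask] <- cvec
    am <- matrix(NA_real_, dom$nz, dom$nr); am[dom$mask] <- avec
    snaps[[length(snaps) + 1L]] <<- list(cdk1 = cm, apc = am)
    times <<- c(times, tnow)
    mass <<- c(mass, sum(op$w * cvec))
  }
  push(0, cvec, avec)
  for (step in seq_len(n_steps)) {
    if (!is.null(sol_c))
      cvec <- as.numeric(Matrix::solve(sol_c, op$w * cvec))
    if (!is.null(sol_a))
      avec <- as.numeric(Matrix::solve(sol_a, op$w * avec))
    # reactions: exponential update, exact for frozen coefficients
    deg <- params$k0 + if (identical(params$degradation, "michaelis"))
      params$k1 * avec / (params$J + cvec)
    else params$k1 * avec / (params$J^2 + cvec^2)
    prod <- params$k2 * in_nuc
    ecd <- exp(-deg * dt)
    cvec <- cvec * ecd + ifelse(deg > 0, prod * (1 - ecd) / deg, prod * dt)
    gain <- params$k4 * avec^2 / (params$K^2 + avec^2) * cvec
    ea <- exp(-params$k3 * dt)
    avec <- if (params$k3 > 0)
      avec * ea + gain * (1 - ea) / params$k3 else avec + gain * dt
    if (any(!is.finite(cvec)) || any(!is.finite(avec)) ||
        max(cvec) > 1e6 * max(scale0, 1))
      stop(sprintf("instability detected at t = %g with dt = %g",
                   step * dt, dt))
    if (any(cvec < 0) || any(avec < 0)) {
      if (min(cvec, avec) < -1e-12 * scale0)
        warning("negative concentrations clipped")
      cvec <- pmax(cvec, 0); avec <- pmax(avec, 0)
    }
    if (step %% save_every == 0L || step == n_steps)
      push(step * dt, cvec, avec)
  }
  structure(list(snapshots = snaps, times = times, domain = dom,
                 mass = mass, params = params, nucleus = field$nucleus),
            class = "scw_gradient_series")
}

# arc length from the animal pole along the meridional contour, and contour
# sampling points at a given inward depth, parameterised by the polar angle
# from the +z (animal) axis.
.contour_samples <- function(dom, n_ang = 181L, depth = 0) {
  ang <- seq(0, pi, length.out = n_ang)
  # radial distance from centre to contour along each ray, by bisection
  ray_r <- vapply(ang, function(a) {
    f <- function(t) t * sin(a) - dom$rho(t * cos(a))
    hi <- max(abs(dom$zlim)) + dom$radius
    if (a < 1e-9) return(max(dom$zlim))
    if (abs(a - pi) < 1e-9) return(-min(dom$zlim))
    stats::uniroot(f, c(1e-6, hi))$root
  }, numeric(1))
  zc <- ray_r * cos(ang)
  rc <- ray_r * sin(ang)
  seg <- sqrt(diff(zc)^2 + diff(rc)^2)
  s <- c(0, cumsum(seg))
  zs <- (ray_r - depth) * cos(ang)
  rs <- (ray_r - depth) * sin(ang)
  list(angle = ang, s = s, z = zs, r = rs)
}

# bilinear interpolation of a domain matrix at (z, r) points, with fallback
# to the nearest in-domain cell
.interp_field <- function(dom, m, z, r) {
  gi <- (z - dom$z[1]) / dom$dz + 1
  gj <- (r - dom$r[1]) / dom$dr + 1
  vapply(seq_along(z), function(k) {
    i0 <- floor(gi[k]); j0 <- floor(gj[k])
    wi <- gi[k] - i0; wj <- gj[k] - j0
    acc <- 0; wtot <- 0
    for (di in 0:1) for (dj in 0:1) {
      i <- i0 + di; j <- j0 + dj
      if (i >= 1 && i <= dom$nz && j >= 1 && j <= dom$nr && !is.na(m[i, j])) {
        wgt <- (if (di == 1) wi else 1 - wi) * (if (dj == 1) wj else 1 - wj)
        acc <- acc + wgt * m[i, j]; wtot <- wtot + wgt
      }
    }
    if (wtot > 0) acc / wtot else {
      ii <- pmin(pmax(round(gi[k]), 1), dom$nz)
      jj <- pmin(pmax(round(gj[k]), 1), dom$nr)
      sub <- m[max(1, ii - 3):min(dom$nz, ii + 3),
               max(1, jj - 3):min(dom$nr, jj + 3)]
      mean(sub, na.rm = TRUE)
    }
  }, numeric(1))
}

#' Subcortical kymograph of the simulated cdk1-cyclinB field
#'
#' Samples cdk1 at a fixed depth beneath the cell surface, parameterised by
#' arc length along the meridional contour from the animal pole, at every
#' stored time point. The result is the same kymograph type the wavefront
#' tools consume.
#'
#' @param series an \code{scw_gradient_series}.
#' @param depth sampling depth beneath the surface (um).
#' @param n_ang number of polar-angle samples from animal (0) to vegetal
#'   (pi) pole.
#' @return an \code{scw_kymograph} with semantics \code{"fluorescence"}.
#' @export
subcortical_kymograph <- function(series, depth = 4, n_ang = 181L) {
  stopifnot(inherits(series, "scw_gradient_series"))
  dom <- series$domain
  if (depth >= 0.5 * min(dom$radius, diff(dom$zlim) / 2))
    stop("sampling depth too large for this domain")
  cs <- .contour_samples(dom, n_ang, depth)
  vals <- vapply(series$snapshots, function(sn)
    .interp_field(dom, sn$cdk1, cs$z, cs$r), numeric(n_ang))
  # drop duplicate arc positions at the exact poles if present
  kymograph(vals, s = cs$s, t = series$times, semantics = "fluorescence",
            meta = list(depth = depth))
}

#' Threshold front of the cdk1-cyclinB field
#'
#' The wave-guiding front is where cdk1 activity first drops below the
#' critical level \code{c_star}. Starting from the vegetal end of each time
#' column, the contiguous below-threshold region is located and its boundary
#' (linearly interpolated) is reported as arc length travelled from the
#' vegetal pole, with a least-squares speed fit as in
#' \code{\link{track_band}}.
#'
#' @param kymo an \code{scw_kymograph} whose s axis runs from the animal
#'   pole (0) to the vegetal pole (max s), as produced by
#'   \code{\link{subcortical_kymograph}}.
#' @param c_star critical concentration; must lie within the value range.
#' @param interior_frac only front positions within this central fraction of
#'   the pole-to-pole arc enter the speed fit.
#' @return an \code{scw_front_track} (positions = arc from the vegetal pole)
#'   with extra fields \code{initiation_s_from_animal},
#'   \code{initiation_time} (where/when the field first dips below
#'   \code{c_star}) and \code{degenerate} (first crossing happened
#'   everywhere at once).
#' @export
threshold_front <- function(kymo, c_star, interior_frac = 0.9) {
  stopifnot(inherits(kymo, "scw_kymograph"))
  V <- kymo$values
  rg <- range(V)
  if (c_star <= rg[1] || c_star >= rg[2])
    stop(sprintf("threshold %g never crossed (range [%g, %g])",
                 c_star, rg[1], rg[2]))
  s <- kymo$s
  smax <- max(s)
  nt <- ncol(V)
  pos <- rep(NA_real_, nt)
  first_t <- NA_real_; first_s <- NA_real_; degenerate <- FALSE
  for (j in seq_len(nt)) {
    below <- V[, j] < c_star
    if (!any(below)) next
    if (is.na(first_t)) {
      first_t <- kymo$t[j]
      first_s <- s[which.min(V[, j])]
      degenerate <- all(below)
    }
    # contiguous below-threshold run touching the vegetal end
    n <- length(below)
    if (!below[n]) next
    i <- n
    while (i > 1 && below[i - 1]) i <- i - 1
    if (i == 1) { pos[j] <- smax } else {
      # linear interpolation of the crossing between i-1 (above) and i
      f <- (c_star - V[i - 1, j]) / (V[i, j] - V[i - 1, j])
      s_cross <- s[i - 1] + f * (s[i] - s[i - 1])
      pos[j] <- smax - s_cross
    }
  }
  det <- which(!is.na(pos))
  if (length(det) == 0)
    stop("threshold never crossed from the vegetal side within the series")
  lo <- smax * (1 - interior_frac) / 2
  fit_idx <- det[pos[det] > lo & pos[det] < smax - lo]
  if (length(fit_idx) >= 3) {
    fit <- stats::lm(pos[fit_idx] ~ kymo$t[fit_idx])
    slope <- unname(stats::coef(fit)[2]) * 60
    icpt <- unname(stats::coef(fit)[1])
    r2 <- summary(fit)$r.squared
  } else {
    slope <- NA_real_; icpt <- NA_real_; r2 <- NA_real_
  }
  structure(list(times = kymo$t[det], positions = pos[det],
                 speed_um_min = slope, intercept = icpt, r_squared = r2,
                 duration_s = diff(range(kymo$t[det])), width_um = NA_real_,
                 detected = det, folded = TRUE,
                 initiation_s_from_animal = first_s,
                 initiation_time = first_t, degenerate = degenerate),
            class = "scw_front_track")
}
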
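test_that("icosphere meshes have the right combinatorics and volume", {
  m0 <- make_sphere_mesh(85, 0)
  expect_equal(nrow(m0$V), 12)
  expect_equal(nrow(m0$F), 20)
  expect_equal(mesh_euler(m0), 2)

  m3 <- make_sphere_mesh(85, 3)
  expect_equal(nrow(m3$V), 10 * 4^3 + 2)
  expect_equal(mesh_euler(m3), 2)
  expect_equal(mesh_volume(m3) / (4 / 3 * pi * 85^3), 1, tolerance = 0.01)

  # volume converges monotonically to the sphere volume
  vols <- vapply(0:3, function(k) mesh_volume(make_sphere_mesh(85, k)),
                 numeric(1))
  expect_true(all(diff(vols) > 0))
  expect_true(all(vols < 4 / 3 * pi * 85^3))
})

test_that("the tension band integrates to sigma_max * 2 * width / pi", {
  m <- make_sphere_mesh(85, 3)
  p <- shell_params(sigma_max = 0.4, band_width = 100, sigma_baseline = 0.05)
  i_pole <- which.max(m$Vref[, 3])  # animal pole vertex, outside the band
  expect_equal(tension_field(m, 0.5 * pi * 85, p, "band")[i_pole], 0.05,
               tolerance = 1e-12)
  expect_true(all(tension_field(m, -200, p, "band") == 0.05))
  # integrate sigma - baseline over l on a dense reference contour
  l <- seq(0, pi * 85, length.out = 20001)
  u <- (l - 0.5 * pi * 85) / 100
  sig <- 0.4 * ifelse(abs(u) <= 0.5, cos(pi * u), 0)
  integral <- sum(sig) * diff(l[1:2])
  expect_equal(integral, 0.4 * 2 * 100 / pi, tolerance = 1e-4)
  # per-vertex field matches the same profile
  sv <- tension_field(m, 0.5 * pi * 85, p, "band")
  phi <- acos(pmin(pmax(-m$Vref[, 3] / 85, -1), 1))
  uu <- (85 * phi - 0.5 * pi * 85) / 100
  expect_equal(sv, 0.05 + 0.4 * ifelse(abs(uu) <= 0.5, cos(pi * uu), 0),
               tolerance = 1e-9)
})

test_that("shell energy reproduces closed forms on the sphere", {
  p <- shell_params()
  for (k in 3:4) {
    m <- make_sphere_mesh(85, k)
    e <- shell_energy(m, p)
    expect_equal(e[["stretch"]], 0, tolerance = 1e-10)
    expect_equal(e[["shear"]], 0, tolerance = 1e-10)
    expect_equal(e[["volume"]], 0, tolerance = 1e-10)
    # discrete bending of a sphere: 8 pi kappa_b
    tol <- if (k >= 4) 0.02 else 0.01 * 5
    expect_equal(e[["bending"]] / (8 * pi * p$kappa_b), 1, tolerance = tol)
  }
  # doubling sigma doubles the tension term exactly
  m <- make_sphere_mesh(85, 2)
  sig <- tension_field(m, 100, p)
  e1 <- shell_energy(m, p, sigma = sig)
  e2 <- shell_energy(m, p, sigma = 2 * sig)
  expect_equal(e2[["tension"]], 2 * e1[["tension"]], tolerance = 1e-12)
  # degenerate triangle triggers an error
  bad <- m
  bad$V[bad$F[1, 2], ] <- bad$V[bad$F[1, 1], ]
  expect_error(shell_energy(bad, p), "degenerac")
})

test_that("the local finite-difference gradient matches a full-mesh one", {
  m <- make_sphere_mesh(10, 1)
  p <- shell_params(K_alpha = 0.05, mu = 0.05, k_V = 1e-5, sigma_max = 0.5,
                    band_width = 12)
  sig <- tension_field(m, 0.5 * pi * 10, p)
  V0 <- mesh_volume(m)
  c0 <- colMeans(m$Vref)
  n <- nrow(m$V)
  # perturb away from the symmetric sphere so all terms are active
  set.seed(3)
  m$V <- m$V + matrix(rnorm(3 * n, 0, 0.02), n)
  fn <- function(par) scwave:::cpp_shell_objective(
    matrix(par, n, 3), m$F, m$Vref, sig, p$kappa_b, p$K_alpha, p$mu,
    p$k_V, V0, p$pin_weight, c0)
  gr <- scwave:::cpp_shell_gradient(m$V, m$F, m$Vref, sig, p$kappa_b,
                                    p$K_alpha, p$mu, p$k_V, V0,
                                    p$pin_weight, c0, 1e-4)
  x <- as.vector(m$V)
  h <- 1e-5
  gnum <- vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(gr - gnum)) / max(abs(gnum)), 1e-5)
})

test_that("a uniform-tension sphere is stationary under relaxation", {
  m <- make_sphere_mesh(85, 4)
  p <- shell_params()
  r <- relax_shape(m, p, sigma = rep(2e-4, nrow(m$V)))
  disp <- max(sqrt(rowSums((r$V - m$V)^2)))
  expect_lt(disp / 85, 1e-3)
  e <- attr(r, "energy")
  expect_lt(abs(attr(e, "enclosed_volume") - mesh_volume(m)) / mesh_volume(m),
            0.01)
})

test_that("an equatorial band produces a mirror-symmetric waist", {
  m <- make_sphere_mesh(85, 3)
  p <- shell_params()
  sig <- tension_field(m, 0.5 * pi * 85, p)
  r <- suppressWarnings(relax_shape(m, p, sigma = sig))
  o <- mesh_to_outline(r)
  # indented at the equator
  expect_gt(1 - min(o$r) / mean(o$r), 0.03)
  # mirror symmetry about the equatorial plane: r(theta) ~ r(pi - theta)
  rs <- o$r
  n <- length(rs)
  mirrored <- rs[(n / 2):1]          # theta -> pi - theta for first half
  expect_lt(max(abs(rs[1:(n / 2)] - mirrored)) / 85, 0.02)
  # energy is non-increasing relative to the starting sphere
  e_sphere <- scwave:::cpp_shell_objective(
    m$V, m$F, m$Vref, sig, p$kappa_b, p$K_alpha, p$mu, p$k_V,
    mesh_volume(m), p$pin_weight, colMeans(m$Vref))
  e_rel <- scwave:::cpp_shell_objective(
    r$V, r$F, r$Vref, sig, p$kappa_b, p$K_alpha, p$mu, p$k_V,
    mesh_volume(m), p$pin_weight, colMeans(m$Vref))
  expect_lt(e_rel, e_sphere)
})

test_that("band sweeps are independent of the sweep direction", {
  m <- make_sphere_mesh(85, 2)
  p <- shell_params()
  arcs <- c(0.3, 0.5, 0.7) * pi * 85
  fw <- suppressWarnings(sweep_band(m, p, arcs))
  bw <- suppressWarnings(sweep_band(m, p, rev(arcs)))
  for (i in seq_along(arcs)) {
    d <- fw$meshes[[i]]$V - bw$meshes[[length(arcs) + 1 - i]]$V
    expect_lt(max(sqrt(rowSums(d^2))) / 85, 5e-3)
  }
})

test_that("meridional outlines are plane-independent and perimeter-consistent", {
  m <- make_sphere_mesh(85, 3)
  o <- mesh_to_outline(m)
  expect_lt(max(abs(o$r - 85)) / 85, 0.01)
  o2 <- mesh_to_outline(m, plane_angle = pi / 3)
  expect_lt(max(abs(o$r - o2$r)) / 85, 0.01)
  # perimeter of the section is within 1% of the circle perimeter
  expect_equal(outline_perimeter(o), 2 * pi * 85, tolerance = 0.01 * 2 * pi * 85)
  expect_error(mesh_to_outline(structure(list(
    V = m$V + matrix(c(0, 1e5, 0), nrow(m$V), 3, byrow = TRUE),
    F = m$F, Vref = m$Vref, sigma = m$sigma, radius = 85),
    class = "scw_trimesh")), "empty")
})

test_that("relaxed shapes stay volume-true and refine consistently", {
  p <- shell_params()
  e_tot <- c()
  for (k in 3:4) {
    m <- make_sphere_mesh(85, k)
    sig <- tension_field(m, 0.5 * pi * 85, p)
    r <- suppressWarnings(relax_shape(m, p, sigma = sig))
    e <- attr(r, "energy")
    expect_lt(abs(attr(e, "enclosed_volume") - mesh_volume(m)) /
                mesh_volume(m), 0.01)
    e_tot <- c(e_tot, e[["total"]])
  }
  expect_lt(abs(diff(e_tot)) / e_tot[2], 0.03)
})

test_that("meshes round-trip to OFF files", {
  m <- make_sphere_mesh(10, 1)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "m.off")
  write_mesh_off(m, f)
  lines <- readLines(f)
  expect_equal(lines[1], "OFF")
  expect_equal(as.integer(strsplit(lines[2], " ")[[1]][1:2]),
               c(nrow(m$V), nrow(m$F)))
})
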
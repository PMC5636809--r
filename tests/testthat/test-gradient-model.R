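test_that("axisymmetric domains report geometry faithfully", {
  dom <- build_domain("sphere", radius = 85, nz = 120, nr = 60)
  expect_equal(dom$av_distance, 170)
  # meridional half-plane area -> half the circle cross-section
  expect_equal(2 * sum(dom$mask) * dom$dz * dom$dr, pi * 85^2,
               tolerance = 0.01 * pi * 85^2)
  pro <- build_domain("prolate", radius = 85, av_scale = 1.3)
  expect_equal(pro$av_distance, 221)
  expect_error(build_domain("prolate", av_scale = 0.9), "av_scale")
  obl <- build_domain("oblate", radius = 85, av_scale = 0.8)
  expect_equal(obl$av_distance, 136)
})

test_that("initial states hold the nuclear bolus and its mass bookkeeping", {
  dom <- build_domain("sphere", radius = 85, nz = 120, nr = 60)
  gp <- gradient_params()
  f <- initial_state(dom, gp)
  expect_true(all(f$cdk1[dom$mask] %in% c(gp$cytoplasmic_level,
                                          gp$nuclear_level)))
  op <- scwave:::.fv_operator(dom)
  mass <- sum(op$w * f$cdk1[dom$mask])
  V_cell <- sum(op$w)
  zc <- dom$z[op$zc]; rc <- dom$r[op$rc]
  zn <- f$nucleus$z
  V_nuc <- sum(op$w[(zc - zn)^2 + rc^2 <= gp$R_nucleus^2])
  expect_equal(mass,
               gp$cytoplasmic_level * V_cell +
                 (gp$nuclear_level - gp$cytoplasmic_level) * V_nuc,
               tolerance = 1e-9)
  # uniform when the two levels coincide
  gpu <- gradient_params(nuclear_level = 1, cytoplasmic_level = 1)
  fu <- initial_state(dom, gpu)
  expect_true(all(fu$cdk1[dom$mask] == 1))
  # nucleus that pokes out of the cell is rejected
  expect_error(initial_state(dom, gp, sources = list(
    list(z = 80, R = 35, level = 5))), "outside")
})

test_that("reaction-free diffusion conserves cdk1 mass", {
  dom <- build_domain("sphere", radius = 85, nz = 100, nr = 50)
  gp <- gradient_params(k0 = 0, k1 = 0, k2 = 0, k3 = 0, k4 = 0)
  ser <- run_gradient(initial_state(dom, gp), gp, dt = 10, T_end = 1000,
                      save_every = 10)
  expect_lt(max(abs(ser$mass / ser$mass[1] - 1)), 0.001)
  # concentrations stay non-negative
  expect_true(all(ser$snapshots[[length(ser$snapshots)]]$cdk1 >= 0,
                  na.rm = TRUE))
})

test_that("basal-degradation-only dynamics match exponential decay pointwise", {
  dom <- build_domain("sphere", radius = 85, nz = 100, nr = 50)
  gp <- gradient_params(D_cdk1 = 0, D_APC = 0, k1 = 0, k2 = 0, k4 = 0,
                        k0 = 2e-4)
  f0 <- initial_state(dom, gp)
  t_end <- 3 / gp$k0
  ser <- run_gradient(f0, gp, dt = t_end / 50, T_end = t_end, save_every = 50)
  last <- ser$snapshots[[length(ser$snapshots)]]$cdk1
  expected <- f0$cdk1 * exp(-gp$k0 * t_end)
  expect_lt(max(abs(last / expected - 1), na.rm = TRUE), 0.005)
})

test_that("APC feedback accelerates cdk1 decay everywhere", {
  dom <- build_domain("sphere", radius = 85, nz = 100, nr = 50)
  gp_slow <- gradient_params(k1 = 0, k4 = 0)         # basal decay only
  gp_fast <- gradient_params(k4 = 9e-3, K = 0.1)     # strong, early feedback
  s1 <- run_gradient(initial_state(dom, gp_slow), gp_slow, dt = 10,
                     T_end = 2400, save_every = 240)
  s2 <- run_gradient(initial_state(dom, gp_fast), gp_fast, dt = 10,
                     T_end = 2400, save_every = 240)
  a <- s1$snapshots[[length(s1$snapshots)]]$cdk1
  b <- s2$snapshots[[length(s2$snapshots)]]$cdk1
  expect_true(all(b <= a + 1e-9, na.rm = TRUE))
})

test_that("subcortical kymographs sample the field along the contour", {
  dom <- build_domain("sphere", radius = 85, nz = 120, nr = 60)
  gp <- gradient_params(nuclear_level = 1, cytoplasmic_level = 1)
  f <- initial_state(dom, gp)
  ser <- structure(list(snapshots = list(list(cdk1 = f$cdk1)), times = 0,
                        domain = dom), class = "scw_gradient_series")
  km <- subcortical_kymograph(ser, depth = 4, n_ang = 61)
  expect_true(all(abs(km$values - 1) < 1e-9))
  expect_error(subcortical_kymograph(ser, depth = 80), "depth")

  # nuclear bolus at the animal pole dominates the t = 0 profile at angle 0
  gp2 <- gradient_params()
  f2 <- initial_state(dom, gp2)
  ser2 <- structure(list(snapshots = list(list(cdk1 = f2$cdk1)), times = 0,
                         domain = dom), class = "scw_gradient_series")
  km2 <- subcortical_kymograph(ser2, depth = 4, n_ang = 61)
  expect_equal(which.max(km2$values[, 1]), 1)
})

test_that("threshold fronts initiate opposite the nucleus and advance monotonically", {
  g <- gradient_run_default()
  km <- g$kymo
  expect_error(threshold_front(km, 1e6), "never crossed")
  fr <- threshold_front(km, 0.4)
  smax <- max(km$s)
  # first sub-threshold point is the vegetal pole (farthest from the nucleus)
  expect_lt(abs(fr$initiation_s_from_animal - smax), 0.05 * smax)
  expect_false(fr$degenerate)
  # positions (arc from the vegetal pole) advance monotonically
  expect_true(all(diff(fr$positions) > -0.02 * smax))
  expect_gt(fr$speed_um_min, 0)
  # pre-collapse angular profile decreases from animal to vegetal
  j <- max(which(km$t <= 900))
  expect_true(all(diff(km$values[, j]) < 0.02))
})

test_that("uniform decay crosses the threshold everywhere at once (flagged)", {
  dom <- build_domain("sphere", radius = 85, nz = 100, nr = 50)
  gp <- gradient_params(D_cdk1 = 0, D_APC = 0, k1 = 0, k2 = 0, k4 = 0,
                        k0 = 2e-4, nuclear_level = 1)
  ser <- run_gradient(initial_state(dom, gp), gp, dt = 60, T_end = 6000,
                      save_every = 5)
  km <- subcortical_kymograph(ser, depth = 4, n_ang = 61)
  fr <- threshold_front(km, 0.5)
  expect_true(fr$degenerate)
})

test_that("two polar boluses make the front initiate near the equator", {
  dom <- build_domain("sphere", radius = 85, nz = 160, nr = 80)
  gp <- gradient_params(k2 = 0)  # one-time injection, no ongoing production
  zn <- max(dom$zlim) - 1.05 * gp$R_nucleus
  src <- list(list(z = zn, R = gp$R_nucleus, level = gp$nuclear_level),
              list(z = -zn, R = gp$R_nucleus, level = gp$nuclear_level))
  ser <- run_gradient(initial_state(dom, gp, sources = src), gp, dt = 10,
                      T_end = 4800, save_every = 6)
  km <- subcortical_kymograph(ser, depth = 4, n_ang = 121)
  jt <- min(which(apply(km$values, 2, min) < 0.4))
  s_init <- km$s[which.min(km$values[, jt])]
  expect_lt(abs(s_init - max(km$s) / 2), 0.15 * max(km$s))
})

test_that("grid refinement barely moves the front arrival time", {
  gp <- gradient_params()
  arrive <- function(nz, nr) {
    dom <- build_domain("sphere", radius = 85, nz = nz, nr = nr)
    ser <- run_gradient(initial_state(dom, gp), gp, dt = 10, T_end = 4800,
                        save_every = 1)
    km <- subcortical_kymograph(ser, depth = 4, n_ang = 121)
    fr <- threshold_front(km, 0.4)
    fr$times[fr$positions > 0.98 * max(km$s)][1]
  }
  t_coarse <- arrive(100, 50)
  t_fine <- arrive(200, 100)
  expect_lt(abs(t_coarse - t_fine) / t_fine, 0.02)
})
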
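# construct a kymograph holding a clean half-sine ridge moving at speed v
ridge_kymo <- function(v_um_min = 42, dt = 10, n_s = 120, n_t = 30,
                       ds = 2.5, width = 60, amp = 30, base = 100, sd = 0) {
  s <- (seq_len(n_s) - 0.5) * ds
  t <- (seq_len(n_t) - 1) * dt
  V <- outer(s, t, function(ss, tt) {
    u <- (ss - v_um_min / 60 * tt) / width
    base + amp * ifelse(abs(u) <= 0.5, cos(pi * u), 0)
  })
  if (sd > 0) V <- V + matrix(rnorm(length(V), 0, sd), nrow(V))
  kymograph(V, s, t, semantics = "curvature-radius")
}

test_that("a constructed ridge advancing 7 um per frame gives 42 um/min", {
  km <- ridge_kymo(v_um_min = 42, dt = 10)
  tr <- track_band(km)
  expect_equal(tr$speed_um_min, 42, tolerance = 1e-3)
  expect_gt(tr$r_squared, 0.9999)
  # half-sine FWHM recovery: width = 1.5 * FWHM
  expect_equal(tr$width_um, 60, tolerance = 0.15)
})

test_that("band tracking errors on static kymographs and shrugs off offsets", {
  set.seed(1)
  V <- matrix(rnorm(80 * 15, 100, 1), 80)
  km <- kymograph(V, s = 1:80, t = seq(0, 140, 10))
  expect_error(track_band(km), "no travelling wave")

  km1 <- ridge_kymo()
  km2 <- km1; km2$values <- km2$values + 55
  t1 <- track_band(km1); t2 <- track_band(km2)
  expect_equal(t1$speed_um_min, t2$speed_um_min, tolerance = 1e-9)
})

test_that("pure-translation kymographs are tracked at the true speed", {
  for (v in c(20, 50)) {
    km <- ridge_kymo(v_um_min = v, n_s = 200, ds = 2, n_t = 25)
    tr <- track_band(km)
    expect_equal(tr$speed_um_min, v, tolerance = 0.02 * v)
  }
})

test_that("isolines are extracted along analytic level sets", {
  # value = s + t: the isoline at level L is the anti-diagonal s + t = L
  # (L off the lattice so the contour interpolates cleanly within cells)
  s <- seq(0, 50, by = 1); t <- seq(0, 50, by = 1)
  km <- kymograph(outer(s, t, `+`), s, t, semantics = "fluorescence")
  iso <- extract_isoline(km, 50.5)
  expect_true(all(abs(iso$s + iso$t - 50.5) < 1e-9))
  expect_error(extract_isoline(km, 1000), "outside")

  # level at the global maximum: degenerate single point
  km2 <- kymograph(outer(s, t, function(a, b) -(a - 25)^2 - (b - 25)^2),
                   s, t, semantics = "fluorescence")
  iso2 <- extract_isoline(km2, 0)
  expect_true(iso2$degenerate)
  expect_lt(max(abs(c(iso2$s, iso2$t) - 25)), 1)
})

test_that("nested isolines of a monotone-decay kymograph do not cross", {
  s <- seq(0, 100, by = 2); t <- seq(0, 300, by = 10)
  km <- kymograph(outer(s, t, function(ss, tt) exp(-tt / 100) * (1 + ss / 100)),
                  s, t, semantics = "fluorescence")
  lo <- extract_isoline(km, 0.5)
  hi <- extract_isoline(km, 0.8)
  # single-valued in t per s, and the higher level is crossed earlier
  t_lo <- approx(lo$s, lo$t, xout = s, ties = mean, rule = 1)$y
  t_hi <- approx(hi$s, hi$t, xout = s, ties = mean, rule = 1)$y
  ok <- !is.na(t_lo) & !is.na(t_hi)
  expect_gt(sum(ok), 10)
  expect_true(all(t_hi[ok] < t_lo[ok]))
})

test_that("isoline-wave overlap reports rms offsets and correlation", {
  tr <- structure(list(times = seq(0, 90, 10), positions = seq(5, 95, 10),
                       speed_um_min = 60, folded = FALSE),
                  class = "scw_front_track")
  iso_same <- structure(list(level = 1, s = tr$positions, t = tr$times,
                             degenerate = FALSE), class = "scw_isoline")
  ov <- isoline_wave_overlap(iso_same, tr)
  expect_equal(ov$rms_um, 0)
  expect_equal(ov$pearson_r, 1)

  iso_off <- iso_same; iso_off$s <- iso_off$s + 7
  ov2 <- isoline_wave_overlap(iso_off, tr)
  expect_equal(ov2$rms_um, 7)
  expect_equal(ov2$pearson_r, 1)

  iso_short <- iso_same; iso_short$t <- iso_short$t + 1000
  expect_error(isoline_wave_overlap(iso_short, tr), "fewer than 3")
})

test_that("speed-versus-distance tables and correlations are computed", {
  mk <- function(speed) structure(list(speed_um_min = speed),
                                  class = "scw_front_track")
  runs <- list(list(distance = 140, track = mk(30)),
               list(distance = 170, track = mk(42)),
               list(distance = 220, track = mk(62)))
  sv <- speed_vs_distance(runs)
  expect_equal(nrow(sv$table), 3)
  expect_gt(sv$pearson_r, 0.99)

  runs_flat <- list(list(distance = 100, track = mk(30)),
                    list(distance = 100, track = mk(40)),
                    list(distance = 100, track = mk(50)))
  expect_error(speed_vs_distance(runs_flat), "undefined")

  # perfectly linear set
  runs_lin <- lapply(1:4, function(i)
    list(distance = 100 + 20 * i, track = mk(10 + 2 * i)))
  expect_equal(speed_vs_distance(runs_lin)$pearson_r, 1, tolerance = 1e-12)
})

test_that("folded tracking recovers the vegetal-to-animal march on mirrored ridges", {
  # full-perimeter kymograph: two mirrored ridges about the vegetal pole
  P <- 500
  s <- seq(1.25, P - 1.25, by = 2.5)
  t <- seq(0, 290, by = 10)
  v <- 45 / 60
  # band enters the surface only after the baseline columns
  V <- outer(s, t, function(ss, tt) {
    arc_veg <- abs(ss - P / 2)
    u <- (arc_veg - v * (tt - 60)) / 80
    100 + 25 * ifelse(abs(u) <= 0.5, cos(pi * u), 0)
  })
  km <- kymograph(V, s, t, semantics = "curvature-radius")
  tr <- track_band(km, fold = TRUE)
  expect_equal(tr$speed_um_min, 45, tolerance = 0.05 * 45)
})
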
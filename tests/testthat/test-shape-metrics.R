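test_that("outline smoothing reproduces circles, noisy circles and ellipses", {
  sm <- smooth_outline(circle_outline(85))
  expect_lt(max(abs(sm$r - 85)), 1e-6)
  expect_lt(sm$residual_rms, 1e-6)

  smn <- smooth_outline(circle_outline(85, n = 360, sd = 0.3, seed = 5))
  expect_lt(max(abs(smn$r - 85)), 0.3)

  sme <- smooth_outline(ellipse_outline(100, 80), k = 60)
  th <- sme$theta
  r_true <- 100 * 80 / sqrt((80 * cos(th))^2 + (100 * sin(th))^2)
  expect_lt(max(abs(sme$r - r_true) / r_true), 0.005)

  o <- circle_outline(85)
  o$theta <- o$theta[1:10]; o$r <- o$r[1:10]
  expect_error(smooth_outline(o), "too few")
})

test_that("curvature profiles match analytic circles and ellipses", {
  pr <- curvature_profile(smooth_outline(circle_outline(85)), seg_len = 2)
  expect_true(all(abs(pr$radii - 85) / 85 < 0.001))
  expect_equal(length(pr$s), round(pr$perimeter / 2))

  pre <- curvature_profile(smooth_outline(ellipse_outline(100, 80), k = 60),
                           seg_len = 2)
  # radius of curvature at the end of the major axis is b^2/a = 64
  at_major <- pre$radii[c(1, length(pre$radii))]
  expect_lt(abs(at_major[1] - 64) / 64, 0.01)
  # and at the end of the minor axis a^2/b = 125
  at_minor <- pre$radii[which.min(abs(pre$s - pre$perimeter / 4))]
  expect_lt(abs(at_minor - 125) / 125, 0.015)

  expect_error(curvature_profile(smooth_outline(circle_outline(85)),
                                 seg_len = 100), "seg_len")
})

test_that("flat arcs are reported at the radius cap", {
  # squircle-like outline: |cos|^(2/n) superellipse has near-flat sides
  th <- 2 * pi * (seq_len(720) - 1L) / 720
  n <- 8
  r <- (abs(cos(th))^n + abs(sin(th))^n)^(-1 / n) * 50
  o <- outline(th, r, c(0, 0))
  pr <- curvature_profile(smooth_outline(o, k = 80), seg_len = 2, r_max = 100)
  expect_true(any(abs(pr$radii) == 100))
  expect_true(all(abs(pr$radii) <= 100))
})

test_that("turning number of simple outlines is one", {
  expect_equal(turning_number(smooth_outline(circle_outline(85))), 1,
               tolerance = 0.01)
  expect_equal(turning_number(smooth_outline(ellipse_outline(120, 60), k = 60)),
               1, tolerance = 0.01)
  set.seed(2)
  expect_equal(turning_number(smooth_outline(circle_outline(85, sd = 0.5))),
               1, tolerance = 0.01)
})

test_that("relative curvature is zero for identical frames and tracks the band", {
  pr <- curvature_profile(smooth_outline(circle_outline(85)))
  rel <- relative_curvature(list(pr, pr))
  expect_true(all(rel[[2]]$kappa == 0))

  p <- band_movie_params(band_depth = 0.1, image_size = 512, band_speed = 60)
  R <- p$cell_radius
  t_mid <- (pi / 2 * R) / (p$band_speed / 60)
  # moderate smoothing: the deformation has a slope kink at the band edges
  # which stronger bases resolve into spurious curvature spikes
  profs <- lapply(c(-100, t_mid), function(t)
    curvature_profile(smooth_outline(true_outline(p, t, n = 720), k = 16)))
  rel2 <- relative_curvature(profs)
  dk <- rel2[[2]]$kappa
  # flattening = most negative curvature change; the band edges carry small
  # positive slope-kink spikes, so track the signed minimum
  s_ext <- rel2[[2]]$s[which.min(dk)]
  # extremum of the curvature change lies within band_width/4 of the band
  # centre (a quarter-turn from the vegetal pole, on either side)
  P <- rel2[[2]]$perimeter
  arc_veg <- abs(s_ext - P / 2)               # arc from vegetal pole
  expect_lt(abs(arc_veg - pi / 2 * R), p$band_width / 4)
})

test_that("kymograph assembly preserves values and axes", {
  pr <- curvature_profile(smooth_outline(circle_outline(85)))
  km1 <- build_kymograph(list(pr), frame_interval = 10)
  expect_equal(ncol(km1$values), 1)
  expect_identical(km1$values[, 1], pr$radii)

  km3 <- build_kymograph(list(pr, pr, pr), frame_interval = 10)
  expect_equal(km3$t, c(0, 10, 20))
  expect_identical(km3$values[, 3], pr$radii)
  expect_equal(km3$meta$r_max, pr$r_max)
})

test_that("wave-strength statistic behaves on null and band movies", {
  set.seed(9)
  km <- kymograph(matrix(rnorm(50 * 20, 100, 3), 50), s = 1:50, t = 1:20)
  expect_error(scw_strength(km, 1:5, 4:8), "overlap")
  expect_error(scw_strength(km, 1:5, 6:9), "equal length")
  expect_identical(scw_strength(km, 1:5, 11:15),
                   stats::var(as.vector(km$values[, 1:5])) -
                     stats::var(as.vector(km$values[, 11:15])))

  # static noisy movie: strength within 3 bootstrap sd of zero
  st <- scw_strength(km, 1:8, 12:19)
  boots <- replicate(200, {
    cols <- sample(20)
    scw_strength(km, cols[1:8], cols[9:16])
  })
  expect_lt(abs(st), 3 * stats::sd(boots))

  # automatic window selection flags the high-variance epoch
  V <- matrix(rnorm(50 * 20, 100, 1), 50)
  V[, 9:12] <- V[, 9:12] + rnorm(50 * 4, 0, 15)
  kmv <- kymograph(V, s = 1:50, t = seq(0, 190, by = 10))
  win <- auto_windows(kmv, duration = 40)
  expect_true(all(9:12 %in% win$scw_window))
  expect_gt(scw_strength(kmv, win$scw_window, win$baseline_window), 0)
})

test_that("intensity rings share the curvature segment grid and conserve totals", {
  # synthetic frame: circle with a bright cortical rim, gain on one side
  n <- 200; R_px <- 70
  ctr <- (n + 1) / 2
  X <- matrix(seq_len(n), n, n); Y <- matrix(seq_len(n), n, n, byrow = TRUE)
  rp <- sqrt((X - ctr)^2 + (Y - ctr)^2)
  th <- atan2(Y - ctr, X - ctr)
  img <- 0.05 + 1 * (abs(rp - R_px) <= 2) * ifelse(cos(th) > 0.5, 2, 1)
  o <- circle_outline(R_px, n = 256)
  o$centroid <- c(ctr, ctr)
  sm <- smooth_outline(o)
  pr <- curvature_profile(sm, seg_len = 4)
  rings <- intensity_rings(img, sm, pr, cortical_width = 4,
                           subcortical_band = 8)
  expect_length(rings$cortical, length(pr$s))
  # gain region (theta near 0 = first and last segments) is brighter
  ngl <- length(pr$s)
  bright <- c(seq_len(ngl %/% 8), (ngl - ngl %/% 8):ngl)
  dim_ <- seq(ngl %/% 3, 2 * ngl %/% 3)
  expect_gt(min(rings$cortical[bright], na.rm = TRUE),
            max(rings$cortical[dim_], na.rm = TRUE))
  # bookkeeping: sum(count * mean) equals the summed pixel intensity in ring
  cal <- sm$calibration
  rhat <- 70
  depth_ok <- (rp <= rhat) & (rp > rhat - 4)
  expect_equal(sum(rings$cortical * rings$cortical_n, na.rm = TRUE),
               sum(img[depth_ok]), tolerance = 0.03)
  # uniform image: all segments equal
  ru <- intensity_rings(matrix(2, n, n), sm, pr, 4, 8)
  expect_true(all(abs(ru$cortical - 2) < 1e-12, na.rm = TRUE))
  expect_error(intensity_rings(img, sm, pr, 40, 40), "centroid")
})

test_that("wave strength is invariant to rigid translation of the movie", {
  p <- small_movie_params(n_frames = 8)
  mv <- render_movie(p)
  outl <- suppressWarnings(segment_stack(mv$density, levelset_params(),
                                         calibration = p$pixel_size))
  shifted <- lapply(outl, function(o) { o$centroid <- o$centroid + c(5, -3); o })
  km1 <- curvature_kymographs(outl, p$frame_interval)$radius_kymo
  km2 <- curvature_kymographs(shifted, p$frame_interval)$radius_kymo
  s1 <- scw_strength(km1, 5:8, 1:4)
  s2 <- scw_strength(km2, 5:8, 1:4)
  expect_equal(s1, s2, tolerance = 1e-9)
})
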
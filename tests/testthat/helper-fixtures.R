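# Shared fixtures, built in code. Heavy objects are computed once per test
# run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# binary disk image, package [x, y] convention
make_disk <- function(n = 256, R = 100, noise = 0, bg = 0.1, fg = 1,
                      center = NULL) {
  ctr <- if (is.null(center)) c((n + 1) / 2, (n + 1) / 2) else center
  X <- matrix(seq_len(n), n, n)
  Y <- matrix(seq_len(n), n, n, byrow = TRUE)
  img <- bg + (fg - bg) * (((X - ctr[1])^2 + (Y - ctr[2])^2) <= R^2)
  if (noise > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, noise * (fg - bg)), n)
  img
}

# exact polar samples of an axis-aligned ellipse (a along x, b along y)
ellipse_outline <- function(a = 100, b = 80, n = 256, calibration = 1) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  outline(th, r, centroid = c(0, 0), calibration = calibration)
}

circle_outline <- function(R = 85, n = 256, sd = 0, calibration = 1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- rep(R, n)
  if (sd > 0) r <- r + stats::rnorm(n, 0, sd)
  outline(th, r, centroid = c(0, 0), calibration = calibration)
}

# small, fast synthetic movie for unit tests (not the acceptance conditions)
small_movie_params <- function(image_size = 144, pixel_size = 1.5,
                               n_frames = 10, frame_interval = 30,
                               band_depth = 0.12, noise_gaussian_sd = 0.01,
                               noise_poisson_scale = 500, ...) {
  band_movie_params(image_size = image_size, pixel_size = pixel_size,
                    n_frames = n_frames, frame_interval = frame_interval,
                    band_depth = band_depth,
                    noise_gaussian_sd = noise_gaussian_sd,
                    noise_poisson_scale = noise_poisson_scale,
                    start_time = -30, seed = 7L, ...)
}

# default shell band sweep (subdivision 3, baseline frame first), cached
shell_band_sweep <- function() fixture("shell_band_sweep", function() {
  m <- make_sphere_mesh(85, 3)
  p <- shell_params(sigma_baseline = 2e-4)
  arcs <- c(-60, seq(0.1, 0.7, length.out = 7) * pi * 85)
  suppressWarnings(sweep_band(m, p, arcs))
})

shell_front_sweep <- function() fixture("shell_front_sweep", function() {
  m <- make_sphere_mesh(85, 3)
  p <- shell_params(sigma_baseline = 2e-4)
  arcs <- c(-60, seq(0.1, 0.7, length.out = 7) * pi * 85)
  suppressWarnings(sweep_band(m, p, arcs, profile = "front"))
})

# default gradient run on the standard sphere, cached
gradient_run_default <- function() fixture("gradient_run_default", function() {
  dom <- build_domain("sphere", radius = 85, nz = 200, nr = 100)
  gp <- gradient_params()
  ser <- run_gradient(initial_state(dom, gp), gp, dt = 10, T_end = 4200,
                      save_every = 3)
  list(domain = dom, params = gp, series = ser,
       kymo = subcortical_kymograph(ser, depth = 4, n_ang = 121))
})
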
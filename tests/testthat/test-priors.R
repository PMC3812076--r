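test_that("speed KDE integrates to one and beats a histogram on Weibull data", {
  set.seed(61)
  x <- rweibull(1e4, 2, 45)
  x <- x[x <= 100]
  d <- kde_speed(x, v_max = 100)
  expect_equal(runstop:::density_integral(d), 1, tolerance = 1e-3)

  truth <- function(v) dweibull(v, 2, 45) / pweibull(100, 2, 45)
  ise_kde <- sum((d$values - truth(d$grid))^2 * diff(d$grid)[1])
  br <- seq(0, 100, length.out = 51)
  h <- hist(x, breaks = br, plot = FALSE)
  hval <- approx(h$mids, h$density, xout = d$grid, rule = 2)$y
  ise_hist <- sum((hval - truth(d$grid))^2 * diff(d$grid)[1])
  expect_lt(ise_kde, ise_hist)
})

test_that("speed KDE copes with degenerate and boundary-heavy samples", {
  d <- kde_speed(rep(3.7, 500), v_max = 10)
  expect_equal(runstop:::density_integral(d), 1, tolerance = 1e-3)
  expect_equal(d$grid[which.max(d$values)], 3.7, tolerance = 0.1)

  set.seed(62)
  x <- abs(rnorm(2e4, 5, 1))
  d <- kde_speed(x, v_max = 20)
  expect_equal(d$grid[which.max(d$values)], 5, tolerance = 0.2)
  expect_error(kde_speed(numeric(0), 10), "empty")
  expect_error(kde_speed(c(1, 50), v_max = 10), "v_max")
})

test_that("circular KDE is periodic and consistent", {
  set.seed(63)
  u <- runif(2e4, -pi, pi)
  d <- kde_angle(u)
  expect_equal(runstop:::density_integral(d), 1, tolerance = 1e-2)
  expect_lt(max(abs(d$values - 1 / (2 * pi))), 0.2 / (2 * pi))

  # mass clustered at the wrap point must not leak a mode to zero
  x <- wrap_angle(pi + rnorm(5000, 0, 0.1))
  d <- kde_angle(x)
  at <- function(a) approx(d$grid, d$values, a)$y
  expect_gt(at(pi - 0.01), 1)
  expect_lt(at(0), 0.01)
  expect_equal(runstop:::density_integral(d), 1, tolerance = 1e-2)

  # total variation distance to a wrapped normal decreases with n
  wn <- function(a) {
    k <- -3:3
    rowSums(vapply(k, function(kk) dnorm(a + 2 * pi * kk, 0.5, 0.7), a))
  }
  tv <- vapply(c(200, 20000), function(n) {
    x <- wrap_angle(rnorm(n, 0.5, 0.7))
    d <- kde_angle(x)
    sum(abs(d$values - wn(d$grid))) * diff(d$grid)[1] / 2
  }, 0)
  expect_lt(tv[2], tv[1])
})

test_that("observation model wires mutant densities to the right state pairs", {
  set.seed(64)
  nm <- add_noise(simulate_tracks(sim_config(
    n_tracks = 30, n_frames = 100, variant = "non_motile", seed = 64))$tracks,
    0.1, seed = 65)
  nc <- add_noise(simulate_tracks(sim_config(
    n_tracks = 30, n_frames = 100, variant = "non_chemotactic",
    seed = 66))$tracks, 0.1, seed = 67)
  m <- build_observation_model(nm, nc, v_max = 100)

  # identical source data -> identical angle densities for matched pairs
  m2 <- build_observation_model(nm, nm, v_max = 100)
  expect_identical(m2$angle_nonmotile$values, m2$angle_nonchemotactic$values)
  for (th in c(-2, 0.3, 3)) {
    expect_equal(runstop:::om_angle(m2, 1, 1, th),
                 runstop:::om_angle(m2, 2, 2, th))
  }

  # stop/run speed densities come from the right strains: the stop density
  # peaks at the noise scale (Rayleigh mode sqrt(2)*sigma/dt), the run
  # density at the swimming speed
  mode_stop <- m$speed_stop$grid[which.max(m$speed_stop$values)]
  expect_equal(mode_stop, sqrt(2) * 0.1 / 0.02, tolerance = 0.35)
  mode_run <- m$speed_run$grid[which.max(m$speed_run$values)]
  expect_gt(mode_run, 25)

  # pair mapping: stop-involving pairs use the non-motile density
  for (pair in list(c(1, 1), c(2, 1), c(1, 2))) {
    expect_equal(runstop:::om_angle(m, pair[1], pair[2], 1.1),
                 approx(m$angle_nonmotile$grid, m$angle_nonmotile$values,
                        1.1)$y + m$floor_eps)
  }
  expect_equal(runstop:::om_angle(m, 2, 2, 1.1),
               approx(m$angle_nonchemotactic$grid,
                      m$angle_nonchemotactic$values, 1.1)$y + m$floor_eps)

  # flooring keeps every permissible speed strictly positive
  expect_gte(min(runstop:::om_speed(m, 2, seq(0, 100, by = 0.5))), 1e-6)
  expect_gt(m$floor_eps, 0)
})

test_that("a noiseless stationary strain falls back to uniform angles", {
  nm <- simulate_tracks(sim_config(n_tracks = 10, n_frames = 50,
                                   variant = "non_motile", seed = 70))$tracks
  nc <- simulate_tracks(sim_config(n_tracks = 10, n_frames = 50,
                                   variant = "non_chemotactic",
                                   seed = 71))$tracks
  m <- build_observation_model(nm, nc, v_max = 100)
  expect_true(isTRUE(m$angle_nonmotile$uniform))
  expect_equal(runstop:::om_angle(m, 1, 1, 2.2), 1 / (2 * pi) + m$floor_eps)
})

test_that("heuristic cutoff sits at the density intersection", {
  # equal variances, modes 0 and 4: densities cross at 2
  m <- synthetic_model(function(v) dnorm(v, 0, 1),
                       function(v) dnorm(v, 4, 1), v_max = 10)
  expect_equal(heuristic_cutoff(m), 2, tolerance = 0.02)

  m2 <- synthetic_model(function(v) dnorm(v, 0.5, 0.1),
                        function(v) dnorm(v, 4, 0.5), v_max = 10)
  cut <- heuristic_cutoff(m2)
  expect_gt(cut, 0.5); expect_lt(cut, 4)
  expect_lt(cut - 0.5, 4 - cut)  # nearer the stop mode
  # numeric root of the density difference, independently via uniroot
  f <- function(v) dnorm(v, 4, 0.5) - dnorm(v, 0.5, 0.1)
  root <- uniroot(f, c(0.6, 3.9))$root
  expect_equal(cut, root, tolerance = 0.01)

  same <- synthetic_model(function(v) dnorm(v, 2, 1),
                          function(v) dnorm(v, 2, 1), v_max = 10)
  expect_error(heuristic_cutoff(same), "never cross")
})

test_that("a well-separated cutoff classifies noiseless mutants correctly", {
  b <- sim_bundle(n_tracks = 40, n_frames = 80, noise_sd = 0, seed = 600)
  m <- build_observation_model(b$nm$tracks, b$nc$tracks, v_max = 100)
  cut <- heuristic_cutoff(m)
  v_nm <- track_kinematics(b$nm$tracks)$v
  v_nc <- track_kinematics(b$nc$tracks)$v
  acc <- (sum(v_nm <= cut) + sum(v_nc > cut)) / (length(v_nm) + length(v_nc))
  expect_gte(acc, 0.99)
})

test_that("MSD slope recovers a known diffusion coefficient", {
  set.seed(68)
  D <- 0.5; dt <- 0.02
  brown <- do.call(rbind, lapply(1:40, function(id) {
    n <- 200
    data.frame(track_id = id, frame = 0:(n - 1),
               x_um = cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))),
               y_um = cumsum(c(0, rnorm(n - 1, 0, sqrt(2 * D * dt)))))
  }))
  est <- estimate_diffusion(trackset(brown, dt = dt))
  expect_equal(est$D, D, tolerance = 0.15)

  frozen <- simulate_tracks(sim_config(n_tracks = 3, n_frames = 60,
                                       variant = "non_motile", seed = 69))
  expect_equal(estimate_diffusion(frozen$tracks)$D, 0, tolerance = 1e-12)

  # doubling the noise scale quadruples the apparent short-lag MSD level,
  # checked through the sigma <-> D helpers
  expect_equal(diffusion_from_sigma(2 * 0.1, dt) / diffusion_from_sigma(0.1, dt), 4)
  expect_equal(sigma_from_diffusion(diffusion_from_sigma(0.3, dt), dt), 0.3)
})

test_that("observation models serialise losslessly", {
  b <- sim_bundle(n_tracks = 10, n_frames = 60, noise_sd = 0.1, seed = 610)
  m <- build_observation_model(b$nm$tracks, b$nc$tracks, v_max = 100)
  path <- withr::local_tempfile(fileext = ".json")
  write_observation_model(m, path)
  m2 <- read_observation_model(path)
  expect_equal(m2$speed_run$values, m$speed_run$values, tolerance = 1e-12)
  expect_equal(m2$angle_map, m$angle_map)
  expect_equal(runstop:::om_angle(m2, 2, 2, 0.5),
               runstop:::om_angle(m, 2, 2, 0.5), tolerance = 1e-12)
})
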
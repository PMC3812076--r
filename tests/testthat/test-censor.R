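test_that("minimum bounding diameter matches circumcircle geometry", {
  expect_equal(min_bounding_diameter(rbind(c(0, 0), c(2, 0), c(0, 2))),
               2 * sqrt(2), tolerance = 1e-9)
  expect_equal(min_bounding_diameter(matrix(c(3, 4), 1, 2)), 0)
  expect_equal(min_bounding_diameter(rbind(c(0, 0), c(4, 0))), 4)
})

test_that("minimum bounding diameter agrees with the brute-force oracle", {
  set.seed(31)
  for (rep in 1:8) {
    pos <- cbind(runif(40, -5, 5), runif(40, -5, 5))
    expect_equal(min_bounding_diameter(pos), brute_force_mec_diameter(pos),
                 tolerance = 1e-7)
  }
  pos <- cbind(runif(100), runif(100))
  expect_equal(min_bounding_diameter(pos), brute_force_mec_diameter(pos),
               tolerance = 1e-7)
})

test_that("three-point curvature matches circle geometry and the law of sines", {
  expect_equal(curvature_three_point(c(0, 0), c(1, 0), c(2, 0)), 0,
               ignore_attr = TRUE)
  expect_equal(curvature_three_point(c(1, 0), c(0, 1), c(-1, 0)), 1,
               tolerance = 1e-12)
  expect_true(attr(curvature_three_point(c(0, 0), c(0, 0), c(1, 1)),
                   "degenerate"))
  set.seed(5)
  for (rep in 1:25) {
    p <- matrix(rnorm(6, sd = 3), 3, 2)
    # circumradius from the law of sines: R = a / (2 sin A)
    a <- sqrt(sum((p[2, ] - p[3, ])^2))
    b <- sqrt(sum((p[1, ] - p[3, ])^2))
    cc <- sqrt(sum((p[1, ] - p[2, ])^2))
    A <- acos(pmin(1, pmax(-1, (b^2 + cc^2 - a^2) / (2 * b * cc))))
    expect_equal(curvature_three_point(p[1, ], p[2, ], p[3, ]),
                 2 * sin(A) / a, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("track summaries behave on straight, circular and diffusive tracks", {
  st <- straight_track(n = 30, speed = 40)
  s <- summarise_tracks(st)
  expect_equal(s$nems, 1, tolerance = 1e-9)
  expect_equal(s$mac, 0, tolerance = 1e-9)
  expect_equal(s$median_curv, 0, tolerance = 1e-9)

  # three points on the unit circle -> curvature 1
  ang <- c(0, 0.3, 0.6)
  circ <- make_track(cbind(cos(ang), sin(ang)))
  expect_equal(summarise_tracks(circ)$median_curv, 1, tolerance = 1e-9)

  # pure positional noise around a fixed point: low NEMS, high MAC
  set.seed(8)
  nm <- add_noise(simulate_tracks(sim_config(
    n_tracks = 1, n_frames = 400, variant = "non_motile", seed = 8))$tracks,
    0.5, seed = 9)
  s <- summarise_tracks(nm)
  expect_lt(s$nems, 0.5)
  expect_gt(s$mac, 1.0)

  expect_error(summarise_tracks(make_track(rbind(c(0, 0), c(1, 0)))),
               "fewer than 3 frames")
})

test_that("censoring stages remove the right tracks and counts add up", {
  set.seed(14)
  sim <- simulate_tracks(sim_config(n_tracks = 40, n_frames = 60, seed = 14))
  ts <- sim$tracks
  # corrupt one track with a huge jump
  idx <- which(ts$track_id == 1 & ts$frame == 30)
  ts$x_um[idx] <- ts$x_um[idx] + 1000
  ts <- trackset(as.data.frame(ts), dt = 0.02)
  res <- censor_tracks(ts, censor_config(rho_fs = 100, mbd_min = 10,
                                         curvature_fraction = 0.05))
  expect_false("1" %in% unique(res$tracks$track_id))
  r <- res$report
  expect_equal(r$initial,
               r$removed_speed + r$removed_mbd + r$removed_curvature +
                 r$remaining)
  expect_equal(r$removed_curvature,
               as.integer(ceiling(0.05 * (r$initial - r$removed_speed -
                                            r$removed_mbd))))

  # fraction 0 removes nothing at the curvature stage
  res0 <- censor_tracks(sim$tracks,
                        censor_config(curvature_fraction = 0))
  expect_equal(res0$report$removed_curvature, 0L)

  # non-motile strains only pass through the speed stage
  nm <- simulate_tracks(sim_config(n_tracks = 10, n_frames = 60,
                                   variant = "non_motile", noise_sd = 0.1,
                                   seed = 15))
  rn <- censor_tracks(nm$tracks, motile = FALSE)
  expect_true(is.na(rn$report$removed_mbd))
  expect_equal(rn$report$remaining, 10L)
})

test_that("curvature-stage removal follows the ceiling convention", {
  for (n in c(20, 21, 39, 40)) {
    sim <- simulate_tracks(sim_config(n_tracks = n, n_frames = 20,
                                      noise_sd = 0.05, seed = 100 + n))
    res <- censor_tracks(sim$tracks,
                         censor_config(rho_fs = 1e6, mbd_min = 1e-9,
                                       curvature_fraction = 0.05))
    expect_equal(res$report$removed_curvature, as.integer(ceiling(0.05 * n)))
    expect_equal(res$report$remaining, n - ceiling(0.05 * n))
  }
})

test_that("mixed motile/non-motile populations separate in MAC-NEMS space", {
  set.seed(44)
  wt <- simulate_tracks(sim_config(n_tracks = 25, n_frames = 120,
                                   noise_sd = 0.05, seed = 44))
  nm <- simulate_tracks(sim_config(n_tracks = 25, n_frames = 120,
                                   variant = "non_motile", noise_sd = 0.3,
                                   seed = 45))
  nm_tracks <- as.data.frame(nm$tracks)
  nm_tracks$track_id <- nm_tracks$track_id + 1000
  mixed <- trackset(rbind(as.data.frame(wt$tracks), nm_tracks), dt = 0.02)
  smry <- summarise_tracks(mixed)
  motile <- smry$track_id < 1000
  # the two modes are separated before censoring...
  expect_gt(mean(smry$mac[!motile]), mean(smry$mac[motile]) + 0.5)
  expect_lt(mean(smry$nems[!motile]), mean(smry$nems[motile]))
  # ...and censoring depletes the high-MAC/low-NEMS mode
  res <- censor_tracks(mixed, censor_config(rho_fs = 200, mbd_min = 10,
                                            curvature_fraction = 0.05))
  kept <- summarise_tracks(res$tracks)
  expect_lt(mean(as.numeric(kept$track_id) >= 1000), 0.1)
})
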
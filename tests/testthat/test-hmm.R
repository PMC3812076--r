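test_that("transition matrix matches the dwell-time parameterisation", {
  A <- transition_matrix(0.14, 0.86, 0.02)
  expect_equal(unname(A[1, ]), c(1 - 0.02 / 0.14, 0.02 / 0.14))
  expect_equal(unname(A[2, ]), c(0.02 / 0.86, 1 - 0.02 / 0.86))

  A2 <- transition_matrix(0.04, 0.04, 0.02)
  expect_equal(unname(A2[1, 2]), 0.5)
  expect_equal(unname(A2[2, 1]), 0.5)

  for (i in 1:5) {
    t12 <- runif(1, 0.05, 2); t21 <- runif(1, 0.05, 2)
    expect_equal(rowSums(transition_matrix(t12, t21, 0.02)), c(stop = 1, run = 1))
  }
  expect_error(transition_matrix(0.01, 0.86, 0.02), "dt")
})

test_that("forward-backward equals the exhaustive path-sum oracle", {
  set.seed(71)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    m <- random_model()
    kin <- random_kinematics(n)
    t12 <- runif(1, 0.05, 1); t21 <- runif(1, 0.05, 2)
    mode <- sample(c("full", "speed_only"), 1)
    got <- forward_backward(kin, m, t12, t21, 0.02, mode = mode)
    want <- brute_force_hmm(kin, m, t12, t21, 0.02, mode = mode)
    expect_lt(abs(got$loglik - want$loglik), 1e-10)
    expect_lt(max(abs(got$p_run - want$p_run)), 1e-10)
    expect_equal(got$p_run + (1 - got$p_run), rep(1, n))
  }
})

test_that("disjoint emission supports give deterministic state probabilities", {
  m <- synthetic_model(function(v) ifelse(v < 1, 1, 0),
                       function(v) ifelse(v > 1, 1, 0),
                       v_max = 2)
  kin <- tibble::tibble(track_id = 1, step = 1:3, v = c(0.5, 1.5, 1.5),
                        theta = c(NA, 0.1, -0.2), theta_flag = FALSE)
  fb <- forward_backward(kin, m, 0.14, 0.86, 0.02)
  expect_equal(fb$p_run, c(0, 1, 1), tolerance = 1e-9)
})

test_that("speed-only mode equals full mode under uniform angle densities", {
  set.seed(72)
  m <- synthetic_model(function(v) dnorm(v, 1, 0.5),
                       function(v) dnorm(v, 5, 1), v_max = 10)
  kin <- random_kinematics(50)
  a <- forward_backward(kin, m, 0.2, 0.8, 0.02, mode = "full")
  b <- forward_backward(kin, m, 0.2, 0.8, 0.02, mode = "speed_only")
  expect_identical(a$loglik, b$loglik)
  expect_identical(a$p_run, b$p_run)
})

test_that("pooled likelihood is additive over tracks", {
  set.seed(73)
  m <- random_model()
  kin1 <- random_kinematics(30, id = 1)
  one <- pooled_nll(kin1, m, 0.2, 0.8, 0.02)
  fb <- forward_backward(kin1, m, 0.2, 0.8, 0.02)
  expect_equal(one, -fb$loglik)
  kin2 <- kin1; kin2$track_id <- 2
  both <- pooled_nll(rbind(kin1, kin2), m, 0.2, 0.8, 0.02)
  expect_equal(both, 2 * one, tolerance = 1e-10)
})

test_that("the likelihood prefers the generating parameters", {
  b <- sim_bundle(n_tracks = 80, n_frames = 150, noise_sd = 0.05, seed = 740)
  m <- build_observation_model(
    censor_tracks(b$nm$tracks, motile = FALSE)$tracks,
    censor_tracks(b$nc$tracks)$tracks, v_max = 100)
  kin <- track_kinematics(censor_tracks(b$wt$tracks)$tracks)
  at_truth <- pooled_nll(kin, m, 0.14, 0.86, 0.02)
  expect_lt(at_truth, pooled_nll(kin, m, 3 * 0.14, 0.86, 0.02))
  expect_lt(at_truth, pooled_nll(kin, m, 0.14, 3 * 0.86, 0.02))
  expect_lt(at_truth, pooled_nll(kin, m, 0.14 / 3, 0.86 / 3, 0.02))
})

test_that("the MLE is deterministic, order-invariant and start-insensitive", {
  b <- sim_bundle(n_tracks = 50, n_frames = 120, noise_sd = 0.05, seed = 750)
  m <- build_observation_model(
    censor_tracks(b$nm$tracks, motile = FALSE)$tracks,
    censor_tracks(b$nc$tracks)$tracks, v_max = 100)
  wt <- censor_tracks(b$wt$tracks)$tracks
  f1 <- fit_hmm(wt, m, mode = "full")
  f2 <- fit_hmm(wt, m, mode = "full", start = c(0.5, 2))
  expect_equal(f1$tau12, f2$tau12, tolerance = 1e-5)
  expect_equal(f1$tau21, f2$tau21, tolerance = 1e-5)

  # reverse the track order
  df <- as.data.frame(wt)
  df$track_id <- -df$track_id
  rev_ts <- trackset(df[order(df$track_id, df$frame), ], dt = 0.02)
  f3 <- fit_hmm(rev_ts, m, mode = "full")
  expect_equal(f1$tau12, f3$tau12, tolerance = 1e-6)
  expect_equal(f1$nll, f3$nll, tolerance = 1e-8)
})

test_that("datasets without stops raise the non-identifiability error", {
  nc <- simulate_tracks(sim_config(n_tracks = 30, n_frames = 100,
                                   variant = "non_chemotactic",
                                   noise_sd = 0.05, seed = 76))
  nm <- simulate_tracks(sim_config(n_tracks = 30, n_frames = 100,
                                   variant = "non_motile", noise_sd = 0.05,
                                   seed = 77))
  m <- build_observation_model(
    censor_tracks(nm$tracks, motile = FALSE)$tracks,
    censor_tracks(nc$tracks)$tracks, v_max = 100)
  nc2 <- simulate_tracks(sim_config(n_tracks = 30, n_frames = 100,
                                    variant = "non_chemotactic",
                                    noise_sd = 0.05, seed = 78))
  expect_error(fit_hmm(censor_tracks(nc2$tracks)$tracks, m, mode = "full"),
               class = "runstop_nonidentifiable")
})

test_that("bootstrap intervals collapse in degenerate cases", {
  b <- sim_bundle(n_tracks = 25, n_frames = 120, noise_sd = 0.05, seed = 790)
  m <- build_observation_model(
    censor_tracks(b$nm$tracks, motile = FALSE)$tracks,
    censor_tracks(b$nc$tracks)$tracks, v_max = 100)
  wt <- censor_tracks(b$wt$tracks)$tracks
  fit <- fit_hmm(wt, m, mode = "speed_only")

  # a dataset of copies of one track has no resampling variance
  one <- as.data.frame(wt[wt$track_id == unique(wt$track_id)[1], ])
  copies <- do.call(rbind, lapply(1:8, function(i) {
    d <- one; d$track_id <- i; d
  }))
  cts <- trackset(copies, dt = 0.02)
  cfit <- fit_hmm(cts, m, mode = "speed_only")
  cfit <- bootstrap_ci(cts, m, cfit, n_boot = 5, seed = 1)
  expect_equal(diff(cfit$ci12), 0, tolerance = 1e-6)
  expect_equal(diff(cfit$ci21), 0, tolerance = 1e-6)

  # n_boot = 1 collapses to the single resample's estimate
  f1 <- bootstrap_ci(wt, m, fit, n_boot = 1, seed = 2)
  expect_equal(diff(f1$ci12), 0)
  expect_true(f1$ci12[1] >= 1.5 * 0.02)

  f2 <- bootstrap_ci(wt, m, fit, n_boot = 20, seed = 3)
  expect_true(f2$ci12[1] <= f2$ci12[2])
  expect_gt(diff(f2$ci12), 0)
})

test_that("speeds beyond the model support raise a step-identifying error", {
  m <- synthetic_model(function(v) dnorm(v, 1, 0.5),
                       function(v) dnorm(v, 5, 1), v_max = 10)
  kin <- random_kinematics(5)
  kin$v[3] <- 12
  expect_error(forward_backward(kin, m, 0.2, 0.8, 0.02), "censored")
})
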
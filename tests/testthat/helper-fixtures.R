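# Shared fixtures and independent oracles used across the test files.

make_track <- function(pos, dt = 0.02, id = 1) {
  trackset(data.frame(track_id = id, frame = seq_len(nrow(pos)) - 1L,
                      x_um = pos[, 1], y_um = pos[, 2]), dt = dt)
}

straight_track <- function(n = 20, speed = 40, dt = 0.02, angle = 0) {
  step <- speed * dt
  t <- (seq_len(n) - 1) * step
  make_track(cbind(t * cos(angle), t * sin(angle)), dt = dt)
}

# A synthetic observation model with piecewise-linear densities given on
# coarse grids; used to exercise the HMM recursion independently of the KDE
# machinery.
synthetic_model <- function(stop_fun, run_fun, angle_funs = NULL,
                            v_max = 10, floor_eps = 0, n_grid = 401) {
  grid_v <- seq(0, v_max, length.out = n_grid)
  grid_a <- seq(-pi, pi, length.out = n_grid)
  mk <- function(grid, vals) {
    structure(list(grid = grid, values = vals, bandwidth = 1, n = 100L),
              class = "runstop_density")
  }
  if (is.null(angle_funs)) {
    angle_funs <- list(nonmotile = function(a) rep(1 / (2 * pi), length(a)),
                       nonchemotactic = function(a) rep(1 / (2 * pi), length(a)))
  }
  structure(list(
    speed_stop = mk(grid_v, stop_fun(grid_v)),
    speed_run = mk(grid_v, run_fun(grid_v)),
    angle_nonmotile = mk(grid_a, angle_funs$nonmotile(grid_a)),
    angle_nonchemotactic = mk(grid_a, angle_funs$nonchemotactic(grid_a)),
    angle_map = c(ss = "nonmotile", sr = "nonmotile", rs = "nonmotile",
                  rr = "nonchemotactic"),
    v_max = v_max, floor_eps = floor_eps), class = "observation_model")
}

# Random synthetic model: positive random densities (not normalised; the
# recursion and the oracle share them, so normalisation is irrelevant).
random_model <- function(v_max = 10) {
  bump <- function() {
    ctr <- runif(1, 0, v_max); wd <- runif(1, 0.5, 3)
    function(v) 0.05 + exp(-((v - ctr) / wd)^2)
  }
  abump <- function() {
    ctr <- runif(1, -pi, pi); wd <- runif(1, 0.3, 2)
    function(a) 0.02 + exp(-((a - ctr) / wd)^2)
  }
  synthetic_model(bump(), bump(),
                  angle_funs = list(nonmotile = abump(),
                                    nonchemotactic = abump()),
                  v_max = v_max)
}

random_kinematics <- function(n_steps, v_max = 10, id = 1) {
  tibble::tibble(
    track_id = id, step = seq_len(n_steps),
    v = runif(n_steps, 0, v_max),
    theta = c(NA_real_, runif(n_steps - 1, -pi, pi)),
    theta_flag = c(FALSE, runif(n_steps - 1) < 0.2))
}

# --- Independent oracles -------------------------------------------------

# Exhaustive path-sum likelihood and posteriors for the modified HMM:
# enumerates all 2^T state paths, weighting transitions by the
# previous-state-dependent observation density. Completely independent of
# the scaled forward-backward recursion under test.
brute_force_hmm <- function(kin, model, tau12, tau21, dt,
                            mode = c("full", "speed_only")) {
  mode <- match.arg(mode)
  n <- nrow(kin)
  A <- transition_matrix(tau12, tau21, dt)
  pi0 <- c(tau12, tau21) / (tau12 + tau21)
  bv <- function(j, t) runstop:::om_speed(model, j, kin$v[t])
  ba <- function(i, j, t) {
    if (mode == "speed_only") return(1 / (2 * pi))
    if (is.na(kin$theta[t]) || kin$theta_flag[t]) return(1 / (2 * pi))
    runstop:::om_angle(model, i, j, kin$theta[t])
  }
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  w <- apply(paths, 1, function(s) {
    p <- pi0[s[1]] * bv(s[1], 1)
    if (n >= 2) {
      for (t in 2:n) {
        p <- p * A[s[t - 1], s[t]] * ba(s[t - 1], s[t], t) * bv(s[t], t)
      }
    }
    p
  })
  total <- sum(w)
  p_run <- vapply(seq_len(n), function(t) {
    sum(w[paths[, t] == 2]) / total
  }, 0)
  list(loglik = log(total), p_run = p_run)
}

# O(n^3) smallest enclosing circle: tries all pair- and triple-defined
# candidate circles and keeps the smallest that contains every point.
brute_force_mec_diameter <- function(pos) {
  n <- nrow(pos)
  if (n == 1) return(0)
  contains_all <- function(ctr, r) {
    all(sqrt(rowSums(sweep(pos, 2, ctr)^2)) <= r + 1e-9)
  }
  best <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ctr <- (pos[i, ] + pos[j, ]) / 2
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2)) / 2
    if (contains_all(ctr, r)) best <- min(best, r)
  }
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      a <- pos[i, ]; b <- pos[j, ]; c <- pos[k, ]
      d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
      if (abs(d) < 1e-12) next
      ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
             sum(c^2) * (a[2] - b[2])) / d
      uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
             sum(c^2) * (b[1] - a[1])) / d
      r <- sqrt(sum((a - c(ux, uy))^2))
      if (contains_all(c(ux, uy), r)) best <- min(best, r)
    }
  }
  2 * best
}

# Literal four-step implementation of the minimum-duration smoother, written
# against phase boundaries found by scanning, not run-length encoding.
brute_force_postprocess <- function(states, p_run_min, p_stop_min) {
  phases <- function(s) {
    out <- list(); start <- 1
    for (t in seq_along(s)[-1]) {
      if (s[t] != s[t - 1]) {
        out[[length(out) + 1]] <- c(start, t - 1)
        start <- t
      }
    }
    out[[length(out) + 1]] <- c(start, length(s))
    out
  }
  s <- as.integer(states)
  for (ph in phases(s)) {  # steps 1-2: short runs -> stops
    if (s[ph[1]] == 2 && (ph[2] - ph[1] + 1) < p_run_min) s[ph[1]:ph[2]] <- 1L
  }
  for (ph in phases(s)) {  # steps 3-4: short stops -> runs
    if (s[ph[1]] == 1 && (ph[2] - ph[1] + 1) < p_stop_min) s[ph[1]:ph[2]] <- 2L
  }
  s
}

# Brute-force event-level FP/FN counts by direct interval intersection.
brute_force_confusion <- function(inferred, truth) {
  seg <- function(s) {
    out <- list(); t <- 1
    while (t <= length(s)) {
      if (s[t] == 1) {
        u <- t
        while (u < length(s) && s[u + 1] == 1) u <- u + 1
        out[[length(out) + 1]] <- t:u
        t <- u + 1
      } else t <- t + 1
    }
    out
  }
  si <- seg(inferred); st <- seg(truth)
  fp <- sum(vapply(si, function(a) {
    !any(vapply(st, function(b) length(intersect(a, b)) > 0, TRUE))
  }, TRUE))
  fn <- sum(vapply(st, function(b) {
    !any(vapply(si, function(a) length(intersect(a, b)) > 0, TRUE))
  }, TRUE))
  list(n_true = length(st), n_fp = fp, n_fn = fn)
}

# Recursive flood fill, 4-neighbourhood; independent of the two-pass
# union-find labeller and of EBImage.
brute_force_label4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + dd
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# Canonical form of a labelling: map of pixel index -> component id in
# first-appearance order, so two labellings can be compared structurally.
canonical_labels <- function(lab) {
  v <- lab[lab > 0]
  match(v, unique(v))
}

# Small simulated three-strain bundle used by several tests.
sim_bundle <- function(n_tracks = 60, n_frames = 150, noise_sd = 0,
                       seed = 500) {
  cfg <- function(variant, off) {
    sim_config(n_tracks = n_tracks, n_frames = n_frames, variant = variant,
               noise_sd = noise_sd, seed = seed + off)
  }
  list(wt = simulate_tracks(cfg("wildtype", 1)),
       nc = simulate_tracks(cfg("non_chemotactic", 2)),
       nm = simulate_tracks(cfg("non_motile", 3)))
}
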
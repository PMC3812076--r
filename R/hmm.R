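#' Transition matrix of the two-state run/stop chain
#'
#' The discrete-time transition matrix implied by mean dwell times `tau12`
#' (stop) and `tau21` (run) at frame interval `dt`:
#' `[[1 - dt/tau12, dt/tau12], [dt/tau21, 1 - dt/tau21]]` with state order
#' (stop, run). The frame interval must be shorter than both dwell times so
#' that the off-diagonal probabilities lie in (0, 1) -- in practice the
#' camera frame rate must be set sufficiently high.
#'
#' @param tau12 Mean stop duration (s).
#' @param tau21 Mean run duration (s).
#' @param dt Frame interval (s).
#' @return A 2x2 stochastic matrix.
#' @examples
#' transition_matrix(0.14, 0.86, 0.02)
#' @export
transition_matrix <- function(tau12, tau21, dt) {
  stopifnot(tau12 > 0, tau21 > 0, dt > 0)
  if (dt >= min(tau12, tau21)) {
    stop("`dt` must be smaller than both dwell times (dt < min(tau12, tau21))")
  }
  matrix(c(1 - dt / tau12, dt / tau21,
           dt / tau12, 1 - dt / tau21),
         nrow = 2, dimnames = list(c("stop", "run"), c("stop", "run")))
}

# Stationary distribution of the chain: pi_stop = tau12 / (tau12 + tau21).
stationary_dist <- function(tau12, tau21) {
  c(stop = tau12, run = tau21) / (tau12 + tau21)
}

# Per-track emission matrices for the modified HMM.
#
# Returns, for each track, bv (T-1 x 2 floored speed densities) and ba
# (T-1 x 4 angle densities in (ss, sr, rs, rr) order). The first row of ba
# is 1 (no preceding angle: speed-only emission); steps whose angle is
# flagged as undefined (zero-length displacement) get the circular uniform
# 1/(2*pi) in all four slots, falling back to the speed information alone.
# In speed-only mode every defined angle is replaced by the circular
# uniform, which makes the full and speed-only recursions coincide exactly
# when the empirical angle densities are themselves uniform.
hmm_emissions <- function(kin, model, mode = c("full", "speed_only")) {
  mode <- match.arg(mode)
  ids <- unique(kin$track_id)
  lapply(setNames(ids, ids), function(id) {
    k <- kin[kin$track_id == id, ]
    n <- nrow(k)
    bv <- cbind(om_speed(model, .STOP, k$v), om_speed(model, .RUN, k$v))
    ba <- matrix(1 / (2 * pi), n, 4)
    if (mode == "full" && n >= 2) {
      def <- which(!is.na(k$theta) & !k$theta_flag)
      if (length(def) > 0) {
        th <- k$theta[def]
        ba[def, 1] <- om_angle(model, .STOP, .STOP, th)
        ba[def, 2] <- om_angle(model, .STOP, .RUN, th)
        ba[def, 3] <- om_angle(model, .RUN, .STOP, th)
        ba[def, 4] <- om_angle(model, .RUN, .RUN, th)
      }
    }
    ba[1, ] <- 1
    list(bv = bv, ba = ba)
  })
}

#' Forward-backward inference for one track
#'
#' Runs the scaled forward-backward recursions of the modified two-state
#' HMM, in which the observation density of a displacement depends on the
#' previous hidden state as well as the current one (the angle observed on
#' leaving a stop is judged against the noisy stop-phase distribution). The
#' first displacement has no preceding angle and uses the speed-only
#' emission together with the initial distribution, which is taken to be the
#' stationary distribution of the transition matrix (tracks begin at
#' arbitrary times of a stationary process).
#'
#' @param kin Kinematics of a single track ([track_kinematics()] rows).
#' @param model An observation model ([build_observation_model()]).
#' @param tau12,tau21 Mean dwell times (s).
#' @param dt Frame interval (s).
#' @param mode `"full"` uses speeds and angle changes; `"speed_only"`
#'   replaces every angle density by the circular uniform.
#' @return A list with `p_run` (per-displacement posterior run
#'   probabilities, summing with the stop probabilities to one) and
#'   `loglik`.
#' @export
forward_backward <- function(kin, model, tau12, tau21, dt,
                             mode = c("full", "speed_only")) {
  mode <- match.arg(mode)
  if (length(unique(kin$track_id)) != 1L) stop("supply a single track")
  e <- hmm_emissions(kin, model, mode)[[1]]
  A <- transition_matrix(tau12, tau21, dt)
  res <- fb_two_state(e$bv, e$ba, A, stationary_dist(tau12, tau21),
                      want_posterior = TRUE)
  list(p_run = res$p_run, loglik = res$loglik)
}

#' Pooled negative log-likelihood of a tracking dataset
#'
#' Sum of per-track negative log-likelihoods under the modified HMM; the
#' quantity minimised by [fit_hmm()]. Pooling makes the dwell-time estimate
#' an ensemble quantity, which is essential when individual tracks are
#' short.
#'
#' @inheritParams forward_backward
#' @param kin Kinematics of one or more tracks.
#' @return A scalar negative log-likelihood.
#' @export
pooled_nll <- function(kin, model, tau12, tau21, dt,
                       mode = c("full", "speed_only")) {
  mode <- match.arg(mode)
  emis <- hmm_emissions(kin, model, mode)
  nll_from_emissions(emis, tau12, tau21, dt)
}

nll_from_emissions <- function(emis, tau12, tau21, dt) {
  A <- transition_matrix(tau12, tau21, dt)
  pooled_nll_cpp(emis, A, stationary_dist(tau12, tau21))
}

#' Maximum-likelihood estimation of the mean dwell times
#'
#' Minimises the pooled negative log-likelihood over `(tau12, tau21)` by
#' deterministic box-constrained quasi-Newton optimisation (L-BFGS-B). The
#' likelihood surface is smooth with a unique minimum for data that contain
#' both states, so a deterministic local optimiser suffices.
#'
#' A dataset without stops leaves the likelihood flat in `tau12` (no stop
#' phase is ever entered, so the mean stop duration is unidentifiable); this
#' is detected after convergence by probing the likelihood at perturbed
#' `tau12` values and raised as an error of class
#' `runstop_nonidentifiable` rather than silently returning an arbitrary
#' number. This is the expected outcome when fitting non-chemotactic
#' (never-stopping) tracks.
#'
#' @inheritParams pooled_nll
#' @param x A [trackset] or a kinematics tibble.
#' @param bounds Box bounds (s) applied to both dwell times.
#' @param start Starting point `c(tau12, tau21)` (s).
#' @return A list of class `hmm_fit`: `tau12`, `tau21`, `nll`, `n_tracks`,
#'   `mode`, `dt`, `convergence`, and `ci12`/`ci21` (NULL until
#'   [bootstrap_ci()] is run).
#' @export
fit_hmm <- function(x, model, dt = NULL, mode = c("full", "speed_only"),
                    bounds = NULL, start = NULL) {
  mode <- match.arg(mode)
  if (inherits(x, "trackset")) {
    dt <- track_dt(x)
    kin <- track_kinematics(x)
  } else {
    kin <- x
    if (is.null(dt)) dt <- attr(kin, "dt")
    if (is.null(dt)) stop("supply `dt` with a kinematics table")
  }
  if (is.null(bounds)) bounds <- c(1.5 * dt, 60)
  if (is.null(start)) start <- c(5 * dt, 25 * dt)
  emis <- hmm_emissions(kin, model, mode)
  fit <- fit_hmm_emissions(emis, dt, bounds, start)
  structure(c(fit, list(n_tracks = length(emis), mode = mode, dt = dt,
                        ci12 = NULL, ci21 = NULL)),
            class = "hmm_fit")
}

fit_hmm_emissions <- function(emis, dt, bounds, start,
                              check_identifiable = TRUE) {
  obj <- function(par) nll_from_emissions(emis, par[1], par[2], dt)
  opt <- optim(start, obj, method = "L-BFGS-B",
               lower = bounds[1], upper = bounds[2],
               control = list(factr = 1e4, maxit = 200))
  if (check_identifiable) {
    # A dataset without stops leaves tau12 without an interior optimum (the
    # likelihood is essentially independent of it): the optimiser slides to
    # a box bound and the posterior stop occupancy at the optimum is
    # negligible. Either signature voids the stop-duration estimate.
    A <- transition_matrix(opt$par[1], opt$par[2], dt)
    pi0 <- stationary_dist(opt$par[1], opt$par[2])
    occ <- 0; steps <- 0
    for (e in emis) {
      r <- fb_two_state(e$bv, e$ba, A, pi0, want_posterior = TRUE)
      occ <- occ + sum(1 - r$p_run)
      steps <- steps + length(r$p_run)
    }
    at_bound <- min(abs(opt$par[1] - bounds)) < 1e-6
    if (at_bound || occ < max(1, 1e-4 * steps)) {
      stop(structure(class = c("runstop_nonidentifiable", "error", "condition"),
                     list(message = paste0(
                       "the likelihood carries no information on tau12 ",
                       "(posterior stop occupancy ", signif(occ, 3), " of ",
                       steps, " displacement intervals): the dataset appears ",
                       "to contain no stops, so the mean stop duration is ",
                       "not identifiable"),
                       call = sys.call(-1))))
    }
  }
  list(tau12 = opt$par[1], tau21 = opt$par[2], nll = opt$value,
       convergence = opt$convergence)
}

#' @export
print.hmm_fit <- function(x, ...) {
  ci <- function(v) if (is.null(v)) "" else
    sprintf(" [95%% CI %.3f, %.3f]", v[1], v[2])
  cat(sprintf("<hmm_fit mode=%s> tau12 = %.4f s%s, tau21 = %.4f s%s\n",
              x$mode, x$tau12, ci(x$ci12), x$tau21, ci(x$ci21)))
  cat(sprintf("  pooled nll = %.2f over %d tracks (dt = %g s)\n",
              x$nll, x$n_tracks, x$dt))
  invisible(x)
}

#' Bootstrap confidence intervals for the dwell-time MLE
#'
#' Percentile bootstrap at the track level: the dataset is resampled by
#' drawing the same number of tracks with replacement, the MLE is recomputed
#' on each resample, and the 2.5th and 97.5th percentiles of the resampled
#' estimates form the 95% two-tailed intervals. A resample that happens to
#' be non-identifiable (no stops) is redrawn, up to `retry_cap` attempts per
#' iteration.
#'
#' @inheritParams fit_hmm
#' @param fit An `hmm_fit` from [fit_hmm()] on the same data.
#' @param n_boot Number of bootstrap iterations.
#' @param seed RNG seed for the resampling.
#' @param retry_cap Maximum redraws per iteration before giving up.
#' @return The `hmm_fit` with `ci12`, `ci21` (length-2 vectors) and
#'   `n_boot` filled in.
#' @export
bootstrap_ci <- function(x, model, fit, n_boot = 1000, seed = NULL,
                         retry_cap = 5) {
  stopifnot(inherits(fit, "hmm_fit"), n_boot >= 1)
  if (inherits(x, "trackset")) {
    kin <- track_kinematics(x)
  } else {
    kin <- x
  }
  dt <- fit$dt
  emis <- hmm_emissions(kin, model, fit$mode)
  n <- length(emis)
  bounds <- c(1.5 * dt, 60)
  start <- c(fit$tau12, fit$tau21)
  if (!is.null(seed)) set.seed(seed)
  est <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    for (attempt in seq_len(retry_cap)) {
      idx <- sample.int(n, n, replace = TRUE)
      r <- tryCatch(
        fit_hmm_emissions(emis[idx], dt, bounds, start),
        runstop_nonidentifiable = function(e) NULL)
      if (!is.null(r)) break
      r <- NULL
    }
    if (is.null(r)) {
      stop("bootstrap resample repeatedly non-identifiable after ",
           retry_cap, " redraws")
    }
    est[b, ] <- c(r$tau12, r$tau21)
  }
  fit$ci12 <- unname(quantile(est[, 1], c(0.025, 0.975), type = 7))
  fit$ci21 <- unname(quantile(est[, 2], c(0.025, 0.975), type = 7))
  fit$n_boot <- n_boot
  fit$boot_estimates <- tibble::tibble(tau12 = est[, 1], tau21 = est[, 2])
  fit
}

#' Segment tracks into run and stop phases
#'
#' Computes posterior run probabilities for every displacement of every
#' track with the fitted HMM and rounds them to hard states; optionally
#' applies the minimum-duration post-processing smoother.
#'
#' @inheritParams fit_hmm
#' @param fit An `hmm_fit`.
#' @param post Optional [postprocess_config()]; `NULL` for no smoothing
#'   (smoothing makes little difference to HMM output and is chiefly useful
#'   for the heuristic classifier).
#' @return A tibble with columns `track_id`, `step`, `p_run`, `state`
#'   (1 = stop, 2 = run).
#' @export
segment_tracks <- function(x, model, fit, post = NULL) {
  stopifnot(inherits(fit, "hmm_fit"))
  kin <- if (inherits(x, "trackset")) track_kinematics(x) else x
  emis <- hmm_emissions(kin, model, fit$mode)
  A <- transition_matrix(fit$tau12, fit$tau21, fit$dt)
  pi0 <- stationary_dist(fit$tau12, fit$tau21)
  out <- lapply(names(emis), function(id) {
    e <- emis[[id]]
    res <- fb_two_state(e$bv, e$ba, A, pi0, want_posterior = TRUE)
    st <- round_to_state(res$p_run)
    if (!is.null(post)) st <- postprocess_states(st, post)
    tibble::tibble(track_id = id, step = seq_along(res$p_run),
                   p_run = res$p_run, state = st)
  })
  do.call(rbind, out)
}
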
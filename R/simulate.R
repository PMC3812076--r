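#' Simulation settings for run-and-stop tracks
#'
#' Bundles the parameters of the velocity-jump simulator. Defaults describe a
#' fast-swimming bacterium observed at 50 frames per second: mean stop
#' duration 0.14 s, mean run duration 0.86 s (values in line with classical
#' single-cell tracking measurements of E. coli), 500 tracks of 250 frames,
#' Weibull-distributed run speeds with mean 40 um/s, and no observation
#' noise. All fields are configurable.
#'
#' @param tau12 Mean stop duration in seconds (stop -> run rate is `1/tau12`).
#' @param tau21 Mean run duration in seconds.
#' @param dt Sampling (frame) interval in seconds.
#' @param n_tracks Number of tracks to simulate.
#' @param n_frames Number of frames per track.
#' @param weibull_shape,weibull_scale Parameters of the run-speed
#'   distribution (um/s). The default scale gives a mean run speed of
#'   40 um/s at shape 2.
#' @param noise_sd Per-coordinate standard deviation of the additive
#'   Gaussian observation noise, in micrometres.
#' @param variant One of `"wildtype"` (alternating runs and stops),
#'   `"non_chemotactic"` (a single uninterrupted run) or `"non_motile"`
#'   (permanently stopped).
#' @param seed Optional RNG seed; when supplied, simulation output is
#'   reproducible bit-for-bit.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tau12 = 0.14, tau21 = 0.86, dt = 0.02,
                       n_tracks = 500, n_frames = 250,
                       weibull_shape = 2, weibull_scale = 40 / gamma(1.5),
                       noise_sd = 0,
                       variant = c("wildtype", "non_chemotactic", "non_motile"),
                       seed = NULL) {
  variant <- match.arg(variant)
  stopifnot(tau12 > 0, tau21 > 0, dt > 0, n_tracks >= 1, n_frames >= 2,
            weibull_shape > 0, weibull_scale > 0, noise_sd >= 0)
  if (variant == "wildtype" && dt >= min(tau12, tau21)) {
    stop("`dt` must be smaller than both mean dwell times for wildtype ",
         "simulations")
  }
  structure(list(tau12 = tau12, tau21 = tau21, dt = dt,
                 n_tracks = n_tracks, n_frames = n_frames,
                 weibull_shape = weibull_shape, weibull_scale = weibull_scale,
                 noise_sd = noise_sd, variant = variant, seed = seed),
            class = "sim_config")
}

#' Simulate bacterial tracks from a run-and-stop velocity-jump process
#'
#' Wildtype cells alternate between runs and stops. Run durations are
#' exponential with mean `tau21` and stop durations exponential with mean
#' `tau12`. During a run the cell moves in a straight line at a constant
#' speed drawn once per run from a Weibull distribution; during a stop the
#' position is frozen. A new direction of travel is drawn from the circular
#' uniform distribution at the end of every stop. The initial state is drawn
#' from the stationary distribution of the two-state chain and, by
#' memorylessness, the first dwell is a fresh exponential. Positions are
#' sampled on the frame grid `0, dt, 2*dt, ...`; the continuous-time state
#' history is recorded before any observation noise is applied.
#'
#' The `non_chemotactic` variant is a single run spanning the whole track and
#' the `non_motile` variant is permanently stopped; both emulate the mutant
#' strains used to build empirical observation densities.
#'
#' @param config A [sim_config].
#' @return A list with elements `tracks` (a [trackset], noise applied if
#'   `noise_sd > 0`) and `truth` (a tibble of continuous-time state events
#'   with columns `track_id`, `state` (1 = stop, 2 = run), `start_s`,
#'   `duration_s`, tiling each track's time span).
#' @examples
#' sim <- simulate_tracks(sim_config(n_tracks = 2, n_frames = 50, seed = 1))
#' head(sim$truth)
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  span <- (config$n_frames - 1) * config$dt
  t_frames <- seq(0, by = config$dt, length.out = config$n_frames)

  tracks <- vector("list", config$n_tracks)
  truths <- vector("list", config$n_tracks)
  for (k in seq_len(config$n_tracks)) {
    ev <- simulate_events(config, span)
    pos <- sample_positions(ev, t_frames)
    tracks[[k]] <- tibble::tibble(track_id = k,
                                  frame = seq_len(config$n_frames) - 1L,
                                  x_um = pos[, 1], y_um = pos[, 2])
    truths[[k]] <- tibble::tibble(track_id = k, state = ev$state,
                                  start_s = ev$start,
                                  duration_s = pmin(ev$dur, span - ev$start))
  }
  ts <- trackset(do.call(rbind, tracks), dt = config$dt)
  if (config$noise_sd > 0) ts <- add_noise(ts, config$noise_sd)
  list(tracks = ts, truth = do.call(rbind, truths))
}

# Continuous-time event list for one track: states, start times, durations,
# per-event speed and heading. Events tile [0, span] (the last event is
# truncated on output, not here).
simulate_events <- function(config, span) {
  variant <- config$variant
  if (variant == "non_motile") {
    return(list(state = .STOP, start = 0, dur = span + config$dt,
                speed = 0, angle = 0))
  }
  new_run <- function() {
    c(speed = rweibull(1, config$weibull_shape, config$weibull_scale),
      angle = runif(1, -pi, pi))
  }
  if (variant == "non_chemotactic") {
    r <- new_run()
    return(list(state = .RUN, start = 0, dur = span + config$dt,
                speed = r[["speed"]], angle = r[["angle"]]))
  }
  p_stop <- config$tau12 / (config$tau12 + config$tau21)
  state <- if (runif(1) < p_stop) .STOP else .RUN
  states <- integer(0); durs <- numeric(0)
  speeds <- numeric(0); angles <- numeric(0)
  elapsed <- 0
  r <- new_run()
  while (elapsed < span) {
    dur <- rexp(1, 1 / if (state == .STOP) config$tau12 else config$tau21)
    if (state == .RUN && length(states) > 0) r <- new_run()
    states <- c(states, state); durs <- c(durs, dur)
    speeds <- c(speeds, if (state == .RUN) r[["speed"]] else 0)
    angles <- c(angles, r[["angle"]])
    elapsed <- elapsed + dur
    state <- if (state == .STOP) .RUN else .STOP
  }
  list(state = states, start = cumsum(c(0, durs[-length(durs)])),
       dur = durs, speed = speeds, angle = angles)
}

# Sample the piecewise-linear continuous trajectory on the frame grid.
sample_positions <- function(ev, t_frames) {
  n_ev <- length(ev$state)
  vx <- ev$speed * cos(ev$angle)
  vy <- ev$speed * sin(ev$angle)
  # positions at event starts
  px <- cumsum(c(0, vx[-n_ev] * ev$dur[-n_ev]))
  py <- cumsum(c(0, vy[-n_ev] * ev$dur[-n_ev]))
  idx <- findInterval(t_frames, ev$start)
  rel <- t_frames - ev$start[idx]
  cbind(px[idx] + vx[idx] * rel, py[idx] + vy[idx] * rel)
}

#' Add Gaussian observation noise to a track set
#'
#' Perturbs each coordinate of every recorded position independently by a
#' zero-mean Gaussian of standard deviation `noise_sd` micrometres. Ground
#' truth (recorded before noise) is unaffected.
#'
#' @param x A [trackset].
#' @param noise_sd Per-coordinate standard deviation in micrometres
#'   (non-negative).
#' @param seed Optional RNG seed for reproducibility.
#' @return A [trackset] with perturbed coordinates.
#' @export
add_noise <- function(x, noise_sd, seed = NULL) {
  dt <- track_dt(x)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("`noise_sd` must be a single non-negative number")
  }
  if (noise_sd == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  x$x_um <- x$x_um + rnorm(nrow(x), 0, noise_sd)
  x$y_um <- x$y_um + rnorm(nrow(x), 0, noise_sd)
  trackset(as.data.frame(x), dt = dt)
}

#' Convert a per-coordinate noise s.d. to / from a diffusion coefficient
#'
#' For uncorrelated Gaussian positional noise applied at every frame, the
#' apparent 2D diffusion behaviour at short lags corresponds to
#' `sigma = sqrt(2 * D * dt)`. These helpers convert between the two
#' parameterisations so simulated noise levels can be compared with the
#' MSD-based diffusion estimate of [estimate_diffusion()].
#'
#' @param D Diffusion coefficient in um^2/s.
#' @param sigma Per-coordinate noise s.d. in um.
#' @param dt Frame interval in seconds.
#' @return A scalar (`sigma` in um, or `D` in um^2/s).
#' @export
sigma_from_diffusion <- function(D, dt) sqrt(2 * D * dt)

#' @rdname sigma_from_diffusion
#' @export
diffusion_from_sigma <- function(sigma, dt) sigma^2 / (2 * dt)

#' Discretise a continuous-time ground truth onto displacement intervals
#'
#' Each displacement interval `[k*dt, (k+1)*dt)` is labelled a stop if it
#' overlaps any part of a continuous-time stop event, however briefly;
#' otherwise it is a run. This is the discretisation used when scoring an
#' inferred state sequence against the simulator's ground truth, and it can
#' only inflate the stop fraction relative to the continuous truth.
#'
#' @param truth Ground-truth event tibble as returned by [simulate_tracks()].
#' @param dt Frame interval in seconds.
#' @param n_frames Number of frames per track.
#' @return A named list (by `track_id`) of integer state vectors of length
#'   `n_frames - 1` (1 = stop, 2 = run).
#' @export
discretise_truth <- function(truth, dt, n_frames) {
  n_int <- n_frames - 1L
  starts <- (seq_len(n_int) - 1L) * dt
  ids <- unique(truth$track_id)
  out <- lapply(ids, function(id) {
    ev <- truth[truth$track_id == id & truth$state == .STOP, ]
    st <- rep(.RUN, n_int)
    for (j in seq_len(nrow(ev))) {
      a <- ev$start_s[j]
      b <- a + ev$duration_s[j]
      overlap <- a < (starts + dt) & b > starts
      st[overlap] <- .STOP
    }
    st
  })
  names(out) <- as.character(ids)
  out
}
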
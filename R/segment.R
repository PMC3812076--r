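#' Post-processing settings
#'
#' Minimum permissible phase durations for the two-pass smoothing of a state
#' sequence. A value of 1 disables smoothing for that phase type.
#'
#' @param p_run_min Minimum run duration in displacement intervals.
#' @param p_stop_min Minimum stop duration in displacement intervals.
#' @return A list of class `postprocess_config`.
#' @export
postprocess_config <- function(p_run_min = 2, p_stop_min = 2) {
  stopifnot(p_run_min >= 1, p_stop_min >= 1)
  structure(list(p_run_min = p_run_min, p_stop_min = p_stop_min),
            class = "postprocess_config")
}

#' Heuristic threshold classifier
#'
#' Labels each displacement a run if and only if its framewise speed
#' strictly exceeds the cutoff. The cutoff is typically chosen as the
#' intersection of the empirical stop- and run-phase speed densities
#' ([heuristic_cutoff()]). Simple and fast, but sensitive to any overlap
#' between the two speed distributions: noise in the crossover region
#' produces spurious state flips.
#'
#' @param v Framewise speeds (um/s), or a kinematics tibble from
#'   [track_kinematics()] (a single track).
#' @param cutoff Cutoff speed in um/s (positive).
#' @return Integer state vector (1 = stop, 2 = run).
#' @examples
#' heuristic_classify(c(1, 10, 3), cutoff = 5)
#' @export
heuristic_classify <- function(v, cutoff) {
  stopifnot(cutoff > 0)
  if (is.data.frame(v)) v <- v$v
  ifelse(v > cutoff, .RUN, .STOP)
}

#' Minimum-duration post-processing of a state sequence
#'
#' Smooths an inferred run/stop sequence in exactly four steps: (1) find the
#' durations of all running phases; (2) relabel every running phase shorter
#' than `p_run_min` as a stop; (3) recompute the stopping-phase durations;
#' (4) relabel every stopping phase shorter than `p_stop_min` as a run.
#' Relabelling short runs before short stops deliberately biases rapidly
#' oscillating stretches towards stops (short runs are absorbed first,
#' creating longer stops that then survive step 4): identifying every stop
#' is valued above avoiding occasional overlong stop phases. Phases touching
#' the track boundaries are subject to the same rules as interior phases.
#' The output contains no stop phase shorter than `p_stop_min`, and the
#' operation is idempotent.
#'
#' @param states Integer state vector (1 = stop, 2 = run).
#' @param config A [postprocess_config()].
#' @return The smoothed integer state vector.
#' @examples
#' postprocess_states(c(2, 2, 1, 2, 2), postprocess_config(2, 2))
#' @export
postprocess_states <- function(states, config = postprocess_config()) {
  stopifnot(inherits(config, "postprocess_config"),
            all(states %in% c(.STOP, .RUN)))
  r <- rle(as.integer(states))
  r$values[r$values == .RUN & r$lengths < config$p_run_min] <- .STOP
  s <- inverse.rle(r)
  r <- rle(s)
  r$values[r$values == .STOP & r$lengths < config$p_stop_min] <- .RUN
  inverse.rle(r)
}
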
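#' Track sets
#'
#' A track set is a tidy table of 2D cell centroid positions, one row per
#' frame, holding one or many tracks recorded at a fixed frame interval.
#' Positions are in micrometres; `frame` is the 0-based frame index within a
#' track, so that time is `frame * dt` seconds.
#'
#' @param x A data frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @param dt Frame interval in seconds (positive scalar).
#'
#' @details Each track must span at least two frames, its frames must be
#' consecutive (no gaps) and all coordinates finite. These invariants are
#' checked at construction.
#'
#' @return A `trackset`: a tibble with the columns above and a `dt` attribute.
#' @examples
#' ts <- trackset(data.frame(track_id = 1, frame = 0:2,
#'                           x_um = c(0, 1, 1), y_um = c(0, 0, 1)), dt = 0.02)
#' track_dt(ts)
#' @export
trackset <- function(x, dt) {
  stopifnot(is.data.frame(x))
  need <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("trackset is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)")
  }
  x <- tibble::as_tibble(x[need])
  if (!all(is.finite(x$x_um)) || !all(is.finite(x$y_um))) {
    stop("all coordinates must be finite")
  }
  x <- x[order(match(x$track_id, unique(x$track_id)), x$frame), ]
  for (id in unique(x$track_id)) {
    fr <- x$frame[x$track_id == id]
    if (length(fr) < 2L) {
      stop("track ", id, " has fewer than 2 frames")
    }
    if (any(diff(fr) != 1L)) {
      stop("track ", id, " has non-consecutive frames")
    }
  }
  attr(x, "dt") <- dt
  class(x) <- c("trackset", class(x))
  x
}

#' @rdname trackset
#' @export
track_dt <- function(x) {
  dt <- attr(x, "dt")
  if (is.null(dt)) stop("not a trackset: missing `dt` attribute")
  dt
}

#' @export
print.trackset <- function(x, ...) {
  cat(sprintf("<trackset> %d tracks, %d positions, dt = %g s\n",
              length(unique(x$track_id)), nrow(x), track_dt(x)))
  NextMethod()
}

#' Read and write track tables
#'
#' Track tables are plain CSV files with header columns
#' `track_id, frame, x_um, y_um`. One file may hold many tracks. The frame
#' interval is not stored in the file and must be supplied on reading.
#'
#' @param path Path to a CSV file.
#' @param dt Frame interval in seconds.
#' @return `read_tracks()` returns a [trackset]; `write_tracks()` invisibly
#'   returns `path`.
#' @export
read_tracks <- function(path, dt) {
  trackset(read.csv(path), dt = dt)
}

#' @rdname read_tracks
#' @param x A [trackset].
#' @export
write_tracks <- function(x, path) {
  write.csv(as.data.frame(x)[c("track_id", "frame", "x_um", "y_um")],
            path, row.names = FALSE)
  invisible(path)
}

# Split a trackset into a named list of position matrices (rows = frames).
split_positions <- function(x) {
  ids <- unique(x$track_id)
  out <- lapply(ids, function(id) {
    sel <- x$track_id == id
    cbind(x = x$x_um[sel], y = x$y_um[sel])
  })
  names(out) <- as.character(ids)
  out
}

#' Framewise kinematics of tracks
#'
#' Derives, for every track, the framewise displacement speeds and the signed
#' framewise angle changes. A track of `T` frames yields `T - 1` speeds
#' `v_t = |d_t| / dt` and `T - 2` angle changes, where the angle change at
#' step `t` (`t >= 2`) is the difference in polar angle between displacement
#' `d_t` and the preceding displacement `d_{t-1}`, wrapped to `(-pi, pi]`.
#'
#' If either displacement of a pair has exactly zero length its polar angle is
#' undefined; the angle change is then recorded as 0 and flagged via
#' `theta_flag`, so downstream consumers (notably the HMM) can fall back to a
#' speed-only treatment of that step. The first step of every track has no
#' preceding displacement and carries `theta = NA`.
#'
#' @param x A [trackset].
#' @return A tibble with columns `track_id`, `step` (1-based displacement
#'   index), `v` (um/s), `theta` (radians, `NA` for the first step) and
#'   `theta_flag` (logical).
#' @examples
#' ts <- trackset(data.frame(track_id = 1, frame = 0:2,
#'                           x_um = c(0, 1, 1), y_um = c(0, 0, 1)), dt = 0.02)
#' track_kinematics(ts)  # speeds 50, 50; angle +pi/2
#' @export
track_kinematics <- function(x) {
  dt <- track_dt(x)
  pos <- split_positions(x)
  out <- lapply(names(pos), function(id) {
    p <- pos[[id]]
    d <- diff(p)
    v <- sqrt(rowSums(d^2)) / dt
    n <- nrow(d)
    theta <- rep(NA_real_, n)
    flag <- rep(FALSE, n)
    if (n >= 2) {
      ang <- atan2(d[, 2], d[, 1])
      zero <- sqrt(rowSums(d^2)) == 0
      th <- wrap_angle(diff(ang))
      bad <- zero[-n] | zero[-1]
      th[bad] <- 0
      theta[-1] <- th
      flag[-1] <- bad
    }
    tibble::tibble(track_id = id, step = seq_len(n), v = v,
                   theta = theta, theta_flag = flag)
  })
  kin <- do.call(rbind, out)
  attr(kin, "dt") <- dt
  kin
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param theta Numeric vector of angles in radians.
#' @return Angles wrapped to `(-pi, pi]`.
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Round run probabilities to a state sequence
#'
#' Converts per-displacement run probabilities into a hard state sequence:
#' probabilities of at least 0.5 become runs (state 2), the rest stops
#' (state 1). The tie at exactly 0.5 rounds to a run; with continuous
#' posterior probabilities this case has probability zero, and the convention
#' is fixed so that results are deterministic. Binary input is returned
#' unchanged, so the operation is idempotent.
#'
#' @param p Numeric vector of run probabilities in `[0, 1]`.
#' @return Integer vector of states (1 = stop, 2 = run).
#' @examples
#' round_to_state(c(0.9, 0.2, 0.51))
#' @export
round_to_state <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("run probabilities must lie in [0, 1]")
  }
  ifelse(p >= 0.5, .RUN, .STOP)
}
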
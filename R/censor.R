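#' Censoring settings
#'
#' Parameters of the three-stage track censoring protocol. `rho_fs` is the
#' framewise-speed threshold above which a whole track is considered a
#' tracking failure and discarded; it should sit well above the population's
#' mean swimming speed. `mbd_min` removes tracks whose minimum bounding
#' diameter is too small to distinguish swimming from diffusion (non-motile
#' cells and very short tracks). `curvature_fraction` is the fraction of the
#' surviving tracks removed from the top of the median-absolute-curvature
#' ranking, discarding the most tortuous tracks without a per-dataset
#' threshold.
#'
#' @param rho_fs Framewise-speed cutoff in um/s.
#' @param mbd_min Minimum bounding diameter in um.
#' @param curvature_fraction Fraction in `[0, 1)` removed by median curvature.
#' @return A list of class `censor_config`.
#' @export
censor_config <- function(rho_fs = 100, mbd_min = 10, curvature_fraction = 0.05) {
  stopifnot(rho_fs > 0, mbd_min > 0,
            curvature_fraction >= 0, curvature_fraction < 1)
  structure(list(rho_fs = rho_fs, mbd_min = mbd_min,
                 curvature_fraction = curvature_fraction),
            class = "censor_config")
}

#' Minimum bounding diameter of a track
#'
#' Diameter of the smallest circle enclosing every recorded position of the
#' track, computed with Welzl's randomised algorithm (expected linear time).
#'
#' @param pos A two-column matrix of positions (um), or a [trackset]
#'   containing a single track.
#' @return The diameter in um (0 for a single point).
#' @examples
#' min_bounding_diameter(rbind(c(0, 0), c(2, 0), c(0, 2)))  # 2 * sqrt(2)
#' @export
min_bounding_diameter <- function(pos) {
  if (inherits(pos, "trackset")) {
    p <- split_positions(pos)
    if (length(p) != 1L) stop("supply a single track")
    pos <- p[[1]]
  }
  pos <- unique(pos[stats::complete.cases(pos), , drop = FALSE])
  2 * welzl_circle(pos)$r
}

# Smallest enclosing circle, iterative variant of Welzl's move-to-front
# algorithm. Deterministic permutation keeps results reproducible.
welzl_circle <- function(pos) {
  n <- nrow(pos)
  if (n == 0L) return(list(c = c(0, 0), r = 0))
  if (n == 1L) return(list(c = pos[1, ], r = 0))
  # deterministic pseudo-shuffle: expected O(n) without touching the global RNG
  ord <- order((sin(seq_len(n) * 12.9898) * 43758.5453) %% 1)
  pos <- pos[ord, , drop = FALSE]
  inside <- function(circ, p) {
    sqrt(sum((p - circ$c)^2)) <= circ$r * (1 + 1e-10) + 1e-12
  }
  circ2 <- function(a, b) list(c = (a + b) / 2, r = sqrt(sum((a - b)^2)) / 2)
  circ3 <- function(a, b, c) {
    # circumcircle; falls back to the largest two-point circle if collinear
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-12) {
      cands <- list(circ2(a, b), circ2(a, c), circ2(b, c))
      for (cc in cands[order(vapply(cands, `[[`, 0, "r"))]) {
        if (inside(cc, a) && inside(cc, b) && inside(cc, c)) return(cc)
      }
      return(cands[[which.max(vapply(cands, `[[`, 0, "r"))]])
    }
    ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
           sum(c^2) * (a[2] - b[2])) / d
    uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
           sum(c^2) * (b[1] - a[1])) / d
    ctr <- c(ux, uy)
    list(c = ctr, r = sqrt(sum((a - ctr)^2)))
  }
  circ <- circ2(pos[1, ], pos[2, ])
  for (i in seq_len(n)) {
    p <- pos[i, ]
    if (inside(circ, p)) next
    circ <- list(c = p, r = 0)
    for (j in seq_len(i - 1L)) {
      q <- pos[j, ]
      if (inside(circ, q)) next
      circ <- circ2(p, q)
      for (k in seq_len(j - 1L)) {
        s <- pos[k, ]
        if (inside(circ, s)) next
        circ <- circ3(p, q, s)
      }
    }
  }
  circ
}

#' Three-point curvature estimate
#'
#' Unsigned curvature of the circle through three consecutive positions:
#' `4 * area(triangle) / (|ab| * |bc| * |ca|)`, in 1/um. Collinear points
#' give 0; coincident points (degenerate triangle) also give 0, with the
#' `degenerate` attribute set.
#'
#' @param p_prev,p,p_next Numeric length-2 position vectors (um).
#' @return Curvature in 1/um.
#' @examples
#' curvature_three_point(c(1, 0), c(0, 1), c(-1, 0))  # unit circle -> 1
#' @export
curvature_three_point <- function(p_prev, p, p_next) {
  a <- sqrt(sum((p - p_prev)^2))
  b <- sqrt(sum((p_next - p)^2))
  c <- sqrt(sum((p_next - p_prev)^2))
  if (a == 0 || b == 0 || c == 0) {
    return(structure(0, degenerate = TRUE))
  }
  cross <- (p[1] - p_prev[1]) * (p_next[2] - p_prev[2]) -
           (p[2] - p_prev[2]) * (p_next[1] - p_prev[1])
  area2 <- abs(cross)  # twice the triangle area
  2 * area2 / (a * b * c)
}

# Median absolute three-point curvature over the interior points of a
# position matrix; NA for fewer than 3 points.
median_abs_curvature <- function(pos) {
  n <- nrow(pos)
  if (n < 3L) return(NA_real_)
  k <- vapply(2:(n - 1L), function(i) {
    as.numeric(curvature_three_point(pos[i - 1L, ], pos[i, ], pos[i + 1L, ]))
  }, 0)
  median(abs(k))
}

#' Per-track summary statistics
#'
#' Summarises each track by its maximum framewise speed, minimum bounding
#' diameter (MBD), effective mean speed (EMS = MBD divided by the track
#' duration, taken as number-of-displacements times `dt` so that a straight
#' constant-speed track scores exactly 1), normalised effective mean speed
#' (NEMS = EMS / mean framewise speed), mean absolute framewise angle change
#' (MAC, over the angles that are defined) and the median absolute
#' three-point curvature.
#'
#' @param x A [trackset] with tracks of at least 3 frames.
#' @return A tibble with one row per track: `track_id`, `n_frames`,
#'   `max_speed`, `mbd`, `ems`, `nems`, `mac`, `median_curv`.
#' @export
summarise_tracks <- function(x) {
  dt <- track_dt(x)
  pos <- split_positions(x)
  rows <- lapply(names(pos), function(id) {
    p <- pos[[id]]
    n <- nrow(p)
    if (n < 3L) stop("track ", id, " has fewer than 3 frames; summary undefined")
    d <- diff(p)
    v <- sqrt(rowSums(d^2)) / dt
    mbd <- min_bounding_diameter(p)
    ems <- mbd / ((n - 1L) * dt)
    ang <- atan2(d[, 2], d[, 1])
    lens <- sqrt(rowSums(d^2))
    ok <- lens[-length(lens)] > 0 & lens[-1] > 0
    th <- wrap_angle(diff(ang))[ok]
    tibble::tibble(track_id = id, n_frames = n,
                   max_speed = max(v), mbd = mbd, ems = ems,
                   nems = if (mean(v) > 0) ems / mean(v) else NA_real_,
                   mac = if (length(th) > 0) mean(abs(th)) else NA_real_,
                   median_curv = median_abs_curvature(p))
  })
  do.call(rbind, rows)
}

#' Censor a tracking dataset
#'
#' Removes spurious and uninformative tracks in up to three stages:
#' \enumerate{
#'   \item tracks containing any framewise speed above `rho_fs` (tracking
#'     failures) are discarded, for every strain;
#'   \item tracks with minimum bounding diameter below `mbd_min` are
#'     discarded (motile strains only -- applying it to a non-motile strain
#'     would remove essentially every track);
#'   \item the top `ceiling(curvature_fraction * n)` of the remaining tracks,
#'     ordered by decreasing median absolute curvature, are discarded
#'     (motile strains only). Ties are broken by the original track order, so
#'     the removal count is exact and deterministic.
#' }
#'
#' @param x A [trackset].
#' @param config A [censor_config].
#' @param motile Logical; apply stages 2-3? Use `FALSE` for non-motile
#'   strains.
#' @return A list with `tracks` (the censored [trackset], or `NULL` when no
#'   track survives), `report` (a one-row tibble of per-stage counts:
#'   `initial`, `removed_speed`, `removed_mbd`, `removed_curvature`,
#'   `remaining`; stage counts are `NA` when the stage does not apply) and
#'   `summary` (per-track statistics of the tracks entering stage 2, see
#'   [summarise_tracks()]).
#' @export
censor_tracks <- function(x, config = censor_config(), motile = TRUE) {
  stopifnot(inherits(config, "censor_config"))
  dt <- track_dt(x)
  smry <- summarise_tracks(x)
  n0 <- nrow(smry)

  fast <- smry$track_id[smry$max_speed > config$rho_fs]
  keep <- smry[!smry$track_id %in% fast, ]
  n_speed <- length(fast)

  n_mbd <- NA_integer_
  n_curv <- NA_integer_
  if (motile) {
    small <- keep$track_id[keep$mbd < config$mbd_min]
    n_mbd <- length(small)
    keep <- keep[!keep$track_id %in% small, ]
    n_rm <- ceiling(config$curvature_fraction * nrow(keep))
    n_curv <- as.integer(n_rm)
    if (n_rm > 0) {
      ord <- order(-keep$median_curv)  # stable: ties keep original order
      drop_ids <- keep$track_id[ord[seq_len(n_rm)]]
      keep <- keep[!keep$track_id %in% drop_ids, ]
    }
  }
  remaining <- nrow(keep)
  report <- tibble::tibble(initial = n0, removed_speed = n_speed,
                           removed_mbd = n_mbd, removed_curvature = n_curv,
                           remaining = remaining)
  out <- if (remaining > 0) {
    trackset(as.data.frame(x[x$track_id %in% keep$track_id, ]), dt = dt)
  }
  list(tracks = out, report = report, summary = smry)
}
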
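# Maximal stop phases of a state vector as (start, end) displacement indices.
stop_phases <- function(states) {
  r <- rle(as.integer(states))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == .STOP
  cbind(start = starts[keep], end = ends[keep])
}

#' Event-level confusion rates against a discretised ground truth
#'
#' Matches maximal inferred stop phases to maximal true stop phases by
#' interval overlap: an inferred stop phase that shares no displacement
#' interval with any true stop phase counts as one false positive (FP), and
#' a true stop phase that shares no interval with any inferred stop phase
#' counts as one false negative (FN). Sharing a single interval suffices for
#' a match -- the most permissive criterion, applied identically to every
#' method under comparison.
#'
#' Rates are reported in two conventions: the headline `fp_rate`/`fn_rate`
#' is the ratio of the total number of FPs (FNs) across tracks to the total
#' number of true stop events, and `fp_rate_mean`/`fn_rate_mean` averages
#' the per-track ratios over the tracks that contain at least one true stop.
#'
#' @param inferred,truth Integer state vectors (1 = stop, 2 = run) for a
#'   single track, or named lists of such vectors for a dataset; names and
#'   lengths must match pairwise.
#' @return A list: `n_true_stops`, `n_fp`, `n_fn`, `fp_rate`, `fn_rate`,
#'   `fp_rate_mean`, `fn_rate_mean`, `per_track` (tibble).
#' @export
confusion_rates <- function(inferred, truth) {
  if (!is.list(inferred)) inferred <- list(track = inferred)
  if (!is.list(truth)) truth <- list(track = truth)
  if (length(inferred) != length(truth)) {
    stop("`inferred` and `truth` must contain the same tracks")
  }
  if (!is.null(names(inferred)) && !is.null(names(truth))) {
    truth <- truth[names(inferred)]
  }
  rows <- lapply(seq_along(inferred), function(n) {
    a <- inferred[[n]]; b <- truth[[n]]
    if (length(a) != length(b)) {
      stop("state sequences differ in length for track ", names(inferred)[n])
    }
    pa <- stop_phases(a); pb <- stop_phases(b)
    overlaps <- function(p, q) any(p[1] <= q[, 2] & p[2] >= q[, 1])
    n_fp <- if (nrow(pb) == 0) nrow(pa) else
      sum(!apply(pa, 1, overlaps, q = pb))
    n_fn <- if (nrow(pa) == 0) nrow(pb) else
      sum(!apply(pb, 1, overlaps, q = pa))
    tibble::tibble(track = n, n_true = nrow(pb), n_fp = n_fp, n_fn = n_fn)
  })
  per <- do.call(rbind, rows)
  tot_true <- sum(per$n_true)
  with_true <- per[per$n_true > 0, ]
  list(n_true_stops = tot_true, n_fp = sum(per$n_fp), n_fn = sum(per$n_fn),
       fp_rate = if (tot_true > 0) sum(per$n_fp) / tot_true else NA_real_,
       fn_rate = if (tot_true > 0) sum(per$n_fn) / tot_true else NA_real_,
       fp_rate_mean = if (nrow(with_true) > 0)
         mean(with_true$n_fp / with_true$n_true) else NA_real_,
       fn_rate_mean = if (nrow(with_true) > 0)
         mean(with_true$n_fn / with_true$n_true) else NA_real_,
       per_track = per)
}

#' Stopwise angle changes of inferred stop events
#'
#' For every maximal stop phase flanked on both sides by at least one run
#' displacement, computes the signed change in direction of travel across
#' the stop: the polar-angle difference between the last run displacement
#' before the event and the first run displacement after it, wrapped to
#' `(-pi, pi]`. Stops touching a track boundary have no defined angle and
#' are returned with `angle = NA`. Small stopwise angles indicate
#' directional persistence across reorientation events.
#'
#' @param x A [trackset] (single track or many).
#' @param states Integer state vector for a single track, or a named list /
#'   a segmentation tibble (from [segment_tracks()]) covering every track
#'   in `x`.
#' @return A tibble with columns `track_id`, `start`, `length`, `angle`.
#' @export
stopwise_angles <- function(x, states) {
  pos <- split_positions(x)
  if (is.data.frame(states)) states <- split(states$state, states$track_id)
  if (!is.list(states)) states <- setNames(list(states), names(pos)[1])
  rows <- lapply(names(pos), function(id) {
    st <- states[[id]]
    d <- diff(pos[[id]])
    if (is.null(st) || length(st) != nrow(d)) {
      stop("state sequence for track ", id,
           " does not match its number of displacements")
    }
    ph <- stop_phases(st)
    if (nrow(ph) == 0) return(NULL)
    ang <- apply(ph, 1, function(p) {
      before <- p[[1]] - 1L
      after <- p[[2]] + 1L
      if (before < 1L || after > nrow(d)) return(NA_real_)
      db <- d[before, ]; da <- d[after, ]
      if (all(db == 0) || all(da == 0)) return(NA_real_)
      wrap_angle(atan2(da[2], da[1]) - atan2(db[2], db[1]))
    })
    tibble::tibble(track_id = id, start = ph[, "start"],
                   length = ph[, "end"] - ph[, "start"] + 1L, angle = ang)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    return(tibble::tibble(track_id = character(), start = integer(),
                          length = integer(), angle = numeric()))
  }
  do.call(rbind, rows)
}

#' Two-sample Kuiper test
#'
#' Kuiper's statistic `V = max(F_a - F_b) + max(F_b - F_a)` over the two
#' empirical CDFs, with an asymptotic p-value from the standard series using
#' the effective sample size `n_a * n_b / (n_a + n_b)`. Unlike the
#' Kolmogorov-Smirnov statistic, `V` is invariant to a common cyclic shift
#' of both samples, which makes the test appropriate for circular data such
#' as angle distributions.
#'
#' @param a,b Numeric samples on a common (linear or circular) scale.
#' @return A list with `statistic` (V) and `p_value`.
#' @export
kuiper_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  xs <- sort(unique(c(a, b)))
  Fa <- ecdf_at(a, xs)
  Fb <- ecdf_at(b, xs)
  V <- max(Fa - Fb) + max(Fb - Fa)
  n_e <- length(a) * length(b) / (length(a) + length(b))
  lambda <- (sqrt(n_e) + 0.155 + 0.24 / sqrt(n_e)) * V
  p <- if (lambda < 0.4) 1 else {
    j <- 1:100
    min(1, max(0, 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))))
  }
  list(statistic = V, p_value = p)
}

ecdf_at <- function(x, xs) {
  vapply(xs, function(q) mean(x <= q), 0)
}

#' Histogram of stopwise angles, overall and for false positives
#'
#' Builds paired histogram counts of the inferred stopwise angle changes:
#' all inferred stop events versus the subset flagged as false positives.
#' False positives tend to concentrate near zero (a run misread as a stop
#' rarely changes direction), so the FP histogram visualises the systematic
#' bias a method introduces into the reorientation-angle distribution.
#'
#' @param angles Stopwise angles in radians, `(-pi, pi]`.
#' @param is_fp Logical vector flagging which events are false positives.
#' @param n_bins Number of equal-width bins over `(-pi, pi]`.
#' @return A tibble with `mid` (bin midpoint), `n_all`, `n_fp`.
#' @export
bias_histogram <- function(angles, is_fp, n_bins = 24) {
  stopifnot(length(angles) == length(is_fp))
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  cut_all <- cut(angles, breaks, include.lowest = TRUE)
  tibble::tibble(mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
                 n_all = as.integer(table(cut_all)),
                 n_fp = as.integer(table(cut_all[is_fp])))
}
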
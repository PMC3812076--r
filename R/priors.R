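#' Kernel density estimate of framewise speeds
#'
#' Gaussian-kernel KDE on `[0, v_max]`, boundary-corrected at zero by
#' reflection. The bandwidth is chosen by the diffusion-based plug-in of
#' Botev, Grotowski and Kroese (an automatic, non-parametric selector that
#' avoids hand-picked bin widths), with Silverman's rule as a fallback for
#' samples on which the plug-in fixed point cannot be solved (including
#' degenerate, zero-spread samples).
#'
#' @param samples Framewise speeds in um/s, all within `[0, v_max]`.
#' @param v_max Upper bound of the speed support (um/s); speeds above it are
#'   not permissible (such tracks should have been censored).
#' @param n_grid Number of evaluation points.
#' @param bw Bandwidth method, `"botev"` or `"silverman"`, or a positive
#'   number to use directly.
#' @return A `runstop_density`: list with `grid`, `values`, `bandwidth`, `n`.
#' @export
kde_speed <- function(samples, v_max, n_grid = 2^14, bw = "botev") {
  if (length(samples) == 0) stop("empty speed sample")
  if (any(!is.finite(samples)) || any(samples < 0)) {
    stop("speeds must be finite and non-negative")
  }
  if (any(samples > v_max)) {
    stop("speed sample exceeds v_max; censor the dataset first")
  }
  h <- resolve_bandwidth(samples, bw)
  h <- max(h, 2 * v_max / n_grid)  # must be representable on the grid
  d_pos <- density(samples, bw = h, from = 0, to = v_max, n = n_grid)
  d_neg <- density(samples, bw = h, from = -v_max, to = 0, n = n_grid)
  d_hi <- density(samples, bw = h, from = v_max, to = 2 * v_max, n = n_grid)
  # reflect kernel mass that spilled outside the supported speed range
  vals <- d_pos$y + rev(d_neg$y) + rev(d_hi$y)
  structure(list(grid = d_pos$x, values = vals, bandwidth = h,
                 n = length(samples)),
            class = "runstop_density")
}

#' Circular kernel density estimate of framewise angle changes
#'
#' Gaussian-kernel KDE on the circle: samples are wrapped to `(-pi, pi]` and
#' kernel mass is re-wrapped across the +/-pi boundary so the estimate is
#' periodic and integrates to one over a single period.
#'
#' @param samples Angles in radians.
#' @param n_grid Number of evaluation points on `(-pi, pi]`.
#' @param bw As in [kde_speed()].
#' @return A `runstop_density` whose `grid` spans `[-pi, pi]`.
#' @export
kde_angle <- function(samples, n_grid = 2^10, bw = "botev") {
  if (length(samples) == 0) stop("empty angle sample")
  x <- wrap_angle(samples)
  h <- resolve_bandwidth(x, bw)
  h <- max(h, 2 * (2 * pi) / n_grid)  # must be representable on the grid
  h <- min(h, pi / 2)  # wider kernels make no sense on the circle
  ext <- c(x - 2 * pi, x, x + 2 * pi)
  d <- density(ext, bw = h, from = -pi, to = pi, n = n_grid)
  structure(list(grid = d$x, values = 3 * d$y, bandwidth = h, n = length(x)),
            class = "runstop_density")
}

resolve_bandwidth <- function(x, bw) {
  if (is.numeric(bw)) {
    stopifnot(length(bw) == 1L, bw > 0)
    return(bw)
  }
  bw <- match.arg(bw, c("botev", "silverman"))
  # The diffusion plug-in assumes an absolutely continuous density; on
  # effectively discrete samples (mostly tied values) it collapses towards
  # zero bandwidth, so fall back to Silverman's rule in that regime.
  ties <- length(unique(signif(x, 8))) < max(10, 0.1 * length(x))
  if (bw == "botev" && !ties) {
    h <- tryCatch(botev_bandwidth(x), error = function(e) NA_real_)
    if (is.finite(h) && h > 0) return(h)
  }
  bw.nrd0(x)  # never returns zero, even for constant samples
}

#' Diffusion plug-in bandwidth (Botev-Grotowski-Kroese)
#'
#' Solves the fixed-point equation of the diffusion-based plug-in bandwidth
#' selector on a dyadic grid via the discrete cosine transform. Errors on
#' degenerate samples (zero range); callers are expected to fall back to
#' Silverman's rule in that case.
#'
#' @param x Numeric sample.
#' @param n_grid Dyadic grid size used internally.
#' @return Bandwidth (same units as `x`).
#' @export
botev_bandwidth <- function(x, n_grid = 2^14) {
  n <- length(unique(x))
  rng <- range(x)
  R <- diff(rng) * 1.1
  if (R <= 0 || n < 2) stop("degenerate sample")
  lo <- rng[1] - diff(rng) * 0.05
  counts <- tabulate(pmin(pmax(floor((x - lo) / R * n_grid) + 1L, 1L), n_grid),
                     nbins = n_grid)
  a <- dct1d(counts / length(x))
  I <- (seq_len(n_grid - 1L))^2
  a2 <- (a[-1] / 2)^2
  fixed_point <- function(t) {
    l <- 7
    f <- 2 * pi^(2 * l) * sum(I^l * a2 * exp(-I * pi^2 * t))
    for (s in (l - 1):2) {
      K0 <- prod(seq(1, 2 * s - 1, by = 2)) / sqrt(2 * pi)
      const <- (1 + (1 / 2)^(s + 1 / 2)) / 3
      time <- (2 * const * K0 / (n * f))^(2 / (3 + 2 * s))
      f <- 2 * pi^(2 * s) * sum(I^s * a2 * exp(-I * pi^2 * time))
    }
    t - (2 * n * sqrt(pi) * f)^(-2 / 5)
  }
  t_star <- tryCatch(
    stats::uniroot(fixed_point, c(1e-12, 0.1), tol = 1e-12)$root,
    error = function(e) 0.28 * n^(-2 / 5))
  sqrt(t_star) * R
}

# DCT-II (unitary up to the conventional scaling used by the plug-in).
dct1d <- function(x) {
  n <- length(x)
  w <- c(1, 2 * exp(-1i * seq_len(n - 1L) * pi / (2 * n)))
  x2 <- c(x[seq(1L, n, by = 2L)], x[seq(2L * (n %/% 2L), 2L, by = -2L)])
  Re(w * fft(x2))
}

# Trapezoidal integral of a runstop_density over its grid.
density_integral <- function(d) {
  sum(diff(d$grid) * (head(d$values, -1) + tail(d$values, -1)) / 2)
}

#' Build the empirical observation model from mutant-strain tracks
#'
#' Constructs the per-state observation densities used by the HMM. The speed
#' density of the stop state is the KDE of framewise speeds observed in the
#' non-motile mutant, and that of the run state comes from the
#' non-chemotactic mutant. Both are floored by adding `floor_eps` so no
#' permissible speed has exactly zero density (a zero observation density
#' would declare a displacement to be in neither state, breaking the
#' two-state assumption).
#'
#' The angle density depends on the previous state as well as the current
#' one: tracking a stopped cell is noise-dominated, so the apparent heading
#' during a stop is unreliable and the angle observed at a stop-to-run
#' transition must be judged against the stop-phase (non-motile) angle
#' distribution rather than the tight run-phase one. Accordingly the
#' non-motile angle KDE serves every state pair involving a stop --
#' (stop,stop), (run,stop), (stop,run) -- and the non-chemotactic angle KDE
#' serves (run,run) only. The mapping is stored in the model (`angle_map`)
#' and can be overridden. Angle densities are floored like the speed
#' densities, for the same reason.
#'
#' A source dataset whose tracks contain fewer than `min_angle_samples`
#' well-defined angle changes (a noiseless stationary cell has none: every
#' displacement is zero-length) contributes the circular uniform density
#' instead, the isotropic limit appropriate for a direction carrying no
#' information.
#'
#' @param nonmotile,nonchemotactic [trackset]s of the two mutant strains,
#'   already censored.
#' @param v_max Upper speed bound in um/s; should equal the censoring
#'   threshold `rho_fs`.
#' @param floor_eps Positivity floor added to the stored densities
#'   (per um/s for speeds, per radian for angles).
#' @param bw Bandwidth method passed to [kde_speed()] / [kde_angle()].
#' @param min_angle_samples Minimum number of valid angle changes required
#'   before an empirical angle density is used.
#' @param angle_map Named character vector mapping the state pairs
#'   `c("ss", "sr", "rs", "rr")` (previous state then current state,
#'   s = stop, r = run) to `"nonmotile"` or `"nonchemotactic"`.
#' @return An object of class `observation_model`.
#' @export
build_observation_model <- function(nonmotile, nonchemotactic,
                                    v_max = 100, floor_eps = 1e-6,
                                    bw = "botev", min_angle_samples = 10,
                                    angle_map = c(ss = "nonmotile",
                                                  sr = "nonmotile",
                                                  rs = "nonmotile",
                                                  rr = "nonchemotactic")) {
  stopifnot(v_max > 0, floor_eps >= 0)
  stopifnot(setequal(names(angle_map), c("ss", "sr", "rs", "rr")),
            all(angle_map %in% c("nonmotile", "nonchemotactic")))
  kin <- list(nonmotile = track_kinematics(nonmotile),
              nonchemotactic = track_kinematics(nonchemotactic))
  speed <- lapply(kin, function(k) {
    if (nrow(k) == 0) stop("no framewise speeds in mutant dataset")
    kde_speed(k$v, v_max = v_max, bw = bw)
  })
  angle <- lapply(names(kin), function(nm) {
    k <- kin[[nm]]
    th <- k$theta[!is.na(k$theta) & !k$theta_flag]
    if (length(th) < min_angle_samples) {
      structure(list(grid = seq(-pi, pi, length.out = 2^10),
                     values = rep(1 / (2 * pi), 2^10),
                     bandwidth = NA_real_, n = length(th), uniform = TRUE),
                class = "runstop_density")
    } else {
      kde_angle(th, bw = bw)
    }
  })
  names(angle) <- names(kin)
  structure(list(speed_stop = speed$nonmotile,
                 speed_run = speed$nonchemotactic,
                 angle_nonmotile = angle$nonmotile,
                 angle_nonchemotactic = angle$nonchemotactic,
                 angle_map = angle_map,
                 v_max = v_max, floor_eps = floor_eps),
            class = "observation_model")
}

#' @export
print.observation_model <- function(x, ...) {
  unif <- function(d) if (isTRUE(d$uniform)) " (circular uniform)" else ""
  cat("<observation_model>\n",
      sprintf("  speed densities: stop n=%d, run n=%d on [0, %g] um/s\n",
              x$speed_stop$n, x$speed_run$n, x$v_max),
      sprintf("  angle densities: non-motile n=%d%s, non-chemotactic n=%d%s\n",
              x$angle_nonmotile$n, unif(x$angle_nonmotile),
              x$angle_nonchemotactic$n, unif(x$angle_nonchemotactic)),
      sprintf("  floor_eps = %g; angle map: %s\n", x$floor_eps,
              paste(names(x$angle_map), x$angle_map, sep = "=", collapse = ", ")),
      sep = "")
  invisible(x)
}

# Evaluate a stored density by linear interpolation on its grid.
eval_density <- function(d, x) {
  approx(d$grid, d$values, xout = x, rule = 1)$y
}

# Floored speed density of state j (1 stop, 2 run) at speeds v.
om_speed <- function(model, j, v) {
  if (any(v < 0 | v > model$v_max)) {
    bad <- which(v < 0 | v > model$v_max)[1]
    stop("observed speed ", signif(v[bad], 4), " um/s (step ", bad,
         ") is outside the permissible range [0, ", model$v_max,
         "]; the track should have been censored")
  }
  d <- if (j == .STOP) model$speed_stop else model$speed_run
  eval_density(d, v) + model$floor_eps
}

# Floored angle density for previous state i, current state j, at angles th.
om_angle <- function(model, i, j, th) {
  key <- paste0(c("s", "r")[i], c("s", "r")[j])
  src <- model$angle_map[[key]]
  d <- if (src == "nonmotile") model$angle_nonmotile else model$angle_nonchemotactic
  eval_density(d, wrap_angle(th)) + model$floor_eps
}

#' Heuristic speed cutoff from the observation model
#'
#' The heuristic classifier needs a single cutoff speed separating stop-like
#' from run-like framewise speeds. It is chosen as the intersection of the
#' two empirical speed densities: the smallest speed above the mode of the
#' stop density at which the run density exceeds the stop density, located
#' by linear interpolation between grid points. Densities are compared
#' before flooring.
#'
#' @param model An [build_observation_model()] result.
#' @return Cutoff speed in um/s.
#' @export
heuristic_cutoff <- function(model) {
  g <- model$speed_stop$grid
  f_stop <- model$speed_stop$values
  f_run <- approx(model$speed_run$grid, model$speed_run$values,
                  xout = g, rule = 2)$y
  mode_idx <- which.max(f_stop)
  diff_fun <- f_run - f_stop
  idx <- which(diff_fun > 0 & seq_along(g) > mode_idx)
  if (length(idx) == 0) {
    stop("speed densities never cross above the stop mode; ",
         "the two populations are not separable")
  }
  i <- idx[1]
  if (i == 1) return(g[1])
  # linear interpolation of the sign change between grid points i-1 and i
  x0 <- g[i - 1]; x1 <- g[i]
  y0 <- diff_fun[i - 1]; y1 <- diff_fun[i]
  if (y1 == y0) return(x1)
  x0 - y0 * (x1 - x0) / (y1 - y0)
}

#' Estimate a diffusion coefficient from non-motile tracks
#'
#' Computes the ensemble mean squared displacement (MSD) over lag times,
#' pooling all tracks and time origins, then fits a straight line to the
#' linear region (lags beyond `burn_in`). In 2D, `MSD(tau) = 4 * D * tau`,
#' so the returned estimate is a quarter of the fitted slope. Short lags are
#' excluded because uncorrelated localisation noise adds a constant offset
#' that distorts the origin of the MSD curve.
#'
#' @param x A [trackset] of non-motile (or otherwise diffusive) tracks whose
#'   tracks have at least 10 frames.
#' @param max_lag Largest lag (in frames) entering the MSD curve.
#' @param burn_in Number of initial lags excluded from the linear fit.
#' @return A list with `D` (um^2/s), `msd` (tibble of `lag_s`, `msd`), and
#'   `fit` (the `lm` object).
#' @export
estimate_diffusion <- function(x, max_lag = 20, burn_in = 4) {
  dt <- track_dt(x)
  pos <- split_positions(x)
  if (any(vapply(pos, nrow, 0L) < 10L)) {
    stop("all tracks must have at least 10 frames for the MSD estimate")
  }
  max_lag <- min(max_lag, min(vapply(pos, nrow, 0L)) - 1L)
  if (max_lag <= burn_in + 1L) stop("tracks too short for the requested lags")
  msd <- vapply(seq_len(max_lag), function(lag) {
    sq <- unlist(lapply(pos, function(p) {
      n <- nrow(p)
      d <- p[(lag + 1):n, , drop = FALSE] - p[1:(n - lag), , drop = FALSE]
      rowSums(d^2)
    }))
    mean(sq)
  }, 0)
  tab <- tibble::tibble(lag_s = seq_len(max_lag) * dt, msd = msd)
  use <- tab[seq_len(max_lag) > burn_in, ]
  fit <- lm(msd ~ lag_s, data = use)
  list(D = unname(coef(fit)[["lag_s"]]) / 4, msd = tab, fit = fit)
}

#' Serialise an observation model
#'
#' Writes the full model (grids included) to a single JSON file so that
#' segmentation runs need not re-fit the densities, and reads it back.
#'
#' @param model An `observation_model`.
#' @param path File path.
#' @return `read_observation_model()` returns the restored model.
#' @export
write_observation_model <- function(model, path) {
  plain <- lapply(unclass(model), function(x) {
    if (inherits(x, "runstop_density")) unclass(x) else x
  })
  plain$angle_map <- as.list(plain$angle_map)  # keep the pair names in JSON
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observation_model
#' @export
read_observation_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("speed_stop", "speed_run", "angle_nonmotile",
              "angle_nonchemotactic")) {
    class(m[[f]]) <- "runstop_density"
  }
  m$angle_map <- unlist(m$angle_map)
  class(m) <- "observation_model"
  m
}
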
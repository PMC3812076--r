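#' Detection settings
#'
#' Thresholds of the frame-by-frame centroid detector. After per-pixel
#' background subtraction, pixels whose intensity lies strictly above
#' `t_low` and strictly below `t_high` are kept (the band rejects both the
#' background and saturated artefacts); 4-connected clusters smaller than
#' `a_min` pixels are discarded as sub-cellular speckle.
#'
#' @param t_low,t_high Intensity band limits after background subtraction
#'   (`t_low < t_high`).
#' @param a_min Minimum cluster size in pixels.
#' @param absolute Use the absolute value of the background-subtracted
#'   intensity before thresholding (for dark-background imagery where cells
#'   may appear darker than the background).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(t_low, t_high, a_min = 20, absolute = FALSE) {
  stopifnot(t_low < t_high, a_min >= 1)
  structure(list(t_low = t_low, t_high = t_high, a_min = a_min,
                 absolute = absolute),
            class = "detection_config")
}

#' Detect cell centroids in a greyscale image stack
#'
#' Implements the object-detection stage of a tracking pipeline:
#' \enumerate{
#'   \item compute the background value of each pixel as its mean intensity
#'     over all frames;
#'   \item subtract the background from every frame;
#'   \item keep pixels with background-subtracted intensity above `t_low`
#'     and below `t_high`;
#'   \item label 4-connected clusters of surviving pixels;
#'   \item discard clusters of fewer than `a_min` pixels;
#'   \item report the centroid (unweighted centre of mass) of each
#'     remaining cluster.
#' }
#' Detections are invariant to adding a constant to every pixel of every
#' frame, since the mean background absorbs it. Data association of
#' detections into tracks is a separate concern and is not performed here.
#'
#' @param stack A numeric 3D array (rows x cols x frames) or a list of
#'   equally-sized numeric matrices, with at least two frames.
#' @param config A [detection_config()].
#' @return A tibble with columns `frame` (1-based), `x_px`, `y_px`
#'   (0-based pixel coordinates: x = column, y = row) and `cluster_px`.
#' @export
detect_centroids <- function(stack, config) {
  stopifnot(inherits(config, "detection_config"))
  frames <- as_frame_list(stack)
  if (length(frames) < 2L) stop("image stack must contain at least 2 frames")
  dims <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), dims), TRUE))) {
    stop("all frames must have identical dimensions")
  }
  background <- Reduce(`+`, frames) / length(frames)
  rows <- lapply(seq_along(frames), function(fi) {
    img <- frames[[fi]] - background
    if (config$absolute) img <- abs(img)
    mask <- img > config$t_low & img < config$t_high
    lab <- label_components4(mask)
    if (max(lab) == 0L) return(NULL)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= config$a_min)
    if (length(keep) == 0L) return(NULL)
    idx <- which(lab > 0L, arr.ind = TRUE)
    comp <- lab[lab > 0L]
    cent <- lapply(keep, function(k) {
      pix <- idx[comp == k, , drop = FALSE]
      # 0-based, x = column, y = row
      c(x = mean(pix[, 2]) - 1, y = mean(pix[, 1]) - 1, n = nrow(pix))
    })
    cent <- do.call(rbind, cent)
    tibble::tibble(frame = fi, x_px = unname(cent[, "x"]),
                   y_px = unname(cent[, "y"]),
                   cluster_px = as.integer(cent[, "n"]))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(tibble::tibble(frame = integer(), x_px = numeric(),
                          y_px = numeric(), cluster_px = integer()))
  }
  do.call(rbind, rows)
}

as_frame_list <- function(stack) {
  if (is.list(stack)) return(lapply(stack, as.matrix))
  if (is.array(stack) && length(dim(stack)) == 3L) {
    return(lapply(seq_len(dim(stack)[3]), function(i) stack[, , i]))
  }
  stop("`stack` must be a 3D array or a list of matrices")
}

# 4-connected component labelling. Uses EBImage::bwlabel (verified to use
# 4-connectivity) when available; otherwise a two-pass union-find fallback.
label_components4 <- function(mask) {
  storage.mode(mask) <- "integer"
  if (requireNamespace("EBImage", quietly = TRUE)) {
    lab <- EBImage::bwlabel(mask)
    return(matrix(as.integer(lab), nrow(mask), ncol(mask)))
  }
  label_components4_r(mask)
}

label_components4_r <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      up <- if (i > 1L) lab[i - 1L, j] else 0L
      left <- if (j > 1L) lab[i, j - 1L] else 0L
      if (up == 0L && left == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else if (up != 0L && left != 0L) {
        lab[i, j] <- min(up, left)
        ru <- find(up); rl <- find(left)
        if (ru != rl) parent[max(ru, rl)] <- min(ru, rl)
      } else {
        lab[i, j] <- max(up, left)
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path Path to a greyscale multi-page TIFF.
#' @return A list of numeric matrices, one per frame.
#' @export
read_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF stacks requires the `tiff` package")
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f <- f[, , 1]
    as.matrix(f)
  })
}

#' Convert pixel detections to micrometre track coordinates
#'
#' @param detections A tibble from [detect_centroids()].
#' @param px_size Pixel size in micrometres.
#' @return The tibble with added `x_um`, `y_um` columns.
#' @export
detections_to_um <- function(detections, px_size) {
  stopifnot(px_size > 0)
  detections$x_um <- detections$x_px * px_size
  detections$y_um <- detections$y_px * px_size
  detections
}
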
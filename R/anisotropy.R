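#' Mask of high-energy anisotropy features
#'
#' Thresholds the tensor energy map to select the "white" high-energy
#' features whose orientation distribution is the pipeline's headline polar
#' statistic. The default keeps the top 5% of pixels by energy (the
#' quantile method); Otsu's method on the energy histogram is available as
#' an alternative. The threshold value and method are stored as attributes
#' for provenance.
#'
#' @param tf a `tensor_field`.
#' @param method `"quantile"` (default) or `"otsu"`.
#' @param quantile probability cut for the quantile method (default 0.95:
#'   top 5% of pixels).
#' @return logical matrix with attributes `threshold` and `method`.
#' @export
high_energy_mask <- function(tf, method = c("quantile", "otsu"),
                             quantile = 0.95) {
  method <- match.arg(method)
  e <- tf$energy
  if (max(e) <= 0) {
    warning("high_energy_mask: energy is identically zero; empty mask")
    mask <- matrix(FALSE, nrow(e), ncol(e))
    attr(mask, "threshold") <- NA_real_
    attr(mask, "method") <- method
    return(mask)
  }
  thr <- if (method == "quantile") {
    stats::quantile(e, quantile, names = FALSE)
  } else {
    .otsu_threshold(e)
  }
  mask <- e > thr
  attr(mask, "threshold") <- thr
  attr(mask, "method") <- method
  mask
}

# Otsu threshold on a 256-bin histogram of a non-negative map
.otsu_threshold <- function(x) {
  v <- as.vector(x)
  brks <- seq(min(v), max(v), length.out = 257L)
  cnt <- hist(v, breaks = brks, plot = FALSE)$counts
  p <- cnt / sum(cnt)
  mids <- (brks[-1] + brks[-257]) / 2
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[256]
  sb <- (mt * w0 - m0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Polar orientation histogram of a tensor field
#'
#' Bins the per-pixel orientations over a selection of pixels (optionally
#' a high-energy mask and/or a rectangular ROI), optionally weighting each
#' pixel by its energy. The histogram covers [-90, 90) with wrap-aware
#' binning (orientations are pi-periodic; the display view duplicates the
#' curve to [90, 270)). Also retains the selected angles (subsampled
#' deterministically beyond `max_sample`) so circular summaries and
#' permutation comparisons can operate on the underlying data.
#'
#' @param tf a `tensor_field`.
#' @param mask optional logical matrix selecting pixels (e.g. from
#'   [high_energy_mask()]).
#' @param roi optional rectangle `c(x0, y0, w, h)` in um.
#' @param weighting `"none"` or `"energy"`.
#' @param n_bins number of bins over 180 degrees (default 72, 2.5 deg/bin).
#' @param pixel_size_um scale used to interpret `roi` (default 0.5).
#' @param max_sample cap on retained per-pixel angles (default 20000).
#' @return object of class `orientation_histogram`: list with
#'   `bin_edges_deg`, `bin_mid_deg`, `weights`, `normalized`, `weighting`,
#'   `roi`, `display_scale`, `summary` (a [circular_summary()]), plus the
#'   retained `angles_deg` and `angle_weights`.
#' @export
orientation_polar <- function(tf, mask = NULL, roi = NULL,
                              weighting = c("none", "energy"),
                              n_bins = 72L, pixel_size_um = 0.5,
                              max_sample = 20000L) {
  weighting <- match.arg(weighting)
  sel <- !is.na(tf$orientation_deg)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(sel)))
      stop("orientation_polar: mask shape mismatch")
    sel <- sel & mask
  }
  if (!is.null(roi)) {
    h <- nrow(sel); w <- ncol(sel); ps <- pixel_size_um
    c0 <- floor(roi[1] / ps) + 1L; r0 <- floor(roi[2] / ps) + 1L
    c1 <- ceiling((roi[1] + roi[3]) / ps); r1 <- ceiling((roi[2] + roi[4]) / ps)
    if (c0 < 1L || r0 < 1L || c1 > w || r1 > h)
      stop("orientation_polar: ROI outside the frame")
    rm <- matrix(FALSE, h, w)
    rm[r0:r1, c0:c1] <- TRUE
    sel <- sel & rm
  }
  ang <- tf$orientation_deg[sel]
  wts <- if (weighting == "energy") tf$energy[sel] else rep(1, length(ang))
  if (length(ang) == 0L)
    warning("orientation_polar: empty selection")
  edges <- seq(-90, 90, length.out = n_bins + 1L)
  bin <- findInterval(fold_orientation_deg(ang), edges,
                      rightmost.closed = TRUE)
  bin[bin > n_bins] <- 1L   # +90 wraps onto -90
  wsum <- vapply(seq_len(n_bins), function(b) sum(wts[bin == b]), numeric(1))
  tot <- sum(wsum)
  if (length(ang) > max_sample) {
    idx <- round(seq(1L, length(ang), length.out = max_sample))
    ang_keep <- ang[idx]; wts_keep <- wts[idx]
  } else {
    ang_keep <- ang; wts_keep <- wts
  }
  structure(list(bin_edges_deg = edges,
                 bin_mid_deg = (edges[-1] + edges[-(n_bins + 1L)]) / 2,
                 weights = wsum,
                 normalized = if (tot > 0) wsum / tot else wsum,
                 weighting = weighting, roi = roi, display_scale = 1,
                 summary = circular_summary(ang_keep, wts_keep),
                 angles_deg = ang_keep, angle_weights = wts_keep),
            class = "orientation_histogram")
}

#' @export
print.orientation_histogram <- function(x, ...) {
  cat(sprintf(
    "<orientation_histogram> %d bins, weighting '%s', display x%g\n",
    length(x$weights), x$weighting, x$display_scale))
  print(x$summary)
  invisible(x)
}

#' Dominant (modal) orientation of a histogram
#'
#' With `smooth_bins = 0` the raw argmax bin midpoint is returned. When the
#' bin width is finer than the spread of the distribution the raw argmax
#' jitters between near-equal neighbouring bins; `smooth_bins > 0` reads
#' the peak off a circular moving average over `2 * smooth_bins + 1` bins
#' instead, the way a peak is read off a smooth polar curve.
#'
#' @param h an `orientation_histogram`.
#' @param smooth_bins non-negative integer half-width of the circular
#'   moving average (default 0 = raw argmax).
#' @return bin midpoint (degrees) of the maximal (smoothed) weight.
#' @export
histogram_mode_deg <- function(h, smooth_bins = 0L) {
  w <- h$weights
  if (smooth_bins > 0L) {
    n <- length(w)
    k <- 2L * smooth_bins + 1L
    wx <- c(utils::tail(w, smooth_bins), w, utils::head(w, smooth_bins))
    w <- vapply(seq_len(n), function(i) mean(wx[i:(i + k - 1L)]), numeric(1))
  }
  h$bin_mid_deg[which.max(w)]
}

#' Compare two orientation histograms
#'
#' Reports the axial circular-mean difference and resultant-length
#' difference, plus a seeded permutation p-value for equality of the two
#' circular distributions. The permutation statistic is the axial distance
#' between weighted circular means of the retained per-pixel angle
#' samples; group labels are permuted `n_perm` times.
#'
#' @param a,b `orientation_histogram` objects with identical binning.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `mean_difference_deg`, `resultant_difference`,
#'   `p_value`, `n_perm`.
#' @export
compare_histograms <- function(a, b, n_perm = 999L, seed = 1L) {
  if (length(a$weights) != length(b$weights) ||
      max(abs(a$bin_edges_deg - b$bin_edges_deg)) > 1e-9)
    stop("compare_histograms: binning mismatch")
  obs <- axial_difference_deg(a$summary$circular_mean_deg,
                              b$summary$circular_mean_deg)
  rdiff <- a$summary$resultant_length - b$summary$resultant_length
  ang <- c(a$angles_deg, b$angles_deg)
  wts <- c(a$angle_weights, b$angle_weights)
  na <- length(a$angles_deg)
  n <- length(ang)
  stat <- function(lab) {
    ca <- circular_summary(ang[lab], wts[lab])
    cb <- circular_summary(ang[!lab], wts[!lab])
    axial_difference_deg(ca$circular_mean_deg, cb$circular_mean_deg)
  }
  perm <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- logical(n)
      lab[sample.int(n, na)] <- TRUE
      stat(lab)
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  list(mean_difference_deg = obs, resultant_difference = rdiff,
       p_value = p, n_perm = n_perm)
}

#' Scale a histogram for polar display
#'
#' Multiplies the bin weights by `factor` and records the display scale,
#' the device used to make a low-signal ROI-restricted curve comparable to
#' a full-frame curve on the same polar axes (e.g. a x10 green curve next
#' to the raw red one). The normalized view and the circular summary are
#' unchanged.
#'
#' @param h an `orientation_histogram`.
#' @param factor positive display factor.
#' @return the scaled histogram.
#' @export
scale_for_display <- function(h, factor) {
  if (!is.numeric(factor) || factor <= 0)
    stop("scale_for_display: factor must be positive")
  h$weights <- h$weights * factor
  h$display_scale <- h$display_scale * factor
  h
}

#' Display view of a polar histogram over the full circle
#'
#' Orientations are pi-periodic; polar renderings duplicate the curve to
#' [90, 270) so the plot closes.
#'
#' @param h an `orientation_histogram`.
#' @return data.frame with `angle_deg` over [-90, 270) and `weight`.
#' @export
polar_display_frame <- function(h) {
  data.frame(angle_deg = c(h$bin_mid_deg, h$bin_mid_deg + 180),
             weight = rep(h$weights, 2L))
}
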
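#' Segment nuclei in a fluorescence (DAPI-like) channel
#'
#' Classical pipeline fulfilling the same output contract as a learned
#' detector: large-radius morphological opening for background
#' subtraction, Gaussian smoothing, Otsu thresholding on the smoothed
#' foreground, distance-transform watershed to split touching blobs, and
#' an area filter. Returns an integer label mask (0 = background,
#' consecutive labels from 1).
#'
#' @param dapi a [raster_image()] (nuclei channel) or matrix.
#' @param pixel_size_um pixel size; taken from the raster if available.
#' @param min_area_um2,max_area_um2 area filter bounds (defaults 20 and
#'   500 um^2, the plausible range of endothelial nuclei cross-sections).
#' @param expected_radius_um typical nucleus radius, controls the
#'   background-opening radius (5x) and the smoothing sigma.
#' @param contour_fraction fraction of the per-object smoothed peak at
#'   which the object footprint is cut (default 0.6, calibrated so the
#'   footprint of a soft-edged blob matches its nominal-radius disc under
#'   the pipeline's smoothing).
#' @return integer label matrix with attribute `pixel_size_um`.
#' @export
segment_nuclei <- function(dapi, pixel_size_um = NULL,
                           min_area_um2 = 20, max_area_um2 = 500,
                           expected_radius_um = 3, contour_fraction = 0.6) {
  m <- if (is_raster_image(dapi)) dapi$pixels else as.matrix(dapi)
  if (is.null(pixel_size_um))
    pixel_size_um <- if (is_raster_image(dapi)) dapi$pixel_size_um else 0.5
  ps <- pixel_size_um
  z <- .rescale01(m)
  out0 <- matrix(0L, nrow(m), ncol(m))
  attr(out0, "pixel_size_um") <- ps
  if (all(z == 0)) return(out0)
  # EBImage works column-major x/y; transpose in and out
  ei <- EBImage::Image(t(z))
  bg_r <- max(3L, round(5 * expected_radius_um / ps))
  brush <- EBImage::makeBrush(2L * bg_r + 1L, shape = "disc")
  bg <- EBImage::opening(ei, brush)
  fg <- ei - bg
  fg[fg < 0] <- 0
  sm <- EBImage::gblur(fg, sigma = max(1, 0.25 * expected_radius_um / ps))
  rng <- range(sm)
  if (rng[2] <= rng[1]) return(out0)
  smn <- (sm - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(smn, range = c(0, 1))
  bin <- smn > thr
  if (!any(bin)) return(out0)
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  labm <- t(EBImage::imageData(lab))
  # refine each object to a fixed fraction of its own smoothed peak: the
  # Otsu cut dilates soft-edged blobs, while a per-object relative contour
  # is invariant to intensity rescaling and tracks the nominal footprint
  smm <- t(EBImage::imageData(sm))
  if (max(labm) > 0) {
    peak <- vapply(seq_len(max(labm)), function(i) {
      v <- smm[labm == i]
      if (length(v)) max(v) else 0
    }, numeric(1))
    labm[smm < contour_fraction * peak[pmax(labm, 1L)] | labm == 0L] <- 0L
  }
  # area filter in um^2, then relabel consecutively
  areas_px <- tabulate(labm[labm > 0])
  keep <- which(areas_px * ps^2 >= min_area_um2 &
                  areas_px * ps^2 <= max_area_um2)
  out <- matrix(0L, nrow(labm), ncol(labm))
  if (length(keep)) {
    remap <- integer(max(labm))
    remap[keep] <- seq_along(keep)
    pos <- labm > 0
    out[pos] <- remap[labm[pos]]
  }
  attr(out, "pixel_size_um") <- ps
  out
}

#' Nuclei statistics over a region of interest
#'
#' Object count, per-object areas in um^2, percentage coverage of the ROI
#' by labelled pixels, and an area histogram — the N_obj / Cvg summary
#' reported per 350 um x 350 um region.
#'
#' @param labels integer label mask (from [segment_nuclei()] or ground
#'   truth); attribute `pixel_size_um` or argument must give the scale.
#' @param roi optional ROI as `c(x0, y0, width, height)` in um (origin at
#'   the top-left pixel corner); default the full frame.
#' @param pixel_size_um pixel size in um (defaults to the mask attribute).
#' @param bin_width_um2 width of the area-histogram bins (default 10).
#' @return object of class `nuclei_stats`: list with `n_obj`, `areas_um2`,
#'   `coverage_pct`, `roi_um`, `histogram` (data.frame mid/count).
#' @export
nuclei_stats <- function(labels, roi = NULL, pixel_size_um = NULL,
                         bin_width_um2 = 10) {
  ps <- if (!is.null(pixel_size_um)) pixel_size_um
        else attr(labels, "pixel_size_um")
  if (is.null(ps)) stop("nuclei_stats: pixel size unknown")
  h <- nrow(labels); w <- ncol(labels)
  if (is.null(roi)) roi <- c(0, 0, w * ps, h * ps)
  c0 <- floor(roi[1] / ps) + 1L; r0 <- floor(roi[2] / ps) + 1L
  c1 <- ceiling((roi[1] + roi[3]) / ps); r1 <- ceiling((roi[2] + roi[4]) / ps)
  if (c0 < 1L || r0 < 1L || c1 > w || r1 > h)
    stop("nuclei_stats: ROI outside the image")
  sub <- labels[r0:r1, c0:c1, drop = FALSE]
  ids <- sort(unique(sub[sub > 0]))
  areas_px <- if (length(ids)) tabulate(match(sub[sub > 0], ids)) else integer(0)
  areas_um2 <- areas_px * ps^2
  coverage_pct <- 100 * sum(sub > 0) / length(sub)
  hist_df <- if (length(areas_um2)) {
    brks <- seq(0, max(areas_um2) + bin_width_um2, by = bin_width_um2)
    cnt <- hist(areas_um2, breaks = brks, plot = FALSE)
    data.frame(area_um2_mid = cnt$mids, count = cnt$counts)
  } else data.frame(area_um2_mid = numeric(0), count = integer(0))
  structure(list(n_obj = length(ids), areas_um2 = areas_um2,
                 coverage_pct = coverage_pct, roi_um = roi,
                 histogram = hist_df, pixel_size_um = ps),
            class = "nuclei_stats")
}

#' @export
print.nuclei_stats <- function(x, ...) {
  cat(sprintf("<nuclei_stats> N_obj = %d, Cvg = %.2f%% over %g x %g um ROI\n",
              x$n_obj, x$coverage_pct, x$roi_um[3], x$roi_um[4]))
  if (x$n_obj > 0)
    cat(sprintf("  area um^2: median %.1f, range [%.1f, %.1f]\n",
                stats::median(x$areas_um2), min(x$areas_um2),
                max(x$areas_um2)))
  invisible(x)
}

#' Sample rectangular ROIs avoiding an exclusion mask
#'
#' Draws seeded candidate positions until `n_rois` axis-aligned square ROIs
#' are found that do not intersect the exclusion mask (e.g. the pore mask,
#' so that cell-depleted regions are avoided), or errors after a bounded
#' number of attempts.
#'
#' @param img a [raster_image()] or matrix (defines the frame).
#' @param roi_size_um side of the square ROI in um (e.g. 350).
#' @param n_rois number of ROIs requested.
#' @param exclusion_mask optional logical matrix, TRUE = forbidden pixels.
#' @param pixel_size_um scale (defaults to the raster's).
#' @param seed integer seed for the sampler.
#' @param max_attempts total rejection budget.
#' @return list of ROIs, each `c(x0, y0, w, h)` in um.
#' @export
roi_sampler <- function(img, roi_size_um, n_rois = 2L,
                        exclusion_mask = NULL, pixel_size_um = NULL,
                        seed = 1L, max_attempts = 5000L) {
  m <- if (is_raster_image(img)) img$pixels else as.matrix(img)
  ps <- if (!is.null(pixel_size_um)) pixel_size_um
        else if (is_raster_image(img)) img$pixel_size_um else 0.5
  h <- nrow(m); w <- ncol(m)
  side_px <- round(roi_size_um / ps)
  if (side_px > h || side_px > w)
    stop("roi_sampler: ROI does not fit in the frame")
  .with_seed(seed, {
    rois <- list()
    seen <- character(0)
    att <- 0L
    while (length(rois) < n_rois && att < max_attempts) {
      att <- att + 1L
      c0 <- sample.int(w - side_px + 1L, 1L)
      r0 <- sample.int(h - side_px + 1L, 1L)
      key <- paste(r0, c0)
      if (key %in% seen) next
      if (!is.null(exclusion_mask)) {
        sub <- exclusion_mask[r0:(r0 + side_px - 1L),
                              c0:(c0 + side_px - 1L)]
        if (any(sub)) next
      }
      seen <- c(seen, key)
      rois[[length(rois) + 1L]] <-
        c((c0 - 1L) * ps, (r0 - 1L) * ps, roi_size_um, roi_size_um)
    }
    if (length(rois) < n_rois)
      stop("roi_sampler: could not place ", n_rois,
           " ROIs avoiding the exclusion mask")
    rois
  })
}
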
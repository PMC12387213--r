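#' Riesz-filter image gradient
#'
#' Computes the two Riesz components of the grey-level intensity function in
#' the frequency domain, with transfer functions -i u / ||(u,v)|| and
#' -i v / ||(u,v)|| (zero at DC). The Riesz operator is translation-,
#' rotation- and scale-invariant and acts as an all-pass phase-shifting
#' gradient, which tempers the amplification of high frequencies relative
#' to a finite-difference derivative.
#'
#' Output components are real-valued and mean-free. `gy` is oriented so that
#' angles derived from (gx, gy) are counterclockwise-positive in the
#' displayed image with 0 deg along the horizontal axis.
#'
#' @param img a [raster_image()] or numeric matrix.
#' @param method `"riesz"` (default) or `"finite_diff"` (central
#'   differences; cross-check only).
#' @return list with matrices `gx` and `gy`.
#' @export
riesz_gradient <- function(img, method = c("riesz", "finite_diff")) {
  method <- match.arg(method)
  m <- if (is_raster_image(img)) img$pixels else as.matrix(img)
  if (!all(is.finite(m))) stop("riesz_gradient: non-finite input")
  m <- m - mean(m)
  if (method == "riesz") return(.riesz_pair_padded(m))
  # central differences, replicate boundary; y points up
  nr <- nrow(m); nc <- ncol(m)
  gx <- (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
  gy_down <- (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
  list(gx = gx, gy = -gy_down)
}

#' Gradient structure tensor field
#'
#' Smooths the gradient products with a normalized Gaussian window (mirror
#' boundary) and derives per-pixel orientation, energy and coherency:
#' energy E is the trace jxx + jyy of the tensor; coherency
#' C = sqrt((jxx - jyy)^2 + 4 jxy^2) / (jxx + jyy) lies in [0, 1], with
#' C = 1 marking high elongation (a dominant local orientation) and C = 0
#' local isotropy. The reported orientation is the structure axis (minor
#' eigenvector of the tensor, i.e. along the filaments), in degrees in
#' [-90, 90), counterclockwise-positive, 0 deg horizontal. Where energy
#' does not exceed `1e-12 * max(energy)` the coherency and orientation are
#' flagged `NA`.
#'
#' @param gx,gy gradient components from [riesz_gradient()].
#' @param window_sigma_px positive Gaussian window sigma in pixels
#'   (default 2, an OrientationJ-like local window).
#' @return object of class `tensor_field` with `jxx`, `jxy`, `jyy`,
#'   `orientation_deg`, `energy`, `coherency`, `window_sigma_px`.
#' @export
structure_tensor <- function(gx, gy, window_sigma_px = 2) {
  if (!is.numeric(window_sigma_px) || window_sigma_px <= 0)
    stop("structure_tensor: window_sigma_px must be positive")
  if (!all(dim(gx) == dim(gy)))
    stop("structure_tensor: gx and gy shapes differ")
  jxx <- .gauss_blur(gx * gx, window_sigma_px)
  jxy <- .gauss_blur(gx * gy, window_sigma_px)
  jyy <- .gauss_blur(gy * gy, window_sigma_px)
  energy <- jxx + jyy
  energy[energy < 0] <- 0        # clip tiny negative FFT round-off
  eps <- 1e-12 * max(energy)
  defined <- energy > eps
  # gradient axis is the major eigenvector; the structure (filament) axis
  # is perpendicular to it
  ori <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi + 90
  ori <- fold_orientation_deg(ori)
  ori[!defined] <- NA_real_
  coh <- matrix(NA_real_, nrow(gx), ncol(gx))
  coh[defined] <- sqrt((jxx[defined] - jyy[defined])^2 +
                         4 * jxy[defined]^2) / energy[defined]
  coh[coh > 1] <- 1
  structure(list(jxx = jxx, jxy = jxy, jyy = jyy,
                 orientation_deg = ori, energy = energy, coherency = coh,
                 window_sigma_px = window_sigma_px),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %d x %d px, window sigma %.3g px\n",
              nrow(x$energy), ncol(x$energy), x$window_sigma_px))
  cat(sprintf("  energy max %.4g, median coherency %.3f (defined pixels)\n",
              max(x$energy), stats::median(x$coherency, na.rm = TRUE)))
  invisible(x)
}

#' Structure-tensor analysis of an image
#'
#' Convenience wrapper: Riesz gradient followed by [structure_tensor()].
#'
#' @inheritParams riesz_gradient
#' @inheritParams structure_tensor
#' @return a `tensor_field`.
#' @export
tensor_analysis <- function(img, window_sigma_px = 2,
                            method = c("riesz", "finite_diff")) {
  g <- riesz_gradient(img, method = match.arg(method))
  structure_tensor(g$gx, g$gy, window_sigma_px)
}

#' Interior margin mask for summary statistics
#'
#' Boundary pixels within `2 * window_sigma` of the frame edge are excluded
#' from summary statistics of tensor fields.
#'
#' @param tf a `tensor_field`.
#' @param factor margin in units of window sigma (default 2).
#' @return logical matrix, TRUE on interior pixels.
#' @export
interior_mask <- function(tf, factor = 2) {
  h <- nrow(tf$energy); w <- ncol(tf$energy)
  m <- ceiling(factor * tf$window_sigma_px)
  out <- matrix(FALSE, h, w)
  out[(m + 1):(h - m), (m + 1):(w - m)] <- TRUE
  out
}

# vectorized HSV -> RGB on [0,1] inputs
.hsv_to_rgb <- function(hue, sat, val) {
  h6 <- pmin(pmax(hue, 0), 1 - 1e-12) * 6
  i <- floor(h6); f <- h6 - i
  p <- val * (1 - sat)
  q <- val * (1 - sat * f)
  t <- val * (1 - sat * (1 - f))
  r <- ifelse(i == 0, val, ifelse(i == 1, q, ifelse(i == 2, p,
        ifelse(i == 3, p, ifelse(i == 4, t, val)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, val, ifelse(i == 2, val,
        ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
        ifelse(i == 3, val, ifelse(i == 4, val, q)))))
  list(r = r, g = g, b = b)
}

#' Hue-saturation-brightness orientation composite
#'
#' Encodes the tensor field as a color image: hue is the local orientation
#' (mapped from [-90, 90) onto the color wheel), saturation is coherency
#' (0 where coherency is undefined), and brightness is the min-max rescaled
#' source intensity.
#'
#' @param tf a `tensor_field`.
#' @param source the source [raster_image()] (or matrix) the tensor was
#'   computed from.
#' @return object of class `hsb_composite` with an `rgb` array
#'   (rows x cols x 3) in [0, 1].
#' @export
hsb_composite <- function(tf, source) {
  src <- if (is_raster_image(source)) source$pixels else as.matrix(source)
  if (!all(dim(src) == dim(tf$energy)))
    stop("hsb_composite: source and tensor shapes differ")
  hue <- (ifelse(is.na(tf$orientation_deg), 0, tf$orientation_deg) + 90) / 180
  sat <- ifelse(is.na(tf$coherency), 0, tf$coherency)
  val <- .rescale01(src)
  ch <- .hsv_to_rgb(hue, sat, val)
  rgb <- array(0, c(nrow(src), ncol(src), 3L))
  rgb[, , 1] <- ch$r; rgb[, , 2] <- ch$g; rgb[, , 3] <- ch$b
  structure(list(rgb = rgb), class = "hsb_composite")
}

#' Write an HSB composite as an 8-bit RGB PNG
#'
#' @param comp an `hsb_composite`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hsb_png <- function(comp, path) {
  png::writePNG(comp$rgb, path)
  invisible(path)
}
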
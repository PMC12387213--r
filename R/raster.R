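#' Raster image with physical pixel size
#'
#' The universal input of the pipeline: a 2-D matrix of real intensities
#' together with the physical pixel size in micrometres and the role the
#' channel plays in a multi-channel acquisition (actin cytoskeleton,
#' nuclei counterstain, bright-field, or other).
#'
#' @param pixels numeric matrix of finite intensities, at least 8 x 8.
#'   Rows are image rows (top to bottom), columns are image columns.
#' @param pixel_size_um positive scalar, physical size of one pixel in um.
#' @param channel_role one of `"actin"`, `"nuclei"`, `"brightfield"`,
#'   `"other"`.
#' @return an object of class `raster_image`.
#' @export
raster_image <- function(pixels, pixel_size_um = 0.5, channel_role = "other") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop("raster_image: image must be at least 8 x 8 pixels")
  if (!all(is.finite(pixels)))
    stop("raster_image: non-finite pixel values")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("raster_image: pixel_size_um must be a positive scalar")
  channel_role <- match.arg(channel_role,
                            c("actin", "nuclei", "brightfield", "other"))
  structure(list(pixels = pixels,
                 pixel_size_um = pixel_size_um,
                 channel_role = channel_role),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px @ %.4g um/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$channel_role))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels)

is_raster_image <- function(x) inherits(x, "raster_image")

#' Read a TIFF or PNG micrograph
#'
#' Reads 8- or 16-bit (or 32-bit float) TIFF, multi-page TIFF, or PNG.
#' Integer images are returned on their native integer scale so that a
#' write/read round trip is exact.
#'
#' @param path file path; format inferred from the extension.
#' @param channel_role role tag attached to the returned image(s).
#' @param pixel_size_um physical pixel size in um.
#' @return a `raster_image`, or a list of them for a multi-page TIFF.
#' @export
read_image <- function(path, channel_role = "other", pixel_size_um = 0.5) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    sidecar <- paste0(path, ".range")
    if (file.exists(sidecar)) {
      # float map stored min-max rescaled; undo using the recorded range
      nums <- scan(sidecar, quiet = TRUE)
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      pages <- lapply(pages, function(p) p * (nums[2] - nums[1]) + nums[1])
    } else {
      pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
      if (!is.list(pages)) pages <- list(pages)
    }
    imgs <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]  # first sample of RGB pages
      raster_image(p, pixel_size_um, channel_role)
    })
    if (length(imgs) == 1L) imgs[[1L]] else imgs
  } else if (ext == "png") {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    raster_image(p, pixel_size_um, channel_role)
  } else {
    stop("read_image: unsupported format '", ext, "' (TIFF/PNG only)")
  }
}

#' Write a raster to TIFF
#'
#' Integer dtypes round-trip exactly; float maps are stored as 32-bit
#' float TIFF, min-max rescaled to [0, 1] (the writer's representable
#' range) with the physical range recorded in a `<path>.range` sidecar
#' that [read_image()] consumes transparently.
#'
#' @param raster a `raster_image` or plain matrix.
#' @param path output path (.tif).
#' @param dtype `"uint8"`, `"uint16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, dtype = c("float32", "uint16", "uint8")) {
  dtype <- match.arg(dtype)
  m <- if (is_raster_image(raster)) raster$pixels else as.matrix(raster)
  if (dtype == "float32") {
    # the TIFF writer clamps samples to [0, 1]; store the map min-max
    # rescaled, with the original range in a small sidecar text file that
    # read_image() uses to restore physical values
    rg <- range(m)
    z <- if (rg[2] > rg[1]) (m - rg[1]) / (rg[2] - rg[1]) else m * 0
    tiff::writeTIFF(z, path, bits.per.sample = 32L, reduce = FALSE)
    writeLines(sprintf("%.17g %.17g", rg[1], rg[2]),
               paste0(path, ".range"))
  } else {
    maxv <- if (dtype == "uint8") 255 else 65535
    if (any(m < 0) || any(m > maxv) || any(m != round(m)))
      stop("write_raster: values not representable as ", dtype)
    # tiff scales [0,1] doubles to the integer range on write
    tiff::writeTIFF(m / maxv, path,
                    bits.per.sample = if (dtype == "uint8") 8L else 16L,
                    reduce = FALSE)
  }
  invisible(path)
}

# ---- internal numerics shared across modules --------------------------------

# fftfreq-style signed frequency vector (cycles per sample)
.fft_freq <- function(n) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / n
}

# Riesz-pair transfer applied in the frequency domain.
# Returns list(gx, gy) where x runs along columns and y points *up*
# (i.e. against the row index), so angles are counterclockwise-positive
# in the displayed image with 0 deg = horizontal.
# `pad` mirror-pads before the FFT to suppress wrap-around ringing from the
# non-periodic frame border (the Riesz kernel has global support).
.riesz_pair_padded <- function(m, pad = NULL) {
  if (is.null(pad)) pad <- min(64L, floor((min(dim(m)) - 1) / 2))
  if (pad %% 2L == 1L) pad <- pad - 1L   # keep padded dims even/even parity
  if (pad > 0L) {
    mp <- .mirror_pad(m, pad)
    g <- .riesz_pair(mp)
    idx_r <- (pad + 1L):(pad + nrow(m))
    idx_c <- (pad + 1L):(pad + ncol(m))
    list(gx = g$gx[idx_r, idx_c], gy = g$gy[idx_r, idx_c])
  } else {
    .riesz_pair(m)
  }
}

.riesz_pair <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  v <- .fft_freq(nr)              # row (vertical, downward) frequency
  u <- .fft_freq(nc)              # column (horizontal) frequency
  U <- matrix(u, nr, nc, byrow = TRUE)
  V <- matrix(v, nr, nc)
  rho <- sqrt(U^2 + V^2)
  fx <- ifelse(rho > 0, -1i * U / rho, 0 + 0i)
  fy <- ifelse(rho > 0, -1i * V / rho, 0 + 0i)
  # zero the Nyquist lines of the odd (purely imaginary) transfer so the
  # inverse transform is exactly real and 90-degree rotation covariance
  # holds to machine precision on even-sized frames
  if (nr %% 2L == 0L) { fx[nr / 2L + 1L, ] <- 0; fy[nr / 2L + 1L, ] <- 0 }
  if (nc %% 2L == 0L) { fx[, nc / 2L + 1L] <- 0; fy[, nc / 2L + 1L] <- 0 }
  Fm <- stats::fft(m)
  gx <- Re(stats::fft(fx * Fm, inverse = TRUE)) / (nr * nc)
  gy_down <- Re(stats::fft(fy * Fm, inverse = TRUE)) / (nr * nc)
  list(gx = gx, gy = -gy_down)
}

# symmetric (mirror) padding by r pixels on every side
.mirror_pad <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc)
    stop("mirror padding radius exceeds image size")
  ri <- c(r:1, 1:nr, nr:(nr - r + 1L))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1L))
  m[ri, ci, drop = FALSE]
}

# circular 2-D convolution with a kernel centred at (1,1) via FFT
.conv2_circ <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(k); kc <- ncol(k)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L, kr <= nr, kc <= nc)
  kp <- matrix(0, nr, nc)
  rr <- ((seq_len(kr) - (kr + 1L) / 2L) %% nr) + 1L
  cc <- ((seq_len(kc) - (kc + 1L) / 2L) %% nc) + 1L
  kp[rr, cc] <- k
  Re(stats::fft(stats::fft(m) * stats::fft(kp), inverse = TRUE)) / (nr * nc)
}

# Gaussian smoothing with mirror boundary handling
.gauss_blur <- function(m, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  r <- max(2L, ceiling(4 * sigma))
  r <- min(r, nrow(m) - 1L, ncol(m) - 1L)   # pad cannot exceed the frame
  k1 <- stats::dnorm(seq(-r, r), sd = sigma)
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  p <- .mirror_pad(m, r)
  out <- .conv2_circ(p, k2)
  out[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m)), drop = FALSE]
}

# min-max rescale to [0,1]; constant input maps to 0
.rescale01 <- function(m) {
  rg <- range(m)
  if (rg[2] > rg[1]) (m - rg[1]) / (rg[2] - rg[1]) else m * 0
}

# run expr with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
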
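#' Pore-lattice specification for a membrane write pattern
#'
#' Regular rectangular (or square) lattice of circular through-pores, the
#' geometry written into the membrane: nominal pore diameter 25 um with
#' centre-to-centre pitch variable between about 50 and 190 um.
#'
#' @param pore_diameter_um pore diameter in um (> 0).
#' @param pitch_x_um,pitch_y_um centre-to-centre spacing along x and y.
#' @param frame_um length-2 frame (width, height) in um.
#' @param allow_overlap permit pore_diameter > pitch (default FALSE).
#' @return list of class `pore_lattice`.
#' @export
pore_lattice <- function(pore_diameter_um = 25, pitch_x_um = 100,
                         pitch_y_um = pitch_x_um,
                         frame_um = c(1000, 1000),
                         allow_overlap = FALSE) {
  if (pore_diameter_um < 0 || pitch_x_um <= 0 || pitch_y_um <= 0)
    stop("pore_lattice: negative diameter or non-positive pitch")
  if (!allow_overlap && pore_diameter_um > min(pitch_x_um, pitch_y_um))
    stop("pore_lattice: pores overlap (diameter > pitch); ",
         "set allow_overlap = TRUE to override")
  structure(list(pore_diameter_um = pore_diameter_um,
                 pitch_x_um = pitch_x_um, pitch_y_um = pitch_y_um,
                 arrangement = if (pitch_x_um == pitch_y_um) "square"
                               else "rectangular",
                 frame_um = as.numeric(frame_um)),
            class = "pore_lattice")
}

#' @export
print.pore_lattice <- function(x, ...) {
  cat(sprintf(
    "<pore_lattice> d = %g um, pitch %g x %g um (%s), frame %g x %g um\n",
    x$pore_diameter_um, x$pitch_x_um, x$pitch_y_um, x$arrangement,
    x$frame_um[1], x$frame_um[2]))
  cat(sprintf("  porosity %.4g%%\n", 100 * porosity(x)))
  invisible(x)
}

#' Fractional-area porosity of a pore pattern
#'
#' For a periodic lattice of cylindrical through-pores the fractional
#' volume equals the fractional area: pi (d/2)^2 / (pitch_x pitch_y).
#' For an explicit list of pore centres, total pore area over frame area.
#'
#' @param lat a [pore_lattice()], or a list with `centers_um` (n x 2),
#'   `pore_diameter_um` and `frame_um` for a custom pattern.
#' @return porosity as a fraction in [0, 1].
#' @export
porosity <- function(lat) {
  if (inherits(lat, "pore_lattice")) {
    r <- lat$pore_diameter_um / 2
    pi * r^2 / (lat$pitch_x_um * lat$pitch_y_um)
  } else if (is.list(lat) && !is.null(lat$centers_um)) {
    r <- lat$pore_diameter_um / 2
    nrow(lat$centers_um) * pi * r^2 / prod(lat$frame_um)
  } else {
    stop("porosity: unsupported pattern description")
  }
}

#' Pore-centre coordinates of a lattice
#'
#' Centres on the rectangular grid (pitch/2 + k * pitch) along each axis,
#' restricted to pores whose disc lies fully inside the frame, in
#' deterministic row-major order (y outer, x inner).
#'
#' @param lat a [pore_lattice()].
#' @return n x 2 matrix of (x, y) centres in um.
#' @export
lattice_coordinates <- function(lat) {
  r <- lat$pore_diameter_um / 2
  xs <- seq(lat$pitch_x_um / 2, lat$frame_um[1], by = lat$pitch_x_um)
  ys <- seq(lat$pitch_y_um / 2, lat$frame_um[2], by = lat$pitch_y_um)
  xs <- xs[xs - r >= 0 & xs + r <= lat$frame_um[1]]
  ys <- ys[ys - r >= 0 & ys + r <= lat$frame_um[2]]
  if (!length(xs) || !length(ys))
    return(matrix(numeric(0), 0L, 2L,
                  dimnames = list(NULL, c("x_um", "y_um"))))
  out <- cbind(x_um = rep(xs, times = length(ys)),
               y_um = rep(ys, each = length(xs)))
  out
}

#' Rasterize a pore lattice to a logical mask
#'
#' Pixel-centre test against the pore discs; shared with the synthetic
#' scene generator.
#'
#' @param lat a [pore_lattice()].
#' @param frame_um frame to rasterize (defaults to the lattice frame).
#' @param pixel_size_um raster resolution.
#' @return logical matrix (TRUE inside pores).
#' @export
rasterize_pores <- function(lat, frame_um = lat$frame_um,
                            pixel_size_um = 0.5) {
  lat2 <- lat
  lat2$frame_um <- as.numeric(frame_um)
  centers <- lattice_coordinates(lat2)
  .rasterize_discs(centers, lat$pore_diameter_um / 2, lat2$frame_um,
                   pixel_size_um)
}

#' Monte-Carlo raster estimate of lattice porosity
#'
#' Jittered-grid (stratified Monte-Carlo) pixel counting over one unit
#' cell of the lattice: the sampling grid at `pixel_size_um` is shifted by
#' `n_jitter` seeded sub-pixel offsets and the inside-disc fraction
#' averaged, giving an unbiased estimate whose precision resolves the
#' analytic value at the 0.1% level.
#'
#' @param lat a [pore_lattice()].
#' @param pixel_size_um sampling pitch (default 0.25 um).
#' @param n_jitter number of seeded grid offsets to average (default 16).
#' @param seed integer seed.
#' @return estimated porosity fraction.
#' @export
porosity_raster <- function(lat, pixel_size_um = 0.25, n_jitter = 16L,
                            seed = 1L) {
  r <- lat$pore_diameter_um / 2
  px <- lat$pitch_x_um; py <- lat$pitch_y_um
  nx <- round(px / pixel_size_um); ny <- round(py / pixel_size_um)
  hx <- px / nx; hy <- py / ny
  cx <- px / 2; cy <- py / 2
  .with_seed(seed, {
    fr <- vapply(seq_len(n_jitter), function(i) {
      ox <- stats::runif(1, -0.5, 0.5) * hx
      oy <- stats::runif(1, -0.5, 0.5) * hy
      xs <- (seq_len(nx) - 0.5) * hx + ox
      ys <- (seq_len(ny) - 0.5) * hy + oy
      inside <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= r^2
      mean(inside)
    }, numeric(1))
    mean(fr)
  })
}

#' Convert proton fluence to ion areal density
#'
#' Charge fluence in pC/mm^2 divided by the elementary charge
#' (singly charged ions): ions/mm^2 = fluence x 1e-12 / 1.602176634e-19.
#'
#' @param fluence_pC_per_mm2 non-negative charge fluence.
#' @return ion areal density in ions/mm^2.
#' @export
fluence_to_ion_density <- function(fluence_pC_per_mm2) {
  if (any(fluence_pC_per_mm2 < 0))
    stop("fluence_to_ion_density: fluence must be non-negative")
  fluence_pC_per_mm2 * 1e-12 / 1.602176634e-19
}
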
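#' Synthetic microscopy scene configuration
#'
#' Frame geometry, pixel size, seed and noise model shared by all scene
#' generators. Defaults emulate a fluorescence field of view large enough to
#' resolve both 8 um and 25 um pores at 0.5 um/px.
#'
#' @param width_px,height_px frame size in pixels (>= 64).
#' @param pixel_size_um physical pixel size in um.
#' @param seed integer seed; identical (seed, spec) pairs give bit-identical
#'   scenes.
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param snr target signal-to-noise ratio of the rendered structures
#'   (ignored for `noise_model = "none"`).
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(width_px = 1024L, height_px = 1024L,
                         pixel_size_um = 0.5, seed = 1L,
                         noise_model = c("none", "gaussian", "poisson"),
                         snr = 10) {
  noise_model <- match.arg(noise_model)
  width_px <- as.integer(width_px); height_px <- as.integer(height_px)
  if (width_px < 64L || height_px < 64L)
    stop("scene_config: frame must be at least 64 x 64 px")
  if (pixel_size_um <= 0) stop("scene_config: pixel_size_um must be positive")
  if (snr <= 0) stop("scene_config: snr must be positive")
  structure(list(width_px = width_px, height_px = height_px,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed),
                 noise_model = noise_model, snr = snr),
            class = "scene_config")
}

#' Actin-filament texture specification
#'
#' Filaments are anti-aliased line segments with a Gaussian cross profile;
#' their orientations are drawn from an axial von Mises distribution
#' (angles doubled before sampling, halved after). `kappa = 0` yields an
#' isotropic texture. An optional `domains` list partitions the frame into
#' disjoint rectangles, each with its own (mu, kappa), emulating fields
#' showing preferred directions in small areas.
#'
#' @param mu_deg mean orientation in degrees, in [-90, 90).
#' @param kappa non-negative von Mises concentration (doubled-angle scale).
#' @param spatial_period_um characteristic spacing/width scale of the
#'   filament texture in um.
#' @param n_filaments number of filaments to render.
#' @param length_factor filament length in units of the spatial period
#'   (default 3). Short factors give stubby segments whose end caps are
#'   genuine isotropic features; validation of orientation recovery uses
#'   frame-spanning fibers (large factor) so the nominal mu is the exact
#'   ground truth of the energy-weighted orientation.
#' @param saturate apply soft detector saturation 1 - exp(-I) to the
#'   accumulated fiber intensity (default FALSE). Emulates camera clipping
#'   in bright confluent layers so no overlap hot spot dominates the
#'   intensity budget; used for pore scenes where the pore/cytoplasm step
#'   is the feature of interest.
#' @param domains optional list of lists with fields `x0, x1, y0, y1`
#'   (pixel bounds, inclusive, 1-based) and `mu_deg`, `kappa`. Must tile
#'   the frame exactly.
#' @return a list of class `filament_texture_spec`.
#' @export
filament_texture_spec <- function(mu_deg = 0, kappa = 10,
                                  spatial_period_um = 4,
                                  n_filaments = 600L, length_factor = 3,
                                  saturate = FALSE, domains = NULL) {
  if (kappa < 0) stop("filament_texture_spec: kappa must be non-negative")
  if (spatial_period_um <= 0)
    stop("filament_texture_spec: spatial_period_um must be positive")
  if (n_filaments < 1L)
    stop("filament_texture_spec: n_filaments must be positive")
  if (length_factor <= 0)
    stop("filament_texture_spec: length_factor must be positive")
  structure(list(mu_deg = fold_orientation_deg(mu_deg), kappa = kappa,
                 spatial_period_um = spatial_period_um,
                 n_filaments = as.integer(n_filaments),
                 length_factor = length_factor,
                 saturate = isTRUE(saturate), domains = domains),
            class = "filament_texture_spec")
}

#' Nuclei field specification
#'
#' Nuclei are rendered as smooth soft-edged blobs of random radius; centers
#' are placed by dart throwing with a minimum separation. `clustering`
#' interpolates between uniform placement (0) and strong aggregation around
#' earlier nuclei (1).
#'
#' @param n_nuclei number of nuclei (>= 0).
#' @param radius_um_range length-2 positive range of nucleus radii in um.
#' @param min_separation_um minimal center-to-center distance enforced when
#'   `clustering = 0` (relaxed proportionally as clustering grows).
#' @param clustering real in [0, 1].
#' @return a list of class `nuclei_field_spec`.
#' @export
nuclei_field_spec <- function(n_nuclei = 50L, radius_um_range = c(2.5, 4),
                              min_separation_um = 10, clustering = 0) {
  if (n_nuclei < 0L) stop("nuclei_field_spec: n_nuclei must be >= 0")
  if (length(radius_um_range) != 2L || any(radius_um_range <= 0) ||
      radius_um_range[1] > radius_um_range[2])
    stop("nuclei_field_spec: invalid radius range")
  if (min_separation_um < 0)
    stop("nuclei_field_spec: min_separation_um must be >= 0")
  if (clustering < 0 || clustering > 1)
    stop("nuclei_field_spec: clustering must be in [0, 1]")
  structure(list(n_nuclei = as.integer(n_nuclei),
                 radius_um_range = as.numeric(radius_um_range),
                 min_separation_um = min_separation_um,
                 clustering = clustering),
            class = "nuclei_field_spec")
}

# apply the configured noise model; called inside the generator's seed scope
.apply_noise <- function(img, cfg) {
  if (cfg$noise_model == "none") return(img)
  sig <- mean(img[img > 0.05 * max(img)])
  if (!is.finite(sig) || sig <= 0) sig <- max(img, 1e-6)
  if (cfg$noise_model == "gaussian") {
    img + matrix(stats::rnorm(length(img), sd = sig / cfg$snr),
                 nrow(img), ncol(img))
  } else {
    # Poisson: scale so the typical signal carries snr^2 expected photons
    counts <- cfg$snr^2
    scale <- counts / sig
    matrix(stats::rpois(length(img), lambda = pmax(img, 0) * scale) / scale,
           nrow(img), ncol(img))
  }
}

# validate a domain partition: disjoint rectangles exactly tiling the frame
.check_domains <- function(domains, h, w) {
  cover <- matrix(0L, h, w)
  for (d in domains) {
    if (any(!is.finite(c(d$x0, d$x1, d$y0, d$y1))) ||
        d$x0 < 1 || d$x1 > w || d$y0 < 1 || d$y1 > h ||
        d$x0 > d$x1 || d$y0 > d$y1)
      stop("filament texture: invalid domain rectangle")
    cover[d$y0:d$y1, d$x0:d$x1] <- cover[d$y0:d$y1, d$x0:d$x1] + 1L
  }
  if (any(cover > 1L)) stop("filament texture: domains overlap")
  if (any(cover == 0L)) stop("filament texture: domains do not cover the frame")
  invisible(TRUE)
}

# render one Gaussian-profile segment into acc/ori/amax (by reference-ish:
# returns the three updated matrices)
.render_segment <- function(acc, ori, amax, cx, cy, theta_deg, len_px,
                            sigma_px, clip = NULL) {
  h <- nrow(acc); w <- ncol(acc)
  th <- theta_deg * pi / 180
  # direction in (col, row) space; screen-CCW angles mean row decreases
  dx <- cos(th); dy <- -sin(th)
  hx <- len_px / 2 * dx; hy <- len_px / 2 * dy
  pad <- 3 * sigma_px
  # rendering is clipped to the filament's own domain rectangle so domain
  # partitions stay exact
  cl <- if (is.null(clip)) c(1L, w, 1L, h)
        else c(clip$x0, clip$x1, clip$y0, clip$y1)
  c0 <- max(cl[1], floor(cx - abs(hx) - pad)); c1 <- min(cl[2], ceiling(cx + abs(hx) + pad))
  r0 <- max(cl[3], floor(cy - abs(hy) - pad)); r1 <- min(cl[4], ceiling(cy + abs(hy) + pad))
  if (c0 > c1 || r0 > r1) return(list(acc = acc, ori = ori, amax = amax))
  cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  # distance from pixel to the segment [center - h, center + h]
  px <- cc - cx; py <- rr - cy
  t <- (px * dx + py * dy)
  t <- pmax(pmin(t, len_px / 2), -len_px / 2)
  dxs <- px - t * dx; dys <- py - t * dy
  d2 <- dxs^2 + dys^2
  a <- exp(-d2 / (2 * sigma_px^2))
  sub_acc <- acc[r0:r1, c0:c1]
  sub_ori <- ori[r0:r1, c0:c1]
  sub_max <- amax[r0:r1, c0:c1]
  upd <- a > sub_max
  sub_ori[upd] <- theta_deg
  sub_max[upd] <- a[upd]
  acc[r0:r1, c0:c1] <- sub_acc + a
  ori[r0:r1, c0:c1] <- sub_ori
  amax[r0:r1, c0:c1] <- sub_max
  list(acc = acc, ori = ori, amax = amax)
}

#' Generate a synthetic actin-filament texture with ground truth
#'
#' Renders `n_filaments` anti-aliased line segments (length about three
#' spatial periods, Gaussian cross profile) whose orientations are drawn
#' from the axial von Mises distribution of the spec (per domain when a
#' domain partition is given). The ground truth records the per-pixel
#' intended orientation (the orientation of the locally dominant filament)
#' and the exact sampled angles.
#'
#' @param cfg a [scene_config()].
#' @param spec a [filament_texture_spec()].
#' @return list with `image` (a `raster_image`, actin role) and
#'   `ground_truth` (list: `orientation_map_deg`, `label_mask`, `pore_mask`,
#'   `angles_deg`, `params_used`).
#' @export
make_filament_texture <- function(cfg, spec) {
  stopifnot(inherits(cfg, "scene_config"),
            inherits(spec, "filament_texture_spec"))
  h <- cfg$height_px; w <- cfg$width_px
  domains <- spec$domains
  if (is.null(domains)) {
    domains <- list(list(x0 = 1L, x1 = w, y0 = 1L, y1 = h,
                         mu_deg = spec$mu_deg, kappa = spec$kappa))
  }
  .check_domains(domains, h, w)
  period_px <- spec$spatial_period_um / cfg$pixel_size_um
  sigma_px <- max(0.8, period_px / 5)
  len_px <- spec$length_factor * period_px
  .with_seed(cfg$seed, {
    acc <- matrix(0, h, w)
    amax <- matrix(0, h, w)
    ori <- matrix(NA_real_, h, w)
    # split filaments across domains proportionally to area
    areas <- vapply(domains, function(d)
      (d$x1 - d$x0 + 1) * (d$y1 - d$y0 + 1), numeric(1))
    nd <- pmax(1L, round(spec$n_filaments * areas / sum(areas)))
    all_angles <- list()
    for (k in seq_along(domains)) {
      d <- domains[[k]]
      # seed the no-coverage fallback with the domain mean orientation
      ori[d$y0:d$y1, d$x0:d$x1][is.na(ori[d$y0:d$y1, d$x0:d$x1])] <- d$mu_deg
      ang <- raxial_vonmises(nd[k], d$mu_deg, d$kappa)
      all_angles[[k]] <- ang
      cxs <- stats::runif(nd[k], d$x0, d$x1)
      cys <- stats::runif(nd[k], d$y0, d$y1)
      for (i in seq_len(nd[k])) {
        st <- .render_segment(acc, ori, amax, cxs[i], cys[i], ang[i],
                              len_px, sigma_px,
                              clip = if (length(domains) > 1L) d else NULL)
        acc <- st$acc; ori <- st$ori; amax <- st$amax
      }
    }
    if (spec$saturate) acc <- 1 - exp(-acc)
    img <- .apply_noise(acc, cfg)
    gt <- list(orientation_map_deg = ori,
               label_mask = matrix(0L, h, w),
               pore_mask = matrix(FALSE, h, w),
               angles_deg = unlist(all_angles),
               params_used = list(cfg = cfg, spec = spec,
                                  sigma_px = sigma_px, len_px = len_px))
    list(image = raster_image(img, cfg$pixel_size_um, "actin"),
         ground_truth = gt)
  })
}

#' Generate a synthetic nuclei (DAPI-like) image with ground truth
#'
#' Places `n_nuclei` soft-edged blobs by bounded rejection sampling and
#' paints an exact integer label mask (label i = pixels within radius i of
#' center i, consecutive labels from 1).
#'
#' @param cfg a [scene_config()].
#' @param spec a [nuclei_field_spec()].
#' @param max_attempts rejection-sampling budget per nucleus.
#' @return list with `image` (nuclei role) and `ground_truth` (list:
#'   `label_mask`, `centers_px` (n x 2, col/row), `radii_um`, `params_used`).
#' @export
make_nuclei_image <- function(cfg, spec, max_attempts = 2000L) {
  stopifnot(inherits(cfg, "scene_config"),
            inherits(spec, "nuclei_field_spec"))
  h <- cfg$height_px; w <- cfg$width_px
  ps <- cfg$pixel_size_um
  n <- spec$n_nuclei
  .with_seed(cfg$seed + 7L, {
    img <- matrix(0, h, w)
    labels <- matrix(0L, h, w)
    centers <- matrix(numeric(0), 0, 2)
    radii_px <- numeric(0)
    if (n > 0L) {
      rmin <- spec$radius_um_range[1] / ps
      rmax <- spec$radius_um_range[2] / ps
      sep_px <- spec$min_separation_um / ps * (1 - spec$clustering)
      margin <- rmax + 2
      if (2 * margin >= min(h, w))
        stop("make_nuclei_image: nuclei do not fit in the frame")
      for (i in seq_len(n)) {
        placed <- FALSE
        for (a in seq_len(max_attempts)) {
          if (spec$clustering > 0 && nrow(centers) > 0 &&
              stats::runif(1) < spec$clustering) {
            j <- sample(nrow(centers), 1L)
            cx <- centers[j, 1] + stats::rnorm(1, sd = 3 * rmax)
            cy <- centers[j, 2] + stats::rnorm(1, sd = 3 * rmax)
          } else {
            cx <- stats::runif(1, margin, w - margin)
            cy <- stats::runif(1, margin, h - margin)
          }
          if (cx < margin || cx > w - margin || cy < margin || cy > h - margin)
            next
          if (nrow(centers) > 0) {
            dmin <- min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2))
            if (dmin < sep_px) next
          }
          placed <- TRUE
          break
        }
        if (!placed)
          stop("make_nuclei_image: could not place nucleus ", i,
               " at the requested separation (infeasible packing)")
        r <- stats::runif(1, rmin, rmax)
        centers <- rbind(centers, c(cx, cy))
        radii_px <- c(radii_px, r)
      }
      # paint blobs and labels
      for (i in seq_len(n)) {
        cx <- centers[i, 1]; cy <- centers[i, 2]; r <- radii_px[i]
        pad <- ceiling(r * 2.5)
        c0 <- max(1L, floor(cx - pad)); c1 <- min(w, ceiling(cx + pad))
        r0 <- max(1L, floor(cy - pad)); r1 <- min(h, ceiling(cy + pad))
        cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
        rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
        d <- sqrt((cc - cx)^2 + (rr - cy)^2)
        blob <- 1 / (1 + exp((d - r) / (0.12 * r)))   # soft-edged disc
        img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + blob
        sub <- labels[r0:r1, c0:c1]
        sub[d <= r] <- i
        labels[r0:r1, c0:c1] <- sub
      }
    }
    img <- .apply_noise(img, cfg)
    gt <- list(label_mask = labels,
               centers_px = centers,
               radii_um = radii_px * ps,
               orientation_map_deg = matrix(NA_real_, h, w),
               pore_mask = matrix(FALSE, h, w),
               params_used = list(cfg = cfg, spec = spec))
    list(image = raster_image(img, ps, "nuclei"), ground_truth = gt)
  })
}

#' Compose a pore scene: filament texture over a porous membrane
#'
#' Multiplies a filament texture to near zero inside pores and attenuates
#' it linearly with distance inside an optional cell-depletion halo around
#' each pore, emulating micrographs of cells on regularly drilled (25 um
#' lattice) or track-etched (random 8 um) membranes.
#'
#' @param cfg a [scene_config()].
#' @param pores either a [pore_lattice()] or a list
#'   `list(random = TRUE, pore_diameter_um =, porosity =)` for random
#'   track-etched-style pores (density from porosity = rho * pi r^2).
#' @param texture a [filament_texture_spec()].
#' @param depletion_halo_um non-negative halo width in um.
#' @return list with `image`, `ground_truth` (including `pore_mask` and the
#'   texture's orientation map).
#' @export
make_pore_scene <- function(cfg, pores, texture,
                            depletion_halo_um = 0) {
  stopifnot(inherits(cfg, "scene_config"))
  if (depletion_halo_um < 0)
    stop("make_pore_scene: depletion_halo_um must be >= 0")
  tex <- make_filament_texture(cfg, texture)
  h <- cfg$height_px; w <- cfg$width_px
  ps <- cfg$pixel_size_um
  if (inherits(pores, "pore_lattice")) {
    mask <- rasterize_pores(pores, c(w, h) * ps, ps)
  } else if (is.list(pores) && isTRUE(pores$random)) {
    r_um <- pores$pore_diameter_um / 2
    # Boolean (Poisson disc) model: coverage 1 - exp(-lambda pi r^2), so the
    # intensity matching a target porosity is lambda = -log(1 - p)/(pi r^2);
    # centers are sampled in a frame extended by r so edge discs contribute
    # their full share
    density_per_um2 <- -log(1 - pores$porosity) / (pi * r_um^2)
    area_ext <- (w * ps + 2 * r_um) * (h * ps + 2 * r_um)
    n_pores <- .with_seed(cfg$seed + 13L,
                          stats::rpois(1, density_per_um2 * area_ext))
    centers <- .with_seed(cfg$seed + 17L,
                          cbind(stats::runif(n_pores, -r_um, w * ps + r_um),
                                stats::runif(n_pores, -r_um, h * ps + r_um)))
    mask <- .rasterize_discs(centers, r_um, c(w, h) * ps, ps)
  } else {
    stop("make_pore_scene: pores must be a pore_lattice or random-pore spec")
  }
  img <- tex$image$pixels
  if (any(mask)) {
    att <- matrix(1, h, w)
    att[mask] <- 0.01                      # near-zero inside pores
    if (depletion_halo_um > 0) {
      dist_px <- EBImage::distmap(EBImage::Image(t(1 - mask)))
      dist_um <- t(EBImage::imageData(dist_px)) * ps
      halo <- !mask & dist_um < depletion_halo_um
      att[halo] <- pmin(att[halo], 0.01 + 0.99 * dist_um[halo] / depletion_halo_um)
    }
    img <- img * att
  }
  gt <- tex$ground_truth
  gt$pore_mask <- mask
  gt$params_used$pores <- pores
  gt$params_used$depletion_halo_um <- depletion_halo_um
  list(image = raster_image(img, ps, "actin"), ground_truth = gt)
}

# pixel-center rasterization of discs; centers in um (col, row), frame in um
.rasterize_discs <- function(centers_um, radius_um, frame_um, pixel_size_um) {
  w <- round(frame_um[1] / pixel_size_um)
  h <- round(frame_um[2] / pixel_size_um)
  mask <- matrix(FALSE, h, w)
  if (nrow(centers_um) == 0L) return(mask)
  xs <- (seq_len(w) - 0.5) * pixel_size_um
  ys <- (seq_len(h) - 0.5) * pixel_size_um
  for (i in seq_len(nrow(centers_um))) {
    cx <- centers_um[i, 1]; cy <- centers_um[i, 2]
    ci <- which(abs(xs - cx) <= radius_um)
    ri <- which(abs(ys - cy) <= radius_um)
    if (!length(ci) || !length(ri)) next
    d2 <- outer((ys[ri] - cy)^2, (xs[ci] - cx)^2, `+`)
    mask[ri, ci] <- mask[ri, ci] | (d2 <= radius_um^2)
  }
  mask
}
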
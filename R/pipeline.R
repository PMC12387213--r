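#' End-to-end analysis of a set of micrographs
#'
#' Reproduces the comparative workflow on a list of scenes (e.g. glass
#' coverslip vs track-etched membrane vs drilled membrane): for each scene
#' the actin channel is run through the structure tensor (orientation,
#' energy, coherency maps, HSB composite), the high-energy polar statistic
#' and the monogenic transform; the nuclei channel through segmentation
#' and N_obj / coverage statistics; and the actin images jointly through
#' the GLCM + PCA texture stage. All map artifacts are written under
#' `out_dir` and a single machine-readable JSON report (no timestamps, so
#' reruns are byte-identical) summarizes every stage.
#'
#' @param scenes named list; each element a list with fields `actin`
#'   (a [raster_image()]; required for the tensor/monogenic/texture
#'   stages), optional `nuclei` (a `raster_image`), and optional
#'   `pore_mask` (logical matrix used as ROI exclusion).
#' @param out_dir output directory (created if missing).
#' @param window_sigma_px tensor window (default 2).
#' @param scale_px monogenic scale (default 8).
#' @param levels,distances,angles texture-stage parameters.
#' @param mask_quantile high-energy quantile (default 0.95).
#' @param roi_size_um nuclei-statistics ROI side (default 350).
#' @param n_rois ROIs per nuclei image (default 2).
#' @param seed global seed; per-stage sub-seeds are derived from it.
#' @return the report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(scenes, out_dir,
                         window_sigma_px = 2, scale_px = 8,
                         levels = 32L, distances = c(0L, 2L),
                         angles = c(0, 45, 90),
                         mask_quantile = 0.95,
                         roi_size_um = 350, n_rois = 2L, seed = 1L) {
  if (is.null(names(scenes)) || any(names(scenes) == ""))
    stop("run_pipeline: scenes must be a named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(parameters = list(window_sigma_px = window_sigma_px,
                                   scale_px = scale_px, levels = levels,
                                   distances = distances, angles = angles,
                                   mask_quantile = mask_quantile,
                                   roi_size_um = roi_size_um,
                                   n_rois = n_rois, seed = seed),
                 scenes = list())
  actin_imgs <- list()
  for (nm in names(scenes)) {
    sc <- scenes[[nm]]
    entry <- list(files = list())
    if (!is.null(sc$actin)) {
      img <- sc$actin
      actin_imgs[[nm]] <- img
      tf <- tensor_analysis(img, window_sigma_px)
      base <- file.path(out_dir, nm)
      write_raster(ifelse(is.na(tf$orientation_deg), 0, tf$orientation_deg),
                   paste0(base, "_orientation.tif"))
      write_raster(tf$energy, paste0(base, "_energy.tif"))
      write_raster(ifelse(is.na(tf$coherency), 0, tf$coherency),
                   paste0(base, "_coherency.tif"))
      write_hsb_png(hsb_composite(tf, img), paste0(base, "_hsb.png"))
      mask <- high_energy_mask(tf, quantile = mask_quantile)
      hist_all <- orientation_polar(tf, weighting = "energy",
                                    pixel_size_um = img$pixel_size_um)
      hist_feat <- orientation_polar(tf, mask = mask, weighting = "none",
                                     pixel_size_um = img$pixel_size_um)
      utils::write.csv(
        data.frame(bin_mid_deg = hist_feat$bin_mid_deg,
                   weight = hist_feat$weights,
                   normalized_weight = hist_feat$normalized),
        paste0(base, "_polar_energy_features.csv"), row.names = FALSE)
      mf <- monogenic_transform(img, scale_px)
      write_raster(mf$amplitude, paste0(base, "_monogenic_amplitude.tif"))
      write_raster(mf$phase_rad, paste0(base, "_monogenic_phase.tif"))
      write_raster(enhance_modulus(mf$amplitude),
                   paste0(base, "_monogenic_amplitude_display.tif"))
      entry$orientation <- list(
        circular_mean_deg = hist_all$summary$circular_mean_deg,
        resultant_length = hist_all$summary$resultant_length,
        median_coherency = stats::median(tf$coherency, na.rm = TRUE),
        energy_feature_mode_deg = histogram_mode_deg(hist_feat),
        high_energy_threshold = as.numeric(attr(mask, "threshold")))
      entry$files$maps <- paste0(nm, c("_orientation.tif", "_energy.tif",
                                       "_coherency.tif", "_hsb.png"))
    }
    if (!is.null(sc$nuclei)) {
      lab <- segment_nuclei(sc$nuclei)
      rois <- roi_sampler(sc$nuclei, roi_size_um, n_rois,
                          exclusion_mask = sc$pore_mask,
                          seed = seed + 101L)
      roi_stats <- lapply(rois, function(r)
        nuclei_stats(lab, roi = r, pixel_size_um = sc$nuclei$pixel_size_um))
      entry$nuclei <- list(
        n_obj_full = nuclei_stats(lab)$n_obj,
        coverage_pct_full = nuclei_stats(lab)$coverage_pct,
        rois = lapply(roi_stats, function(s)
          list(n_obj = s$n_obj, coverage_pct = s$coverage_pct,
               roi_um = s$roi_um)))
      utils::write.csv(
        data.frame(area_um2 = nuclei_stats(lab)$areas_um2),
        file.path(out_dir, paste0(nm, "_nuclei_areas.csv")),
        row.names = FALSE)
    } else {
      entry$nuclei <- NULL   # stage skipped; pipeline still completes
    }
    report$scenes[[nm]] <- entry
  }
  if (length(actin_imgs) >= 2L) {
    tab <- texture_feature_table(actin_imgs, levels = levels,
                                 distances = distances, angles = angles)
    utils::write.csv(tab, file.path(out_dir, "texture_features.csv"),
                     row.names = FALSE)
    std <- suppressWarnings(standardize_features(tab))
    k <- min(2L, nrow(std) - 1L)
    pc <- texture_pca(std, k)
    utils::write.csv(
      cbind(pc$keys, as.data.frame(pc$scores)),
      file.path(out_dir, "texture_pca_scores.csv"), row.names = FALSE)
    report$texture <- list(
      n_descriptors = length(glcm_descriptor_names()),
      explained_variance_pct = pc$explained_variance_pct)
  }
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(out_dir, "report.json"))
  invisible(report)
}
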
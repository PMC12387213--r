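#!/usr/bin/env Rscript
# Generates the three ground-truthed synthetic substrates the downstream
# scripts analyse: a coverslip-like continuous fiber field, a track-etched
# membrane with random 8 um pores, and a drilled membrane with 25 um pores
# on a 100 um lattice. Images go to results/scenes/ as float TIFF; ground
# truth (counts, masks, parameters) as JSON/CSV.

suppressMessages(library(poretex))
out <- "results/scenes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20250925L

scenes <- list()

# coverslip: globally aligned fibers (strong cell-cell contact guidance)
glass <- make_filament_texture(
  scene_config(600, 600, 0.5, seed = seed),
  filament_texture_spec(mu_deg = 15, kappa = 20, spatial_period_um = 16,
                        n_filaments = 300L, length_factor = 10,
                        saturate = TRUE))
scenes$glass <- glass

# track-etched membrane: weakly ordered fibers over random 8 um pores at
# 3.4% porosity
pc <- make_pore_scene(
  scene_config(600, 600, 0.5, seed = seed + 1L),
  list(random = TRUE, pore_diameter_um = 8, porosity = 0.034),
  filament_texture_spec(mu_deg = 0, kappa = 2, spatial_period_um = 16,
                        n_filaments = 300L, length_factor = 10,
                        saturate = TRUE),
  depletion_halo_um = 4)
scenes$pc_membrane <- pc

# drilled membrane: 25 um pores, 100 um pitch, cell-depletion halos
pbw <- make_pore_scene(
  scene_config(600, 600, 0.5, seed = seed + 2L),
  pore_lattice(25, 100, 100, c(300, 300)),
  filament_texture_spec(mu_deg = 0, kappa = 5, spatial_period_um = 16,
                        n_filaments = 300L, length_factor = 10,
                        saturate = TRUE),
  depletion_halo_um = 8)
scenes$pbw_membrane <- pbw

# one nuclei channel per substrate, increasingly clustered on the membranes
nuclei_specs <- list(
  glass = nuclei_field_spec(n_nuclei = 120L, radius_um_range = c(2.5, 4),
                            min_separation_um = 12, clustering = 0),
  pc_membrane = nuclei_field_spec(n_nuclei = 150L,
                                  radius_um_range = c(2.5, 4),
                                  min_separation_um = 10, clustering = 0.3),
  pbw_membrane = nuclei_field_spec(n_nuclei = 180L,
                                   radius_um_range = c(2.5, 4),
                                   min_separation_um = 9, clustering = 0.5))

summary_rows <- list()
for (nm in names(scenes)) {
  sc <- scenes[[nm]]
  write_raster(sc$image, file.path(out, paste0(nm, "_actin.tif")))
  nuc <- make_nuclei_image(scene_config(600, 600, 0.5,
                                        seed = seed + 10L + match(nm, names(scenes)),
                                        noise_model = "gaussian", snr = 8),
                           nuclei_specs[[nm]])
  write_raster(nuc$image, file.path(out, paste0(nm, "_nuclei.tif")))
  pore_frac <- mean(sc$ground_truth$pore_mask)
  write.csv(data.frame(which = which(sc$ground_truth$pore_mask)),
            file.path(out, paste0(nm, "_pore_mask_idx.csv")),
            row.names = FALSE)
  summary_rows[[nm]] <- data.frame(
    scene = nm, pore_area_pct = 100 * pore_frac,
    n_nuclei_truth = nuclei_specs[[nm]]$n_nuclei,
    gt_nuclei_coverage_pct = 100 * mean(nuc$ground_truth$label_mask > 0))
  cat(sprintf("%-12s pore area %5.2f%%, %d nuclei (GT coverage %.2f%%)\n",
              nm, 100 * pore_frac, nuclei_specs[[nm]]$n_nuclei,
              100 * mean(nuc$ground_truth$label_mask > 0)))
}
write.csv(do.call(rbind, summary_rows),
          file.path(out, "scene_summary.csv"), row.names = FALSE)
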
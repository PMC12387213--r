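#!/usr/bin/env Rscript
# Membrane pattern design: pore-lattice coordinates, porosity across the
# studied pitch range, and proton-dose conversions for the write step.
# Writes results/design/*.csv.

suppressMessages(library(poretex))
out <- "results/design"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# 25 um pores at the pitches explored on the drilled membrane (50-190 um),
# plus the 8 um track-etched reference
pitches <- c(50, 55, 75, 100, 150, 190)
design <- data.frame(
  pore_diameter_um = 25,
  pitch_um = pitches,
  porosity_pct = vapply(pitches, function(p)
    100 * porosity(pore_lattice(25, p)), numeric(1)))
write.csv(design, file.path(out, "lattice_porosity.csv"), row.names = FALSE)
cat("porosity of a 25 um pore lattice across pitches:\n")
print(design, row.names = FALSE)

# write-pattern coordinates for a 1 x 1 mm field at 100 um pitch
coords <- lattice_coordinates(pore_lattice(25, 100, 100, c(1000, 1000)))
write.csv(as.data.frame(coords), file.path(out, "pore_centers_1mm_100um.csv"),
          row.names = FALSE)
cat(sprintf("\n%d pore centres fit a 1 x 1 mm field at 100 um pitch\n",
            nrow(coords)))

# dose conversions: the hole-drilling and channel-writing fluences
doses <- data.frame(
  step = c("hole drilling", "channel writing"),
  fluence_pC_per_mm2 = c(122293, 6000))
doses$ion_density_per_mm2 <- fluence_to_ion_density(doses$fluence_pC_per_mm2)
write.csv(doses, file.path(out, "dose_conversions.csv"), row.names = FALSE)
cat(sprintf("\n%s: %g pC/mm^2 = %.3g ions/mm^2\n",
            doses$step, doses$fluence_pC_per_mm2,
            doses$ion_density_per_mm2))
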
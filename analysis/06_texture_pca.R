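#!/usr/bin/env Rscript
# GLCM texture comparison of the three substrates: 23 descriptors per
# (scene, distance, angle) at theta = {0, 45, 90} deg and d = {0, 2},
# z-scored, box-plot summarized, and projected on two principal
# components.

suppressMessages(library(poretex))
src <- "results/scenes"; out <- "results/texture"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

imgs <- list()
for (nm in c("glass", "pc_membrane", "pbw_membrane"))
  imgs[[nm]] <- read_image(file.path(src, paste0(nm, "_actin.tif")),
                           channel_role = "actin", pixel_size_um = 0.5)

tab <- texture_feature_table(imgs, levels = 32L, distances = c(0L, 2L),
                             angles = c(0, 45, 90))
write.csv(tab, file.path(out, "glcm_features.csv"), row.names = FALSE)

std <- suppressWarnings(standardize_features(tab))
box <- feature_boxplot_summary(std, by = "image")
box$outliers <- vapply(box$outliers, function(o)
  paste(signif(o, 4), collapse = ";"), character(1))
write.csv(box, file.path(out, "feature_boxplot_summary.csv"),
          row.names = FALSE)

pc <- texture_pca(std, k = 2L)
write.csv(cbind(pc$keys, as.data.frame(pc$scores)),
          file.path(out, "pca_scores.csv"), row.names = FALSE)
write.csv(data.frame(descriptor = rownames(pc$loadings), pc$loadings),
          file.path(out, "pca_loadings.csv"), row.names = FALSE)
cat(sprintf("PC1 and PC2 retain %.1f%% and %.1f%% of the variance\n",
            pc$explained_variance_pct[1], pc$explained_variance_pct[2]))
agg <- aggregate(pc$scores, by = list(scene = pc$keys$image), FUN = mean)
print(agg, row.names = FALSE)
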
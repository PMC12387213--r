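test_that("identical seed and spec give bit-identical scenes", {
  cfg <- scene_config(64, 64, 0.5, seed = 3, noise_model = "gaussian",
                      snr = 8)
  spec <- filament_texture_spec(mu_deg = 20, kappa = 5, n_filaments = 30L)
  a <- make_filament_texture(cfg, spec)
  b <- make_filament_texture(cfg, spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$ground_truth$orientation_map_deg,
                   b$ground_truth$orientation_map_deg)
  # generators restore the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(make_filament_texture(cfg, spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("noise-free scenes are deterministic functions of the spec", {
  cfg <- scene_config(64, 64, 0.5, seed = 1, noise_model = "none")
  spec <- nuclei_field_spec(n_nuclei = 5L)
  a <- make_nuclei_image(cfg, spec)
  b <- make_nuclei_image(cfg, spec)
  expect_identical(a$image$pixels, b$image$pixels)
})

test_that("degenerate von Mises concentration fixes every ground-truth orientation", {
  sc <- oriented_scene(30, seed = 7, size = 256L)
  ori <- sc$ground_truth$orientation_map_deg
  expect_true(all(abs(ori - 30) < 1e-9))
  expect_true(all(abs(sc$ground_truth$angles_deg - 30) < 1e-9))
})

test_that("kappa = 0 gives an isotropic fiber population", {
  cfg <- scene_config(256, 256, 0.5, seed = 13)
  spec <- filament_texture_spec(kappa = 0, n_filaments = 600L,
                                spatial_period_um = 6)
  sc <- make_filament_texture(cfg, spec)
  s <- circular_summary(sc$ground_truth$angles_deg)
  expect_lt(s$resultant_length, 0.1)
})

test_that("two-domain ground truth is bimodal at the domain orientations", {
  sc <- two_domain_scene(seed = 5)
  ori <- sc$ground_truth$orientation_map_deg
  h <- hist(ori, breaks = seq(-90, 90, by = 5), plot = FALSE)
  w <- h$counts / sum(h$counts)
  near0 <- sum(w[abs(h$mids) < 10])
  near45 <- sum(w[abs(h$mids - 45) < 10])
  background <- sum(w[abs(h$mids + 60) < 10])
  expect_gt(near0, 5 * background)
  expect_gt(near45, 5 * background)
})

test_that("domain partitions must tile the frame", {
  cfg <- scene_config(64, 64, 0.5, seed = 1)
  gap <- list(list(x0 = 1, x1 = 30, y0 = 1, y1 = 64, mu_deg = 0, kappa = 5),
              list(x0 = 40, x1 = 64, y0 = 1, y1 = 64, mu_deg = 45, kappa = 5))
  expect_error(make_filament_texture(
    cfg, filament_texture_spec(domains = gap)), "cover")
  overlap <- list(list(x0 = 1, x1 = 40, y0 = 1, y1 = 64, mu_deg = 0, kappa = 5),
                  list(x0 = 30, x1 = 64, y0 = 1, y1 = 64, mu_deg = 45, kappa = 5))
  expect_error(make_filament_texture(
    cfg, filament_texture_spec(domains = overlap)), "overlap")
})

test_that("nuclei scenes honour the requested count and separation", {
  cfg <- scene_config(256, 256, 0.5, seed = 2)
  blank <- make_nuclei_image(cfg, nuclei_field_spec(n_nuclei = 0L))
  expect_true(all(blank$image$pixels == 0))
  expect_equal(sum(blank$ground_truth$label_mask), 0L)

  spec <- nuclei_field_spec(n_nuclei = 20L, radius_um_range = c(2.5, 4),
                            min_separation_um = 16)   # 4 x max radius
  sc <- make_nuclei_image(cfg, spec)
  lab <- sc$ground_truth$label_mask
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), 20L)
  # connected components: labels are disjoint discs here
  eb <- EBImage::bwlabel(EBImage::Image(t(lab > 0)))
  expect_equal(max(eb), 20)
  # centers respect the separation
  d <- as.matrix(dist(sc$ground_truth$centers_px))
  expect_gte(min(d[upper.tri(d)]) * 0.5, 16 - 1e-9)  # px -> um at 0.5 um/px
})

test_that("ground-truth mask coverage equals summed blob areas for disjoint nuclei", {
  cfg <- scene_config(256, 256, 0.5, seed = 4)
  spec <- nuclei_field_spec(n_nuclei = 15L, radius_um_range = c(3, 3),
                            min_separation_um = 14)
  sc <- make_nuclei_image(cfg, spec)
  mask_frac <- mean(sc$ground_truth$label_mask > 0)
  analytic <- 15 * pi * (3 / 0.5)^2 / (256 * 256)
  expect_lt(abs(mask_frac - analytic) / analytic, 0.01 + 0.05)  # pixelation
})

test_that("infeasible nucleus packing raises a placement error", {
  cfg <- scene_config(64, 64, 0.5, seed = 1)
  spec <- nuclei_field_spec(n_nuclei = 60L, radius_um_range = c(3, 4),
                            min_separation_um = 30)
  expect_error(make_nuclei_image(cfg, spec, max_attempts = 50L),
               "infeasible|could not place")
})

test_that("pore scenes suppress texture inside pores and match analytic porosity", {
  sc <- pore_scene_standard(seed = 8)
  pm <- sc$ground_truth$pore_mask
  img <- sc$image$pixels
  expect_lt(mean(img[pm]), 0.05 * mean(img[!pm]))
  # 25 um pores on 100 um pitch: pi r^2 / p^2 = 4.909%
  expect_lt(abs(mean(pm) - 0.04909), 0.002)
})

test_that("random-pore scenes hit the requested track-etch porosity", {
  cfg <- scene_config(512, 512, 1, seed = 21)
  tex <- filament_texture_spec(mu_deg = 0, kappa = 5, spatial_period_um = 8,
                               n_filaments = 200L)
  fracs <- vapply(1:4, function(s) {
    cfg <- scene_config(512, 512, 1, seed = 20 + s)
    sc <- make_pore_scene(cfg, list(random = TRUE, pore_diameter_um = 8,
                                    porosity = 0.034), tex)
    mean(sc$ground_truth$pore_mask)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.034), 0.003)
})

test_that("negative depletion halo is rejected", {
  cfg <- scene_config(64, 64, 1, seed = 1)
  tex <- filament_texture_spec(n_filaments = 10L)
  expect_error(make_pore_scene(cfg, pore_lattice(25, 100, 100, c(64, 64)),
                               tex, depletion_halo_um = -1), ">= 0")
})

test_that("depletion halo attenuates the texture near pore rims", {
  sc0 <- pore_scene_standard(seed = 3, halo_um = 0)
  sc1 <- pore_scene_standard(seed = 3, halo_um = 10)
  pm <- sc0$ground_truth$pore_mask
  dpx <- pore_distance_px(pm)
  near <- !pm & dpx * 0.5 < 10
  expect_lt(mean(sc1$image$pixels[near]), 0.8 * mean(sc0$image$pixels[near]))
})
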
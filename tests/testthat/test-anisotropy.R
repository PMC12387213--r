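test_that("high-energy mask selects the stated pixel share", {
  set.seed(3)
  tf <- tensor_analysis(matrix(rnorm(128 * 128), 128), 2)
  m <- high_energy_mask(tf, quantile = 0.95)
  expect_lt(abs(mean(m) - 0.05), 0.001)
  expect_true(is.finite(attr(m, "threshold")))
  expect_identical(attr(m, "method"), "quantile")

  tf0 <- tensor_analysis(matrix(1, 64, 64), 2)
  expect_warning(m0 <- high_energy_mask(tf0), "zero")
  expect_false(any(m0))
})

test_that("otsu threshold separates a bimodal energy field", {
  tf <- tensor_analysis(make_grating(0, 128, 128, 8), 2)
  tf$energy[1:64, ] <- tf$energy[1:64, ] * 1e-3   # synthetic low-energy half
  m <- high_energy_mask(tf, method = "otsu")
  expect_gt(mean(m[65:128, ]), 5 * mean(m[1:64, ]))
})

test_that("polar histogram finds the mode and concentration of an oriented texture", {
  sc <- oriented_scene(0, seed = 9)
  tf <- tensor_analysis(sc$image, 2)
  h <- orientation_polar(tf, weighting = "energy")
  # 0 deg lies on a bin edge: admissible modes reach 1.5 bin widths
  expect_lt(axial_difference_deg(histogram_mode_deg(h, 2), 0), 3.76)
  expect_gt(h$summary$resultant_length, 0.9)
  # histogram mass is normalized
  expect_lt(abs(sum(h$normalized) - 1), 1e-12)
})

test_that("isotropic noise gives a flat orientation distribution", {
  set.seed(17)
  tf <- tensor_analysis(matrix(rnorm(256 * 256), 256), 4)
  h <- orientation_polar(tf)
  expect_lt(h$summary$resultant_length, 0.1)
})

test_that("full mask without weighting reproduces the plain histogram", {
  sc <- oriented_scene(40, seed = 11, size = 128L)
  tf <- tensor_analysis(sc$image, 2)
  h1 <- orientation_polar(tf, weighting = "none")
  h2 <- orientation_polar(tf, mask = matrix(TRUE, 128, 128),
                          weighting = "none")
  expect_equal(h1$weights, h2$weights)
})

test_that("empty selections warn and produce empty histograms", {
  tf <- tensor_analysis(make_grating(10, 64, 64, 8), 2)
  expect_warning(h <- orientation_polar(tf, mask = matrix(FALSE, 64, 64)),
                 "empty")
  expect_equal(sum(h$weights), 0)
})

test_that("ROI restriction turns a bimodal field unimodal at the domain orientation", {
  sc <- two_domain_scene(seed = 3)
  tf <- tensor_analysis(sc$image, 2)
  hfull <- orientation_polar(tf, weighting = "energy")
  w <- hfull$normalized; mids <- hfull$bin_mid_deg
  near0 <- sum(w[abs(mids) < 7]); near45 <- sum(w[abs(mids - 45) < 7])
  background <- sum(w[abs(mids + 60) < 7])
  expect_gt(near0, 5 * background)
  expect_gt(near45, 5 * background)

  hL <- orientation_polar(tf, roi = c(8, 8, 80, 176), weighting = "energy",
                          pixel_size_um = 0.5)
  # one bin of the left-domain mode carries the peak; the 45-degree mode
  # is gone relative to the full frame
  expect_lt(axial_difference_deg(histogram_mode_deg(hL, 3), 0), 3.76)
  wL <- hL$normalized
  expect_lt(sum(wL[abs(mids - 45) < 7]), 0.3 * sum(wL[abs(mids) < 7]))
})

test_that("a histogram compared with itself shows no difference", {
  sc <- oriented_scene(20, seed = 5, size = 128L)
  tf <- tensor_analysis(sc$image, 2)
  h <- orientation_polar(tf, weighting = "energy")
  cmp <- compare_histograms(h, h, n_perm = 99, seed = 1)
  expect_equal(cmp$mean_difference_deg, 0)
  expect_equal(cmp$resultant_difference, 0)
  expect_gt(cmp$p_value, 0.9)
})

test_that("distinct orientation distributions are detected by the permutation test", {
  cfg <- scene_config(192, 192, 0.5, seed = 6)
  s0 <- make_filament_texture(cfg, filament_texture_spec(
    mu_deg = 0, kappa = 50, spatial_period_um = 8, n_filaments = 80L,
    length_factor = 15))
  s45 <- make_filament_texture(scene_config(192, 192, 0.5, seed = 7),
                               filament_texture_spec(
    mu_deg = 45, kappa = 50, spatial_period_um = 8, n_filaments = 80L,
    length_factor = 15))
  h0 <- orientation_polar(tensor_analysis(s0$image, 2), weighting = "energy",
                          max_sample = 2000L)
  h45 <- orientation_polar(tensor_analysis(s45$image, 2),
                           weighting = "energy", max_sample = 2000L)
  cmp <- compare_histograms(h0, h45, n_perm = 999, seed = 2)
  expect_lt(abs(cmp$mean_difference_deg - 45), 3)
  expect_lt(cmp$p_value, 0.01)

  hx <- h0; hx$bin_edges_deg <- hx$bin_edges_deg + 1
  expect_error(compare_histograms(h0, hx), "binning")
})

test_that("the permutation p-value is calibrated under the null", {
  set.seed(23)
  ps <- vapply(1:60, function(i) {
    a <- runif(150, -90, 90); b <- runif(150, -90, 90)
    mk <- function(x) {
      edges <- seq(-90, 90, length.out = 73)
      mid <- (edges[-1] + edges[-73]) / 2
      bin <- findInterval(x, edges, rightmost.closed = TRUE)
      w <- vapply(1:72, function(k) sum(bin == k), numeric(1))
      structure(list(bin_edges_deg = edges, bin_mid_deg = mid, weights = w,
                     normalized = w / sum(w), weighting = "none", roi = NULL,
                     display_scale = 1, summary = circular_summary(x),
                     angles_deg = x, angle_weights = rep(1, length(x))),
                class = "orientation_histogram")
    }
    compare_histograms(mk(a), mk(b), n_perm = 99, seed = i)$p_value
  }, numeric(1))
  # under the null the rejection rate at 0.05 stays near nominal and the
  # p-values are not degenerate
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps < 0.5), 0.3)
})

test_that("display scaling changes weights but not the distribution", {
  sc <- oriented_scene(10, seed = 8, size = 128L)
  tf <- tensor_analysis(sc$image, 2)
  h <- orientation_polar(tf, weighting = "energy")
  expect_equal(scale_for_display(h, 1)$weights, h$weights)
  h10 <- scale_for_display(h, 10)
  expect_equal(h10$weights, 10 * h$weights)
  expect_equal(h10$display_scale, 10)
  expect_equal(h10$summary$circular_mean_deg, h$summary$circular_mean_deg)
  expect_lt(max(abs(h10$normalized - h$normalized)), 1e-12)
  expect_error(scale_for_display(h, 0), "positive")
  # full-circle display view duplicates the half-circle curve
  disp <- polar_display_frame(h10)
  expect_equal(nrow(disp), 144L)
  expect_equal(disp$weight[1:72], disp$weight[73:144])
})
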
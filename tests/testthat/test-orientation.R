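test_that("Riesz gradient of a constant image is exactly zero", {
  g <- riesz_gradient(matrix(7, 64, 64))
  expect_true(all(g$gx == 0))
  expect_true(all(g$gy == 0))
})

test_that("Riesz gradient of a horizontal grating is purely vertical", {
  img <- cos(2 * pi * matrix(seq_len(128), 128, 128) / 16)  # varies with row
  g <- riesz_gradient(img)
  amp <- max(abs(img))
  expect_lt(max(abs(g$gx)) / amp, 1e-6)
  expect_gt(sqrt(mean(g$gy^2)), 0.5)
  # components are near mean-free (DC removed before the transform; the
  # boundary crop retains a small residual)
  expect_lt(abs(mean(g$gx)), 0.05)
  expect_lt(abs(mean(g$gy)), 0.05)
})

test_that("90-degree rotation maps (gx, gy) to (-gy, gx) to machine precision", {
  set.seed(4)
  img <- matrix(rnorm(64 * 64), 64, 64)
  g <- riesz_gradient(img)
  gr <- riesz_gradient(rot_ccw90(img))
  scale <- max(abs(g$gx), abs(g$gy))
  expect_lt(max(abs(gr$gx - rot_ccw90(-g$gy))) / scale, 1e-6)
  expect_lt(max(abs(gr$gy - rot_ccw90(g$gx))) / scale, 1e-6)
})

test_that("structure tensor recovers the orientation of gratings exactly", {
  for (mu in c(-75, -30, 0, 30, 61)) {
    tf <- tensor_analysis(make_grating(mu, 128, 128, 8), 2)
    im <- interior_mask(tf)
    expect_lt(axial_difference_deg(
      median(tf$orientation_deg[im]), mu), 1)
    expect_gt(median(tf$coherency[im]), 0.95)
  }
})

test_that("constant images have zero energy and flagged coherency", {
  tf <- tensor_analysis(matrix(3, 64, 64), 2)
  expect_true(all(tf$energy == 0))
  expect_true(all(is.na(tf$coherency)))
  expect_true(all(is.na(tf$orientation_deg)))
})

test_that("white noise is measured as isotropic and incoherent", {
  set.seed(6)
  tf <- tensor_analysis(matrix(rnorm(256 * 256), 256, 256), 4)
  im <- interior_mask(tf)
  expect_lt(mean(tf$coherency[im], na.rm = TRUE), 0.3)
  s <- circular_summary(tf$orientation_deg[im])
  expect_lt(s$resultant_length, 0.1)
})

test_that("tensor components match a direct spatial convolution oracle", {
  set.seed(9)
  img <- matrix(rnorm(16 * 16), 16, 16)
  g <- riesz_gradient(img)
  sigma <- 1.5
  tf <- structure_tensor(g$gx, g$gy, sigma)
  # oracle: explicit mirror-padded convolution with the same kernel
  r <- max(2L, ceiling(4 * sigma))
  k1 <- dnorm(seq(-r, r), sd = sigma); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  conv_oracle <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- c(r:1, 1:nr, nr:(nr - r + 1)); ci <- c(r:1, 1:nc, nc:(nc - r + 1))
    p <- m[ri, ci]
    out <- matrix(0, nr, nc)
    for (a in seq_len(nr)) for (b in seq_len(nc)) {
      out[a, b] <- sum(p[a:(a + 2 * r), b:(b + 2 * r)] * k2)
    }
    out
  }
  expect_lt(max(abs(tf$jxx - conv_oracle(g$gx * g$gx))), 1e-8)
  expect_lt(max(abs(tf$jxy - conv_oracle(g$gx * g$gy))), 1e-8)
  expect_lt(max(abs(tf$jyy - conv_oracle(g$gy * g$gy))), 1e-8)
})

test_that("energy is non-negative and coherency bounded on random images", {
  set.seed(31)
  for (i in 1:200) {
    img <- matrix(rnorm(16 * 16, sd = runif(1, 0.1, 10)), 16, 16)
    tf <- tensor_analysis(img, runif(1, 0.8, 4))
    expect_true(all(tf$energy >= 0))
    coh <- tf$coherency[!is.na(tf$coherency)]
    expect_true(all(coh >= 0 & coh <= 1))
  }
})

test_that("widening the window never roughens the orientation map", {
  sc <- oriented_scene(25, seed = 3, size = 128L)
  g <- riesz_gradient(sc$image$pixels)
  vars <- vapply(c(1, 2, 4, 8), function(s) {
    tf <- structure_tensor(g$gx, g$gy, s)
    im <- recovery_mask(128L, 20L)
    stats::var(tf$orientation_deg[im], na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(vars) <= 1e-6))
})

test_that("rotating a texture shifts the measured mean orientation by the same angle", {
  base <- 10
  tf0 <- tensor_analysis(make_grating(base, 128, 128, 8), 2)
  im <- recovery_mask(128L, 8L)
  m0 <- circular_summary(tf0$orientation_deg[im], tf0$energy[im])$circular_mean_deg
  for (delta in c(15, 30, 45)) {
    tfd <- tensor_analysis(make_grating(base + delta, 128, 128, 8), 2)
    md <- circular_summary(tfd$orientation_deg[im], tfd$energy[im])$circular_mean_deg
    expect_lt(abs(axial_difference_deg(md, m0) - delta), 1)
  }
})

test_that("invalid window sigma is rejected", {
  g <- riesz_gradient(matrix(rnorm(64 * 64), 64))
  expect_error(structure_tensor(g$gx, g$gy, 0), "positive")
  expect_error(structure_tensor(g$gx, g$gy[1:32, ], 2), "differ")
})

test_that("HSB composite encodes orientation, coherency and brightness", {
  img <- make_grating(30, 64, 64, 8)
  tf <- tensor_analysis(img, 2)
  comp <- hsb_composite(tf, img)
  expect_true(all(comp$rgb >= 0 & comp$rgb <= 1))
  # brightness channel equals the min-max rescaled source exactly
  v <- pmax(comp$rgb[, , 1], pmax(comp$rgb[, , 2], comp$rgb[, , 3]))
  expect_equal(v, (img - min(img)) / (max(img) - min(img)), tolerance = 1e-12)

  # zero coherency (constant image) gives a grayscale composite
  tf0 <- tensor_analysis(matrix(5, 64, 64), 2)
  comp0 <- hsb_composite(tf0, matrix(5, 64, 64))
  expect_equal(comp0$rgb[, , 1], comp0$rgb[, , 2])
  expect_equal(comp0$rgb[, , 2], comp0$rgb[, , 3])
})

test_that("finite-difference gradients cross-check the Riesz path on gratings", {
  img <- make_grating(40, 128, 128, 12)
  tf_r <- tensor_analysis(img, 2, method = "riesz")
  tf_f <- tensor_analysis(img, 2, method = "finite_diff")
  im <- recovery_mask(128L, 8L)
  expect_lt(axial_difference_deg(
    median(tf_r$orientation_deg[im]), median(tf_f$orientation_deg[im])), 1)
})
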
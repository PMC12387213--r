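test_that("quantization bins the intensity range as specified", {
  expect_true(all(quantize(matrix(5, 8, 8), 16) == 0L))
  ramp <- matrix(rep(0:255, each = 8), 8, 256)
  q2 <- quantize(ramp, 2)
  expect_true(all(q2[, 1:128] == 0L))
  expect_true(all(q2[, 129:256] == 1L))
  # hand-computed binning of a 4x4 toy image into 4 levels over [0, 15]:
  # width 4 -> levels 0:3 for values 0-3, 4-7, 8-11, 12-15
  toy <- matrix(c(0, 3, 4, 7, 8, 11, 12, 15, 1, 5, 9, 13, 2, 6, 10, 14),
                4, 4)
  expect_equal(as.vector(quantize(toy, 4)),
               c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L, 0L, 1L, 2L, 3L,
                 0L, 1L, 2L, 3L))
  expect_error(quantize(matrix(0, 8, 8), 1), "levels")
})

test_that("co-occurrence counts match hand-enumerated pairs", {
  z <- matrix(0L, 5, 5); attr(z, "levels") <- 2L
  g <- glcm(z, distance_px = 1, angle_deg = 0)
  expect_equal(g$matrix[1, 1], 1)
  expect_equal(sum(g$matrix), 1)

  q <- rbind(c(0L, 1L), c(2L, 3L)); attr(q, "levels") <- 4L
  g2 <- glcm(q, distance_px = 1, angle_deg = 0, symmetric = FALSE,
             normalized = FALSE)
  expected <- matrix(0, 4, 4)
  expected[1, 2] <- 1   # (0,1)
  expected[3, 4] <- 1   # (2,3)
  expect_equal(g2$matrix, expected)

  # d = 0 self-pairing: diagonal with trace = pixel count
  set.seed(1)
  qq <- quantize(matrix(runif(64), 8), 4)
  g0 <- glcm(qq, distance_px = 0, angle_deg = 0, symmetric = FALSE,
             normalized = FALSE)
  expect_true(all(g0$matrix[row(g0$matrix) != col(g0$matrix)] == 0))
  expect_equal(sum(diag(g0$matrix)), 64)

  expect_error(glcm(qq, distance_px = 20, angle_deg = 0), "no valid")
  expect_error(glcm(qq, distance_px = 1, angle_deg = 30), "angle")
})

test_that("GLCM invariants hold: symmetry and normalization", {
  set.seed(7)
  q <- quantize(matrix(runif(15 * 12), 15, 12), 5)
  for (d in c(0L, 1L, 2L)) for (th in c(0, 45, 90)) {
    g <- glcm(q, distance_px = d, angle_deg = th)
    expect_lt(abs(sum(g$matrix) - 1), 1e-12)
    expect_equal(g$matrix, t(g$matrix))
  }
})

test_that("GLCM agrees with brute-force pair enumeration on sampled small images", {
  set.seed(42)
  n_checked <- 0L
  while (n_checked < 1000L) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    q <- matrix(sample(0:2, nr * nc, replace = TRUE), nr, nc)
    attr(q, "levels") <- 3L
    d <- sample(0:2, 1); th <- sample(c(0, 45, 90), 1)
    dr <- if (th == 0) 0L else d; dc <- if (th == 90) 0L else d
    if (dr >= nr || dc >= nc) next    # offset leaves no pairs
    sym <- sample(c(TRUE, FALSE), 1)
    g <- glcm(q, distance_px = d, angle_deg = th, symmetric = sym,
              normalized = FALSE)
    bf <- glcm_bruteforce(q, 3L, d, th, symmetric = sym, normalized = FALSE)
    expect_equal(g$matrix, bf)
    n_checked <- n_checked + 1L
  }
})

test_that("descriptor vector has 23 named entries with textbook values on degenerate inputs", {
  nm <- glcm_descriptor_names()
  expect_length(nm, 23L)
  expect_false(any(duplicated(nm)))

  qc <- quantize(matrix(1, 8, 8), 8)
  f <- haralick_features(glcm(qc, distance_px = 1, angle_deg = 0))
  expect_length(f, 23L)
  expect_identical(names(f), nm)
  expect_equal(unname(f["asm"]), 1)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["entropy"]), 0)

  # 2-level checkerboard: every horizontal pair is (0,1) or (1,0)
  cb <- quantize((outer(1:8, 1:8, "+") %% 2), 2)
  fcb <- haralick_features(glcm(cb, distance_px = 1, angle_deg = 0))
  expect_equal(unname(fcb["contrast"]), 1)
  expect_equal(unname(fcb["correlation"]), -1)

  expect_error(haralick_features(glcm(cb, distance_px = 1, angle_deg = 0,
                                      normalized = FALSE)), "normalized")
})

test_that("all 23 descriptors agree with an independent brute-force oracle", {
  set.seed(14)
  for (i in 1:20) {
    q <- matrix(sample(0:5, 64, replace = TRUE), 8, 8)
    attr(q, "levels") <- 6L
    g <- glcm(q, distance_px = sample(1:2, 1),
              angle_deg = sample(c(0, 45, 90), 1))
    f <- haralick_features(g)
    bf <- haralick_bruteforce(g$matrix)
    expect_lt(max(abs(unname(f) - bf)), 1e-10)
  }
})

test_that("standardization follows the population-variance convention", {
  t0 <- data.frame(image = c("a", "b"), distance_px = 1L, angle_deg = 0,
                   f1 = c(1, 3), f2 = c(5, 5))
  s <- suppressWarnings(standardize_features(t0))
  expect_equal(s$f1, c(-1, 1))
  expect_equal(s$f2, c(0, 0))
  expect_warning(standardize_features(t0), "constant")
  # idempotent
  s2 <- suppressWarnings(standardize_features(s))
  expect_equal(s2$f1, s$f1, tolerance = 1e-12)
  expect_error(standardize_features(t0[1, ]), "at least 2")
})

test_that("standardized tables have zero mean and unit variance per column", {
  set.seed(5)
  imgs <- lapply(1:5, function(i) matrix(runif(256) * i, 16))
  tab <- texture_feature_table(imgs, levels = 8, distances = c(1L),
                               angles = c(0))
  s <- suppressWarnings(standardize_features(tab))
  X <- as.matrix(s[, glcm_descriptor_names()])
  expect_lt(max(abs(colMeans(X))), 1e-10)
  popvar <- apply(X, 2, function(x) mean((x - mean(x))^2))
  nonconst <- popvar > 0
  expect_lt(max(abs(popvar[nonconst] - 1)), 1e-10)
})

test_that("PCA explains variance correctly on constructed data", {
  # collinear data: one component carries everything
  base <- data.frame(image = letters[1:6], distance_px = 1L, angle_deg = 0)
  v <- seq(1, 6)
  line <- cbind(base, f1 = v, f2 = 2 * v, f3 = -v)
  s <- standardize_features(line)
  p <- texture_pca(s, 1)
  expect_gt(p$explained_variance_pct[1], 100 - 1e-8)

  # isotropic 2-feature cloud splits variance evenly
  set.seed(10)
  cloud <- data.frame(image = sprintf("i%04d", 1:1000), distance_px = 1L,
                      angle_deg = 0, f1 = rnorm(1000), f2 = rnorm(1000))
  sp <- standardize_features(cloud)
  pp <- texture_pca(sp, 2)
  expect_lt(abs(pp$explained_variance_pct[1] - 50), 3)
  expect_lt(abs(sum(pp$all_variance_pct) - 100), 1e-8)
  # loadings are orthonormal
  expect_lt(max(abs(crossprod(pp$loadings) - diag(2))), 1e-8)

  expect_error(texture_pca(sp, 50), "out of range")
  expect_error(texture_pca(cloud, 2), "standardize")
})

test_that("PCA separates coarse from fine textures in the leading plane", {
  set.seed(20)
  imgs <- c(lapply(1:10, function(i)
    make_grating(0, 48, 48, 16) + matrix(rnorm(48 * 48, sd = 0.1), 48)),
    lapply(1:10, function(i)
      make_grating(0, 48, 48, 4) + matrix(rnorm(48 * 48, sd = 0.1), 48)))
  names(imgs) <- c(sprintf("coarse%02d", 1:10), sprintf("fine%02d", 1:10))
  tab <- texture_feature_table(imgs, levels = 16, distances = c(1L, 2L),
                               angles = c(0, 90))
  s <- suppressWarnings(standardize_features(tab))
  p <- texture_pca(s, 2)
  # one point per image in the leading plane: average the (d, theta) rows
  agg <- aggregate(p$scores, by = list(img = p$keys$image), FUN = mean)
  S <- as.matrix(agg[, 2:3])
  grp <- grepl("^coarse", agg$img)
  ca <- colMeans(S[grp, , drop = FALSE])
  cb <- colMeans(S[!grp, , drop = FALSE])
  between <- sqrt(sum((ca - cb)^2))
  within <- mean(c(
    sqrt(rowSums((S[grp, ] - matrix(ca, sum(grp), 2, byrow = TRUE))^2)),
    sqrt(rowSums((S[!grp, ] - matrix(cb, sum(!grp), 2, byrow = TRUE))^2))))
  expect_gt(between, 3 * within)
})

test_that("box-plot summaries follow the type-7 quantile and 1.5 IQR rules", {
  b <- poretex:::.box_summary(1:9)
  expect_equal(b$median, 5)
  expect_equal(b$q1, 3)   # type-7 on 1..9
  expect_equal(b$q3, 7)
  expect_equal(b$n_outliers, 0L)

  ball <- poretex:::.box_summary(rep(2, 6))
  expect_equal(ball$q1, ball$q3)
  expect_equal(ball$n_outliers, 0L)

  bout <- poretex:::.box_summary(c(0, 0, 0, 0, 100))
  expect_equal(bout$n_outliers, 1L)
  expect_equal(bout$outliers[[1]], 100)
  expect_lte(bout$whisker_high, 0)
})
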
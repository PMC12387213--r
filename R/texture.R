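#' Names of the 23 co-occurrence texture descriptors, in fixed order
#'
#' Haralick's fourteen classical descriptors plus nine later extensions
#' (autocorrelation, dissimilarity, cluster shade/prominence, maximum
#' probability, inverse difference and its normalized variants, and an
#' intensity second moment). The count and order are frozen; every feature
#' table names its columns with this vector.
#'
#' @return character vector of length 23.
#' @export
glcm_descriptor_names <- function() {
  c("asm", "contrast", "correlation", "variance", "idm",
    "sum_average", "sum_variance", "sum_entropy", "entropy",
    "difference_variance", "difference_entropy", "imc1", "imc2",
    "autocorrelation", "dissimilarity", "cluster_shade",
    "cluster_prominence", "maximum_probability", "inverse_difference",
    "inverse_difference_normalized", "inverse_difference_moment_normalized",
    "sum_of_squares_intensity", "maximal_correlation_coefficient")
}

#' Quantize an image to integer grey levels
#'
#' Equal-width binning of the intensity range [min, max] into `levels`
#' labels 0..levels-1. A constant image maps entirely to level 0.
#'
#' @param img [raster_image()] or matrix.
#' @param levels number of grey levels, in [2, 256] (default 32).
#' @return integer matrix of labels.
#' @export
quantize <- function(img, levels = 32L) {
  m <- if (is_raster_image(img)) img$pixels else as.matrix(img)
  levels <- as.integer(levels)
  if (levels < 2L || levels > 256L)
    stop("quantize: levels must be in [2, 256]")
  rg <- range(m)
  if (rg[2] <= rg[1]) {
    q <- matrix(0L, nrow(m), ncol(m))
  } else {
    q <- floor((m - rg[1]) / (rg[2] - rg[1]) * levels)
    q[q >= levels] <- levels - 1L
    storage.mode(q) <- "integer"
  }
  attr(q, "levels") <- levels
  q
}

# offsets follow the image-processing convention (row index downward):
# theta = 0 deg -> (0, +d); 45 -> (-d, +d); 90 -> (-d, 0)
.glcm_offset <- function(distance_px, angle_deg) {
  switch(as.character(angle_deg),
         "0"  = c(0L, distance_px),
         "45" = c(-distance_px, distance_px),
         "90" = c(-distance_px, 0L),
         stop("glcm: angle must be one of 0, 45, 90"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs (q[p], q[p + offset]) of quantized grey levels over
#' all pixels p whose offset partner lies inside the image, at angles
#' theta in {0, 45, 90} degrees and integer distance d >= 0. A distance of
#' zero pairs each pixel with itself, giving a diagonal self-co-occurrence
#' matrix (implemented literally; see Details). Optionally symmetrized
#' (matrix plus its transpose) and normalized to sum 1.
#'
#' @details A zero offset is degenerate — its matrix is diagonal with trace
#' equal to the pixel count — but it is retained because texture protocols
#' sometimes list d = 0 alongside positive distances; descriptors computed
#' from it reduce to functions of the grey-level histogram.
#'
#' @param q integer label matrix from [quantize()].
#' @param levels number of grey levels (defaults to the `levels` attribute
#'   of `q`).
#' @param distance_px non-negative integer offset length.
#' @param angle_deg 0, 45 or 90.
#' @param symmetric add the transpose (default TRUE).
#' @param normalized divide by the total count (default TRUE).
#' @return object of class `glcm`: list with `matrix` (levels x levels),
#'   `levels`, `distance_px`, `angle_deg`, `symmetric`, `normalized`.
#' @export
glcm <- function(q, levels = attr(q, "levels"), distance_px = 1L,
                 angle_deg = 0, symmetric = TRUE, normalized = TRUE) {
  if (is.null(levels)) levels <- max(q) + 1L
  levels <- as.integer(levels)
  if (any(q < 0L) || any(q >= levels))
    stop("glcm: labels outside [0, levels)")
  d <- as.integer(distance_px)
  if (d < 0L) stop("glcm: distance must be >= 0")
  off <- .glcm_offset(d, angle_deg)
  nr <- nrow(q); nc <- ncol(q)
  r0 <- max(1L, 1L - off[1]); r1 <- min(nr, nr - off[1])
  c0 <- max(1L, 1L - off[2]); c1 <- min(nc, nc - off[2])
  if (r0 > r1 || c0 > c1)
    stop("glcm: offset leaves no valid pixel pairs")
  a <- q[r0:r1, c0:c1, drop = FALSE]
  b <- q[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2]),
         drop = FALSE]
  idx <- as.vector(a) * levels + as.vector(b) + 1L
  counts <- tabulate(idx, nbins = levels * levels)
  m <- matrix(as.numeric(counts), levels, levels, byrow = TRUE)
  if (symmetric) m <- m + t(m)
  if (normalized) m <- m / sum(m)
  structure(list(matrix = m, levels = levels, distance_px = d,
                 angle_deg = angle_deg, symmetric = symmetric,
                 normalized = normalized),
            class = "glcm")
}

#' The 23 co-occurrence descriptors of a normalized GLCM
#'
#' Computes the descriptor vector named by [glcm_descriptor_names()] from a
#' normalized co-occurrence matrix. Grey levels are indexed 0..G-1;
#' logarithms are natural with the convention 0 log 0 = 0. Degenerate
#' denominators (zero marginal variance) yield 0 for the affected
#' correlation-type descriptors.
#'
#' @param m a [glcm()] with `normalized = TRUE`, or a matrix summing to 1.
#' @return named numeric vector of length 23.
#' @export
haralick_features <- function(m) {
  if (inherits(m, "glcm")) {
    if (!m$normalized) stop("haralick_features: GLCM must be normalized")
    p <- m$matrix
  } else {
    p <- as.matrix(m)
    if (abs(sum(p) - 1) > 1e-8)
      stop("haralick_features: matrix must be normalized (sum 1)")
  }
  G <- nrow(p)
  i <- matrix(0:(G - 1), G, G)          # row level index
  j <- t(i)                             # column level index
  px <- rowSums(p); py <- colSums(p)
  lev <- 0:(G - 1)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px)); sdy <- sqrt(sum((lev - muy)^2 * py))
  xlog <- function(x) ifelse(x > 0, log(x), 0)

  # sum and difference marginals p_{x+y}(k), k = 0..2G-2; p_{|x-y|}(k)
  k_sum <- 0:(2 * G - 2)
  psum <- vapply(k_sum, function(k) sum(p[i + j == k]), numeric(1))
  k_dif <- 0:(G - 1)
  pdif <- vapply(k_dif, function(k) sum(p[abs(i - j) == k]), numeric(1))

  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  sij <- sum(i * j * p)
  correlation <- if (sdx > 0 && sdy > 0) (sij - mux * muy) / (sdx * sdy) else 0
  variance <- sum((i - mux)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  sum_average <- sum(k_sum * psum)
  sum_variance <- sum((k_sum - sum_average)^2 * psum)
  sum_entropy <- -sum(psum * xlog(psum))
  entropy <- -sum(p * xlog(p))
  dif_average <- sum(k_dif * pdif)
  difference_variance <- sum((k_dif - dif_average)^2 * pdif)
  difference_entropy <- -sum(pdif * xlog(pdif))
  hx <- -sum(px * xlog(px)); hy <- -sum(py * xlog(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * xlog(pxy))
  hxy2 <- -sum(pxy * xlog(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  autocorrelation <- sij
  dissimilarity <- sum(abs(i - j) * p)
  cluster_shade <- sum((i + j - mux - muy)^3 * p)
  cluster_prominence <- sum((i + j - mux - muy)^4 * p)
  maximum_probability <- max(p)
  inverse_difference <- sum(p / (1 + abs(i - j)))
  idn <- sum(p / (1 + abs(i - j) / G))
  idmn <- sum(p / (1 + (i - j)^2 / G^2))
  sos_intensity <- sum(i^2 * p)
  # maximal correlation coefficient: sqrt of the 2nd largest eigenvalue of
  # Q(a,b) = sum_k p(a,k) p(b,k) / (px(a) py(k))
  nzx <- px > 0; nzy <- py > 0
  mcc <- 0
  if (sum(nzx) >= 2L && sum(nzy) >= 2L) {
    psub <- p[nzx, nzy, drop = FALSE]
    Q <- (psub / px[nzx]) %*% t(psub / matrix(py[nzy], nrow = sum(nzx),
                                              ncol = sum(nzy), byrow = TRUE))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2L) mcc <- sqrt(max(0, min(ev[2], 1)))
  }
  out <- c(asm, contrast, correlation, variance, idm, sum_average,
           sum_variance, sum_entropy, entropy, difference_variance,
           difference_entropy, imc1, imc2, autocorrelation, dissimilarity,
           cluster_shade, cluster_prominence, maximum_probability,
           inverse_difference, idn, idmn, sos_intensity, mcc)
  names(out) <- glcm_descriptor_names()
  out
}

#' Texture feature table over images, distances and angles
#'
#' Builds one row of the 23 descriptors per (image, distance, angle)
#' combination, the tabulation used to compare substrates: co-occurrence at
#' theta in {0, 45, 90} degrees and d in {0, 2} by default.
#'
#' @param images named list of [raster_image()] or matrices.
#' @param levels quantization levels (default 32).
#' @param distances integer vector of offsets (default c(0, 2)).
#' @param angles angle vector, subset of c(0, 45, 90).
#' @return data.frame of class `texture_feature_table` with key columns
#'   `image`, `distance_px`, `angle_deg` followed by the 23 descriptors.
#' @export
texture_feature_table <- function(images, levels = 32L,
                                  distances = c(0L, 2L),
                                  angles = c(0, 45, 90)) {
  if (is.null(names(images)))
    names(images) <- sprintf("img%02d", seq_along(images))
  rows <- list()
  for (nm in names(images)) {
    q <- quantize(images[[nm]], levels)
    for (d in distances) for (th in angles) {
      g <- glcm(q, distance_px = d, angle_deg = th)
      f <- haralick_features(g)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(image = nm, distance_px = d, angle_deg = th,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(f)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("texture_feature_table", class(out))
  out
}

# feature columns of a texture table (everything after the 3 key columns)
.feature_cols <- function(t) setdiff(names(t),
                                     c("image", "distance_px", "angle_deg"))

#' Z-score standardization of a texture feature table
#'
#' Centers each descriptor column to mean 0 and scales it to variance 1
#' (population variance, denominator n). Constant columns are mapped to 0
#' with a warning. Standardizing twice is idempotent.
#'
#' @param t a `texture_feature_table` (or data.frame with the same layout).
#' @return the table with standardized descriptor columns; attribute
#'   `standardized = TRUE`.
#' @export
standardize_features <- function(t) {
  if (nrow(t) < 2L)
    stop("standardize_features: need at least 2 rows")
  fc <- .feature_cols(t)
  const <- character(0)
  for (cn in fc) {
    x <- t[[cn]]
    s <- sqrt(mean((x - mean(x))^2))
    if (!is.finite(s) || s == 0) {
      t[[cn]] <- rep(0, length(x))
      const <- c(const, cn)
    } else {
      t[[cn]] <- (x - mean(x)) / s
    }
  }
  if (length(const))
    warning("standardize_features: constant columns set to 0: ",
            paste(const, collapse = ", "))
  attr(t, "standardized") <- TRUE
  t
}

#' Principal-component projection of a standardized feature table
#'
#' Eigen-decomposition of the covariance of the standardized descriptors
#' (via [stats::prcomp()]); reports scores, loadings and the percentage of
#' variance retained by each component, sorted descending.
#'
#' @param t a standardized `texture_feature_table`.
#' @param k number of components (<= min(n - 1, 23)).
#' @return object of class `texture_pca`: list with `scores` (n x k),
#'   `loadings` (23 x k), `explained_variance_pct` (length k) and the key
#'   columns of `t` as `keys`.
#' @export
texture_pca <- function(t, k = 2L) {
  fc <- .feature_cols(t)
  X <- as.matrix(t[, fc])
  if (!isTRUE(attr(t, "standardized")))
    stop("texture_pca: standardize the table first (standardize_features)")
  k <- as.integer(k)
  if (k < 1L || k > min(nrow(X) - 1L, ncol(X)))
    stop("texture_pca: k out of range")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  pct <- 100 * ev / sum(ev)
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_variance_pct = pct[seq_len(k)],
                 all_variance_pct = pct,
                 keys = t[, c("image", "distance_px", "angle_deg")]),
            class = "texture_pca")
}

#' @export
print.texture_pca <- function(x, ...) {
  cat(sprintf("<texture_pca> %d rows, %d components: %s%% variance\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f", x$explained_variance_pct),
                    collapse = " + ")))
  invisible(x)
}

#' Five-number box-plot summaries of feature distributions
#'
#' For each descriptor, the median, 25th and 75th percentiles (type-7
#' quantiles, linear interpolation), whiskers at the most extreme points
#' within 1.5 IQR of the box, and individually listed outliers beyond them.
#'
#' @param t a `texture_feature_table` (standardized or not).
#' @param by optional key column to group rows by (e.g. `"image"`).
#' @return data.frame with columns `feature`, `group`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `n_outliers`, and a list column
#'   `outliers`.
#' @export
feature_boxplot_summary <- function(t, by = NULL) {
  fc <- .feature_cols(t)
  groups <- if (is.null(by)) list(all = seq_len(nrow(t)))
            else split(seq_len(nrow(t)), t[[by]])
  rows <- list()
  for (gn in names(groups)) {
    idx <- groups[[gn]]
    for (cn in fc) {
      x <- t[[cn]][idx]
      rows[[length(rows) + 1L]] <- .box_summary(x, cn, gn)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.box_summary <- function(x, feature = "x", group = "all") {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  inside <- x >= lo & x <= hi
  out <- data.frame(feature = feature, group = group,
                    median = q[2], q1 = q[1], q3 = q[3],
                    whisker_low = if (any(inside)) min(x[inside]) else q[1],
                    whisker_high = if (any(inside)) max(x[inside]) else q[3],
                    n_outliers = sum(!inside),
                    stringsAsFactors = FALSE)
  out$outliers <- I(list(sort(x[!inside])))
  out
}
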
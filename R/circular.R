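#' Axial (orientation) circular statistics
#'
#' Orientations of filaments and textures are axial data: an angle theta and
#' theta + 180 deg describe the same structure. All summaries therefore
#' double the angles, compute vector statistics on the doubled circle, and
#' halve the mean back. Angles are in degrees in [-90, 90), measured
#' counterclockwise from the image horizontal axis.
#'
#' @param angles_deg numeric vector of orientations in degrees.
#' @param weights optional non-negative weights (e.g. tensor energy).
#' @return a list of class `circular_summary` with `circular_mean_deg` in
#'   [-90, 90), `resultant_length` in [0, 1] and
#'   `circular_variance = 1 - resultant_length`.
#' @export
circular_summary <- function(angles_deg, weights = NULL) {
  a <- angles_deg[is.finite(angles_deg)]
  if (is.null(weights)) {
    w <- rep(1, length(a))
  } else {
    w <- weights[is.finite(angles_deg)]
    if (any(w < 0)) stop("circular_summary: negative weights")
  }
  if (length(a) == 0L || sum(w) == 0) {
    return(structure(list(circular_mean_deg = NA_real_,
                          resultant_length = NA_real_,
                          circular_variance = NA_real_,
                          n = 0L), class = "circular_summary"))
  }
  phi <- 2 * a * pi / 180            # doubled angles, radians
  C <- sum(w * cos(phi)) / sum(w)
  S <- sum(w * sin(phi)) / sum(w)
  R <- sqrt(C^2 + S^2)
  mu <- fold_orientation_deg(atan2(S, C) / 2 * 180 / pi)
  structure(list(circular_mean_deg = mu,
                 resultant_length = R,
                 circular_variance = 1 - R,
                 n = length(a)), class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat(sprintf(
    "<circular_summary> mean %.2f deg, resultant length %.3f, variance %.3f (n = %d)\n",
    x$circular_mean_deg, x$resultant_length, x$circular_variance, x$n))
  invisible(x)
}

#' Fold an angle into the orientation range [-90, 90)
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles folded modulo 180 into [-90, 90).
#' @export
fold_orientation_deg <- function(deg) {
  ((deg + 90) %% 180) - 90
}

#' Smallest axial difference between two orientations
#'
#' @param a_deg,b_deg orientations in degrees.
#' @return absolute axial difference in [0, 90].
#' @export
axial_difference_deg <- function(a_deg, b_deg) {
  d <- abs(fold_orientation_deg(a_deg - b_deg))
  pmin(d, 180 - d)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler on the full circle. `kappa = 0` reduces to
#' the uniform distribution. Used by the scene generator with doubled
#' orientation angles (axial data live on the half-circle).
#'
#' @param n number of draws.
#' @param mu_rad mean direction in radians.
#' @param kappa non-negative concentration.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu_rad, kappa) {
  if (kappa < 0) stop("rvonmises: kappa must be non-negative")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa > 5e5) return(rep(((mu_rad + pi) %% (2 * pi)) - pi, n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      theta <- mu_rad + sign(u3 - 0.5) * acos(f)
      out[i] <- ((theta + pi) %% (2 * pi)) - pi
      i <- i + 1L
    }
  }
  out
}

#' Sample axial orientations from a doubled-angle von Mises distribution
#'
#' Orientations are pi-periodic, so the generator doubles the mean, samples
#' von Mises on the full circle, and halves the draws back.
#'
#' @param n number of draws.
#' @param mu_deg mean orientation in degrees, in [-90, 90).
#' @param kappa concentration of the doubled-angle distribution.
#' @return orientations in degrees in [-90, 90).
#' @export
raxial_vonmises <- function(n, mu_deg, kappa) {
  th2 <- rvonmises(n, 2 * mu_deg * pi / 180, kappa)
  fold_orientation_deg(th2 / 2 * 180 / pi)
}
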
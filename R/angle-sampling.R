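#' Tract fibre-orientation profile
#'
#' Describes the distribution of fibre axes in a tract by a mean
#' fibre-to-field angle and a Watson-type axial concentration. Axes are
#' drawn from a Watson distribution (density proportional to
#' `exp(kappa * (mu . x)^2)` on the sphere) around a mean direction
#' making `mean_deg` with B0; the fibre-to-field angle theta is the
#' angle between the drawn axis and B0, folded into \[0, 90\] degrees
#' (fibre axes are antipodally symmetric).
#'
#' `dispersion` is the Watson concentration kappa: `0` gives an
#' isotropic axis distribution (theta density proportional to
#' sin(theta) on \[0, 90\] degrees) and `Inf` collapses every angle to
#' `mean_deg`. Larger values give narrower tract profiles, e.g. the
#' splenium, where fibres run almost perpendicular to B0.
#'
#' @param mean_deg mean fibre-to-field angle in degrees, in \[0, 90\].
#' @param dispersion Watson concentration parameter, `>= 0` (possibly
#'   `Inf`). Note that despite the name this is a *concentration*:
#'   larger values mean less angular spread.
#' @return An object of class `angle_profile`.
#' @examples
#' sample_fibre_angles(angle_profile(90, 25), 5, seed = 1)
#' @export
angle_profile <- function(mean_deg, dispersion) {
  stopifnot(is.numeric(mean_deg), length(mean_deg) == 1L,
            mean_deg >= 0, mean_deg <= 90,
            is.numeric(dispersion), length(dispersion) == 1L)
  if (is.na(dispersion) || dispersion < 0)
    stop("'dispersion' must be a non-negative concentration parameter")
  structure(list(mean_deg = mean_deg, dispersion = dispersion),
            class = "angle_profile")
}

#' @export
print.angle_profile <- function(x, ...) {
  cat(sprintf("<angle_profile> mean %.1f deg, concentration %.3g\n",
              x$mean_deg, x$dispersion))
  invisible(x)
}

## Draw cos(psi) for the angle psi between a Watson axis and its mean
## direction, on [0, 1] (axial fold). kappa = 0 is exactly uniform.
sample_watson_cosine <- function(kappa, n) {
  if (kappa == 0) return(runif(n))
  ## numeric inversion of the CDF of f(t) proportional to exp(kappa t^2);
  ## for large kappa restrict the grid to where the mass lives
  lo <- if (kappa > 50) max(0, 1 - 8 / sqrt(kappa)) else 0
  grid <- seq(lo, 1, length.out = 4097L)
  w <- exp(kappa * (grid^2 - 1))
  steps <- (w[-1L] + w[-length(w)]) / 2 * diff(grid)
  cdf <- c(0, cumsum(steps))
  cdf <- cdf / cdf[length(cdf)]
  ## strip duplicated cdf values (flat underflowed tail) for approx()
  keep <- c(TRUE, diff(cdf) > 0)
  approx(cdf[keep], grid[keep], runif(n), rule = 2)$y
}

#' Sample fibre-to-field angles for a tract profile
#'
#' Draws `n` fibre axes from the Watson model of an [angle_profile()]
#' and returns their angles to the main field, in degrees folded into
#' \[0, 90\].
#'
#' @param profile an [angle_profile()].
#' @param n number of angles, `> 0`.
#' @param seed optional integer seed; the caller's RNG state is left
#'   untouched when given.
#' @return Numeric vector of `n` angles in degrees, in \[0, 90\].
#' @export
sample_fibre_angles <- function(profile, n, seed = NULL) {
  stopifnot(inherits(profile, "angle_profile"),
            is.numeric(n), length(n) == 1L, n > 0)
  n <- as.integer(n)
  with_seed(seed, {
    if (is.infinite(profile$dispersion)) return(rep(profile$mean_deg, n))
    t <- sample_watson_cosine(profile$dispersion, n)
    phi <- runif(n, 0, 2 * pi)
    alpha <- profile$mean_deg * pi / 180
    sin_psi <- sqrt(pmax(0, 1 - t^2))
    ## z-component of the axis after rotating the mean direction to
    ## make angle alpha with B0; antipodal fold via abs()
    z <- abs(cos(alpha) * t - sin(alpha) * sin_psi * cos(phi))
    acos(pmin(1, z)) * 180 / pi
  })
}
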
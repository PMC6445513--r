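#' Optical and imaging configuration
#'
#' Bundles the fixed optical constants of an RICM acquisition: pixel size,
#' illumination wavelength and numerical aperture, the refractive index of the
#' immersion medium, the phase shift picked up at reflection, and the radial
#' extent (in pixels) of the generated templates. Derived quantities -- the
#' illumination aperture half-angle and the wavenumber in the medium -- are
#' computed on demand by [aperture_angle()] and [wavenumber()], not stored.
#'
#' @param u Pixel length in micrometres per pixel.
#' @param lambda Illumination wavelength in micrometres (in vacuum).
#' @param INA Illumination numerical aperture (dimensionless); must satisfy
#'   `0 < INA < n` for the aperture half-angle to be defined.
#' @param n Refractive index of the aqueous medium.
#' @param theta Phase shift of the reflected wave in radians. `pi` for the
#'   usual glass/water/particle stack, where the contact zone appears dark.
#' @param r_max Radial extent of templates in pixels (integer, at least 2).
#' @return An object of class `ricm_optics`.
#' @examples
#' opt <- optical_config()
#' aperture_angle(opt)
#' @export
optical_config <- function(u = 0.067, lambda = 0.53, INA = 0.67,
                           n = 1.332, theta = pi, r_max = 100L) {
  stopifnot(is.numeric(u), length(u) == 1L, is.finite(u),
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(INA), length(INA) == 1L, is.finite(INA),
            is.numeric(n), length(n) == 1L, is.finite(n),
            is.numeric(theta), length(theta) == 1L, is.finite(theta),
            is.numeric(r_max), length(r_max) == 1L, is.finite(r_max))
  if (u <= 0) stop("pixel length 'u' must be positive")
  if (lambda <= 0) stop("wavelength 'lambda' must be positive")
  if (INA <= 0 || INA >= n)
    stop("invalid optics: need 0 < INA < n, got INA = ", INA, ", n = ", n)
  if (r_max < 2 || r_max != round(r_max))
    stop("'r_max' must be an integer >= 2")
  structure(
    list(u = u, lambda = lambda, INA = INA, n = n, theta = theta,
         r_max = as.integer(r_max)),
    class = "ricm_optics"
  )
}

#' @export
print.ricm_optics <- function(x, ...) {
  cat("RICM optical configuration\n")
  cat(sprintf("  pixel length u      : %.4g um/px\n", x$u))
  cat(sprintf("  wavelength lambda   : %.4g um\n", x$lambda))
  cat(sprintf("  illum. NA (INA)     : %.4g\n", x$INA))
  cat(sprintf("  refractive index n  : %.4g\n", x$n))
  cat(sprintf("  phase shift theta   : %.4g rad\n", x$theta))
  cat(sprintf("  template radius     : %d px (%.3g um)\n",
              x$r_max, x$r_max * x$u))
  invisible(x)
}

#' Illumination aperture half-angle
#'
#' The half-angle of the illumination cone inside the medium,
#' `alpha = asin(INA / n)`. A finite aperture damps the fringe contrast with
#' a sinc envelope; see [template_intensity()].
#'
#' @param config An [optical_config()].
#' @return Angle in radians, in (0, pi/2).
#' @export
aperture_angle <- function(config) {
  stopifnot(inherits(config, "ricm_optics"))
  asin(config$INA / config$n)
}

#' Wavenumber in the medium
#'
#' `k = 2 * pi * n / lambda`, in inverse micrometres.
#'
#' @param config An [optical_config()].
#' @return Wavenumber in um^-1.
#' @export
wavenumber <- function(config) {
  stopifnot(inherits(config, "ricm_optics"))
  2 * pi * config$n / config$lambda
}
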
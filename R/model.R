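#' Template parameters
#'
#' The three free parameters of a radial fringe template: particle height
#' above the coverslip `d` (micrometres; `d <= 0` means the sphere touches and
#' indents by `|d|`), particle radius `p` (micrometres), and the dimensionless
#' empirical decay strength `dec` attenuating outer fringes.
#'
#' @param d Particle height in um; may be negative (contact).
#' @param p Particle radius in um; must be positive and at least cover the
#'   sampled radial extent (`p >= r_max * u` is checked where an optical
#'   configuration is in scope).
#' @param dec Decay strength, non-negative.
#' @return An object of class `ricm_template_params`.
#' @export
template_params <- function(d, p, dec = 0) {
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d),
            is.numeric(p), length(p) == 1L, is.finite(p),
            is.numeric(dec), length(dec) == 1L, is.finite(dec))
  if (p <= 0) stop("particle radius 'p' must be positive")
  if (dec < 0) stop("decay strength 'dec' must be non-negative")
  if (abs(d) > p) stop("invalid indentation: |d| exceeds the particle radius")
  structure(list(d = d, p = p, dec = dec), class = "ricm_template_params")
}

#' Height of a sphere above the coverslip plane
#'
#' Height of the lower surface of a sphere of radius `p` whose lowest point
#' sits at height `d` above the plane, evaluated at lateral distance `r` from
#' the contact axis:  `h(r) = max(0, d + p - sqrt(p^2 - r^2))`.
#' The clamp at zero crops the sphere for touching/indenting particles
#' (`d <= 0`), producing a flat circular contact zone.
#'
#' @param r Lateral distance(s) from the axis, um; must satisfy `0 <= r <= p`.
#' @param d Particle height, um (negative for indentation).
#' @param p Particle radius, um.
#' @return Height(s) in um, non-negative, vectorized over `r`.
#' @export
height_profile <- function(r, d, p) {
  stopifnot(is.numeric(r), is.numeric(d), length(d) == 1L,
            is.numeric(p), length(p) == 1L, p > 0)
  if (any(r < 0)) stop("radial distance 'r' must be non-negative")
  if (any(r > p)) stop("radial distance 'r' exceeds the sphere radius 'p'")
  pmax(0, d + p - sqrt(p^2 - r^2))
}

#' Theoretical RICM fringe intensity at one radius
#'
#' The interference intensity (normalized, dimensionless in \[-1, 1\]) of a
#' sphere at height `h(r)` over the coverslip, for monochromatic illumination
#' with a finite aperture:
#' \deqn{p(r) = \mathrm{sinc}(y)\,\cos(2 k h(r) (1 - \sin^2(\alpha/2)) + \theta)}
#' with `y = 2 k h(r) sin^2(alpha/2)`, `k` the wavenumber in the medium and
#' `alpha` the illumination aperture half-angle. The sinc term is the
#' contrast envelope caused by averaging over illumination angles.
#'
#' @param r Radial distance(s), um.
#' @param params A [template_params()] (the `dec` field is ignored here;
#'   decay is applied separately by [apply_decay()]).
#' @param config An [optical_config()].
#' @return Intensity value(s) in \[-1, 1\], vectorized over `r`.
#' @export
template_intensity <- function(r, params, config) {
  stopifnot(inherits(params, "ricm_template_params"),
            inherits(config, "ricm_optics"))
  h <- height_profile(r, params$d, params$p)
  k <- wavenumber(config)
  alpha <- aperture_angle(config)
  s2 <- sin(alpha / 2)^2
  y <- 2 * k * h * s2
  sinc <- ifelse(y == 0, 1, sin(y) / y)
  sinc * cos(2 * k * h * (1 - s2) + config$theta)
}

#' Exponential decay of outer fringes
#'
#' Multiplies a radial profile sampled at pixel radii `1 ... r_max` by the
#' empirical attenuation `exp(-dec * (r / r_max)^2)`, which accounts for the
#' loss of fringe contrast at large radii that the planar-interface model
#' does not capture. `dec = 0` is the identity.
#'
#' @param values Numeric vector, entry `j` at pixel radius `j`.
#' @param dec Decay strength, non-negative.
#' @param r_max Template radius in pixels (the normalization scale).
#' @return Vector of the same length, attenuated pointwise.
#' @export
apply_decay <- function(values, dec, r_max) {
  stopifnot(is.numeric(values), is.numeric(dec), length(dec) == 1L,
            is.numeric(r_max), length(r_max) == 1L, r_max >= 1)
  if (dec < 0) stop("decay strength 'dec' must be non-negative")
  r_px <- seq_along(values)
  values * exp(-dec * (r_px / r_max)^2)
}

#' Generate one radial template
#'
#' Evaluates the forward model at pixel radii `1 ... r_max` (radius in um is
#' `r_px * u`) and applies the decay, yielding the discrete radial profile
#' that is matched against measured profiles. The value at radius 0 is not
#' stored; measured profiles start at pixel radius 1 as well.
#'
#' @param params A [template_params()].
#' @param config An [optical_config()].
#' @return An object of class `ricm_template`: a list with `params` and
#'   `values` (numeric vector of length `r_max`).
#' @export
generate_template <- function(params, config) {
  stopifnot(inherits(params, "ricm_template_params"),
            inherits(config, "ricm_optics"))
  if (params$p < config$r_max * config$u)
    stop("particle radius p = ", params$p,
         " um does not cover the template extent r_max * u = ",
         config$r_max * config$u, " um")
  r_um <- seq_len(config$r_max) * config$u
  base <- template_intensity(r_um, params, config)
  structure(
    list(params = params,
         values = apply_decay(base, params$dec, config$r_max)),
    class = "ricm_template"
  )
}

#' Parameter search grid
#'
#' Ordered value lists for the three template parameters, spanning the search
#' space of the matcher. Defaults are the standard acquisition search space:
#' heights -0.45 to 0 um in 0.01 um steps, radii 10 to 30 um in 1 um steps,
#' decay 0 to 10 in unit steps.
#'
#' @param d_values Strictly increasing heights, um.
#' @param p_values Strictly increasing particle radii, um.
#' @param dec_values Strictly increasing decay strengths.
#' @return An object of class `ricm_grid`.
#' @export
parameter_grid <- function(d_values = seq(-0.45, 0, by = 0.01),
                           p_values = seq(10, 30, by = 1),
                           dec_values = seq(0, 10, by = 1)) {
  chk <- function(v, nm) {
    if (length(v) == 0L || anyNA(v) || !is.numeric(v))
      stop("'", nm, "' must be a non-empty numeric vector")
    if (length(v) > 1L && any(diff(v) <= 0))
      stop("'", nm, "' must be strictly increasing")
    as.numeric(v)
  }
  structure(
    list(d_values = chk(d_values, "d_values"),
         p_values = chk(p_values, "p_values"),
         dec_values = chk(dec_values, "dec_values")),
    class = "ricm_grid"
  )
}

#' Pre-computed template bank
#'
#' Generates one template per grid point, in lexicographic order over
#' `(d, p, dec)` (d varies slowest). The bank stores the raw template values
#' as an `n x r_max` matrix together with a standardized copy used for fast
#' Pearson correlation, and the sign pattern of successive differences used
#' by the slope-synchronism refinement.
#'
#' @param grid A [parameter_grid()].
#' @param config An [optical_config()].
#' @return An object of class `ricm_bank` with elements `config`, `grid`,
#'   `params` (data frame with columns d, p, dec; row i generates template i)
#'   and `values` (matrix, one template per row).
#' @export
build_bank <- function(grid, config) {
  stopifnot(inherits(grid, "ricm_grid"), inherits(config, "ricm_optics"))
  bad <- grid$p_values < config$r_max * config$u
  if (any(bad))
    stop("grid point p = ", grid$p_values[which(bad)[1]],
         " um does not cover the template extent r_max * u = ",
         config$r_max * config$u, " um")
  if (any(abs(grid$d_values) > min(grid$p_values)))
    stop("grid contains |d| exceeding the smallest particle radius")

  r_um <- seq_len(config$r_max) * config$u
  k <- wavenumber(config)
  s2 <- sin(aperture_angle(config) / 2)^2

  # base profiles for all (d, p) pairs, p varying fastest within d
  dp <- expand.grid(p = grid$p_values, d = grid$d_values,
                    KEEP.OUT.ATTRS = FALSE)
  h <- outer(dp$d + dp$p, rep(1, length(r_um))) -
    sqrt(outer(dp$p^2, r_um^2, "-"))
  h[h < 0] <- 0
  y <- 2 * k * h * s2
  sinc <- ifelse(y == 0, 1, sin(y) / y)
  base <- sinc * cos(2 * k * h * (1 - s2) + config$theta)

  decay <- exp(-outer(grid$dec_values, (seq_len(config$r_max) / config$r_max)^2))
  n_dp <- nrow(dp)
  n_dec <- length(grid$dec_values)
  values <- base[rep(seq_len(n_dp), each = n_dec), , drop = FALSE] *
    decay[rep(seq_len(n_dec), n_dp), , drop = FALSE]

  params <- data.frame(
    d = rep(dp$d, each = n_dec),
    p = rep(dp$p, each = n_dec),
    dec = rep(grid$dec_values, n_dp)
  )

  ctr <- values - rowMeans(values)
  norms <- sqrt(rowSums(ctr^2))
  std <- ctr / ifelse(norms > 0, norms, 1)
  std[norms == 0, ] <- 0  # constant templates correlate with nothing

  diffs <- values[, -1L, drop = FALSE] - values[, -ncol(values), drop = FALSE]

  structure(
    list(config = config, grid = grid, params = params, values = values,
         values_std = std, diffs = diffs,
         values_range = apply(values, 1L, max) - apply(values, 1L, min)),
    class = "ricm_bank"
  )
}

#' @export
print.ricm_bank <- function(x, ...) {
  cat(sprintf("RICM template bank: %d templates x %d radii\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  d  : %d values in [%g, %g] um\n", length(x$grid$d_values),
              min(x$grid$d_values), max(x$grid$d_values)))
  cat(sprintf("  p  : %d values in [%g, %g] um\n", length(x$grid$p_values),
              min(x$grid$p_values), max(x$grid$p_values)))
  cat(sprintf("  dec: %d values in [%g, %g]\n", length(x$grid$dec_values),
              min(x$grid$dec_values), max(x$grid$dec_values)))
  invisible(x)
}

#' Retrieve one template from a bank
#'
#' @param bank A [build_bank()] result.
#' @param index Template index (row of the bank).
#' @return An `ricm_template` identical to regenerating from the stored
#'   parameters.
#' @export
bank_template <- function(bank, index) {
  stopifnot(inherits(bank, "ricm_bank"),
            index >= 1, index <= nrow(bank$values))
  pr <- bank$params[index, ]
  structure(
    list(params = template_params(pr$d, pr$p, pr$dec),
         values = as.numeric(bank$values[index, ])),
    class = "ricm_template"
  )
}

#' Index of the bank template generated by given parameters
#'
#' @param bank A [build_bank()] result.
#' @param d,p,dec Parameter values; must be grid points.
#' @return Integer index such that `bank_template(bank, i)` has these params.
#' @export
bank_index <- function(bank, d, p, dec) {
  stopifnot(inherits(bank, "ricm_bank"))
  id <- which(abs(bank$grid$d_values - d) < 1e-9)
  ip <- which(abs(bank$grid$p_values - p) < 1e-9)
  ic <- which(abs(bank$grid$dec_values - dec) < 1e-9)
  if (length(id) != 1L || length(ip) != 1L || length(ic) != 1L)
    stop("parameters are not grid points of this bank")
  n_p <- length(bank$grid$p_values)
  n_dec <- length(bank$grid$dec_values)
  as.integer(((id - 1L) * n_p + (ip - 1L)) * n_dec + ic)
}

#' Export a template bank as a plain-text matrix
#'
#' Writes one template per row with its generating parameters as leading
#' columns, for external inspection.
#'
#' @param bank A [build_bank()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_bank <- function(bank, path) {
  stopifnot(inherits(bank, "ricm_bank"))
  df <- cbind(bank$params,
              as.data.frame(bank$values,
                            col.names = paste0("r", seq_len(ncol(bank$values)))))
  names(df)[-(1:3)] <- paste0("r", seq_len(ncol(bank$values)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Contact radius of an indenting sphere
#'
#' Radius of the circle in which a sphere of radius `p`, indented to height
#' `d < 0`, intersects the coverslip plane: `r_c = sqrt(2 p |d| - d^2)`.
#' For `d >= 0` the sphere does not touch and the contact radius is 0.
#'
#' @param d Particle height, um (vectorized).
#' @param p Particle radius, um.
#' @return Contact radius in um.
#' @export
contact_radius <- function(d, p) {
  stopifnot(is.numeric(d), is.numeric(p), all(p > 0))
  if (any(abs(d) > p)) stop("invalid indentation: |d| exceeds 'p'")
  ifelse(d >= 0, 0, sqrt(2 * p * abs(d) - d^2))
}

#' Relative particle height
#'
#' The fringe pattern determines the particle height only up to an integer
#' number of half-wavelengths in the medium (corrected for the finite
#' aperture): `d_rel = offset + i * lambda / (2 n) * (1 - sin^2(alpha/2))`.
#' For adhering probes the branch `i = 0` is the physical one.
#'
#' @param offset Height of the best-matching template, um.
#' @param i Integer branch index.
#' @param config An [optical_config()].
#' @return Relative height in um.
#' @export
relative_height <- function(offset, i, config) {
  stopifnot(inherits(config, "ricm_optics"))
  s2 <- sin(aperture_angle(config) / 2)^2
  offset + i * config$lambda / (2 * config$n) * (1 - s2)
}

#' JKR adhesion energy from contact and particle radius
#'
#' Johnson-Kendall-Roberts contact mechanics for a purely adhesion-driven
#' (zero external load) contact:
#' \deqn{W_{adh} = \frac{r_c^3}{6 \pi p^2} \cdot \frac{4E}{3(1-v^2)}}
#' with `E` the Young's modulus and `v` the Poisson ratio of the probe.
#' Radii are supplied in micrometres and converted to metres internally, so
#' the result is in J/m^2.
#'
#' @param r_c Contact radius, um (vectorized).
#' @param p Particle radius, um.
#' @param E Young's modulus, Pa.
#' @param v Poisson ratio, in \[0, 1).
#' @return Adhesion energy in J/m^2.
#' @export
adhesion_energy <- function(r_c, p, E, v) {
  stopifnot(is.numeric(r_c), is.numeric(p), all(p > 0), all(r_c >= 0))
  if (!is.numeric(E) || any(E <= 0)) stop("Young's modulus 'E' must be positive")
  if (!is.numeric(v) || any(v < 0) || any(v >= 1))
    stop("invalid Poisson ratio 'v': need 0 <= v < 1")
  rc_m <- r_c * 1e-6
  p_m <- p * 1e-6
  rc_m^3 / (6 * pi * p_m^2) * (4 * E) / (3 * (1 - v^2))
}
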
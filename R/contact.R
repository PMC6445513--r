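#' Intensity-based contact radius by 1D region growing
#'
#' Reference measurement of the contact radius that does not use the
#' template fit: the contact zone appears as a flat dark core of the
#' azimuthally averaged profile, so the region is grown outward from the
#' center while the intensity stays within a threshold (a fraction of the
#' profile's overall amplitude) of the center intensity.
#'
#' The center reference intensity is the mean of the first `i0_window`
#' radial samples rather than the single innermost value, because azimuthal
#' averaging barely reduces noise at small radii (at radius 0 every ray
#' samples the same pixel).
#'
#' @param mean_profile Azimuthally averaged radial profile (pixel radii
#'   `1 ... r_max`).
#' @param threshold Stopping threshold as a fraction of the profile
#'   amplitude, in (0, 1).
#' @param u Pixel length, um/px.
#' @param i0_window Number of innermost samples averaged into the reference
#'   intensity.
#' @return List with `threshold`, `radius` (um, the last accepted pixel
#'   radius times `u`) and `grew_to_edge` (`TRUE` if the stopping criterion
#'   never triggered before `r_max`).
#' @export
region_grow_radius <- function(mean_profile, threshold, u, i0_window = 3L) {
  stopifnot(is.numeric(mean_profile), length(mean_profile) >= 2,
            threshold > 0, threshold < 1, u > 0)
  amp <- diff(range(mean_profile))
  if (amp == 0) stop("undefined amplitude: the profile is constant")
  i0 <- mean(mean_profile[seq_len(min(i0_window, length(mean_profile)))])
  stop_at <- which(mean_profile - i0 >= threshold * amp)
  if (length(stop_at) == 0L) {
    list(threshold = threshold,
         radius = length(mean_profile) * u, grew_to_edge = TRUE)
  } else {
    list(threshold = threshold,
         radius = (stop_at[1L] - 1L) * u, grew_to_edge = FALSE)
  }
}

#' Region growing over a sweep of thresholds
#'
#' Runs [region_grow_radius()] for each threshold; the default sweep is 40
#' uniformly spaced thresholds from 1 to 40 percent of the profile
#' amplitude. The grown radius is non-decreasing in the threshold.
#'
#' @param mean_profile Azimuthally averaged radial profile.
#' @param thresholds Vector of thresholds in (0, 1).
#' @param u Pixel length, um/px.
#' @param i0_window Passed to [region_grow_radius()].
#' @return Data frame with columns `threshold`, `radius_um`, `grew_to_edge`.
#' @export
threshold_sweep <- function(mean_profile,
                            thresholds = seq(0.01, 0.40, length.out = 40),
                            u = 0.067, i0_window = 3L) {
  res <- lapply(thresholds, function(th)
    region_grow_radius(mean_profile, th, u, i0_window))
  data.frame(
    threshold = vapply(res, `[[`, numeric(1), "threshold"),
    radius_um = vapply(res, `[[`, numeric(1), "radius"),
    grew_to_edge = vapply(res, `[[`, logical(1), "grew_to_edge")
  )
}

#' Regress the model-based contact radius on the intensity-based one
#'
#' Ordinary least squares fit of `c_model = a * c_intensity + b`, comparing
#' the contact radius derived from the best-matching template against the
#' region-growing reference. A slope near 1 with a small negative intercept
#' (the region growing stops late and overestimates) and a high adjusted
#' R-squared indicate agreement of the two measurements.
#'
#' @param pairs Data frame with columns `c_intensity` and `c_model` (um).
#' @return List with `slope`, `intercept` (um), `adjusted_r2`, `n`, and the
#'   underlying `stats::lm` fit.
#' @export
compare_model_vs_intensity <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("c_intensity", "c_model") %in% names(pairs)))
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  if (stats::var(pairs$c_intensity) == 0)
    stop("degenerate predictor: all intensity-based radii are equal")
  fit <- stats::lm(c_model ~ c_intensity, data = pairs)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       adjusted_r2 = s$adj.r.squared,
       n = nrow(pairs),
       fit = fit)
}
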
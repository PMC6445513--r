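#' Extraction configuration
#'
#' @param t1 Minimum first-pass correlation a detection must reach.
#' @param r_max Suppression radius in pixels: after each accepted detection,
#'   the correlation map is cleared within this radius before the next
#'   maximum is taken. Usually equal to the template radius.
#' @param max_iterations Upper bound on the number of extracted detections.
#' @return An object of class `ricm_extraction_config`.
#' @export
extraction_config <- function(t1 = 0.9, r_max = 100L, max_iterations = 100L) {
  stopifnot(t1 >= -1, t1 <= 1, r_max >= 1, max_iterations >= 1)
  structure(list(t1 = t1, r_max = as.integer(r_max),
                 max_iterations = as.integer(max_iterations)),
            class = "ricm_extraction_config")
}

#' Slope-synchronism score between a profile and a template
#'
#' Fraction of radial positions at which the measured profile and the
#' template rise or fall together. Successive differences are compared by
#' sign; a zero difference only matches a zero difference (a flat contact
#' zone is synchronous with a flat contact zone, not with a moving fringe).
#' The count is normalized by `r_max` although only `r_max - 1` differences
#' exist, so a perfect match scores `(r_max - 1) / r_max`, not 1.
#'
#' With `flat_tol > 0`, differences smaller in magnitude than
#' `flat_tol * (max - min)` of their own vector are treated as flat (sign
#' 0): a noisy measurement of a flat contact core then still registers as
#' flat instead of as random rises and falls.
#'
#' @param profile,template Numeric vectors of equal length `r_max`.
#' @param flat_tol Flatness tolerance as a fraction of each vector's
#'   amplitude; 0 compares raw difference signs.
#' @return Score in \[0, 1).
#' @export
slope_sync_score <- function(profile, template, flat_tol = 0) {
  if (length(profile) != length(template)) stop("length mismatch")
  sp <- .tol_sign(diff(profile), flat_tol * diff(range(profile)))
  st <- .tol_sign(diff(template), flat_tol * diff(range(template)))
  sum(sp == st) / length(profile)
}

.tol_sign <- function(d, tol) {
  s <- sign(d)
  if (any(tol > 0)) s[abs(d) <= tol] <- 0
  s
}

#' Refine the template fit by extrema synchronism
#'
#' Second matching pass at an accepted position: instead of Pearson
#' correlation (which weights by amplitude), the template maximizing the
#' slope-synchronism score is selected, because the positions of the fringe
#' extrema carry the particle-size information. Ties are broken by the
#' higher Pearson correlation, then by the lower bank index.
#'
#' Measured slopes are compared at the noise resolution of the averaged
#' profile: the spread of the m directional samples at each radius gives a
#' standard error for every mean-profile value, and a difference smaller
#' than `noise_k` of its propagated standard errors counts as flat. The
#' same floor, rescaled to template units by the amplitude ratio, flattens
#' the template, so "both flat within noise" registers as synchronous. A
#' noisy measurement of the flat dark contact core of an adhering particle
#' then still matches a flat-core template — the core width carries size
#' information, as intended — while fringes buried below the noise floor
#' stop injecting random sign flips. Noise-free profiles reduce to the
#' exact sign comparison.
#'
#' @param sampleset An [radial_sample()] result at the detection position.
#' @param bank A [build_bank()] result.
#' @param noise_k Flatness floor in units of the propagated standard error
#'   of a mean-profile difference.
#' @return A [template_params()] object, with the winning bank index in
#'   attribute `"index"` and its slope score in attribute `"slope_score"`.
#' @export
refine_template <- function(sampleset, bank, noise_k = 2) {
  stopifnot(inherits(sampleset, "ricm_samples"), inherits(bank, "ricm_bank"))
  pm <- sampleset$mean_profile
  S <- sampleset$samples
  n_in <- colSums(!is.na(S))
  se <- apply(S, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(n_in, 1L))
  se[!is.finite(se)] <- 0
  tol <- noise_k * sqrt(se[-length(se)]^2 + se[-1L]^2)  # per difference
  sp <- .tol_sign(diff(pm), tol)
  st <- sign(bank$diffs)
  if (any(tol > 0)) {
    # rescale the tolerance to each template's units via the amplitude ratio
    amp_pm <- diff(range(pm))
    scale <- ifelse(bank$values_range > 0,
                    bank$values_range / max(amp_pm, .Machine$double.eps), 1)
    st[abs(bank$diffs) <= outer(scale, tol)] <- 0
  }
  scores <- rowSums(st == rep(sp, each = nrow(st))) / length(pm)
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    corr <- .bank_correlation(bank, pm)[best]
    best <- best[corr == max(corr)]
    best <- best[1L]  # lowest index among remaining ties
  }
  pr <- bank$params[best, ]
  out <- template_params(pr$d, pr$p, pr$dec)
  attr(out, "index") <- as.integer(best)
  attr(out, "slope_score") <- scores[best]
  out
}

#' Attach derived physical measurements to a detection
#'
#' Fills in the contact radius (sphere-plane intersection), the particle
#' diameter, and -- when the elastic constants are supplied -- the JKR
#' adhesion energy. The reported height is the template offset, i.e. the
#' relative height on the `i = 0` branch; the absolute height is ambiguous
#' up to half-wavelength multiples, which is recorded in the
#' `height_ambiguity` field.
#'
#' @param detection A one-row data frame with at least `d` and `p` columns
#'   (um), as produced by [extract_detections()].
#' @param optical An [optical_config()].
#' @param E Young's modulus in Pa, or `NULL`.
#' @param v Poisson ratio, or `NULL`.
#' @return The detection with `contact_radius_um`, `particle_diameter_um`,
#'   `d_relative_um`, `height_ambiguity_um` and (if `E` and `v` are given)
#'   `adhesion_energy_J_m2` columns.
#' @export
derive_measurements <- function(detection, optical, E = NULL, v = NULL) {
  stopifnot(inherits(optical, "ricm_optics"))
  rc <- contact_radius(detection$d, detection$p)
  detection$contact_radius_um <- rc
  detection$particle_diameter_um <- 2 * detection$p
  detection$d_relative_um <- relative_height(detection$d, 0L, optical)
  # one fringe period: the spacing of the unresolvable height branches
  detection$height_ambiguity_um <-
    relative_height(0, 1L, optical)
  if (!is.null(E) && !is.null(v))
    detection$adhesion_energy_J_m2 <- adhesion_energy(rc, detection$p, E, v)
  detection
}

#' Extract ranked detections from a correlation map
#'
#' Repeatedly takes the global maximum of the correlation map; a maximum
#' below `t1` (or an exhausted map, or the iteration cap) stops the
#' extraction. Each accepted maximum is re-sampled, its template re-fit by
#' [refine_template()] (the refined parameters replace the first-pass ones
#' for all derived measurements), and a disc of radius `r_max` around it is
#' cleared before the next iteration, so no two detections lie within
#' `r_max` pixels of each other.
#'
#' @param map A [build_correlation_map()] result.
#' @param image The image the map was computed from.
#' @param bank The [build_bank()] used for the map.
#' @param config An [extraction_config()].
#' @param E,v Optional elastic constants for the adhesion energy.
#' @return Data frame of class `ricm_detections`, one row per detection in
#'   descending first-pass correlation order, with columns x, y (px),
#'   correlation, slope_score, d, p, dec, and the derived measurement
#'   columns of [derive_measurements()].
#' @export
extract_detections <- function(map, image, bank,
                               config = extraction_config(
                                 r_max = bank$config$r_max),
                               E = NULL, v = NULL) {
  stopifnot(inherits(map, "ricm_corr_map"), inherits(bank, "ricm_bank"),
            inherits(config, "ricm_extraction_config"))
  corr <- map$best_corr
  nr <- nrow(corr); nc <- ncol(corr)
  rows <- list()
  for (iter in seq_len(config$max_iterations)) {
    if (all(is.na(corr))) break
    best <- which.max(corr)
    val <- corr[best]
    if (val < config$t1) break
    y <- (best - 1L) %% nr + 1L
    x <- (best - 1L) %/% nr + 1L
    ss <- radial_sample(image, x, y, map$m, bank$config$r_max)
    prm <- refine_template(ss, bank)
    det <- data.frame(
      x = as.integer(x), y = as.integer(y),
      correlation = val,
      slope_score = attr(prm, "slope_score"),
      d = prm$d, p = prm$p, dec = prm$dec,
      first_pass_template = map$best_template[best],
      refined_template = attr(prm, "index")
    )
    rows[[length(rows) + 1L]] <- derive_measurements(det, bank$config, E, v)
    # suppress a disc of radius r_max around the accepted maximum
    xs <- max(1L, x - config$r_max):min(nc, x + config$r_max)
    ys <- max(1L, y - config$r_max):min(nr, y + config$r_max)
    d2 <- outer((ys - y)^2, (xs - x)^2, "+")
    sub <- corr[ys, xs]
    sub[d2 <= config$r_max^2] <- NA_real_
    corr[ys, xs] <- sub
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = integer(0), y = integer(0), correlation = numeric(0),
               slope_score = numeric(0), d = numeric(0), p = numeric(0),
               dec = numeric(0), first_pass_template = integer(0),
               refined_template = integer(0),
               contact_radius_um = numeric(0),
               particle_diameter_um = numeric(0),
               d_relative_um = numeric(0), height_ambiguity_um = numeric(0))
  if (length(rows)) out$rank <- seq_len(nrow(out)) else out$rank <- integer(0)
  class(out) <- c("ricm_detections", "data.frame")
  out
}
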
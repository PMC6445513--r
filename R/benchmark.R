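#' Closed-loop localization and size benchmark on synthetic scenes
#'
#' Renders `n` single-particle scenes with ground truth (parameters drawn
#' from the search grid, sub-pixel centers, mild Gaussian noise), runs the
#' full detection pipeline on each, and tabulates the top-ranked detection
#' against the truth. Also records, at each true center, the best Pearson
#' correlation achievable against the full template bank (the match-quality
#' ceiling of the search space).
#'
#' @param n Number of scenes.
#' @param seed Integer master seed; every scene seed derives from it.
#' @param config An [run_config()]; defaults are the standard acquisition
#'   parameters.
#' @param image_size Scene side length, px.
#' @param noise_sigma Gaussian noise level (fraction of dynamic range).
#' @param bank Optional pre-built [build_bank()] matching `config` (built
#'   once here otherwise).
#' @param verbose Print one progress line per scene.
#' @return Data frame with one row per scene: ground truth (`cx`, `cy`,
#'   `d`, `p`, `dec`), top detection (`det_x`, `det_y`, `det_d`, `det_p`,
#'   `det_dec`, `correlation`), the Pearson-only (first-pass) radius
#'   estimate `naive_p`, the center errors `center_err_px` (against the
#'   nearest integer pixel of the true center -- the detector's own grid)
#'   and `center_err_subpx_px` (against the real-valued center), and
#'   `center_best_corr` (best bank correlation at the true center).
#'   Undetected scenes carry `NA` detection fields.
#' @export
localization_benchmark <- function(n = 50L, seed = 1L,
                                   config = run_config(),
                                   image_size = 512L, noise_sigma = 0.02,
                                   bank = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "ricm_run_config"))
  if (is.null(bank)) bank <- build_bank(config$grid, config$optical)
  opt <- config$optical
  base <- (seed %% 100003L) * 20011L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- sample_scene_spec(base + i, 1L, image_size, image_size,
                              config$grid, opt, noise_sigma = noise_sigma)
    sc <- render_scene(spec, opt)
    det <- detect_particles(sc$image, bank, config)
    tr <- spec$particles
    # match-quality ceiling at the (rounded) true center
    ctr <- radial_sample(sc$image, round(tr$cx), round(tr$cy), config$m,
                         opt$r_max)
    cbc <- max(.bank_correlation(bank, ctr$mean_profile))
    row <- data.frame(scene = i, cx = tr$cx, cy = tr$cy, d = tr$d, p = tr$p,
                      dec = tr$dec, center_best_corr = cbc,
                      det_x = NA_integer_, det_y = NA_integer_,
                      det_d = NA_real_, det_p = NA_real_, det_dec = NA_real_,
                      correlation = NA_real_, naive_p = NA_real_,
                      center_err_px = NA_real_,
                      center_err_subpx_px = NA_real_)
    if (nrow(det) >= 1) {
      top <- det[1L, ]
      row$det_x <- top$x; row$det_y <- top$y
      row$det_d <- top$d; row$det_p <- top$p; row$det_dec <- top$dec
      row$correlation <- top$correlation
      row$naive_p <- bank$params$p[top$first_pass_template]
      row$center_err_px <- sqrt((top$x - round(tr$cx))^2 +
                                  (top$y - round(tr$cy))^2)
      row$center_err_subpx_px <- sqrt((top$x - tr$cx)^2 + (top$y - tr$cy)^2)
    }
    rows[[i]] <- row
    if (verbose)
      message(sprintf("scene %d/%d: err = %.2f px", i, n, row$center_err_px))
  }
  do.call(rbind, rows)
}

#' Contact-radius validation benchmark
#'
#' Renders `n` adhering particles (heights drawn from the negative grid
#' values), runs the detection pipeline, and for each top-ranked detection
#' compares the model-based contact radius (from the refined template) with
#' the intensity-based reference from 1D region growing on the measured
#' mean profile.
#'
#' The scenes are rendered decay-free: the intensity reference assumes a
#' flat dark contact core, and any decay tilts wide cores across the
#' stopping threshold (see the package vignette).
#'
#' @param n Number of scenes.
#' @param seed Integer master seed.
#' @param config An [run_config()].
#' @param image_size Scene side length, px.
#' @param noise_sigma Gaussian noise level.
#' @param scene_dec Decay value(s) used for rendering (the bank still
#'   searches the full grid).
#' @param threshold Region-growing stopping threshold (fraction of profile
#'   amplitude).
#' @param bank Optional pre-built bank.
#' @param verbose Print progress.
#' @return Data frame with truth (`d`, `p`, true contact radius `rc_true`),
#'   detection-derived `c_model`, and region-growing `c_intensity` (all um);
#'   undetected scenes carry `NA`.
#' @export
contact_benchmark <- function(n = 100L, seed = 1L, config = run_config(),
                              image_size = 256L, noise_sigma = 0.02,
                              scene_dec = 0, threshold = 0.30,
                              bank = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "ricm_run_config"))
  if (is.null(bank)) bank <- build_bank(config$grid, config$optical)
  opt <- config$optical
  scene_grid <- parameter_grid(d_values = config$grid$d_values,
                               p_values = config$grid$p_values,
                               dec_values = scene_dec)
  base <- (seed %% 100003L) * 20011L + 7L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- sample_scene_spec(base + i, 1L, image_size, image_size,
                              scene_grid, opt, adhering_only = TRUE,
                              noise_sigma = noise_sigma)
    sc <- render_scene(spec, opt)
    det <- detect_particles(sc$image, bank, config)
    tr <- spec$particles
    row <- data.frame(scene = i, d = tr$d, p = tr$p,
                      rc_true = contact_radius(tr$d, tr$p),
                      c_model = NA_real_, c_intensity = NA_real_)
    if (nrow(det) >= 1) {
      top <- det[1L, ]
      row$c_model <- top$contact_radius_um
      ss <- radial_sample(sc$image, top$x, top$y, config$m, opt$r_max)
      row$c_intensity <- region_grow_radius(ss$mean_profile, threshold,
                                            opt$u)$radius
    }
    rows[[i]] <- row
    if (verbose)
      message(sprintf("scene %d/%d: c_model = %.2f, c_intensity = %.2f um",
                      i, n, row$c_model, row$c_intensity))
  }
  do.call(rbind, rows)
}
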
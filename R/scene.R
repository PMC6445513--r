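#' Synthetic scene specification
#'
#' Describes a ground-truthed synthetic RICM image: image size, the particles
#' it contains (sub-pixel center positions plus the forward-model parameters
#' of each), and the camera/illumination nuisances. Model values in
#' \[-1, 1\] are mapped to intensities by `background + contrast * value`;
#' a radially symmetric multiplicative vignette and i.i.d. Gaussian noise are
#' applied on top, then the image is clipped to \[0, 1\].
#'
#' @param width,height Image size in pixels.
#' @param particles Data frame with columns `cx`, `cy` (center, px, may be
#'   fractional; x = column, y = row, 1-based), `d`, `p` (um) and `dec`.
#' @param background Mean intensity as a fraction of the dynamic range.
#' @param contrast Fringe amplitude as a fraction of the dynamic range;
#'   `background +/- contrast` must stay within \[0, 1\].
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param vignette_strength Strength of the quadratic vignette falloff
#'   (0 disables it; 0.1 darkens the image corners by 10 percent).
#' @param seed Integer seed making the rendered noise reproducible.
#' @return An object of class `ricm_scene_spec`.
#' @export
scene_spec <- function(width, height, particles,
                       background = 0.5, contrast = 0.25,
                       noise_sigma = 0, vignette_strength = 0,
                       seed = 1L) {
  stopifnot(width >= 1, height >= 1, is.data.frame(particles))
  need <- c("cx", "cy", "d", "p", "dec")
  if (nrow(particles) > 0 && !all(need %in% names(particles)))
    stop("'particles' must have columns ", paste(need, collapse = ", "))
  if (background - contrast < 0 || background + contrast > 1)
    stop("background +/- contrast must lie within [0, 1]")
  if (noise_sigma < 0) stop("'noise_sigma' must be non-negative")
  if (vignette_strength < 0) stop("'vignette_strength' must be non-negative")
  structure(
    list(width = as.integer(width), height = as.integer(height),
         particles = particles[, intersect(c(need), names(particles)), drop = FALSE],
         background = background, contrast = contrast,
         noise_sigma = noise_sigma, vignette_strength = vignette_strength,
         seed = as.integer(seed)),
    class = "ricm_scene_spec"
  )
}

#' Render a synthetic RICM scene
#'
#' Evaluates the fringe forward model around every particle center (out to
#' one pixel past `r_max`; farther pixels keep the background), maps model
#' values to
#' intensities, applies the vignette, adds Gaussian noise, and clips to
#' \[0, 1\]. Rendering is deterministic given the spec's seed; the caller's
#' RNG state is left untouched.
#'
#' @param spec A [scene_spec()].
#' @param config An [optical_config()]; its `u` and `r_max` set the physical
#'   scale and the rendered fringe extent.
#' @return An object of class `ricm_scene`: list with `image` (matrix,
#'   `height x width`, rows = y) and `spec`.
#' @export
render_scene <- function(spec, config) {
  stopifnot(inherits(spec, "ricm_scene_spec"), inherits(config, "ricm_optics"))
  w <- spec$width; h <- spec$height
  r_max <- config$r_max
  pts <- spec$particles
  if (nrow(pts) >= 2) {
    dd <- as.matrix(stats::dist(pts[, c("cx", "cy")]))
    if (any(dd[upper.tri(dd)] < r_max))
      warning("particles closer than r_max px overlap; rendered additively")
  }
  img <- matrix(0, nrow = h, ncol = w)
  for (ii in seq_len(nrow(pts))) {
    cx <- pts$cx[ii]; cy <- pts$cy[ii]
    prm <- template_params(pts$d[ii], pts$p[ii], pts$dec[ii])
    if (prm$p < r_max * config$u)
      stop("particle radius does not cover the fringe extent r_max * u")
    # render one pixel past r_max so bilinear sampling at radius r_max sees
    # a fully modeled neighborhood rather than a hard cut to background
    ext <- r_max + 1
    xs <- max(1L, floor(cx - ext)):min(w, ceiling(cx + ext))
    ys <- max(1L, floor(cy - ext)):min(h, ceiling(cy + ext))
    dx <- xs - cx
    dy <- ys - cy
    dist_px <- sqrt(outer(dy^2, dx^2, "+"))
    inside <- dist_px <= ext
    r_um <- dist_px[inside] * config$u
    vals <- template_intensity(r_um, prm, config) *
      exp(-prm$dec * (dist_px[inside] / r_max)^2)
    patch <- matrix(0, nrow = length(ys), ncol = length(xs))
    patch[inside] <- vals
    img[ys, xs] <- img[ys, xs] + patch
  }
  img <- spec$background + spec$contrast * img
  if (spec$vignette_strength > 0) {
    cxm <- (w + 1) / 2; cym <- (h + 1) / 2
    rho2 <- outer((seq_len(h) - cym)^2, (seq_len(w) - cxm)^2, "+")
    rho2max <- (1 - cym)^2 + (1 - cxm)^2
    img <- img * (1 - spec$vignette_strength * rho2 / rho2max)
  }
  if (spec$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(spec$seed)
    img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sigma), h, w)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  structure(list(image = img, spec = spec), class = "ricm_scene")
}

#' Draw a random scene specification
#'
#' Particle parameters are drawn uniformly from the grid values (so that a
#' matcher searching that grid can in principle recover them exactly);
#' centers are uniform over the image with a margin of `r_max` pixels so the
#' full fringe pattern lies in bounds.
#'
#' @param seed Integer seed; the draw is reproducible and the caller's RNG
#'   state is untouched.
#' @param n_particles Number of particles.
#' @param width,height Image size, px.
#' @param grid A [parameter_grid()] giving the value sets for d, p, dec.
#' @param config An [optical_config()] (for the `r_max` margin).
#' @param adhering_only If `TRUE`, heights are drawn from the negative grid
#'   values only (touching, indenting particles).
#' @param subpixel If `FALSE`, centers are rounded to integer pixels.
#' @param ... Passed to [scene_spec()] (background, contrast, noise_sigma,
#'   vignette_strength).
#' @return An `ricm_scene_spec` whose own seed is derived from `seed`.
#' @export
sample_scene_spec <- function(seed, n_particles, width, height,
                              grid = parameter_grid(),
                              config = optical_config(),
                              adhering_only = FALSE, subpixel = TRUE, ...) {
  stopifnot(inherits(grid, "ricm_grid"), inherits(config, "ricm_optics"))
  margin <- config$r_max
  if (width - 2 * margin < 1 || height - 2 * margin < 1)
    stop("image too small for a margin of r_max = ", margin, " px")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  d_pool <- grid$d_values
  if (adhering_only) {
    d_pool <- d_pool[d_pool < 0]
    if (length(d_pool) == 0L) stop("grid has no negative heights")
  }
  draw <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]
  n <- n_particles
  cx <- stats::runif(n, 1 + margin, width - margin)
  cy <- stats::runif(n, 1 + margin, height - margin)
  if (!subpixel) { cx <- round(cx); cy <- round(cy) }
  particles <- data.frame(
    cx = cx, cy = cy,
    d = if (n) draw(d_pool, n) else numeric(0),
    p = if (n) draw(grid$p_values, n) else numeric(0),
    dec = if (n) draw(grid$dec_values, n) else numeric(0)
  )
  scene_spec(width, height, particles,
             seed = sample.int(.Machine$integer.max, 1L), ...)
}

#' Write a set of rendered fixtures with their ground truth
#'
#' Renders each spec, writes one grayscale TIFF per scene, and a manifest
#' (CSV for the per-particle ground truth, JSON mirroring the full specs)
#' that round-trips losslessly through [read_fixture_manifest()].
#'
#' @param directory Output directory (created if missing).
#' @param specs List of [scene_spec()] objects.
#' @param config An [optical_config()].
#' @param bits TIFF bit depth, 8 or 16.
#' @return Invisibly, the manifest data frame (columns file, particle, cx,
#'   cy, d, p, dec).
#' @export
write_fixture_set <- function(directory, specs, config, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  rows <- list()
  spec_js <- list()
  for (i in seq_along(specs)) {
    sc <- render_scene(specs[[i]], config)
    file <- sprintf("scene_%03d.tif", i)
    path <- file.path(directory, file)
    ok <- try(tiff::writeTIFF(sc$image, path, bits.per.sample = bits),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("failed to write TIFF '", path, "': ", attr(ok, "condition")$message)
    pt <- specs[[i]]$particles
    if (nrow(pt))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(file = file, particle = seq_len(nrow(pt))), pt)
    spec_js[[file]] <- unclass(specs[[i]])
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(file = character(0), particle = integer(0), cx = numeric(0),
               cy = numeric(0), d = numeric(0), p = numeric(0),
               dec = numeric(0))
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(spec_js, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a fixture manifest
#'
#' @param directory Directory written by [write_fixture_set()].
#' @return List with `truth` (the per-particle CSV as a data frame) and
#'   `specs` (named list of `ricm_scene_spec`, keyed by file name).
#' @export
read_fixture_manifest <- function(directory) {
  truth <- utils::read.csv(file.path(directory, "manifest.csv"))
  js <- jsonlite::read_json(file.path(directory, "manifest.json"),
                            simplifyVector = TRUE)
  specs <- lapply(js, function(s) {
    part <- as.data.frame(s$particles)
    scene_spec(s$width, s$height, part, background = s$background,
               contrast = s$contrast, noise_sigma = s$noise_sigma,
               vignette_strength = s$vignette_strength, seed = s$seed)
  })
  list(truth = truth, specs = specs)
}
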
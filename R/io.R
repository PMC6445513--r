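#' Load a grayscale image normalized to \[0, 1\]
#'
#' Reads an 8- or 16-bit grayscale TIFF (or PNG, used for fixtures) and
#' scales it by the bit-depth maximum, so intensities are comparable across
#' a batch regardless of per-image exposure. Multi-page TIFFs are returned
#' as a list of frames.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A numeric matrix in \[0, 1\] (rows = y), or a list of such
#'   matrices for a multi-page TIFF.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, all = TRUE)
  } else if (ext == "png") {
    list(png::readPNG(path))
  } else {
    stop("unsupported image format '", ext, "' for ", path)
  }
  frames <- lapply(img, function(fr) {
    if (length(dim(fr)) == 3L) {
      if (dim(fr)[3] == 1L) fr <- fr[, , 1L]
      else stop("RGB/multichannel input not supported; convert '", path,
                "' to grayscale first")
    }
    fr
  })
  if (length(frames) == 1L) frames[[1L]] else frames
}

#' Run configuration
#'
#' All tunable parameters of a batch run, with the standard acquisition
#' defaults: `m = 90` radial rays, `c = 1` percent of pixels kept by the
#' pre-selection, amplitude gate `a = 0.05`, symmetry gate `t2 = 0.5`,
#' correlation threshold `t1 = 0.9`.
#'
#' @param optical An [optical_config()].
#' @param grid A [parameter_grid()].
#' @param m Number of radial sampling rays.
#' @param c Percentage of pixels kept by the pre-selection.
#' @param a,t2 Match constraints, see [match_constraints()].
#' @param t1,max_iterations Extraction settings, see [extraction_config()].
#' @param magnitude_floor Gradient floor of the pre-selection.
#' @param E,v Optional elastic constants (Pa, dimensionless) enabling the
#'   adhesion-energy output.
#' @param seed Integer seed (used only by fixture simulation; the detection
#'   pipeline itself is deterministic).
#' @return An object of class `ricm_run_config`.
#' @export
run_config <- function(optical = optical_config(), grid = parameter_grid(),
                       m = 90L, c = 1, a = 0.05, t2 = 0.5, t1 = 0.9,
                       max_iterations = 100L, magnitude_floor = 0.05,
                       E = NULL, v = NULL, seed = 1L) {
  stopifnot(inherits(optical, "ricm_optics"), inherits(grid, "ricm_grid"))
  structure(
    list(optical = optical, grid = grid, m = as.integer(m), c = c,
         constraints = match_constraints(a, t2),
         extraction = extraction_config(t1, optical$r_max, max_iterations),
         magnitude_floor = magnitude_floor, E = E, v = v,
         seed = as.integer(seed)),
    class = "ricm_run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors the parameter table of an acquisition: scalar keys `u`,
#' `lambda`, `INA`, `r_max`, `n`, `theta`, `m`, `c`, `a`, `t1`, `t2`, and
#' range keys `dec_range`, `d_range`, `p_range` as `[min, step, max]`
#' triplets. Missing keys fall back to the defaults of [run_config()].
#' `theta` may be given as the string `"pi"`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `ricm_run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: ", path)
  gv <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  theta <- gv("theta", pi)
  if (identical(theta, "pi")) theta <- pi
  rng <- function(key, default) {
    tr <- raw[[key]]
    if (is.null(tr)) return(default)
    if (length(tr) != 3) stop("'", key, "' must be a [min, step, max] triplet")
    seq(tr[1], tr[3], by = tr[2])
  }
  def <- parameter_grid()
  optical <- optical_config(u = gv("u", 0.067), lambda = gv("lambda", 0.53),
                            INA = gv("INA", 0.67), n = gv("n", 1.332),
                            theta = theta, r_max = gv("r_max", 100L))
  grid <- parameter_grid(d_values = rng("d_range", def$d_values),
                         p_values = rng("p_range", def$p_values),
                         dec_values = rng("dec_range", def$dec_values))
  run_config(optical = optical, grid = grid,
             m = gv("m", 90L), c = gv("c", 1), a = gv("a", 0.05),
             t2 = gv("t2", 0.5), t1 = gv("t1", 0.9),
             max_iterations = gv("max_iterations", 100L),
             magnitude_floor = gv("magnitude_floor", 0.05),
             E = raw[["E"]], v = raw[["v"]], seed = gv("seed", 1L))
}

#' Write a run configuration to YAML
#'
#' Inverse of [read_run_config()]: ranges are written back as
#' `[min, step, max]` triplets.
#'
#' @param config An `ricm_run_config`.
#' @param path Output path (`.yaml`).
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "ricm_run_config"))
  tr <- function(v) if (length(v) == 1L) c(v, 1, v) else
    c(v[1], v[2] - v[1], v[length(v)])
  out <- list(
    u = config$optical$u, lambda = config$optical$lambda,
    INA = config$optical$INA, n = config$optical$n,
    theta = config$optical$theta, r_max = config$optical$r_max,
    dec_range = tr(config$grid$dec_values),
    d_range = tr(config$grid$d_values),
    p_range = tr(config$grid$p_values),
    m = config$m, c = config$c, a = config$constraints$a,
    t1 = config$extraction$t1, t2 = config$constraints$t2,
    max_iterations = config$extraction$max_iterations,
    magnitude_floor = config$magnitude_floor, seed = config$seed
  )
  if (!is.null(config$E)) out$E <- config$E
  if (!is.null(config$v)) out$v <- config$v
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Detect particles in a single image
#'
#' The full pipeline on one frame: gradient pre-selection, template
#' matching at the surviving candidates, iterative extraction with
#' slope-synchronism refinement, and derived measurements.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param bank A [build_bank()] result (build it once per batch).
#' @param config An [run_config()]; its grid must be the bank's.
#' @param debug If `TRUE`, the intermediate line image and correlation map
#'   are attached as attributes `"line_image"` and `"correlation_map"`.
#' @return An `ricm_detections` data frame (see [extract_detections()]),
#'   with the candidate count in attribute `"n_candidates"` and the number
#'   of fully evaluated positions in `"n_evaluated"`.
#' @export
detect_particles <- function(image, bank, config = run_config(),
                             debug = FALSE) {
  stopifnot(is.matrix(image), inherits(bank, "ricm_bank"),
            inherits(config, "ricm_run_config"))
  cand <- preselect(image, bank$config$r_max, config$c,
                    config$magnitude_floor)
  cmap <- build_correlation_map(image, cand, bank, config$constraints,
                                m = config$m)
  det <- extract_detections(cmap, image, bank, config$extraction,
                            E = config$E, v = config$v)
  attr(det, "n_candidates") <- nrow(cand$positions)
  attr(det, "n_evaluated") <- cmap$n_evaluated
  if (debug) {
    attr(det, "line_image") <- attr(cand, "line_image")
    attr(det, "correlation_map") <- cmap
  }
  det
}

#' Batch processing of an image series
#'
#' Builds the template bank once, then runs [detect_particles()] on every
#' input image (frames of multi-page TIFFs are processed individually).
#' Detections are concatenated into one results table; per-image candidate
#' and detection counts are logged. Failures of individual images are
#' caught, logged, and skipped.
#'
#' @param input Character vector of file paths, or a glob pattern.
#' @param config An [run_config()].
#' @param output_dir Optional directory; when given, `detections.csv` is
#'   written there.
#' @param save_line_image,save_correlation_map Write the per-frame debug
#'   rasters into `output_dir`: the gradient-vote line image (scaled by its
#'   maximum, 16-bit) and the correlation map (32-bit float, stored as
#'   `(corr + 2) / 3` so unevaluated positions -- sentinel -2 -- map to 0).
#' @param verbose Print per-image progress lines.
#' @return Data frame of all detections with leading `image` and `frame`
#'   columns; attribute `"failed"` lists files that could not be processed.
#' @export
run_batch <- function(input, config = run_config(), output_dir = NULL,
                      save_line_image = FALSE, save_correlation_map = FALSE,
                      verbose = TRUE) {
  stopifnot(inherits(config, "ricm_run_config"))
  files <- if (length(input) == 1L && !file.exists(input))
    Sys.glob(input) else input
  if (length(files) == 0L) stop("no input images match: ", input)
  bank <- build_bank(config$grid, config$optical)
  all_rows <- list()
  failed <- character(0)
  for (f in files) {
    res <- try({
      frames <- load_image(f)
      if (!is.list(frames)) frames <- list(frames)
      for (fi in seq_along(frames)) {
        t0 <- proc.time()[["elapsed"]]
        want_debug <- (save_line_image || save_correlation_map) &&
          !is.null(output_dir)
        det <- detect_particles(frames[[fi]], bank, config,
                                debug = want_debug)
        if (want_debug) {
          if (!dir.exists(output_dir))
            dir.create(output_dir, recursive = TRUE)
          stem <- sprintf("%s_f%d", tools::file_path_sans_ext(basename(f)),
                          fi)
          if (save_line_image) {
            li <- attr(det, "line_image")$accumulator
            tiff::writeTIFF(li / max(max(li), 1),
                            file.path(output_dir,
                                      paste0(stem, "_line_image.tif")),
                            bits.per.sample = 16L)
          }
          if (save_correlation_map) {
            cm <- attr(det, "correlation_map")$best_corr
            cm[is.na(cm)] <- -2  # sentinel for unevaluated positions
            tiff::writeTIFF((cm + 2) / 3,
                            file.path(output_dir,
                                      paste0(stem, "_correlation_map.tif")),
                            bits.per.sample = 32L)
          }
        }
        if (verbose)
          message(sprintf(
            "%s frame %d: %d candidates, %d evaluated, %d detections (%.1f s)",
            basename(f), fi, attr(det, "n_candidates"),
            attr(det, "n_evaluated"), nrow(det),
            proc.time()[["elapsed"]] - t0))
        if (nrow(det)) {
          det <- cbind(data.frame(image = basename(f), frame = fi), det)
          all_rows[[length(all_rows) + 1L]] <- as.data.frame(det)
        }
      }
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      failed <- c(failed, f)
      message("FAILED ", f, ": ", attr(res, "condition")$message)
    }
  }
  out <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame(image = character(0), frame = integer(0))
  rownames(out) <- NULL
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    utils::write.csv(out, file.path(output_dir, "detections.csv"),
                     row.names = FALSE)
  }
  attr(out, "failed") <- failed
  out
}
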
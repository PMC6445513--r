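#' Match constraints
#'
#' Gates that a sampled radial profile must pass before template correlation
#' is attempted: a minimum amplitude `a` (fraction of the observed image
#' intensity range; Pearson correlation is amplitude-blind, so flat noise
#' would otherwise match), and a minimum mean circular correlation `t2`
#' between the directional profiles and their average (a radial-symmetry
#' gate rejecting asymmetric structures).
#'
#' @param a Minimum amplitude as a fraction of the image range, in \[0, 1\].
#' @param t2 Minimum mean circular correlation, in \[-1, 1\].
#' @return An object of class `ricm_constraints`.
#' @export
match_constraints <- function(a = 0.05, t2 = 0.5) {
  stopifnot(a >= 0, a <= 1, t2 >= -1, t2 <= 1)
  structure(list(a = a, t2 = t2), class = "ricm_constraints")
}

# Precomputed unit direction offsets for m rays: i = 0 ... m-1, direction
# (sin(2*pi*i/m), cos(2*pi*i/m)); i = 0 points along +y.
.ray_offsets <- function(m, r_max) {
  ang <- 2 * pi * (seq_len(m) - 1L) / m
  r <- seq_len(r_max)
  list(ox = outer(sin(ang), r), oy = outer(cos(ang), r))  # m x r_max
}

# Bilinear interpolation of image at (x, y) (vectors); returns list with
# values (0 where out of bounds) and in-bounds flags.
.bilinear <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  inb <- x >= 1 & x <= nc & y >= 1 & y <= nr
  xc <- pmin(pmax(x, 1), nc)
  yc <- pmin(pmax(y, 1), nr)
  x1 <- pmin(floor(xc), nc - 1); x2 <- x1 + 1
  y1 <- pmin(floor(yc), nr - 1); y2 <- y1 + 1
  fx <- xc - x1; fy <- yc - y1
  i11 <- (x1 - 1) * nr + y1
  v <- (1 - fx) * (1 - fy) * image[i11] +
       fx * (1 - fy) * image[i11 + nr] +
       (1 - fx) * fy * image[i11 + 1] +
       fx * fy * image[i11 + nr + 1]
  v[!inb] <- 0
  list(values = v, inbounds = inb)
}

#' Radially sample an image around a center
#'
#' Samples the image along `m` equally spaced rays at integer pixel radii
#' `1 ... r_max` from center `(x, y)`; ray `i` (0-based) points along
#' `(sin(2*pi*i/m), cos(2*pi*i/m))`, i.e. ray 0 along +y. Non-integer sample
#' coordinates are bilinearly interpolated; out-of-bounds points are flagged
#' and excluded from the azimuthal mean.
#'
#' @param image Numeric matrix (rows = y).
#' @param x,y Center position, px (column, row; may be fractional).
#' @param m Number of rays.
#' @param r_max Maximum sampled radius, px.
#' @return An object of class `ricm_samples`: list with `samples` (m x r_max
#'   matrix, `NA` out of bounds), `mean_profile` (length `r_max`),
#'   `amplitude` (max - min of the mean profile), `coverage` (fraction of
#'   in-bounds sample points) and `rejected` (`TRUE` when coverage < 0.5 or
#'   some radius has no in-bounds sample).
#' @export
radial_sample <- function(image, x, y, m, r_max) {
  stopifnot(is.matrix(image), m >= 1, r_max >= 1)
  if (x < 1 || x > ncol(image) || y < 1 || y > nrow(image))
    stop("center (x, y) must lie inside the image")
  off <- .ray_offsets(m, r_max)
  bi <- .bilinear(image, x + off$ox, y + off$oy)
  vals <- matrix(bi$values, m, r_max)
  inb <- matrix(bi$inbounds, m, r_max)
  vals[!inb] <- NA_real_
  cnt <- colSums(inb)
  mean_profile <- ifelse(cnt > 0, colSums(vals * inb, na.rm = TRUE) / cnt,
                         NA_real_)
  coverage <- mean(inb)
  structure(
    list(samples = vals, mean_profile = mean_profile,
         amplitude = if (all(is.na(mean_profile))) 0 else
           diff(range(mean_profile, na.rm = TRUE)),
         coverage = coverage,
         rejected = coverage < 0.5 || any(cnt == 0)),
    class = "ricm_samples"
  )
}

#' Pearson correlation with a zero-variance convention
#'
#' Standard Pearson correlation coefficient, except that a constant vector
#' correlates 0 with anything ("no similarity"), which prevents flat image
#' regions from matching flat-contact templates spuriously.
#'
#' @param u,v Numeric vectors of equal length (at least 2); `NA`s are
#'   dropped pairwise.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  ok <- !is.na(u) & !is.na(v)
  u <- u[ok]; v <- v[ok]
  if (length(u) < 2L) return(0)
  du <- u - mean(u); dv <- v - mean(v)
  su <- sqrt(sum(du^2)); sv <- sqrt(sum(dv^2))
  if (su == 0 || sv == 0) return(0)
  sum(du * dv) / (su * sv)
}

#' Circular-symmetry score of a sample set
#'
#' Mean Pearson correlation of the individual directional profiles with the
#' azimuthally averaged profile. Radially symmetric patterns score near 1;
#' off-center or asymmetric structures score low.
#'
#' @param sampleset An [radial_sample()] result.
#' @return Mean correlation in \[-1, 1\].
#' @export
circular_symmetry <- function(sampleset) {
  stopifnot(inherits(sampleset, "ricm_samples"))
  pm <- sampleset$mean_profile
  mean(apply(sampleset$samples, 1L, pearson, v = pm))
}

#' Match one sampled profile against a template bank
#'
#' Applies the amplitude and circular-symmetry gates, then returns the bank
#' template with the highest Pearson correlation to the mean profile; ties
#' go to the lowest index.
#'
#' @param sampleset An [radial_sample()] result.
#' @param bank A [build_bank()] result.
#' @param constraints A [match_constraints()].
#' @param image_range Observed intensity range (max - min) of the image.
#' @return List with `index`, `correlation`, and `accepted`; when a gate
#'   fails, `accepted` is `FALSE` and `reason` names the failed gate.
#' @export
match_position <- function(sampleset, bank, constraints, image_range) {
  stopifnot(inherits(sampleset, "ricm_samples"), inherits(bank, "ricm_bank"),
            inherits(constraints, "ricm_constraints"))
  if (sampleset$rejected)
    return(list(accepted = FALSE, reason = "coverage"))
  if (sampleset$amplitude < constraints$a * image_range)
    return(list(accepted = FALSE, reason = "amplitude"))
  if (circular_symmetry(sampleset) < constraints$t2)
    return(list(accepted = FALSE, reason = "symmetry"))
  corr <- .bank_correlation(bank, sampleset$mean_profile)
  best <- which.max(corr)  # which.max takes the first (lowest) index on ties
  list(accepted = TRUE, index = as.integer(best),
       correlation = corr[best])
}

# Mean Pearson correlation of the rows of S (m x r_max, complete) with the
# profile pm; rows or profiles of zero variance contribute 0. Matrix form of
# the scalar pearson() loop.
.symmetry_fast <- function(S, pm) {
  z <- pm - mean(pm)
  sz <- sqrt(sum(z^2))
  if (sz == 0) return(0)
  Sc <- S - rowMeans(S)
  den <- sqrt(rowSums(Sc^2)) * sz
  num <- as.numeric(Sc %*% z)
  mean(ifelse(den > 0, num / den, 0))
}

# Pearson correlation of one profile against every bank row (vector n_t).
.bank_correlation <- function(bank, profile) {
  z <- profile - mean(profile)
  nz <- sqrt(sum(z^2))
  if (nz == 0) return(rep(0, nrow(bank$values_std)))
  as.numeric(bank$values_std %*% (z / nz))
}

#' Evaluate the template match at every candidate position
#'
#' For each candidate pixel: radially sample the image, apply the gates, and
#' correlate the mean profile against the whole bank. Results are stored in
#' image-shaped maps with `NA` at unevaluated (non-candidate or rejected)
#' positions. Per-position results are independent, so the map is a pure
#' function of its inputs.
#'
#' Internally the work is vectorized over blocks of candidates; results are
#' identical to calling [match_position()] pixel by pixel.
#'
#' @param image Numeric matrix.
#' @param candidates An `ricm_candidates` object (or a data frame of x, y).
#' @param bank A [build_bank()] result.
#' @param constraints A [match_constraints()].
#' @param m Number of radial sampling rays.
#' @param block Number of candidates processed per vectorized block.
#' @return An object of class `ricm_corr_map`: list with matrices
#'   `best_corr`, `best_template` (bank indices), the `m`, and counters
#'   `n_candidates`, `n_evaluated`.
#' @export
build_correlation_map <- function(image, candidates, bank,
                                  constraints = match_constraints(),
                                  m = 90L, block = 256L) {
  stopifnot(is.matrix(image), inherits(bank, "ricm_bank"),
            inherits(constraints, "ricm_constraints"))
  pos <- if (inherits(candidates, "ricm_candidates")) candidates$positions
         else as.data.frame(candidates)
  nr <- nrow(image); nc <- ncol(image)
  r_max <- bank$config$r_max
  best_corr <- matrix(NA_real_, nr, nc)
  best_template <- matrix(NA_integer_, nr, nc)
  n_eval <- 0L
  npos <- nrow(pos)
  if (npos > 0) {
    img_range <- diff(range(image))
    off <- .ray_offsets(m, r_max)
    ox <- as.numeric(off$ox); oy <- as.numeric(off$oy)  # length K = m * r_max
    K <- m * r_max
    for (start in seq(1L, npos, by = block)) {
      idx <- start:min(start + block - 1L, npos)
      xs <- pos$x[idx]; ys <- pos$y[idx]
      C <- length(idx)
      bi <- sample_block(image, as.integer(xs), as.integer(ys), ox, oy)
      vals <- array(bi$values, dim = c(m, r_max, C))
      inb <- array(bi$inbounds, dim = c(m, r_max, C))
      cnt <- colSums(inb)                       # r_max x C
      pm <- colSums(vals * inb) / ifelse(cnt > 0, cnt, NA_real_)
      coverage <- colMeans(inb, dims = 2L)      # length C
      amp <- apply(pm, 2L, function(v)
        if (all(is.na(v))) 0 else diff(range(v, na.rm = TRUE)))
      pass <- coverage >= 0.5 & !apply(cnt == 0, 2L, any) &
        amp >= constraints$a * img_range
      # circular-symmetry gate for amplitude survivors
      for (j in which(pass)) {
        sym <- if (all(inb[, , j])) {
          .symmetry_fast(vals[, , j], pm[, j])
        } else {
          S <- vals[, , j]
          S[!inb[, , j]] <- NA_real_
          mean(apply(S, 1L, pearson, v = pm[, j]))
        }
        if (is.na(sym) || sym < constraints$t2) pass[j] <- FALSE
      }
      surv <- which(pass)
      if (length(surv)) {
        Z <- pm[, surv, drop = FALSE]
        Z <- Z - rep(colMeans(Z), each = r_max)
        nz <- sqrt(colSums(Z^2))
        keep_nz <- nz > 0
        corr <- matrix(0, nrow = length(surv), ncol = nrow(bank$values_std))
        if (any(keep_nz)) {
          Zs <- Z[, keep_nz, drop = FALSE] /
            rep(nz[keep_nz], each = r_max)
          corr[keep_nz, ] <- t(Zs) %*% t(bank$values_std)
        }
        bt <- max.col(corr, ties.method = "first")
        bc <- corr[cbind(seq_along(surv), bt)]
        ii <- (xs[surv] - 1L) * nr + ys[surv]
        best_corr[ii] <- bc
        best_template[ii] <- bt
        n_eval <- n_eval + length(surv)
      }
    }
  }
  structure(
    list(best_corr = best_corr, best_template = best_template, m = m,
         n_candidates = npos, n_evaluated = n_eval),
    class = "ricm_corr_map"
  )
}
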
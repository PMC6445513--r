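#' Sobel image gradient
#'
#' Horizontal and vertical derivatives with the standard 3x3 Sobel kernels.
#' Image borders are handled by edge replication. `gx` responds to intensity
#' changes along x (columns), `gy` along y (rows).
#'
#' @param image Numeric matrix (rows = y, columns = x), at least 3x3.
#' @return An object of class `ricm_gradient`: list with matrices `gx`, `gy`.
#' @export
sobel_gradient <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a 2D numeric matrix")
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) stop("image must be at least 3x3")
  # replicate-pad by one pixel
  P <- matrix(0, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- image
  P[1, ] <- P[2, ]; P[nr + 2, ] <- P[nr + 1, ]
  P[, 1] <- P[, 2]; P[, nc + 2] <- P[, nc + 1]
  sh <- function(dy, dx) P[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  structure(list(gx = gx, gy = gy), class = "ricm_gradient")
}

#' Gradient-voting line image
#'
#' For every pixel whose gradient magnitude exceeds a floor (a fraction of
#' the maximum magnitude), a straight line is rasterized through the pixel
#' along the gradient orientation, extending `r_max` pixels in both
#' directions, and each covered pixel of an accumulator is incremented by 1.
#' Because the fringe-edge gradients of a circular pattern point radially,
#' the lines of all rings intersect at the pattern center, which therefore
#' accumulates a far higher count than any surrounding pixel.
#'
#' Lines are drawn in both directions because successive fringe edges
#' alternate between inward- and outward-pointing gradients; votes are
#' unweighted so bright outer rings do not dominate.
#'
#' @param field An [sobel_gradient()] result.
#' @param r_max Line half-length in pixels (the expected profile radius).
#' @param magnitude_floor Fraction of the maximum gradient magnitude below
#'   which a pixel casts no votes.
#' @return An object of class `ricm_line_image`: list with `accumulator`
#'   (non-negative matrix, same shape as the image).
#' @export
draw_line_image <- function(field, r_max, magnitude_floor = 0.05) {
  stopifnot(inherits(field, "ricm_gradient"), r_max >= 1)
  gx <- field$gx; gy <- field$gy
  nr <- nrow(gx); nc <- ncol(gx)
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  acc <- matrix(0, nr, nc)
  if (mmax == 0)
    return(structure(list(accumulator = acc), class = "ricm_line_image"))
  keep <- which(mag > magnitude_floor * mmax)
  if (length(keep) == 0L)
    return(structure(list(accumulator = acc), class = "ricm_line_image"))
  ux <- gx[keep] / mag[keep]
  uy <- gy[keep] / mag[keep]
  # step so that the major axis advances one pixel per step: every step of
  # the rasterization lands on a distinct pixel (Bresenham-like DDA)
  s <- pmax(abs(ux), abs(uy))
  ys <- (keep - 1L) %% nr + 1L
  xs <- (keep - 1L) %/% nr + 1L
  acc <- line_accumulate(xs, ys, ux / s, uy / s, as.integer(r_max), nr, nc)
  structure(list(accumulator = acc), class = "ricm_line_image")
}

#' Select candidate centers from a line image
#'
#' Keeps the brightest `c` percent of accumulator pixels (zero-valued pixels
#' never qualify). The threshold is the value of the `ceil(c% * area)`-th
#' brightest pixel; ties at the threshold are all included, so the candidate
#' count can slightly exceed the nominal budget.
#'
#' @param line_image A [draw_line_image()] result.
#' @param c Percentage of image pixels to keep, in (0, 100\].
#' @return An object of class `ricm_candidates`: list with `positions`
#'   (data frame of integer columns x, y), `c`, and `threshold`.
#' @export
select_candidates <- function(line_image, c = 1) {
  stopifnot(inherits(line_image, "ricm_line_image"), c > 0, c <= 100)
  acc <- line_image$accumulator
  nr <- nrow(acc); nc <- ncol(acc)
  v <- as.vector(acc)
  k <- ceiling(c / 100 * length(v))
  kth <- length(v) - k + 1L
  thr <- sort(v, partial = kth)[kth]
  sel <- which(v >= thr & v > 0)
  positions <- data.frame(
    x = as.integer((sel - 1L) %/% nr + 1L),
    y = as.integer((sel - 1L) %% nr + 1L)
  )
  structure(list(positions = positions, c = c, threshold = thr),
            class = "ricm_candidates")
}

#' Full gradient pre-selection
#'
#' Convenience wrapper: Sobel gradient, line image, brightest-`c`-percent
#' selection.
#'
#' @param image Numeric matrix.
#' @param r_max Expected profile radius, px.
#' @param c Percentage of pixels to keep.
#' @param magnitude_floor Gradient magnitude floor (fraction of maximum).
#' @return An `ricm_candidates` object; the line image is attached as
#'   attribute `"line_image"`.
#' @export
preselect <- function(image, r_max, c = 1, magnitude_floor = 0.05) {
  li <- draw_line_image(sobel_gradient(image), r_max, magnitude_floor)
  out <- select_candidates(li, c)
  attr(out, "line_image") <- li
  out
}
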
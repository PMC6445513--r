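# Shared small-scale fixtures: a reduced optical configuration and grid keep
# most tests fast; full-scale (r_max = 100) objects are built only where a
# test needs them.

small_optics <- function(r_max = 40L) optical_config(r_max = r_max)

small_grid <- function() {
  parameter_grid(d_values = seq(-0.4, 0, by = 0.1),
                 p_values = c(10, 15, 20, 25, 30),
                 dec_values = c(0, 2, 5))
}

# one-particle scene spec with explicit parameters
one_particle_spec <- function(cx, cy, d, p, dec, width = 160L, height = 160L,
                              noise_sigma = 0, seed = 1L, ...) {
  scene_spec(width, height,
             data.frame(cx = cx, cy = cy, d = d, p = p, dec = dec),
             noise_sigma = noise_sigma, seed = seed, ...)
}

# scalar, loop-based reference evaluation of the fringe model: an oracle
# independent of the package's vectorized template path
oracle_profile <- function(d, p, dec, config) {
  alpha <- asin(config$INA / config$n)
  k <- 2 * pi * config$n / config$lambda
  s2 <- sin(alpha / 2)^2
  vapply(seq_len(config$r_max), function(j) {
    r <- j * config$u
    h <- max(0, d + p - sqrt(p^2 - r^2))
    y <- 2 * k * h * s2
    sinc <- if (y == 0) 1 else sin(y) / y
    sinc * cos(2 * k * h * (1 - s2) + config$theta) *
      exp(-dec * (j / config$r_max)^2)
  }, numeric(1))
}

# scalar bilinear interpolation, independent of the package samplers
oracle_bilinear <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  if (x < 1 || x > nc || y < 1 || y > nr) return(NA_real_)
  x1 <- min(floor(x), nc - 1); y1 <- min(floor(y), nr - 1)
  fx <- x - x1; fy <- y - y1
  (1 - fx) * (1 - fy) * image[y1, x1] +
    fx * (1 - fy) * image[y1, x1 + 1] +
    (1 - fx) * fy * image[y1 + 1, x1] +
    fx * fy * image[y1 + 1, x1 + 1]
}
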
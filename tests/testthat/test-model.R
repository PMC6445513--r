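test_that("aperture angle and wavenumber follow the optical definitions", {
  opt <- optical_config()
  expect_equal(aperture_angle(opt), asin(0.67 / 1.332), tolerance = 1e-12)
  expect_equal(aperture_angle(opt), 0.52707, tolerance = 1e-5)
  expect_true(sin(aperture_angle(opt)) * opt$n - 0.67 < 1e-12)
  expect_equal(wavenumber(opt), 2 * pi * 1.332 / 0.53, tolerance = 1e-12)
  expect_equal(wavenumber(opt), 15.791, tolerance = 1e-4)
  expect_equal(wavenumber(optical_config(lambda = 2 * pi, n = 1, INA = 0.5)), 1)
  # halving comes from inverse proportionality in lambda
  expect_equal(wavenumber(optical_config(lambda = 1.06)),
               wavenumber(opt) / 2)
  # vanishing aperture
  expect_lt(aperture_angle(optical_config(INA = 1e-9)), 1e-8)
  expect_error(optical_config(INA = 1.4, n = 1.332), "invalid optics")
})

test_that("height profile is a clamped sphere cap", {
  expect_equal(height_profile(0, 0, 10), 0)
  expect_equal(height_profile(0, 0.1, 10), 0.1)
  expect_equal(height_profile(0, -0.2, 10), 0)  # clamp active in contact
  r <- seq(0, 5, by = 0.01)
  h <- height_profile(r, -0.2, 10)
  expect_true(all(h >= 0))
  expect_true(all(diff(h) >= 0))  # non-decreasing in r
  # zero exactly up to the contact circle, positive beyond
  rc <- contact_radius(-0.2, 10)
  expect_true(all(h[r <= rc] == 0))
  expect_true(all(h[r > rc + 0.01] > 0))
  expect_error(height_profile(11, 0, 10), "exceeds the sphere radius")
})

test_that("contact radius equals the root of the height profile", {
  expect_equal(contact_radius(0, 10), 0)
  expect_equal(contact_radius(0.3, 25), 0)
  expect_equal(contact_radius(-0.2, 10), sqrt(2 * 10 * 0.2 - 0.04))
  expect_equal(contact_radius(-0.2, 10), 1.98997, tolerance = 1e-5)
  expect_equal(contact_radius(-0.45, 30), 5.1768, tolerance = 1e-4)
  # independent root-finder oracle on the height function
  for (cs in list(c(-0.2, 10), c(-0.45, 30), c(-0.01, 15), c(-0.44, 10))) {
    root <- uniroot(function(r) height_profile(r, cs[1], cs[2]) - 1e-15,
                    c(1e-9, cs[2] * 0.99), tol = 1e-12)$root
    expect_equal(contact_radius(cs[1], cs[2]), root, tolerance = 1e-9)
  }
  expect_error(contact_radius(-11, 10), "invalid indentation")
})

test_that("template intensity matches a scalar composition of the model", {
  opt <- optical_config()
  prm <- template_params(0, 10, 0)
  # h = 0: pure cos(theta)
  expect_equal(template_intensity(0, prm, opt), cos(pi))
  opt0 <- optical_config(theta = 0)
  expect_equal(template_intensity(0, prm, opt0), 1)
  # independent scalar oracle at several radii and parameter sets
  for (ps in list(c(0, 10, 0), c(-0.3, 20, 0), c(0.05, 12, 0))) {
    p2 <- template_params(ps[1], ps[2], ps[3])
    for (r in c(0.5, 1, 3, 6)) {
      alpha <- asin(opt$INA / opt$n); k <- 2 * pi * opt$n / opt$lambda
      h <- max(0, ps[1] + ps[2] - sqrt(ps[2]^2 - r^2))
      y <- 2 * k * h * sin(alpha / 2)^2
      want <- (if (y == 0) 1 else sin(y) / y) *
        cos(2 * k * h * (1 - sin(alpha / 2)^2) + opt$theta)
      expect_equal(template_intensity(r, p2, opt), want, tolerance = 1e-14)
    }
  }
  # envelope bound
  r <- seq(0, 6.7, by = 0.01)
  vals <- template_intensity(r, template_params(-0.3, 15), opt)
  expect_true(all(abs(vals) <= 1))
})

test_that("decay attenuates outer radii and is the identity at dec = 0", {
  v <- rnorm(100)
  expect_equal(apply_decay(v, 0, 100), v)
  out <- apply_decay(rep(1, 100), 10, 100)
  expect_equal(out[100], exp(-10))
  expect_true(all(diff(out) < 0))  # strictly decreasing factor
  expect_true(all(abs(apply_decay(v, 3, 100)) <= abs(v)))
  expect_error(apply_decay(v, -1, 100), "non-negative")
})

test_that("generated templates have a flat dark contact core", {
  opt <- optical_config()
  tpl <- generate_template(template_params(-0.45, 10, 0), opt)
  expect_length(tpl$values, 100)
  expect_true(all(abs(tpl$values) <= 1))
  rc_px <- contact_radius(-0.45, 10) / opt$u
  core <- tpl$values[seq_len(floor(rc_px))]
  expect_true(all(core == cos(opt$theta)))  # theta = pi: exactly -1
  # first deviation at the next pixel radius
  expect_false(tpl$values[ceiling(rc_px) + 1] == cos(opt$theta))
  # with decay, the core follows the decay curve exactly
  tpl2 <- generate_template(template_params(-0.45, 10, 4), opt)
  j <- seq_len(floor(rc_px))
  expect_equal(tpl2$values[j], -exp(-4 * (j / 100)^2), tolerance = 1e-12)
  expect_error(generate_template(template_params(-0.1, 5, 0), opt),
               "does not cover")
})

test_that("templates reduce to pure cosine fringes as the aperture vanishes", {
  opt <- optical_config(INA = 1e-6)
  tpl <- generate_template(template_params(0.1, 10, 0), opt)
  r <- seq_len(100) * opt$u
  h <- height_profile(r, 0.1, 10)
  pure <- cos(2 * wavenumber(opt) * h + pi)
  expect_equal(tpl$values, pure, tolerance = 1e-9)
})

test_that("fringe spacing of a touching sphere is chirped (rings densify outward)", {
  # the cap height grows ~ r^2 / 2p, so the local fringe frequency grows ~ r
  # and successive extrema move closer together at larger radii
  opt <- optical_config(r_max = 200L)
  tpl <- generate_template(template_params(0, 15, 0), opt)
  extrema <- which(diff(sign(diff(tpl$values))) != 0) + 1
  spacing <- diff(extrema)
  expect_gt(length(spacing), 5)
  expect_lt(spacing[length(spacing)], spacing[1])
  expect_true(all(diff(spacing) <= 1))  # monotone up to pixel quantization
})

test_that("template bank enumerates the grid lexicographically", {
  opt <- optical_config()
  bank <- build_bank(parameter_grid(), opt)
  expect_equal(nrow(bank$values), 46 * 21 * 11)  # full standard grid
  expect_equal(nrow(bank$values), 10626)
  # bijective, stable index <-> params round trip
  for (i in c(1L, 12L, 500L, 10626L)) {
    pr <- bank$params[i, ]
    expect_equal(bank_index(bank, pr$d, pr$p, pr$dec), i)
  }
  # lexicographic over (d, p, dec): dec fastest, d slowest
  expect_equal(bank$params$dec[1:11], seq(0, 10))
  expect_equal(bank$params$p[c(1, 12)], c(10, 11))
  expect_equal(bank$params$d[c(1, 11 * 21 + 1)], c(-0.45, -0.44))
  # rows equal the scalar generator (independent oracle path)
  sg <- small_grid()
  bank2 <- build_bank(sg, opt)
  expect_equal(nrow(bank2$values), 5 * 5 * 3)
  i <- bank_index(bank2, -0.3, 20, 5)
  expect_equal(as.numeric(bank2$values[i, ]),
               oracle_profile(-0.3, 20, 5, opt), tolerance = 1e-12)
  # singleton grid
  b1 <- build_bank(parameter_grid(0, 10, 0), opt)
  expect_equal(nrow(b1$values), 1)
  expect_error(build_bank(parameter_grid(0, c(5, 10), 0), opt),
               "does not cover")
})

test_that("bank export round-trips through CSV", {
  opt <- small_optics(20L)
  bank <- build_bank(parameter_grid(0, c(10, 20), c(0, 1)), opt)
  path <- withr::local_tempfile(fileext = ".csv")
  export_bank(bank, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 4)
  expect_equal(as.numeric(df[1, -(1:3)]), as.numeric(bank$values[1, ]),
               tolerance = 1e-12)
  expect_equal(df$d, bank$params$d)
})

test_that("relative height is linear in the branch index", {
  opt <- optical_config()
  expect_equal(relative_height(-0.2, 0, opt), -0.2)
  per <- relative_height(0, 1, opt)
  expect_equal(per, (0.53 / 2.664) * (1 - sin(asin(0.67 / 1.332) / 2)^2),
               tolerance = 1e-12)
  expect_equal(per, 0.1854487, tolerance = 1e-6)
  d <- relative_height(-0.1, -3:3, opt)
  expect_equal(diff(d), rep(per, 6), tolerance = 1e-12)
})

test_that("JKR adhesion energy has the right value and scaling", {
  expect_equal(adhesion_energy(0, 10, 4e4, 0.5), 0)
  # E = 40 kPa hydrogel probe, 2 um contact on a 10 um sphere
  w <- adhesion_energy(2, 10, 4e4, 0.5)
  # independent evaluation of the algebraically simplified form
  expect_equal(w, 2 * 4e4 * (2e-6)^3 / (9 * pi * (1 - 0.25) * (10e-6)^2),
               tolerance = 1e-12)
  expect_equal(w, 3.02e-4, tolerance = 1e-2)
  expect_equal(adhesion_energy(4, 10, 4e4, 0.5), 8 * w, tolerance = 1e-12)
  expect_error(adhesion_energy(2, 10, 4e4, 1.2), "Poisson")
  expect_error(adhesion_energy(2, 10, -1, 0.5), "positive")
})
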
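test_that("pearson matches the standard definition with a zero-variance convention", {
  u <- c(0.3, 1.2, -0.5, 2.2, 0.9, -1.4)
  v <- c(1.0, 0.8, -0.2, 1.9, 1.1, -0.6)
  expect_equal(pearson(u, v), cor(u, v), tolerance = 1e-12)
  expect_equal(pearson(u, u), 1)
  expect_equal(pearson(u, -u), -1)
  expect_equal(pearson(u, 3 * u + 2), 1, tolerance = 1e-12)
  expect_equal(pearson(u, rep(1, 6)), 0)  # constant -> "no similarity"
  expect_equal(pearson(rep(2, 6), rep(1, 6)), 0)
  expect_error(pearson(u, v[-1]), "length mismatch")
})

test_that("radial sampling follows the ray convention and handles borders", {
  img <- matrix(0.5, 40, 40)
  ss <- radial_sample(img, 20, 20, m = 8, r_max = 10)
  expect_equal(ss$samples, matrix(0.5, 8, 10), tolerance = 1e-12)
  expect_equal(ss$amplitude, 0)
  expect_equal(ss$coverage, 1)
  expect_false(ss$rejected)
  # ray i (0-based) points along (sin, cos) of 2*pi*i/m: +y, +x, -y, -x
  img2 <- matrix(0, 41, 41)
  img2[21 + 3, 21] <- 1  # +y at radius 3
  img2[21, 21 + 5] <- 2  # +x at radius 5
  img2[21 - 7, 21] <- 3  # -y at radius 7
  img2[21, 21 - 9] <- 4  # -x at radius 9
  ss2 <- radial_sample(img2, 21, 21, m = 4, r_max = 10)
  expect_equal(ss2$samples[1, 3], 1)
  expect_equal(ss2$samples[2, 5], 2)
  expect_equal(ss2$samples[3, 7], 3)
  expect_equal(ss2$samples[4, 9], 4)
  # off-grid sampling agrees with a scalar bilinear oracle
  img3 <- matrix(runif(900), 30, 30)
  ss3 <- radial_sample(img3, 14, 17, m = 5, r_max = 6)
  ang <- 2 * pi * (0:4) / 5
  for (i in 1:5) for (r in c(2, 5)) {
    expect_equal(ss3$samples[i, r],
                 oracle_bilinear(img3, 14 + r * sin(ang[i]),
                                 17 + r * cos(ang[i])),
                 tolerance = 1e-12)
  }
  # border center: out-of-bounds points are excluded, coverage drops
  ss4 <- radial_sample(img3, 2, 15, m = 12, r_max = 10)
  expect_true(any(is.na(ss4$samples)))
  expect_lt(ss4$coverage, 1)
  expect_false(ss4$rejected)  # still more than half in bounds
  corner <- radial_sample(img3, 1, 2, m = 12, r_max = 10)
  expect_true(corner$rejected)  # most of the disc is outside
  expect_error(radial_sample(img3, 200, 15, 4, 5), "inside the image")
})

test_that("circular symmetry separates centered from off-center patterns", {
  opt <- small_optics()
  sc <- render_scene(one_particle_spec(80, 80, -0.2, 15, 2), opt)
  at_center <- radial_sample(sc$image, 80, 80, m = 90, r_max = opt$r_max)
  expect_gte(circular_symmetry(at_center), 0.999)
  # at the operating scale, an offset of r_max / 2 breaks the symmetry gate
  optf <- optical_config()
  scf <- render_scene(one_particle_spec(200, 200, -0.2, 15, 2,
                                        width = 400L, height = 400L), optf)
  offc <- radial_sample(scf$image, 200 + optf$r_max / 2, 200, m = 90,
                        r_max = optf$r_max)
  expect_lt(circular_symmetry(offc), 0.5)
  # all-constant samples score 0 by the zero-variance convention
  flat <- radial_sample(matrix(1, 50, 50), 25, 25, m = 8, r_max = 5)
  expect_equal(circular_symmetry(flat), 0)
})

test_that("match_position gates on amplitude and symmetry, then maximizes", {
  opt <- small_optics()
  bank <- build_bank(small_grid(), opt)
  constraints <- match_constraints(a = 0.05, t2 = 0.5)
  sc <- render_scene(one_particle_spec(80, 80, -0.2, 15, 2), opt)
  rng <- diff(range(sc$image))
  # flat background position: amplitude rejection
  far <- radial_sample(sc$image, 150, 20, m = 90, r_max = opt$r_max)
  res <- match_position(far, bank, constraints, rng)
  expect_false(res$accepted)
  expect_equal(res$reason, "amplitude")
  # true center: the generating template wins
  ctr <- radial_sample(sc$image, 80, 80, m = 90, r_max = opt$r_max)
  res <- match_position(ctr, bank, constraints, rng)
  expect_true(res$accepted)
  expect_equal(res$index, bank_index(bank, -0.2, 15, 2))
  expect_gt(res$correlation, 0.999)
  # half-ring artifact: symmetric gate rejects
  half <- sc$image
  half[1:80, ] <- 0.5  # wipe the upper half of the pattern
  hs <- radial_sample(half, 80, 80, m = 90, r_max = opt$r_max)
  res <- match_position(hs, bank, constraints, diff(range(half)))
  expect_false(res$accepted)
  expect_equal(res$reason, "symmetry")
})

test_that("correlation map equals a naive per-position, per-template loop", {
  # independent scalar oracle on a small fixture, including tie-breaking
  opt <- optical_config(r_max = 12L)
  grid <- parameter_grid(d_values = c(-0.3, -0.1, 0),
                         p_values = c(10, 20),
                         dec_values = c(0, 5))
  bank <- build_bank(grid, opt)
  spec <- one_particle_spec(31.5, 33.5, -0.1, 20, 0, width = 64L,
                            height = 64L, noise_sigma = 0.03, seed = 5)
  img <- render_scene(spec, opt)$image
  # candidates everywhere on a coarse lattice, including border positions
  pos <- expand.grid(x = seq(2L, 63L, by = 5L), y = seq(2L, 63L, by = 5L))
  cand <- structure(list(positions = pos, c = 100), class = "ricm_candidates")
  constraints <- match_constraints(a = 0.05, t2 = 0.3)
  m <- 16L
  cmap <- build_correlation_map(img, cand, bank, constraints, m = m)

  img_range <- diff(range(img))
  ang <- 2 * pi * (seq_len(m) - 1) / m
  for (k in seq_len(nrow(pos))) {
    x <- pos$x[k]; y <- pos$y[k]
    # scalar sampling loop
    S <- matrix(NA_real_, m, opt$r_max)
    for (i in seq_len(m)) for (r in seq_len(opt$r_max))
      S[i, r] <- oracle_bilinear(img, x + r * sin(ang[i]), y + r * cos(ang[i]))
    inb <- !is.na(S)
    pm <- colMeans(S, na.rm = TRUE)
    want_na <- TRUE
    if (mean(inb) >= 0.5 && !any(colSums(inb) == 0)) {
      amp <- diff(range(pm))
      if (amp >= constraints$a * img_range) {
        sym <- mean(apply(S, 1, pearson, v = pm))
        if (!is.na(sym) && sym >= constraints$t2) {
          best_i <- NA_integer_; best_c <- -Inf
          for (ti in seq_len(nrow(bank$values))) {
            cc <- pearson(pm, as.numeric(bank$values[ti, ]))
            if (cc > best_c) { best_c <- cc; best_i <- ti }
          }
          expect_false(is.na(cmap$best_corr[y, x]))
          expect_equal(cmap$best_corr[y, x], best_c, tolerance = 1e-10)
          expect_identical(cmap$best_template[y, x], best_i)
          want_na <- FALSE
        }
      }
    }
    if (want_na) expect_true(is.na(cmap$best_corr[y, x]))
  }
  expect_equal(cmap$n_evaluated, sum(!is.na(cmap$best_corr)))
})

test_that("map maxima land on particle centers", {
  opt <- small_optics()
  bank <- build_bank(small_grid(), opt)
  # two particles well apart
  # contact cores must fit inside the reduced fringe extent r_max * u
  pts <- data.frame(cx = c(70, 230), cy = c(80, 150),
                    d = c(-0.1, 0), p = c(15, 25), dec = c(2, 0))
  spec <- scene_spec(300, 230, pts, noise_sigma = 0.01, seed = 3)
  img <- render_scene(spec, opt)$image
  cand <- preselect(img, opt$r_max, c = 1)
  cmap <- build_correlation_map(img, cand, bank, match_constraints(), m = 90)
  # empty candidate set -> all-sentinel map
  empty <- build_correlation_map(img, data.frame(x = integer(0),
                                                 y = integer(0)),
                                 bank, match_constraints(), m = 90)
  expect_true(all(is.na(empty$best_corr)))
  # the two strongest local maxima sit near the two centers
  det <- extract_detections(cmap, img, bank,
                            extraction_config(t1 = 0.9, r_max = opt$r_max))
  expect_equal(nrow(det), 2)
  d1 <- min(sqrt((det$x - 70)^2 + (det$y - 80)^2))
  d2 <- min(sqrt((det$x - 230)^2 + (det$y - 150)^2))
  expect_lt(d1, 2); expect_lt(d2, 2)
})

test_that("no low-amplitude position is ever evaluated", {
  opt <- small_optics()
  bank <- build_bank(small_grid(), opt)
  spec <- one_particle_spec(80, 80, -0.2, 15, 2, noise_sigma = 0.02, seed = 2)
  img <- render_scene(spec, opt)$image
  cand <- preselect(img, opt$r_max, c = 2)
  constraints <- match_constraints(a = 0.05, t2 = -1)  # isolate the amp gate
  cmap <- build_correlation_map(img, cand, bank, constraints, m = 24)
  rng <- diff(range(img))
  ev <- which(!is.na(cmap$best_corr), arr.ind = TRUE)
  for (k in seq_len(min(nrow(ev), 40))) {
    ss <- radial_sample(img, ev[k, 2], ev[k, 1], m = 24, r_max = opt$r_max)
    expect_gte(ss$amplitude, 0.05 * rng)
  }
})
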
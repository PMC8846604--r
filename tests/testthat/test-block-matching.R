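test_that("windowed-sinc up-sampling preserves nodes and reconstructs band-limited signals", {
  m <- matrix(rnorm(200), 50, 4)
  expect_identical(upsample_rf(m, 1, 1), m)
  expect_error(upsample_rf(m, 1.5, 1), "integer")
  # pure sinusoid below Nyquist, axial factor 2
  z <- 0:199
  f <- matrix(sin(2 * pi * 0.08 * z), 200, 4)
  u <- upsample_rf(f, 2, 1)
  zi <- seq(0, 199.5, by = 0.5)
  expect_lt(max(abs(u[30:370, 2] - sin(2 * pi * 0.08 * zi[30:370]))), 1e-3)
  expect_equal(u[seq(1, 399, 2), ], f, tolerance = 0)  # original nodes kept
  # impulse: lateral profile equals the windowed-sinc kernel
  imp <- matrix(0, 5, 41); imp[3, 21] <- 1
  ui <- upsample_rf(imp, 1, 2)
  h <- function(x, taps = 8)
    ifelse(abs(x) >= taps, 0,
           ifelse(x == 0, 1, sin(pi * x) / (pi * x) * 0.5 * (1 + cos(pi * x / taps))))
  ks <- seq(-6.5, 6.5, by = 0.5)
  expect_equal(ui[3, 41 + 2 * ks], h(ks), tolerance = 1e-12)
})

test_that("pyramid decimation has the right shapes and preserves DC", {
  cfg3 <- bm_config()
  m <- matrix(rnorm(300 * 100), 300, 100)
  pyr <- build_pyramid(m, cfg3)
  expect_equal(dim(pyr[[1]]), c(100, 50))
  expect_equal(dim(pyr[[2]]), c(150, 100))
  expect_identical(pyr[[3]], m)  # factors (1,1) level equals input
  dc <- matrix(3.7, 120, 40)
  for (lev in build_pyramid(dc, cfg3))
    expect_equal(as.vector(lev), rep(3.7, length(lev)), tolerance = 1e-12)
})

test_that("compute_smi matches pure translations and stays within [-1, 1]", {
  set.seed(11)
  pre <- matrix(rnorm(90 * 30), 90, 30)
  s0 <- compute_smi(pre, pre, c(45, 15), kernel = c(31, 11), search = c(5, 3))
  expect_equal(s0$values[6, 4], 1, tolerance = 1e-12)  # lag (0,0)
  expect_true(all(s0$values >= -1 - 1e-12 & s0$values <= 1 + 1e-12))
  post <- rbind(matrix(0, 3, 30), pre[1:87, ])
  s3 <- compute_smi(pre, post, c(45, 15), kernel = c(31, 11), search = c(5, 3))
  expect_equal(unname(which(s3$values == max(s3$values), arr.ind = TRUE)[1, ]),
               c(3 + 5 + 1, 0 + 3 + 1))
  expect_equal(max(s3$values), 1, tolerance = 1e-12)
  # zero-variance kernel flagged with zero correlation
  flatpre <- matrix(1, 90, 30)
  sf <- compute_smi(flatpre, pre, c(45, 15), kernel = c(31, 11), search = c(2, 2))
  expect_true(sf$flag)
  expect_true(all(sf$values == 0))
})

test_that("compute_smi equals the two-loop NCC definition on random instances", {
  set.seed(21)
  for (rep in 1:8) {
    pre <- matrix(rnorm(70 * 40), 70, 40)
    post <- matrix(rnorm(70 * 40), 70, 40)
    s <- compute_smi(pre, post, c(35, 20), kernel = c(31, 15), search = c(10, 5))
    expect_lt(max(abs(s$values -
                      brute_ncc(pre, post, c(35, 20), c(31, 15), c(10, 5)))),
              1e-12)
  }
})

test_that("sub-sample peak refinement recovers analytic peaks and documented tie-breaks", {
  # grid-aligned delta comes back at its node (within refinement resolution)
  s <- matrix(0, 11, 7); s[8, 5] <- 1
  expect_equal(as.vector(subsample_peak(s)), c(2, 1), tolerance = 1e-9)
  # raised cosine peaked off-grid recovered within 0.02 lags
  pk <- c(1.37, -0.52)
  rc <- outer(-10:10, -5:5, function(i, j)
    (0.5 * (1 + cos(pi * pmin(abs(i - pk[1]), 4) / 4))) *
    (0.5 * (1 + cos(pi * pmin(abs(j - pk[2]), 4) / 4))))
  expect_lt(max(abs(unname(subsample_peak(rc)) - pk)), 0.02)
  # two-way tie with unequal magnitudes: the smaller displacement wins
  tie <- matrix(0, 13, 7); tie[7 + 3, 4] <- 1; tie[7 - 5, 4] <- 1
  r <- subsample_peak(tie)
  expect_equal(unname(r)[1], 3, tolerance = 0.1)
  # symmetric tie (equal magnitude): the smaller signed axial lag is kept
  tie2 <- matrix(0, 13, 7); tie2[7 + 4, 4] <- 1; tie2[7 - 4, 4] <- 1
  r2 <- subsample_peak(tie2)
  expect_equal(unname(r2)[1], -4, tolerance = 0.1)
  # flat surface: degenerate flag, zero displacement
  fl <- subsample_peak(matrix(0.3, 9, 9))
  expect_equal(as.vector(fl), c(0, 0))
  expect_equal(attr(fl, "flag"), 1L)
})

test_that("companding removes the motion it is given", {
  set.seed(31)
  m <- matrix(rnorm(120 * 40), 120, 40)
  geom <- list(fs = 40, pitch = 0.2, f0 = 8, c = 1540)
  mk_field <- function(ax, lat)
    ustrain:::displacement_field(ax, lat, seq(10, 110, by = 20),
                                 seq(5, 35, by = 10),
                                 matrix(FALSE, 6, 4), c(0, 1), geom)
  # zero field: unchanged
  f0 <- mk_field(matrix(0, 6, 4), matrix(0, 6, 4))
  expect_identical(compand_rf(m, f0), m)
  # uniform integer shift: inverse shift applied exactly in the interior
  post <- rbind(m[4:120, ], matrix(0, 3, 40))  # post(r) = m(r + 3)... shifted up
  f3 <- mk_field(matrix(3, 6, 4), matrix(0, 6, 4))
  w <- compand_rf(m, f3)
  expect_equal(w[1:117, ], m[4:120, ], tolerance = 1e-12)
  # 1 % axial strain pair companded by the true linear field: residual NCC
  # peak returns to lag (0,0) at interior blocks
  cfg <- imaging_config(lines = 24, depth = 4)
  dzmm <- cfg$c / (2 * cfg$fs * 1000)
  fld <- generate_scatterers(c(-2, 6, -2, 6.8), 30, 4)
  mo <- motion_model("uniform_strain", rate = c(0.01, 0), center = c(0, 0))
  pre <- simulate_rf_frame(fld, cfg)$samples
  post2 <- simulate_rf_frame(deform_scatterers(fld, mo, 1), cfg)$samples
  centers <- seq(20, nrow(pre) - 20, by = 40)
  ccols <- seq(3, 21, by = 6)
  fl <- ustrain:::displacement_field(
    matrix(rep(0.01 * centers, length(ccols)), ncol = length(ccols)),
    matrix(0, length(centers), length(ccols)),
    centers, ccols, matrix(FALSE, length(centers), length(ccols)),
    c(0, 1), geom)
  aligned <- compand_rf(post2, fl)
  for (ctr in list(c(120, 12), c(240, 12), c(320, 16))) {
    s <- compute_smi(pre, aligned, ctr, kernel = c(41, 11), search = c(4, 2))
    pk <- which(s$values == max(s$values), arr.ind = TRUE)[1, ]
    expect_equal(unname(pk), c(5, 3))  # residual motion < 1 lag
  }
})

test_that("multilevel NCC recovers a noiseless rigid shift exactly at interior blocks", {
  fr <- shifted_speckle_frames(4, 1, seed = 1)
  f <- estimate_displacement_multilevel(list(fr$pre, fr$post), bm_config(), "none")
  ok <- interior_blocks(f)
  expect_gt(sum(ok), 500)
  expect_lt(max(abs(f$ax[ok] - 4)), 1e-6)
  expect_lt(max(abs(f$lat[ok] - 1)), 1e-6)
})

test_that("displacement estimation is shift-equivariant", {
  fr <- shifted_speckle_frames(2, 0, seed = 6)
  f1 <- estimate_displacement_multilevel(list(fr$pre, fr$post), bm_config(), "none")
  shift_frame <- function(f, k) { f$samples <- rbind(f$samples[-seq_len(k), ],
                                                     f$samples[1:k, ]); f }
  f2 <- estimate_displacement_multilevel(list(shift_frame(fr$pre, 6),
                                              shift_frame(fr$post, 6)),
                                         bm_config(), "none")
  ok <- interior_blocks(f1, margin_rows = 5) & interior_blocks(f2, margin_rows = 5)
  expect_lt(max(abs(f1$ax[ok] - f2$ax[ok])), 1e-6)
  expect_lt(max(abs(f1$lat[ok] - f2$lat[ok])), 1e-6)
})

test_that("zero-motion noisy pairs stay near zero displacement", {
  cfg <- imaging_config(lines = 32, depth = 4)
  sc <- phantom_scene(imaging = cfg,
                      motion = motion_model("rigid_shift", shift = c(0, 0)),
                      n_frames = 4, wall = c(1.5, 2.5),
                      snr_bands = list(list(snr_db = 40)))
  seq <- generate_sequence(sc, 9)
  # finest-level windows widened so the sub-sample interpolant has full
  # support; the axial jitter bound then reflects estimator noise alone.
  # Lateral localization is resolution-limited (wide correlation peak).
  bm <- bm_config(search_ax = c(10, 5, 6), search_lat = c(5, 3, 3))
  f <- track_sequence(seq$frames[1:2], bm, "none")[[1]]
  ok <- interior_blocks(f)
  expect_lt(median(abs(f$ax[ok])), 0.05)
  expect_lt(median(abs(f$lat[ok])), 0.35)
})

test_that("frame-count contracts per regularizer are enforced", {
  fr <- shifted_speckle_frames(1, 0, seed = 2, lines = 16, depth = 2)
  expect_error(estimate_displacement_multilevel(list(fr$pre), bm_config(), "none"),
               "2 frames")
  expect_error(estimate_displacement_multilevel(list(fr$pre, fr$post),
                                                bm_config(), "stbr2"),
               "4 frames")
  expect_error(track_sequence(list(fr$pre, fr$post), bm_config(), "stbr1"),
               "4 consecutive")
})
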
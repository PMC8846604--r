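half_annulus <- function(r, n = 100) {
  th <- seq(0, pi, length.out = n)
  data.frame(z = 5 - r * sin(th), x = 5 + r * cos(th))
}

test_that("mesh construction yields orthonormal wall frames and equal segments", {
  mesh <- build_mesh(half_annulus(2), half_annulus(3), 600)
  expect_equal(length(mesh$z0), 600)
  expect_equal(as.vector(table(mesh$segment)), rep(100L, 6))
  # radial and longitudinal frames orthonormal by construction
  expect_lt(max(abs(rowSums(mesh$rad * mesh$lon))), 1e-9)
  expect_lt(max(abs(rowSums(mesh$rad^2) - 1)), 1e-12)
  # radial points outward (from endo r=2 toward epi r=3): away from (5,5)
  v <- cbind(mesh$z0 - 5, mesh$x0 - 5)
  expect_gt(min(rowSums(v * mesh$rad)), 0)
  # straight parallel contours: all radial vectors identical
  line <- function(z) data.frame(z = rep(z, 20), x = seq(0, 10, length.out = 20))
  ms <- build_mesh(line(2), line(4), 120)
  expect_lt(max(abs(sweep(ms$rad, 2, ms$rad[1, ]))), 1e-12)
  expect_error(build_mesh(line(2), line(4), 100), "multiple of 6")
  # crossing contours rejected
  cross <- data.frame(z = seq(4, 0, length.out = 20),
                      x = seq(0, 10, length.out = 20))
  expect_error(build_mesh(line(2), cross, 120), "cross")
})

test_that("median filtering removes outliers and matches the sort-based definition", {
  geom <- list(fs = 40, pitch = 0.2, f0 = 8, c = 1540)
  mk <- function(ax) ustrain:::displacement_field(
    ax, ax * 0, seq(10, 10 * nrow(ax), by = 10), seq(2, 2 * ncol(ax), by = 2),
    matrix(FALSE, nrow(ax), ncol(ax)), c(0, 1), geom)
  expect_error(median_filter_field(mk(matrix(0, 8, 8)), c(4, 5)), "odd")
  const <- mk(matrix(2.5, 9, 9))
  expect_equal(median_filter_field(const)$ax, const$ax)
  spike <- matrix(1, 9, 9); spike[5, 5] <- 40
  expect_equal(median_filter_field(mk(spike))$ax, matrix(1, 9, 9))
  set.seed(3)
  rnd <- matrix(rnorm(110), 11, 10)
  got <- median_filter_field(mk(rnd), c(5, 5))$ax
  pr <- c(1, 1, 1:11, 11, 11); pc <- c(1, 1, 1:10, 10, 10)
  pad <- rnd[pr, pc]
  for (i in 1:11) for (j in 1:10)
    expect_equal(got[i, j], sort(as.vector(pad[i:(i + 4), j:(j + 4)]))[13])
})

test_that("Lagrangian accumulation integrates inter-frame fields along trajectories", {
  geom <- list(fs = 78.84, pitch = 0.2, f0 = 8, c = 1540)
  line <- function(z) data.frame(z = rep(z, 20), x = seq(0.5, 5.5, length.out = 20))
  mesh <- build_mesh(line(2), line(3.5), 300)
  mkf <- function(dz_mm, dx_mm) {
    ax <- matrix(dz_mm / (geom$c / (2 * geom$fs * 1000)), 30, 25)
    lat <- matrix(dx_mm / geom$pitch, 30, 25)
    ustrain:::displacement_field(ax, lat, seq(20, 600, by = 20),
                                 seq(1, 29.8, length.out = 25),
                                 matrix(FALSE, 30, 25), c(0, 1), geom)
  }
  # all-zero fields: constant trajectories
  m0 <- accumulate_lagrangian(mesh, list(mkf(0, 0), mkf(0, 0)))
  expect_equal(m0$traj_z[, 3], mesh$z0)
  expect_false(any(m0$frozen))
  # constant field d over T frames: displacement T * d
  mc <- accumulate_lagrangian(mesh, rep(list(mkf(0.05, 0.02)), 4))
  expect_equal(mc$traj_z[, 5], mesh$z0 + 4 * 0.05, tolerance = 1e-12)
  expect_equal(mc$traj_x[, 5], mesh$x0 + 4 * 0.02, tolerance = 1e-12)
})

test_that("tracking ground-truth fields reproduces the analytic motion", {
  # uniform-strain truth sampled onto a block grid, accumulated over 3 frames
  geom <- list(fs = 78.84, pitch = 0.2, f0 = 8, c = 1540)
  dzs <- geom$c / (2 * geom$fs * 1000)
  sc <- phantom_scene(imaging = imaging_config(),
                      motion = motion_model("uniform_strain",
                                            rate = c(0.005, 0.002),
                                            center = c(3, 3.2)),
                      n_frames = 4, wall = c(2, 4))
  truth <- generate_sequence(sc, 1)$truth
  cz <- seq(40, 580, by = 20); cx <- seq(1, 31, length.out = 20)
  mkf <- function(f) {
    zz <- rep(cz * dzs, length(cx)); xx <- rep(cx * 0.2, each = length(cz))
    d <- truth_pair_disp(truth, zz, xx, f)
    ustrain:::displacement_field(matrix(d$dz / dzs, length(cz)),
                                 matrix(d$dx / 0.2, length(cz)),
                                 cz, cx, matrix(FALSE, length(cz), length(cx)),
                                 c(f, f + 1), geom)
  }
  line <- function(z) data.frame(z = rep(z, 20), x = seq(1, 5, length.out = 20))
  mesh <- build_mesh(line(2.2), line(3.8), 300)
  mesh <- accumulate_lagrangian(mesh, lapply(0:2, mkf))
  tr <- truth_cum_disp(truth, mesh$z0, mesh$x0, 3)
  expect_lt(max(abs(mesh$traj_z[, 4] - (mesh$z0 + tr$dz))) / dzs, 0.1)
  expect_lt(max(abs(mesh$traj_x[, 4] - (mesh$x0 + tr$dx))) / 0.2, 0.1)
})

test_that("least-squares strain recovers affine and quadratic displacement fields", {
  line <- function(z) data.frame(z = rep(z, 30), x = seq(0, 6, length.out = 30))
  mesh <- build_mesh(line(2), line(4), 600)
  put_traj <- function(mesh, uz, ux) {
    mesh$traj_z <- cbind(mesh$z0, mesh$z0 + uz)
    mesh$traj_x <- cbind(mesh$x0, mesh$x0 + ux)
    mesh$frozen <- rep(FALSE, length(mesh$z0))
    mesh
  }
  # u_z = 0.01 z: E = [[0.01, 0], [0, 0]] exactly
  m1 <- ls_strain_tensor(put_traj(mesh, 0.01 * mesh$z0, 0), 1, c(0.8, 1))
  ok <- !m1$flags
  expect_gt(sum(ok), 400)
  expect_equal(m1$E_zz[ok], rep(0.01, sum(ok)), tolerance = 1e-10)
  expect_lt(max(abs(m1$E_zx[ok])), 1e-10)
  expect_lt(max(abs(m1$E_xx[ok])), 1e-10)
  # rigid translation: zero strain
  m2 <- ls_strain_tensor(put_traj(mesh, 0.3, -0.2), 1, c(0.8, 1))
  expect_lt(max(abs(c(m2$E_zz, m2$E_zx, m2$E_xx)[!is.na(c(m2$E_zz, m2$E_zx, m2$E_xx))])), 1e-9)
  # quadratic field: per-point OLS solved independently via normal equations
  uz <- 0.004 * mesh$z0^2; ux <- 0.003 * mesh$z0 * mesh$x0
  m3 <- ls_strain_tensor(put_traj(mesh, uz, ux), 1, c(0.8, 1))
  p <- which(!m3$flags)[200]
  nb <- which(abs(mesh$z0 - mesh$z0[p]) <= 0.4 & abs(mesh$x0 - mesh$x0[p]) <= 0.5)
  A <- cbind(1, mesh$z0[nb] - mesh$z0[p], mesh$x0[nb] - mesh$x0[p])
  cz <- solve(t(A) %*% A, t(A) %*% uz[nb])
  cx <- solve(t(A) %*% A, t(A) %*% ux[nb])
  G <- rbind(c(cz[2], cz[3]), c(cx[2], cx[3]))
  E <- (G + t(G)) / 2
  expect_equal(c(m3$E_zz[p], m3$E_zx[p], m3$E_xx[p]),
               c(E[1, 1], E[1, 2], E[2, 2]), tolerance = 1e-9)
})

test_that("strain transformation projects onto the wall directions", {
  line <- function(z) data.frame(z = rep(z, 10), x = seq(0, 3, length.out = 10))
  mesh <- build_mesh(line(1), line(2), 60)   # wall along x: rad = z axis
  rec <- list(E_zz = rep(0.02, 60), E_zx = rep(0, 60), E_xx = rep(-0.01, 60),
              flags = rep(FALSE, 60), frame_index = 1)
  class(rec) <- "strain_record"
  r1 <- transform_strain(rec, mesh)
  expect_equal(r1$e_r, rep(0.02, 60))
  expect_equal(r1$e_l, rep(-0.01, 60))
  # rotate frames 90 degrees: values swap
  m90 <- mesh; m90$rad <- mesh$lon; m90$lon <- mesh$rad
  r2 <- transform_strain(rec, m90)
  expect_equal(r2$e_r, r1$e_l)
  expect_equal(r2$e_l, r1$e_r)
  # 45-degree frames with diagonal tensor: both become (a + b) / 2
  m45 <- mesh
  m45$rad <- matrix(rep(c(1, 1) / sqrt(2), each = 60), ncol = 2)
  m45$lon <- matrix(rep(c(-1, 1) / sqrt(2), each = 60), ncol = 2)
  r3 <- transform_strain(rec, m45)
  expect_equal(r3$e_r, rep((0.02 - 0.01) / 2, 60), tolerance = 1e-12)
  expect_equal(r3$e_l, rep((0.02 - 0.01) / 2, 60), tolerance = 1e-12)
  # trace identity with orthonormal frames
  expect_equal(r1$e_r + r1$e_l, rec$E_zz + rec$E_xx, tolerance = 1e-12)
  mbad <- mesh; mbad$rad <- mesh$rad * 2
  expect_error(transform_strain(rec, mbad), "unit")
})

test_that("segmental curves average unflagged points and start at zero at ED", {
  line <- function(z) data.frame(z = rep(z, 30), x = seq(0, 6, length.out = 30))
  mesh <- build_mesh(line(2), line(3), 300)
  mkrec <- function(val, f) {
    r <- list(E_zz = rep(val, 300), E_zx = rep(0, 300), E_xx = rep(0, 300),
              e_r = rep(val, 300), e_l = rep(0, 300),
              flags = rep(FALSE, 300), frame_index = f)
    class(r) <- "strain_record"
    r
  }
  cur <- segment_strain_curves(list(mkrec(0, 0), mkrec(0.02, 1)), mesh)
  expect_equal(cur$e_r[1, ], rep(0, 6))          # ED exactly zero
  expect_equal(cur$e_r[2, ], rep(0.02, 6))       # uniform: identical segments
  expect_false(any(cur$empty))
})
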
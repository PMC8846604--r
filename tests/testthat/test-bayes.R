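test_that("SMI-to-PDF transform adds one and normalizes by the sum", {
  s <- matrix(c(1, 0, -1, 0.5), 2, 2)  # [[1,-1],[0,0.5]] row-major
  p <- smi_to_pdf(s)
  expect_equal(p$values, matrix(c(2, 1, 0, 1.5), 2, 2) / 4.5, tolerance = 1e-15)
  # constant SMI gives the uniform PDF
  pu <- smi_to_pdf(matrix(0.3, 5, 7))
  expect_equal(as.vector(pu$values), rep(1 / 35, 35))
  # all -1 (zero denominator): uniform, flagged
  pz <- smi_to_pdf(matrix(-1, 3, 3))
  expect_true(pz$flag)
  expect_equal(as.vector(pz$values), rep(1 / 9, 9))
  expect_error(smi_to_pdf(matrix(2, 3, 3)), "\\[-1, 1\\]")
  # normalization contract on random valid SMIs
  set.seed(5)
  for (i in 1:20) {
    p <- smi_to_pdf(matrix(runif(63, -1, 1), 9, 7))
    expect_equal(sum(p$values), 1, tolerance = 1e-12)
    expect_gte(min(p$values), 0)
  }
})

test_that("sigma coupling converts strain widths to lag widths by block spacing", {
  expect_equal(couple_sigma(c(0.01, 0.01), c(50, 50)), c(0.5, 0.5))
  expect_error(couple_sigma(c(0.01, 0.01), c(0, 50)), "spacing")
  expect_equal(couple_sigma(c(0.02, 0.02), c(50, 10)),
               2 * couple_sigma(c(0.01, 0.01), c(50, 10)))
})

test_that("neighbour likelihood matches its analytic and brute-force definitions", {
  # delta PDF: Gaussian within the truncation window, floor outside
  la <- 15; ll <- 15
  delta <- matrix(0, la, ll); delta[8, 8] <- 1
  L <- neighbor_likelihood(delta, c(1, 1))
  for (iu in 1:la) for (ju in 1:ll) {
    du <- iu - 8; dl <- ju - 8
    expected <- if (abs(du) <= 3 && abs(dl) <= 3)
      exp(-(du^2 + dl^2) / 2) else 1e-12
    expect_equal(L[iu, ju], max(expected, 1e-12), tolerance = 1e-14)
  }
  # uniform PDF: constant over interior lags
  Lu <- neighbor_likelihood(matrix(1 / 49, 7, 7), c(1.5, 1.5))
  expect_equal(max(Lu) - min(Lu), 0, tolerance = 1e-15)
  # brute-force over all (u, v) pairs, with and without offsets
  set.seed(8)
  for (i in 1:10) {
    nb <- matrix(runif(49), 7, 7); nb <- nb / sum(nb)
    doff <- sample(-2:2, 2, replace = TRUE)
    L1 <- neighbor_likelihood(nb, c(1.2, 0.8), offset_delta = doff)
    expect_lt(max(abs(L1 - brute_lik(nb, c(1.2, 0.8), doff))), 1e-14)
  }
})

test_that("SBR posterior matches brute-force evaluation and its fixed points", {
  set.seed(13)
  # brute-force oracle on 3x3 blocks x 9x9 lags
  arr <- random_pdf_stack(9, 9, 3, 3)
  g <- pdf_grid(arr)
  post <- sbr_posterior(g, reg_params(n_iterations = 2), sigma_u = c(1.5, 1.5))
  expect_lt(max(abs(post$values - brute_sbr(arr, c(1.5, 1.5), iters = 2))), 1e-12)
  # with per-block lag offsets
  offa <- matrix(sample(-1:1, 9, TRUE), 3, 3)
  offl <- matrix(sample(-1:1, 9, TRUE), 3, 3)
  g2 <- pdf_grid(arr, offa, offl)
  post2 <- sbr_posterior(g2, reg_params(), sigma_u = c(1.5, 0.9))
  expect_lt(max(abs(post2$values -
                    brute_sbr(arr, c(1.5, 0.9), offa, offl))), 1e-12)
  # consensus fixed point: identical symmetric single-peak PDFs keep argmax
  cons <- array(0, c(9, 9, 3, 3))
  pk <- peaked_pdf(9, 9, c(2, -1), bg = 0)
  for (i in 1:3) for (j in 1:3) cons[, , i, j] <- pk
  pc <- sbr_posterior(pdf_grid(cons), reg_params(), sigma_u = c(1, 1))
  for (i in 1:3) for (j in 1:3)
    expect_equal(which.max(pc$values[, , i, j]), which.max(pk))
  # outlier block pulled to the consensus lag
  out <- cons
  out[, , 2, 2] <- peaked_pdf(9, 9, c(-3, 3), bg = 0.02)
  po <- sbr_posterior(pdf_grid(out), reg_params(), sigma_u = c(1, 1))
  expect_equal(which.max(po$values[, , 2, 2]), which.max(pk))
  # empty neighbourhood: posterior equals the prior
  single <- pdf_grid(array(arr[, , 1, 1], c(9, 9, 1, 1)))
  ps <- sbr_posterior(single, reg_params(), sigma_u = c(1, 1))
  expect_equal(ps$values, single$values, tolerance = 1e-12)
})

test_that("STBR-1 regularizes spatially then temporally", {
  set.seed(17)
  arr <- lapply(1:3, function(i) random_pdf_stack(7, 7, 3, 3))
  gs <- lapply(1:3, function(i) pdf_grid(arr[[i]], time_index = i - 1))
  post <- stbr1_posterior(gs[[1]], gs[[2]], gs[[3]], reg_params(),
                          sigma_u = c(1.3, 1.3), sigma_t_lags = c(0.9, 0.9))
  s1 <- lapply(arr, brute_sbr, sigma = c(1.3, 1.3))
  ref <- brute_temporal(s1[[2]], s1[[1]], s1[[3]], c(0.9, 0.9))
  expect_lt(max(abs(post$values - ref)), 1e-12)
  # full spatial and temporal consensus keeps the argmax
  pk <- peaked_pdf(7, 7, c(1, 1), bg = 0)
  cons <- array(rep(pk, 9), c(7, 7, 3, 3))
  gcons <- pdf_grid(cons)
  pc <- stbr1_posterior(gcons, gcons, gcons, reg_params(),
                        sigma_u = c(1, 1), sigma_t_lags = c(1, 1))
  expect_equal(which.max(pc$values[, , 2, 2]), which.max(pk))
  # temporal outlier at t with agreeing past/future moves toward the
  # temporal consensus (single-block grids isolate the temporal stage)
  g1 <- function(p) pdf_grid(array(p, c(7, 7, 1, 1)))
  po <- stbr1_posterior(g1(pk), g1(peaked_pdf(7, 7, c(-2, -2), bg = 0.03)),
                        g1(pk), reg_params(),
                        sigma_u = c(1, 1), sigma_t_lags = c(1, 1))
  expect_equal(which.max(po$values[, , 1, 1]), which.max(pk))
  # infinite temporal width: stage 2 flat, posterior = stage-1 SBR
  pinf <- stbr1_posterior(gs[[1]], gs[[2]], gs[[3]], reg_params(),
                          sigma_u = c(1.3, 1.3), sigma_t_lags = c(Inf, Inf))
  expect_lt(max(abs(pinf$values - s1[[2]])), 1e-9)
  # missing both neighbours: SBR fallback, flagged
  pf <- stbr1_posterior(NULL, gs[[2]], NULL, reg_params(), sigma_u = c(1.3, 1.3))
  expect_true(attr(pf, "temporal_fallback"))
  expect_lt(max(abs(pf$values - s1[[2]])), 1e-12)
})

test_that("STBR-2 matches brute force and reduces to SBR as sigma_t grows", {
  set.seed(19)
  arr <- lapply(1:3, function(i) random_pdf_stack(7, 7, 3, 3))
  gs <- lapply(1:3, function(i) pdf_grid(arr[[i]], time_index = i - 1))
  post <- stbr2_posterior(gs[[1]], gs[[2]], gs[[3]], reg_params(),
                          sigma_u = c(1.1, 0.7), sigma_t_lags = c(0.8, 0.6))
  ref <- brute_stbr2(arr[[2]], arr[[1]], arr[[3]], c(1.1, 0.7), c(0.8, 0.6))
  expect_lt(max(abs(post$values - ref)), 1e-12)
  # SBR-reduction limit
  pinf <- stbr2_posterior(gs[[1]], gs[[2]], gs[[3]], reg_params(),
                          sigma_u = c(1.1, 0.7), sigma_t_lags = c(Inf, Inf))
  psbr <- sbr_posterior(gs[[2]], reg_params(), sigma_u = c(1.1, 0.7))
  expect_lt(max(abs(pinf$values - psbr$values)), 1e-9)
  # consensus across space and time keeps the argmax
  pk <- peaked_pdf(7, 7, c(-1, 2), bg = 0)
  cons <- pdf_grid(array(rep(pk, 9), c(7, 7, 3, 3)))
  pc <- stbr2_posterior(cons, cons, cons, reg_params(),
                        sigma_u = c(1, 1), sigma_t_lags = c(1, 1))
  expect_equal(which.max(pc$values[, , 2, 2]), which.max(pk))
})

test_that("posteriors are valid PDFs and symmetric under grid relabelling", {
  set.seed(23)
  for (i in 1:5) {
    arr <- random_pdf_stack(7, 5, 3, 4)
    gs <- pdf_grid(arr)
    for (post in list(sbr_posterior(gs, reg_params(), sigma_u = c(1, 1)),
                      stbr2_posterior(pdf_grid(random_pdf_stack(7, 5, 3, 4)),
                                      gs,
                                      pdf_grid(random_pdf_stack(7, 5, 3, 4)),
                                      reg_params(), sigma_u = c(1, 1),
                                      sigma_t_lags = c(1, 1)))) {
      sums <- apply(post$values, c(3, 4), sum)
      expect_lt(max(abs(sums - 1)), 1e-12)
      expect_gte(min(post$values), 0)
    }
    # left-right relabelling of the block grid commutes with SBR
    flip <- arr[, , , 4:1]
    pf <- sbr_posterior(pdf_grid(flip), reg_params(), sigma_u = c(1, 1))
    p0 <- sbr_posterior(gs, reg_params(), sigma_u = c(1, 1))
    expect_lt(max(abs(pf$values - p0$values[, , , 4:1])), 1e-13)
  }
})

test_that("MAP displacement reads posteriors with sub-sample precision", {
  d <- matrix(0, 11, 9); d[3 + 6, -1 + 5] <- 1
  expect_equal(as.vector(map_displacement(d)), c(3, -1), tolerance = 1e-9)
  # posterior equal to the prior gives the plain correlation estimate
  set.seed(29)
  s <- matrix(runif(99, -0.2, 0.8), 11, 9)
  single <- pdf_grid(array(smi_to_pdf(s)$values, c(11, 9, 1, 1)))
  ps <- sbr_posterior(single, reg_params(), sigma_u = c(1, 1))
  m <- map_displacement(ps)
  direct <- subsample_peak(smi_to_pdf(s)$values)
  # identical up to the refinement grid resolution (renormalization noise)
  expect_equal(c(m$axial[1, 1], m$lateral[1, 1]), as.vector(direct),
               tolerance = 0.02)
})
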
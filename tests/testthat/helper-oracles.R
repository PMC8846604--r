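# Independent brute-force oracles: textbook definitions written as plain
# loops, kept deliberately separate from the package's computational path.

# two-loop zero-normalized cross-correlation over a lag grid
brute_ncc <- function(pre, post, ctr, kernel, search) {
  hk <- (kernel - 1) / 2
  a <- pre[(ctr[1] - hk[1]):(ctr[1] + hk[1]),
           (ctr[2] - hk[2]):(ctr[2] + hk[2])]
  out <- matrix(0, 2 * search[1] + 1, 2 * search[2] + 1)
  for (j in -search[2]:search[2])
    for (i in -search[1]:search[1]) {
      b <- post[(ctr[1] + i - hk[1]):(ctr[1] + i + hk[1]),
                (ctr[2] + j - hk[2]):(ctr[2] + j + hk[2])]
      da <- a - mean(a); db <- b - mean(b)
      out[i + search[1] + 1, j + search[2] + 1] <-
        sum(da * db) / sqrt(sum(da^2) * sum(db^2))
    }
  out
}

# likelihood from one neighbouring PDF: exhaustive double max over (u, v)
brute_lik <- function(nb, sigma, doff = c(0, 0), floor_v = 1e-12) {
  la <- nrow(nb); ll <- ncol(nb)
  L <- matrix(floor_v, la, ll)
  for (ju in 1:ll) for (iu in 1:la) {
    best <- 0
    for (jv in 1:ll) for (iv in 1:la) {
      da <- iv + doff[1] - iu; dl <- jv + doff[2] - ju
      ok_a <- !is.finite(sigma[1]) || abs(da) <= 3 * sigma[1]
      ok_l <- !is.finite(sigma[2]) || abs(dl) <= 3 * sigma[2]
      if (ok_a && ok_l) {
        wa <- if (is.finite(sigma[1])) exp(-da^2 / (2 * sigma[1]^2)) else 1
        wl <- if (is.finite(sigma[2])) exp(-dl^2 / (2 * sigma[2]^2)) else 1
        best <- max(best, nb[iv, jv] * wa * wl)
      }
    }
    L[iu, ju] <- max(best, floor_v)
  }
  L
}

# spatial posterior per block: prior times product of neighbour likelihoods
brute_sbr <- function(arr, sigma, offa = NULL, offl = NULL, iters = 1,
                      floor_v = 1e-12) {
  d <- dim(arr); nbr <- d[3]; nbc <- d[4]
  if (is.null(offa)) offa <- matrix(0L, nbr, nbc)
  if (is.null(offl)) offl <- matrix(0L, nbr, nbc)
  cur <- arr
  for (it in seq_len(iters)) {
    nxt <- cur
    for (bc in 1:nbc) for (br in 1:nbr) {
      post <- cur[, , br, bc]
      for (nb in list(c(br - 1, bc), c(br + 1, bc), c(br, bc - 1), c(br, bc + 1))) {
        if (nb[1] < 1 || nb[1] > nbr || nb[2] < 1 || nb[2] > nbc) next
        doff <- c(offa[nb[1], nb[2]] - offa[br, bc],
                  offl[nb[1], nb[2]] - offl[br, bc])
        post <- post * brute_lik(cur[, , nb[1], nb[2]], sigma, doff, floor_v)
      }
      nxt[, , br, bc] <- post / sum(post)
    }
    cur <- nxt
  }
  cur
}

# temporal combination: prior(t) times past/future likelihoods
brute_temporal <- function(cur, past, fut, sigma_t, floor_v = 1e-12) {
  d <- dim(cur)
  out <- cur
  for (bc in 1:d[4]) for (br in 1:d[3]) {
    post <- cur[, , br, bc]
    if (!is.null(past)) post <- post * brute_lik(past[, , br, bc], sigma_t,
                                                 floor_v = floor_v)
    if (!is.null(fut)) post <- post * brute_lik(fut[, , br, bc], sigma_t,
                                                floor_v = floor_v)
    out[, , br, bc] <- post / sum(post)
  }
  out
}

# simultaneous spatiotemporal posterior
brute_stbr2 <- function(arr, past, fut, sigma_s, sigma_t, iters = 1,
                        floor_v = 1e-12) {
  d <- dim(arr); nbr <- d[3]; nbc <- d[4]
  cur <- arr
  for (it in seq_len(iters)) {
    nxt <- cur
    for (bc in 1:nbc) for (br in 1:nbr) {
      post <- cur[, , br, bc]
      for (nb in list(c(br - 1, bc), c(br + 1, bc), c(br, bc - 1), c(br, bc + 1))) {
        if (nb[1] < 1 || nb[1] > nbr || nb[2] < 1 || nb[2] > nbc) next
        post <- post * brute_lik(cur[, , nb[1], nb[2]], sigma_s, floor_v = floor_v)
      }
      if (!is.null(past)) post <- post * brute_lik(past[, , br, bc], sigma_t,
                                                   floor_v = floor_v)
      if (!is.null(fut)) post <- post * brute_lik(fut[, , br, bc], sigma_t,
                                                  floor_v = floor_v)
      nxt[, , br, bc] <- post / sum(post)
    }
    cur <- nxt
  }
  cur
}

# random stack of PDF surfaces (each non-negative, summing to 1)
random_pdf_stack <- function(la, ll, nbr, nbc) {
  v <- array(runif(la * ll * nbr * nbc), dim = c(la, ll, nbr, nbc))
  m <- matrix(v, la * ll)
  array(sweep(m, 2, colSums(m), "/"), dim = dim(v))
}

# single-peak PDF surface with background noise
peaked_pdf <- function(la, ll, pk, height = 1, bg = 0.05) {
  v <- matrix(runif(la * ll) * bg, la, ll)
  v[pk[1] + (la + 1) / 2, pk[2] + (ll + 1) / 2] <- height
  v / sum(v)
}

# small phantom frames for tracking tests: rigid shift in sample/line units
shifted_speckle_frames <- function(shift_samples = 4, shift_lines = 1,
                                   seed = 1, lines = 32, depth = 6) {
  cfg <- imaging_config(lines = lines, depth = depth)
  dzmm <- cfg$c / (2 * cfg$fs * 1000)
  fld <- generate_scatterers(c(-2, depth + 2, -2, lines * cfg$pitch + 2),
                             30, seed)
  mm <- motion_model("rigid_shift",
                     shift = c(shift_samples * dzmm, shift_lines * cfg$pitch))
  list(pre = simulate_rf_frame(fld, cfg, 0),
       post = simulate_rf_frame(deform_scatterers(fld, mm, 1), cfg, 1),
       cfg = cfg)
}

# interior block mask: away from lateral sinc-boundary region and frame edges
interior_blocks <- function(field, margin_lines = 12, margin_rows = 3) {
  nlines <- max(field$centers_lat) + min(field$centers_lat)
  ok_c <- field$centers_lat >= margin_lines &
          field$centers_lat <= nlines - margin_lines
  ok_r <- seq_along(field$centers_ax) > margin_rows &
          seq_along(field$centers_ax) <= length(field$centers_ax) - margin_rows
  outer(ok_r, ok_c) & !field$flags
}
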
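#' Strain estimation bias
#'
#' Mean of (true - estimated) strain over the masked points.  Inputs are
#' expected in percent strain; the result is in percent.
#'
#' @param true_map,est_map aligned numeric arrays of strain values (%)
#' @param mask logical array of points to include (default: all finite)
#' @export
strain_bias <- function(true_map, est_map, mask = NULL) {
  m <- eval_mask(true_map, est_map, mask)
  if (!any(m)) stop("empty evaluation mask")
  mean(true_map[m] - est_map[m])
}

#' Normalized strain error
#'
#' \code{sum(|true - est|) / sum(|true|) * 100} over the masked points.
#' Scale-invariant, so inputs may be in percent or fractional strain.
#'
#' @inheritParams strain_bias
#' @export
normalized_error <- function(true_map, est_map, mask = NULL) {
  m <- eval_mask(true_map, est_map, mask)
  if (!any(m)) stop("empty evaluation mask")
  den <- sum(abs(true_map[m]))
  if (den == 0) stop("normalized error undefined: true strain is zero everywhere")
  sum(abs(true_map[m] - est_map[m])) / den * 100
}

#' Total temporal relative error between strain curves
#'
#' \code{sum_t |true(t) - est(t)| / sum_t |true(t)| * 100} over a cardiac
#' cycle's segmental strain curve.
#'
#' @param true_curve,est_curve equal-length numeric vectors
#' @export
ttr <- function(true_curve, est_curve) {
  if (length(true_curve) != length(est_curve))
    stop("curves must have equal length")
  ok <- is.finite(true_curve) & is.finite(est_curve)
  den <- sum(abs(true_curve[ok]))
  if (den == 0) stop("TTR undefined: true curve is zero everywhere")
  sum(abs(true_curve[ok] - est_curve[ok])) / den * 100
}

eval_mask <- function(a, b, mask) {
  if (length(a) != length(b)) stop("maps must be aligned")
  m <- is.finite(a) & is.finite(b)
  if (!is.null(mask)) m <- m & mask
  m
}

#' Elastographic signal-to-noise ratio map
#'
#' Per mesh-lattice point, SNR_e = mu / sigma of the strain values inside a
#' sliding window (default 5 transmural x 9 arc points, truncated at the
#' lattice edges).  Points whose window standard deviation falls below
#' 1e-12 are excluded and flagged.
#'
#' @param strain_map matrix of strain values on the mesh lattice
#'   (transmural x arc)
#' @param window odd window dims \code{c(transmural, arc)}
#' @return list with \code{snr} (NA where flagged) and \code{flags}
#' @export
snr_e_map <- function(strain_map, window = c(5, 9)) {
  if (any(window %% 2 != 1)) stop("window dims must be odd")
  nr <- nrow(strain_map); nc <- ncol(strain_map)
  if (window[1] > nr || window[2] > nc)
    stop("window larger than the mesh lattice")
  ha <- (window[1] - 1) / 2; hl <- (window[2] - 1) / 2
  snr <- matrix(NA_real_, nr, nc)
  flags <- matrix(FALSE, nr, nc)
  for (j in seq_len(nc))
    for (i in seq_len(nr)) {
      w <- strain_map[max(1, i - ha):min(nr, i + ha),
                      max(1, j - hl):min(nc, j + hl)]
      w <- w[is.finite(w)]
      if (length(w) < 2) { flags[i, j] <- TRUE; next }
      s <- sd(w)
      if (s < 1e-12) { flags[i, j] <- TRUE; next }
      snr[i, j] <- mean(w) / s
    }
  list(snr = snr, flags = flags)
}

#' Strain filter: expected elastographic SNR conditioned on strain
#'
#' Builds the 2-D histogram f(SNR_e, strain) over (strain, SNR_e) pairs,
#' normalizes each strain bin by the strain marginal f(strain) to obtain the
#' conditional PDF, and integrates SNR bin centres against it:
#' E(SNR_e | strain) per strain bin.  Empty strain bins are flagged and left
#' NA.
#'
#' @param snr_pairs data frame or list with components \code{strain} and
#'   \code{snr}
#' @param strain_bins strain bin edges, or a count (default 50 bins over the
#'   observed range)
#' @param snr_bins SNR bin edges, or a count (default 60 bins over [0, 30])
#' @return a \code{strain_filter}: \code{joint} counts, \code{conditional}
#'   PDF, \code{expected_snr}, bin centres and edges, \code{empty} flags
#' @export
strain_filter <- function(snr_pairs, strain_bins = 50, snr_bins = 60) {
  eps <- snr_pairs$strain; snr <- snr_pairs$snr
  ok <- is.finite(eps) & is.finite(snr)
  eps <- eps[ok]; snr <- snr[ok]
  if (length(eps) == 0) stop("no usable (strain, SNR_e) pairs")
  if (length(strain_bins) == 1) {
    rg <- range(eps)
    if (rg[1] == rg[2]) rg <- rg + c(-0.5, 0.5)
    strain_bins <- seq(rg[1], rg[2], length.out = strain_bins + 1)
  }
  if (length(snr_bins) == 1) snr_bins <- seq(0, 30, length.out = snr_bins + 1)
  if (is.unsorted(strain_bins, strictly = TRUE) ||
      is.unsorted(snr_bins, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  ns <- length(strain_bins) - 1; nq <- length(snr_bins) - 1
  bi <- findInterval(eps, strain_bins, rightmost.closed = TRUE)
  bj <- findInterval(snr, snr_bins, rightmost.closed = TRUE)
  keep <- bi >= 1 & bi <= ns & bj >= 1 & bj <= nq
  joint <- matrix(0, nq, ns)
  for (k in which(keep)) joint[bj[k], bi[k]] <- joint[bj[k], bi[k]] + 1
  marg <- colSums(joint)
  cond <- sweep(joint, 2, pmax(marg, 1), "/")
  cond[, marg == 0] <- NA
  qc <- (snr_bins[-1] + snr_bins[-(nq + 1)]) / 2
  esnr <- as.numeric(qc %*% ifelse(is.na(cond), 0, cond))
  esnr[marg == 0] <- NA
  out <- list(joint = joint, conditional = cond, expected_snr = esnr,
              strain_centers = (strain_bins[-1] + strain_bins[-(ns + 1)]) / 2,
              snr_centers = qc, strain_edges = strain_bins,
              snr_edges = snr_bins, empty = marg == 0)
  class(out) <- "strain_filter"
  out
}

#' @export
print.strain_filter <- function(x, ...) {
  cat(sprintf("<strain_filter> %d strain bins (%d occupied), %d SNR bins\n",
              length(x$expected_snr), sum(!x$empty), length(x$snr_centers)))
  invisible(x)
}
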
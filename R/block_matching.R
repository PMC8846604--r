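#' Block-matching configuration
#'
#' Multi-level 2-D NCC block matching parameters.  Defaults follow the
#' standard three-level setup for linear-array RF data: axial decimation
#' factors 3/2/1 and lateral 2/1/1 from coarse to fine, axial kernel lengths
#' of 8, 5 and 1 wavelengths (converted to an odd number of samples via the
#' sampling-to-centre frequency ratio at each level), lateral kernel lengths
#' of 15, 12 and 10 A-lines, 10% axial and 90% lateral kernel overlap, and
#' 1:2 axial:lateral RF up-sampling.  Search half-ranges per level are not
#' standardized and default to 10/5/2 samples axially and 5/3/1 lines
#' laterally; they must exceed the residual inter-frame motion at each
#' level.  Wider finest-level ranges buy extra sub-sample precision (more
#' support for the peak interpolant) at the cost of admitting larger
#' outliers in noisy data.
#'
#' @param n_levels number of pyramid levels
#' @param ax_decim,lat_decim per-level decimation factors (coarse to fine)
#' @param ax_kernel_wl per-level axial kernel lengths in wavelengths
#' @param lat_kernel per-level lateral kernel lengths in A-lines
#' @param overlap kernel overlap \code{c(axial, lateral)} in percent
#' @param search_ax,search_lat per-level search half-ranges (samples / lines)
#' @param upsample RF up-sampling factors \code{c(axial, lateral)}
#' @param refine_step sub-sample refinement resolution (lags)
#' @param taps windowed-sinc half-width (samples) used for RF up-sampling and
#'   peak refinement
#' @param compand if \code{TRUE}, levels are chained by fractional
#'   align-and-stretch resampling of the post frame; by default they are
#'   chained by integer search-window offsets, which avoids resampling error
#'   at small inter-frame strains
#' @export
bm_config <- function(n_levels = 3,
                      ax_decim = c(3, 2, 1), lat_decim = c(2, 1, 1),
                      ax_kernel_wl = c(8, 5, 1), lat_kernel = c(15, 12, 10),
                      overlap = c(10, 90),
                      search_ax = c(10, 5, 2), search_lat = c(5, 3, 1),
                      upsample = c(1, 2), refine_step = 0.01, taps = 8,
                      compand = FALSE) {
  stopifnot(n_levels >= 1,
            length(ax_decim) == n_levels, length(lat_decim) == n_levels,
            length(ax_kernel_wl) == n_levels, length(lat_kernel) == n_levels,
            length(search_ax) == n_levels, length(search_lat) == n_levels,
            all(ax_decim >= 1), all(lat_decim >= 1),
            all(overlap >= 0), all(overlap < 100),
            all(upsample >= 1), refine_step > 0)
  cfg <- list(n_levels = n_levels, ax_decim = ax_decim, lat_decim = lat_decim,
              ax_kernel_wl = ax_kernel_wl, lat_kernel = lat_kernel,
              overlap = overlap, search_ax = search_ax,
              search_lat = search_lat, upsample = upsample,
              refine_step = refine_step, taps = taps, compand = compand)
  class(cfg) <- "bm_config"
  cfg
}

round_odd <- function(x) {
  k <- 2 * floor(x / 2) + 1
  as.integer(pmax(1, k + ifelse(x - k > 1, 2, 0)))
}

as_samples <- function(x) if (inherits(x, "rf_frame")) x$samples else x

#' Up-sample an RF frame with a windowed-sinc interpolator
#'
#' Densifies the RF grid by integer factors using a Hann-windowed sinc
#' kernel; original samples are preserved at their nodes.  The frame's
#' sampling frequency and pitch metadata are scaled accordingly.
#'
#' @param frame an \code{rf_frame} (or plain matrix)
#' @param axial_factor,lateral_factor integer factors >= 1
#' @param taps windowed-sinc half-width
#' @export
upsample_rf <- function(frame, axial_factor = 1, lateral_factor = 2, taps = 8) {
  if (axial_factor != round(axial_factor) || lateral_factor != round(lateral_factor))
    stop("up-sampling factors must be integers")
  stopifnot(axial_factor >= 1, lateral_factor >= 1)
  m <- cpp_upsample2d(as_samples(frame), as.integer(axial_factor),
                      as.integer(lateral_factor), as.integer(taps))
  if (!inherits(frame, "rf_frame")) return(m)
  out <- frame
  out$samples <- m
  out$fs <- frame$fs * axial_factor
  out$pitch <- frame$pitch / lateral_factor
  out
}

#' Build a multi-level pyramid by anti-aliased decimation
#'
#' Level k is the input low-pass filtered (windowed-sinc FIR at cutoff 1/f,
#' DC preserved) and decimated by the level-k factors; a level with factors
#' (1,1) equals the input exactly.
#'
#' @param frame an \code{rf_frame} or matrix
#' @param config a \code{\link{bm_config}}
#' @return list of frames, coarse to fine
#' @export
build_pyramid <- function(frame, config = bm_config()) {
  if (any(config$ax_decim < 1) || any(config$lat_decim < 1))
    stop("decimation factors must be >= 1")
  lapply(seq_len(config$n_levels), function(k)
    decimate_frame(frame, config$ax_decim[k], config$lat_decim[k], config$taps))
}

decimate_frame <- function(frame, fa, fl, taps = 8) {
  s <- as_samples(frame)
  m <- if (fa == 1 && fl == 1) s else
    cpp_decimate2d(s, as.integer(fa), as.integer(fl), as.integer(taps))
  if (!inherits(frame, "rf_frame")) return(m)
  out <- frame
  out$samples <- m
  out$fs <- frame$fs / fa
  out$pitch <- frame$pitch * fl
  out
}

#' Similarity metric image (2-D NCC surface) at one block location
#'
#' Zero-normalized cross-correlation between the pre-frame kernel centred at
#' \code{block_location} and equally sized post-frame windows over the lag
#' grid \code{offset + (-search, ..., +search)}.  Values lie in [-1, 1]; lags
#' whose window leaves the frame, and zero-variance kernels or windows, give
#' correlation 0 and flag the block.
#'
#' @param pre_frame,post_frame \code{rf_frame}s or matrices
#' @param block_location kernel centre \code{c(row, col)}, 1-based
#' @param kernel kernel size \code{c(axial, lateral)}, odd
#' @param search search half-range \code{c(axial, lateral)}
#' @param offset integer lag offset \code{c(axial, lateral)} shifting the
#'   search window (seeding from a coarser level)
#' @return an \code{smi}: list with \code{values} (lag matrix),
#'   \code{lag_offset} (minimum axial/lateral lag), \code{block_location},
#'   \code{flag}
#' @export
compute_smi <- function(pre_frame, post_frame, block_location,
                        kernel = c(31, 11), search = c(10, 5),
                        offset = c(0L, 0L)) {
  pre <- as_samples(pre_frame); post <- as_samples(post_frame)
  stopifnot(all(kernel %% 2 == 1), all(search >= 0))
  res <- cpp_smi_grid(pre, post,
                      as.integer(block_location[1] - 1L),
                      as.integer(block_location[2] - 1L),
                      as.integer(kernel[1]), as.integer(kernel[2]),
                      as.integer(search[1]), as.integer(search[2]),
                      as.integer(offset[1]), as.integer(offset[2]))
  v <- array(res$values, dim = c(2 * search[1] + 1, 2 * search[2] + 1))
  s <- list(values = v,
            lag_offset = c(offset[1] - search[1], offset[2] - search[2]),
            block_location = block_location, flag = res$flags[1])
  class(s) <- "smi"
  s
}

#' Sub-sample peak location of a lag surface
#'
#' Refines the integer argmax of a similarity or posterior surface by
#' evaluating its 2-D Hann-windowed-sinc interpolant on a fine grid around
#' the peak (two-stage search reaching \code{refine_step} lag resolution).
#' Ties between equal maxima break to the smallest Euclidean displacement
#' magnitude, then the smallest axial lag.  A flat surface returns zero
#' displacement with the \code{degenerate} flag; a boundary maximum returns
#' the integer lag with the \code{boundary} flag.  On correlation surfaces an
#' integer-lag peak of 1 (within 1e-9) is an exact match and is returned
#' without refinement.
#'
#' @param x an \code{smi}, a posterior surface, or a plain matrix (optionally
#'   with a \code{lag_offset} attribute)
#' @param refine_step refinement resolution in lags
#' @param taps windowed-sinc half-width
#' @return \code{c(axial, lateral)} displacement in lag units, with
#'   attribute \code{flag} (0 ok, 1 degenerate, 2 boundary)
#' @export
subsample_peak <- function(x, refine_step = 0.01, taps = 8) {
  guard <- inherits(x, "smi")
  if (inherits(x, "smi") || inherits(x, "pdf_surface")) {
    v <- x$values
    off <- x$lag_offset
  } else {
    v <- x
    off <- attr(x, "lag_offset")
    if (is.null(off)) off <- -c((nrow(v) - 1) / 2, (ncol(v) - 1) / 2)
  }
  ha <- (nrow(v) - 1) / 2; hl <- (ncol(v) - 1) / 2
  r <- cpp_subsample_peak(v, as.integer(off[1] + ha), as.integer(off[2] + hl),
                          refine_step, as.integer(taps), guard)
  out <- c(axial = r[1], lateral = r[2])
  attr(out, "flag") <- as.integer(r[3])
  out
}

#' Align-and-stretch (compand) a post-deformation frame
#'
#' Resamples the post frame by the displacement field, bilinearly
#' interpolated from the block grid to the sample grid, so that residual
#' motion relative to the pre frame is small.  Out-of-range samples are
#' extrapolated by edge replication.
#'
#' @param post_frame \code{rf_frame} or matrix at the resolution the field's
#'   units refer to
#' @param field a \code{displacement_field}
#' @export
compand_rf <- function(post_frame, field) {
  s <- as_samples(post_frame)
  da <- dense_field(field$ax, field$centers_ax, field$centers_lat,
                    nrow(s), ncol(s))
  dl <- dense_field(field$lat, field$centers_ax, field$centers_lat,
                    nrow(s), ncol(s))
  m <- cpp_warp_bilinear(s, da, dl)
  if (!inherits(post_frame, "rf_frame")) return(m)
  out <- post_frame
  out$samples <- m
  out
}

# bilinear interpolation of block-grid values onto a dense 0-based sample
# grid, with edge-value extrapolation
dense_field <- function(vals, cr, cc, nr, nc) {
  qr <- rep(0:(nr - 1), times = nc)
  qc <- rep(0:(nc - 1), each = nr)
  matrix(cpp_interp_grid(vals, cr, cc, qr, qc), nr, nc)
}

# interpolate block-grid values at scattered query points (same convention)
interp_grid <- function(vals, cr, cc, qr, qc) {
  cpp_interp_grid(vals, cr, cc, qr, qc)
}

displacement_field <- function(ax, lat, centers_ax, centers_lat, flags,
                               frame_pair, geom) {
  f <- list(ax = ax, lat = lat, centers_ax = centers_ax,
            centers_lat = centers_lat, flags = flags,
            frame_pair = frame_pair, geom = geom)
  class(f) <- "displacement_field"
  f
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %d x %d blocks, pair (%d, %d), %d flagged\n",
              nrow(x$ax), ncol(x$ax), x$frame_pair[1], x$frame_pair[2],
              sum(x$flags)))
  invisible(x)
}

#' Block-centre positions of a displacement field in millimetres
#' @param field a \code{displacement_field}
#' @return list with vectors \code{z} (axial) and \code{x} (lateral), mm
#' @export
field_positions_mm <- function(field) {
  g <- field$geom
  list(z = field$centers_ax * g$c / (2 * g$fs * 1000),
       x = field$centers_lat * g$pitch)
}

#' Displacement components of a field in millimetres
#' @param field a \code{displacement_field}
#' @export
field_mm <- function(field) {
  g <- field$geom
  list(dz = field$ax * g$c / (2 * g$fs * 1000), dx = field$lat * g$pitch)
}

# block grid for a level-k frame: odd kernel sizes, centres leaving kernel +
# zero-offset search margin, steps from the configured overlaps
level_grid <- function(nr, nc, fs_level, f0, config, k) {
  ka <- round_odd(config$ax_kernel_wl[k] * fs_level / f0)
  kl <- round_odd(config$lat_kernel[k])
  ha <- config$search_ax[k]; hl <- config$search_lat[k]
  ma <- (ka - 1) / 2 + ha; ml <- (kl - 1) / 2 + hl
  step_a <- max(1L, as.integer(round(ka * (1 - config$overlap[1] / 100))))
  step_l <- max(1L, as.integer(round(kl * (1 - config$overlap[2] / 100))))
  if (nr - 1 - 2 * ma < 0 || nc - 1 - 2 * ml < 0)
    stop(sprintf("level %d frame (%d x %d) too small for kernel %d x %d with search (%d, %d)",
                 k, nr, nc, ka, kl, ha, hl))
  ctr_r <- seq(ma, nr - 1 - ma, by = step_a)
  ctr_c <- seq(ml, nc - 1 - ml, by = step_l)
  list(ka = ka, kl = kl, ha = ha, hl = hl,
       ctr_r = as.integer(ctr_r), ctr_c = as.integer(ctr_c),
       step = c(step_a, step_l))
}

#' Multi-level block-matching over an RF sequence
#'
#' Runs the full multi-level pipeline (sinc up-sampling, pyramid decimation,
#' per-level NCC similarity surfaces, optional Bayesian regularization,
#' sub-sample peak refinement) for every adjacent frame pair of a sequence.
#' Coarse-level estimates seed the finer levels through per-block integer
#' search-window offsets (or fractional companding if
#' \code{config$compand}).  For the spatiotemporal regularizers the
#' similarity surfaces of the previous and next frame pairs act as temporal
#' neighbours; the first and last pairs lack one neighbour and fall back to
#' spatial-only regularization (flagged in the result).
#'
#' @param frames list of \code{rf_frame}s (2 or more; 4 or more for STBR)
#' @param config a \code{\link{bm_config}}
#' @param regularizer \code{"none"}, \code{"sbr"}, \code{"stbr1"} or
#'   \code{"stbr2"}
#' @param params a \code{\link{reg_params}}
#' @return list of \code{displacement_field}s, one per adjacent pair
#' @export
track_sequence <- function(frames, config = bm_config(),
                           regularizer = c("none", "sbr", "stbr1", "stbr2"),
                           params = reg_params()) {
  regularizer <- match.arg(regularizer)
  stopifnot(length(frames) >= 2)
  if (regularizer %in% c("stbr1", "stbr2") && length(frames) < 4)
    stop("spatiotemporal regularization needs at least 4 consecutive RF frames")
  geom <- list(fs = frames[[1]]$fs, pitch = frames[[1]]$pitch,
               f0 = frames[[1]]$f0, c = frames[[1]]$c)
  ua <- config$upsample[1]; ul <- config$upsample[2]
  ups <- lapply(frames, upsample_rf, axial_factor = ua, lateral_factor = ul,
                taps = config$taps)
  f0 <- frames[[1]]$f0
  fs_up <- frames[[1]]$fs * ua
  npair <- length(frames) - 1
  fields <- vector("list", npair)      # per-pair level fields (ups units)
  post_work <- lapply(seq_len(npair), function(p) ups[[p + 1]])
  base_ax <- base_lat <- vector("list", npair)  # companded amount per pair
  tflag <- rep(FALSE, npair)

  for (k in seq_len(config$n_levels)) {
    fa <- config$ax_decim[k]; fl <- config$lat_decim[k]
    pre_k <- lapply(seq_len(npair), function(p)
      decimate_frame(ups[[p]], fa, fl, config$taps))
    post_k <- lapply(seq_len(npair), function(p)
      decimate_frame(post_work[[p]], fa, fl, config$taps))
    nr <- nrow(pre_k[[1]]$samples); nc <- ncol(pre_k[[1]]$samples)
    g <- level_grid(nr, nc, fs_up / fa, f0, config, k)
    nbr <- length(g$ctr_r); nbc <- length(g$ctr_c)
    ctr_r <- rep(g$ctr_r, times = nbc)
    ctr_c <- rep(g$ctr_c, each = nbr)
    cr_ups <- g$ctr_r * fa; cc_ups <- g$ctr_c * fl

    smis <- vector("list", npair)
    offs_a <- offs_l <- vector("list", npair)
    flags <- vector("list", npair)
    for (p in seq_len(npair)) {
      if (is.null(fields[[p]])) {
        oa <- matrix(0L, nbr, nbc); ol <- matrix(0L, nbr, nbc)
      } else {
        fp <- fields[[p]]
        qr <- rep(cr_ups, times = nbc); qc <- rep(cc_ups, each = nbr)
        pa <- interp_grid(fp$ax, fp$cr, fp$cc, qr, qc)
        pl <- interp_grid(fp$lat, fp$cr, fp$cc, qr, qc)
        if (config$compand) {
          ba <- interp_grid(base_ax[[p]]$v, base_ax[[p]]$cr, base_ax[[p]]$cc, qr, qc)
          bl <- interp_grid(base_lat[[p]]$v, base_lat[[p]]$cr, base_lat[[p]]$cc, qr, qc)
          pa <- pa - ba; pl <- pl - bl
        }
        oa <- matrix(as.integer(round(pa / fa)), nbr, nbc)
        ol <- matrix(as.integer(round(pl / fl)), nbr, nbc)
      }
      res <- cpp_smi_grid(pre_k[[p]]$samples, post_k[[p]]$samples,
                          ctr_r, ctr_c, g$ka, g$kl, g$ha, g$hl,
                          as.integer(oa), as.integer(ol))
      smis[[p]] <- array(res$values, dim = c(2 * g$ha + 1, 2 * g$hl + 1, nbr, nbc))
      offs_a[[p]] <- oa; offs_l[[p]] <- ol
      flags[[p]] <- matrix(res$flags, nbr, nbc)
    }

    surfs <- regularize_level(smis, offs_a, offs_l, regularizer, params, g$step)
    tflag <- tflag | surfs$tflag
    guard <- regularizer == "none"

    for (p in seq_len(npair)) {
      v <- surfs$values[[p]]
      ax <- lat <- matrix(0, nbr, nbc)
      bflag <- flags[[p]]
      for (b in seq_len(nbr * nbc)) {
        br <- (b - 1) %% nbr + 1; bc <- (b - 1) %/% nbr + 1
        r <- cpp_subsample_peak(matrix(v[, , br, bc], 2 * g$ha + 1),
                                offs_a[[p]][br, bc], offs_l[[p]][br, bc],
                                config$refine_step, as.integer(config$taps),
                                guard)
        ax[br, bc] <- r[1] * fa; lat[br, bc] <- r[2] * fl
        if (r[3] > 0) bflag[br, bc] <- TRUE
      }
      if (config$compand && !is.null(base_ax[[p]])) {
        qr <- rep(cr_ups, times = nbc); qc <- rep(cc_ups, each = nbr)
        ax <- ax + matrix(interp_grid(base_ax[[p]]$v, base_ax[[p]]$cr,
                                      base_ax[[p]]$cc, qr, qc), nbr, nbc)
        lat <- lat + matrix(interp_grid(base_lat[[p]]$v, base_lat[[p]]$cr,
                                        base_lat[[p]]$cc, qr, qc), nbr, nbc)
      }
      fields[[p]] <- list(ax = ax, lat = lat, cr = cr_ups, cc = cc_ups,
                          flags = bflag)
    }

    if (config$compand && k < config$n_levels) {
      for (p in seq_len(npair)) {
        fp <- fields[[p]]
        s <- ups[[p + 1]]$samples
        da <- dense_field(fp$ax, fp$cr, fp$cc, nrow(s), ncol(s))
        dl <- dense_field(fp$lat, fp$cr, fp$cc, nrow(s), ncol(s))
        post_work[[p]]$samples <- cpp_warp_bilinear(s, da, dl)
        base_ax[[p]] <- list(v = fp$ax, cr = fp$cr, cc = fp$cc)
        base_lat[[p]] <- list(v = fp$lat, cr = fp$cr, cc = fp$cc)
      }
    }
  }

  lapply(seq_len(npair), function(p) {
    fp <- fields[[p]]
    fl <- fp$flags
    if (tflag[p]) attr(fl, "temporal_fallback") <- TRUE
    displacement_field(fp$ax / ua, fp$lat / ul,
                       fp$cr / ua, fp$cc / ul, fl,
                       frame_pair = c(frames[[p]]$frame_index,
                                      frames[[p + 1]]$frame_index),
                       geom = geom)
  })
}

# apply the chosen regularizer to the level's SMI stacks; returns surfaces to
# peak-pick plus per-pair temporal-fallback flags
regularize_level <- function(smis, offs_a, offs_l, regularizer, params, spacing) {
  npair <- length(smis)
  tflag <- rep(FALSE, npair)
  if (regularizer == "none")
    return(list(values = smis, tflag = tflag))
  su <- sigma_lags(params$sigma_eps, spacing, "strain")
  st <- sigma_lags(params$sigma_t, spacing, params$coupling_mode)
  pdfs <- lapply(smis, smi_stack_to_pdf)
  out <- vector("list", npair)
  if (regularizer == "sbr") {
    for (p in seq_len(npair))
      out[[p]] <- cpp_sbr_grid(pdfs[[p]], offs_a[[p]], offs_l[[p]],
                               su[1], su[2], params$n_iterations, params$likelihood_floor)
  } else if (regularizer == "stbr1") {
    s1 <- lapply(seq_len(npair), function(p)
      cpp_sbr_grid(pdfs[[p]], offs_a[[p]], offs_l[[p]], su[1], su[2],
                   1L, params$likelihood_floor))
    for (p in seq_len(npair)) {
      hp <- p > 1; hf <- p < npair
      if (!hp && !hf) { out[[p]] <- s1[[p]]; tflag[p] <- TRUE; next }
      if (!hp || !hf) tflag[p] <- TRUE
      out[[p]] <- cpp_temporal_grid(
        s1[[p]],
        if (hp) s1[[p - 1]] else NULL, if (hf) s1[[p + 1]] else NULL,
        offs_a[[p]], offs_l[[p]],
        if (hp) offs_a[[p - 1]] else NULL, if (hp) offs_l[[p - 1]] else NULL,
        if (hf) offs_a[[p + 1]] else NULL, if (hf) offs_l[[p + 1]] else NULL,
        st[1], st[2], params$likelihood_floor)
    }
  } else {  # stbr2
    for (p in seq_len(npair)) {
      hp <- p > 1; hf <- p < npair
      if (!hp || !hf) tflag[p] <- TRUE
      out[[p]] <- cpp_stbr2_grid(
        pdfs[[p]],
        if (hp) pdfs[[p - 1]] else NULL, if (hf) pdfs[[p + 1]] else NULL,
        offs_a[[p]], offs_l[[p]],
        if (hp) offs_a[[p - 1]] else NULL, if (hp) offs_l[[p - 1]] else NULL,
        if (hf) offs_a[[p + 1]] else NULL, if (hf) offs_l[[p + 1]] else NULL,
        su[1], su[2], st[1], st[2],
        params$n_iterations, params$likelihood_floor)
    }
  }
  list(values = out, tflag = tflag)
}

# normalize an SMI stack (la, ll, nbr, nbc) to PDFs block-wise
smi_stack_to_pdf <- function(v) {
  d <- dim(v)
  nl <- d[1] * d[2]
  m <- matrix(v + 1, nrow = nl)
  s <- colSums(m)
  zero <- s <= 0
  if (any(zero)) { m[, zero] <- 1; s[zero] <- nl }
  m <- sweep(m, 2, s, "/")
  array(m, dim = d)
}

#' Multi-level displacement estimation for one frame pair
#'
#' Convenience wrapper around \code{\link{track_sequence}}.  With
#' \code{"none"} or \code{"sbr"} exactly two frames (the pair) are expected;
#' with \code{"stbr1"}/\code{"stbr2"} exactly four consecutive frames, the
#' estimated pair being the middle one (frames 2 and 3) while the outer
#' frames provide the temporal neighbourhood.
#'
#' @inheritParams track_sequence
#' @return a \code{displacement_field}
#' @export
estimate_displacement_multilevel <- function(frames, config = bm_config(),
                                             regularizer = c("none", "sbr", "stbr1", "stbr2"),
                                             params = reg_params()) {
  regularizer <- match.arg(regularizer)
  n_need <- if (regularizer %in% c("stbr1", "stbr2")) 4L else 2L
  if (length(frames) != n_need)
    stop(sprintf("regularizer '%s' expects exactly %d frames", regularizer, n_need))
  fields <- track_sequence(frames, config, regularizer, params)
  fields[[if (n_need == 4L) 2L else 1L]]
}
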
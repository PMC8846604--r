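#' Regularization parameters
#'
#' Controls the Bayesian regularization of similarity surfaces.  The strain
#' regularization sigma (SRS) \code{sigma_eps} is the maximum strain expected
#' between adjacent blocks; it is coupled to the displacement-domain Gaussian
#' width \code{sigma_u} by the inter-block spacing (the displacement
#' difference two adjacent blocks exhibit at that strain).  The temporal
#' width \code{sigma_t} plays the same role for the past/future similarity
#' surfaces; smaller values enforce stronger temporal continuity.  By default
#' \code{sigma_t} is converted to lag units with the same block-spacing
#' coupling as \code{sigma_eps} (\code{coupling_mode = "strain"}); set
#' \code{coupling_mode = "lag"} to use it directly in lag units.
#'
#' @param sigma_eps strain regularization widths \code{c(axial, lateral)},
#'   unitless strain
#' @param sigma_t temporal widths \code{c(axial, lateral)}
#' @param n_iterations number of synchronous regularization passes
#' @param likelihood_floor lower bound applied to likelihood values before
#'   log-domain accumulation (guards against empty truncation windows)
#' @param coupling_mode \code{"strain"} or \code{"lag"} conversion of
#'   \code{sigma_t}
#' @export
reg_params <- function(sigma_eps = c(0.1, 0.1), sigma_t = c(0.01, 0.01),
                       n_iterations = 1L, likelihood_floor = 1e-12,
                       coupling_mode = c("strain", "lag")) {
  coupling_mode <- match.arg(coupling_mode)
  stopifnot(is.numeric(sigma_eps), is.numeric(sigma_t),
            all(sigma_eps > 0), all(sigma_t > 0), n_iterations >= 1,
            likelihood_floor > 0)
  p <- list(sigma_eps = sigma_eps, sigma_t = sigma_t,
            n_iterations = as.integer(n_iterations),
            likelihood_floor = likelihood_floor,
            coupling_mode = coupling_mode)
  class(p) <- "reg_params"
  p
}

sigma_lags <- function(sigma, spacing, mode) {
  if (mode == "lag") return(sigma)
  couple_sigma(sigma, spacing)
}

#' Couple a strain sigma to a displacement sigma
#'
#' \code{sigma_u = sigma_eps * spacing} per axis: the displacement difference
#' (in lags) that two adjacent blocks separated by \code{spacing}
#' samples/lines exhibit at the maximum expected strain.
#'
#' @param sigma_eps strain widths \code{c(axial, lateral)}
#' @param block_spacing inter-block spacing \code{c(samples, lines)}
#' @return displacement widths in lag units
#' @export
couple_sigma <- function(sigma_eps, block_spacing) {
  if (any(block_spacing <= 0)) stop("degenerate block grid: spacing must be positive")
  if (any(sigma_eps <= 0)) stop("sigma_eps must be positive")
  sigma_eps * block_spacing
}

#' Transform a similarity surface into a probability density surface
#'
#' Adds one to every NCC value and normalizes by the sum, yielding a
#' non-negative surface summing to 1.  An all-(-1) surface (zero denominator)
#' returns the uniform PDF with a flag.
#'
#' @param smi an \code{smi} object or a matrix of NCC values in [-1, 1]
#' @return a \code{pdf_surface}: list with \code{values}, \code{lag_offset},
#'   \code{flag}
#' @export
smi_to_pdf <- function(smi) {
  if (inherits(smi, "smi")) {
    v <- smi$values; off <- smi$lag_offset; loc <- smi$block_location
  } else {
    v <- smi
    off <- attr(smi, "lag_offset")
    if (is.null(off)) off <- -c((nrow(v) - 1) / 2, (ncol(v) - 1) / 2)
    loc <- NULL
  }
  if (any(v < -1 - 1e-9) || any(v > 1 + 1e-9))
    stop("SMI values must lie in [-1, 1]")
  w <- v + 1
  s <- sum(w)
  flag <- FALSE
  if (s <= 0) { w[] <- 1; s <- length(w); flag <- TRUE }
  p <- list(values = w / s, lag_offset = off, block_location = loc, flag = flag)
  class(p) <- "pdf_surface"
  p
}

#' Grid of PDF surfaces over block locations
#'
#' Container used by the grid-level regularizers: an array of lag surfaces,
#' one per block of an \code{nbr x nbc} grid, with a per-block integer lag
#' offset.  All surfaces share the lag-window dimensions.
#'
#' @param values array with dim \code{c(lags_axial, lags_lateral, nbr, nbc)},
#'   each block surface non-negative and summing to 1
#' @param off_ax,off_lat per-block integer lag offsets (scalar or
#'   \code{nbr x nbc} matrices)
#' @param time_index frame-pair index the grid belongs to
#' @export
pdf_grid <- function(values, off_ax = 0L, off_lat = 0L, time_index = 0L) {
  stopifnot(length(dim(values)) == 4)
  nbr <- dim(values)[3]; nbc <- dim(values)[4]
  if (length(off_ax) == 1) off_ax <- matrix(as.integer(off_ax), nbr, nbc)
  if (length(off_lat) == 1) off_lat <- matrix(as.integer(off_lat), nbr, nbc)
  g <- list(values = values, off_ax = off_ax, off_lat = off_lat,
            time_index = time_index)
  class(g) <- "pdf_grid"
  g
}

#' Bayesian likelihood surface from one neighbouring PDF
#'
#' For each candidate displacement u, the likelihood is the maximum over
#' displacements v within the truncation window (|v - u| <= 3 sigma per
#' axis) of the neighbour PDF at v weighted by an anisotropic Gaussian in
#' (v - u).  Values are floored at \code{floor} so empty windows never
#' produce zero likelihood.  Infinite sigma gives a flat weight over the
#' whole grid.
#'
#' @param neighbor_pdf a \code{pdf_surface} or matrix
#' @param sigma_lags Gaussian widths \code{c(axial, lateral)} in lag units
#' @param offset_delta neighbour lag offset minus current block lag offset
#' @param floor likelihood floor
#' @export
neighbor_likelihood <- function(neighbor_pdf, sigma_lags,
                                offset_delta = c(0L, 0L), floor = 1e-12) {
  v <- if (inherits(neighbor_pdf, "pdf_surface")) neighbor_pdf$values else neighbor_pdf
  if (any(sigma_lags <= 0)) stop("sigma must be positive")
  cpp_lik_neighbor(v, as.integer(offset_delta[1]), as.integer(offset_delta[2]),
                   sigma_lags[1], sigma_lags[2], floor)
}

check_aligned <- function(present, past, future) {
  d <- dim(present$values)
  for (g in list(past, future))
    if (!is.null(g) && !identical(dim(g$values)[1:2], d[1:2]))
      stop("temporal neighbour grids must share the lag-window dimensions")
}

grid_sigmas <- function(params, spacing, sigma_u, sigma_t_lags) {
  su <- if (!is.null(sigma_u)) sigma_u
        else couple_sigma(params$sigma_eps, spacing)
  st <- if (!is.null(sigma_t_lags)) sigma_t_lags
        else sigma_lags(params$sigma_t, spacing, params$coupling_mode)
  list(su = su, st = st)
}

#' Spatial Bayesian regularization (SBR) of a PDF grid
#'
#' Per block, the posterior is proportional to the prior PDF times the
#' product over available spatial neighbours (left, right, top, bottom) of
#' their likelihood surfaces, accumulated in the log domain and renormalized
#' to sum 1.  Updates are synchronous (all likelihoods from the pre-iteration
#' grid) and repeated \code{params$n_iterations} times.  A block with no
#' neighbours returns its prior.
#'
#' @param grid a \code{\link{pdf_grid}}
#' @param params a \code{\link{reg_params}}
#' @param spacing block spacing \code{c(samples, lines)} used to couple
#'   \code{sigma_eps} to lag units (ignored when \code{sigma_u} is given)
#' @param sigma_u displacement widths in lag units, overriding the coupling
#' @return a \code{pdf_grid} of posteriors
#' @export
sbr_posterior <- function(grid, params = reg_params(), spacing = c(1, 1),
                          sigma_u = NULL) {
  stopifnot(inherits(grid, "pdf_grid"))
  sg <- grid_sigmas(params, spacing, sigma_u, sigma_u)
  out <- cpp_sbr_grid(grid$values, grid$off_ax, grid$off_lat,
                      sg$su[1], sg$su[2], params$n_iterations,
                      params$likelihood_floor)
  pdf_grid(out, grid$off_ax, grid$off_lat, grid$time_index)
}

#' Spatial-then-temporal Bayesian regularization (STBR-1)
#'
#' Stage 1 applies one iteration of SBR independently to the past, present
#' and future grids.  Stage 2 treats the present stage-1 posterior as the
#' prior and multiplies in temporal likelihoods built from the stage-1
#' posteriors of the past and future grids with the temporal widths.  A
#' missing temporal neighbour leaves the stage-1 (SBR) result for that side;
#' with both missing the result is flagged as a pure SBR fallback.
#'
#' @param past,present,future \code{\link{pdf_grid}}s at times t-1, t, t+1
#'   (\code{past}/\code{future} may be \code{NULL})
#' @inheritParams sbr_posterior
#' @param sigma_t_lags temporal widths in lag units, overriding the coupling
#' @return a \code{pdf_grid} of posteriors at time t
#' @export
stbr1_posterior <- function(past, present, future, params = reg_params(),
                            spacing = c(1, 1), sigma_u = NULL,
                            sigma_t_lags = NULL) {
  stopifnot(inherits(present, "pdf_grid"))
  check_aligned(present, past, future)
  sg <- grid_sigmas(params, spacing, sigma_u, sigma_t_lags)
  p1 <- list(n_iterations = 1L, likelihood_floor = params$likelihood_floor)
  s1 <- function(g) cpp_sbr_grid(g$values, g$off_ax, g$off_lat,
                                 sg$su[1], sg$su[2], 1L, params$likelihood_floor)
  cur <- s1(present)
  hp <- !is.null(past); hf <- !is.null(future)
  if (!hp && !hf) {
    out <- pdf_grid(cur, present$off_ax, present$off_lat, present$time_index)
    attr(out, "temporal_fallback") <- TRUE
    return(out)
  }
  pg <- if (hp) s1(past) else NULL
  fg <- if (hf) s1(future) else NULL
  post <- cpp_temporal_grid(cur, pg, fg,
                            present$off_ax, present$off_lat,
                            if (hp) past$off_ax else NULL,
                            if (hp) past$off_lat else NULL,
                            if (hf) future$off_ax else NULL,
                            if (hf) future$off_lat else NULL,
                            sg$st[1], sg$st[2], params$likelihood_floor)
  out <- pdf_grid(post, present$off_ax, present$off_lat, present$time_index)
  if (!hp || !hf) attr(out, "temporal_fallback") <- TRUE
  out
}

#' Simultaneous spatiotemporal Bayesian regularization (STBR-2)
#'
#' Per block at time t, the posterior is proportional to the unregularized
#' prior times the product of the four spatial neighbour likelihoods (widths
#' from \code{sigma_eps}) and the past/future temporal likelihoods (widths
#' from \code{sigma_t}), accumulated in the log domain and renormalized.
#' With both temporal neighbours missing this degrades to
#' \code{\link{sbr_posterior}} (flagged).  As \code{sigma_t} grows to
#' infinity the temporal likelihoods flatten and STBR-2 reduces to SBR.
#'
#' @inheritParams stbr1_posterior
#' @return a \code{pdf_grid} of posteriors at time t
#' @export
stbr2_posterior <- function(past, present, future, params = reg_params(),
                            spacing = c(1, 1), sigma_u = NULL,
                            sigma_t_lags = NULL) {
  stopifnot(inherits(present, "pdf_grid"))
  check_aligned(present, past, future)
  sg <- grid_sigmas(params, spacing, sigma_u, sigma_t_lags)
  hp <- !is.null(past); hf <- !is.null(future)
  post <- cpp_stbr2_grid(present$values,
                         if (hp) past$values else NULL,
                         if (hf) future$values else NULL,
                         present$off_ax, present$off_lat,
                         if (hp) past$off_ax else NULL,
                         if (hp) past$off_lat else NULL,
                         if (hf) future$off_ax else NULL,
                         if (hf) future$off_lat else NULL,
                         sg$su[1], sg$su[2], sg$st[1], sg$st[2],
                         params$n_iterations, params$likelihood_floor)
  out <- pdf_grid(post, present$off_ax, present$off_lat, present$time_index)
  if (!hp && !hf) attr(out, "temporal_fallback") <- TRUE
  out
}

#' Maximum a posteriori displacement with sub-sample precision
#'
#' Reads the displacement off a posterior surface by sinc-interpolated peak
#' refinement (delegates to \code{\link{subsample_peak}}).
#'
#' @param posterior a \code{pdf_surface}, a matrix, or a \code{pdf_grid}
#'   (in which case a matrix of axial and lateral displacements per block is
#'   returned)
#' @param refine_step refinement resolution in lags
#' @export
map_displacement <- function(posterior, refine_step = 0.01) {
  if (inherits(posterior, "pdf_grid")) {
    d <- dim(posterior$values)
    ax <- lat <- matrix(0, d[3], d[4])
    for (bc in seq_len(d[4]))
      for (br in seq_len(d[3])) {
        r <- cpp_subsample_peak(matrix(posterior$values[, , br, bc], d[1]),
                                posterior$off_ax[br, bc],
                                posterior$off_lat[br, bc],
                                refine_step, 8L, FALSE)
        ax[br, bc] <- r[1]; lat[br, bc] <- r[2]
      }
    return(list(axial = ax, lateral = lat))
  }
  subsample_peak(posterior, refine_step = refine_step)
}
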
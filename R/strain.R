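#' Build a myocardial mesh between two wall contours
#'
#' Fills the region between the endocardial and epicardial contours with a
#' transmural x arc-length lattice of material points at end-diastole.
#' Contours are ordered point lists (columns \code{z} axial, \code{x}
#' lateral, in mm) resampled by normalized arc length.  The longitudinal
#' direction at a point is the local mid-wall tangent; the radial direction
#' is its exact 90-degree rotation oriented from endo- to epicardium, so the
#' two are orthonormal by construction.  The wall is divided into six equal
#' arc-length segments labelled 1-6 from base through apex back to base.
#'
#' @param endo_contour,epi_contour matrices or data frames with columns
#'   \code{z}, \code{x} (mm); must not cross
#' @param n_points total number of mesh points; must be a multiple of 6
#' @return a \code{cardiac_mesh}: ED positions \code{z0}, \code{x0},
#'   per-point unit \code{rad} and \code{lon} direction matrices (columns
#'   z, x), \code{segment} labels, lattice dims \code{n_trans},
#'   \code{n_arc}, and empty trajectory slots
#' @export
build_mesh <- function(endo_contour, epi_contour, n_points = 600) {
  en <- as.matrix(as.data.frame(endo_contour)[, c("z", "x")])
  ep <- as.matrix(as.data.frame(epi_contour)[, c("z", "x")])
  if (n_points %% 6 != 0) stop("n_points must be a multiple of 6")
  per_seg <- n_points / 6
  n_trans <- max(which(per_seg %% seq_len(floor(sqrt(per_seg))) == 0))
  n_arc <- n_points / n_trans
  s_arc <- (seq_len(n_arc) - 0.5) / n_arc
  r_tr <- (seq_len(n_trans) - 0.5) / n_trans

  en_s <- contour_at(en, s_arc)
  ep_s <- contour_at(ep, s_arc)
  # tangent of the mid-wall curve, rotated to a radial unit vector
  mid <- (en_s + ep_s) / 2
  tz <- grad_1d(mid[, 1]); tx <- grad_1d(mid[, 2])
  tn <- sqrt(tz^2 + tx^2)
  if (any(tn == 0)) stop("degenerate contour tangent")
  lz <- tz / tn; lx <- tx / tn
  rz <- -lx; rx <- lz
  # orient radial endo -> epi consistently along the wall; a sign change of
  # the transmural direction means the contours cross
  wall_sign <- rz * (ep_s[, 1] - en_s[, 1]) + rx * (ep_s[, 2] - en_s[, 2])
  if (any(wall_sign == 0) || length(unique(sign(wall_sign))) > 1)
    stop("contours cross or touch")
  if (wall_sign[1] < 0) { rz <- -rz; rx <- -rx }

  idx_arc <- rep(seq_len(n_arc), each = n_trans)
  rr <- rep(r_tr, times = n_arc)
  z0 <- (1 - rr) * en_s[idx_arc, 1] + rr * ep_s[idx_arc, 1]
  x0 <- (1 - rr) * en_s[idx_arc, 2] + rr * ep_s[idx_arc, 2]
  seg <- ceiling(idx_arc / (n_arc / 6))
  mesh <- list(z0 = z0, x0 = x0,
               rad = cbind(z = rz[idx_arc], x = rx[idx_arc]),
               lon = cbind(z = lz[idx_arc], x = lx[idx_arc]),
               segment = as.integer(seg),
               n_trans = n_trans, n_arc = n_arc,
               traj_z = NULL, traj_x = NULL, frozen = NULL)
  class(mesh) <- "cardiac_mesh"
  mesh
}

# resample an ordered contour at normalized arc-length positions
contour_at <- function(P, s) {
  d <- sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)
  cs <- c(0, cumsum(d))
  if (cs[length(cs)] == 0) stop("degenerate contour")
  cs <- cs / cs[length(cs)]
  cbind(approx(cs, P[, 1], xout = s, rule = 2)$y,
        approx(cs, P[, 2], xout = s, rule = 2)$y)
}

grad_1d <- function(v) {
  n <- length(v)
  if (n == 1) return(0)
  c(v[2] - v[1], if (n > 2) (v[3:n] - v[1:(n - 2)]) / 2 else NULL,
    v[n] - v[n - 1])
}

#' @export
print.cardiac_mesh <- function(x, ...) {
  cat(sprintf("<cardiac_mesh> %d points (%d transmural x %d arc), 6 segments%s\n",
              length(x$z0), x$n_trans, x$n_arc,
              if (is.null(x$traj_z)) "" else
                sprintf(", tracked over %d frames", ncol(x$traj_z))))
  invisible(x)
}

#' Median-filter a displacement field
#'
#' Component-wise 2-D median filtering over the block grid with edge
#' replication, removing outlier displacement vectors before Lagrangian
#' accumulation.
#'
#' @param field a \code{displacement_field}
#' @param kernel odd window dims \code{c(axial, lateral)}; 5 x 5 by default
#' @export
median_filter_field <- function(field, kernel = c(5, 5)) {
  if (any(kernel %% 2 != 1)) stop("median filter kernel dims must be odd")
  field$ax <- median2d(field$ax, kernel)
  field$lat <- median2d(field$lat, kernel)
  field
}

median2d <- function(m, kernel) {
  nr <- nrow(m); nc <- ncol(m)
  ha <- (kernel[1] - 1) / 2; hl <- (kernel[2] - 1) / 2
  pr <- c(rep(1, ha), seq_len(nr), rep(nr, ha))
  pc <- c(rep(1, hl), seq_len(nc), rep(nc, hl))
  pm <- m[pr, pc, drop = FALSE]
  out <- m
  for (j in seq_len(nc))
    for (i in seq_len(nr))
      out[i, j] <- median(pm[i:(i + 2 * ha), j:(j + 2 * hl)])
  out
}

#' Accumulate inter-frame displacements along tracked material points
#'
#' Lagrangian description of motion starting from end-diastole: each mesh
#' point's position is advanced per frame by the inter-frame displacement
#' field bilinearly interpolated from the block grid to the tracked
#' position.  Points leaving the block grid's bounding box are frozen and
#' flagged.
#'
#' @param mesh a \code{\link{build_mesh}} result
#' @param fields list of \code{displacement_field}s for pairs
#'   (0,1), (1,2), ... starting at ED
#' @return the mesh with \code{traj_z}, \code{traj_x} (points x frames,
#'   mm, first column = ED) and \code{frozen} filled
#' @export
accumulate_lagrangian <- function(mesh, fields) {
  n <- length(mesh$z0)
  nf <- length(fields) + 1
  tz <- matrix(0, n, nf); tx <- matrix(0, n, nf)
  tz[, 1] <- mesh$z0; tx[, 1] <- mesh$x0
  frozen <- rep(FALSE, n)
  for (t in seq_along(fields)) {
    f <- fields[[t]]
    pos <- field_positions_mm(f)
    dm <- field_mm(f)
    z <- tz[, t]; x <- tx[, t]
    out <- z < min(pos$z) | z > max(pos$z) | x < min(pos$x) | x > max(pos$x)
    frozen <- frozen | out
    dz <- interp_grid(dm$dz, pos$z, pos$x, z, x)
    dx <- interp_grid(dm$dx, pos$z, pos$x, z, x)
    dz[frozen] <- 0; dx[frozen] <- 0
    tz[, t + 1] <- z + dz
    tx[, t + 1] <- x + dx
  }
  mesh$traj_z <- tz; mesh$traj_x <- tx; mesh$frozen <- frozen
  mesh
}

#' Least-squares Lagrangian strain tensor at one frame
#'
#' Fits the accumulated displacement components (tracked position minus ED
#' position) as affine functions of ED position over the neighbours inside
#' an axial x lateral kernel, by ordinary least squares.  The strain tensor
#' is the symmetric part of the fitted displacement gradient (infinitesimal
#' strain); set \code{finite = TRUE} to add the Green-Lagrange quadratic
#' term.  Points with fewer than 6 usable neighbours, or rank-deficient
#' neighbourhoods, are flagged and their strain left undefined.
#'
#' @param mesh a tracked mesh (see \code{\link{accumulate_lagrangian}})
#' @param frame_index frame (0 = ED) whose accumulated displacement is used
#' @param kernel_mm kernel dims \code{c(axial, lateral)} in mm
#' @param finite include the quadratic finite-strain term
#' @return a \code{strain_record}: per-point tensor components \code{E_zz},
#'   \code{E_zx}, \code{E_xx}, \code{flags}, \code{frame_index}
#' @export
ls_strain_tensor <- function(mesh, frame_index, kernel_mm = c(0.5, 1),
                             finite = FALSE) {
  if (is.null(mesh$traj_z)) stop("mesh has no trajectories; run accumulate_lagrangian first")
  n <- length(mesh$z0)
  uz <- mesh$traj_z[, frame_index + 1] - mesh$z0
  ux <- mesh$traj_x[, frame_index + 1] - mesh$x0
  hz <- kernel_mm[1] / 2; hx <- kernel_mm[2] / 2
  Ezz <- Ezx <- Exx <- rep(NA_real_, n)
  flags <- rep(FALSE, n)
  z0 <- mesh$z0; x0 <- mesh$x0
  usable <- !mesh$frozen
  for (p in seq_len(n)) {
    nb <- which(abs(z0 - z0[p]) <= hz & abs(x0 - x0[p]) <= hx & usable)
    if (length(nb) < 6) { flags[p] <- TRUE; next }
    A <- cbind(1, z0[nb] - z0[p], x0[nb] - x0[p])
    fit <- tryCatch(qr(A), error = function(e) NULL)
    if (is.null(fit) || fit$rank < 3) { flags[p] <- TRUE; next }
    cf <- qr.coef(fit, cbind(uz[nb], ux[nb]))
    G <- rbind(cf[2:3, 1], cf[2:3, 2])  # G[i,j] = d u_i / d x_j, (z, x)
    E <- (G + t(G)) / 2
    if (finite) E <- E + 0.5 * t(G) %*% G
    Ezz[p] <- E[1, 1]; Ezx[p] <- E[1, 2]; Exx[p] <- E[2, 2]
  }
  flags <- flags | mesh$frozen
  rec <- list(E_zz = Ezz, E_zx = Ezx, E_xx = Exx,
              e_r = NULL, e_l = NULL, flags = flags,
              frame_index = frame_index)
  class(rec) <- "strain_record"
  rec
}

#' Radial and longitudinal strain by coordinate transformation
#'
#' Projects the strain tensor onto the per-point wall directions:
#' \code{e_r = r' E r}, \code{e_l = l' E l} with unit radial \code{r} and
#' longitudinal \code{l} vectors from the mesh.
#'
#' @param record a \code{strain_record} with tensor components filled
#' @param mesh the mesh carrying \code{rad} and \code{lon} wall frames
#' @return the record with \code{e_r} and \code{e_l} filled (unitless)
#' @export
transform_strain <- function(record, mesh) {
  r <- mesh$rad; l <- mesh$lon
  if (any(abs(rowSums(r^2) - 1) > 1e-9) || any(abs(rowSums(l^2) - 1) > 1e-9))
    stop("wall direction vectors must be unit length")
  quad <- function(v)
    v[, 1]^2 * record$E_zz + 2 * v[, 1] * v[, 2] * record$E_zx +
      v[, 2]^2 * record$E_xx
  record$e_r <- quad(r)
  record$e_l <- quad(l)
  record
}

#' Segmental strain curves over the cardiac cycle
#'
#' Per segment and frame, the mean radial and longitudinal strain over
#' non-flagged mesh points.  Curves start at exactly 0 at end-diastole.
#'
#' @param records list of \code{strain_record}s, one per frame starting at
#'   ED (frame 0)
#' @param mesh the segmented mesh
#' @return list with matrices \code{e_r} and \code{e_l}
#'   (frames x 6 segments) and \code{empty} flags for segments with no
#'   usable points
#' @export
segment_strain_curves <- function(records, mesh) {
  nf <- length(records)
  er <- el <- matrix(0, nf, 6)
  empty <- rep(FALSE, 6)
  for (s in 1:6) {
    in_seg <- mesh$segment == s
    if (!any(in_seg)) { empty[s] <- TRUE; er[, s] <- el[, s] <- NA; next }
    for (t in seq_len(nf)) {
      rec <- records[[t]]
      if (rec$frame_index == 0) next  # ED reference: strain 0 by construction
      ok <- in_seg & !rec$flags
      if (!any(ok)) { er[t, s] <- el[t, s] <- NA; next }
      er[t, s] <- mean(rec$e_r[ok])
      el[t, s] <- mean(rec$e_l[ok])
    }
  }
  list(e_r = er, e_l = el, empty = empty)
}
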
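#' Imaging configuration for the synthetic RF phantom
#'
#' Describes a linear-array acquisition: centre frequency, RF sampling
#' frequency, element pitch, speed of sound, fractional pulse bandwidth and
#' the imaged field of view.  The axial sample spacing is
#' \code{c/(2 fs)} (two-way travel) and the RF carrier completes one cycle
#' every \code{fs/f0} samples.
#'
#' @param center_frequency transducer centre frequency (MHz)
#' @param sampling_frequency RF sampling frequency (MHz); must exceed twice
#'   the centre frequency
#' @param pitch A-line spacing (mm)
#' @param speed_of_sound assumed sound speed (m/s)
#' @param psf_bandwidth fractional -6 dB bandwidth of the Gaussian pulse
#' @param lines number of A-lines
#' @param depth imaged depth (mm)
#' @param lateral_sigma lateral Gaussian beam width (mm); defaults to twice
#'   the pitch
#' @return an object of class \code{imaging_config}
#' @export
imaging_config <- function(center_frequency = 8, sampling_frequency = 78.84,
                           pitch = 0.2, speed_of_sound = 1540,
                           psf_bandwidth = 0.6, lines = 32, depth = 6,
                           lateral_sigma = NULL) {
  stopifnot(center_frequency > 0, pitch > 0, speed_of_sound > 0,
            psf_bandwidth > 0, lines >= 1, depth > 0)
  if (sampling_frequency <= 2 * center_frequency)
    stop("sampling_frequency must exceed twice the center_frequency")
  if (is.null(lateral_sigma)) lateral_sigma <- 2 * pitch
  cfg <- list(f0 = center_frequency, fs = sampling_frequency, pitch = pitch,
              c = speed_of_sound, bandwidth = psf_bandwidth, lines = lines,
              depth = depth, lateral_sigma = lateral_sigma)
  class(cfg) <- "imaging_config"
  cfg
}

# axial sample spacing in mm (two-way)
axial_dz_mm <- function(cfg) cfg$c / (2 * cfg$fs * 1000)

# Gaussian envelope sigma in axial samples from the -6 dB fractional bandwidth
axial_sigma_samples <- function(cfg) {
  cfg$fs * sqrt(2 * log(2)) / (pi * cfg$bandwidth * cfg$f0)
}

#' Generate a random point-scatterer field
#'
#' Scatterer count is Poisson with mean \code{density * area}; positions are
#' uniform over the region and reflectivities are standard normal, giving
#' fully developed speckle when the density exceeds roughly ten scatterers
#' per resolution cell.
#'
#' @param region bounding box \code{c(z0, z1, x0, x1)} in mm
#'   (axial from, axial to, lateral from, lateral to)
#' @param density_per_mm2 expected scatterers per square millimetre (> 0)
#' @param seed RNG seed; identical seeds give identical fields
#' @return an object of class \code{scatterer_field} with elements
#'   \code{z}, \code{x} (mm), \code{amp} and \code{region}
#' @export
generate_scatterers <- function(region, density_per_mm2, seed) {
  stopifnot(length(region) == 4)
  if (region[2] <= region[1] || region[4] <= region[3])
    stop("degenerate scatterer region")
  if (density_per_mm2 <= 0) stop("scatterer density must be positive")
  area <- (region[2] - region[1]) * (region[4] - region[3])
  set.seed(seed)
  n <- rpois(1, density_per_mm2 * area)
  fld <- list(z = runif(n, region[1], region[2]),
              x = runif(n, region[3], region[4]),
              amp = rnorm(n), region = region)
  class(fld) <- "scatterer_field"
  fld
}

#' Prescribed motion model for the phantom
#'
#' Three kinds are supported. \code{rigid_shift} translates the whole field by
#' \code{shift} mm per frame.  \code{uniform_strain} applies a cumulative
#' strain of \code{rate * frame} about \code{center}, per axis.
#' \code{cyclic_wall} applies a cyclic strain
#' \code{peak * sin(pi * frame / cycle_frames)^2} about the wall centre, so
#' the deformation returns exactly to identity at the cycle end.
#'
#' @param kind one of \code{"rigid_shift"}, \code{"uniform_strain"},
#'   \code{"cyclic_wall"}
#' @param shift per-frame shift \code{c(axial, lateral)} in mm (rigid)
#' @param rate per-frame strain \code{c(axial, lateral)} (uniform)
#' @param peak peak strain \code{c(axial, lateral)} at mid cycle (cyclic)
#' @param cycle_frames cycle length in frames (cyclic)
#' @param center strain centre \code{c(z, x)} in mm
#' @param frame_rate acquisition frame rate (Hz), metadata only
#' @return an object of class \code{motion_model}
#' @export
motion_model <- function(kind = c("rigid_shift", "uniform_strain", "cyclic_wall"),
                         shift = c(0, 0), rate = c(0, 0), peak = c(0, 0),
                         cycle_frames = 20, center = c(0, 0), frame_rate = 250) {
  kind <- match.arg(kind)
  if (kind == "cyclic_wall" && cycle_frames < 2)
    stop("cycle_frames must be at least 2")
  m <- list(kind = kind, shift = shift, rate = rate, peak = peak,
            cycle_frames = cycle_frames, center = center,
            frame_rate = frame_rate)
  class(m) <- "motion_model"
  m
}

#' Cumulative strain of a motion model at a frame
#'
#' Returns \code{c(axial, lateral)} engineering strain of the mapping from
#' frame 0 to \code{frame}; zero for rigid motion.
#' @param model a \code{\link{motion_model}}
#' @param frame frame index (0 = reference)
#' @export
motion_strain <- function(model, frame) {
  switch(model$kind,
         rigid_shift = c(0, 0),
         uniform_strain = model$rate * frame,
         cyclic_wall = model$peak * sin(pi * frame / model$cycle_frames)^2)
}

# cumulative displacement (mm) of material at reference position (z, x)
motion_disp <- function(model, z, x, frame) {
  if (model$kind == "rigid_shift") {
    list(dz = rep(model$shift[1] * frame, length(z)),
         dx = rep(model$shift[2] * frame, length(x)))
  } else {
    e <- motion_strain(model, frame)
    list(dz = (z - model$center[1]) * e[1], dx = (x - model$center[2]) * e[2])
  }
}

#' Deform a scatterer field to a given frame
#'
#' Positions are mapped by the model's cumulative displacement at
#' \code{frame_index}; amplitudes are unchanged.  Scatterers mapped outside
#' the field's region expanded by \code{guard_mm} are dropped (their count is
#' reported via a message).
#'
#' @param field a \code{\link{generate_scatterers}} result
#' @param motion a \code{\link{motion_model}}
#' @param frame_index frame to deform to (0 returns the field unchanged)
#' @param guard_mm guard margin beyond the region before dropping (mm)
#' @export
deform_scatterers <- function(field, motion, frame_index, guard_mm = 2) {
  if (motion$kind == "cyclic_wall" &&
      (frame_index < 0 || frame_index > motion$cycle_frames))
    stop("frame_index outside the motion cycle")
  d <- motion_disp(motion, field$z, field$x, frame_index)
  z <- field$z + d$dz
  x <- field$x + d$dx
  r <- field$region
  keep <- z >= r[1] - guard_mm & z <= r[2] + guard_mm &
          x >= r[3] - guard_mm & x <= r[4] + guard_mm
  if (any(!keep))
    message(sum(!keep), " scatterer(s) left the guard region and were dropped")
  out <- list(z = z[keep], x = x[keep], amp = field$amp[keep], region = r)
  class(out) <- "scatterer_field"
  out
}

#' Simulate one noiseless RF frame
#'
#' Convolutional speckle model: the RF value at (sample, line) is the sum over
#' scatterers of reflectivity times a separable point-spread function --
#' Gaussian envelope modulated by a cosine carrier at the centre frequency
#' axially, Gaussian laterally.  Deterministic given the scatterer field.
#'
#' @param field a \code{scatterer_field} (positions in mm)
#' @param cfg an \code{\link{imaging_config}}
#' @param frame_index stored in the frame metadata
#' @return an \code{rf_frame}: list with \code{samples} (axial sample x
#'   A-line matrix), \code{fs}, \code{pitch}, \code{f0}, \code{c},
#'   \code{frame_index}
#' @export
simulate_rf_frame <- function(field, cfg, frame_index = 0L) {
  stopifnot(inherits(cfg, "imaging_config"))
  dz <- axial_dz_mm(cfg)
  n_samp <- round(cfg$depth / dz)
  samples <- cpp_render_rf(field$z / dz, field$x / cfg$pitch, field$amp,
                           n_samp, cfg$lines, 2 * pi * cfg$f0 / cfg$fs,
                           axial_sigma_samples(cfg),
                           cfg$lateral_sigma / cfg$pitch)
  rf_frame(samples, cfg, frame_index)
}

rf_frame <- function(samples, cfg, frame_index = 0L) {
  f <- list(samples = samples, fs = cfg$fs, pitch = cfg$pitch, f0 = cfg$f0,
            c = cfg$c, frame_index = as.integer(frame_index))
  class(f) <- "rf_frame"
  f
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d samples x %d lines, fs = %g MHz, pitch = %g mm\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$pitch))
  invisible(x)
}

# add white Gaussian noise to `samples` so that the power ratio measured in
# the reference ROI equals snr_db; returns the noisy matrix
awgn_apply <- function(samples, snr_db, roi, rows = NULL) {
  if (is.infinite(snr_db) && snr_db > 0) return(samples)
  p_sig <- mean(samples[roi$rows, roi$cols]^2)
  sdn <- sqrt(p_sig / 10^(snr_db / 10))
  if (is.null(rows)) rows <- seq_len(nrow(samples))
  noise <- matrix(rnorm(length(rows) * ncol(samples), sd = sdn),
                  nrow = length(rows))
  samples[rows, ] <- samples[rows, ] + noise
  samples
}

#' Superimpose additive white Gaussian noise at a prescribed sonographic SNR
#'
#' The noise variance is set so that
#' \code{10 log10(signal power in ROI / noise power) = snr_db}, with the
#' signal power measured over the noiseless frame in the reference ROI.
#'
#' @param frame an \code{rf_frame}
#' @param snr_db sonographic SNR in dB; \code{Inf} returns the frame unchanged
#' @param reference_roi list with integer vectors \code{rows} and \code{cols}
#' @param seed RNG seed
#' @export
add_awgn <- function(frame, snr_db, reference_roi, seed = NULL) {
  stopifnot(inherits(frame, "rf_frame"))
  if (!is.finite(snr_db) && snr_db < 0) stop("snr_db must be finite or +Inf")
  if (length(reference_roi$rows) == 0 || length(reference_roi$cols) == 0)
    stop("empty reference ROI")
  if (max(reference_roi$rows) > nrow(frame$samples) ||
      max(reference_roi$cols) > ncol(frame$samples))
    stop("reference ROI outside the frame")
  if (!is.null(seed)) set.seed(seed)
  frame$samples <- awgn_apply(frame$samples, snr_db, reference_roi)
  frame
}

#' Scene description for the synthetic phantom
#'
#' Bundles the imaging configuration, the motion model, the myocardial wall
#' band used for meshing and noise bands.  Each noise band applies AWGN at its
#' own sonographic SNR to a range of depth samples, with the reference ROI
#' measured on the noiseless frame; this reproduces depth-dependent SNR (for
#' example an anterior/posterior split) without modelling attenuation.
#'
#' @param imaging an \code{\link{imaging_config}}
#' @param motion a \code{\link{motion_model}}
#' @param n_frames number of frames to simulate (at least 4)
#' @param density scatterers per square millimetre
#' @param wall axial band \code{c(z_from, z_to)} mm defining the wall
#' @param snr_bands list of bands, each a list with \code{snr_db},
#'   optional \code{rows} (default: all) and optional \code{roi};
#'   defaults to a single noiseless band
#' @param guard_mm scatterer guard margin beyond the field of view (mm)
#' @export
phantom_scene <- function(imaging = imaging_config(),
                          motion = motion_model("cyclic_wall",
                                                peak = c(0.04, -0.02),
                                                cycle_frames = 16,
                                                center = c(imaging$depth / 2,
                                                           imaging$lines * imaging$pitch / 2)),
                          n_frames = motion$cycle_frames + 1,
                          density = 30, wall = NULL, snr_bands = NULL,
                          guard_mm = 2) {
  if (is.null(wall)) wall <- imaging$depth / 2 + c(-1, 1) * imaging$depth / 8
  sc <- list(imaging = imaging, motion = motion, n_frames = n_frames,
             density = density, wall = wall, snr_bands = snr_bands,
             guard_mm = guard_mm)
  class(sc) <- "phantom_scene"
  sc
}

#' Generate an RF sequence with ground truth
#'
#' Draws one scatterer realization, deforms it per frame with the scene's
#' motion model, renders noiseless RF and superimposes AWGN per noise band.
#' At least four frames are required: the spatiotemporal regularizers need
#' four consecutive RF frames to form the minimum set of three similarity
#' surfaces in time.
#'
#' @param scene a \code{\link{phantom_scene}}
#' @param seed RNG seed; the whole sequence is a pure function of
#'   (scene, seed)
#' @return list with \code{frames} (list of \code{rf_frame}),
#'   \code{truth} (a \code{ground_truth} object) and \code{scene}
#' @export
generate_sequence <- function(scene, seed = 1) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (scene$n_frames < 4)
    stop("at least 4 frames are required (STBR needs four consecutive RF frames)")
  cfg <- scene$imaging
  dz <- axial_dz_mm(cfg)
  n_samp <- round(cfg$depth / dz)
  width <- cfg$lines * cfg$pitch
  region <- c(-scene$guard_mm, cfg$depth + scene$guard_mm,
              -scene$guard_mm, width + scene$guard_mm)
  field0 <- generate_scatterers(region, scene$density, seed)
  bands <- scene$snr_bands
  if (is.null(bands)) bands <- list(list(snr_db = Inf))
  frames <- vector("list", scene$n_frames)
  for (f in seq_len(scene$n_frames) - 1L) {
    fld <- suppressMessages(
      deform_scatterers(field0, scene$motion, f, guard_mm = scene$guard_mm))
    fr <- simulate_rf_frame(fld, cfg, frame_index = f)
    for (b in bands) {
      if (is.infinite(b$snr_db) && b$snr_db > 0) next
      rows <- if (is.null(b$rows)) seq_len(n_samp) else b$rows
      roi <- b$roi
      if (is.null(roi)) {
        qr <- range(rows)
        roi <- list(rows = seq(qr[1] + floor(diff(qr) / 4),
                               qr[2] - floor(diff(qr) / 4)),
                    cols = seq(max(1, floor(cfg$lines / 4)),
                               ceiling(3 * cfg$lines / 4)))
      }
      fr$samples <- awgn_apply(fr$samples, b$snr_db, roi, rows)
    }
    frames[[f + 1L]] <- fr
  }
  truth <- list(motion = scene$motion, scene = scene)
  class(truth) <- "ground_truth"
  list(frames = frames, truth = truth, scene = scene)
}

#' Ground-truth displacement between consecutive frames at lab positions
#'
#' Displacement (mm) experienced between \code{frame} and \code{frame + 1}
#' by the material located at lab position (z, x) at \code{frame}; this is
#' what inter-frame block matching measures.
#'
#' @param truth a \code{ground_truth} object
#' @param z,x lab positions (mm) at \code{frame}
#' @param frame first frame of the pair (0-based)
#' @return list with \code{dz}, \code{dx} in mm
#' @export
truth_pair_disp <- function(truth, z, x, frame) {
  m <- truth$motion
  if (m$kind == "rigid_shift")
    return(list(dz = rep(m$shift[1], length(z)), dx = rep(m$shift[2], length(x))))
  e0 <- motion_strain(m, frame)
  e1 <- motion_strain(m, frame + 1)
  list(dz = (z - m$center[1]) * (e1[1] - e0[1]) / (1 + e0[1]),
       dx = (x - m$center[2]) * (e1[2] - e0[2]) / (1 + e0[2]))
}

#' Ground-truth cumulative displacement from the reference frame
#'
#' @param truth a \code{ground_truth} object
#' @param z0,x0 material (frame-0) positions in mm
#' @param frame target frame
#' @export
truth_cum_disp <- function(truth, z0, x0, frame) {
  motion_disp(truth$motion, z0, x0, frame)
}

#' Ground-truth cumulative strain tensor components at a frame
#'
#' For the affine motion models the Lagrangian strain tensor is spatially
#' uniform: \code{diag(e_axial, e_lateral)}.
#' @param truth a \code{ground_truth} object
#' @param frame target frame
#' @return \code{c(e_axial, e_lateral)}
#' @export
truth_strain <- function(truth, frame) {
  motion_strain(truth$motion, frame)
}
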
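#' Pipeline configuration
#'
#' Bundles the per-stage configurations of the end-to-end pipeline
#' (phantom -> tracking -> Lagrangian strain -> evaluation).  All randomness
#' derives from the single \code{seed}.
#'
#' @param scene a \code{\link{phantom_scene}}
#' @param bm a \code{\link{bm_config}}
#' @param reg a \code{\link{reg_params}}
#' @param regularizer \code{"none"}, \code{"sbr"}, \code{"stbr1"} or
#'   \code{"stbr2"}
#' @param mesh_points mesh size (multiple of 6)
#' @param ls_kernel_mm least-squares strain kernel \code{c(axial, lateral)} mm
#' @param median_kernel median filter dims \code{c(axial, lateral)}
#' @param snr_window elastographic SNR window (mesh points)
#' @param seed root RNG seed
#' @param out_dir optional output directory for artifacts
#' @export
pipeline_config <- function(scene = phantom_scene(), bm = bm_config(),
                            reg = reg_params(),
                            regularizer = c("stbr2", "none", "sbr", "stbr1"),
                            mesh_points = 600, ls_kernel_mm = c(0.5, 1),
                            median_kernel = c(5, 5), snr_window = c(5, 9),
                            seed = 1, out_dir = NULL) {
  regularizer <- match.arg(regularizer)
  if (regularizer %in% c("stbr1", "stbr2") && scene$n_frames < 4)
    stop("spatiotemporal regularization requires a scene with at least 4 frames")
  cfg <- list(scene = scene, bm = bm, reg = reg, regularizer = regularizer,
              mesh_points = mesh_points, ls_kernel_mm = ls_kernel_mm,
              median_kernel = median_kernel, snr_window = snr_window,
              seed = seed, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file with optional sections \code{scene} (with nested
#' \code{imaging} and \code{motion}), \code{bm}, \code{reg} and top-level
#' keys matching \code{\link{pipeline_config}} arguments; unspecified values
#' keep their defaults.
#'
#' @param path YAML file path
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc_y <- y[["scene"]] %||% list()
  imaging <- do.call(imaging_config, sc_y[["imaging"]] %||% list())
  motion <- if (is.null(sc_y[["motion"]])) NULL else
    do.call(motion_model, lapply(sc_y[["motion"]], unlist_num))
  sargs <- sc_y
  sargs$imaging <- imaging
  if (!is.null(motion)) sargs$motion <- motion
  scene <- do.call(phantom_scene, sargs)
  args <- list(scene = scene,
               bm = do.call(bm_config, lapply(y[["bm"]] %||% list(), unlist_num)),
               reg = do.call(reg_params, lapply(y[["reg"]] %||% list(), unlist_num)))
  for (k in c("regularizer", "mesh_points", "ls_kernel_mm", "median_kernel",
              "snr_window", "seed", "out_dir"))
    if (!is.null(y[[k]])) args[[k]] <- unlist_num(y[[k]])
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
unlist_num <- function(x) if (is.list(x)) unlist(x) else x

# straight wall-band contours spanning the lateral coverage of the block grid
wall_contours <- function(scene, field) {
  pos <- field_positions_mm(field)
  xr <- range(pos$x)
  xs <- seq(xr[1], xr[2], length.out = 50)
  list(endo = data.frame(z = rep(scene$wall[2], 50), x = xs),
       epi = data.frame(z = rep(scene$wall[1], 50), x = xs))
}

#' Run the end-to-end strain estimation pipeline
#'
#' Generates the phantom sequence, estimates inter-frame displacement with
#' the configured regularizer, median-filters the fields, accumulates them
#' along a wall mesh from end-diastole, derives least-squares Lagrangian
#' strain with radial/longitudinal decomposition and segmental curves, and
#' evaluates against the phantom ground truth (strain bias, normalized
#' strain error, per-segment TTR, displacement RMSE).  Deterministic given
#' (config, seed); artifacts are written when \code{out_dir} is set.
#'
#' @param config a \code{\link{pipeline_config}}
#' @return report list with \code{fields}, \code{mesh}, \code{records},
#'   \code{curves}, \code{truth_curves}, \code{metrics}, \code{flag_counts}
#'   and the serialized \code{config}
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))

  seq <- stage("phantom", generate_sequence(config$scene, config$seed))
  fields <- stage("tracking",
                  track_sequence(seq$frames, config$bm, config$regularizer,
                                 config$reg))
  fields <- stage("median_filter",
                  lapply(fields, median_filter_field, kernel = config$median_kernel))
  ct <- stage("mesh", wall_contours(config$scene, fields[[1]]))
  mesh <- stage("mesh", build_mesh(ct$endo, ct$epi, config$mesh_points))
  mesh <- stage("accumulate", accumulate_lagrangian(mesh, fields))
  nf <- length(seq$frames)
  records <- stage("strain", lapply(seq_len(nf) - 1L, function(t)
    transform_strain(ls_strain_tensor(mesh, t, config$ls_kernel_mm), mesh)))
  curves <- stage("curves", segment_strain_curves(records, mesh))
  ev <- stage("evaluation",
              evaluate_against_truth(seq$truth, fields, records, curves, mesh,
                                     config))
  report <- list(fields = fields, mesh = mesh, records = records,
                 curves = curves, truth_curves = ev$truth_curves,
                 metrics = ev$metrics,
                 flag_counts = vapply(fields, function(f) sum(f$flags), 0),
                 config = jsonlite::toJSON(serialize_config(config),
                                           auto_unbox = TRUE, digits = NA))
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# metrics against the analytic phantom ground truth; strains in percent
evaluate_against_truth <- function(truth, fields, records, curves, mesh, config) {
  nf <- length(records)
  wall <- config$scene$wall
  # per-point true radial/longitudinal strain from the (diagonal) tensor
  er_true_pt <- function(e) mesh$rad[, 1]^2 * e[1] + mesh$rad[, 2]^2 * e[2]
  el_true_pt <- function(e) mesh$lon[, 1]^2 * e[1] + mesh$lon[, 2]^2 * e[2]
  bias_r <- dle_r <- bias_l <- dle_l <- c()
  max_err_r <- 0
  for (t in 2:nf) {
    e <- truth_strain(truth, t - 1)
    rec <- records[[t]]
    ok <- !rec$flags
    if (!any(ok)) next
    max_err_r <- max(max_err_r, abs(100 * er_true_pt(e)[ok] - 100 * rec$e_r[ok]))
    bias_r <- c(bias_r, strain_bias(100 * er_true_pt(e)[ok], 100 * rec$e_r[ok]))
    bias_l <- c(bias_l, strain_bias(100 * el_true_pt(e)[ok], 100 * rec$e_l[ok]))
    if (max(abs(e)) < 1e-12) next  # normalized errors undefined against zero truth
    dle_r <- c(dle_r, normalized_error(100 * er_true_pt(e)[ok], 100 * rec$e_r[ok]))
    dle_l <- c(dle_l, normalized_error(100 * el_true_pt(e)[ok], 100 * rec$e_l[ok]))
  }
  # true segmental curves (uniform across segments for affine motion)
  es <- t(vapply(seq_len(nf) - 1L, function(f) truth_strain(truth, f), c(0, 0)))
  seg_mean <- function(col) {
    m <- matrix(NA_real_, nf, 6)
    for (s in 1:6) {
      in_seg <- mesh$segment == s
      m[, s] <- vapply(seq_len(nf), function(t)
        mean(if (col == "r") er_true_pt(es[t, ])[in_seg]
             else el_true_pt(es[t, ])[in_seg]), 0)
    }
    m * 100
  }
  tc <- list(e_r = seg_mean("r"), e_l = seg_mean("l"))
  ttr_r <- ttr_l <- rep(NA_real_, 6)
  for (s in 1:6) {
    if (sum(abs(tc$e_r[, s]), na.rm = TRUE) > 0)
      ttr_r[s] <- ttr(tc$e_r[, s], 100 * curves$e_r[, s])
    if (sum(abs(tc$e_l[, s]), na.rm = TRUE) > 0)
      ttr_l[s] <- ttr(tc$e_l[, s], 100 * curves$e_l[, s])
  }
  # displacement RMSE (mm) over unflagged wall blocks, both components
  se <- n_se <- 0
  for (f in fields) {
    pos <- field_positions_mm(f)
    dm <- field_mm(f)
    tr <- truth_pair_disp(truth, rep(pos$z, times = length(pos$x)),
                          rep(pos$x, each = length(pos$z)), f$frame_pair[1])
    in_wall <- rep(pos$z >= wall[1] & pos$z <= wall[2], times = length(pos$x))
    ok <- !as.vector(f$flags) & in_wall
    se <- se + sum((as.vector(dm$dz)[ok] - tr$dz[ok])^2 +
                   (as.vector(dm$dx)[ok] - tr$dx[ok])^2)
    n_se <- n_se + sum(ok)
  }
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  metrics <- list(
    bias_radial = mean_or_na(bias_r), bias_longitudinal = mean_or_na(bias_l),
    max_abs_err_radial = max_err_r,
    delta_eps_radial = mean_or_na(dle_r),
    delta_eps_longitudinal = mean_or_na(dle_l),
    ttr_radial = ttr_r, ttr_longitudinal = ttr_l,
    ttr_radial_mean = mean(ttr_r, na.rm = TRUE),
    ttr_longitudinal_mean = mean(ttr_l, na.rm = TRUE),
    disp_rmse_mm = sqrt(se / max(n_se, 1)))
  list(metrics = metrics, truth_curves = tc)
}

serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  strip(unclass(config))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_along(report$fields))
    save_field(report$fields[[p]], file.path(out_dir, sprintf("disp_%03d", p - 1)))
  cr <- as.data.frame(report$curves$e_r)
  names(cr) <- paste0("segment_", 1:6)
  write.csv(cbind(frame = seq_len(nrow(cr)) - 1, cr),
            file.path(out_dir, "curves_radial.csv"), row.names = FALSE)
  cl <- as.data.frame(report$curves$e_l)
  names(cl) <- paste0("segment_", 1:6)
  write.csv(cbind(frame = seq_len(nrow(cl)) - 1, cl),
            file.path(out_dir, "curves_longitudinal.csv"), row.names = FALSE)
  jsonlite::write_json(list(metrics = report$metrics,
                            flag_counts = report$flag_counts,
                            config = jsonlite::fromJSON(report$config)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
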
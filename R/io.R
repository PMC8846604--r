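#' Save an RF sequence as a directory of CSV frames with a JSON sidecar
#'
#' Each frame is written as a full-precision CSV matrix
#' (\code{frame_000.csv}, ...) plus \code{meta.json} holding the acquisition
#' geometry and a format version tag.  \code{\link{load_rf_sequence}}
#' reproduces values bitwise.
#'
#' @param frames list of \code{rf_frame}s
#' @param dir output directory (created if needed)
#' @export
save_rf_sequence <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames))
    write_mat(frames[[i]]$samples, file.path(dir, sprintf("frame_%03d.csv", i - 1)))
  f1 <- frames[[1]]
  meta <- list(version = "ustrain-1", n_frames = length(frames),
               fs = f1$fs, pitch = f1$pitch, f0 = f1$f0, c = f1$c,
               frame_index = vapply(frames, function(f) f$frame_index, 0L))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load an RF sequence saved by \code{\link{save_rf_sequence}}
#' @param dir directory containing \code{meta.json} and frame CSVs
#' @export
load_rf_sequence <- function(dir) {
  mp <- file.path(dir, "meta.json")
  if (!file.exists(mp)) stop("missing metadata file: ", mp)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  for (key in c("n_frames", "fs", "pitch", "f0", "c"))
    if (is.null(meta[[key]])) stop("RF metadata missing key: ", key)
  check_version(meta$version)
  cfg <- list(fs = meta$fs, pitch = meta$pitch, f0 = meta$f0, c = meta$c)
  lapply(seq_len(meta$n_frames), function(i) {
    s <- read_mat(file.path(dir, sprintf("frame_%03d.csv", i - 1)))
    f <- list(samples = s, fs = cfg$fs, pitch = cfg$pitch, f0 = cfg$f0,
              c = cfg$c, frame_index = as.integer(meta$frame_index[i]))
    class(f) <- "rf_frame"
    f
  })
}

#' Save a displacement field (CSV matrices + JSON metadata)
#'
#' Writes \code{<prefix>_ax.csv}, \code{<prefix>_lat.csv},
#' \code{<prefix>_flags.csv} and \code{<prefix>_meta.json}.
#' @param field a \code{displacement_field}
#' @param prefix file path prefix
#' @export
save_field <- function(field, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  write_mat(field$ax, paste0(prefix, "_ax.csv"))
  write_mat(field$lat, paste0(prefix, "_lat.csv"))
  write_mat(matrix(as.integer(field$flags), nrow(field$ax)),
            paste0(prefix, "_flags.csv"))
  meta <- list(version = "ustrain-1",
               centers_ax = field$centers_ax, centers_lat = field$centers_lat,
               frame_pair = field$frame_pair, geom = field$geom)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Load a displacement field saved by \code{\link{save_field}}
#' @param prefix file path prefix used at save time
#' @export
load_field <- function(prefix) {
  mp <- paste0(prefix, "_meta.json")
  if (!file.exists(mp)) stop("missing metadata file: ", mp)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  for (key in c("centers_ax", "centers_lat", "frame_pair", "geom"))
    if (is.null(meta[[key]])) stop("field metadata missing key: ", key)
  check_version(meta$version)
  ax <- read_mat(paste0(prefix, "_ax.csv"))
  lat <- read_mat(paste0(prefix, "_lat.csv"))
  flags <- read_mat(paste0(prefix, "_flags.csv")) != 0
  displacement_field(ax, lat, meta$centers_ax, meta$centers_lat, flags,
                     meta$frame_pair, as.list(meta$geom))
}

check_version <- function(v) {
  if (is.null(v) || !identical(v, "ustrain-1"))
    warning("unrecognized format version tag '", v,
            "'; attempting best-effort load")
  invisible(v)
}

# full-precision CSV round trip: %.17g preserves doubles bitwise
write_mat <- function(m, path) {
  ch <- matrix(sprintf("%.17g", m), nrow(m))
  utils::write.table(ch, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

read_mat <- function(path) {
  if (!file.exists(path)) stop("missing data file: ", path)
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}
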
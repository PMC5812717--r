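#' Write / read a passive-stretch recording as CSV
#'
#' Plain CSV with two metadata header lines (`# L0_mm=` and `# mass_mg=`)
#' followed by the columns `time_s`, `length_mm`, `force_mN`.
#'
#' @param rec A [stretch_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stretch_csv <- function(rec, path) {
  stopifnot(inherits(rec, "stretch_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# L0_mm=%.10g", rec$L0_mm),
               sprintf("# mass_mg=%.10g", rec$mass_mg)), con)
  utils::write.csv(
    data.frame(time_s = rec$time_s, length_mm = rec$length_mm,
               force_mN = rec$force_mN),
    con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stretch_csv
#' @export
read_stretch_csv <- function(path) {
  hdr <- readLines(path, n = 2L)
  meta <- function(key) {
    line <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(line)) stop("missing metadata line for ", key, call. = FALSE)
    as.numeric(sub(paste0("^# ", key, "="), "", line))
  }
  df <- utils::read.csv(path, comment.char = "#")
  stretch_recording(df$time_s, df$length_mm, df$force_mN,
                    L0_mm = meta("L0_mm"), mass_mg = meta("mass_mg"))
}

#' Write / read a breath log or cohort table as CSV
#'
#' One-line header, one row per minute (breath log) or per animal (cohort).
#'
#' @param x Data.frame to write.
#' @param path File path.
#' @return `path` invisibly (write); data.frame (read).
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Save / load an OCE field as multi-page TIFF plus JSON metadata
#'
#' Each time frame becomes one 32-bit float TIFF page (depth x lateral);
#' acquisition metadata (frame interval, pixel pitches, wavelength,
#' refractive index, mode, direction) goes to a `.json` sidecar next to
#' the TIFF.
#'
#' @param field An `oce_field`.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_oce_tiff <- function(field, path) {
  stopifnot(inherits(field, "oce_field"))
  d <- dim(field$data)
  # TIFF stores samples in [0, 1]; affine-rescale and record the transform
  lo <- min(field$data); hi <- max(field$data)
  span <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[3L]),
                  function(k) (field$data[, , k] - lo) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  acq <- field$acq
  meta <- list(mode = field$mode, direction = field$direction,
               data_offset = lo, data_scale = span,
               frame_interval_s = acq$frame_interval_s,
               axial_pixel_um = acq$axial_pixel_um,
               lateral_pixel_um = acq$lateral_pixel_um,
               n_depth = d[1L], n_lateral = d[2L], n_frames = d[3L],
               displacement_noise_nm = acq$displacement_noise_nm,
               wavelength_nm = acq$wavelength_nm,
               refractive_index = acq$refractive_index)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_oce_tiff
#' @export
read_oce_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  data <- array(0, dim = c(meta$n_depth, meta$n_lateral, meta$n_frames))
  for (k in seq_along(pages)) {
    data[, , k] <- pages[[k]] * meta$data_scale + meta$data_offset
  }
  if (meta$mode == "phase") data <- wrap_phase(data)
  acq <- acquisition_config(
    frame_interval_s = meta$frame_interval_s,
    axial_pixel_um = meta$axial_pixel_um,
    lateral_pixel_um = meta$lateral_pixel_um,
    n_depth = meta$n_depth, n_lateral = meta$n_lateral,
    n_frames = meta$n_frames,
    displacement_noise_nm = meta$displacement_noise_nm,
    wavelength_nm = meta$wavelength_nm,
    refractive_index = meta$refractive_index)
  oce_field(data, mode = meta$mode, acq = acq, direction = meta$direction)
}

#' Save / load an image stack as 16-bit multi-page TIFF
#'
#' @param stack An `image_stack` (intensities in [0, 1]).
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  frames <- if (inherits(stack, "image_stack")) stack$frames else stack
  pages <- lapply(seq_len(dim(frames)[3L]), function(k) frames[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]]
  structure(list(frames = frames, pixel_um = NA_real_, ground_truth = NULL),
            class = "image_stack")
}

#' Write an analysis result as JSON
#'
#' @param x A result object (list-like); classes are dropped.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
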
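# Stack I/O: multi-page 32-bit float TIFF plus a JSON sidecar carrying
# pitches, stage, seed, and the intensity scale factor.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a B-scan stack to disk
#'
#' Frames are stored as a multi-page 32-bit float TIFF. Linear intensities
#' are divided by their maximum before storage (TIFF float samples live in
#' [0, 1]); the scale factor, pitches, stage and seed go into a `<path>.json`
#' sidecar. Writing is deterministic: identical stacks produce identical
#' bytes.
#'
#' @param stack a [bscan_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "bscan_stack"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("directory does not exist: %s", dir)
  scale <- max(stack$frames)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(f) stack$frames[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(n_frames = n_frames(stack),
               n_depth_px = dim(stack$frames)[1],
               n_alines = dim(stack$frames)[2],
               lateral_pitch_um = stack$lateral_pitch_um,
               axial_pitch_um = stack$axial_pitch_um,
               intensity_scale = scale,
               stage = stack$stage, seed = stack$seed)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a B-scan stack written by [write_stack()]
#'
#' @param path TIFF path; the `<path>.json` sidecar must be present (it
#'   carries the pixel pitches and intensity scale) unless both pitches are
#'   given explicitly.
#' @param lateral_pitch_um,axial_pitch_um pitch overrides for foreign TIFFs
#'   without a sidecar.
#' @return a [bscan_stack()].
#' @export
read_stack <- function(path, lateral_pitch_um = NULL, axial_pitch_um = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  has_sidecar <- file.exists(sidecar_path(path))
  if (!has_sidecar && (is.null(lateral_pitch_um) || is.null(axial_pitch_um)))
    stopf(paste("missing sidecar %s: supply lateral_pitch_um and",
                "axial_pitch_um explicitly to read a foreign TIFF"),
          sidecar_path(path))
  meta <- if (has_sidecar) jsonlite::read_json(sidecar_path(path)) else list()
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (has_sidecar && length(pages) != meta$n_frames)
    stopf("corrupt stack: sidecar declares %d frame(s) but TIFF holds %d",
          meta$n_frames, length(pages))
  scale <- meta$intensity_scale %||% 1
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]] * scale
  bscan_stack(frames,
              lateral_pitch_um = lateral_pitch_um %||% meta$lateral_pitch_um,
              axial_pitch_um = axial_pitch_um %||% meta$axial_pitch_um,
              stage = if (!is.null(meta$stage)) meta$stage,
              seed = if (!is.null(meta$seed)) meta$seed)
}
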
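# A-scan pipeline: averaging, smoothing, normalization, peak detection,
# layer thickness, attenuation-coefficient estimation.

#' Averaged A-line (1-D depth profile)
#'
#' @param values non-negative (linear scale) or real (dB scale) intensities,
#'   one per depth pixel.
#' @param scale `"linear"` or `"dB"`.
#' @param axial_pitch_um depth pixel pitch (um/px).
#' @param provenance free-form list (frames averaged, lateral window, ...).
#' @param normalized logical; `TRUE` only after [normalize_aline()].
#' @export
aline <- function(values, scale = c("linear", "dB"), axial_pitch_um,
                  provenance = list(), normalized = FALSE) {
  scale <- match.arg(scale)
  if (!length(values)) stopf("aline must have length > 0")
  if (scale == "linear" && any(values < 0)) stopf("linear-scale aline must be >= 0")
  if (axial_pitch_um <= 0) stopf("axial_pitch_um must be > 0")
  structure(list(values = as.numeric(values), scale = scale,
                 axial_pitch_um = axial_pitch_um, provenance = provenance,
                 normalized = isTRUE(normalized)),
            class = "aline")
}

#' @export
print.aline <- function(x, ...) {
  cat(sprintf("<aline> %d depth px (%.3f um/px), %s scale%s\n",
              length(x$values), x$axial_pitch_um, x$scale,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Pixelwise mean image across the frames of a stack
#'
#' @param stack a [bscan_stack()] with at least one frame.
#' @return depth x width matrix (linear scale).
#' @export
average_frames <- function(stack) {
  stopifnot(inherits(stack, "bscan_stack"))
  if (n_frames(stack) < 1) stopf("stack is empty")
  rowMeans(stack$frames, dims = 2)
}

#' Laterally averaged A-line from a B-scan image
#'
#' Averages `count` adjacent A-lines (columns). By default the window is
#' centered in the image, following the convention of averaging 100 central
#' A-lines of the frame-averaged B-scan.
#'
#' @param image depth x width matrix, linear scale.
#' @param axial_pitch_um depth pixel pitch (um/px).
#' @param start_aline first column of the window (1-based); `NULL` centers it.
#' @param count number of columns to average.
#' @return an [aline()] (linear scale) with provenance recorded.
#' @export
extract_averaged_aline <- function(image, axial_pitch_um, start_aline = NULL,
                                   count = 100L) {
  if (!is.matrix(image)) stopf("image must be a matrix")
  if (!is_count(count) || count > ncol(image))
    stopf("count must be in [1, %d]", ncol(image))
  if (is.null(start_aline)) start_aline <- (ncol(image) - count) %/% 2 + 1L
  if (!is_count(start_aline) || start_aline + count - 1L > ncol(image))
    stopf("A-line window [%d, %d] lies outside the image (width %d)",
          start_aline, start_aline + count - 1, ncol(image))
  cols <- start_aline:(start_aline + count - 1L)
  aline(rowMeans(image[, cols, drop = FALSE]), scale = "linear",
        axial_pitch_um = axial_pitch_um,
        provenance = list(n_alines = as.integer(count),
                          start_aline = as.integer(start_aline)))
}

#' Moving-average smoothing of an A-line
#'
#' Odd-width moving-average convolution (the speckle-compensation filter
#' applied before peak detection), with symmetric boundary handling; the
#' profile length is preserved.
#'
#' @param aline an [aline()].
#' @param kernel_width_px odd positive kernel width; width 1 is the identity.
#' @export
smooth_aline <- function(aline, kernel_width_px = 5L) {
  stopifnot(inherits(aline, "aline"))
  w <- kernel_width_px
  if (!is_count(w) || w %% 2 == 0) stopf("kernel_width_px must be odd and >= 1")
  if (w == 1) return(aline)
  r <- (w - 1L) %/% 2L
  v <- aline$values
  padded <- c(v[r:1], v, v[length(v):(length(v) - r + 1L)])
  sm <- stats::filter(padded, rep(1 / w, w), sides = 2)
  out <- aline
  out$values <- as.numeric(sm[(r + 1L):(r + length(v))])
  out$normalized <- FALSE
  out
}

#' Normalize a linear A-line by its maximum
#'
#' @param aline an [aline()] on the linear scale with a positive maximum.
#' @export
normalize_aline <- function(aline) {
  stopifnot(inherits(aline, "aline"))
  if (aline$scale != "linear") stopf("normalization is defined on the linear scale")
  m <- max(aline$values)
  if (m <= 0) stopf("cannot normalize an all-zero profile")
  out <- aline
  out$values <- aline$values / m
  out$normalized <- TRUE
  out
}

#' Convert a linear A-line to dB
#'
#' Uses the intensity convention `10 * log10(I)`.
#'
#' @param aline an [aline()] on the linear scale.
#' @param floor optional positive floor applied before the logarithm; without
#'   it, non-positive values are rejected.
#' @export
to_db <- function(aline, floor = NULL) {
  stopifnot(inherits(aline, "aline"))
  if (aline$scale != "linear") stopf("aline is already in dB")
  v <- aline$values
  if (!is.null(floor)) {
    if (floor <= 0) stopf("floor must be > 0")
    v <- pmax(v, floor)
  } else if (any(v <= 0)) {
    stopf("non-positive values cannot be converted to dB without a floor")
  }
  out <- aline
  out$values <- 10 * log10(v)
  out$scale <- "dB"
  out$normalized <- FALSE
  out
}

# Prominence of a local maximum: height above the higher of the two deepest
# valleys separating it from higher terrain (profile ends act as terrain).
peak_prominence <- function(v, i) {
  side_min <- function(idx) {
    if (!length(idx)) return(v[i])
    lo <- v[i]
    for (j in idx) {
      if (v[j] > v[i]) break
      lo <- min(lo, v[j])
    }
    lo
  }
  left <- side_min(rev(seq_len(i - 1L)))
  right <- side_min(seq(i + 1L, length(v))[seq_len(max(0L, length(v) - i))])
  v[i] - max(left, right)
}

#' Detect layer peaks in an averaged A-line
#'
#' Local maxima are screened by prominence and minimum separation; the
#' global maximum is reported as the surface (first) peak. Profile endpoints
#' are not eligible peaks (a monotone ramp therefore yields an empty set).
#' On the linear scale the prominence threshold is `min_prominence` times the
#' profile maximum; on the dB scale, where attenuation hides deep interfaces
#' from any linear-scale criterion, it is an absolute `min_prominence_db`.
#'
#' @param aline an [aline()], linear (typically normalized) or dB.
#' @param min_prominence prominence threshold as a fraction of the maximum
#'   (linear scale).
#' @param min_separation_um minimum peak separation; default 14 um (twice
#'   the 7-um axial resolution).
#' @param min_prominence_db prominence threshold in dB (dB scale).
#' @return a `peak_set`: list with `peaks` (data.frame `depth_px`,
#'   `depth_um`, `height`, `prominence`, ordered by depth), `surface_index`,
#'   and `empty` flag.
#' @export
detect_peaks <- function(aline, min_prominence = 0.05, min_separation_um = 14,
                         min_prominence_db = 3) {
  stopifnot(inherits(aline, "aline"))
  v <- aline$values
  n <- length(v)
  thr <- if (aline$scale == "dB") min_prominence_db else min_prominence * max(v)
  cand <- integer(0)
  i <- 2L
  while (i < n) {             # plateaus count once, at their first index
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  prom <- vapply(cand, function(k) peak_prominence(v, k), numeric(1))
  keep <- prom >= thr
  cand <- cand[keep]; prom <- prom[keep]
  # greedy separation filter, strongest peaks first
  ord <- order(v[cand], decreasing = TRUE)
  sel <- integer(0)
  min_sep_px <- min_separation_um / aline$axial_pitch_um
  for (k in ord) {
    if (all(abs(cand[k] - cand[sel]) >= min_sep_px)) sel <- c(sel, k)
  }
  sel <- sort(cand[sel])
  peaks <- data.frame(depth_px = sel,
                      depth_um = (sel - 1L) * aline$axial_pitch_um,
                      height = v[sel],
                      prominence = prom[match(sel, cand)])
  surface <- if (length(sel)) sel[which.max(v[sel])] else which.max(v)[1]
  structure(list(peaks = peaks, surface_index = as.integer(surface),
                 axial_pitch_um = aline$axial_pitch_um,
                 empty = nrow(peaks) == 0L),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s), surface at depth px %d\n",
              nrow(x$peaks), x$surface_index))
  if (nrow(x$peaks)) print(x$peaks, row.names = FALSE)
  invisible(x)
}

#' Thickness between two detected layer peaks
#'
#' @param peaks a `peak_set`.
#' @param i,j peak indices (in depth order) with `i < j`.
#' @return thickness in um.
#' @export
layer_thickness <- function(peaks, i, j) {
  stopifnot(inherits(peaks, "peak_set"))
  n <- nrow(peaks$peaks)
  if (!is_count(i) || !is_count(j) || i > n || j > n)
    stopf("peak indices must lie in [1, %d]", n)
  if (i >= j) stopf("need i < j (got i=%d, j=%d)", i, j)
  (peaks$peaks$depth_px[j] - peaks$peaks$depth_px[i]) * peaks$axial_pitch_um
}

#' Least-squares attenuation fit of a dB A-line
#'
#' Ordinary least squares of dB intensity against depth (um) over the window
#' starting `offset_px` pixels below the surface peak and extending
#' `window_um` into the tissue.
#'
#' @param aline_db an [aline()] on the dB scale.
#' @param surface_index depth pixel (1-based) of the air/sample interface.
#' @param offset_px pixels skipped below the surface to avoid the strong
#'   specular reflection; default 10.
#' @param window_um axial extent of the fit; default 320 um.
#' @return an `attenuation_fit`: `slope_db_per_um`, `intercept_db`,
#'   `r_squared`, `window` (start/end px, half-open), `n_points`.
#' @export
fit_attenuation <- function(aline_db, surface_index, offset_px = 10L,
                            window_um = 320) {
  stopifnot(inherits(aline_db, "aline"))
  if (aline_db$scale != "dB") stopf("fit_attenuation expects a dB profile; see to_db()")
  n_pts <- round(window_um / aline_db$axial_pitch_um)
  start <- surface_index + offset_px
  end <- start + n_pts - 1L
  if (start < 1 || end > length(aline_db$values))
    stopf("fit window [%d, %d] exceeds the profile (length %d)",
          start, end, length(aline_db$values))
  rows <- start:end
  depth_um <- (rows - 1L) * aline_db$axial_pitch_um
  fit <- stats::lm(aline_db$values[rows] ~ depth_um)
  ss_tot <- sum((aline_db$values[rows] - mean(aline_db$values[rows]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope_db_per_um = unname(stats::coef(fit)[2]),
                 intercept_db = unname(stats::coef(fit)[1]),
                 r_squared = max(0, min(1, r2)),
                 window = c(start_px = start, end_px = end + 1L),
                 n_points = length(rows)),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf("<attenuation_fit> slope %.4f dB/um (R^2 %.4f, %d points, rows %d-%d)\n",
              x$slope_db_per_um, x$r_squared, x$n_points,
              x$window[1], x$window[2] - 1L))
  invisible(x)
}

#' Estimate the attenuation coefficient of a B-scan stack
#'
#' Composition of the full pipeline: frame averaging, lateral averaging of
#' `n_alines` central A-lines, surface location by peak detection on the
#' smoothed normalized linear profile, dB conversion, and OLS fitting of the
#' standard window (10 px below the surface, 320 um deep).
#'
#' @param stack a [bscan_stack()].
#' @param n_alines lateral averaging window (columns); default 100.
#' @param offset_px,window_um fit window, see [fit_attenuation()].
#' @param smooth_width_px smoothing kernel for peak detection; default 5.
#' @param min_prominence prominence threshold for surface detection.
#' @return an `attenuation_fit`.
#' @export
estimate_attenuation <- function(stack, n_alines = 100L, offset_px = 10L,
                                 window_um = 320, smooth_width_px = 5L,
                                 min_prominence = 0.05) {
  stopifnot(inherits(stack, "bscan_stack"))
  img <- average_frames(stack)
  al <- extract_averaged_aline(img, axial_pitch_um = stack$axial_pitch_um,
                               count = min(n_alines, ncol(img)))
  norm <- normalize_aline(smooth_aline(al, smooth_width_px))
  peaks <- detect_peaks(norm, min_prominence = min_prominence)
  db <- to_db(normalize_aline(al), floor = .Machine$double.xmin)
  fit_attenuation(db, surface_index = peaks$surface_index,
                  offset_px = offset_px, window_um = window_um)
}

#' Constant-depth (en face) slice of a 3-D stack
#'
#' Interprets the frames of a stack as adjacent B-scans of a volume and
#' extracts the plane at the depth row nearest `depth_um` (measured from the
#' image top, row 1 = 0 um; ties round half up).
#'
#' @param stack a [bscan_stack()].
#' @param depth_um depth of the slice below the image top.
#' @return width x n_frames matrix.
#' @export
enface_slice <- function(stack, depth_um) {
  stopifnot(inherits(stack, "bscan_stack"))
  row <- floor(depth_um / stack$axial_pitch_um + 0.5) + 1L
  if (depth_um < 0 || row > dim(stack$frames)[1])
    stopf("depth %g um lies outside the volume", depth_um)
  stack$frames[row, , ]
}
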
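# SGLDM (GLCM) texture analysis of B-scan regions of interest.

#' Region-of-interest specification
#'
#' 1-based inclusive window; the default 200 x 200 px corresponds to a
#' physical area of 492 um x 533 um at the default pitches.
#'
#' @param x0,z0 top-left pixel (column, row), 1-based.
#' @param width_px,height_px window size in pixels.
#' @export
roi_spec <- function(x0, z0, width_px = 200L, height_px = 200L) {
  if (!is_count(x0) || !is_count(z0) || !is_count(width_px) || !is_count(height_px))
    stopf("ROI coordinates and sizes must be positive integers")
  structure(list(x0 = as.integer(x0), z0 = as.integer(z0),
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px)),
            class = "roi_spec")
}

#' Extract an ROI sub-image
#'
#' @param image depth x width matrix.
#' @param roi a [roi_spec()].
#' @return height_px x width_px matrix.
#' @export
extract_roi <- function(image, roi) {
  stopifnot(is.matrix(image), inherits(roi, "roi_spec"))
  if (roi$z0 + roi$height_px - 1L > nrow(image) ||
      roi$x0 + roi$width_px - 1L > ncol(image))
    stopf("ROI [%d:%d, %d:%d] lies outside the %d x %d image",
          roi$z0, roi$z0 + roi$height_px - 1L,
          roi$x0, roi$x0 + roi$width_px - 1L, nrow(image), ncol(image))
  image[roi$z0:(roi$z0 + roi$height_px - 1L),
        roi$x0:(roi$x0 + roi$width_px - 1L), drop = FALSE]
}

#' Default automatic ROI for batch processing
#'
#' Centered laterally, top edge `offset_px` pixels below the detected (or
#' supplied) surface row.
#'
#' @param image depth x width matrix.
#' @param surface_index surface row (1-based).
#' @param offset_px rows skipped below the surface; default 10.
#' @param width_px,height_px ROI size.
#' @export
auto_roi <- function(image, surface_index, offset_px = 10L,
                     width_px = 200L, height_px = 200L) {
  x0 <- (ncol(image) - width_px) %/% 2 + 1L
  roi_spec(x0 = max(1L, x0), z0 = surface_index + offset_px,
           width_px = width_px, height_px = height_px)
}

#' Quantize a sub-image to G gray levels
#'
#' Linear binning into `levels` equal-width bins over the chosen range,
#' values clipped to the range. A degenerate range (min = max) maps all
#' pixels to level 0 and sets the `degenerate` attribute.
#'
#' @param x numeric matrix.
#' @param levels number of gray levels G (>= 2).
#' @param range_policy `"minmax"` (ROI minimum/maximum) or `"fixed"`.
#' @param limits numeric `c(lo, hi)`, required for `"fixed"`.
#' @return integer matrix with values in `[0, levels - 1]`, attributes
#'   `levels` and `degenerate`.
#' @export
quantize <- function(x, levels = 64L, range_policy = c("minmax", "fixed"),
                     limits = NULL) {
  range_policy <- match.arg(range_policy)
  if (!is_count(levels, min = 2)) stopf("levels must be an integer >= 2")
  if (range_policy == "fixed") {
    if (is.null(limits) || length(limits) != 2 || limits[2] <= limits[1])
      stopf("fixed range policy requires limits = c(lo, hi) with hi > lo")
    lo <- limits[1]; hi <- limits[2]
  } else {
    lo <- min(x); hi <- max(x)
  }
  degenerate <- hi <= lo
  q <- if (degenerate) {
    array(0L, dim = dim(x))
  } else {
    v <- pmin(pmax(x, lo), hi)
    qi <- as.integer(floor((v - lo) / (hi - lo) * levels))
    array(pmin(qi, levels - 1L), dim = dim(x))
  }
  attr(q, "levels") <- as.integer(levels)
  attr(q, "degenerate") <- degenerate
  q
}

#' Gray-level co-occurrence matrix for one offset
#'
#' Counts ordered pixel pairs `(x, x + offset)` falling inside the image;
#' with `symmetric = TRUE` the transpose is added before normalization, as
#' in the classic SGLDM protocol.
#'
#' @param qimage integer matrix quantized to `[0, levels - 1]` (see
#'   [quantize()]); the `levels` attribute is used when `levels` is missing.
#' @param offset integer `c(dz, dx)` row/column displacement, not `c(0,0)`.
#' @param levels number of gray levels.
#' @param symmetric logical.
#' @return a `glcm`: list with `p` (levels x levels probability matrix,
#'   rows/cols indexed by gray level 0..G-1), `levels`, `offset`, `symmetric`.
#' @export
compute_glcm <- function(qimage, offset, levels = attr(qimage, "levels"),
                         symmetric = TRUE) {
  if (is.null(levels)) stopf("levels must be supplied (or present as attribute)")
  dz <- as.integer(offset[1]); dx <- as.integer(offset[2])
  if (dz == 0 && dx == 0) stopf("offset must not be (0, 0)")
  nr <- nrow(qimage); nc <- ncol(qimage)
  if (abs(dz) >= nr || abs(dx) >= nc) stopf("offset larger than the image")
  rows <- max(1L, 1L - dz):min(nr, nr - dz)
  cols <- max(1L, 1L - dx):min(nc, nc - dx)
  a <- qimage[rows, cols, drop = FALSE]
  b <- qimage[rows + dz, cols + dx, drop = FALSE]
  counts <- tabulate(as.integer(a) * levels + as.integer(b) + 1L,
                     nbins = levels * levels)
  counts <- matrix(counts, levels, levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), levels = as.integer(levels),
                 offset = c(dz = dz, dx = dx), symmetric = isTRUE(symmetric)),
            class = "glcm")
}

#' Marginal distributions and entropies of a GLCM
#'
#' Gray levels are indexed 0..G-1. `p_sum[k + 1]` holds the probability of
#' level sum `k` (k = 0..2G-2); `p_diff[k + 1]` of absolute level difference
#' `k` (k = 0..G-1). Entropies use the configured log base with the
#' convention 0 log 0 = 0.
#'
#' @param glcm a [compute_glcm()] result.
#' @param log_base base of the logarithm for all entropies; default 2.
#' @return list with `p_x`, `p_y`, `p_sum`, `p_diff`, `mu_x`, `mu_y`,
#'   `sigma_x`, `sigma_y`, `HX`, `HY`, `HXY`, `HXY1`, `HXY2`.
#' @export
glcm_marginals <- function(glcm, log_base = 2) {
  stopifnot(inherits(glcm, "glcm"))
  p <- glcm$p
  G <- glcm$levels
  lev <- 0:(G - 1)
  p_x <- rowSums(p)
  p_y <- colSums(p)
  i <- matrix(lev, G, G)        # row level
  j <- matrix(lev, G, G, byrow = TRUE)
  p_sum <- vapply(0:(2 * G - 2), function(k) sum(p[i + j == k]), numeric(1))
  p_diff <- vapply(0:(G - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  mu_x <- sum(lev * p_x)
  mu_y <- sum(lev * p_y)
  pxy <- outer(p_x, p_y)
  list(p_x = p_x, p_y = p_y, p_sum = p_sum, p_diff = p_diff,
       mu_x = mu_x, mu_y = mu_y,
       sigma_x = sqrt(sum((lev - mu_x)^2 * p_x)),
       sigma_y = sqrt(sum((lev - mu_y)^2 * p_y)),
       HX = -sum(xlogx(p_x, log_base)),
       HY = -sum(xlogx(p_y, log_base)),
       HXY = -sum(xlogx(p, log_base)),
       HXY1 = -sum(p * ifelse(pxy > 0, log(pxy, base = log_base), 0)),
       HXY2 = -sum(xlogx(pxy, log_base)))
}

#' Texture analysis configuration
#'
#' @param levels number of gray levels G; default 64.
#' @param distance offset distance in pixels; default 1.
#' @param angles offset angles in degrees (subset of 0, 45, 90, 135);
#'   features are averaged over angles.
#' @param symmetric symmetric co-occurrence matrices; default `TRUE`.
#' @param log_base entropy log base; default 2.
#' @param scale `"db"` computes the co-occurrence features on the
#'   display-scale (10 log10) image, `"linear"` on the raw intensities.
#' @param flatten_depth subtract the mean axial (per-depth-row) profile from
#'   the dB ROI before quantization, the standard attenuation compensation
#'   that isolates lateral/axial heterogeneity from bulk depth decay; only
#'   applied when `scale = "db"`.
#' @param range_policy quantization range policy; defaults to `"fixed"` for
#'   the flattened dB pipeline and `"minmax"` otherwise.
#' @param fixed_range quantization limits (dB) for the fixed policy.
#' @param sum_variance_center `"sum_average"` (the widely used erratum form,
#'   default) or `"sum_entropy"` (Haralick's original) as the centering term
#'   of sum variance.
#' @export
texture_config <- function(levels = 64L, distance = 1L,
                           angles = c(0, 45, 90, 135), symmetric = TRUE,
                           log_base = 2, scale = c("db", "linear"),
                           flatten_depth = TRUE,
                           range_policy = NULL, fixed_range = c(-25, 25),
                           sum_variance_center = c("sum_average", "sum_entropy")) {
  scale <- match.arg(scale)
  if (!all(angles %in% c(0, 45, 90, 135))) stopf("angles must be in {0,45,90,135}")
  if (is.null(range_policy))
    range_policy <- if (scale == "db" && flatten_depth) "fixed" else "minmax"
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 angles = angles, symmetric = isTRUE(symmetric),
                 log_base = log_base, scale = scale,
                 flatten_depth = isTRUE(flatten_depth),
                 range_policy = match.arg(range_policy, c("minmax", "fixed")),
                 fixed_range = fixed_range,
                 sum_variance_center = match.arg(sum_variance_center)),
            class = "texture_config")
}

#' Names of the 14 texture features
#' @export
texture_feature_names <- function() {
  c("energy", "inertia", "inverse_difference_moment", "correlation",
    "variance", "skewness", "entropy", "sum_average", "sum_variance",
    "sum_entropy", "difference_variance", "difference_entropy",
    "imc1", "imc2")
}

# 13 co-occurrence features of a single GLCM (skewness is first-order and
# computed elsewhere). Degenerate matrices (sigma_x = 0) yield NA for
# correlation and imc1.
glcm_features <- function(glcm, log_base = 2,
                          sum_variance_center = "sum_average") {
  m <- glcm_marginals(glcm, log_base = log_base)
  p <- glcm$p
  G <- glcm$levels
  lev <- 0:(G - 1)
  i <- matrix(lev, G, G)
  j <- matrix(lev, G, G, byrow = TRUE)
  ks <- 0:(2 * G - 2)
  kd <- 0:(G - 1)
  sum_average <- sum(ks * m$p_sum)
  sum_entropy <- -sum(xlogx(m$p_sum, log_base))
  sv_center <- if (sum_variance_center == "sum_average") sum_average else sum_entropy
  mu_diff <- sum(kd * m$p_diff)
  denom <- max(m$HX, m$HY)
  c(energy = sum(p^2),
    inertia = sum((i - j)^2 * p),
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    correlation = if (m$sigma_x > 0 && m$sigma_y > 0)
      (sum(i * j * p) - m$mu_x * m$mu_y) / (m$sigma_x * m$sigma_y) else NA_real_,
    variance = sum((i - m$mu_x)^2 * p),
    entropy = m$HXY,
    sum_average = sum_average,
    sum_variance = sum((ks - sv_center)^2 * m$p_sum),
    sum_entropy = sum_entropy,
    difference_variance = sum((kd - mu_diff)^2 * m$p_diff),
    difference_entropy = -sum(xlogx(m$p_diff, log_base)),
    imc1 = if (denom > 0) (m$HXY - m$HXY1) / denom else NA_real_,
    imc2 = sqrt(pmax(0, 1 - exp(-2 * (m$HXY2 - m$HXY)))))
}

# Offset (dz, dx) for a distance-d pair at a given angle (degrees).
angle_offset <- function(angle, distance = 1L) {
  d <- as.integer(distance)
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d),
         stopf("unsupported angle %s", angle))
}

#' Compute the 14 SGLDM texture features of an ROI
#'
#' Thirteen co-occurrence features (Haralick set with the maximal correlation
#' coefficient replaced by skewness) are computed per offset and averaged
#' over the configured angles; skewness is the third standardized central
#' moment of the raw (unquantized, linear-intensity) ROI pixels. With the
#' default configuration the co-occurrence matrix is built from the
#' display-scale (dB) ROI after removal of the mean axial profile.
#'
#' @param x numeric matrix: the ROI on the linear intensity scale (or an
#'   arbitrary gray-scale image when `config$scale = "linear"`).
#' @param config a [texture_config()].
#' @return named numeric vector of the 14 features (see
#'   [texture_feature_names()]); attribute `degenerate` flags a
#'   zero-variance quantization.
#' @export
compute_features <- function(x, config = texture_config()) {
  stopifnot(is.matrix(x), inherits(config, "texture_config"))
  y <- x
  if (config$scale == "db") {
    if (any(x < 0)) stopf("dB-scale pipeline expects non-negative linear intensities")
    y <- 10 * log10(pmax(x, .Machine$double.xmin))
    if (config$flatten_depth) y <- y - rowMeans(y)
  }
  q <- quantize(y, levels = config$levels, range_policy = config$range_policy,
                limits = if (config$range_policy == "fixed") config$fixed_range)
  per_angle <- vapply(config$angles, function(a) {
    g <- compute_glcm(q, angle_offset(a, config$distance),
                      levels = config$levels, symmetric = config$symmetric)
    glcm_features(g, log_base = config$log_base,
                  sum_variance_center = config$sum_variance_center)
  }, numeric(13))
  feats <- rowMeans(per_angle)
  mu <- mean(x); s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
  skew <- if (s > 0) mean((x - mu)^3) / s^3 else 0
  out <- c(feats["energy"], feats["inertia"],
           feats["inverse_difference_moment"], feats["correlation"],
           feats["variance"], skewness = skew, feats["entropy"],
           feats["sum_average"], feats["sum_variance"], feats["sum_entropy"],
           feats["difference_variance"], feats["difference_entropy"],
           feats["imc1"], feats["imc2"])
  names(out) <- texture_feature_names()
  attr(out, "degenerate") <- isTRUE(attr(q, "degenerate"))
  out
}

#' Texture feature table of a labeled dataset
#'
#' For every stack: frame-average, locate the surface on the smoothed
#' normalized central A-line, place the automatic ROI (centered laterally,
#' top `offset_px` below the surface), and compute the 14 features.
#' Per-sample failures are recorded as NA rows with a warning, not fatal.
#'
#' @param dataset list of [bscan_stack()]s (e.g. from
#'   [generate_labeled_dataset()]).
#' @param config a [texture_config()].
#' @param offset_px ROI top offset below the surface; default 10.
#' @param roi optional fixed [roi_spec()] overriding the automatic policy.
#' @param width_px,height_px automatic ROI size; default 200 x 200.
#' @return data.frame with `sample_id`, `label`, `degenerate` and the 14
#'   feature columns.
#' @export
batch_features <- function(dataset, config = texture_config(), offset_px = 10L,
                           roi = NULL, width_px = 200L, height_px = 200L) {
  if (!length(dataset)) stopf("dataset is empty")
  rows <- lapply(seq_along(dataset), function(k) {
    stack <- dataset[[k]]
    res <- tryCatch({
      img <- average_frames(stack)
      r <- roi
      if (is.null(r)) {
        al <- extract_averaged_aline(img, stack$axial_pitch_um,
                                     count = min(100L, ncol(img)))
        pk <- detect_peaks(normalize_aline(smooth_aline(al)))
        r <- auto_roi(img, pk$surface_index, offset_px = offset_px,
                      width_px = width_px, height_px = height_px)
      }
      compute_features(extract_roi(img, r), config)
    }, error = function(e) {
      warning(sprintf("sample %d (%s): %s", k, stack$stage %||% "?",
                      conditionMessage(e)), call. = FALSE)
      structure(rep(NA_real_, 14), names = texture_feature_names(),
                degenerate = NA)
    })
    data.frame(sample_id = k, label = stack$stage %||% NA_character_,
               degenerate = isTRUE(attr(res, "degenerate")),
               as.list(res), check.names = FALSE)
  })
  do.call(rbind, rows)
}
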
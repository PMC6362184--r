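# Synthetic leaf-phantom generator -------------------------------------------
#
# B-scans are depth (rows) x width (columns) matrices of linear intensity;
# each column is one A-line. Depth increases downward. All indexing is
# 1-based and inclusive.

#' Specify one phantom tissue layer
#'
#' A layer contributes (i) a Gaussian specular peak at its top interface and
#' (ii) a constant bulk backscatter level, both subsequently attenuated with
#' depth. Interface width defaults to the system axial resolution (7 um FWHM).
#'
#' @param name text label (e.g. `"cuticle"`).
#' @param top_depth_um depth of the layer top below the sample surface (um).
#' @param thickness_um layer thickness (um), must be positive.
#' @param interface_reflectivity dimensionless peak amplitude of the top
#'   interface, in units of the bulk level; `0` means no visible interface.
#' @param bulk_reflectivity dimensionless mean backscatter level of the bulk.
#' @param interface_sigma_um Gaussian sigma of the interface peak (um).
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(name, top_depth_um, thickness_um,
                       interface_reflectivity = 0, bulk_reflectivity = 1,
                       interface_sigma_um = 7 / (2 * sqrt(2 * log(2)))) {
  if (!is.character(name) || length(name) != 1) stopf("layer name must be a string")
  if (top_depth_um < 0) stopf("layer '%s': top_depth_um must be >= 0", name)
  if (thickness_um <= 0) stopf("layer '%s': thickness_um must be > 0", name)
  if (interface_reflectivity < 0 || bulk_reflectivity < 0)
    stopf("layer '%s': reflectivities must be >= 0", name)
  structure(list(name = name, top_depth_um = top_depth_um,
                 thickness_um = thickness_um,
                 interface_reflectivity = interface_reflectivity,
                 bulk_reflectivity = bulk_reflectivity,
                 interface_sigma_um = interface_sigma_um),
            class = "layer_spec")
}

#' Full parameterization of a synthetic leaf B-scan
#'
#' @param stage stage label, one of `"green"`, `"yellow"`, `"red"` (or any
#'   free label for custom phantoms).
#' @param layers list of [layer_spec()] ordered by increasing top depth,
#'   non-overlapping.
#' @param attenuation_db_per_um signed decay slope of mean dB intensity with
#'   depth inside the tissue; must be `<= 0`.
#' @param surface_depth_px pixel row (1-based) of the air/sample interface.
#' @param n_alines B-scan width in pixels.
#' @param n_depth_px B-scan depth in pixels.
#' @param lateral_pitch_um,axial_pitch_um pixel pitches (um/px). Defaults
#'   2.46 and 2.665 reproduce a 200 px = 492 um lateral, 200 px = 533 um
#'   axial region in an 813 x 750 B-scan.
#' @param speckle `"exponential"` for fully developed speckle (per-pixel
#'   exponential intensity with the configured local mean) or `"none"`.
#' @param texture_corr_um correlation lengths `c(lateral, axial)` in um of
#'   the smooth multiplicative heterogeneity field.
#' @param texture_contrast log-normal sigma (natural-log scale) of the
#'   heterogeneity field; `0` disables it.
#' @param field_norm_columns the heterogeneity field is renormalized to unit
#'   lateral mean over this many central columns at every depth, so laterally
#'   averaged A-lines carry exactly the configured attenuation.
#' @param noise_floor additive background intensity above the surface.
#' @param seed integer seed controlling the (per-sample) heterogeneity field.
#' @return a validated `phantom_config`.
#' @export
phantom_config <- function(stage, layers, attenuation_db_per_um,
                           surface_depth_px = 40L,
                           n_alines = 813L, n_depth_px = 750L,
                           lateral_pitch_um = 2.46, axial_pitch_um = 2.665,
                           speckle = c("exponential", "none"),
                           texture_corr_um = c(30, 30),
                           texture_contrast = 0,
                           field_norm_columns = 100L,
                           noise_floor = 0, seed = 1L) {
  speckle <- match.arg(speckle)
  if (!is_count(n_alines) || !is_count(n_depth_px))
    stopf("n_alines and n_depth_px must be positive integers")
  if (lateral_pitch_um <= 0 || axial_pitch_um <= 0) stopf("pitches must be > 0")
  if (attenuation_db_per_um > 0)
    stopf("attenuation_db_per_um must be <= 0 (got %g)", attenuation_db_per_um)
  if (!is_count(surface_depth_px) || surface_depth_px > n_depth_px)
    stopf("surface_depth_px must lie inside the image")
  if (texture_contrast < 0 || noise_floor < 0)
    stopf("texture_contrast and noise_floor must be >= 0")
  if (!length(layers)) stopf("at least one layer is required")
  if (!all(vapply(layers, inherits, logical(1), "layer_spec")))
    stopf("layers must be a list of layer_spec objects")
  tops <- vapply(layers, `[[`, numeric(1), "top_depth_um")
  bots <- tops + vapply(layers, `[[`, numeric(1), "thickness_um")
  if (is.unsorted(tops, strictly = TRUE)) stopf("layers must be ordered by increasing top depth")
  if (length(layers) > 1 && any(bots[-length(bots)] > tops[-1] + 1e-9))
    stopf("layers must not overlap")
  structure(list(stage = stage, layers = layers,
                 attenuation_db_per_um = attenuation_db_per_um,
                 surface_depth_px = as.integer(surface_depth_px),
                 n_alines = as.integer(n_alines),
                 n_depth_px = as.integer(n_depth_px),
                 lateral_pitch_um = lateral_pitch_um,
                 axial_pitch_um = axial_pitch_um,
                 speckle = speckle,
                 texture_corr_um = rep_len(texture_corr_um, 2),
                 texture_contrast = texture_contrast,
                 field_norm_columns = as.integer(field_norm_columns),
                 noise_floor = noise_floor, seed = as.integer(seed)),
            class = "phantom_config")
}

# Stage constants. Attenuation means are the ground truths recovered by the
# A-scan pipeline; texture contrasts are the calibration constants that give
# the documented stage ordering of energy / skewness / sum variance.
.leaf_stage_presets <- list(
  green  = list(attenuation = -0.78, contrast = 0.15),
  yellow = list(attenuation = -1.10, contrast = 0.60),
  red    = list(attenuation = -1.20, contrast = 1.05)
)

#' Stage preset configurations
#'
#' Returns the fully populated phantom configuration for one senescence
#' stage. The green leaf has two distinct sub-surface interfaces (upper
#' epidermis top at 30 um, palisade top at 120 um); in yellow and red leaves
#' the epidermis/palisade boundary is merged into a single broadened
#' interface (95 um / 110 um, sigma 4.5 um). Stage attenuation means are
#' -0.78, -1.10 and -1.20 dB/um; heterogeneity contrast increases
#' monotonically green < yellow < red.
#'
#' @param stage `"green"`, `"yellow"` or `"red"`.
#' @param n_alines,n_depth_px image geometry (defaults 813 x 750; pass e.g.
#'   256 x 256 for a scaled-down phantom, pitches are unchanged so estimated
#'   attenuation slopes are invariant to frame size).
#' @param seed integer seed for the per-sample heterogeneity field.
#' @return a `phantom_config`.
#' @examples
#' cfg <- leaf_preset("green")
#' cfg$attenuation_db_per_um  # -0.78
#' @export
leaf_preset <- function(stage, n_alines = 813L, n_depth_px = 750L, seed = 1L) {
  if (length(stage) != 1 || !stage %in% names(.leaf_stage_presets))
    stopf("unknown stage '%s': must be one of %s",
          paste(stage, collapse = ","),
          paste(names(.leaf_stage_presets), collapse = ", "))
  p <- .leaf_stage_presets[[stage]]
  layers <- switch(stage,
    green = list(
      layer_spec("cuticle", 0, 30, interface_reflectivity = 40),
      layer_spec("upper_epidermis", 30, 90, interface_reflectivity = 40),
      layer_spec("palisade", 120, 630, interface_reflectivity = 40)),
    yellow = list(
      layer_spec("cuticle", 0, 30, interface_reflectivity = 40),
      layer_spec("epidermis_palisade_merged", 95, 685,
                 interface_reflectivity = 200, interface_sigma_um = 4.5)),
    red = list(
      layer_spec("cuticle", 0, 30, interface_reflectivity = 40),
      layer_spec("epidermis_palisade_merged", 110, 670,
                 interface_reflectivity = 200, interface_sigma_um = 4.5)))
  phantom_config(stage = stage, layers = layers,
                 attenuation_db_per_um = p$attenuation,
                 n_alines = n_alines, n_depth_px = n_depth_px,
                 texture_contrast = p$contrast, seed = seed)
}

#' Noiseless mean depth profile of a phantom
#'
#' The analytic oracle for the speckle generator: `noise_floor` above the
#' surface; below it, bulk backscatter plus Gaussian interface peaks, all
#' multiplied by `10^(attenuation_db_per_um * depth_in_tissue / 10)`.
#'
#' @param config a `phantom_config`.
#' @return an [aline()] on the linear scale with one value per depth pixel.
#' @export
expected_profile <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  z_um <- (seq_len(config$n_depth_px) - config$surface_depth_px) * config$axial_pitch_um
  tissue <- z_um >= 0
  zt <- z_um[tissue]
  tops <- vapply(config$layers, `[[`, numeric(1), "top_depth_um")
  bulks <- vapply(config$layers, `[[`, numeric(1), "bulk_reflectivity")
  idx <- pmax(findInterval(zt, tops), 1L)
  v <- bulks[idx]
  for (ly in config$layers) {
    if (ly$interface_reflectivity > 0)
      v <- v + ly$interface_reflectivity *
        exp(-(zt - ly$top_depth_um)^2 / (2 * ly$interface_sigma_um^2))
  }
  v <- v * 10^(config$attenuation_db_per_um * zt / 10)
  out <- rep(config$noise_floor, config$n_depth_px)
  out[tissue] <- out[tissue] + v
  aline(out, scale = "linear", axial_pitch_um = config$axial_pitch_um,
        provenance = list(source = "expected_profile", stage = config$stage))
}

# Smooth unit-variance Gaussian random field via separable Gaussian filtering
# of white noise (kernels L2-normalized, so the marginal is exactly N(0,1)).
gaussian_field <- function(nz, nx, sigma_z_px, sigma_x_px) {
  band <- function(n, sigma) {
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-r, r), sd = max(sigma, 1e-6))
    k <- k / sqrt(sum(k^2))
    m <- matrix(0, n, n + 2 * r)
    for (i in seq_len(n)) m[i, i:(i + 2 * length(k) %/% 2)] <- k
    m
  }
  Kz <- band(nz, sigma_z_px)
  Kx <- band(nx, sigma_x_px)
  noise <- matrix(stats::rnorm(ncol(Kz) * ncol(Kx)), ncol(Kz), ncol(Kx))
  Kz %*% noise %*% t(Kx)
}

# Multiplicative heterogeneity field of a config (deterministic in
# config$seed): log-normal with unit mean, renormalized to unit lateral mean
# over the central analysis window at every depth.
texture_field <- function(config) {
  nz <- config$n_depth_px
  nx <- config$n_alines
  if (config$texture_contrast == 0) return(matrix(1, nz, nx))
  f <- with_seed(derive_seed(config$seed, 977L), {
    g <- gaussian_field(nz, nx,
                        sigma_z_px = config$texture_corr_um[2] / config$axial_pitch_um,
                        sigma_x_px = config$texture_corr_um[1] / config$lateral_pitch_um)
    exp(config$texture_contrast * g - config$texture_contrast^2 / 2)
  })
  w <- min(config$field_norm_columns, nx)
  first <- (nx - w) %/% 2 + 1L
  f / rowMeans(f[, first:(first + w - 1L), drop = FALSE])
}

# Deterministic per-pixel mean intensity field (profile x heterogeneity).
mean_field <- function(config) {
  expected_profile(config)$values * texture_field(config)
}

#' Generate one speckled B-scan
#'
#' Each pixel is an independent exponential draw whose mean is the expected
#' depth profile at that pixel times the smooth multiplicative heterogeneity
#' field (fully developed speckle). With `speckle = "none"` the mean field
#' itself is returned. Deterministic for a fixed `seed`.
#'
#' @param config a `phantom_config`.
#' @param seed integer seed for the speckle draw.
#' @return a depth x width matrix of non-negative linear intensity.
#' @export
generate_bscan <- function(config, seed) {
  stopifnot(inherits(config, "phantom_config"))
  m <- mean_field(config)
  if (config$speckle == "none") return(m)
  with_seed(seed, m * matrix(stats::rexp(length(m)), nrow(m), ncol(m)))
}

#' Generate a stack of B-scans sharing one configuration
#'
#' Frame `f` uses the seed `derive_seed(seed, f)`, so stacks are reproducible
#' and frames are independent.
#'
#' @param config a `phantom_config`.
#' @param n_frames number of frames (`>= 1`).
#' @param seed integer base seed.
#' @return a `bscan_stack`: list with `frames` (depth x width x n_frames
#'   array), pitches, `stage` and `seed`.
#' @export
generate_stack <- function(config, n_frames, seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is_count(n_frames)) stopf("n_frames must be a positive integer (got %s)", n_frames)
  m <- mean_field(config)
  frames <- array(0, dim = c(nrow(m), ncol(m), n_frames))
  for (f in seq_len(n_frames)) {
    frames[, , f] <- if (config$speckle == "none") m else
      with_seed(derive_seed(seed, f),
                m * matrix(stats::rexp(length(m)), nrow(m), ncol(m)))
  }
  bscan_stack(frames, lateral_pitch_um = config$lateral_pitch_um,
              axial_pitch_um = config$axial_pitch_um,
              stage = config$stage, seed = seed, config = config)
}

#' Construct a B-scan stack
#'
#' @param frames depth x width x n_frames numeric array (or a single matrix),
#'   non-negative linear intensity.
#' @param lateral_pitch_um,axial_pitch_um pixel pitches (um/px).
#' @param stage optional stage label.
#' @param seed optional generating seed.
#' @param config optional generating `phantom_config`.
#' @export
bscan_stack <- function(frames, lateral_pitch_um, axial_pitch_um,
                        stage = NULL, seed = NULL, config = NULL) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (length(dim(frames)) != 3) stopf("frames must be a depth x width x n array")
  if (any(frames < 0)) stopf("intensities must be >= 0 (linear scale)")
  if (lateral_pitch_um <= 0 || axial_pitch_um <= 0) stopf("pitches must be > 0")
  structure(list(frames = frames, lateral_pitch_um = lateral_pitch_um,
                 axial_pitch_um = axial_pitch_um, stage = stage,
                 seed = seed, config = config),
            class = "bscan_stack")
}

#' @export
print.bscan_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<bscan_stack> %d frame(s) of %d x %d px (depth x width), %s\n",
              d[3], d[1], d[2],
              if (is.null(x$stage)) "unlabeled" else paste("stage:", x$stage)))
  cat(sprintf("  pitch: %.3f um/px lateral, %.3f um/px axial\n",
              x$lateral_pitch_um, x$axial_pitch_um))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `bscan_stack`.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Generate a labeled cohort of phantom stacks
#'
#' Per-sample configurations are drawn with small random jitter around the
#' stage presets so that classes overlap slightly rather than being
#' trivially separable: multiplicative log-normal jitter on the attenuation
#' magnitude (`sd` 0.04) and heterogeneity contrast (`sd` 0.06), and additive
#' Gaussian jitter (sd 4 um) on sub-surface interface depths.
#'
#' @param n_green,n_yellow,n_red per-stage sample counts (`>= 0`).
#' @param seed master integer seed; every sample derives its own streams.
#' @param n_frames frames per stack.
#' @param n_alines,n_depth_px frame geometry.
#' @param jitter list with elements `attenuation_sd`, `contrast_sd`,
#'   `depth_sd_um` overriding the documented defaults.
#' @return a list of `bscan_stack`s, each carrying its `stage` label;
#'   retrieve labels with [dataset_labels()].
#' @export
generate_labeled_dataset <- function(n_green, n_yellow, n_red, seed,
                                     n_frames = 24L,
                                     n_alines = 813L, n_depth_px = 750L,
                                     jitter = list()) {
  if (any(c(n_green, n_yellow, n_red) < 0)) stopf("sample counts must be >= 0")
  jit <- utils::modifyList(
    list(attenuation_sd = 0.04, contrast_sd = 0.06, depth_sd_um = 4), jitter)
  stages <- rep(c("green", "yellow", "red"), times = c(n_green, n_yellow, n_red))
  out <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    s_seed <- derive_seed(seed, i)
    cfg <- leaf_preset(stages[i], n_alines = n_alines, n_depth_px = n_depth_px,
                       seed = derive_seed(s_seed, 1L))
    cfg <- with_seed(s_seed, {
      cfg$attenuation_db_per_um <-
        cfg$attenuation_db_per_um * exp(stats::rnorm(1, 0, jit$attenuation_sd))
      cfg$texture_contrast <-
        cfg$texture_contrast * exp(stats::rnorm(1, 0, jit$contrast_sd))
      for (j in seq_along(cfg$layers)[-1]) {
        shift <- stats::rnorm(1, 0, jit$depth_sd_um)
        new_top <- max(cfg$layers[[j]]$top_depth_um + shift,
                       cfg$layers[[j - 1]]$top_depth_um +
                         cfg$layers[[j - 1]]$thickness_um)
        cfg$layers[[j]]$top_depth_um <- new_top
      }
      cfg
    })
    out[[i]] <- generate_stack(cfg, n_frames = n_frames,
                               seed = derive_seed(s_seed, 2L))
  }
  out
}

#' Stage labels of a phantom dataset
#' @param dataset list of `bscan_stack`s as returned by
#'   [generate_labeled_dataset()].
#' @return character vector of stage labels.
#' @export
dataset_labels <- function(dataset) {
  vapply(dataset, function(s) s$stage %||% NA_character_, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
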
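# Independent brute-force oracles used to pin down expected values.
# Deliberately written with explicit loops and definitional formulas,
# sharing no code with the implementation.

oracle_quantize <- function(x, G, lo = min(x), hi = max(x)) {
  q <- array(0L, dim = dim(x))
  if (hi > lo) {
    for (r in seq_len(nrow(x))) for (c in seq_len(ncol(x))) {
      v <- min(max(x[r, c], lo), hi)
      q[r, c] <- min(as.integer(floor((v - lo) / (hi - lo) * G)), G - 1L)
    }
  }
  q
}

oracle_glcm <- function(q, G, dz, dx, symmetric = TRUE) {
  counts <- matrix(0, G, G)
  for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
    r2 <- r + dz; c2 <- c + dx
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
      counts[q[r, c] + 1, q[r2, c2] + 1] <- counts[q[r, c] + 1, q[r2, c2] + 1] + 1
      if (symmetric)
        counts[q[r2, c2] + 1, q[r, c] + 1] <- counts[q[r2, c2] + 1, q[r, c] + 1] + 1
    }
  }
  counts / sum(counts)
}

# The 14 features from their definitional series, averaged over angles.
oracle_features <- function(x, G = 4, angles = c(0, 45, 90, 135),
                            symmetric = TRUE, log_base = 2) {
  q <- oracle_quantize(x, G)
  offs <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0), "135" = c(-1, -1))
  lg <- function(v) log(v, base = log_base)
  per <- sapply(as.character(angles), function(a) {
    o <- offs[[a]]
    p <- oracle_glcm(q, G, o[1], o[2], symmetric)
    lev <- 0:(G - 1)
    px <- py <- numeric(G)
    for (i in 1:G) for (j in 1:G) { px[i] <- px[i] + p[i, j]; py[j] <- py[j] + p[i, j] }
    mux <- sum(lev * px); muy <- sum(lev * py)
    sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
    psum <- numeric(2 * G - 1); pdiff <- numeric(G)
    for (i in 1:G) for (j in 1:G) {
      psum[(i - 1) + (j - 1) + 1] <- psum[(i - 1) + (j - 1) + 1] + p[i, j]
      pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
    }
    ent <- function(v) -sum(sapply(v, function(e) if (e > 0) e * lg(e) else 0))
    HX <- ent(px); HY <- ent(py); HXY <- ent(as.vector(p))
    HXY1 <- 0; HXY2 <- 0
    for (i in 1:G) for (j in 1:G) {
      pij <- px[i] * py[j]
      if (pij > 0) {
        HXY1 <- HXY1 - p[i, j] * lg(pij)
        HXY2 <- HXY2 - pij * lg(pij)
      }
    }
    ij <- 0
    for (i in 1:G) for (j in 1:G) ij <- ij + (i - 1) * (j - 1) * p[i, j]
    ks <- 0:(2 * G - 2); kd <- 0:(G - 1)
    sa <- sum(ks * psum)
    mu_d <- sum(kd * pdiff)
    c(energy = sum(p^2),
      inertia = sum(outer(lev, lev, function(a, b) (a - b)^2) * p),
      inverse_difference_moment = sum(p / (1 + outer(lev, lev, `-`)^2)),
      correlation = if (sx > 0 && sy > 0) (ij - mux * muy) / (sx * sy) else NA_real_,
      variance = sum(outer((lev - mux)^2, rep(1, G)) * p),
      entropy = HXY,
      sum_average = sa,
      sum_variance = sum((ks - sa)^2 * psum),
      sum_entropy = ent(psum),
      difference_variance = sum((kd - mu_d)^2 * pdiff),
      difference_entropy = ent(pdiff),
      imc1 = if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else NA_real_,
      imc2 = sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY)))))
  })
  n <- length(x)
  mu <- sum(x) / n
  s2 <- sum((x - mu)^2) / n
  skew <- if (s2 > 0) (sum((x - mu)^3) / n) / s2^1.5 else 0
  f <- rowMeans(per)
  c(f[1:5], skewness = skew, f[6:13])
}

# OLS slope/intercept by explicit normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  c(intercept = (sy - slope * sx) / n, slope = slope)
}

# Small single-interface phantom without sub-surface structure: the dB
# profile inside the fit window is an exact line.
flat_config <- function(attenuation = -1.0, n_alines = 64L, n_depth_px = 192L,
                        surface_depth_px = 20L, contrast = 0, seed = 1L) {
  phantom_config(stage = "flat",
                 layers = list(layer_spec("surface", 0, 500,
                                          interface_reflectivity = 40)),
                 attenuation_db_per_um = attenuation,
                 surface_depth_px = surface_depth_px,
                 n_alines = n_alines, n_depth_px = n_depth_px,
                 texture_contrast = contrast, seed = seed)
}

# Copy of a config with speckle disabled (the deterministic mean field).
within_none <- function(cfg) { cfg$speckle <- "none"; cfg }
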
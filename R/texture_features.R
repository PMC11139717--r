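# The 61-feature registry and per-family feature formulas.
#
# Registry: 10 first-order + 10 GLCM + 16 run-length + 16 size-zone +
# 5 NGTDM + 4 shape/intensity auxiliaries = 61. The ten names selected by
# the emulated analysis (LRHGE, LZHGE, Variance, GLN, Mean,
# GLCM:Correlation, CoefficientVariation, Entropy, GLV, MeanIntensity) are
# all present under exactly those names. Features whose denominator has
# zero variance are reported as NA (never silently 0), with a warning.

FEATURES_FIRST_ORDER <- c("MeanIntensity", "SDIntensity",
                          "CoefficientVariation", "Range", "Mean",
                          "Variance", "Entropy", "Skewness", "Kurtosis",
                          "Uniformity")
FEATURES_GLCM <- paste0("GLCM:", c("Correlation", "Contrast", "Energy",
                                   "Homogeneity", "Entropy", "Dissimilarity",
                                   "Autocorrelation", "ClusterShade",
                                   "ClusterProminence", "MaxProbability"))
FEATURES_GLRLM <- c("SRE", "LRE", "GLN", "GLNN", "RLN", "RLNN", "RP",
                    "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
                    "RLV", "RGLV", "RE")
FEATURES_GLSZM <- c("SZE", "LZE", "ZGN", "ZGNN", "ZSN", "ZSNN", "ZP",
                    "LGZE", "HGZE", "SZLGE", "SZHGE", "LZLGE", "LZHGE",
                    "GLV", "ZLV", "ZE")
FEATURES_NGTDM <- paste0("NGTDM:", c("Coarseness", "Contrast", "Busyness",
                                     "Complexity", "Strength"))
FEATURES_SHAPE <- c("Area", "Perimeter", "Circularity", "SolidFraction")

#' The 61-feature registry
#'
#' @return data.frame with columns `name` and `family`.
#' @export
feature_registry <- function() {
  data.frame(
    name = c(FEATURES_FIRST_ORDER, FEATURES_GLCM, FEATURES_GLRLM,
             FEATURES_GLSZM, FEATURES_NGTDM, FEATURES_SHAPE),
    family = rep(c("first_order", "glcm", "glrlm", "glszm", "ngtdm", "shape"),
                 times = c(length(FEATURES_FIRST_ORDER), length(FEATURES_GLCM),
                           length(FEATURES_GLRLM), length(FEATURES_GLSZM),
                           length(FEATURES_NGTDM), length(FEATURES_SHAPE))),
    stringsAsFactors = FALSE
  )
}

#' Texture-extraction configuration
#'
#' @param n_levels gray levels for quantization (default 32).
#' @param log_base base of the logarithm in entropy-type features
#'   (default `exp(1)`, natural log; `2` for bits).
#' @param distance GLCM offset length in pixels.
#' @param directions angles for GLCM/GLRLM, subset of `c(0, 45, 90, 135)`.
#' @param connectivity zone connectivity for the GLSZM (4 or 8).
#' @param solid_threshold HU above which a pixel counts as solid.
#' @return a `texture_config` list.
#' @export
texture_config <- function(n_levels = 32L, log_base = exp(1), distance = 1L,
                           directions = c(0, 45, 90, 135), connectivity = 8,
                           solid_threshold = -300) {
  stopifnot(n_levels >= 2L, log_base > 1, distance >= 1L,
            connectivity %in% c(4, 8))
  structure(list(n_levels = as.integer(n_levels), log_base = log_base,
                 distance = as.integer(distance), directions = directions,
                 connectivity = connectivity,
                 solid_threshold = solid_threshold),
            class = "texture_config")
}

entropy_of <- function(p, base) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' First-order intensity statistics
#'
#' `MeanIntensity`, `SDIntensity` (population), `CoefficientVariation`
#' (population SD / mean; NA with a warning when the mean HU is zero),
#' `Range`, `Skewness` and `Kurtosis` are computed on raw HU; `Mean`,
#' `Variance` (population), `Entropy` and `Uniformity` on the quantized
#' level histogram.
#'
#' @param image an [image_patch()]; `roi` a congruent [roi_mask()].
#' @param q the [quantize()]d ROI.
#' @param config a [texture_config()].
#' @return named numeric vector of the 10 first-order features.
#' @export
first_order_features <- function(image, roi, q, config = texture_config()) {
  v <- image$pixels[roi$mask]
  l <- q$levels[roi$mask]
  mu <- mean(v)
  sdp <- pop_sd(v)
  cov <- if (mu == 0) {
    warning("CoefficientVariation undefined: mean HU is zero")
    NA_real_
  } else {
    sdp / mu
  }
  skew <- if (sdp == 0) NA_real_ else mean((v - mu)^3) / sdp^3
  kurt <- if (sdp == 0) NA_real_ else mean((v - mu)^4) / sdp^4
  p <- tabulate(l, nbins = q$Ng) / length(l)
  c(MeanIntensity = mu,
    SDIntensity = sdp,
    CoefficientVariation = cov,
    Range = diff(range(v)),
    Mean = mean(l),
    Variance = mean((l - mean(l))^2),
    Entropy = entropy_of(p, config$log_base),
    Skewness = skew,
    Kurtosis = kurt,
    Uniformity = sum(p^2))
}

#' Co-occurrence features from a GLCM
#'
#' `Correlation` follows the marginal-moment form
#' `(sum_ij p(i,j) i j - mu_x mu_y) / (sigma_x sigma_y)` and is NA (with a
#' warning) when either marginal has zero variance.
#'
#' @param glcm joint probability matrix from [build_glcm()].
#' @param log_base entropy log base.
#' @return named numeric vector of the 10 co-occurrence features.
#' @export
glcm_features <- function(glcm, log_base = exp(1)) {
  Ng <- nrow(glcm)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(glcm)
  py <- colSums(glcm)
  mux <- sum(px * seq_len(Ng))
  muy <- sum(py * seq_len(Ng))
  sx <- sqrt(sum(px * (seq_len(Ng) - mux)^2))
  sy <- sqrt(sum(py * (seq_len(Ng) - muy)^2))
  corr <- if (sx * sy == 0) {
    warning("GLCM:Correlation undefined: a marginal has zero variance")
    NA_real_
  } else {
    (sum(glcm * i * j) - mux * muy) / (sx * sy)
  }
  out <- c(corr,
           sum(glcm * (i - j)^2),
           sum(glcm^2),
           sum(glcm / (1 + (i - j)^2)),
           entropy_of(as.numeric(glcm), log_base),
           sum(glcm * abs(i - j)),
           sum(glcm * i * j),
           sum(glcm * (i + j - mux - muy)^3),
           sum(glcm * (i + j - mux - muy)^4),
           max(glcm))
  names(out) <- FEATURES_GLCM
  out
}

# Run-length features for a single direction's count matrix.
glrlm_features_one <- function(P, n_pixels, log_base) {
  Nr <- sum(P)
  Ng <- nrow(P)
  Rm <- ncol(P)
  i <- seq_len(Ng)
  j <- seq_len(Rm)
  pg <- rowSums(P)
  pr <- colSums(P)
  Iw <- matrix(i, Ng, Rm)
  Jw <- matrix(j, Ng, Rm, byrow = TRUE)
  p <- P / Nr
  mu_j <- sum(p * Jw)
  mu_i <- sum(p * Iw)
  out <- c(SRE = sum(pr / j^2) / Nr,
           LRE = sum(pr * j^2) / Nr,
           GLN = sum(pg^2) / Nr,
           GLNN = sum(pg^2) / Nr^2,
           RLN = sum(pr^2) / Nr,
           RLNN = sum(pr^2) / Nr^2,
           RP = Nr / n_pixels,
           LGRE = sum(pg / i^2) / Nr,
           HGRE = sum(pg * i^2) / Nr,
           SRLGE = sum(P / (Iw^2 * Jw^2)) / Nr,
           SRHGE = sum(P * Iw^2 / Jw^2) / Nr,
           LRLGE = sum(P * Jw^2 / Iw^2) / Nr,
           LRHGE = sum(P * Iw^2 * Jw^2) / Nr,
           RLV = sum(p * (Jw - mu_j)^2),
           RGLV = sum(p * (Iw - mu_i)^2),
           RE = entropy_of(as.numeric(p), log_base))
  out
}

#' Run-length features, direction-averaged
#'
#' Standard run-length formulas per direction, averaged over the direction
#' set of the input list.
#'
#' @param glrlm output of [build_glrlm()].
#' @param log_base entropy log base.
#' @return named numeric vector of the 16 run-length features.
#' @export
glrlm_features <- function(glrlm, log_base = exp(1)) {
  n_px <- attr(glrlm, "n_pixels")
  per_dir <- vapply(glrlm, glrlm_features_one, numeric(16),
                    n_pixels = n_px, log_base = log_base)
  out <- rowMeans(per_dir)
  names(out) <- FEATURES_GLRLM
  out
}

#' Size-zone features
#'
#' Standard size-zone formulas; `GLV` is the gray-level variance and `ZLV`
#' the zone-size variance, both over the zone probability distribution.
#'
#' @param glszm output of [build_glszm()].
#' @param log_base entropy log base.
#' @return named numeric vector of the 16 size-zone features.
#' @export
glszm_features <- function(glszm, log_base = exp(1)) {
  n_px <- attr(glszm, "n_pixels")
  Nz <- sum(glszm)
  Ng <- nrow(glszm)
  Sm <- ncol(glszm)
  i <- seq_len(Ng)
  j <- seq_len(Sm)
  pg <- rowSums(glszm)
  ps <- colSums(glszm)
  Iw <- matrix(i, Ng, Sm)
  Jw <- matrix(j, Ng, Sm, byrow = TRUE)
  p <- glszm / Nz
  mu_i <- sum(p * Iw)
  mu_j <- sum(p * Jw)
  out <- c(SZE = sum(ps / j^2) / Nz,
           LZE = sum(ps * j^2) / Nz,
           ZGN = sum(pg^2) / Nz,
           ZGNN = sum(pg^2) / Nz^2,
           ZSN = sum(ps^2) / Nz,
           ZSNN = sum(ps^2) / Nz^2,
           ZP = Nz / n_px,
           LGZE = sum(pg / i^2) / Nz,
           HGZE = sum(pg * i^2) / Nz,
           SZLGE = sum(glszm / (Iw^2 * Jw^2)) / Nz,
           SZHGE = sum(glszm * Iw^2 / Jw^2) / Nz,
           LZLGE = sum(glszm * Jw^2 / Iw^2) / Nz,
           LZHGE = sum(glszm * Iw^2 * Jw^2) / Nz,
           GLV = sum(p * (Iw - mu_i)^2),
           ZLV = sum(p * (Jw - mu_j)^2),
           ZE = entropy_of(as.numeric(p), log_base))
  names(out) <- FEATURES_GLSZM
  out
}

#' Neighborhood gray-tone-difference features
#'
#' Coarseness, contrast, busyness, complexity and strength per the standard
#' formulation. For a single-gray-level ROI, contrast, busyness and
#' strength are 0 and coarseness is NA (its denominator vanishes), with a
#' warning.
#'
#' @param q a [quantize()]d ROI.
#' @return named numeric vector of the 5 NGTDM features.
#' @export
ngtdm_features <- function(q) {
  m <- build_ngtdm(q)
  p <- m$p_i
  s <- m$s_i
  N <- m$n_valid
  act <- which(p > 0)
  Ngp <- length(act)
  den_coarse <- sum(p * s)
  coarse <- if (den_coarse > 0) 1 / den_coarse else {
    warning("NGTDM:Coarseness undefined: flat neighborhood differences")
    NA_real_
  }
  if (Ngp <= 1L) {
    contrast <- 0
    busyness <- 0
    complexity <- 0
    strength <- 0
  } else {
    ii <- act[rep(seq_len(Ngp), each = Ngp)]
    jj <- act[rep(seq_len(Ngp), times = Ngp)]
    contrast <- sum(p[ii] * p[jj] * (ii - jj)^2) / (Ngp * (Ngp - 1)) *
      sum(s) / N
    den_busy <- sum(abs(ii * p[ii] - jj * p[jj]))
    busyness <- if (den_busy > 0) sum(p * s) / den_busy else 0
    complexity <- sum(abs(ii - jj) * (p[ii] * s[ii] + p[jj] * s[jj]) /
                        (p[ii] + p[jj])) / N
    strength <- if (sum(s) > 0) {
      sum((p[ii] + p[jj]) * (ii - jj)^2) / sum(s)
    } else 0
  }
  out <- c(coarse, contrast, busyness, complexity, strength)
  names(out) <- FEATURES_NGTDM
  out
}

# Shape and intensity auxiliaries: physical area, boundary-edge perimeter,
# circularity (1 for a disk, lower otherwise), and the fraction of ROI
# pixels above the solid-attenuation threshold.
shape_features <- function(image, roi, solid_threshold = -300) {
  m <- roi$mask
  sp <- image$spacing
  n_px <- sum(m)
  area <- n_px * sp[1] * sp[2]
  pad <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  edges_h <- sum(pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] &
                   !pad[1:nrow(m), 2:(ncol(m) + 1L)]) +
    sum(pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] &
          !pad[3:(nrow(m) + 2L), 2:(ncol(m) + 1L)])
  edges_v <- sum(pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] &
                   !pad[2:(nrow(m) + 1L), 1:ncol(m)]) +
    sum(pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] &
          !pad[2:(nrow(m) + 1L), 3:(ncol(m) + 2L)])
  perim <- edges_h * sp[2] + edges_v * sp[1]
  circ <- 4 * pi * area / perim^2
  solid_frac <- mean(image$pixels[m] > solid_threshold)
  c(Area = area, Perimeter = perim, Circularity = circ,
    SolidFraction = solid_frac)
}

#' Extract the full 61-feature vector of a segmented nodule
#'
#' Quantizes the ROI and computes all first-order, GLCM, GLRLM, GLSZM,
#' NGTDM and shape features under one configuration. Feature order and
#' naming follow [feature_registry()] and are stable across runs.
#'
#' @param image an [image_patch()].
#' @param roi a congruent [roi_mask()].
#' @param config a [texture_config()].
#' @return named numeric vector of length 61 with attribute `config`.
#' @export
extract_all <- function(image, roi, config = texture_config()) {
  q <- quantize(image, roi, config$n_levels)
  glcm <- build_glcm(q, distance = config$distance,
                     directions = config$directions, symmetric = TRUE)
  glrlm <- build_glrlm(q, directions = config$directions)
  glszm <- build_glszm(q, connectivity = config$connectivity)
  out <- c(first_order_features(image, roi, q, config),
           glcm_features(glcm, config$log_base),
           glrlm_features(glrlm, config$log_base),
           glszm_features(glszm, config$log_base),
           ngtdm_features(q),
           shape_features(image, roi, config$solid_threshold))
  stopifnot(identical(names(out), feature_registry()$name))
  attr(out, "config") <- config
  out
}

#' Average two readers' feature vectors
#'
#' Element-wise arithmetic mean of two feature vectors with identical
#' names; a value missing in either reader is missing in the average.
#'
#' @param a,b named numeric feature vectors.
#' @return named numeric vector of the same length.
#' @export
average_readers <- function(a, b) {
  if (!identical(names(a), names(b))) {
    stop("feature names of the two readers do not match")
  }
  out <- (as.numeric(a) + as.numeric(b)) / 2
  names(out) <- names(a)
  attr(out, "config") <- attr(a, "config")
  out
}
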
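# Synthetic part-solid ground-glass nodule cohort.
#
# The study cohort this emulates is not publicly deposited, so every
# downstream stage is exercised on synthetic cases with the statistical
# structure the analysis assumes: a 16/48 split of nodules with/without
# solid or micropapillary components, part-solid ground-glass intensity
# structure (lung background around -850 HU, ground-glass around -600 HU,
# solid tissue around -50 HU) on a 1024-pixel matrix at ~0.337 mm/px, and a
# class contrast in heterogeneity carried both by the solid-area fraction
# and by the amplitude of intra-nodule speckle, so that first-order and
# matrix features are all informative and the positive class has higher
# entropy and a more negative coefficient of variation.

#' Specification of a synthetic nodule cohort
#'
#' Defaults encode the emulated study cohort: 16 positive (nodules with a
#' solid or micropapillary component) and 48 negative cases, a 1024-pixel
#' matrix at 345 mm field of view (0.337 mm/px), lung/ground-glass/solid
#' intensity modes at -850/-600/-50 HU and 30 HU acquisition noise.
#' Positive nodules carry a larger solid-area fraction and stronger
#' intra-nodule speckle than negatives.
#'
#' @param n_positive,n_negative class sizes (both at least 1).
#' @param image_size pixels per side of the square matrix.
#' @param pixel_spacing mm per pixel.
#' @param hu_lung,hu_ggo,hu_solid mean intensities (HU) of lung background,
#'   ground-glass and solid tissue; must lie in `[-1024, 500]`.
#' @param noise_sd additive Gaussian pixel noise, HU.
#' @param solid_fraction_pos,solid_fraction_neg fraction of nodule area at
#'   solid intensity, per class, in `[0, 1]`.
#' @param speckle_amplitude_pos,speckle_amplitude_neg HU standard deviation
#'   of the low-pass-filtered intra-nodule texture field, per class.
#' @param seed mandatory random seed; the same spec and seed reproduce the
#'   cohort bit for bit.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_positive = 16L, n_negative = 48L,
                        image_size = 1024L, pixel_spacing = 345 / 1024,
                        hu_lung = -850, hu_ggo = -600, hu_solid = -50,
                        noise_sd = 30,
                        solid_fraction_pos = 0.6, solid_fraction_neg = 0.15,
                        speckle_amplitude_pos = 120,
                        speckle_amplitude_neg = 40,
                        seed) {
  if (missing(seed)) stop("cohort_spec: a seed is mandatory")
  spec <- list(n_positive = as.integer(n_positive),
               n_negative = as.integer(n_negative),
               image_size = as.integer(image_size),
               pixel_spacing = as.numeric(pixel_spacing),
               hu_lung = hu_lung, hu_ggo = hu_ggo, hu_solid = hu_solid,
               noise_sd = noise_sd,
               solid_fraction_pos = solid_fraction_pos,
               solid_fraction_neg = solid_fraction_neg,
               speckle_amplitude_pos = speckle_amplitude_pos,
               speckle_amplitude_neg = speckle_amplitude_neg,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_positive < 1L || spec$n_negative < 1L) {
    stop("both classes must have at least one case (ROC is undefined otherwise)")
  }
  hu <- c(spec$hu_lung, spec$hu_ggo, spec$hu_solid)
  if (any(hu < -1024 | hu > 500)) stop("HU modes must lie within [-1024, 500]")
  sf <- c(spec$solid_fraction_pos, spec$solid_fraction_neg)
  if (any(sf < 0 | sf > 1)) stop("solid fractions must lie in [0, 1]")
  if (spec$noise_sd < 0 || spec$speckle_amplitude_pos < 0 ||
      spec$speckle_amplitude_neg < 0) {
    stop("noise and speckle amplitudes must be non-negative")
  }
  if (spec$image_size < 16L) stop("image_size must be at least 16")
  if (spec$pixel_spacing <= 0) stop("pixel_spacing must be positive")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> %d positive / %d negative, %d px @ ",
                     "%.4f mm, seed %d\n"),
              x$n_positive, x$n_negative, x$image_size, x$pixel_spacing,
              x$seed))
  invisible(x)
}

#' Generate one synthetic part-solid nodule case
#'
#' Draws a rotated ellipse (axes 8-40 px) on lung background, fills it with
#' ground-glass attenuation, adds 1-4 solid-intensity disks covering the
#' class's solid-area fraction, overlays a low-pass-filtered speckle field
#' at the class's amplitude plus white acquisition noise. The truth mask
#' marks the ellipse exactly. Pure function of `(spec, label, case_seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param label 1 = has solid/micropapillary component, 0 = without.
#' @param case_seed per-case random seed.
#' @param case_id identifier carried on the output.
#' @return a `synthetic_case`: list with `image` ([image_patch()]),
#'   `truth_mask` ([roi_mask()]), `label` and `case_id`.
#' @export
generate_nodule <- function(spec, label, case_seed, case_id = "case") {
  validate_cohort_spec(spec)
  stopifnot(label %in% c(0L, 1L))
  label <- as.integer(label)
  n <- spec$image_size
  with_seed(case_seed, {
    a <- runif(1, 8, 40)
    b <- runif(1, 8, 40)
    theta <- runif(1, 0, pi)
    rmax <- max(a, b)
    if (2 * rmax + 4 > n) {
      stop(sprintf("nodule axes (%.1f x %.1f px) do not fit a %d px image",
                   a, b, n))
    }
    cr <- runif(1, rmax + 2, n - rmax - 1)
    cc <- runif(1, rmax + 2, n - rmax - 1)

    # Work on the nodule bounding box only; the rest is background noise.
    r0 <- max(1L, floor(cr - rmax) - 1L)
    r1 <- min(n, ceiling(cr + rmax) + 1L)
    c0 <- max(1L, floor(cc - rmax) - 1L)
    c1 <- min(n, ceiling(cc + rmax) + 1L)
    rr <- r0:r1
    cci <- c0:c1
    gr <- outer(rr - cr, rep(1, length(cci)))
    gc <- outer(rep(1, length(rr)), cci - cc)
    u <- (gr * cos(theta) + gc * sin(theta)) / a
    v <- (-gr * sin(theta) + gc * cos(theta)) / b
    rad2 <- u^2 + v^2
    inside <- rad2 <= 1

    img <- matrix(rnorm(n * n, spec$hu_lung, spec$noise_sd), n, n)

    base <- matrix(spec$hu_ggo, length(rr), length(cci))
    frac <- if (label == 1L) spec$solid_fraction_pos else spec$solid_fraction_neg
    if (frac > 0) {
      k <- sample(1:4, 1)
      area <- sum(inside)
      target <- frac * area
      radii <- sqrt(target / (k * pi)) * runif(k, 0.8, 1.2)
      core <- which(rad2 <= 0.49 & inside)   # centers in the inner 70%
      if (length(core) == 0L) core <- which(inside)
      centers <- sample(core, k, replace = TRUE)
      ctr_r <- (centers - 1L) %% length(rr) + 1L
      ctr_c <- (centers - 1L) %/% length(rr) + 1L
      for (i in seq_len(k)) {
        d2 <- outer(seq_along(rr) - ctr_r[i], rep(1, length(cci)))^2 +
          outer(rep(1, length(rr)), seq_along(cci) - ctr_c[i])^2
        base[d2 <= radii[i]^2 & inside] <- spec$hu_solid
      }
    }

    amp <- if (label == 1L) spec$speckle_amplitude_pos else spec$speckle_amplitude_neg
    vals <- base[inside]
    if (amp > 0) {
      field <- smooth_gaussian(matrix(rnorm(length(rr) * length(cci)),
                                      length(rr), length(cci)), sigma = 2)
      fsd <- pop_sd(as.numeric(field))
      if (fsd > 0) field <- field / fsd
      vals <- vals + amp * field[inside]
    }
    if (spec$noise_sd > 0) vals <- vals + rnorm(length(vals), 0, spec$noise_sd)
    block <- img[rr, cci]
    block[inside] <- vals
    img[rr, cci] <- block
    img[img < -1024] <- -1024
    img[img > 3071] <- 3071

    mask <- matrix(FALSE, n, n)
    mask[rr, cci] <- inside
    structure(list(
      image = image_patch(img, spacing = rep(spec$pixel_spacing, 2L),
                          origin = case_id),
      truth_mask = roi_mask(mask, reader_id = "truth", min_pixels = 64L),
      label = label,
      case_id = as.character(case_id)
    ), class = "synthetic_case")
  })
}

#' Generate a full synthetic cohort
#'
#' Exactly `n_positive` label-1 and `n_negative` label-0 cases in a
#' deterministically shuffled order; per-case seeds are derived from the
#' spec seed, so the whole cohort is a pure function of the spec.
#'
#' @param spec a [cohort_spec()].
#' @return list of `synthetic_case` objects.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n_positive + spec$n_negative
  labels <- c(rep(1L, spec$n_positive), rep(0L, spec$n_negative))
  seeds <- derive_seeds(spec$seed, n + 1L)
  ord <- with_seed(seeds[n + 1L], sample.int(n))
  labels <- labels[ord]
  lapply(seq_len(n), function(i) {
    generate_nodule(spec, labels[i], case_seed = seeds[i],
                    case_id = sprintf("case%03d", i))
  })
}

#' Write a cohort to disk (NIfTI images + manifest CSV)
#'
#' One image and one truth mask per case plus `manifest.csv` with columns
#' `case_id`, `label`, `image`, `mask`.
#'
#' @param cases list of `synthetic_case`.
#' @param dir output directory (created if needed).
#' @param compress write `.nii.gz` (default) or plain `.nii`.
#' @return path of the manifest, invisibly.
#' @export
write_cohort <- function(cases, dir, compress = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  rows <- lapply(cases, function(cs) {
    ip <- file.path(dir, paste0(cs$case_id, "_image", ext))
    mp <- file.path(dir, paste0(cs$case_id, "_mask", ext))
    write_case(cs$image, ip, cs$truth_mask, mp)
    data.frame(case_id = cs$case_id, label = cs$label,
               image = basename(ip), mask = basename(mp))
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(dir, "manifest.csv")
  write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest path to `manifest.csv`.
#' @return list of `synthetic_case` objects.
#' @export
read_cohort <- function(manifest) {
  man <- read.csv(manifest, stringsAsFactors = FALSE)
  dir <- dirname(manifest)
  lapply(seq_len(nrow(man)), function(i) {
    cs <- read_case(file.path(dir, man$image[i]),
                    file.path(dir, man$mask[i]), reader_id = "truth")
    structure(list(image = cs$image, truth_mask = cs$mask,
                   label = as.integer(man$label[i]),
                   case_id = man$case_id[i]),
              class = "synthetic_case")
  })
}

#' Generate a synthetic feature table for the selection stage
#'
#' Noise features are standard normal independent of the label; informative
#' features are shifted upward by `effect_size` standard deviations in the
#' positive class.
#'
#' @param n_cases number of cases (at least 10; cross-validation is
#'   infeasible below that).
#' @param n_features number of feature columns.
#' @param informative integer indices of informative features.
#' @param effect_size standardized mean shift (non-negative).
#' @param label_fraction proportion of positive cases.
#' @param seed random seed.
#' @return a `feature_table`: data.frame with `case_id`, `label` and
#'   feature columns `F01`, `F02`, ...
#' @export
generate_feature_table <- function(n_cases, n_features, informative = integer(0),
                                   effect_size = 0, label_fraction = 0.25,
                                   seed) {
  if (n_cases < 10L) stop("n_cases must be at least 10 (CV infeasible below)")
  if (effect_size < 0) stop("effect_size must be non-negative")
  informative <- as.integer(informative)
  if (length(informative) && (min(informative) < 1L ||
                              max(informative) > n_features)) {
    stop("informative indices must lie in 1..n_features")
  }
  n_pos <- max(1L, round(n_cases * label_fraction))
  with_seed(seed, {
    labels <- sample(c(rep(1L, n_pos), rep(0L, n_cases - n_pos)))
    x <- matrix(rnorm(n_cases * n_features), n_cases, n_features)
    if (length(informative) && effect_size > 0) {
      x[labels == 1L, informative] <- x[labels == 1L, informative] + effect_size
    }
    colnames(x) <- sprintf("F%02d", seq_len(n_features))
    df <- data.frame(case_id = sprintf("case%03d", seq_len(n_cases)),
                     label = labels, x, check.names = FALSE)
    class(df) <- c("feature_table", "data.frame")
    df
  })
}

#' Generate synthetic reader predictions
#'
#' Each positive case is predicted positive with probability `sens`, each
#' negative case predicted negative with probability `spec_`, independently.
#'
#' @param truth binary ground-truth labels.
#' @param sens,spec_ target sensitivity and specificity in `[0, 1]`.
#' @param seed random seed.
#' @return integer vector of 0/1 predictions, same length as `truth`.
#' @export
generate_reader_table <- function(truth, sens, spec_, seed) {
  if (length(truth) == 0L) stop("truth must be non-empty")
  if (!all(truth %in% c(0L, 1L))) stop("truth must be binary")
  if (sens < 0 || sens > 1 || spec_ < 0 || spec_ > 1) {
    stop("sens and spec_ must lie in [0, 1]")
  }
  truth <- as.integer(truth)
  with_seed(seed, {
    p <- ifelse(truth == 1L, sens, 1 - spec_)
    as.integer(rbinom(length(truth), 1L, p))
  })
}
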
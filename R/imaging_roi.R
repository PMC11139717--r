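# Image/ROI containers and the semi-automatic segmentation surrogate.
#
# The workflow this mirrors: a reader surrounds the nodule with a rectangle,
# the software thresholds and delineates the nodule automatically, and the
# reader may overwrite the result with a manually corrected mask. The
# commercial tool's algorithm is unpublished; the surrogate here (bimodal
# threshold inside the rectangle, largest 8-connected component, hole
# filling) is a documented, reproducible stand-in, and externally supplied
# masks are accepted on equal footing.

#' Construct a 2D CT image patch
#'
#' @param pixels numeric matrix of Hounsfield units.
#' @param spacing mm per pixel along (row, col).
#' @param origin free-text identifier of the source slice.
#' @return an `image_patch` object.
#' @export
image_patch <- function(pixels, spacing = c(1, 1), origin = "slice") {
  stopifnot(is.matrix(pixels))
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (!all(is.finite(pixels))) stop("image contains non-finite values")
  if (any(pixels < -1024 | pixels > 3071)) {
    stop("HU values must lie within [-1024, 3071]")
  }
  if (nrow(pixels) < 16L || ncol(pixels) < 16L) {
    stop("image must be at least 16 x 16 pixels")
  }
  structure(list(pixels = pixels, spacing = as.numeric(spacing),
                 origin = as.character(origin)),
            class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("<image_patch> %d x %d px, %.4f x %.4f mm/px, origin '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              x$origin))
  invisible(x)
}

#' Construct a binary region-of-interest mask
#'
#' The foreground must be a single 8-connected region of at least
#' `min_pixels` pixels, congruent with the image it annotates.
#'
#' @param mask logical or 0/1 matrix.
#' @param reader_id identifier of the delineator (reader or algorithm).
#' @param min_pixels minimum foreground size.
#' @return a `roi_mask` object.
#' @export
roi_mask <- function(mask, reader_id = "auto", min_pixels = 16L) {
  stopifnot(is.matrix(mask))
  m <- mask != 0
  n_fg <- sum(m)
  if (n_fg < min_pixels) {
    stop(sprintf("ROI has %d foreground pixels; at least %d required",
                 n_fg, min_pixels))
  }
  lab <- label_components(m, connectivity = 8)
  if (lab$n != 1L) {
    stop(sprintf("ROI foreground must be one 8-connected region (found %d)",
                 lab$n))
  }
  structure(list(mask = m, reader_id = as.character(reader_id)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d px foreground, reader '%s'\n",
              sum(x$mask), x$reader_id))
  invisible(x)
}

# Otsu's bimodal histogram split: threshold maximizing between-class
# variance over a fixed-bin histogram of the rectangle's intensities.
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins)
  between[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  edges[which.max(between) + 1L]   # upper edge of the best split bin
}

#' Semi-automatic nodule segmentation inside a seed rectangle
#'
#' Thresholds the rectangle's intensities at an automatically chosen level
#' (Otsu bimodal split), keeps the largest 8-connected foreground component
#' and fills its interior holes. Deterministic for fixed input.
#'
#' The threshold is estimated on intensities clipped from above at
#' `clip_hu`: part-solid nodules have a trimodal histogram (lung,
#' ground-glass, solid) and the boundary of interest is lung-vs-nodule;
#' clipping folds the solid mode — which is unambiguously nodule — into
#' the ground-glass mode so the bimodal split lands on that boundary.
#'
#' @param image an [image_patch()].
#' @param rect integer vector `c(row_min, row_max, col_min, col_max)`,
#'   1-based inclusive bounds of the seed rectangle.
#' @param reader_id recorded on the returned mask.
#' @param min_pixels minimum acceptable nodule size in pixels.
#' @param clip_hu upper clip for threshold estimation (default -300, the
#'   solid-attenuation cap); use `Inf` for plain Otsu.
#' @return a full-image [roi_mask()].
#' @export
segment_nodule <- function(image, rect, reader_id = "auto", min_pixels = 16L,
                           clip_hu = -300) {
  stopifnot(inherits(image, "image_patch"), length(rect) == 4L)
  rect <- as.integer(rect)
  px <- image$pixels
  if (rect[1] < 1L || rect[3] < 1L || rect[2] > nrow(px) || rect[4] > ncol(px) ||
      rect[1] > rect[2] || rect[3] > rect[4]) {
    stop("rectangle out of image bounds or degenerate")
  }
  if ((rect[2] - rect[1] + 1L) * (rect[4] - rect[3] + 1L) < 16L) {
    stop("rectangle must cover at least 16 pixels")
  }
  sub <- px[rect[1]:rect[2], rect[3]:rect[4], drop = FALSE]
  thr <- otsu_threshold(pmin(as.numeric(sub), clip_hu))
  fg <- sub > thr
  if (!any(fg)) stop("empty segmentation: no pixels above threshold")
  lab <- label_components(fg, connectivity = 8)
  sizes <- component_sizes(lab)
  fg <- lab$labels == which.max(sizes)
  # Hole filling: background components (4-connectivity) that do not touch
  # the rectangle border are interior holes.
  bg <- label_components(!fg, connectivity = 4)
  if (bg$n > 0L) {
    border_labs <- unique(c(bg$labels[1, ], bg$labels[nrow(bg$labels), ],
                            bg$labels[, 1], bg$labels[, ncol(bg$labels)]))
    hole <- bg$labels > 0L & !(bg$labels %in% border_labs)
    fg[hole] <- TRUE
  }
  if (sum(fg) < min_pixels) {
    stop(sprintf("empty segmentation: largest component has %d < %d pixels",
                 sum(fg), min_pixels))
  }
  full <- matrix(FALSE, nrow(px), ncol(px))
  full[rect[1]:rect[2], rect[3]:rect[4]] <- fg
  roi_mask(full, reader_id = reader_id, min_pixels = min_pixels)
}

#' Apply an optional manual mask correction
#'
#' Mirrors the reading workflow: the automatic delineation stands unless the
#' reader supplies a corrected mask, which then replaces it verbatim (after
#' validation against the ROI invariants).
#'
#' @param auto the automatic [roi_mask()].
#' @param manual optional corrected mask (`roi_mask`, matrix, or `NULL`).
#' @param reader_id recorded on a matrix-supplied manual mask.
#' @return a validated [roi_mask()].
#' @export
apply_manual_override <- function(auto, manual = NULL, reader_id = "manual") {
  stopifnot(inherits(auto, "roi_mask"))
  if (is.null(manual)) return(auto)
  if (is.matrix(manual)) manual <- roi_mask(manual, reader_id = reader_id)
  stopifnot(inherits(manual, "roi_mask"))
  if (!identical(dim(manual$mask), dim(auto$mask))) {
    stop("manual mask shape does not match the automatic mask")
  }
  manual
}

#' Select the cross-section with the largest solid component
#'
#' Given an ordered stack of image/mask pairs, returns the (1-based) index
#' of the slice whose ROI contains the most pixels above the solid-component
#' threshold; if no ROI pixel anywhere exceeds it (a pure ground-glass
#' lesion), falls back to the slice with the largest ROI area. Ties go to
#' the earliest slice.
#'
#' @param images list of [image_patch()].
#' @param masks list of [roi_mask()] congruent with `images`.
#' @param solid_threshold HU above which a pixel counts as solid
#'   (default -300, separating ground-glass from solid attenuation).
#' @return integer slice index.
#' @export
select_max_solid_slice <- function(images, masks, solid_threshold = -300) {
  if (length(images) == 0L) stop("empty slice stack")
  stopifnot(length(images) == length(masks))
  solid <- vapply(seq_along(images), function(i) {
    sum(images[[i]]$pixels[masks[[i]]$mask] > solid_threshold)
  }, numeric(1))
  if (any(solid > 0)) return(which.max(solid))
  areas <- vapply(masks, function(m) sum(m$mask), numeric(1))
  which.max(areas)
}

#' Dice overlap of two masks
#'
#' @param a,b `roi_mask` objects or logical matrices of equal shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  ma <- if (inherits(a, "roi_mask")) a$mask else a != 0
  mb <- if (inherits(b, "roi_mask")) b$mask else b != 0
  stopifnot(identical(dim(ma), dim(mb)))
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}

#' Write an image/mask pair as NIfTI
#'
#' @param image an [image_patch()]; `mask` a congruent [roi_mask()] or NULL.
#' @param image_path,mask_path output paths (`.nii` / `.nii.gz`).
#' @return invisibly, the paths written.
#' @export
write_case <- function(image, image_path, mask = NULL, mask_path = NULL) {
  write_nifti(image$pixels, image_path, spacing = image$spacing,
              datatype = "float64")
  if (!is.null(mask)) {
    stopifnot(!is.null(mask_path))
    write_nifti(mask$mask + 0L, mask_path, spacing = image$spacing,
                datatype = "uint8")
  }
  invisible(c(image_path, mask_path))
}

#' Read an image (and optional mask) written by [write_case()]
#'
#' @param image_path,mask_path NIfTI paths.
#' @param reader_id recorded on the returned mask.
#' @return list with `image` and (if requested) `mask`.
#' @export
read_case <- function(image_path, mask_path = NULL, reader_id = "file") {
  img <- read_nifti(image_path)
  out <- list(image = image_patch(img$pixels, spacing = img$spacing,
                                  origin = basename(image_path)))
  if (!is.null(mask_path)) {
    mk <- read_nifti(mask_path)
    out$mask <- roi_mask(mk$pixels, reader_id = reader_id)
  }
  out
}
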
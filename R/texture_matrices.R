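# Gray-level quantization and texture-matrix construction.
#
# All matrices operate on a quantized ROI: integer levels 1..Ng inside the
# mask, 0 outside. Conventions (2D defaults; the source analysis specifies
# none): GLCM distance 1 with four directions (0, 45, 90, 135 degrees),
# symmetric, direction-averaged; GLRLM over the same four directions,
# direction-averaged; GLSZM zones under 8-connectivity; NGTDM over the
# 8-neighborhood restricted to the ROI.

#' Quantize an ROI to equal-width gray levels
#'
#' Equal-width binning of the ROI's HU range into `n_levels` bins; a
#' constant ROI maps entirely to level 1.
#'
#' @param image an [image_patch()].
#' @param roi a congruent [roi_mask()].
#' @param n_levels number of gray levels (at least 2; default 32).
#' @return a `quantized_roi`: list with `levels` (integer matrix, 0 outside
#'   the ROI), `Ng`, and `bin_edges` (length `n_levels + 1`).
#' @export
quantize <- function(image, roi, n_levels = 32L) {
  stopifnot(inherits(image, "image_patch"), inherits(roi, "roi_mask"),
            identical(dim(image$pixels), dim(roi$mask)))
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be at least 2")
  v <- image$pixels[roi$mask]
  rng <- range(v)
  lev <- matrix(0L, nrow(image$pixels), ncol(image$pixels))
  if (diff(rng) == 0) {
    lev[roi$mask] <- 1L
    edges <- seq(rng[1] - 0.5, rng[1] + 0.5, length.out = n_levels + 1L)
  } else {
    edges <- seq(rng[1], rng[2], length.out = n_levels + 1L)
    lev[roi$mask] <- findInterval(v, edges, all.inside = TRUE)
  }
  structure(list(levels = lev, Ng = n_levels, bin_edges = edges),
            class = "quantized_roi")
}

# Crop the level matrix to the ROI bounding box (all matrix builders are
# translation-invariant, and this keeps costs proportional to nodule size).
crop_levels <- function(q) {
  lev <- q$levels
  rs <- which(rowSums(lev > 0L) > 0L)
  cs <- which(colSums(lev > 0L) > 0L)
  lev[min(rs):max(rs), min(cs):max(cs), drop = FALSE]
}

direction_offsets <- function(directions, distance = 1L) {
  lapply(directions, function(ang) {
    switch(as.character(ang),
           "0" = c(0L, distance),
           "45" = c(-distance, distance),
           "90" = c(-distance, 0L),
           "135" = c(-distance, -distance),
           stop("directions must be a subset of {0, 45, 90, 135}"))
  })
}

#' Build a gray-level co-occurrence matrix
#'
#' Counts co-occurring level pairs at the given pixel offset(s), restricted
#' to pairs with both pixels inside the ROI, symmetrized, normalized to sum
#' 1 per direction and averaged over directions.
#'
#' @param q a [quantize()]d ROI.
#' @param distance offset length in pixels.
#' @param directions angles in degrees, subset of `c(0, 45, 90, 135)`.
#' @param symmetric count each pair in both orders (default TRUE).
#' @return `Ng x Ng` joint probability matrix.
#' @export
build_glcm <- function(q, distance = 1L, directions = c(0, 45, 90, 135),
                       symmetric = TRUE) {
  stopifnot(inherits(q, "quantized_roi"))
  assert_flag(symmetric, "symmetric")
  lev <- crop_levels(q)
  Ng <- q$Ng
  nr <- nrow(lev)
  nc <- ncol(lev)
  acc <- matrix(0, Ng, Ng)
  used <- 0L
  for (off in direction_offsets(directions, as.integer(distance))) {
    dr <- off[1]
    dc <- off[2]
    r_lo <- max(1L, 1L - dr); r_hi <- min(nr, nr - dr)
    c_lo <- max(1L, 1L - dc); c_hi <- min(nc, nc - dc)
    if (r_lo > r_hi || c_lo > c_hi) next
    r_a <- r_lo:r_hi
    c_a <- c_lo:c_hi
    a <- lev[r_a, c_a, drop = FALSE]
    b <- lev[r_a + dr, c_a + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (!any(keep)) next
    cnt <- matrix(tabulate((a[keep] - 1L) * Ng + b[keep], nbins = Ng * Ng),
                  Ng, Ng, byrow = TRUE)
    if (symmetric) cnt <- cnt + t(cnt)
    acc <- acc + cnt / sum(cnt)
    used <- used + 1L
  }
  if (used == 0L) stop("degenerate ROI: no valid pixel pair for the GLCM")
  acc / used
}

# Extract the pixel sequences along each direction as a list of vectors
# (0 = outside ROI). Line ordering within each vector follows increasing
# column index, which is consecutive along the line for all four angles.
level_lines <- function(lev, direction) {
  idx <- switch(as.character(direction),
                "0" = row(lev),
                "90" = col(lev),
                "45" = row(lev) + col(lev),
                "135" = row(lev) - col(lev),
                stop("directions must be a subset of {0, 45, 90, 135}"))
  split(lev, idx)
}

#' Build gray-level run-length matrices
#'
#' Maximal runs of equal levels along each direction; runs are broken by
#' pixels outside the ROI.
#'
#' @param q a [quantize()]d ROI.
#' @param directions angles in degrees, subset of `c(0, 45, 90, 135)`.
#' @return list of `Ng x Rmax` count matrices, one per direction, with the
#'   ROI pixel count as attribute `n_pixels`.
#' @export
build_glrlm <- function(q, directions = c(0, 45, 90, 135)) {
  stopifnot(inherits(q, "quantized_roi"))
  lev <- crop_levels(q)
  Ng <- q$Ng
  n_px <- sum(lev > 0L)
  out <- lapply(directions, function(dir) {
    runs_val <- integer(0)
    runs_len <- integer(0)
    for (line in level_lines(lev, dir)) {
      r <- rle(as.integer(line))
      keep <- r$values > 0L
      runs_val <- c(runs_val, r$values[keep])
      runs_len <- c(runs_len, r$lengths[keep])
    }
    rmax <- max(runs_len)
    matrix(tabulate((runs_val - 1L) * rmax + runs_len, nbins = Ng * rmax),
           Ng, rmax, byrow = TRUE)
  })
  names(out) <- paste0("deg", directions)
  attr(out, "n_pixels") <- n_px
  out
}

#' Build a gray-level size-zone matrix
#'
#' Zones are connected components of equal level inside the ROI
#' (8-connectivity by default).
#'
#' @param q a [quantize()]d ROI.
#' @param connectivity 4 or 8.
#' @return `Ng x Smax` count matrix with attribute `n_pixels`.
#' @export
build_glszm <- function(q, connectivity = 8) {
  stopifnot(inherits(q, "quantized_roi"))
  lev <- crop_levels(q)
  Ng <- q$Ng
  zones_val <- integer(0)
  zones_size <- integer(0)
  for (g in sort(unique(lev[lev > 0L]))) {
    lab <- label_components(lev == g, connectivity = connectivity)
    sz <- component_sizes(lab)
    zones_val <- c(zones_val, rep(g, length(sz)))
    zones_size <- c(zones_size, sz)
  }
  smax <- max(zones_size)
  out <- matrix(tabulate((zones_val - 1L) * smax + zones_size,
                         nbins = Ng * smax), Ng, smax, byrow = TRUE)
  attr(out, "n_pixels") <- sum(lev > 0L)
  out
}

#' Build the neighborhood gray-tone-difference components
#'
#' For every ROI pixel with at least one ROI neighbor in its 8-neighborhood,
#' the absolute difference between its level and the mean level of its ROI
#' neighbors is accumulated per level.
#'
#' @param q a [quantize()]d ROI.
#' @return list with `n_i` (valid-pixel count per level), `p_i`
#'   (probabilities), `s_i` (summed absolute differences) and `n_valid`.
#' @export
build_ngtdm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  lev <- crop_levels(q)
  Ng <- q$Ng
  nr <- nrow(lev)
  nc <- ncol(lev)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- lev
  nb_sum <- matrix(0, nr, nc)
  nb_cnt <- matrix(0, nr, nc)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      sh <- pad[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc), drop = FALSE]
      nb_sum <- nb_sum + sh
      nb_cnt <- nb_cnt + (sh > 0L)
    }
  }
  valid <- lev > 0L & nb_cnt > 0L
  if (!any(valid)) stop("NGTDM undefined: no ROI pixel has an ROI neighbor")
  diffs <- abs(lev[valid] - nb_sum[valid] / nb_cnt[valid])
  levs <- lev[valid]
  n_i <- tabulate(levs, nbins = Ng)
  s_i <- vapply(seq_len(Ng), function(g) sum(diffs[levs == g]), numeric(1))
  n_valid <- sum(n_i)
  list(n_i = n_i, p_i = n_i / n_valid, s_i = s_i, n_valid = n_valid)
}
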
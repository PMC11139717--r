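roi_of <- function(lev_like, n = NULL) {
  roi_mask(mask_from_levels(lev_like, n), min_pixels = 2L)
}

test_that("quantization bins the ROI range and conserves pixel counts", {
  px <- matrix(-850, 16, 16)
  px[1, 1:4] <- c(-600, -600, 0, 0)
  img <- image_patch(px)
  roi <- roi_mask({m <- matrix(FALSE, 16, 16); m[1, 1:4] <- TRUE; m},
                  min_pixels = 2L)
  q <- quantize(img, roi, 2L)
  expect_identical(q$levels[1, 1:4], c(1L, 1L, 2L, 2L))
  expect_identical(sum(q$levels > 0L), 4L)
  # constant ROI maps entirely to level 1
  px[1, 1:4] <- -600
  qc <- quantize(image_patch(px), roi, 8L)
  expect_true(all(qc$levels[roi$mask] == 1L))
  # conservation on a random patch
  set.seed(2)
  px2 <- matrix(rnorm(32 * 32, -500, 150), 32, 32)
  m2 <- matrix(FALSE, 32, 32); m2[5:20, 7:25] <- TRUE
  q2 <- quantize(image_patch(pmax(pmin(px2, 3071), -1024)), roi_mask(m2), 32L)
  expect_equal(sum(tabulate(q2$levels[m2], 32L)), sum(m2))
  expect_true(all(q2$levels[m2] >= 1L & q2$levels[m2] <= 32L))
})

test_that("first-order features match hand arithmetic and entropy bounds", {
  px <- matrix(-850, 16, 16)
  px[1, 1:2] <- c(-100, -300)
  img <- image_patch(px)
  roi <- roi_mask({m <- matrix(FALSE, 16, 16); m[1, 1:2] <- TRUE; m},
                  min_pixels = 2L)
  fv <- first_order_features(img, roi, quantize(img, roi, 2L))
  expect_equal(unname(fv["MeanIntensity"]), -200)
  expect_equal(unname(fv["CoefficientVariation"]), -0.5)  # pop SD 100 / -200
  # uniform histogram over 32 levels -> maximum entropy log(32)
  vals <- matrix(rep(1:32, each = 2), 8, 8)
  img2 <- patch_from_values(vals)
  roi2 <- roi_of(matrix(1, 8, 8))
  q2 <- quantize(img2, roi2, 32L)
  fv2 <- first_order_features(img2, roi2, q2)
  expect_equal(unname(fv2["Entropy"]), log(32))
  cfg2 <- texture_config(log_base = 2)
  fv2b <- first_order_features(img2, roi2, q2, cfg2)
  expect_equal(unname(fv2b["Entropy"]), log2(32))
  # constant ROI
  img3 <- patch_from_values(matrix(-600, 4, 4))
  roi3 <- roi_of(matrix(1, 4, 4))
  fv3 <- first_order_features(img3, roi3, quantize(img3, roi3, 32L))
  expect_equal(unname(fv3["Variance"]), 0)
  expect_equal(unname(fv3["Entropy"]), 0)
})

test_that("GLCM matches the worked 2x2 example and its correlation", {
  lev <- matrix(c(1L, 2L, 1L, 2L), 2, 2, byrow = TRUE)  # [[1,2],[1,2]]
  q <- make_q(lev, 2L)
  g <- build_glcm(q, directions = 0)
  expected <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(g, expected)
  expect_equal(sum(g), 1)
  expect_equal(g, t(g))
  expect_no_warning(f <- glcm_features(g))
  expect_equal(unname(f["GLCM:Correlation"]), -1)
  # two disjoint constant blocks: all co-occurrence mass on the diagonal,
  # marginals still vary -> correlation +1 (checked against the oracle too)
  lev2 <- rbind(matrix(1L, 2, 2), matrix(0L, 1, 2), matrix(2L, 2, 2))
  q2 <- make_q(lev2, 2L)
  g2 <- build_glcm(q2, directions = 90)
  expect_equal(g2, oracle_glcm(lev2, 2L, directions = 90))
  expect_equal(unname(glcm_features(g2)["GLCM:Correlation"]), 1)
  # constant image -> correlation undefined
  g3 <- build_glcm(make_q(matrix(1L, 3, 3), 1L), directions = 0)
  expect_warning(f3 <- glcm_features(g3), "zero variance")
  expect_true(is.na(f3["GLCM:Correlation"]))
  # degenerate ROI: no adjacent pair
  lev4 <- matrix(0L, 3, 3); lev4[1, 1] <- 1L; lev4[3, 3] <- 0L
  expect_error(build_glcm(make_q(lev4, 1L), directions = 0), "degenerate ROI")
})

test_that("run-length matrices match the worked row example and conserve", {
  lev <- matrix(c(1L, 1L, 2L, 2L, 2L), 1, 5)
  rl <- build_glrlm(make_q(lev, 2L), directions = 0)
  P <- rl$deg0
  expect_equal(P[1, 2], 1)   # run (level 1, length 2)
  expect_equal(P[2, 3], 1)   # run (level 2, length 3)
  expect_equal(sum(P), 2)
  # conservation: sum(length x count) = pixel count
  expect_equal(sum(sweep(P, 2, seq_len(ncol(P)), "*")), 5)
  f <- glrlm_features(rl)
  expect_equal(unname(f["LRHGE"]), (1 * 4 + 4 * 9) / 2)  # = 20
  # constant 3x3 ROI, horizontal: value from the independent oracle
  lev3 <- matrix(1L, 3, 3)
  rl3 <- build_glrlm(make_q(lev3, 1L), directions = 0)
  expect_equal(unname(rl3$deg0), unname(oracle_glrlm_dir(lev3, 1L, 0)))
  f3 <- glrlm_features(rl3)
  o3 <- oracle_glrlm_dir(lev3, 1L, 0)
  expect_equal(unname(f3["GLN"]), sum(rowSums(o3)^2) / sum(o3))
})

test_that("size-zone matrices count zones and conserve pixels", {
  lev <- matrix(1L, 4, 4)
  sz <- build_glszm(make_q(lev, 1L))
  expect_equal(sum(sz), 1)          # one zone
  expect_equal(ncol(sz), 16L)       # of size 16
  f <- glszm_features(sz)
  expect_equal(unname(f["LZHGE"]), 256)   # 1^2 * 16^2 / 1
  # two separated same-level blobs -> 2 zones
  lev2 <- matrix(0L, 5, 5)
  lev2[1:2, 1:2] <- 1L
  lev2[4:5, 4:5] <- 1L
  sz2 <- build_glszm(make_q(lev2, 1L))
  expect_equal(sum(sz2), 2)
  expect_equal(sum(sweep(sz2, 2, seq_len(ncol(sz2)), "*")), 8)
})

test_that("NGTDM components match brute force and handle degenerate input", {
  lev <- matrix(rep(c(1L, 2L), 8), 4, 4)   # 2-level checkerboard columns
  m <- build_ngtdm(make_q(lev, 2L))
  o <- oracle_ngtdm(lev, 2L)
  expect_equal(m$s_i, o$s_i)
  expect_equal(m$n_i, o$n_i)
  f0 <- suppressWarnings(ngtdm_features(make_q(matrix(1L, 3, 3), 1L)))
  expect_equal(unname(f0["NGTDM:Contrast"]), 0)
  lone <- matrix(0L, 3, 3); lone[2, 2] <- 1L
  expect_error(build_ngtdm(make_q(lone, 1L)), "no ROI pixel")
})

test_that("extract_all returns the stable 61-feature registry", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 61L)
  expect_true(all(c("LRHGE", "LZHGE", "Variance", "GLN", "Mean",
                    "GLCM:Correlation", "CoefficientVariation", "Entropy",
                    "GLV", "MeanIntensity") %in% reg$name))
  spec <- cohort_spec(image_size = 128L, seed = 8)
  cs <- generate_nodule(spec, 1L, 17L)
  fv <- extract_all(cs$image, cs$truth_mask)
  expect_identical(names(fv), reg$name)
  expect_length(fv, 61L)
  expect_identical(names(extract_all(cs$image, cs$truth_mask)), names(fv))
  # bounds
  expect_gte(unname(fv["Entropy"]), 0)
  expect_lte(unname(fv["Entropy"]), log(32) + 1e-12)
  expect_true(abs(fv["GLCM:Correlation"]) <= 1)
  expect_true(all(fv[c("SRE", "LRE", "LRHGE", "SZE", "LZHGE")] >= 0))
})

test_that("adding a constant HU shift moves MeanIntensity only among
           quantized-level features", {
  spec <- cohort_spec(image_size = 128L, seed = 8)
  cs <- generate_nodule(spec, 0L, 23L)
  fv1 <- extract_all(cs$image, cs$truth_mask)
  shifted <- image_patch(cs$image$pixels + 100, spacing = cs$image$spacing)
  fv2 <- extract_all(shifted, cs$truth_mask)
  level_feats <- setdiff(names(fv1),
                         c("MeanIntensity", "CoefficientVariation",
                           "SolidFraction"))
  expect_equal(fv2[level_feats], fv1[level_feats], tolerance = 1e-12)
  expect_equal(unname(fv2["MeanIntensity"] - fv1["MeanIntensity"]), 100)
})

test_that("direction-averaged features are invariant to 90-degree rotation", {
  spec <- cohort_spec(image_size = 128L, seed = 8)
  cs <- generate_nodule(spec, 1L, 31L)
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  img_r <- image_patch(rot90(cs$image$pixels), spacing = cs$image$spacing)
  roi_r <- roi_mask(rot90(cs$truth_mask$mask), reader_id = "truth")
  fv <- extract_all(cs$image, cs$truth_mask)
  fv_r <- extract_all(img_r, roi_r)
  expect_equal(fv_r, fv, tolerance = 1e-10)
})

test_that("reader averaging is element-wise with missing propagation", {
  a <- c(x = 2, y = 4)
  expect_equal(average_readers(a, a), a)
  expect_equal(average_readers(c(x = 2, y = 4), c(x = 4, y = 8)),
               c(x = 3, y = 6))
  withNA <- average_readers(c(x = 2, y = NA), c(x = 4, y = 8))
  expect_true(is.na(withNA["y"]))
  expect_equal(unname(withNA["x"]), 3)
  expect_error(average_readers(c(x = 1), c(z = 1)), "do not match")
})
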
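test_that("NIfTI write/read round-trips pixels and spacing exactly", {
  set.seed(4)
  m <- matrix(rnorm(24 * 19, -500, 120), 24, 19)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(m, p, spacing = c(0.25, 0.5))
  r <- read_nifti(p)
  expect_identical(r$pixels, m)           # float64 on disk: bit-exact
  expect_identical(r$spacing, c(0.25, 0.5))
  # uint8 masks
  mask <- matrix(0L, 20, 20)
  mask[4:11, 6:15] <- 1L
  pm <- withr::local_tempfile(fileext = ".nii")
  write_nifti(mask, pm, spacing = c(0.25, 0.25), datatype = "uint8")
  rm_ <- read_nifti(pm)
  expect_identical(rm_$pixels, mask)
})

test_that("NIfTI output is readable by an independent implementation", {
  # nibabel serves as the format oracle for the hand-rolled writer
  set.seed(9)
  m <- matrix(rnorm(15 * 22, -400, 90), 15, 22)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(m, p, spacing = c(0.337, 0.337))
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import nibabel, numpy\n",
    "img = nibabel.load('", p, "')\n",
    "d = numpy.asarray(img.dataobj)\n",
    "print(d.shape[0], d.shape[1], '%.6f' % float(d.sum()))"
  ))), stdout = TRUE, stderr = TRUE))
  parts <- strsplit(tail(out, 1), " ")[[1]]
  expect_equal(as.integer(parts[1:2]), c(15L, 22L))
  expect_equal(as.numeric(parts[3]), sum(m), tolerance = 1e-9)
})

test_that("segmentation recovers a solid disk with high Dice", {
  n <- 96L
  px <- matrix(-850, n, n)
  d2 <- outer(seq_len(n) - 48, rep(1, n))^2 + outer(rep(1, n), seq_len(n) - 48)^2
  truth <- d2 <= 15^2
  px[truth] <- -50
  set.seed(21)
  px <- px + matrix(rnorm(n * n, 0, 30), n, n)
  img <- image_patch(px, spacing = c(0.337, 0.337))
  roi <- segment_nodule(img, c(30, 66, 30, 66))
  expect_gt(dice_overlap(roi, truth), 0.9)
  expect_equal(noduletex:::label_components(roi$mask, 8)$n, 1L)
})

test_that("segmentation errors on background-only rectangles", {
  px <- matrix(-850, 64, 64)
  img <- image_patch(px)
  expect_error(segment_nodule(img, c(5, 30, 5, 30)), "empty segmentation")
  expect_error(segment_nodule(img, c(1, 2, 1, 2)), "at least 16 pixels")
  expect_error(segment_nodule(img, c(0, 30, 5, 300)), "out of image bounds")
})

test_that("interior holes are filled", {
  n <- 64L
  px <- matrix(-850, n, n)
  d2 <- outer(seq_len(n) - 32, rep(1, n))^2 + outer(rep(1, n), seq_len(n) - 32)^2
  ring <- d2 <= 14^2 & d2 >= 7^2
  px[ring] <- -50
  img <- image_patch(px)
  roi <- segment_nodule(img, c(10, 54, 10, 54))
  expect_true(all(roi$mask[d2 <= 6^2]))   # lumen reclaimed
})

test_that("manual override replaces the automatic mask only when given", {
  m_auto <- matrix(FALSE, 32, 32); m_auto[5:12, 5:12] <- TRUE
  auto <- roi_mask(m_auto, reader_id = "auto")
  expect_identical(apply_manual_override(auto), auto)
  m_man <- matrix(FALSE, 32, 32); m_man[6:14, 6:14] <- TRUE
  man <- apply_manual_override(auto, m_man, reader_id = "r2")
  expect_identical(man$mask, m_man)
  expect_identical(man$reader_id, "r2")
  m_bad <- matrix(FALSE, 32, 32)
  m_bad[1:5, 1:5] <- TRUE; m_bad[20:26, 20:26] <- TRUE  # two components
  expect_error(apply_manual_override(auto, m_bad), "8-connected")
  m_small <- matrix(FALSE, 16, 16); m_small[1:5, 1:5] <- TRUE
  expect_error(apply_manual_override(auto, roi_mask(m_small)),
               "does not match")
})

test_that("max-solid-slice selection follows solid count then ROI area", {
  mk <- function(n_solid, n_ggo) {
    px <- matrix(-850, 48, 48)
    m <- matrix(FALSE, 48, 48)
    k <- n_solid + n_ggo
    m[8, 8 + seq_len(k) - 1] <- TRUE
    if (n_solid > 0) px[8, 8 + seq_len(n_solid) - 1] <- -50
    if (n_ggo > 0) px[8, 8 + n_solid + seq_len(n_ggo) - 1] <- -600
    list(image = image_patch(px), mask = roi_mask(m, min_pixels = 1L))
  }
  s <- lapply(list(c(5, 0), c(20, 0), c(7, 0)), function(x) mk(x[1], x[2]))
  expect_equal(select_max_solid_slice(lapply(s, `[[`, "image"),
                                      lapply(s, `[[`, "mask")), 2L)
  expect_equal(select_max_solid_slice(list(s[[1]]$image),
                                      list(s[[1]]$mask)), 1L)
  g <- lapply(list(c(0, 10), c(0, 30), c(0, 20)), function(x) mk(x[1], x[2]))
  expect_equal(select_max_solid_slice(lapply(g, `[[`, "image"),
                                      lapply(g, `[[`, "mask")), 2L)
  expect_error(select_max_solid_slice(list(), list()), "empty")
})

test_that("cohort write/read round-trips through NIfTI + manifest", {
  spec <- cohort_spec(n_positive = 1L, n_negative = 1L, image_size = 96L,
                      seed = 13)
  cases <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(cases, dir)
  back <- read_cohort(manifest)
  expect_length(back, 2L)
  for (i in 1:2) {
    expect_identical(back[[i]]$image$pixels, cases[[i]]$image$pixels)
    expect_identical(back[[i]]$truth_mask$mask, cases[[i]]$truth_mask$mask)
    expect_identical(back[[i]]$label, cases[[i]]$label)
  }
})
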
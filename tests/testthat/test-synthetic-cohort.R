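# Tests use small image matrices (the generator is ROI-local, so image size
# does not affect nodule statistics) to stay fast; the spec defaults keep
# the full 1024-pixel matrix.

small_spec <- function(seed = 1, ...) {
  cohort_spec(image_size = 192L, seed = seed, ...)
}

test_that("nodule generation is a pure function of (spec, label, case_seed)", {
  spec <- small_spec()
  a <- generate_nodule(spec, 1L, 42L)
  b <- generate_nodule(spec, 1L, 42L)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth_mask$mask, b$truth_mask$mask)
  d <- generate_nodule(spec, 1L, 43L)
  expect_false(identical(a$image$pixels, d$image$pixels))
  # truth mask: one connected region of at least 64 pixels
  expect_gte(sum(a$truth_mask$mask), 64L)
  expect_equal(noduletex:::label_components(a$truth_mask$mask, 8)$n, 1L)
})

test_that("degenerate generator settings give a constant nodule", {
  spec <- cohort_spec(image_size = 96L, noise_sd = 0,
                      solid_fraction_pos = 0, solid_fraction_neg = 0,
                      speckle_amplitude_pos = 0, speckle_amplitude_neg = 0,
                      seed = 3)
  cs <- generate_nodule(spec, 1L, 7L)
  roi_vals <- cs$image$pixels[cs$truth_mask$mask]
  expect_equal(var(roi_vals), 0)
  expect_equal(unique(roi_vals), spec$hu_ggo)
})

test_that("oversized nodules are rejected with the offending dimensions", {
  spec <- cohort_spec(image_size = 48L, seed = 1)
  expect_error(generate_nodule(spec, 1L, 5L), "do not fit a 48 px image")
})

test_that("default cohort spec encodes the 16/48 class split", {
  spec <- cohort_spec(seed = 1)
  expect_identical(spec$n_positive, 16L)
  expect_identical(spec$n_negative, 48L)
  expect_identical(spec$image_size, 1024L)
  expect_equal(spec$pixel_spacing, 345 / 1024)
})

test_that("generate_cohort conserves class counts and is seed-determined", {
  spec <- small_spec(seed = 5)
  cases <- generate_cohort(spec)
  labels <- vapply(cases, `[[`, integer(1), "label")
  expect_length(cases, 64L)
  expect_equal(sum(labels == 1L), 16L)
  expect_equal(sum(labels == 0L), 48L)
  cases2 <- generate_cohort(small_spec(seed = 6))
  labels2 <- vapply(cases2, `[[`, integer(1), "label")
  expect_equal(sum(labels2 == 1L), 16L)
  expect_false(identical(cases[[1]]$image$pixels, cases2[[1]]$image$pixels))
  expect_error(cohort_spec(n_positive = 0, seed = 1), "at least one case")
})

test_that("positive nodules have higher ROI entropy and more negative CoV", {
  spec <- small_spec(seed = 11, n_positive = 50L, n_negative = 50L)
  seeds <- seq_len(100L)
  stats <- vapply(seeds, function(i) {
    lab <- as.integer(i <= 50L)
    cs <- generate_nodule(spec, lab, case_seed = 1000L + i)
    fv <- first_order_features(cs$image, cs$truth_mask,
                               quantize(cs$image, cs$truth_mask, 32L))
    c(lab, fv["Entropy"], fv["CoefficientVariation"])
  }, numeric(3))
  lab <- stats[1, ]
  expect_gt(mean(stats[2, lab == 1]), mean(stats[2, lab == 0]))
  expect_lt(mean(stats[3, lab == 1]), mean(stats[3, lab == 0]))
})

test_that("synthetic feature tables carry the requested effect structure", {
  expect_error(generate_feature_table(5, 10, seed = 1), "at least 10")
  tab <- generate_feature_table(200, 20, informative = c(3, 7),
                                effect_size = 3, seed = 9)
  expect_identical(tab, generate_feature_table(200, 20, informative = c(3, 7),
                                               effect_size = 3, seed = 9))
  y <- tab$label
  for (f in c("F03", "F07")) {
    expect_lt(wilcox.test(tab[[f]][y == 1], tab[[f]][y == 0])$p.value, 0.01)
  }
  # a null table has no label-dependent feature (rank test not significant
  # for a fixed arbitrary column at a lenient level)
  tab0 <- generate_feature_table(200, 20, informative = c(3, 7),
                                 effect_size = 0, seed = 9)
  expect_gt(wilcox.test(tab0$F03[tab0$label == 1],
                        tab0$F03[tab0$label == 0])$p.value, 0.001)
})

test_that("reader-prediction generator hits its operating point", {
  truth <- c(rep(1L, 16), rep(0L, 48))
  expect_identical(generate_reader_table(truth, 1, 1, seed = 2), truth)
  expect_identical(generate_reader_table(truth, 0, 1, seed = 2),
                   rep(0L, 64L))
  expect_error(generate_reader_table(integer(0), 1, 1, seed = 1), "non-empty")
  spec_hat <- vapply(seq_len(1000L), function(s) {
    pred <- generate_reader_table(truth, sens = 1, spec_ = 0.396, seed = s)
    mean(pred[truth == 0L] == 0L)
  }, numeric(1))
  expect_lt(abs(mean(spec_hat) - 0.396), 0.02)
  # sensitivity 1 is exact
  pred <- generate_reader_table(truth, 1, 0.396, seed = 77)
  expect_true(all(pred[truth == 1L] == 1L))
})
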
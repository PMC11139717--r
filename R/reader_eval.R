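# Paired reader-study statistics: confusion metrics, McNemar tests on
# correctness, paired-difference confidence intervals, and paired AUC
# comparison by the DeLong method.
#
# Discordance is defined on correctness (agreement with truth), because the
# compared quantities are the accuracy/sensitivity/specificity of the same
# reader across two sessions on identical cases.

#' Assemble and validate a reader-study table
#'
#' @param case_id case identifiers.
#' @param truth binary ground truth (both classes present).
#' @param ... named binary prediction vectors, one per (reader, session),
#'   e.g. `r1_s1 = ..., r1_s2 = ...`.
#' @return a `reader_study_table` data.frame.
#' @export
reader_study_table <- function(case_id, truth, ...) {
  preds <- list(...)
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L)) || length(unique(truth)) < 2L) {
    stop("truth must be binary with both classes present")
  }
  if (!length(preds)) stop("at least one prediction column is required")
  for (nm in names(preds)) {
    p <- preds[[nm]]
    if (length(p) != length(truth) || anyNA(p) || !all(p %in% c(0L, 1L))) {
      stop(sprintf("prediction column '%s' must be complete binary of length %d",
                   nm, length(truth)))
    }
  }
  df <- data.frame(case_id = as.character(case_id), truth = truth,
                   lapply(preds, as.integer), stringsAsFactors = FALSE)
  class(df) <- c("reader_study_table", "data.frame")
  df
}

#' Confusion-matrix metrics of binary predictions
#'
#' Standard 2x2 definitions; metrics are returned as proportions with the
#' integer counts alongside and pre-formatted percentages (1 decimal,
#' matching the usual reporting convention). An empty predicted-positive
#' set leaves PPV missing.
#'
#' @param pred,truth binary vectors of equal length.
#' @return list with `tp`, `fp`, `fn`, `tn`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` and `percent` (named, 1-decimal).
#' @export
confusion_metrics <- function(pred, truth) {
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  stopifnot(length(pred) == length(truth),
            all(pred %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  ppv <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  npv <- if (tn + fn == 0L) NA_real_ else tn / (tn + fn)
  out <- list(tp = tp, fp = fp, fn = fn, tn = tn,
              accuracy = (tp + tn) / length(truth),
              sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
              specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
              ppv = ppv, npv = npv)
  out$percent <- round(100 * unlist(out[c("accuracy", "sensitivity",
                                          "specificity", "ppv", "npv")]), 1)
  out
}

restrict_cases <- function(truth, restrict) {
  switch(restrict,
         all = rep(TRUE, length(truth)),
         positives = truth == 1L,
         negatives = truth == 0L)
}

#' McNemar's test on paired correctness
#'
#' Counts cases where prediction A is correct and B wrong (`b`) and vice
#' versa (`c`), optionally restricted to positive cases (a sensitivity
#' comparison) or negative cases (specificity). Uses the exact two-sided
#' binomial test when `b + c <= exact_max` (default 25), the
#' continuity-corrected chi-square otherwise. No discordance gives p = 1
#' with a flag.
#'
#' @param pred_a,pred_b paired binary predictions on identical cases.
#' @param truth binary ground truth.
#' @param restrict `"all"` (accuracy), `"positives"` (sensitivity) or
#'   `"negatives"` (specificity).
#' @param exact_max largest `b + c` for which the exact test is used.
#' @return a `mcnemar_result`: `b`, `c`, `p_value`, `method`,
#'   `no_discordance`.
#' @export
mcnemar <- function(pred_a, pred_b, truth,
                    restrict = c("all", "positives", "negatives"),
                    exact_max = 25L) {
  restrict <- match.arg(restrict)
  pred_a <- as.integer(pred_a)
  pred_b <- as.integer(pred_b)
  truth <- as.integer(truth)
  stopifnot(length(pred_a) == length(truth), length(pred_b) == length(truth))
  keep <- restrict_cases(truth, restrict)
  ca <- pred_a[keep] == truth[keep]
  cb <- pred_b[keep] == truth[keep]
  b <- sum(ca & !cb)
  cc <- sum(!ca & cb)
  n <- b + cc
  if (n == 0L) {
    return(structure(list(b = b, c = cc, statistic = NA_real_, p_value = 1,
                          method = "exact", no_discordance = TRUE),
                     class = "mcnemar_result"))
  }
  if (n <= exact_max) {
    p <- min(1, 2 * pbinom(min(b, cc), n, 0.5))
    method <- "exact"
    stat <- NA_real_
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square"
  }
  structure(list(b = b, c = cc, statistic = stat, p_value = p,
                 method = method, no_discordance = FALSE),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("<mcnemar> b = %d, c = %d, p = %.4g (%s)%s\n", x$b, x$c,
              x$p_value, x$method,
              if (x$no_discordance) " [no discordance]" else ""))
  invisible(x)
}

#' Paired difference of a reader metric with confidence interval
#'
#' Point difference (B minus A, in percentage points) of accuracy,
#' sensitivity or specificity between two paired prediction sets, with the
#' Wald paired-proportion interval based on the discordant counts.
#'
#' @param pred_a,pred_b paired binary predictions.
#' @param truth binary ground truth.
#' @param metric `"accuracy"`, `"sensitivity"` or `"specificity"`.
#' @param level confidence level (default 0.95).
#' @return list with `value_a`, `value_b` (percent), `difference`
#'   (percentage points), `ci` (length 2), `method`.
#' @export
paired_diff_ci <- function(pred_a, pred_b, truth,
                           metric = c("accuracy", "sensitivity", "specificity"),
                           level = 0.95) {
  metric <- match.arg(metric)
  restrict <- switch(metric, accuracy = "all", sensitivity = "positives",
                     specificity = "negatives")
  truth <- as.integer(truth)
  keep <- restrict_cases(truth, restrict)
  if (!any(keep)) stop("no cases left after restriction")
  ca <- as.integer(pred_a)[keep] == truth[keep]
  cb <- as.integer(pred_b)[keep] == truth[keep]
  n <- sum(keep)
  b <- sum(ca & !cb)
  cc <- sum(!ca & cb)
  d <- (cc - b) / n
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt((b + cc) / n^2 - (b - cc)^2 / n^3)
  list(value_a = 100 * mean(ca), value_b = 100 * mean(cb),
       difference = 100 * d,
       ci = 100 * (d + c(-1, 1) * z * se),
       method = "wald-paired")
}

#' Paired AUC comparison (DeLong)
#'
#' Compares two sets of paired scores on identical cases by the DeLong
#' covariance of their placement values; for binary predictions the AUC
#' equals (sensitivity + specificity) / 2. Identical placements give
#' p = 1.
#'
#' @param scores_a,scores_b paired scores (continuous or binary).
#' @param truth binary ground truth with both classes present.
#' @return list with `auc_a`, `auc_b`, `ci_a`, `ci_b`, `difference`, `z`,
#'   `p_value`, `method`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, truth) {
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2L) stop("both classes must be present")
  stopifnot(length(scores_a) == length(truth),
            length(scores_b) == length(truth))
  pa <- delong_placements(scores_a, truth)
  pb <- delong_placements(scores_b, truth)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  d <- pa$auc - pb$auc
  if (v <= 0) {
    z <- 0
    p <- if (d == 0) 1 else 0
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  ra <- roc_auc(scores_a, truth)
  rb <- roc_auc(scores_b, truth)
  list(auc_a = pa$auc, auc_b = pb$auc, ci_a = ra$ci, ci_b = rb$ci,
       difference = d, z = z, p_value = p, method = "delong-paired")
}

#' Full reader-study evaluation
#'
#' For each reader with predictions in two sessions, computes accuracy,
#' sensitivity and specificity per session, the paired difference with its
#' confidence interval, the McNemar p-value, and the paired AUC comparison
#' across sessions.
#'
#' @param table a [reader_study_table()] with columns named
#'   `<reader>_s1` / `<reader>_s2`.
#' @param level confidence level.
#' @return list with `metrics` (data.frame, one row per reader x metric)
#'   and `auc` (data.frame, one row per reader).
#' @export
evaluate_readers <- function(table, level = 0.95) {
  stopifnot(inherits(table, "reader_study_table"))
  cols <- setdiff(names(table), c("case_id", "truth"))
  readers <- unique(sub("_s[12]$", "", cols))
  truth <- table$truth
  rows <- list()
  aucs <- list()
  for (rd in readers) {
    a <- table[[paste0(rd, "_s1")]]
    b <- table[[paste0(rd, "_s2")]]
    if (is.null(a) || is.null(b)) next
    for (metric in c("accuracy", "sensitivity", "specificity")) {
      restrict <- switch(metric, accuracy = "all",
                         sensitivity = "positives", specificity = "negatives")
      diff <- paired_diff_ci(a, b, truth, metric, level)
      mc <- mcnemar(a, b, truth, restrict)
      rows[[length(rows) + 1L]] <- data.frame(
        reader = rd, metric = metric,
        session1 = diff$value_a, session2 = diff$value_b,
        difference = diff$difference,
        ci_lower = diff$ci[1], ci_upper = diff$ci[2],
        p_value = mc$p_value, mcnemar_method = mc$method,
        stringsAsFactors = FALSE)
    }
    cmp <- compare_auc_paired(a, b, truth)
    aucs[[length(aucs) + 1L]] <- data.frame(
      reader = rd, auc_s1 = cmp$auc_a, auc_s2 = cmp$auc_b,
      ci_s1_lower = cmp$ci_a[1], ci_s1_upper = cmp$ci_a[2],
      ci_s2_lower = cmp$ci_b[1], ci_s2_upper = cmp$ci_b[2],
      p_value = cmp$p_value, stringsAsFactors = FALSE)
  }
  list(metrics = do.call(rbind, rows), auc = do.call(rbind, aucs))
}
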
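# End-to-end pipeline: simulate (or ingest) -> segment -> extract ->
# average readers -> select -> cutoffs -> models -> reader evaluation,
# under one JSON-serializable configuration with explicit seeds throughout.

#' Build and validate a pipeline configuration
#'
#' @param cohort a [cohort_spec()] (synthetic input) or a manifest path for
#'   an ingested cohort written by [write_cohort()].
#' @param texture a [texture_config()].
#' @param n_folds,n_repeats,k selection settings: outer folds, repeats, and
#'   the number of top features carried forward.
#' @param p_enter,p_remove stepwise entry/removal thresholds.
#' @param conf_level confidence level for all intervals.
#' @param readers named list of per-session operating points for the
#'   synthetic reader study, each `c(sens, spec)`; defaults mirror the
#'   emulated study's observed operating points.
#' @param seed pipeline seed (mandatory) controlling selection folds and
#'   reader simulation; the cohort keeps its own seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort, texture = texture_config(),
                            n_folds = 10L, n_repeats = 10L, k = 10L,
                            p_enter = 0.05, p_remove = 0.1,
                            conf_level = 0.95,
                            readers = list(
                              r1 = list(s1 = c(1.0, 0.396), s2 = c(1.0, 0.604)),
                              r2 = list(s1 = c(0.937, 0.417), s2 = c(0.75, 0.896))),
                            seed) {
  if (missing(seed) || is.null(seed)) {
    stop("pipeline_config: a seed is mandatory")
  }
  if (inherits(cohort, "cohort_spec")) {
    validate_cohort_spec(cohort)
  } else if (!is.character(cohort)) {
    stop("cohort must be a cohort_spec or a manifest path")
  }
  structure(list(cohort = cohort, texture = texture,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), k = as.integer(k),
                 p_enter = p_enter, p_remove = p_remove,
                 conf_level = conf_level, readers = readers,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration as JSON
#'
#' Configurations round-trip unchanged; the seed is mandatory in the file.
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$texture <- unclass(x$texture)
  if (inherits(config$cohort, "cohort_spec")) x$cohort <- unclass(x$cohort)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$seed)) stop("config is missing the mandatory seed")
  cohort <- if (is.list(x$cohort)) {
    if (is.null(x$cohort$seed)) stop("cohort spec is missing the mandatory seed")
    do.call(cohort_spec, x$cohort)
  } else {
    x$cohort
  }
  readers <- lapply(x$readers, function(rd) lapply(rd, as.numeric))
  pipeline_config(cohort = cohort,
                  texture = do.call(texture_config, as.list(x$texture)),
                  n_folds = x$n_folds, n_repeats = x$n_repeats, k = x$k,
                  p_enter = x$p_enter, p_remove = x$p_remove,
                  conf_level = x$conf_level, readers = readers,
                  seed = x$seed)
}

# Seed rectangle around a truth mask with a margin, clipped to the image.
mask_rect <- function(mask, margin = 3L) {
  rs <- range(which(rowSums(mask) > 0))
  cs <- range(which(colSums(mask) > 0))
  c(max(1L, rs[1] - margin), min(nrow(mask), rs[2] + margin),
    max(1L, cs[1] - margin), min(ncol(mask), cs[2] + margin))
}

#' Extract per-case features for a cohort, two readers, averaged
#'
#' Reader 1 uses the semi-automatic segmentation surrogate seeded by a
#' rectangle around the nodule; reader 2 applies a manual-mask override
#' (the truth mask stands in for the corrected delineation). Each case's
#' feature vectors are averaged across readers.
#'
#' @param cases list of `synthetic_case` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param texture a [texture_config()].
#' @param two_readers set `FALSE` to extract from the automatic mask only.
#' @return a `feature_table` data.frame: `case_id`, `label`, 61 features.
#' @export
extract_cohort_features <- function(cases, texture = texture_config(),
                                    two_readers = TRUE) {
  rows <- lapply(cases, function(cs) {
    rect <- mask_rect(cs$truth_mask$mask)
    roi1 <- tryCatch(
      segment_nodule(cs$image, rect, reader_id = "reader1"),
      error = function(e) cs$truth_mask)   # fall back to the manual mask
    fv <- if (two_readers) {
      roi2 <- apply_manual_override(roi1, cs$truth_mask)
      average_readers(extract_all(cs$image, roi1, texture),
                      extract_all(cs$image, roi2, texture))
    } else {
      extract_all(cs$image, roi1, texture)
    }
    data.frame(case_id = cs$case_id, label = cs$label, t(fv),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Cross-validated AUC of the cutoff + stepwise modelling stage
#'
#' Stratified k-fold cross-validation of the downstream modelling chain:
#' on each training split, per-feature Youden cutoffs are recomputed, the
#' binarized features are screened by univariate logistic regression, the
#' stepwise model is refit, and held-out cases are scored; the pooled
#' out-of-fold scores give one AUC. Feature selection (the top-k list) is
#' taken as given, matching the emulated analysis, which did not nest it.
#'
#' @param table a `feature_table`.
#' @param features character vector of feature names to model.
#' @param n_folds folds (default 5).
#' @param seed fold-assignment seed.
#' @param p_enter,p_remove stepwise thresholds.
#' @return list with `auc`, `ci` and the pooled out-of-fold `scores`.
#' @export
cv_model_auc <- function(table, features, n_folds = 5L, seed,
                         p_enter = 0.05, p_remove = 0.1) {
  fm <- feature_matrix(table)
  y <- fm$y
  x <- fm$x[, features, drop = FALSE]
  fold <- stratified_folds(y, n_folds, seed)
  scores <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    bin_tr <- matrix(0L, sum(tr), length(features),
                     dimnames = list(NULL, features))
    bin_te <- matrix(0L, sum(!tr), length(features),
                     dimnames = list(NULL, features))
    keep <- logical(length(features))
    for (i in seq_along(features)) {
      v_tr <- x[tr, i]
      if (length(unique(v_tr)) < 2L) next
      rule <- youden_cutoff(v_tr, y[tr], feature = features[i])
      suppressWarnings({
        bin_tr[, i] <- binarize(v_tr, rule)
        bin_te[, i] <- binarize(x[!tr, i], rule)
      })
      keep[i] <- length(unique(bin_tr[, i])) > 1L
    }
    sig <- keep & vapply(seq_along(features), function(i) {
      if (!keep[i]) return(FALSE)
      fit <- univariate_logistic(bin_tr[, i], y[tr])
      fit$terms$p_value[fit$terms$term == "x"] <= p_enter || fit$separation
    }, logical(1))
    cand <- if (any(sig)) features[sig] else features[keep]
    if (!length(cand)) {
      scores[!tr] <- 0.5
      next
    }
    sw <- stepwise_logistic(as.data.frame(bin_tr[, cand, drop = FALSE],
                                          optional = TRUE),
                            y[tr], p_enter, p_remove)
    newdata <- as.data.frame(bin_te[, cand, drop = FALSE], optional = TRUE)
    scores[!tr] <- predict(sw$model, newdata = newdata, type = "response")
  }
  r <- roc_auc(scores, y)
  list(auc = r$auc, ci = r$ci, scores = scores)
}

#' Run the full pipeline
#'
#' Simulate (or ingest) the cohort, segment, extract and average features,
#' select by repeated-CV LASSO importance, derive Youden cutoffs, fit
#' univariate and stepwise logistic models, cross-validate the final
#' model's AUC, and evaluate the synthetic reader study. When `out_dir` is
#' given, writes `manifest`-, feature-, importance-, cutoff-, model- and
#' reader-report files there.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param write_images also write the cohort images as NIfTI (off by
#'   default; the manifest and tables are always written).
#' @param verbose log each stage via `message()`.
#' @return a results bundle (list) with elements `features`, `importance`,
#'   `selected`, `cutoffs`, `univariate`, `stepwise`, `cv_auc`,
#'   `reader_table`, `reader_eval`, `signature`, `config`.
#' @export
run_all <- function(config, out_dir = NULL, write_images = FALSE,
                    verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("[1/7] cohort")
  cases <- if (inherits(config$cohort, "cohort_spec")) {
    generate_cohort(config$cohort)
  } else {
    read_cohort(config$cohort)
  }
  labels <- vapply(cases, function(cs) cs$label, integer(1))
  say("      %d cases (%d positive / %d negative)", length(cases),
      sum(labels == 1L), sum(labels == 0L))

  say("[2/7] segmentation + feature extraction (61 features, 2 readers)")
  feats <- extract_cohort_features(cases, config$texture)

  say("[3/7] LASSO importance (%d x %d-fold CV)", config$n_repeats,
      config$n_folds)
  imp <- lasso_importance(feats, n_folds = config$n_folds,
                          n_repeats = config$n_repeats, seed = config$seed)
  selected <- select_top(imp, config$k)
  say("      top %d: %s", config$k, paste(selected, collapse = ", "))
  signature <- fit_radiomics_signature(feats, imp, config$k)

  say("[4/7] Youden cutoffs + univariate screening")
  fm <- feature_matrix(feats)
  cutoffs <- lapply(selected, function(f) {
    youden_cutoff(fm$x[, f], fm$y, feature = f)
  })
  names(cutoffs) <- selected
  bins <- vapply(selected, function(f) {
    suppressWarnings(binarize(fm$x[, f], cutoffs[[f]]))
  }, integer(length(fm$y)))
  uni <- lapply(selected, function(f) {
    if (length(unique(bins[, f])) < 2L) return(NULL)
    univariate_logistic(bins[, f], fm$y)
  })
  names(uni) <- selected
  sig_feats <- selected[vapply(selected, function(f) {
    fit <- uni[[f]]
    !is.null(fit) &&
      (fit$terms$p_value[fit$terms$term == "x"] <= config$p_enter ||
         fit$separation)
  }, logical(1))]
  if (!length(sig_feats)) sig_feats <- selected[colSums(bins) > 0]

  say("[5/7] stepwise multivariable model (%d candidates)", length(sig_feats))
  sw <- stepwise_logistic(as.data.frame(bins[, sig_feats, drop = FALSE],
                                        optional = TRUE),
                          fm$y, config$p_enter, config$p_remove,
                          config$conf_level)
  say("      included: %s (apparent AUC %.3f)",
      if (length(sw$included)) paste(sw$included, collapse = ", ") else "none",
      sw$auc)

  say("[6/7] cross-validated model AUC")
  cv <- cv_model_auc(feats, selected, n_folds = 5L, seed = config$seed + 77L,
                     p_enter = config$p_enter, p_remove = config$p_remove)
  say("      cv AUC %.3f (%.3f-%.3f)", cv$auc, cv$ci[1], cv$ci[2])

  say("[7/7] reader study")
  rseeds <- derive_seeds(config$seed + 101L, 4L)
  preds <- list()
  i <- 0L
  for (rd in names(config$readers)) {
    for (ss in names(config$readers[[rd]])) {
      i <- i + 1L
      op <- config$readers[[rd]][[ss]]
      preds[[paste0(rd, "_", ss)]] <-
        generate_reader_table(labels, op[1], op[2], seed = rseeds[i])
    }
  }
  rtab <- do.call(reader_study_table,
                  c(list(case_id = vapply(cases, `[[`, "", "case_id"),
                         truth = labels), preds))
  reval <- evaluate_readers(rtab, config$conf_level)

  res <- list(features = feats, importance = imp, selected = selected,
              signature = signature, cutoffs = cutoffs, univariate = uni,
              stepwise = sw, cv_auc = cv, reader_table = rtab,
              reader_eval = reval, config = config,
              elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) write_results(res, out_dir, cases, write_images)
  res
}

write_results <- function(res, out_dir, cases = NULL, write_images = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (write_images && !is.null(cases)) {
    write_cohort(cases, file.path(out_dir, "cohort"))
  }
  write.csv(res$features, file.path(out_dir, "features.csv"),
            row.names = FALSE)
  imp_df <- data.frame(feature = names(res$importance$counts),
                       count = as.integer(res$importance$counts),
                       mean_abs_coef = res$importance$mean_abs_coef)
  imp_df <- imp_df[order(-imp_df$count, -imp_df$mean_abs_coef,
                         imp_df$feature), ]
  write.csv(imp_df, file.path(out_dir, "importance.csv"), row.names = FALSE)
  cut_df <- do.call(rbind, lapply(res$cutoffs, function(r) {
    data.frame(feature = r$feature, threshold = r$threshold,
               direction = r$direction, youden_j = r$youden_j,
               sensitivity = r$sensitivity, specificity = r$specificity)
  }))
  write.csv(cut_df, file.path(out_dir, "cutoffs.csv"), row.names = FALSE)
  write.csv(res$reader_table, file.path(out_dir, "readers.csv"),
            row.names = FALSE)
  write.csv(res$reader_eval$metrics, file.path(out_dir, "reader_metrics.csv"),
            row.names = FALSE)
  model <- list(
    selected = res$selected,
    signature = list(features = res$signature$features,
                     coefficients = as.list(res$signature$coefficients),
                     intercept = res$signature$intercept,
                     center = as.list(res$signature$center),
                     scale = as.list(res$signature$scale),
                     lambda = res$signature$lambda),
    stepwise = list(included = res$stepwise$included,
                    terms = res$stepwise$terms,
                    auc = res$stepwise$auc, auc_ci = res$stepwise$auc_ci),
    cv_auc = list(auc = res$cv_auc$auc, ci = res$cv_auc$ci),
    texture = unclass(res$config$texture),
    seed = res$config$seed,
    n_fits = res$importance$n_fits)
  jsonlite::write_json(model, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write the synthetic cohort), `extract`
#' (features CSV for a cohort manifest), `run-all` (full pipeline).
#' Exit codes: 0 ok, 1 validation error, 2 runtime error. Used by the
#' `noduletex` script in `inst/cli/`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: noduletex <simulate|extract|run-all> --config PATH --out DIR",
    "[--seed INT] [--quiet]", sep = " ")
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list(config = NULL, out = NULL, seed = NULL,
              quiet = "--quiet" %in% args)
  for (key in c("config", "out", "seed")) {
    i <- which(args == paste0("--", key))
    if (length(i) == 1L && i < length(args)) opt[[key]] <- args[i + 1L]
  }
  status <- tryCatch({
    if (is.null(opt$config) || is.null(opt$out)) {
      message(usage)
      return(invisible(1L))
    }
    config <- read_pipeline_config(opt$config)
    if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
    switch(cmd,
           "simulate" = {
             stopifnot(inherits(config$cohort, "cohort_spec"))
             write_cohort(generate_cohort(config$cohort), opt$out)
             0L
           },
           "extract" = {
             cases <- if (inherits(config$cohort, "cohort_spec")) {
               generate_cohort(config$cohort)
             } else read_cohort(config$cohort)
             feats <- extract_cohort_features(cases, config$texture)
             dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
             write.csv(feats, file.path(opt$out, "features.csv"),
                       row.names = FALSE)
             0L
           },
           "run-all" = {
             run_all(config, out_dir = opt$out, verbose = !opt$quiet)
             0L
           },
           {
             message("unknown subcommand: ", cmd, "\n", usage)
             1L
           })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
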
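# Feature-importance selection by L1-penalized logistic regression under
# ten repeats of stratified tenfold cross-validation.
#
# Protocol: for each repeat, a fresh stratified partition; for each outer
# fold, features are standardized on the training portion only, the penalty
# is chosen on a 50-point grid spanning four decades below the smallest
# all-zero penalty by inner 5-fold cross-validated deviance, and every
# feature with a non-zero coefficient at the chosen penalty scores one
# count. Counts therefore range over 0..(n_repeats * n_folds), 100 by
# default. The L1 solver is glmnet; folds, grids and standardization are
# controlled here so the procedure is a pure function of (table, seed).

feature_matrix <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  if (anyNA(table$label)) stop("labels must not be missing")
  y <- as.integer(table$label)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  drop <- intersect(c("case_id", "label"), names(table))
  x <- as.matrix(table[, setdiff(names(table), drop), drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature table contains missing values")
  list(x = x, y = y)
}

# Deterministic stratified fold assignment.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

standardize_train <- function(x_tr) {
  ctr <- colMeans(x_tr)
  scl <- apply(x_tr, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

lambda_grid <- function(x_std, y, n_lambda = 50L, decades = 4) {
  lam_max <- max(abs(crossprod(x_std, y - mean(y)))) / length(y)
  if (lam_max <= 0) lam_max <- 1e-3
  exp(seq(log(lam_max), log(lam_max * 10^(-decades)), length.out = n_lambda))
}

#' Feature importance by repeated cross-validated LASSO
#'
#' Counts, over `n_repeats` repeats of stratified `n_folds`-fold
#' cross-validation, how many fitted L1-penalized logistic models give each
#' feature a non-zero coefficient (at the per-fold penalty chosen by inner
#' 5-fold cross-validated deviance). Constant feature columns are excluded
#' with a warning and receive count 0.
#'
#' @param table a `feature_table` data.frame (`label` column plus feature
#'   columns), e.g. from [generate_feature_table()] or the pipeline.
#' @param n_folds outer folds (default 10); each class must have at least
#'   `n_folds` cases.
#' @param n_repeats repeats (default 10); repeat `r` uses `seed + r`.
#' @param seed base random seed.
#' @param k_inner inner folds for penalty choice (default 5).
#' @param family `"binomial"` (default) or `"gaussian"` (linear-LASSO
#'   sensitivity variant).
#' @return an `importance_counts` object: `counts` (named integer),
#'   `mean_abs_coef`, `lambda_chosen`, `n_fits`, and the configuration.
#' @export
lasso_importance <- function(table, n_folds = 10L, n_repeats = 10L, seed,
                             k_inner = 5L, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  if (missing(seed)) stop("lasso_importance: a seed is required")
  fm <- feature_matrix(table)
  x <- fm$x
  y <- fm$y
  if (min(table(y)) < n_folds) {
    stop(sprintf(paste0("stratified %d-fold CV needs at least %d cases per ",
                        "class; got %d. Use a larger cohort or fewer folds."),
                 n_folds, n_folds, min(table(y))))
  }
  const <- apply(x, 2, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warning("constant feature column(s) excluded from selection: ",
            paste(colnames(x)[const], collapse = ", "))
  }
  x_use <- x[, !const, drop = FALSE]
  p <- ncol(x_use)
  counts <- integer(p)
  abs_coef <- numeric(p)
  lambda_chosen <- numeric(0)
  n_fits <- 0L
  for (r in seq_len(n_repeats)) {
    fold <- stratified_folds(y, n_folds, seed = seed + r)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      std <- standardize_train(x_use[tr, , drop = FALSE])
      x_tr <- scale(x_use[tr, , drop = FALSE], std$center, std$scale)
      grid <- lambda_grid(x_tr, y[tr])
      fid <- stratified_folds(y[tr], k_inner, seed = seed + 1000L * r + f)
      # the smallest grid penalties can fail to converge on near-separated
      # folds; deviance-based selection steers away from them, so those
      # warnings are noise
      cvfit <- suppressWarnings(
        glmnet::cv.glmnet(x_tr, y[tr], family = family,
                          lambda = grid, foldid = fid,
                          standardize = FALSE, type.measure = "deviance"))
      co <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]
      counts <- counts + (co != 0)
      abs_coef <- abs_coef + abs(co)
      lambda_chosen <- c(lambda_chosen, cvfit$lambda.min)
      n_fits <- n_fits + 1L
    }
  }
  all_counts <- integer(ncol(x))
  all_abs <- numeric(ncol(x))
  all_counts[!const] <- counts
  all_abs[!const] <- abs_coef
  names(all_counts) <- names(all_abs) <- colnames(x)
  structure(list(counts = all_counts,
                 mean_abs_coef = all_abs / n_fits,
                 lambda_chosen = lambda_chosen,
                 n_fits = n_fits, n_folds = n_folds, n_repeats = n_repeats,
                 family = family, seed = seed),
            class = "importance_counts")
}

#' @export
print.importance_counts <- function(x, ...) {
  cat(sprintf("<importance_counts> %d features, %d fits (%d x %d CV)\n",
              length(x$counts), x$n_fits, x$n_repeats, x$n_folds))
  top <- sort(x$counts, decreasing = TRUE)
  print(head(top, 10L))
  invisible(x)
}

#' Select the top-k features by importance count
#'
#' Ordered by count (descending), ties broken by mean absolute coefficient
#' across fits (descending), then by name; fully deterministic.
#'
#' @param counts an `importance_counts` object.
#' @param k number of features to return (default 10).
#' @return character vector of feature names, most important first.
#' @export
select_top <- function(counts, k = 10L) {
  stopifnot(inherits(counts, "importance_counts"))
  if (k > length(counts$counts)) {
    stop(sprintf("k = %d exceeds the %d available features", k,
                 length(counts$counts)))
  }
  nm <- names(counts$counts)
  ord <- order(-counts$counts, -counts$mean_abs_coef, nm)
  nm[ord][seq_len(k)]
}

#' Fit the radiomics signature (full-data refit)
#'
#' Refits the L1-penalized logistic model on the full table restricted to
#' the selected features, standardized on the full data, at the median of
#' the penalties chosen across the repeated-CV fits. The standardization
#' parameters are stored with the model so scores are computable on new
#' cases.
#'
#' @param table the `feature_table` used for selection.
#' @param counts the matching `importance_counts`.
#' @param k number of top features in the signature (default 10).
#' @return a `radiomics_signature`: features, coefficients, intercept,
#'   center, scale, lambda.
#' @export
fit_radiomics_signature <- function(table, counts, k = 10L) {
  feats <- select_top(counts, k)
  fm <- feature_matrix(table)
  x <- fm$x[, feats, drop = FALSE]
  std <- standardize_train(x)
  x_std <- scale(x, std$center, std$scale)
  lam <- stats::median(counts$lambda_chosen)
  fit <- glmnet::glmnet(x_std, fm$y, family = counts$family, lambda = lam,
                        standardize = FALSE)
  co <- as.numeric(coef(fit))
  structure(list(features = feats, coefficients = stats::setNames(co[-1], feats),
                 intercept = co[1], center = std$center, scale = std$scale,
                 lambda = lam, family = counts$family),
            class = "radiomics_signature")
}

#' Radiomics score of one case
#'
#' Linear combination of the selected features weighted by their
#' coefficients on the standardized scale:
#' `intercept + sum(coef * (x - center) / scale)`.
#'
#' @param features named numeric vector covering the signature's features
#'   (a full 61-feature vector is fine).
#' @param signature a `radiomics_signature` from
#'   [fit_radiomics_signature()]; alternatively supply `coefficients`,
#'   `intercept`, `center`, `scale` directly.
#' @param coefficients,intercept,center,scale manual model parameters used
#'   when `signature` is NULL.
#' @return numeric score.
#' @export
radiomics_score <- function(features, signature = NULL, coefficients = NULL,
                            intercept = 0, center = NULL, scale = NULL) {
  if (!is.null(signature)) {
    stopifnot(inherits(signature, "radiomics_signature"))
    coefficients <- signature$coefficients
    intercept <- signature$intercept
    center <- signature$center
    scale <- signature$scale
  }
  need <- names(coefficients)
  missing_feats <- setdiff(need, names(features))
  if (length(missing_feats)) {
    stop("missing feature value(s): ", paste(missing_feats, collapse = ", "))
  }
  v <- as.numeric(features[need])
  if (anyNA(v)) {
    stop("missing feature value(s): ",
         paste(need[is.na(v)], collapse = ", "))
  }
  if (is.null(center)) center <- stats::setNames(rep(0, length(need)), need)
  if (is.null(scale)) scale <- stats::setNames(rep(1, length(need)), need)
  as.numeric(intercept + sum(coefficients * (v - center[need]) / scale[need]))
}
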
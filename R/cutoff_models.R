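# Youden-index cutoffs, binarization, univariate and stepwise logistic
# modelling, and ROC/AUC with DeLong inference.

#' Optimal cutoff by the Youden index
#'
#' Evaluates every candidate threshold (midpoints between adjacent sorted
#' unique values, plus +/- infinity) in both directions and returns the rule
#' maximizing J = sensitivity + specificity - 1. Ties are broken toward the
#' rule with higher sensitivity, then the smaller absolute threshold, then
#' direction `"greater"`.
#'
#' @param values per-case feature values (no missing values).
#' @param labels binary 0/1 labels, both classes present.
#' @param feature optional feature name recorded on the rule.
#' @return a `cutoff_rule`: `feature`, `threshold`, `direction`
#'   (`"greater"` or `"less_equal"`, indicating the positive side),
#'   `youden_j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(values, labels, feature = NA_character_) {
  stopifnot(length(values) == length(labels))
  if (anyNA(values) || anyNA(labels)) stop("missing values are not allowed")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    stop("labels must be binary with both classes present")
  }
  u <- sort(unique(values))
  if (length(u) < 2L) stop("no discriminating cutoff: values are constant")
  cand <- c(-Inf, (u[-1] + u[-length(u)]) / 2, Inf)
  pos <- values[labels == 1L]
  neg <- values[labels == 0L]
  rows <- do.call(rbind, lapply(cand, function(t) {
    sens_g <- mean(pos > t)
    spec_g <- mean(neg <= t)
    sens_l <- mean(pos <= t)
    spec_l <- mean(neg > t)
    rbind(c(t, 1, sens_g, spec_g, sens_g + spec_g - 1),
          c(t, 2, sens_l, spec_l, sens_l + spec_l - 1))
  }))
  colnames(rows) <- c("t", "dir", "sens", "spec", "j")
  ord <- order(-rows[, "j"], -rows[, "sens"], abs(rows[, "t"]), rows[, "dir"])
  best <- rows[ord[1], ]
  structure(list(feature = feature,
                 threshold = unname(best["t"]),
                 direction = if (best["dir"] == 1) "greater" else "less_equal",
                 youden_j = unname(best["j"]),
                 sensitivity = unname(best["sens"]),
                 specificity = unname(best["spec"])),
            class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  op <- if (x$direction == "greater") ">" else "<="
  cat(sprintf("<cutoff_rule> %s %s %.4g (J = %.3f, sens %.3f, spec %.3f)\n",
              x$feature %||% "value", op, x$threshold, x$youden_j,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Binarize feature values by a cutoff rule
#'
#' Score 1 on the rule's positive side: strictly greater for direction
#' `"greater"`, inclusive for `"less_equal"` (so the threshold itself
#' scores 0 under `"greater"` and 1 under `"less_equal"`).
#'
#' @param values numeric values (no missing).
#' @param rule a `cutoff_rule`.
#' @return integer 0/1 vector; warns if all scores are identical.
#' @export
binarize <- function(values, rule) {
  stopifnot(inherits(rule, "cutoff_rule"))
  if (anyNA(values)) stop("missing values cannot be binarized")
  out <- if (rule$direction == "greater") {
    as.integer(values > rule$threshold)
  } else {
    as.integer(values <= rule$threshold)
  }
  if (length(unique(out)) == 1L) {
    warning("all values fall on one side of the cutoff; scores are constant")
  }
  out
}

wald_fit_rows <- function(fit, conf_level = 0.95) {
  s <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = rownames(s),
             coefficient = s[, "Estimate"],
             se = s[, "Std. Error"],
             odds_ratio = exp(s[, "Estimate"]),
             ci_lower = exp(s[, "Estimate"] - z * s[, "Std. Error"]),
             ci_upper = exp(s[, "Estimate"] + z * s[, "Std. Error"]),
             p_value = s[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Univariate logistic regression of a binarized feature
#'
#' Maximum-likelihood logistic fit with Wald confidence interval and
#' p-value; for a binary predictor the odds ratio equals the 2x2
#' cross-product ratio. Complete separation (a zero cell) is flagged, and a
#' Haldane-Anscombe corrected odds ratio (+0.5 per cell) is reported as a
#' fallback alongside.
#'
#' @param x predictor (binary score or continuous value).
#' @param labels binary outcome.
#' @param conf_level confidence level (default 0.95).
#' @return a `logistic_fit` with `terms` (data.frame), `auc`, `separation`,
#'   and the fitted `model`.
#' @export
univariate_logistic <- function(x, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(x)) < 2L) stop("predictor is constant")
  df <- data.frame(y = labels, x = x)
  fit <- suppressWarnings(glm(y ~ x, data = df, family = binomial()))
  terms <- wald_fit_rows(fit, conf_level)
  separation <- FALSE
  fallback_or <- NA_real_
  if (all(x %in% c(0L, 1L))) {
    tab <- table(factor(x, c(0, 1)), factor(labels, c(0, 1)))
    if (any(tab == 0L)) {
      separation <- TRUE
      tt <- tab + 0.5
      fallback_or <- (tt[2, 2] * tt[1, 1]) / (tt[2, 1] * tt[1, 2])
    }
  } else if (max(abs(coef(fit))) > 15 || !fit$converged) {
    separation <- TRUE
  }
  structure(list(terms = terms,
                 auc = roc_auc(x, labels)$auc,
                 separation = separation,
                 fallback_odds_ratio = fallback_or,
                 model = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>\n")
  print(x$terms, digits = 4)
  if (isTRUE(x$separation)) {
    cat(sprintf("separation detected; Haldane-corrected OR = %.3g\n",
                x$fallback_odds_ratio))
  }
  invisible(x)
}

# Rank of the design matrix for a candidate set; used as collinearity guard.
design_rank <- function(X, included) {
  mm <- cbind(1, as.matrix(X[, included, drop = FALSE]))
  qr(mm)$rank
}

#' Stepwise multivariable logistic regression
#'
#' Forward entry with backward removal on Wald p-values, iterated to a
#' fixed point: at each entry step the candidate with the smallest p-value
#' at or below `p_enter` is added (candidates considered in column order;
#' candidates that do not increase the design-matrix rank are skipped, so
#' duplicated predictors enter once); after each entry, included terms with
#' p-value above `p_remove` are removed, worst first. Deterministic given
#' the column order.
#'
#' @param X data.frame or matrix of candidate predictors (typically the
#'   binarized features).
#' @param labels binary outcome.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.1).
#' @param conf_level confidence level for Wald intervals.
#' @return a `logistic_fit` with the included-term list, per-term odds
#'   ratios, model AUC with DeLong CI, and the final `glm` model. When no
#'   candidate enters, an intercept-only model with a note.
#' @export
stepwise_logistic <- function(X, labels, p_enter = 0.05, p_remove = 0.1,
                              conf_level = 0.95) {
  if (!is.data.frame(X)) X <- as.data.frame(X, optional = TRUE)
  labels <- as.integer(labels)
  stopifnot(nrow(X) == length(labels), ncol(X) >= 1L)
  vars <- names(X)
  included <- character(0)
  fit_model <- function(inc) {
    df <- data.frame(y = labels, X[, inc, drop = FALSE], check.names = FALSE)
    fml <- if (length(inc)) {
      stats::as.formula(paste("y ~", paste(sprintf("`%s`", inc), collapse = "+")))
    } else {
      y ~ 1
    }
    suppressWarnings(glm(fml, data = df, family = binomial()))
  }
  repeat {
    changed <- FALSE
    # Entry: smallest Wald p at or below p_enter among rank-increasing vars.
    cand <- setdiff(vars, included)
    cand <- cand[vapply(cand, function(v) length(unique(X[[v]])) > 1L, logical(1))]
    cand <- cand[vapply(cand, function(v) {
      design_rank(X, c(included, v)) > design_rank(X, included)
    }, logical(1))]
    if (length(cand)) {
      ps <- vapply(cand, function(v) {
        fit <- fit_model(c(included, v))
        s <- summary(fit)$coefficients
        row <- match(sprintf("`%s`", v), rownames(s))
        if (is.na(row)) row <- match(v, rownames(s))
        if (is.na(row)) NA_real_ else s[row, "Pr(>|z|)"]
      }, numeric(1))
      ok <- which(!is.na(ps) & ps <= p_enter)
      if (length(ok)) {
        included <- c(included, cand[ok[which.min(ps[ok])]])
        changed <- TRUE
      }
    }
    # Removal: worst included term above p_remove.
    repeat {
      if (!length(included)) break
      fit <- fit_model(included)
      s <- summary(fit)$coefficients
      rows <- match(sprintf("`%s`", included), rownames(s))
      rows[is.na(rows)] <- match(included[is.na(rows)], rownames(s))
      ps <- s[rows, "Pr(>|z|)"]
      if (max(ps) > p_remove) {
        included <- included[-which.max(ps)]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- fit_model(included)
  note <- if (!length(included)) "no candidate entered; intercept-only model"
          else NA_character_
  scores <- predict(fit, type = "response")
  auc <- if (length(included)) roc_auc(scores, labels) else
    list(auc = 0.5, ci = c(NA_real_, NA_real_), method = "none")
  structure(list(terms = wald_fit_rows(fit, conf_level),
                 included = included,
                 auc = auc$auc, auc_ci = auc$ci,
                 note = note, model = fit,
                 p_enter = p_enter, p_remove = p_remove),
            class = c("stepwise_fit", "logistic_fit"))
}

# DeLong placement components of an empirical AUC.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  m <- length(x)
  n <- length(y)
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(cmp), v10 = rowMeans(cmp), v01 = colMeans(cmp),
       m = m, n = n)
}

#' Empirical AUC with DeLong confidence interval
#'
#' AUC as the normalized Mann-Whitney statistic (ties count 1/2); the
#' confidence interval uses the DeLong placement variance (Wald on the AUC
#' scale, clipped to `[0, 1]`).
#'
#' @param scores continuous or binary predictions.
#' @param labels binary truth with both classes present.
#' @param conf_level confidence level (default 0.95).
#' @return list with `auc`, `ci`, `se`, `method`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pl <- delong_placements(scores, labels)
  v <- if (pl$m > 1L) var(pl$v10) / pl$m else 0
  v <- v + if (pl$n > 1L) var(pl$v01) / pl$n else 0
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmax(0, pmin(1, pl$auc + c(-1, 1) * z * sqrt(v)))
  list(auc = pl$auc, ci = ci, se = sqrt(v), method = "delong")
}
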
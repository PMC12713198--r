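#' Pearson correlation with p-value
#'
#' Thin wrapper around [stats::cor.test()] returning the coefficient and
#' two-tailed p-value from the t distribution on n - 2 degrees of freedom.
#' Zero variance in either variable makes the coefficient undefined; that
#' case returns NAs with a warning instead of erroring, so screening tables
#' over many covariates survive degenerate columns.
#'
#' @param x,y numeric vectors of equal length >= 3 (pairwise-complete cases
#'   are used; NAs dropped).
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Pearson correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Kendall rank correlation (tau-b) with p-value
#'
#' Tie-corrected tau-b via [stats::cor.test()]; with ties the p-value uses
#' the normal approximation. All-tied input returns NAs with a warning.
#'
#' @inheritParams pearson_r
#' @return List with `tau`, `p_value`, `n`.
#' @export
kendall_tau <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("all-tied input: Kendall tau undefined", call. = FALSE)
    return(list(tau = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Multiple linear regression with standardized coefficients
#'
#' Ordinary least squares of a response on several predictors via
#' [stats::lm()], reporting per-coefficient raw and standardized slopes
#' (standardization by z-scoring response and predictors), t statistics,
#' two-tailed p-values and the overall R-squared. Rank-deficient designs
#' are rejected with the collinear columns named.
#'
#' @param data data frame holding response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @return List of class `rotastig_regression`: `coefficients` (data frame
#'   `term`, `estimate`, `std_beta`, `t`, `p_value`), `r_squared`,
#'   `sigma`, `n`, `fit` (the `lm` object).
#' @export
multiple_regression <- function(data, response, predictors) {
  missing <- setdiff(c(response, predictors), names(data))
  if (length(missing))
    stop("columns not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- stats::na.omit(data[, c(response, predictors), drop = FALSE])
  if (nrow(df) <= length(predictors) + 1)
    stop("need n > number of predictors + 1", call. = FALSE)
  X <- as.matrix(cbind(1, df[, predictors, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  sds <- vapply(df, stats::sd, numeric(1))
  std_beta <- c(NA_real_,
                co[predictors, "Estimate"] * sds[predictors] / sds[response])
  list(coefficients = data.frame(term = rownames(co),
                                 estimate = co[, "Estimate"],
                                 std_beta = std_beta,
                                 t = co[, "t value"],
                                 p_value = co[, "Pr(>|t|)"],
                                 row.names = NULL),
       r_squared = sm$r.squared, sigma = sm$sigma, n = nrow(df),
       fit = fit)
}

#' Simple linear fit of an outcome on rotation
#'
#' Least-squares line `y = slope * x + intercept` with the Pearson
#' correlation and its two-tailed p-value.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return List `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
simple_linear_fit <- function(x, y) {
  pr <- pearson_r(x, y)
  ok <- stats::complete.cases(x, y)
  fit <- stats::lm(y[ok] ~ x[ok])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = pr$r, p_value = pr$p_value, n = pr$n)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Empirical ROC of a continuous score against binary labels. The AUC uses
#' the Mann-Whitney pair-counting formulation (tied positive-negative score
#' pairs count one half). Candidate thresholds are the midpoints between
#' adjacent distinct scores, extended below the minimum and above the
#' maximum; a case is called positive when `score >= threshold`. The
#' operating point maximizes Youden's J = sensitivity + specificity - 1,
#' ties broken toward the lower threshold.
#'
#' @param scores numeric vector (here: rotation magnitude, degrees).
#' @param labels 0/1 vector (or logical); both classes must be present.
#' @return List of class `rotastig_roc`: `auc`, `thresholds`,
#'   `sensitivity`, `specificity`, `youden_j` (per threshold),
#'   `optimal_cutoff`, `youden_max`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present for ROC analysis", call. = FALSE)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  # Mann-Whitney AUC via midranks: avoids the O(n_pos * n_neg) outer product
  rk <- rank(c(pos, neg))
  auc <- (sum(rk[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  s <- sort(unique(scores))
  thresholds <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
                  s[length(s)] + 1)
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]  # ties toward the lower threshold
  structure(list(auc = auc, thresholds = thresholds,
                 sensitivity = sens, specificity = spec, youden_j = j,
                 optimal_cutoff = thresholds[best], youden_max = j[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "rotastig_roc")
}

#' @export
print.rotastig_roc <- function(x, ...) {
  best <- which(x$thresholds == x$optimal_cutoff)[1]
  cat(sprintf("ROC: AUC %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  cat(sprintf("Youden-optimal cutoff %.3g: sensitivity %.1f%%, specificity %.1f%% (J = %.3f)\n",
              x$optimal_cutoff, 100 * x$sensitivity[best],
              100 * x$specificity[best], x$youden_max))
  invisible(x)
}

#' Dichotomize residual astigmatism
#'
#' Labels an eye positive when its residual (postoperative) cylinder
#' magnitude reaches the cutoff, the positive-class definition the ROC
#' stage predicts from rotation magnitude. Boundary inclusive.
#'
#' @param magnitude residual cylinder magnitudes, diopters (or an [astig]).
#' @param cutoff positive-class threshold, diopters (> 0); default 0.50 D.
#' @return Integer 0/1 vector.
#' @export
dichotomize_residual <- function(magnitude, cutoff = 0.5) {
  if (is_astig(magnitude)) magnitude <- magnitude$magnitude
  if (!is.finite(cutoff) || cutoff <= 0)
    stop("cutoff must be a positive number of diopters", call. = FALSE)
  as.integer(magnitude >= cutoff)
}
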
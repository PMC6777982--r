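#' Two-sample or paired t test on lag measures
#'
#' Unpaired tests use the pooled-variance (Student) form; paired tests
#' operate on within-subject differences. Two-sided throughout.
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired logical.
#' @return list with `t`, `p`, `df`, `estimate` (mean difference x - y).
#' @export
two_sample_t <- function(x, y, paired = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop_invalid("need n >= 2 per sample")
  if (paired && length(x) != length(y)) {
    stop_invalid("paired samples must have equal length")
  }
  ht <- tryCatch(
    t.test(x, y, paired = paired, var.equal = !paired),
    error = function(e) stop_degenerate(conditionMessage(e))
  )
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       estimate = if (paired) unname(ht$estimate) else unname(diff(rev(ht$estimate))))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors, n >= 3, non-constant.
#' @return list with `r`, `p` (two-sided, t-distributed), `n`.
#' @export
pearson_cor <- function(x, y) {
  check_cor_input(x, y)
  ht <- cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' Spearman rank correlation (average ranks for ties)
#'
#' @param x,y numeric vectors, n >= 3, non-constant.
#' @return list with `rho`, `p` (two-sided), `n`.
#' @export
spearman_cor <- function(x, y) {
  check_cor_input(x, y)
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value, n = length(x))
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("vectors differ in length")
  if (length(x) < 3) stop_invalid("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("correlation inputs must be finite")
  }
  if (sd(x) == 0 || sd(y) == 0) stop_degenerate("constant input to correlation")
  invisible(TRUE)
}

#' Logarithmic remapping of lags
#'
#' Natural-log transform used for pair-level lag analyses; sub-second lags
#' map to negative values. Zero lags are floored at `eps` (one percent of a
#' 2-s TR by default) before the transform; negative lags are rejected
#' (remap magnitudes, not signed lags).
#'
#' @param lags non-negative lags in seconds.
#' @param eps floor applied to zeros.
#' @return `log(pmax(lags, eps))`.
#' @export
log_remap <- function(lags, eps = 0.02) {
  if (any(!is.finite(lags))) stop_invalid("lags must be finite")
  if (any(lags < 0)) stop_invalid("lags must be non-negative (use magnitudes)")
  if (eps <= 0) stop_invalid("`eps` must be > 0")
  log(pmax(lags, eps))
}

#' Variance explained by an ordinary least-squares model
#'
#' Fits `response ~ predictors` with intercept and returns the coefficient
#' of determination. Adding a predictor never decreases the result.
#'
#' @param response numeric vector.
#' @param predictors numeric vector, matrix or data.frame of predictors.
#' @return R-squared in `[0, 1]`.
#' @export
glm_r2 <- function(response, predictors) {
  X <- as.data.frame(predictors)
  names(X) <- make.unique(names(X))
  if (length(response) != nrow(X)) stop_invalid("response/predictor length mismatch")
  if (length(response) < ncol(X) + 2) stop_invalid("need rows >= predictors + 2")
  fit <- lm(response ~ ., data = X)
  if (any(is.na(coef(fit)))) stop_collinear("rank-deficient design matrix")
  summary(fit)$r.squared
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlates the OLS residuals of `x` and `y` on the covariates; the
#' two-sided p value uses `n - 2 - k` degrees of freedom for `k` covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates vector, matrix or data.frame of covariates (factors
#'   allowed).
#' @return list with `r`, `p`, `df`.
#' @export
partial_pearson <- function(x, y, covariates) {
  Z <- as.data.frame(covariates)
  n <- length(x)
  if (length(y) != n || nrow(Z) != n) stop_invalid("input length mismatch")
  if (n < ncol(Z) + 3) stop_invalid("need n >= covariates + 3")
  rx <- resid(lm(x ~ ., data = Z))
  ry <- resid(lm(y ~ ., data = Z))
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    stop_degenerate("a variable is fully explained by the covariates")
  }
  k <- sum(vapply(Z, function(col)
    if (is.factor(col) || is.character(col)) length(unique(col)) - 1L else 1L,
    integer(1)))
  r <- cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tval), df), df = df)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p values, capped at 1, plus the rejection set at level
#' `q`.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param q FDR level for the rejection set (default 0.05).
#' @return list with `p_adjusted` and logical `reject`.
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_invalid("p values must lie in [0, 1]")
  }
  adj <- p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}
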
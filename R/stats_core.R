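#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of paired samples. Zero differences are dropped
#' before ranking (Wilcoxon's original treatment) and `n` reports the pairs
#' that remain; ties receive mid-ranks. The p-value uses the exact signed-rank
#' distribution when the retained sample has no ties and `n <= 25`, otherwise
#' a normal approximation with tie correction and continuity correction.
#'
#' When every difference is zero the test is degenerate: the result carries
#' `p_value = 1` and `degenerate = TRUE` rather than an error, so that
#' edge-wise sweeps over near-constant connectivity data keep running.
#'
#' @param x,y Equal-length paired numeric vectors (length >= 5).
#' @return A `stat_result`: list with `statistic` (V, the positive-rank sum),
#'   `p_value`, `effect` (signed rank statistic V - n(n+1)/4), `n` (pairs used
#'   after dropping zeros), `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  d <- as.numeric(x) - as.numeric(y)
  if (anyNA(d)) stop("NA differences are not supported")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(stat_result(statistic = 0, p_value = 1, effect = 0, n = 0L,
                       method = "wilcoxon_signed_rank", degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (!ties && n <= 25) {
    # exact: psignrank gives P(V <= v); two-sided doubles the smaller tail
    p <- if (v > n * (n + 1) / 4) {
      2 * stats::psignrank(v - 1, n, lower.tail = FALSE)
    } else {
      2 * stats::psignrank(v, n)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie.tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie.tab^3 - tie.tab) / 48
    z <- v - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  stat_result(statistic = v, p_value = p, effect = v - n * (n + 1) / 4,
              n = as.integer(n), method = paste0("wilcoxon_", method),
              degenerate = FALSE)
}

stat_result <- function(statistic, p_value, effect, n, method,
                        degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value, effect = effect,
                 n = n, method = method, degenerate = degenerate),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4g, effect=%.4g, p=%.4g, n=%d%s\n",
              x$method, x$statistic, x$effect, x$p_value, x$n,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Residualize a vector on covariates
#'
#' Least-squares projection of `values` onto the orthogonal complement of the
#' covariate columns plus an intercept. Used to adjust paired differences and
#' rank-transformed scores for age and gender before nonparametric testing.
#'
#' @param values Numeric vector.
#' @param covariates Numeric matrix (or NULL for intercept-only, which just
#'   centers the vector). Columns may be named; names are used in error
#'   messages when the design is rank-deficient.
#' @return Residual vector, orthogonal to the intercept and every covariate.
#' @export
residualize <- function(values, covariates = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (is.null(covariates)) return(values - mean(values))
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == n)
  X <- cbind(`(intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("covariate design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  as.numeric(qr.resid(qx, values))
}

#' Spearman partial correlation
#'
#' Rank-transforms `x` and `y` (mid-ranks), residualizes both on the
#' covariates (plus intercept), and correlates the residuals. The p-value
#' comes from the t-distribution with n - 2 - k degrees of freedom where k is
#' the number of covariates. With no covariates this reduces to the ordinary
#' Spearman rank correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix of covariates.
#' @return A `stat_result` with `effect` = partial rho.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  stopifnot(length(y) == n, n >= 4 + k)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("constant input: ranks undefined")
  }
  rx <- residualize(rank(x), covariates)
  ry <- residualize(rank(y), covariates)
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2 - k
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  stat_result(statistic = tstat, p_value = p, effect = rho, n = as.integer(n),
              method = if (k) "spearman_partial" else "spearman")
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up false-discovery-rate control: reject all hypotheses with p <=
#' p(k*), k* = max{k : p(k) <= k q / m}. Implemented through
#' [stats::p.adjust()] ("BH"), whose adjusted p-values satisfy
#' `adjusted <= q` exactly for the step-up rejection set.
#'
#' @param p_values Numeric vector in \[0,1\].
#' @param q FDR level in (0,1), default 0.05.
#' @return Logical mask aligned with the input order.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values outside [0,1]")
  }
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Confusion-matrix classification metrics
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return Named list `ppv`, `npv`, `sensitivity`, `specificity`. A metric
#'   with a zero denominator is `NA` (undefined); callers average over
#'   defined values only.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn),
       sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp))
}
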
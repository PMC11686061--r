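#' Extract the motor-subnetwork submatrix
#'
#' @param fc ROI x ROI symmetric FC matrix over the full network.
#' @param rois A [motor_roi_set()].
#' @return 14 x 14 matrix, rows/columns in motor-set order (cortical first),
#'   dimnames set to the motor labels.
#' @export
extract_submatrix <- function(fc, rois) {
  stopifnot(inherits(rois, "motor_roi_set"))
  if (max(rois$indices) > nrow(fc)) stop("FC matrix smaller than ROI indices")
  sub <- fc[rois$indices, rois$indices]
  dimnames(sub) <- list(rois$labels, rois$labels)
  sub
}

#' First eigenvariate of a connection matrix
#'
#' One-number-per-row summary of subnetwork connectivity: columns (edges) are
#' mean-centered, the matrix decomposed by SVD, and each row projected onto
#' the first right singular vector. The loading sign is fixed so that its
#' mean is non-negative; `variance_explained` is the first squared singular
#' value over the total.
#'
#' @param x Rows (subject-condition observations) x connections matrix,
#'   at least 2 rows, all finite.
#' @return List of class `eigenvariate_summary`: `scores` (length nrow),
#'   `loadings` (unit-norm, length ncol), `variance_explained`.
#' @export
first_eigenvariate <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (!all(is.finite(x))) stop("non-finite entries in connection matrix")
  xc <- sweep(x, 2, colMeans(x))
  if (all(abs(xc) < .Machine$double.eps * 100) && all(abs(x) < 1e-300)) {
    stop("all-zero connection matrix")
  }
  sv <- svd(xc)
  if (sum(sv$d^2) == 0) stop("degenerate (constant) connection matrix")
  v <- sv$v[, 1]
  if (mean(v) < 0) v <- -v
  structure(list(scores = as.numeric(xc %*% v),
                 loadings = v,
                 variance_explained = sv$d[1]^2 / sum(sv$d^2)),
            class = "eigenvariate_summary")
}

#' Motor-subnetwork eigenvariate scores for a cohort, one band
#'
#' Pools the ON and OFF within-subnetwork edge vectors of all subjects into
#' one matrix so both conditions share a single loading basis, then computes
#' the first eigenvariate.
#'
#' @param cohort Cohort object (synthetic or loaded).
#' @param band Band name.
#' @param rois A [motor_roi_set()]; defaults to the cohort's ROI labels.
#' @return List: `scores_on`, `scores_off` (per subject), `loadings`
#'   (91-vector), `variance_explained`, `loading_matrix` (14 x 14 layout,
#'   cortical regions first).
#' @export
motor_eigenvariate <- function(cohort, band,
                               rois = motor_roi_set(cohort$spec$roi_labels)) {
  n <- length(cohort$subjects)
  rows <- matrix(NA_real_, 2 * n, 91)
  for (s in seq_len(n)) {
    fc <- cohort$subjects[[s]]$fc[[band]]
    if (is.null(fc$ON) || is.null(fc$OFF)) {
      stop("subject ", cohort$subjects[[s]]$id, " lacks a condition in ", band)
    }
    rows[s, ] <- vectorize_edges(extract_submatrix(fc$ON, rois))
    rows[n + s, ] <- vectorize_edges(extract_submatrix(fc$OFF, rois))
  }
  ev <- first_eigenvariate(rows)
  lm14 <- devectorize_edges(ev$loadings, 14)
  dimnames(lm14) <- list(rois$labels, rois$labels)
  list(scores_on = ev$scores[seq_len(n)],
       scores_off = ev$scores[n + seq_len(n)],
       loadings = ev$loadings,
       variance_explained = ev$variance_explained,
       loading_matrix = lm14)
}

# covariate-adjusted paired signed-rank: remove the centered covariates'
# least-squares contribution from the ON-OFF differences (keeping the
# location, which is the quantity under test), then signed-rank against zero
paired_test_adjusted <- function(on, off, covariates = NULL) {
  d <- on - off
  if (!is.null(covariates)) {
    cc <- scale(as.matrix(covariates), center = TRUE, scale = FALSE)
    d <- d - cc %*% stats::coef(stats::lm.fit(cc, d - mean(d)))
    d <- as.numeric(d)
  }
  wilcoxon_signed_rank(d, rep(0, length(d)))
}

#' ON vs OFF motor-subnetwork test across bands
#'
#' Per band: pooled-basis eigenvariate scores, covariate-residualized paired
#' signed-rank test of ON vs OFF, then FDR across bands.
#'
#' @param cohort Cohort object.
#' @param covariates Numeric covariate matrix (e.g. [covariate_matrix()]),
#'   or NULL.
#' @param q FDR level (default 0.05).
#' @return List: `table` (data frame band, statistic, effect, p_value,
#'   degenerate, significant), `eigenvariates` (per-band
#'   [motor_eigenvariate()] results).
#' @export
on_off_subnetwork_test <- function(cohort, covariates = NULL, q = 0.05) {
  bands <- names(cohort$spec$bands)
  evs <- lapply(bands, function(bn) motor_eigenvariate(cohort, bn))
  names(evs) <- bands
  res <- lapply(evs, function(ev) {
    paired_test_adjusted(ev$scores_on, ev$scores_off, covariates)
  })
  tab <- data.frame(
    band = bands,
    statistic = vapply(res, `[[`, 0, "statistic"),
    effect = vapply(res, `[[`, 0, "effect"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    degenerate = vapply(res, `[[`, TRUE, "degenerate"))
  tab$significant <- fdr_bh(tab$p_value, q)
  rownames(tab) <- NULL
  list(table = tab, eigenvariates = evs)
}

#' Seed connectivity of one motor region
#'
#' Mean connectivity of a region with the 13 other motor-subnetwork regions.
#'
#' @param sub 14 x 14 motor submatrix with motor-label dimnames.
#' @param roi Motor ROI label.
#' @return Scalar mean of the 13 off-diagonal entries in that region's row.
#' @export
seed_connectivity <- function(sub, roi) {
  stopifnot(nrow(sub) == 14, ncol(sub) == 14)
  k <- match(roi, rownames(sub))
  if (is.na(k)) stop("unknown motor ROI label: ", roi)
  (sum(sub[k, ]) - sub[k, k]) / 13
}

#' Per-region seed-connectivity post-hoc tests
#'
#' For a band already found significant at the subnetwork level, tests each
#' of the 14 motor regions' average connectivity with the rest of the
#' subnetwork, ON vs OFF, with covariate adjustment and FDR across the 14
#' regions.
#'
#' @param cohort Cohort object.
#' @param band Band name.
#' @param covariates Covariate matrix or NULL.
#' @param q FDR level (default 0.05).
#' @return Data frame: roi, statistic, effect, p_value, degenerate,
#'   significant.
#' @export
seed_posthoc_tests <- function(cohort, band, covariates = NULL, q = 0.05) {
  rois <- motor_roi_set(cohort$spec$roi_labels)
  n <- length(cohort$subjects)
  if (n < 5) stop("insufficient pairs for the signed-rank test (n < 5)")
  seed_on <- seed_off <- matrix(NA_real_, n, 14,
                                dimnames = list(NULL, rois$labels))
  for (s in seq_len(n)) {
    fc <- cohort$subjects[[s]]$fc[[band]]
    sub_on <- extract_submatrix(fc$ON, rois)
    sub_off <- extract_submatrix(fc$OFF, rois)
    for (r in rois$labels) {
      seed_on[s, r] <- seed_connectivity(sub_on, r)
      seed_off[s, r] <- seed_connectivity(sub_off, r)
    }
  }
  res <- lapply(rois$labels, function(r) {
    paired_test_adjusted(seed_on[, r], seed_off[, r], covariates)
  })
  tab <- data.frame(
    roi = rois$labels,
    statistic = vapply(res, `[[`, 0, "statistic"),
    effect = vapply(res, `[[`, 0, "effect"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    degenerate = vapply(res, `[[`, TRUE, "degenerate"))
  tab$significant <- fdr_bh(tab$p_value, q)
  rownames(tab) <- NULL
  tab
}

#' Correlate DBS OFF motor-subnetwork scores with motor improvement
#'
#' Spearman partial correlation (age/gender covariates) between the
#' OFF-state eigenvariate scores and MDS-UPDRS_diff (= ON - OFF; more
#' negative means greater DBS benefit). A negative rho means the OFF-state
#' motor pattern is more prominent in subjects who go on to improve more.
#'
#' @param off_scores Per-subject OFF-state eigenvariate scores.
#' @param updrs_diff Per-subject UPDRS_diff values.
#' @param covariates Covariate matrix or NULL.
#' @return A `stat_result` with `effect` = partial Spearman rho.
#' @export
correlate_off_with_updrs <- function(off_scores, updrs_diff,
                                     covariates = NULL) {
  if (length(off_scores) < 6) stop("need at least 6 subjects")
  if (length(unique(off_scores)) < 2) stop("constant scores")
  spearman_partial(off_scores, updrs_diff, covariates)
}
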
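#' Edge-wise DBS ON vs OFF tests across the whole brain
#'
#' Paired signed-rank test at every connection (4005 edges for 90 ROIs),
#' with FDR across edges within the band.
#'
#' @param cohort Cohort object.
#' @param band Band name.
#' @param q FDR level (default 0.05).
#' @return List: `p_values` (per edge), `significant` (FDR mask), `effect`
#'   (signed rank statistic per edge), `edges` (index map).
#' @export
edgewise_on_off_test <- function(cohort, band, q = 0.05) {
  on <- cohort_edge_matrix(cohort, band, "ON")
  off <- cohort_edge_matrix(cohort, band, "OFF")
  if (nrow(on) < 5) stop("need at least 5 paired subjects")
  res <- apply(on - off, 2, function(d) {
    r <- wilcoxon_signed_rank(d, rep(0, length(d)))
    c(r$p_value, r$effect)
  })
  list(p_values = res[1, ],
       significant = fdr_bh(res[1, ], q),
       effect = res[2, ],
       edges = edge_index_map(cohort$spec$roi_count))
}

#' Whole-brain PCA connectivity patterns of the DBS ON state
#'
#' Column-centered PCA (via SVD) of the subjects x edges matrix of ON-state
#' PLI values, components in descending eigenvalue order.
#'
#' @param on_vectors Subjects x edges matrix (e.g.
#'   `cohort_edge_matrix(cohort, band, "ON")`), at least 3 subjects.
#' @return List of class `pattern_result`: `loadings` (components x edges),
#'   `scores` (subjects x components, column-centered), `variance_explained`
#'   (non-increasing fractions summing to 1 over all retained components).
#' @export
pca_patterns <- function(on_vectors) {
  stopifnot(is.matrix(on_vectors), nrow(on_vectors) >= 3)
  if (!all(is.finite(on_vectors))) stop("non-finite entries")
  xc <- sweep(on_vectors, 2, colMeans(on_vectors))
  sv <- svd(xc)
  keep <- sv$d > sv$d[1] * 1e-12
  d <- sv$d[keep]
  structure(list(loadings = t(sv$v[, keep, drop = FALSE]),
                 scores = sweep(sv$u[, keep, drop = FALSE], 2, d, `*`),
                 variance_explained = d^2 / sum(sv$d^2)),
            class = "pattern_result")
}

# one randomized 1-D k-means elbow estimate on scree values
elbow_once <- function(v, gain_cutoff = 0.95) {
  vals <- unique(v)
  kmax <- min(length(v) - 1L, length(vals), 10L)
  if (kmax < 2) return(1L)
  w <- numeric(kmax)
  fits <- vector("list", kmax)
  for (k in seq_len(kmax)) {
    if (k == 1) {
      w[1] <- sum((v - mean(v))^2)
      fits[[1]] <- list(cluster = rep(1L, length(v)))
    } else {
      centers <- sample(vals, k)
      km <- suppressWarnings(stats::kmeans(v, centers = matrix(centers),
                                           iter.max = 50))
      w[k] <- km$tot.withinss
      fits[[k]] <- km
    }
  }
  total_gain <- w[1] - w[kmax]
  k_star <- if (total_gain <= 0) 1L else {
    which(w[1] - w >= gain_cutoff * total_gain)[1]
  }
  # components = size of the cluster containing the largest scree value
  sum(fits[[k_star]]$cluster == fits[[k_star]]$cluster[which.max(v)])
}

#' Elbow-based component count from a scree vector
#'
#' Repeats a randomized one-dimensional k-means elbow estimate on the
#' explained-variance values: per repetition, cluster the scree values for
#' k = 1..kmax with random initialization, take the smallest k capturing 95%
#' of the achievable within-cluster variance reduction, and report the size
#' of the cluster containing the largest variance fraction. The returned
#' count is the mode across repetitions, ties broken toward the smaller
#' count.
#'
#' @param variance_explained Non-increasing positive scree vector.
#' @param repetitions Number of randomized repetitions (default 100).
#' @param seed Integer seed.
#' @return Integer component count (1 when the scree has fewer than 3
#'   values).
#' @export
elbow_components <- function(variance_explained, repetitions = 100,
                             seed = 1L) {
  v <- variance_explained
  stopifnot(all(v > 0), !is.unsorted(rev(v)))
  if (length(v) < 3) return(1L)
  set.seed(seed)
  counts <- vapply(seq_len(repetitions), function(i) elbow_once(v), 0L)
  tab <- table(counts)
  best <- tab[tab == max(tab)]
  min(as.integer(names(best)))
}

#' Correlate connectivity-pattern scores with cognitive T-scores
#'
#' Spearman partial correlations (age/gender covariates) between each
#' selected component's scores and each neuropsychological T-score, FDR
#' across the full component x test grid. Subjects with a missing T-score
#' are dropped pairwise; constant tests are skipped with a warning.
#'
#' @param scores Subjects x components matrix of pattern scores.
#' @param t_scores Data frame of T-score columns.
#' @param covariates Covariate matrix or NULL.
#' @param q FDR level (default 0.05).
#' @return Data frame: component, test, rho, p_value, n, significant.
#' @export
correlate_patterns_with_cognition <- function(scores, t_scores,
                                              covariates = NULL, q = 0.05) {
  scores <- as.matrix(scores)
  rows <- list()
  for (tn in names(t_scores)) {
    y <- t_scores[[tn]]
    ok <- is.finite(y)
    if (length(unique(y[ok])) < 2) {
      warning("T-score ", tn, " constant across subjects; skipped")
      next
    }
    if (sum(ok) < 6) stop("fewer than 6 complete cases for ", tn)
    if (sum(!ok)) {
      message(sum(!ok), " subject(s) dropped pairwise for ", tn)
    }
    cv <- if (is.null(covariates)) NULL else covariates[ok, , drop = FALSE]
    for (cpt in seq_len(ncol(scores))) {
      r <- spearman_partial(scores[ok, cpt], y[ok], cv)
      rows[[length(rows) + 1]] <- data.frame(
        component = cpt, test = tn, rho = r$effect, p_value = r$p_value,
        n = r$n)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- fdr_bh(out$p_value, q)
  rownames(out) <- NULL
  out
}

#' ON-state pattern analysis for one band
#'
#' Convenience chain: PCA of the ON-state edge vectors, elbow-based
#' component-count selection, and cognition correlations for the selected
#' components.
#'
#' @param cohort Cohort object.
#' @param band Band name.
#' @param covariates Covariate matrix or NULL.
#' @param repetitions Elbow repetitions (default 100).
#' @param seed Seed for the elbow randomization.
#' @param q FDR level.
#' @return List: `pca` ([pca_patterns()] result), `n_selected`,
#'   `correlations` (grid data frame).
#' @export
band_pattern_analysis <- function(cohort, band, covariates = NULL,
                                  repetitions = 100, seed = 1L, q = 0.05) {
  on <- cohort_edge_matrix(cohort, band, "ON")
  pr <- pca_patterns(on)
  n_sel <- elbow_components(pr$variance_explained, repetitions, seed)
  tcols <- grep("^t_", names(cohort$metadata), value = TRUE)
  grid <- correlate_patterns_with_cognition(
    pr$scores[, seq_len(n_sel), drop = FALSE],
    cohort$metadata[tcols], covariates, q)
  list(pca = pr, n_selected = n_sel, correlations = grid)
}
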
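#' Label optimal DBS responders
#'
#' @param updrs_diff Per-subject UPDRS_diff (ON - OFF; more negative =
#'   greater improvement).
#' @param threshold Response threshold.
#' @return Logical vector: TRUE (optimal) where `updrs_diff < threshold`.
#' @export
label_responders <- function(updrs_diff, threshold) {
  updrs_diff < threshold
}

#' Band-major edge representation of a cohort
#'
#' Precomputes, once per cohort, the subjects x (bands * edges) matrices the
#' classifier sweeps over: ON-OFF differences and OFF values, columns grouped
#' band-major in the band-set order.
#'
#' @param cohort Cohort object.
#' @return List of class `edge_data`: `diff` and `off` matrices, `col_band`,
#'   `col_i`, `col_j` column annotations, `band_cols` (per-band column index
#'   list), `updrs_diff`, `ids`.
#' @export
cohort_edge_data <- function(cohort) {
  bands <- names(cohort$spec$bands)
  p <- cohort$spec$roi_count
  em <- edge_index_map(p)
  on <- do.call(cbind, lapply(bands, function(b) cohort_edge_matrix(cohort, b, "ON")))
  off <- do.call(cbind, lapply(bands, function(b) cohort_edge_matrix(cohort, b, "OFF")))
  ne <- nrow(em)
  structure(list(
    diff = on - off, off = off,
    col_band = rep(bands, each = ne),
    col_i = rep(em[, "i"], times = length(bands)),
    col_j = rep(em[, "j"], times = length(bands)),
    band_cols = stats::setNames(
      lapply(seq_along(bands), function(k) (k - 1L) * ne + seq_len(ne)),
      bands),
    updrs_diff = cohort$metadata$updrs_diff,
    ids = cohort$metadata$id), class = "edge_data")
}

# 4-SD rule on a mean-difference vector, given per-band column groups;
# returns selected column indices (band-major order). Exploits the band-major
# layout (equal-sized contiguous blocks) to vectorize across bands.
profile_columns <- function(d, band_cols, n_sd = 4) {
  ne <- length(band_cols[[1]])
  dm <- matrix(d, ne, length(band_cols))
  mu <- colMeans(dm)
  sigma <- sqrt(pmax(colMeans(dm * dm) - mu^2, 0))  # population SD over edges
  # degenerate bands (sigma 0) retain nothing: collapse their bounds
  lo <- ifelse(sigma > 0, mu - n_sd * sigma, -Inf)
  hi <- ifelse(sigma > 0, mu + n_sd * sigma, Inf)
  which(dm >= rep(hi, each = ne) | dm <= rep(lo, each = ne))
}

#' Connectivity profile of a possibly-optimal subset
#'
#' Averages the ON-OFF edge differences over the given subject subset and,
#' within each band, retains the edges deviating at least `n_sd` (default 4)
#' standard deviations from the band's mean edge difference. The direction
#' records whether the connection increases (+1) or decreases (-1) under
#' DBS ON in the subset.
#'
#' @param x A cohort object or an [cohort_edge_data()] result.
#' @param subset Integer indices of the possibly-optimal subjects.
#' @param source_threshold The UPDRS_diff threshold that defined the subset
#'   (stored as metadata).
#' @param n_sd Selection threshold in within-band SDs (default 4).
#' @return Data frame of class `connectivity_profile`: `band`, `i`, `j`,
#'   `direction`, `mean_diff`, `col` (column in the band-major edge matrix);
#'   attribute `source_threshold`. Zero rows when no edge passes (degenerate
#'   bands contribute nothing).
#' @export
profile_from_subset <- function(x, subset, source_threshold = NA_real_,
                                n_sd = 4) {
  ed <- if (inherits(x, "edge_data")) x else cohort_edge_data(x)
  if (length(subset) == 0) stop("empty subset")
  d <- colMeans(ed$diff[subset, , drop = FALSE])
  sel <- profile_columns(d, ed$band_cols, n_sd)
  out <- data.frame(band = ed$col_band[sel], i = ed$col_i[sel],
                    j = ed$col_j[sel],
                    direction = sign(d[sel]), mean_diff = d[sel], col = sel)
  rownames(out) <- NULL
  attr(out, "source_threshold") <- source_threshold
  class(out) <- c("connectivity_profile", class(out))
  out
}

#' DBS OFF feature table for a connectivity profile
#'
#' @param x A cohort object or [cohort_edge_data()] result.
#' @param profile A [profile_from_subset()] result with at least one edge.
#' @return Subjects x edges matrix of OFF-state PLI values, columns in
#'   profile (band-major) order.
#' @export
extract_features <- function(x, profile) {
  ed <- if (inherits(x, "edge_data")) x else cohort_edge_data(x)
  if (nrow(profile) == 0) {
    stop("empty profile: skip this threshold level")
  }
  ed$off[, profile$col, drop = FALSE]
}

# linear SVM with train-fold standardization and balanced class weights;
# the separating hyperplane is extracted once so prediction is a dot product
fit_profile_svm <- function(features, labels) {
  if (all(labels) || !any(labels)) stop("single-class training labels")
  y <- factor(labels, levels = c(FALSE, TRUE),
              labels = c("suboptimal", "optimal"))
  n <- nrow(features)
  mu <- colMeans(features)
  sdv <- sqrt(pmax(colMeans(features^2) - mu^2, 0) * n / (n - 1))
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  tab <- table(y)
  wts <- as.numeric(sum(tab) / (2 * tab))
  names(wts) <- names(tab)
  model <- e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE,
                      class.weights = wts, fitted = FALSE)
  list(w = as.numeric(crossprod(model$coefs, model$SV)), rho = model$rho,
       positive = model$levels[model$labels[1]], mu = mu, sd = sdv,
       model = model)
}

predict_profile_svm <- function(fit, features) {
  X <- sweep(sweep(features, 2, fit$mu), 2, fit$sd, "/")
  dec <- as.numeric(X %*% fit$w) - fit$rho
  if (fit$positive == "optimal") dec > 0 else dec <= 0
}

mode_value <- function(x) {
  tab <- table(x)
  vals <- as.numeric(names(tab[tab == max(tab)]))
  min(vals)   # ties broken toward the smaller value
}

#' Inner leave-one-out threshold sweep
#'
#' On the training subjects only: for every candidate response threshold
#' (each distinct observed UPDRS_diff in the inner-training set), build the
#' 4-SD connectivity profile from the possibly-optimal inner-training
#' subjects, train a linear SVM on their DBS OFF profile features, and
#' classify the inner held-out subject. Confusion counts are aggregated per
#' threshold across inner folds; the most discriminable threshold maximizes
#' the mean of the defined metrics (PPV, NPV, sensitivity, specificity),
#' ties broken uniformly at random under the supplied seed.
#'
#' @param ed An [cohort_edge_data()] result.
#' @param train_idx Integer indices of the training subjects (>= 6).
#' @param tie_seed Integer seed for random tie-breaking.
#' @param n_sd Profile selection threshold in SDs (default 4).
#' @return List: `best_threshold`, `table` (per-threshold counts and score).
#' @export
inner_threshold_sweep <- function(ed, train_idx, tie_seed = 1L, n_sd = 4) {
  stopifnot(length(train_idx) >= 6)
  diffs <- ed$updrs_diff
  grid <- sort(unique(diffs[train_idx]))
  counts <- matrix(0L, length(grid), 4,
                   dimnames = list(NULL, c("tp", "fp", "tn", "fn")))
  for (h in train_idx) {
    inner <- setdiff(train_idx, h)
    it_diff <- diffs[inner]
    ord <- inner[order(it_diff)]
    running <- numeric(ncol(ed$diff))
    m <- 0L
    for (t in sort(unique(it_diff))) {
      while (m < length(ord) && diffs[ord[m + 1L]] < t) {
        m <- m + 1L
        running <- running + ed$diff[ord[m], ]
      }
      n_opt <- m
      n_sub <- length(inner) - m
      if (n_opt < 2L || n_sub < 2L) next      # too few per class: skip
      sel <- profile_columns(running / m, ed$band_cols, n_sd)
      if (length(sel) == 0) next              # empty profile: skip
      fit <- fit_profile_svm(ed$off[inner, sel, drop = FALSE], it_diff < t)
      pred <- predict_profile_svm(fit, ed$off[h, sel, drop = FALSE])
      truth <- diffs[h] < t
      gk <- match(t, grid)
      slot <- if (truth && pred) "tp" else if (!truth && pred) "fp"
        else if (!truth && !pred) "tn" else "fn"
      counts[gk, slot] <- counts[gk, slot] + 1L
    }
  }
  score <- apply(counts, 1, function(cc) {
    if (sum(cc) == 0) return(NA_real_)
    mean(unlist(confusion_metrics(cc["tp"], cc["fp"], cc["tn"], cc["fn"])),
         na.rm = TRUE)
  })
  if (all(is.na(score))) stop("no classifiable threshold in the inner sweep")
  best <- which(score == max(score, na.rm = TRUE))
  if (length(best) > 1) {
    set.seed(tie_seed)
    best <- sample(best, 1)
  }
  list(best_threshold = grid[best],
       table = data.frame(threshold = grid, counts, score = score))
}

# full training path of one outer fold: inner sweep, profile and SVM rebuilt
# on all training subjects at the selected threshold. Touches only train_idx
# rows of ed, which the leakage probe verifies.
fit_fold <- function(ed, train_idx, tie_seed, n_sd = 4) {
  sweep <- tryCatch(inner_threshold_sweep(ed, train_idx, tie_seed, n_sd),
                    error = function(e) NULL)
  if (is.null(sweep)) return(NULL)   # no classifiable threshold at all
  t_star <- sweep$best_threshold
  subset <- train_idx[ed$updrs_diff[train_idx] < t_star]
  if (length(subset) == 0) return(NULL)
  profile <- profile_from_subset(ed, subset, t_star, n_sd)
  if (nrow(profile) == 0) return(NULL)
  labels <- ed$updrs_diff[train_idx] < t_star
  if (length(unique(labels)) < 2) return(NULL)
  fit <- fit_profile_svm(extract_features(ed, profile)[train_idx, , drop = FALSE],
                         labels)
  list(threshold = t_star, profile = profile, fit = fit)
}

#' Nested leave-one-out responder classification
#'
#' Outer loop: remove one test subject; run [inner_threshold_sweep()] on the
#' rest; rebuild the connectivity profile and linear SVM on all non-test
#' subjects at the selected threshold; classify the test subject against the
#' label that threshold induces. Confusion counts accumulate over outer
#' folds; the whole procedure is repeated (100 times in the reference
#' conditions), the only cross-repetition stochasticity being the seeded
#' random tie-breaks in threshold selection. The most frequent threshold
#' across folds and repetitions defines the final connectivity profile,
#' computed on the full cohort.
#'
#' @param cohort Cohort object with >= 10 subjects carrying both conditions
#'   and UPDRS scores.
#' @param repetitions Number of repetitions (default 100).
#' @param seed Integer seed.
#' @param n_sd Profile selection threshold in SDs (default 4).
#' @return Object of class `classification_report`: list with `ppv`, `npv`,
#'   `sensitivity`, `specificity` (averages over folds and repetitions;
#'   undefined fold metrics excluded), `per_repetition` (data frame),
#'   `fold_counts` (per repetition x fold), `chosen_threshold` (per
#'   repetition), `final_threshold`, `final_profile`, `n_unclassifiable`.
#' @export
nested_loocv <- function(cohort, repetitions = 100, seed = 1L, n_sd = 4) {
  ed <- cohort_edge_data(cohort)
  n <- nrow(ed$diff)
  if (n < 10) stop("need at least 10 subjects")
  id_key <- vapply(ed$ids, function(s) sum(utf8ToInt(s)), 0)
  per_rep <- vector("list", repetitions)
  fold_counts <- list()
  all_thresholds <- numeric(0)
  n_unclassifiable <- 0L
  for (rep_i in seq_len(repetitions)) {
    counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
    fold_t <- rep(NA_real_, n)
    for (s in seq_len(n)) {
      # tie seed keyed by subject identity, not manifest position, so
      # metrics do not depend on subject ordering
      tie_seed <- (seed + 7919L * rep_i + id_key[s]) %% .Machine$integer.max
      fold <- fit_fold(ed, setdiff(seq_len(n), s), tie_seed, n_sd)
      if (is.null(fold)) {
        n_unclassifiable <- n_unclassifiable + 1L
        message("fold for subject ", ed$ids[s],
                " unclassifiable at its selected threshold; excluded")
        next
      }
      fold_t[s] <- fold$threshold
      pred <- predict_profile_svm(
        fold$fit, ed$off[s, fold$profile$col, drop = FALSE])
      truth <- ed$updrs_diff[s] < fold$threshold
      slot <- if (truth && pred) "tp" else if (!truth && pred) "fp"
        else if (!truth && !pred) "tn" else "fn"
      counts[slot] <- counts[slot] + 1L
    }
    m <- confusion_metrics(counts["tp"], counts["fp"], counts["tn"],
                           counts["fn"])
    per_rep[[rep_i]] <- data.frame(
      repetition = rep_i, ppv = m$ppv, npv = m$npv,
      sensitivity = m$sensitivity, specificity = m$specificity,
      chosen_threshold = if (any(!is.na(fold_t))) {
        mode_value(fold_t[!is.na(fold_t)])
      } else NA_real_)
    fold_counts[[rep_i]] <- counts
    all_thresholds <- c(all_thresholds, fold_t[!is.na(fold_t)])
  }
  rep_tab <- do.call(rbind, per_rep)
  if (length(all_thresholds) == 0) {
    stop("no outer fold was classifiable: every candidate profile was empty")
  }
  final_threshold <- mode_value(all_thresholds)
  subset <- which(ed$updrs_diff < final_threshold)
  final_profile <- profile_from_subset(ed, subset, final_threshold, n_sd)
  structure(list(
    ppv = mean(rep_tab$ppv, na.rm = TRUE),
    npv = mean(rep_tab$npv, na.rm = TRUE),
    sensitivity = mean(rep_tab$sensitivity, na.rm = TRUE),
    specificity = mean(rep_tab$specificity, na.rm = TRUE),
    per_repetition = rep_tab,
    fold_counts = fold_counts,
    chosen_threshold = rep_tab$chosen_threshold,
    final_threshold = final_threshold,
    final_profile = final_profile,
    n_unclassifiable = n_unclassifiable), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0(
    "nested LOOCV responder classification\n",
    "  PPV = %.3f, NPV = %.3f, sensitivity = %.3f, specificity = %.3f\n",
    "  final threshold: UPDRS_diff < %g; profile edges: %d",
    " (%d unclassifiable folds)\n"),
    x$ppv, x$npv, x$sensitivity, x$specificity, x$final_threshold,
    nrow(x$final_profile), x$n_unclassifiable))
  invisible(x)
}
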
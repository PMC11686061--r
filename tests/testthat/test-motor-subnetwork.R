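test_that("motor ROI set is the 14 bilateral motor regions", {
  rois <- motor_roi_set()
  expect_length(rois$labels, 14)
  expect_length(unique(rois$indices), 14)
  expect_equal(rois$indices[1:2], c(1, 2))         # Precentral L/R lead AAL
  expect_error(motor_roi_set(c("Precentral_L", "Foo")), "not found")
})

test_that("submatrix extraction preserves order and symmetry", {
  labs <- aal90_labels()
  rois <- motor_roi_set(labs)
  set.seed(1)
  fc <- devectorize_edges(runif(4005), 90)
  sub <- extract_submatrix(fc, rois)
  expect_equal(unname(sub), fc[rois$indices, rois$indices])
  expect_equal(sub, t(sub))
  expect_length(vectorize_edges(unname(sub)), 91)
})

test_that("first eigenvariate recovers exact low-rank structure", {
  set.seed(2)
  # rank-1: loadings equal the generating direction, all variance explained
  v <- abs(rnorm(91)); v <- v / sqrt(sum(v^2))
  u <- rnorm(20)
  x <- outer(u, v)
  ev <- first_eigenvariate(x)
  expect_equal(ev$loadings, v, tolerance = 1e-10)
  expect_equal(ev$variance_explained, 1, tolerance = 1e-12)
  expect_equal(ev$scores, u - mean(u), tolerance = 1e-8)

  # two orthogonal equal-energy patterns split the variance evenly
  v2 <- numeric(91); v2[1] <- 1
  v3 <- numeric(91); v3[2] <- 1
  x2 <- rbind(outer(c(2, -2), v2), outer(c(2, -2), v3))
  expect_equal(first_eigenvariate(x2)$variance_explained, 0.5,
               tolerance = 1e-12)

  expect_error(first_eigenvariate(matrix(0, 5, 10)), "zero")
})

test_that("eigenvariate agrees with a power-iteration oracle", {
  set.seed(3)
  x <- matrix(rnorm(20 * 91), 20, 91)
  ev <- first_eigenvariate(x)
  or <- oracle_first_eigenvariate(x)
  expect_equal(ev$loadings, or$loadings, tolerance = 1e-8)
  expect_equal(ev$scores, or$scores, tolerance = 1e-8)
  expect_equal(ev$variance_explained, or$variance_explained,
               tolerance = 1e-10)
})

test_that("variance explained matches the SVD definition on random fixtures", {
  set.seed(4)
  for (i in 1:50) {
    x <- matrix(rnorm(8 * 12), 8, 12)
    xc <- sweep(x, 2, colMeans(x))
    d <- svd(xc)$d
    expect_equal(first_eigenvariate(x)$variance_explained,
                 d[1]^2 / sum(d^2), tolerance = 1e-10)
  }
})

test_that("eigenvariate scores are invariant to subject reordering", {
  coh <- generate_fc_cohort(motor_spec(n_subjects = 10, seed = 5))
  ev <- motor_eigenvariate(coh, "hgamma")
  perm <- c(4, 1, 9, 2, 10, 3, 8, 5, 7, 6)
  coh2 <- coh
  coh2$subjects <- coh$subjects[perm]
  ev2 <- motor_eigenvariate(coh2, "hgamma")
  expect_equal(ev2$scores_on, ev$scores_on[perm], tolerance = 1e-10)
  expect_equal(ev2$loadings, ev$loadings, tolerance = 1e-10)
})

test_that("identical ON and OFF matrices give degenerate non-rejections", {
  coh <- generate_fc_cohort(null_spec(n_subjects = 10, seed = 6))
  for (s in seq_along(coh$subjects)) {
    for (bn in names(coh$spec$bands)) {
      coh$subjects[[s]]$fc[[bn]]$ON <- coh$subjects[[s]]$fc[[bn]]$OFF
    }
  }
  out <- on_off_subnetwork_test(coh)
  expect_true(all(out$table$degenerate))
  expect_true(all(out$table$p_value == 1))
  expect_false(any(out$table$significant))
})

test_that("seed connectivity is the mean row edge weight", {
  rois <- motor_roi_set()
  m <- matrix(0.3, 14, 14); diag(m) <- 0
  dimnames(m) <- list(rois$labels, rois$labels)
  expect_equal(seed_connectivity(m, "Putamen_L"), 0.3)

  m2 <- m
  m2["Putamen_L", "Thalamus_R"] <- m2["Thalamus_R", "Putamen_L"] <- 0.3 + 0.13
  expect_equal(seed_connectivity(m2, "Putamen_L"), 0.3 + 0.13 / 13)

  set.seed(7)
  mr <- devectorize_edges(runif(91), 14)
  dimnames(mr) <- list(rois$labels, rois$labels)
  k <- 5
  expect_equal(seed_connectivity(mr, rois$labels[k]),
               (sum(mr[k, ]) - mr[k, k]) / 13)
  expect_error(seed_connectivity(mr, "STN_L"), "unknown")
})

test_that("seed post-hoc tests refuse cohorts too small to pair", {
  coh <- generate_fc_cohort(motor_spec(n_subjects = 2, seed = 8))
  expect_error(seed_posthoc_tests(coh, "hgamma"), "insufficient")
})

test_that("OFF-state correlation guards degenerate inputs", {
  expect_error(correlate_off_with_updrs(rnorm(5), rnorm(5)), "6 subjects")
  expect_error(correlate_off_with_updrs(rep(1, 10), rnorm(10)), "constant")
  expect_error(correlate_off_with_updrs(rnorm(10), rep(-20, 10)), "constant")
})

test_that("planted loadings are recovered on a large cohort", {
  coh <- generate_fc_cohort(motor_spec(n_subjects = 200, seed = 9))
  ev <- motor_eigenvariate(coh, "hgamma")
  expect_gt(cor(ev$loadings, coh$ground_truth$motor_loading_subnet), 0.9)
})
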
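# Independent brute-force oracles. These re-derive expected values from
# first principles and must stay independent of the implementation paths
# they check.

# exact two-sided signed-rank p-value by exhaustive sign-flip enumeration
oracle_signrank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  lower <- mean(v_all <= v_obs)
  upper <- mean(v_all >= v_obs)
  min(1, 2 * min(lower, upper))
}

# Benjamini-Hochberg step-up by direct evaluation of the definition
oracle_bh_mask <- function(p, q) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ps <- sort(p)
  ks <- which(ps <= seq_len(m) * q / m)
  if (length(ks) == 0) return(rep(FALSE, m))
  p <= ps[max(ks)]
}

# first right singular vector / scores / variance by power iteration on the
# centered cross-product matrix
oracle_first_eigenvariate <- function(x, iters = 2000) {
  xc <- sweep(x, 2, colMeans(x))
  g <- crossprod(xc)
  v <- rep(1 / sqrt(ncol(x)), ncol(x))
  for (i in seq_len(iters)) {
    v <- g %*% v
    v <- v / sqrt(sum(v^2))
  }
  v <- as.numeric(v)
  if (mean(v) < 0) v <- -v
  lambda1 <- as.numeric(t(v) %*% g %*% v)
  list(scores = as.numeric(xc %*% v), loadings = v,
       variance_explained = lambda1 / sum(diag(g)))
}

# Spearman partial correlation from the normal equations on rank residuals
oracle_spearman_partial <- function(x, y, covariates) {
  z <- cbind(1, covariates)
  beta_x <- solve(t(z) %*% z, t(z) %*% rank(x))
  beta_y <- solve(t(z) %*% z, t(z) %*% rank(y))
  rx <- rank(x) - z %*% beta_x
  ry <- rank(y) - z %*% beta_y
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

# PLI of two phase series by the definition, scalar loop
oracle_pli_pair <- function(phi1, phi2) {
  s <- 0
  for (t in seq_along(phi1)) {
    d <- phi1[t] - phi2[t]
    d <- d - 2 * pi * floor(d / (2 * pi))     # [0, 2pi)
    if (d > pi) d <- d - 2 * pi               # (-pi, pi]
    s <- s + sign(d)
  }
  abs(s / length(phi1))
}

# optimal two-cluster split of a 1-D vector by exhaustive contiguous splits
oracle_two_cluster_sizes <- function(v) {
  vs <- sort(v, decreasing = TRUE)
  best <- Inf; best_k <- 1
  for (k in seq_len(length(vs) - 1)) {
    a <- vs[1:k]; b <- vs[(k + 1):length(vs)]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best) { best <- ss; best_k <- k }
  }
  best_k   # size of the cluster holding the largest values
}
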
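# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the code paths they check.

# P(overlap >= k) when drawing n from a universe of N containing K marked,
# by exhaustive enumeration of all draws (N <= 12).
oracle_hypergeom <- function(k, K, n, N) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

# one-sided binomial tail by direct pmf summation
oracle_binom_tail <- function(E, trials, p) {
  if (E <= 0) return(1)
  sum(vapply(E:trials, function(j) choose(trials, j) * p^j * (1 - p)^(trials - j), 1))
}

# exact Wilcoxon rank-sum p-value by enumeration of all group assignments
oracle_wilcox <- function(a, b, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  pooled <- c(a, b)
  n <- length(a)
  obs <- sum(rank(pooled)[seq_len(n)])
  assignments <- combn(length(pooled), n)
  stats <- apply(assignments, 2, function(idx) sum(rank(pooled)[idx]))
  if (alternative == "greater") {
    mean(stats >= obs)
  } else {
    mu <- n * (length(pooled) + 1) / 2
    mean(abs(stats - mu) >= abs(obs - mu))
  }
}

# Cliff's delta by exhaustive pairwise comparison
oracle_cliffs <- function(a, b) {
  gt <- lt <- 0
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1
    if (x < y) lt <- lt + 1
  }
  (gt - lt) / (length(a) * length(b))
}

# OLS by normal equations, plus the textbook prediction interval
oracle_ols_pi <- function(x, y, x0, alpha = 0.05) {
  n <- length(x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  resid <- y - X %*% beta
  s_e <- sqrt(sum(resid^2) / (n - 2))
  xbar <- mean(x); Sxx <- sum((x - xbar)^2)
  yhat <- beta[1] + beta[2] * x0
  half <- qt(1 - alpha / 2, n - 2) * s_e *
    sqrt(1 + 1 / n + (x0 - xbar)^2 / Sxx)
  list(intercept = beta[1], slope = beta[2], s_e = s_e,
       yhat = yhat, lo = yhat - half, hi = yhat + half,
       r_squared = 1 - sum(resid^2) / sum((y - mean(y))^2))
}

# lasso on (1/(2n))||y - Xb||^2 + lambda ||b||_1 (no intercept, no
# standardisation) by cyclic coordinate descent; returns the largest lambda
# in the descending grid at which each coefficient is non-zero.
oracle_lasso_first_entry <- function(X, y, lambda_grid, tol = 1e-10,
                                     max_iter = 10000) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xtx <- colSums(X^2) / n
  first <- rep(0, p)
  b <- rep(0, p)
  for (lam in lambda_grid) {   # warm starts down the path
    for (it in seq_len(max_iter)) {
      delta <- 0
      for (j in seq_len(p)) {
        r <- y - X %*% b + X[, j] * b[j]
        rho <- sum(X[, j] * r) / n
        bj <- sign(rho) * max(abs(rho) - lam, 0) / xtx[j]
        delta <- max(delta, abs(bj - b[j]))
        b[j] <- bj
      }
      if (delta < tol) break
    }
    newly <- which(abs(b) > 1e-7 & first == 0)
    first[newly] <- lam
  }
  first
}

# number of distinct root-to-terminal paths per protein by explicit DFS
oracle_path_count <- function(map) {
  kids <- split(map$edges$child, map$edges$parent)
  all_paths_to <- function(target) {
    found <- 0L
    dfs <- function(node) {
      if (node == target) { found <<- found + 1L; return(invisible()) }
      for (ch in kids[[node]] %||% character(0)) dfs(ch)
    }
    dfs(map$root)
    found
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  prot <- map$assemblies[[map$root]]
  sapply(prot, function(p) {
    containing <- names(map$assemblies)[sapply(map$assemblies, function(m) p %in% m)]
    terminal <- containing[sapply(containing, function(id) {
      ch <- kids[[id]]
      is.null(ch) || !any(sapply(ch, function(c2) p %in% map$assemblies[[c2]]))
    })]
    sum(sapply(terminal, all_paths_to))
  })
}

# leaf assemblies of a planted map (test-side copy)
truth_leaves <- function(truth) {
  setdiff(names(truth$assemblies), unique(truth$parent_edges$parent))
}

# best Jaccard of each planted leaf against a cell map's assemblies
leaf_recovery <- function(truth, map) {
  ids <- setdiff(names(map$assemblies), map$root)
  vapply(truth$assemblies[truth_leaves(truth)], function(m) {
    max(vapply(ids, function(id) {
      length(intersect(m, map$assemblies[[id]])) /
        length(union(m, map$assemblies[[id]]))
    }, 1))
  }, 1)
}

# small aligned bundle + fast config for pipeline-level tests
tiny_pipeline_inputs <- function(n = 60, branching = c(4), seed = 2,
                                 embed_dim = 32) {
  bundle <- make_synthetic_bundle(n, length(branching) + 1, branching,
                                  seed = seed)
  fm_ppi <- embed_network(bundle$network, dim = embed_dim, epochs = 2,
                          seed = seed)
  list(bundle = bundle, fm_x = fm_ppi, fm_y = bundle$image_features)
}

tiny_config <- function(seed = 4) {
  coembed_config(latent_dim = 16, branch_hidden_dim = 32,
                 decoder_hidden_dims = c(32, 32), phase_epochs = c(5, 5, 10),
                 cluster_refresh_epochs = 5, batch_size = 16, seed = seed)
}
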
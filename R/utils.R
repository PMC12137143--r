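#' @useDynLib cellmapr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor density lm p.adjust pbinom phyper predict qt
#'   rbinom rnorm runif setNames wilcox.test coef dnorm median sd var
#' @importFrom utils head combn
NULL

# Row-wise L2 normalisation; all-zero rows are left at zero.
l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nz <- nrm > 0
  m[nz, ] <- m[nz, , drop = FALSE] / nrm[nz]
  m
}

#' Cosine similarity between all row pairs of a matrix
#'
#' @param m numeric matrix (rows are observations).
#' @return symmetric matrix of cosine similarities with unit diagonal
#'   (zero rows yield zero similarity).
#' @export
cosine_similarity_matrix <- function(m) {
  mn <- l2_normalize_rows(as.matrix(m))
  s <- tcrossprod(mn)
  s[s > 1] <- 1
  s[s < -1] <- -1
  s
}

jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# |child %in% parent| / |child|
containment_index <- function(child, parent) {
  if (length(child) == 0L) return(0)
  sum(child %in% parent) / length(child)
}

#' Cliff's delta effect size
#'
#' Nonparametric dominance effect size
#' \eqn{\delta = (\#\{a>b\} - \#\{a<b\}) / (n_a n_b)} comparing two samples,
#' computed in O((n+m) log(n+m)) via midranks.
#'
#' @param a,b numeric vectors.
#' @return delta in \[-1, 1\]; positive when values in `a` tend to exceed `b`.
#' @export
cliffs_delta <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  r <- rank(c(a, b))
  n1 <- length(a); n2 <- length(b)
  # rank-sum of a gives #(a>b) + 0.5 #(a==b) (Mann-Whitney U with ties at 1/2)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  2 * u / (n1 * n2) - 1
}

# Benjamini-Hochberg adjusted p-values (thin wrapper kept for readability).
bh_adjust <- function(p) p.adjust(p, method = "BH")

# Hypergeometric upper-tail P(X >= k) drawing n from a universe of N with K
# successes.
hyper_test <- function(k, K, n, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Deterministic sub-stream seeds below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
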
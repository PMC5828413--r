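#' Standardise columns to zero mean and unit sample variance
#'
#' Uses the sample (n-1) standard deviation.  Constant columns cannot be
#' standardised and raise an error naming the offending variables, so the
#' caller can drop them explicitly rather than carry silent zeros.
#'
#' @param X numeric matrix, observations in rows, variables in columns.
#' @return Matrix of the same shape with each column at mean 0, sd 1.
#' @export
zscore_columns <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 observations to z-score")
  if (anyNA(X)) stop("missing values not allowed in z-scoring")
  s <- apply(X, 2L, stats::sd)
  if (any(s == 0)) {
    ids <- colnames(X)[s == 0]
    if (is.null(ids)) ids <- which(s == 0)
    stop("zero-variance column(s): ", paste(ids, collapse = ", "))
  }
  Z <- scale(X, center = TRUE, scale = s)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  Z
}

#' Pearson correlation matrix of the columns of a matrix
#'
#' @param X numeric matrix (observations x variables), typically z-scored.
#' @return Symmetric variables-by-variables correlation matrix with unit
#'   diagonal, entries clamped to \[-1, 1\].
#' @export
correlation_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 observations for correlations")
  R <- stats::cor(X)
  R <- (R + t(R)) / 2
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  R
}

# Symmetric inverse square root via spectral decomposition, discarding
# eigenvalues below tol * largest (rank-deficient sets are whitened on
# their informative subspace only).
whitening_matrix <- function(R, tol = 1e-10) {
  e <- eigen(R, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) stop("correlation matrix has rank 0 after whitening")
  V <- e$vectors[, keep, drop = FALSE]
  list(W = V %*% (t(V) / sqrt(e$values[keep])), rank = sum(keep))
}

#' Canonical correlation analysis of two z-scored variable sets
#'
#' Finds successive pairs of linear combinations `U = M %*% AA` and
#' `V = N %*% BB` with maximal correlation, each pair uncorrelated with the
#' previous ones.  The decomposition whitens each set's correlation matrix
#' by a spectral pseudo-inverse square root and takes the singular value
#' decomposition of the whitened cross-correlation; singular values are
#' clipped to \[0, 1\] and reported as the canonical correlations.
#'
#' Coefficients are scaled so each variate has unit sample variance.  Signs
#' are fixed deterministically: each first-set coefficient column is
#' flipped so its largest-magnitude entry is positive, and the paired
#' second-set column flips with it, preserving `cor(U[,k], V[,k]) = r[k]`.
#'
#' @param M observations x p matrix (first set), z-scored columns.
#' @param N observations x q matrix (second set), z-scored columns,
#'   same observation order as `M`.
#' @param ridge non-negative ridge added to the diagonal of each within-set
#'   correlation matrix before whitening (for n close to or below p).
#' @param tol relative eigenvalue cutoff for the whitening pseudo-inverse.
#' @return Object of class `cca_result`: coefficient matrices `AA`
#'   (p x pairs) and `BB` (q x pairs), canonical correlations `r`
#'   (non-increasing), variates `U` and `V`, within-set correlation
#'   matrices `r11` and `r22`, and dimensions `n_obs`, `p`, `q`.
#' @examples
#' set.seed(1)
#' M <- zscore_columns(matrix(rnorm(60), 20, 3))
#' N <- zscore_columns(matrix(rnorm(40), 20, 2))
#' fit <- compute_cca(M, N)
#' fit$r
#' @export
compute_cca <- function(M, N, ridge = 0, tol = 1e-10) {
  M <- as.matrix(M)
  N <- as.matrix(N)
  if (nrow(M) != nrow(N)) {
    stop("M and N must have the same number of observations (",
         nrow(M), " vs ", nrow(N), ")")
  }
  n <- nrow(M)
  if (n <= 2L) stop("need more than 2 observations")
  p <- ncol(M)
  q <- ncol(N)
  r11 <- correlation_matrix(M)
  r22 <- correlation_matrix(N)
  if (ridge > 0) {
    r11 <- r11 + diag(ridge, p)
    r22 <- r22 + diag(ridge, q)
  }
  r12 <- stats::cor(M, N)
  w1 <- whitening_matrix(r11, tol)
  w2 <- whitening_matrix(r22, tol)
  K <- w1$W %*% r12 %*% w2$W
  sv <- svd(K)
  s <- min(p, q, w1$rank, w2$rank)
  if (s < 1L) stop("rank 0 after whitening")
  r <- pmin(pmax(sv$d[seq_len(s)], 0), 1)
  AA <- w1$W %*% sv$u[, seq_len(s), drop = FALSE]
  BB <- w2$W %*% sv$v[, seq_len(s), drop = FALSE]
  U <- M %*% AA
  V <- N %*% BB
  # enforce unit sample variance of the variates (exact up to round-off
  # already, since z-scored columns make cov(M) equal r11)
  su <- apply(U, 2L, stats::sd)
  sv_ <- apply(V, 2L, stats::sd)
  ok_u <- su > 0
  ok_v <- sv_ > 0
  AA[, ok_u] <- sweep(AA[, ok_u, drop = FALSE], 2L, su[ok_u], "/")
  U[, ok_u] <- sweep(U[, ok_u, drop = FALSE], 2L, su[ok_u], "/")
  BB[, ok_v] <- sweep(BB[, ok_v, drop = FALSE], 2L, sv_[ok_v], "/")
  V[, ok_v] <- sweep(V[, ok_v, drop = FALSE], 2L, sv_[ok_v], "/")
  for (k in seq_len(s)) {
    j <- which.max(abs(AA[, k]))
    if (AA[j, k] < 0) {
      AA[, k] <- -AA[, k]
      U[, k] <- -U[, k]
      BB[, k] <- -BB[, k]
      V[, k] <- -V[, k]
    }
  }
  rownames(AA) <- colnames(M)
  rownames(BB) <- colnames(N)
  structure(list(AA = AA, BB = BB, r = r, U = U, V = V,
                 r11 = r11, r22 = r22, n_obs = n, p = p, q = q),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("Canonical correlation analysis: p =", x$p, ", q =", x$q,
      ", n =", x$n_obs, "\n")
  cat("canonical correlations:",
      paste(sprintf("%.4f", x$r), collapse = " "), "\n")
  invisible(x)
}

#' Wilks' lambda / Bartlett chi-square significance of canonical pairs
#'
#' For pair k the null hypothesis is that canonical correlations k and
#' beyond are all zero.  Wilks' lambda is the product of `1 - r_i^2` over
#' the remaining pairs; Bartlett's large-sample approximation refers
#' `-(n - 1 - (p + q + 1)/2) * log(lambda)` to a chi-square with
#' `(p - k + 1)(q - k + 1)` degrees of freedom.
#'
#' @param r canonical correlations (each in \[0, 1\], non-increasing).
#' @param n_obs number of observations.
#' @param p,q variable counts of the two sets.
#' @return Data frame with one row per pair: `pair`, `wilks_lambda`,
#'   `chi_square`, `dof`, `p_value`.
#' @export
canonical_pvalues <- function(r, n_obs, p, q) {
  if (any(r < 0 | r > 1)) stop("canonical correlations must lie in [0, 1]")
  if (n_obs <= p + q) {
    warning("n_obs <= p + q; Bartlett chi-square approximation is unreliable")
  }
  s <- length(r)
  lam <- chi <- pv <- numeric(s)
  dof <- integer(s)
  scale_fac <- n_obs - 1 - (p + q + 1) / 2
  for (k in seq_len(s)) {
    lam[k] <- prod(1 - r[k:s]^2)
    chi[k] <- -scale_fac * log(lam[k])
    dof[k] <- as.integer(p - k + 1) * as.integer(q - k + 1)
    pv[k] <- stats::pchisq(chi[k], df = dof[k], lower.tail = FALSE)
  }
  data.frame(pair = seq_len(s), wilks_lambda = lam, chi_square = chi,
             dof = dof, p_value = pv)
}

#' Structure loadings of the canonical variates
#'
#' The loading of variable j on pair k is the correlation between variate k
#' and the standardised variable j; in matrix form `t(AA) %*% r11` for the
#' first set and `t(BB) %*% r22` for the second.
#'
#' @param result a [compute_cca()] result.
#' @return List with `r_1A` (pairs x p, first set) and `r_2B` (pairs x q,
#'   second set).
#' @export
structure_loadings <- function(result) {
  stopifnot(inherits(result, "cca_result"))
  if (nrow(result$AA) != nrow(result$r11) ||
      nrow(result$BB) != nrow(result$r22)) {
    stop("coefficient / correlation matrix dimension mismatch")
  }
  list(r_1A = t(result$AA) %*% result$r11,
       r_2B = t(result$BB) %*% result$r22)
}

#' Variance extracted by one canonical pair
#'
#' Mean squared structure loading of a set's variables on a given pair: the
#' share of the set's (standardised) variance carried by that canonical
#' variate.  High values mean many genes of the set move with the variate,
#' not just one or two.
#'
#' @param loadings pairs x variables loading matrix (`r_1A` or `r_2B` from
#'   [structure_loadings()]).
#' @param pair pair index (default 1, the leading pair).
#' @return A number in \[0, 1\].
#' @export
variance_extracted <- function(loadings, pair = 1L) {
  loadings <- as.matrix(loadings)
  if (length(loadings) == 0L) stop("empty loadings")
  if (pair < 1L || pair > nrow(loadings)) {
    stop("pair index ", pair, " out of range (", nrow(loadings), " pairs)")
  }
  mean(loadings[pair, ]^2)
}
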
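# Independent oracles and small fixture builders shared across tests.

# Brute-force maximum of |cor(M a, N b)| over unit vectors a, b, via
# multi-start numeric optimisation on spherical angles.  Deliberately
# independent of the whitening/SVD route used by compute_cca().
bf_max_cor <- function(M, N, n_starts = 30L) {
  p <- ncol(M)
  q <- ncol(N)
  if (p == 1L && q == 1L) return(abs(stats::cor(M[, 1], N[, 1])))
  sph <- function(theta) {
    d <- length(theta) + 1L
    v <- numeric(d)
    s <- 1
    for (i in seq_along(theta)) {
      v[i] <- s * cos(theta[i])
      s <- s * sin(theta[i])
    }
    v[d] <- s
    v
  }
  na <- p - 1L
  nb <- q - 1L
  obj <- function(par) {
    a <- if (na) sph(par[seq_len(na)]) else 1
    b <- if (nb) sph(par[na + seq_len(nb)]) else 1
    u <- M %*% a
    v <- N %*% b
    if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
    -abs(stats::cor(u, v)[1L])
  }
  if (na + nb == 1L) {
    # one free angle: dense grid + local refinement
    grid <- seq(0, pi, length.out = 2000L)
    vals <- vapply(grid, obj, numeric(1))
    j <- which.min(vals)
    o <- stats::optimize(obj, c(grid[max(j - 2L, 1L)],
                                grid[min(j + 2L, length(grid))]),
                         tol = 1e-12)
    return(-o$objective)
  }
  best <- 0
  for (s in seq_len(n_starts)) {
    par0 <- stats::runif(na + nb, 0, pi)
    o <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-15))
    o2 <- tryCatch(
      suppressWarnings(stats::optim(o$par, obj, method = "BFGS",
                                    control = list(maxit = 500))),
      error = function(e) o)
    best <- max(best, -o$value, -o2$value)
  }
  best
}

# Exhaustive hypergeometric upper tail: fraction of all size-n_draw subsets
# of the background containing at least x pathway members.
enumerate_hyper_tail <- function(n_background, members_idx, n_draw, x) {
  draws <- utils::combn(n_background, n_draw)
  hits <- apply(draws, 2L, function(s) sum(s %in% members_idx))
  mean(hits >= x)
}

# Random z-scored test instance for CCA checks.
random_instance <- function(n, p, q) {
  list(M = zscore_columns(matrix(stats::rnorm(n * p), n, p)),
       N = zscore_columns(matrix(stats::rnorm(n * q), n, q)))
}

# Tiny expression matrix with named genes/experiments.
toy_expression <- function(values, genes, experiments) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, experiments))
  m
}
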
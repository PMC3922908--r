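# Independent ML confirmatory-factor-analysis oracle.
#
# Deliberately shares no code with the package engine: correlated-factor
# model with all loadings free, the factor covariance constrained to a
# correlation matrix via row-normalized Cholesky rows (so the standardized
# solution is directly parameterized), residual variances log-scaled, and
# the discrepancy minimized by stats::optim with numerical gradients.

oracle_fml <- function(S, sigma) {
  p <- nrow(S)
  as.numeric(determinant(sigma)$modulus) +
    sum(diag(S %*% solve(sigma))) -
    as.numeric(determinant(S)$modulus) - p
}

oracle_corr_from_z <- function(z, nf) {
  Lc <- diag(nf)
  if (nf > 1) {
    idx <- 1L
    for (k in 2:nf) {
      row <- c(z[idx:(idx + k - 2L)], 1)
      idx <- idx + k - 1L
      Lc[k, 1:k] <- row / sqrt(sum(row^2))
    }
  }
  tcrossprod(Lc)
}

oracle_sigma <- function(par, fmap, nf) {
  p <- length(fmap)
  l <- par[1:p]
  nz <- nf * (nf - 1) / 2
  z <- if (nz) par[p + seq_len(nz)] else numeric(0)
  th <- exp(par[p + nz + seq_len(p)])
  Phi <- oracle_corr_from_z(z, nf)
  L <- matrix(0, p, nf)
  L[cbind(1:p, fmap)] <- l
  L %*% Phi %*% t(L) + diag(th, p)
}

# fmap: integer factor index per item
oracle_cfa <- function(S, fmap, n_starts = 3L, seed = 1L) {
  p <- length(fmap)
  nf <- max(fmap)
  nz <- nf * (nf - 1) / 2
  fn <- function(par) {
    sigma <- oracle_sigma(par, fmap, nf)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) return(1e9)
    oracle_fml(S, sigma)
  }
  base <- c(sqrt(pmax(diag(S) / 2, 0.05)), rep(0.4, nz),
            log(pmax(diag(S) / 2, 0.05)))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  starts <- c(list(base), lapply(seq_len(n_starts - 1L), function(i)
    base + rnorm(length(base), sd = 0.15)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  best <- NULL
  for (s in starts) {
    o <- optim(s, fn, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, fn, method = "BFGS",        # polish
               control = list(maxit = 2000, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  sigma <- oracle_sigma(best$par, fmap, nf)
  l <- best$par[1:p]
  lambda_std <- l / sqrt(diag(sigma))
  # resolve per-factor sign indeterminacy: loading sums positive
  for (k in seq_len(nf)) {
    sel <- fmap == k
    if (sum(lambda_std[sel]) < 0) lambda_std[sel] <- -lambda_std[sel]
  }
  list(lambda_std = lambda_std, F_min = best$value,
       phi = oracle_corr_from_z(
         if (nz) best$par[p + seq_len(nz)] else numeric(0), nf))
}

# draw multivariate normal data with a given covariance (base R only)
draw_mvn <- function(n, sigma, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  z <- matrix(rnorm(n * nrow(sigma)), n) %*% chol(sigma)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  z
}

# a random small correlated-factor instance: true covariance + sampled S
random_cfa_instance <- function(seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  nf <- sample(2:3, 1)
  k <- sample(2:4, nf, replace = TRUE)
  fmap <- rep(seq_len(nf), times = k)
  p <- length(fmap)
  lambda <- runif(p, 0.5, 0.9)
  z <- rnorm(nf * (nf - 1) / 2, 0.6, 0.3)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  Phi <- oracle_corr_from_z(z, nf)
  L <- matrix(0, p, nf)
  L[cbind(1:p, fmap)] <- lambda
  sigma <- L %*% Phi %*% t(L) + diag(1 - lambda^2, p)
  list(fmap = fmap, lambda = lambda, sigma = sigma,
       S = cov(draw_mvn(2000, sigma, seed + 1000L)), n = 2000L)
}

# spec object matching an fmap, correlated-factors mode
spec_from_fmap <- function(fmap) {
  hbm_model_spec(paste0("G", fmap), second_order = FALSE)
}
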
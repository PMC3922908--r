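#' Model-implied covariance matrix
#'
#' Computes `Sigma(theta) = Lambda Phi Lambda' + Theta` for a simple-structure
#' factor model. With a second-order factor,
#' `Phi = (I - B)^-1 (gamma gamma' + Psi) (I - B)^-T` (second-order factor
#' variance fixed to 1); otherwise `Phi` is supplied directly.
#'
#' @param params a list of raw parameters: `lambda` (item loadings, one per
#'   item, on the item's assigned factor), `theta` (item residual variances)
#'   and either `gamma`, `beta`, `psi` (second-order mode) or `phi` (a
#'   factor covariance matrix, correlated-factors mode).
#' @param spec an [hbm_model_spec()].
#' @return The `p x p` implied covariance matrix.
#' @export
#' @examples
#' spec <- hbm_model_spec(c("F1","F1","F1"), second_order = FALSE)
#' p <- list(lambda = c(.6,.7,.8), theta = 1 - c(.6,.7,.8)^2,
#'           phi = matrix(1, 1, 1))
#' implied_covariance(p, spec)
implied_covariance <- function(params, spec) {
  stopifnot(length(params$lambda) == spec$n_items,
            length(params$theta) == spec$n_items)
  Phi <- factor_covariance(params, spec)
  L <- loading_matrix(params$lambda, spec)
  sigma <- L %*% Phi %*% t(L) + diag(params$theta, spec$n_items)
  dimnames(sigma) <- list(spec$items, spec$items)
  (sigma + t(sigma)) / 2
}

loading_matrix <- function(lambda, spec) {
  L <- matrix(0, spec$n_items, spec$n_factors,
              dimnames = list(spec$items, spec$factors))
  L[cbind(seq_len(spec$n_items), spec$factor_index)] <- lambda
  L
}

factor_covariance <- function(params, spec) {
  if (spec$second_order) {
    nf <- spec$n_factors
    B <- structural_matrix(spec, params$beta)
    IB <- diag(nf) - B
    if (abs(det(IB)) < 1e-12) stop("(I - B) is singular")
    A <- solve(IB)
    A %*% (tcrossprod(unname(params$gamma)) + diag(params$psi, nf)) %*% t(A)
  } else {
    params$phi
  }
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' The normal-theory fit function
#' `F_ML = log det(Sigma) + tr(S Sigma^-1) - log det(S) - p`.
#' `F_ML >= 0`, with equality iff `S == Sigma`; `(n - 1) * F_ML` at the
#' minimizer is the model chi-square.
#'
#' @param S sample covariance matrix (positive definite).
#' @param sigma model-implied covariance matrix (positive definite).
#' @return The scalar discrepancy.
#' @export
#' @examples
#' ml_discrepancy(diag(2) * 2, diag(2))  # 2 - log(4)
ml_discrepancy <- function(S, sigma) {
  p <- nrow(S)
  stopifnot(ncol(S) == p, all(dim(sigma) == p))
  cS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is not positive definite"))
  cSig <- tryCatch(chol(sigma), error = function(e)
    stop("model covariance is not positive definite"))
  logdetS <- 2 * sum(log(diag(cS)))
  logdetSig <- 2 * sum(log(diag(cSig)))
  sig_inv <- chol2inv(cSig)
  as.numeric(logdetSig + sum(sig_inv * S) - logdetS - p)
}

#' Independence (null) model chi-square
#'
#' Fits the independence model `Sigma_0 = diag(S)` -- the ML solution when
#' all covariances are constrained to zero -- giving the baseline statistic
#' for the NFI/CFI/IFI comparative indices.
#'
#' @param S sample covariance matrix.
#' @param n sample size.
#' @return A list with `chi_square_null` and `df_null = p (p - 1) / 2`.
#' @export
null_model <- function(S, n) {
  p <- nrow(S)
  f0 <- ml_discrepancy(S, diag(diag(S), p))
  list(chi_square_null = (n - 1) * f0, df_null = p * (p - 1) / 2)
}

## ---- internal: free-parameter vector <-> parameter list ----
##
## Layout (second-order mode):
##   [free loadings (non-marker)] [gamma (nf)] [beta (n_paths)]
##   [log psi (nf)] [log theta (p)]
## Correlated-factors mode replaces gamma/beta/psi by the lower-triangular
## Cholesky factor of Phi (log diagonal), column-major.

par_template <- function(spec) {
  free_load <- setdiff(seq_len(spec$n_items), spec$markers)
  n_load <- length(free_load)
  nf <- spec$n_factors
  if (spec$second_order) {
    n_struct <- nf + length(spec$structural_paths) + nf
  } else {
    n_struct <- nf * (nf + 1) / 2
  }
  list(free_load = free_load, n_load = n_load,
       n_par = n_load + n_struct + spec$n_items)
}

par_to_list <- function(par, spec, tmpl = par_template(spec)) {
  nf <- spec$n_factors
  p <- spec$n_items
  lambda <- rep(1, p)                        # markers fixed to 1
  lambda[tmpl$free_load] <- par[seq_len(tmpl$n_load)]
  i <- tmpl$n_load
  if (spec$second_order) {
    gamma <- par[i + seq_len(nf)]; i <- i + nf
    np <- length(spec$structural_paths)
    beta <- if (np) par[i + seq_len(np)] else numeric(0); i <- i + np
    psi <- exp(par[i + seq_len(nf)]); i <- i + nf
    theta <- exp(par[i + seq_len(p)])
    list(lambda = lambda, gamma = gamma, beta = beta, psi = psi,
         theta = theta)
  } else {
    Lc <- matrix(0, nf, nf)
    idx <- lower.tri(Lc, diag = TRUE)
    Lc[idx] <- par[i + seq_len(sum(idx))]; i <- i + sum(idx)
    diag(Lc) <- exp(diag(Lc))
    theta <- exp(par[i + seq_len(p)])
    list(lambda = lambda, phi = tcrossprod(Lc), chol_phi = Lc,
         theta = theta)
  }
}

# F_ML and its analytic gradient wrt the free-parameter vector.
# E = Sigma^-1 - Sigma^-1 S Sigma^-1 so that dF = tr(E dSigma).
fml_objective <- function(par, S, spec, tmpl, logdetS, gradient = TRUE) {
  pl <- par_to_list(par, spec, tmpl)
  nf <- spec$n_factors
  p <- spec$n_items
  L <- loading_matrix(pl$lambda, spec)
  if (spec$second_order) {
    B <- structural_matrix(spec, pl$beta)
    A <- tryCatch(solve(diag(nf) - B), error = function(e) NULL)
    if (is.null(A)) return(list(value = 1e10, gradient = rep(0, length(par))))
    G <- tcrossprod(pl$gamma) + diag(pl$psi, nf)
    Phi <- A %*% G %*% t(A)
  } else {
    Phi <- pl$phi
  }
  sigma <- L %*% Phi %*% t(L) + diag(pl$theta, p)
  cSig <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(cSig)) return(list(value = 1e10, gradient = rep(0, length(par))))
  sig_inv <- chol2inv(cSig)
  val <- 2 * sum(log(diag(cSig))) + sum(sig_inv * S) - logdetS - p
  if (!gradient) return(list(value = val))

  E <- sig_inv - sig_inv %*% S %*% sig_inv
  g <- numeric(length(par))
  ELPhi <- E %*% L %*% Phi
  g[seq_len(tmpl$n_load)] <-
    2 * ELPhi[cbind(tmpl$free_load, spec$factor_index[tmpl$free_load])]
  i <- tmpl$n_load
  M <- t(L) %*% E %*% L                      # nf x nf, symmetric
  if (spec$second_order) {
    AMA <- t(A) %*% M %*% A
    g[i + seq_len(nf)] <- 2 * as.numeric(AMA %*% pl$gamma)
    i <- i + nf
    np <- length(spec$structural_paths)
    if (np) {
      PhiMA <- Phi %*% M %*% A
      for (k in seq_len(np)) {
        pth <- spec$structural_paths[[k]]
        from <- match(pth[1], spec$factors); to <- match(pth[2], spec$factors)
        g[i + k] <- 2 * PhiMA[from, to]
      }
      i <- i + np
    }
    g[i + seq_len(nf)] <- diag(AMA) * pl$psi
    i <- i + nf
  } else {
    Lc <- pl$chol_phi
    ML <- M %*% Lc
    gPhi <- 2 * ML
    gPhi[cbind(seq_len(nf), seq_len(nf))] <-
      2 * diag(ML) * diag(Lc)                # chain rule for log diagonal
    idx <- lower.tri(Lc, diag = TRUE)
    g[i + seq_len(sum(idx))] <- gPhi[idx]
    i <- i + sum(idx)
  }
  g[i + seq_len(p)] <- diag(E) * pl$theta
  list(value = val, gradient = g)
}
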
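#' Fit a (second-order) confirmatory factor model by maximum likelihood
#'
#' The package's central fitting function. Estimates the simple-structure
#' factor model described by `spec` -- by default the 22-item health-belief
#' questionnaire model: five first-order constructs driven by one
#' second-order health-belief factor, plus a structural BAR -> CTA path --
#' from raw item responses or from a sample covariance matrix, by minimizing
#' the normal-theory discrepancy [ml_discrepancy()] with an analytic-gradient
#' quasi-Newton optimizer (BFGS) run from several jittered starting points.
#'
#' Identification: the second-order factor variance is fixed to 1 and one
#' marker loading per first-order factor is fixed to 1; variances are
#' log-parameterized, which keeps every estimated variance positive
#' (inadmissible solutions surface as a `heywood` flag when an estimate sits
#' essentially on the zero boundary or a standardized coefficient leaves
#' \[-1, 1\]). The fully standardized solution, total effects and the fit
#' index battery are computed on the way out. Rows with any missing item are
#' removed (listwise deletion) before the covariance is formed; 1-5 Likert
#' scores are treated as continuous, as is conventional for classical ML
#' factor analysis of such questionnaires.
#'
#' The latent-sign indeterminacy (flipping the second-order factor negates
#' every second-order coefficient) is resolved by requiring the sum of
#' standardized second-order coefficients to be positive.
#'
#' @param data either an item-response data frame (metadata columns are
#'   ignored; item columns found by name or, failing that, all numeric
#'   columns) or a `p x p` sample covariance matrix, in which case `n` must
#'   be supplied.
#' @param spec an [hbm_model_spec()]; defaults to [hbm_default_spec()].
#' @param n sample size when `data` is a covariance matrix.
#' @param n_starts number of optimizer starts (first from data-driven
#'   values, the rest jittered).
#' @param start optional explicit starting free-parameter vector.
#' @param grad_tol gradient-norm convergence criterion.
#' @param seed seed for start-value jitter (local; the caller's RNG state is
#'   untouched).
#'
#' @return An object of class `"hbm_cfa"`; see [coef.hbm_cfa()],
#'   [summary.hbm_cfa()], [total_effects()], [fit_indices()].
#' @export
#' @examples
#' cfg <- hbm_benchmark_config(n_pre = 150, n_post = 200, seed = 3)
#' study <- simulate_hbm_study(cfg)
#' fit <- hbm_cfa(study$post, n_starts = 2)
#' fit
hbm_cfa <- function(data, spec = hbm_default_spec(), n = NULL,
                    n_starts = 5L, start = NULL, grad_tol = 1e-6,
                    seed = 1L) {
  if (is.matrix(data) && nrow(data) == ncol(data) &&
      isTRUE(all.equal(unname(data), unname(t(data)), tolerance = 1e-8))) {
    if (is.null(n)) stop("supply n when fitting a covariance matrix")
    S <- (data + t(data)) / 2
    n_used <- as.integer(n)
  } else {
    m <- extract_item_matrix(data, spec)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < ncol(m) + 1)
      stop("need more complete rows than items after listwise deletion")
    S <- stats::cov(m)
    n_used <- nrow(m)
  }
  p <- spec$n_items
  if (nrow(S) != p) stop("covariance dimension does not match the model spec")
  cS <- tryCatch(chol(S), error = function(e)
    stop("sample covariance is not positive definite"))
  logdetS <- 2 * sum(log(diag(cS)))
  tmpl <- par_template(spec)

  # memoize value+gradient so optim's fn/gr pair costs one evaluation
  cache <- new.env(parent = emptyenv())
  evalboth <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- fml_objective(par, S, spec, tmpl, logdetS)
    cache$par <- par; cache$res <- res
    res
  }
  fn <- function(par) evalboth(par)$value
  gr <- function(par) evalboth(par)$gradient

  starts <- if (!is.null(start)) list(start) else
    make_starts(S, spec, tmpl, n_starts, seed)
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, fn, gr, method = "BFGS",
                        control = list(maxit = 1000L, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # polish until the gradient criterion is met (BFGS restarts reset the
  # Hessian approximation, which usually drops the residual gradient fast)
  rounds <- 0L
  gnorm <- sqrt(sum(gr(best$par)^2))
  while (gnorm > grad_tol && rounds < 10L) {
    opt <- stats::optim(best$par, fn, gr, method = "BFGS",
                        control = list(maxit = 1000L, reltol = 1e-15))
    if (opt$value <= best$value) best <- opt
    gnorm <- sqrt(sum(gr(best$par)^2))
    rounds <- rounds + 1L
  }

  pl <- par_to_list(best$par, spec, tmpl)
  # resolve the second-order sign indeterminacy
  if (spec$second_order && sum(pl$gamma) < 0) {
    pl$gamma <- -pl$gamma
    i <- tmpl$n_load
    best$par[i + seq_len(spec$n_factors)] <- pl$gamma
  }
  sigma <- implied_covariance(pl, spec)
  f_min <- ml_discrepancy(S, sigma)
  chi_square <- (n_used - 1) * f_min
  df <- p * (p + 1) / 2 - tmpl$n_par
  nullm <- null_model(S, n_used)

  fit <- structure(
    list(spec = spec,
         lambda = stats::setNames(pl$lambda, spec$items),
         gamma = if (spec$second_order)
           stats::setNames(pl$gamma, spec$factors) else NULL,
         beta = if (spec$second_order) pl$beta else NULL,
         B = if (spec$second_order)
           structural_matrix(spec, pl$beta) else NULL,
         psi = if (spec$second_order)
           stats::setNames(pl$psi, spec$factors) else NULL,
         phi = factor_covariance(pl, spec),
         theta = stats::setNames(pl$theta, spec$items),
         S = S, sigma = sigma, n_used = n_used,
         F_min = f_min, chi_square = chi_square, df = df,
         chi_square_null = nullm$chi_square_null,
         df_null = nullm$df_null,
         n_par = tmpl$n_par,
         converged = gnorm <= grad_tol,
         n_iterations = best$counts[["function"]],
         final_gradient_norm = gnorm,
         par = best$par),
    class = "hbm_cfa")
  fit <- standardize(fit)
  fit$total_effects <- if (spec$second_order) total_effects(fit) else NULL
  fit$fit_indices <- if (df > 0)
    fit_indices(chi_square, df, n_used,
                nullm$chi_square_null, nullm$df_null, S, sigma)
  else NULL   # saturated (just-identified) model: indices undefined
  fit$heywood <- any(pl$theta < 1e-6) ||
    (spec$second_order && any(pl$psi < 1e-6)) ||
    any(abs(fit$std$lambda) > 1 + 1e-8) ||
    (spec$second_order && any(abs(fit$std$gamma) > 1 + 1e-8))
  fit
}

# pull the item score matrix out of a study data frame, in spec item order
extract_item_matrix <- function(data, spec) {
  stopifnot(is.data.frame(data) || is.matrix(data))
  data <- as.data.frame(data)
  if (all(spec$items %in% names(data))) {
    m <- data[spec$items]
  } else {
    num <- vapply(data, is.numeric, logical(1)) &
      !(names(data) %in% c("age"))
    m <- data[num]
    if (ncol(m) != spec$n_items)
      stop(sprintf("expected %d item columns, found %d; missing: %s",
                   spec$n_items, ncol(m),
                   paste(utils::head(setdiff(spec$items, names(data)), 3),
                         collapse = ", ")))
  }
  as.matrix(m)
}

# data-driven starting values plus jittered replicates
make_starts <- function(S, spec, tmpl, n_starts, seed) {
  nf <- spec$n_factors
  p <- spec$n_items
  mvar <- diag(S)[spec$markers]           # marker variances
  fvar <- 0.5 * mvar                      # rough factor variances
  lam0 <- numeric(p)
  for (i in seq_len(p)) {
    k <- spec$factor_index[i]
    m <- spec$markers[k]
    lam0[i] <- if (i == m) 1 else
      max(min(S[i, m] / fvar[k], 3), -3)
  }
  if (spec$second_order) {
    gam0 <- 0.5 * sqrt(fvar)
    psi0 <- pmax(fvar - gam0^2, 0.05 * fvar)
    base <- c(lam0[tmpl$free_load], gam0,
              rep(0, length(spec$structural_paths)),
              log(psi0), log(pmax(0.5 * diag(S), 1e-3)))
  } else {
    Lc <- diag(sqrt(fvar), nf)
    parphi <- Lc[lower.tri(Lc, diag = TRUE)]
    dpos <- which(diag(TRUE, nf)[lower.tri(diag(TRUE, nf), diag = TRUE)])
    parphi[dpos] <- log(parphi[dpos])
    base <- c(lam0[tmpl$free_load], parphi,
              log(pmax(0.5 * diag(S), 1e-3)))
  }
  if (n_starts <= 1L) return(list(base))
  withr_seed(seed, {
    c(list(base), lapply(seq_len(n_starts - 1L), function(j)
      base + stats::rnorm(length(base), sd = 0.1 * pmax(abs(base), 0.5))))
  })
}

#' Fully standardized solution of a fitted model
#'
#' Converts the raw (marker-identified) estimates to the fully standardized
#' metric: loadings are multiplied by the implied factor SD and divided by
#' the implied item SD; second-order coefficients are divided by the factor
#' SD (the second-order factor already has unit variance); a structural
#' coefficient from factor b to factor c is multiplied by `sd(b)/sd(c)`.
#' Residual and disturbance variances become proportions of total variance.
#' Idempotent: recomputing on an already-standardized fit changes nothing.
#'
#' @param fit an `"hbm_cfa"` object.
#' @return The fit with its `$std` component (re)computed.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "hbm_cfa"))
  spec <- fit$spec
  d_f <- sqrt(diag(fit$phi))
  d_y <- sqrt(diag(fit$sigma))
  std <- list(
    lambda = stats::setNames(
      fit$lambda * d_f[spec$factor_index] / d_y, spec$items),
    theta = stats::setNames(fit$theta / d_y^2, spec$items),
    phi_cor = stats::cov2cor(fit$phi)
  )
  if (spec$second_order) {
    std$gamma <- stats::setNames(fit$gamma / d_f, spec$factors)
    std$B <- fit$B * (d_f[col(fit$B)] / d_f[row(fit$B)]) *
      (fit$B != 0)
    std$beta <- vapply(seq_along(spec$structural_paths), function(k) {
      pth <- spec$structural_paths[[k]]
      std$B[pth[2], pth[1]]
    }, numeric(1))
    std$psi <- stats::setNames(fit$psi / d_f^2, spec$factors)
  }
  fit$std <- std
  fit
}

#' Total effects of the second-order factor on each item
#'
#' The standardized total effect of the second-order (health-belief) factor
#' on item i is `W_i = lambda*_i * TE*(HB -> F(k(i)))`, where the
#' factor-level total effects solve `(I - B*) TE* = gamma*`, accumulating
#' the direct second-order route and any structurally mediated routes (for
#' the default model, `TE*(HB -> CTA) = gamma*_CTA + beta* * gamma*_BAR`).
#' This 22-element vector is the CFAWS weight vector.
#'
#' @param fit a converged, second-order `"hbm_cfa"` fit.
#' @return Named numeric vector of per-item total effects.
#' @export
#' @seealso [cfaws_score()]
total_effects <- function(fit) {
  stopifnot(inherits(fit, "hbm_cfa"))
  spec <- fit$spec
  if (!spec$second_order)
    stop("total effects require a second-order model")
  if (is.null(fit$std)) fit <- standardize(fit)
  te_factor <- as.numeric(
    solve(diag(spec$n_factors) - fit$std$B, unname(fit$std$gamma)))
  stats::setNames(unname(fit$std$lambda) * te_factor[spec$factor_index],
                  spec$items)
}
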
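benchmark_continuous_table <- function(n, seed) {
  cfg <- hbm_benchmark_config(response_scale = "continuous", seed = seed)
  simulate_hbm_cohort(cfg, "post", n, 0, seed = seed)
}

test_that("implied covariance reduces to known closed forms", {
  spec3 <- hbm_model_spec(c("F1", "F1", "F1"), second_order = FALSE)
  lam <- c(0.6, 0.7, 0.8)
  sig <- implied_covariance(
    list(lambda = lam, theta = 1 - lam^2, phi = matrix(1, 1, 1)), spec3)
  expect_equal(sig[1, 2], 0.42)
  expect_equal(sig[1, 3], 0.48)
  expect_equal(sig[2, 3], 0.56)
  expect_equal(unname(diag(sig)), rep(1, 3))

  # zero loadings leave only the residual diagonal
  sig0 <- implied_covariance(
    list(lambda = rep(0, 3), theta = c(1, 2, 3), phi = matrix(1, 1, 1)),
    spec3)
  expect_equal(sig0, diag(c(1, 2, 3), 3), ignore_attr = TRUE)

  # the benchmark configuration is exactly standardized
  cfg <- hbm_benchmark_config()
  sigb <- implied_covariance(
    list(lambda = cfg$lambda, gamma = cfg$gamma, beta = cfg$beta,
         psi = unname(cfg$psi), theta = cfg$theta), cfg$spec)
  expect_lt(max(abs(diag(sigb) - 1)), 1e-10)
})

test_that("ML discrepancy has its textbook values and self-consistency", {
  S <- diag(2)
  expect_equal(ml_discrepancy(S, S), 0)
  expect_equal(ml_discrepancy(2 * diag(2), diag(2)), 2 - log(4))
  expect_error(ml_discrepancy(matrix(c(1, 2, 2, 1), 2), diag(2)),
               "positive definite")

  # determinant-identity route vs eigenvalue route agree to 1e-10
  inst <- random_cfa_instance(7)
  f1 <- ml_discrepancy(inst$S, inst$sigma)
  ev <- eigen(solve(inst$sigma) %*% inst$S, only.values = TRUE)$values
  f2 <- sum(Re(ev) - log(Re(ev))) - nrow(inst$S)
  expect_gt(f1, 0)
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("analytic gradient matches finite differences in both modes", {
  skip_if_not_installed("hbmscore")
  for (mode in c("second_order", "correlated")) {
    if (mode == "second_order") {
      spec <- hbm_default_spec()
      tbl <- benchmark_continuous_table(500, seed = 61)
      S <- cov(as.matrix(tbl[, -(1:4)]))
    } else {
      inst <- random_cfa_instance(77)
      spec <- spec_from_fmap(inst$fmap)
      S <- inst$S
    }
    tmpl <- hbmscore:::par_template(spec)
    logdetS <- as.numeric(determinant(S)$modulus)
    par <- hbmscore:::make_starts(S, spec, tmpl, 1, 1)[[1]]
    par <- par + seq(-0.04, 0.04, length.out = length(par))  # off-optimum
    ob <- hbmscore:::fml_objective(par, S, spec, tmpl, logdetS)
    fd <- vapply(seq_along(par), function(i) {
      h <- 1e-6 * max(1, abs(par[i]))
      e <- par; e[i] <- e[i] + h
      (hbmscore:::fml_objective(e, S, spec, tmpl, logdetS,
                                gradient = FALSE)$value - ob$value) / h
    }, numeric(1))
    expect_equal(ob$gradient, fd, tolerance = 1e-4)
  }
})

test_that("a just-identified one-factor model hits the closed-form solution", {
  set.seed(NULL)
  inst_sigma <- {
    lam <- c(0.75, 0.6, 0.85)
    L <- matrix(lam, 3, 1)
    L %*% t(L) + diag(1 - lam^2, 3)
  }
  S <- cov(draw_mvn(800, inst_sigma, seed = 99))
  spec <- hbm_model_spec(c("F1", "F1", "F1"), second_order = FALSE)
  fit <- hbm_cfa(S, spec = spec, n = 800)
  r <- cov2cor(S)
  closed <- c(sqrt(r[1, 2] * r[1, 3] / r[2, 3]),
              sqrt(r[1, 2] * r[2, 3] / r[1, 3]),
              sqrt(r[1, 3] * r[2, 3] / r[1, 2]))
  expect_equal(unname(abs(fit$std$lambda)), closed, tolerance = 1e-6)
  expect_lt(fit$F_min, 1e-10)
  expect_equal(fit$df, 0)
})

test_that("fitted estimates ignore location shifts and respond only to covariance", {
  tbl <- benchmark_continuous_table(800, seed = 17)
  fit1 <- hbm_cfa(tbl, n_starts = 2)
  shifted <- tbl
  shifted[, -(1:4)] <- shifted[, -(1:4)] + 3.7
  fit2 <- hbm_cfa(shifted, n_starts = 2)
  expect_equal(fit1$std$lambda, fit2$std$lambda, tolerance = 1e-7)
  expect_equal(fit1$chi_square, fit2$chi_square, tolerance = 1e-6)
})

test_that("standardized solution is scale-equivariant and idempotent", {
  tbl <- benchmark_continuous_table(800, seed = 23)
  fit1 <- hbm_cfa(tbl, n_starts = 2)
  rescaled <- tbl
  rescaled$item_07 <- rescaled$item_07 * 10
  fit2 <- hbm_cfa(rescaled, n_starts = 2)
  expect_equal(fit1$std$lambda, fit2$std$lambda, tolerance = 1e-6)
  expect_equal(fit1$std$gamma, fit2$std$gamma, tolerance = 1e-6)
  expect_equal(fit1$std$beta, fit2$std$beta, tolerance = 1e-6)
  # raw loadings differ (marker metric), the standardized ones do not
  expect_gt(abs(fit2$lambda["item_07"] / fit1$lambda["item_07"]), 5)
  # idempotence
  fit3 <- standardize(fit1)
  expect_identical(fit3$std, standardize(fit3)$std)
})

test_that("solutions are invariant to starting-value jitter", {
  tbl <- benchmark_continuous_table(1000, seed = 29)
  fit1 <- hbm_cfa(tbl, n_starts = 3, seed = 1)
  fit2 <- hbm_cfa(tbl, n_starts = 3, seed = 2024)
  expect_equal(fit1$std$lambda, fit2$std$lambda, tolerance = 1e-6)
  expect_equal(fit1$std$gamma, fit2$std$gamma, tolerance = 1e-6)
  expect_true(fit1$converged && fit2$converged)
  expect_lt(fit1$final_gradient_norm, 1e-6)
})

test_that("degrees of freedom follow the free-parameter count", {
  tbl <- benchmark_continuous_table(600, seed = 41)
  fit <- hbm_cfa(tbl, n_starts = 1)
  # 253 moments; 17 free loadings + 5 gamma + 1 beta + 5 psi + 22 theta
  expect_equal(fit$n_par, 50)
  expect_equal(fit$df, 22 * 23 / 2 - 50)
})

test_that("freeing the structural path cannot worsen the discrepancy", {
  tbl <- benchmark_continuous_table(900, seed = 43)
  spec_full <- hbm_default_spec()
  spec_nopath <- hbm_model_spec(spec_full$item_factor_map,
                                factors = spec_full$factors,
                                structural_paths = list())
  f_full <- hbm_cfa(tbl, spec_full, n_starts = 2)
  f_nopath <- hbm_cfa(tbl, spec_nopath, n_starts = 2)
  expect_lte(f_full$F_min, f_nopath$F_min + 1e-10)
  expect_equal(f_nopath$df, f_full$df + 1)
})

test_that("null model: diagonal S gives zero, df is p(p-1)/2, and it nests every fit", {
  expect_equal(null_model(diag(c(1, 2, 3)), 100)$chi_square_null, 0)
  expect_equal(null_model(diag(22), 100)$df_null, 231)
  tbl <- benchmark_continuous_table(700, seed = 47)
  fit <- hbm_cfa(tbl, n_starts = 1)
  expect_gte(fit$chi_square_null, fit$chi_square)
})

test_that("total effects compose the direct and mediated routes", {
  # published-solution arithmetic: TE(HB -> CTA) = 0.60 + 0.35 * (-0.18)
  expect_equal(0.60 + 0.35 * (-0.18), 0.537)
  tbl <- benchmark_continuous_table(2000, seed = 53)
  fit <- hbm_cfa(tbl, n_starts = 2)
  te <- total_effects(fit)
  te_factor <- solve(diag(5) - fit$std$B, unname(fit$std$gamma))
  expect_equal(unname(te),
               unname(unname(fit$std$lambda) *
                        te_factor[fit$spec$factor_index]))
  # weights carry the sign of lambda* x factor total effect
  expect_true(all(sign(te) ==
                    sign(unname(fit$std$lambda) *
                           te_factor[fit$spec$factor_index])))

  # without a structural path the weights are lambda* x gamma*
  spec_nopath <- hbm_model_spec(fit$spec$item_factor_map,
                                factors = fit$spec$factors,
                                structural_paths = list())
  f0 <- hbm_cfa(tbl, spec_nopath, n_starts = 2)
  expect_equal(unname(total_effects(f0)),
               unname(f0$std$lambda) *
                 unname(f0$std$gamma)[f0$spec$factor_index],
               tolerance = 1e-12)
})

test_that("second-order sign indeterminacy is resolved consistently", {
  tbl <- benchmark_continuous_table(800, seed = 59)
  fit <- hbm_cfa(tbl, n_starts = 3)
  expect_gt(sum(fit$std$gamma), 0)
  expect_lt(fit$std$gamma["BAR"], 0)   # barrier factor keeps its sign
})

test_that("fitting a covariance matrix requires n and matches the data route", {
  tbl <- benchmark_continuous_table(900, seed = 67)
  m <- as.matrix(tbl[, -(1:4)])
  expect_error(hbm_cfa(cov(m)), "supply n")
  f_cov <- hbm_cfa(cov(m), n = nrow(m), n_starts = 2)
  f_dat <- hbm_cfa(tbl, n_starts = 2)
  expect_equal(f_cov$std$lambda, f_dat$std$lambda, tolerance = 1e-7)
  expect_equal(f_cov$chi_square, f_dat$chi_square, tolerance = 1e-5)
})

test_that("listwise deletion happens before the covariance is formed", {
  cfg <- hbm_benchmark_config(response_scale = "continuous", seed = 71)
  tbl <- simulate_hbm_cohort(cfg, "post", 1500, 0, seed = 71)
  tbl_na <- inject_missing(tbl, 0.02, seed = 72)
  fit <- hbm_cfa(tbl_na, n_starts = 1)
  expect_equal(fit$n_used, nrow(listwise_delete(tbl_na)))
  expect_lt(fit$n_used, 1500L)
})

test_that("non-PD input and schema mismatches raise informative errors", {
  bad <- matrix(1, 22, 22)
  expect_error(hbm_cfa(bad, n = 100), "positive definite")
  tbl <- benchmark_continuous_table(100, seed = 73)
  expect_error(hbm_cfa(tbl[, -5]), "item_01|expected 22")
})
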
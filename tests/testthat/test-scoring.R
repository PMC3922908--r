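# the published per-item total-effect (weight) column
published_weights <- c(0.57, 0.57, 0.66, 0.66, 0.63,
                       0.73, 0.74, 0.71, 0.61,
                       0.72, 0.78, 0.74, 0.79, 0.75,
                       -0.14, -0.14, -0.16, -0.16,
                       0.48, 0.50, 0.53, 0.54)

row_with <- function(values) {
  tbl <- data.frame(respondent_id = "r1", cohort = "pre", age = 16,
                    gender = "male")
  cbind(tbl, as.data.frame(matrix(values, nrow = length(values) %/% 22,
                                  ncol = 22,
                                  dimnames = list(NULL,
                                                  sprintf("item_%02d", 1:22)))))
}

test_that("listwise deletion removes exactly the incomplete rows, in order", {
  cfg <- hbm_benchmark_config(seed = 11)
  tbl <- simulate_hbm_cohort(cfg, "pre", 30, 0, seed = 11)
  expect_identical(listwise_delete(tbl), tbl)
  tbl$item_05[c(3, 17)] <- NA
  out <- listwise_delete(tbl)
  expect_equal(nrow(out), 28L)
  expect_identical(out$respondent_id, tbl$respondent_id[-c(3, 17)])
})

test_that("CFAWS weighted score reproduces hand-computed values", {
  all3 <- row_with(rep(3, 22))
  # all items 3 with the published weights: 3 x 11.11 = 33.33
  expect_equal(cfaws_score(all3, published_weights), 33.33)
  expect_equal(cfaws_score(all3, rep(0, 22)), 0)
  unit7 <- replace(rep(0, 22), 7, 1)
  some_row <- row_with(c(2, 4, 1, 5, 3, 4, 5, 2, 3, 1, 4, 2, 5, 3, 1, 2, 4,
                         3, 5, 2, 1, 4))
  expect_equal(cfaws_score(some_row, unit7), some_row$item_07)
  # missing item propagates to NA rather than a silently partial sum
  na_row <- all3; na_row$item_12 <- NA
  expect_true(is.na(cfaws_score(na_row, published_weights)))
})

test_that("simple sum score uses the negative barrier convention with known bounds", {
  expect_equal(sss_score(row_with(rep(3, 22))), 42)  # 18*3 - 4*3
  expect_equal(sss_score(row_with(rep(5, 22))), 70)  # maximum
  low <- rep(1, 22); low[15:18] <- 5
  expect_equal(sss_score(row_with(low)), -2)         # minimum
})

test_that("CFAWS with unit weights equals SSS without barrier negation", {
  cfg <- hbm_benchmark_config(seed = 13)
  tbl <- simulate_hbm_cohort(cfg, "pre", 100, 0, seed = 13)
  expect_equal(cfaws_score(tbl, rep(1, 22)),
               sss_score(tbl, negate_factors = character(0)))
})

test_that("adding a constant to every weight shifts scores by c times the item sum", {
  cfg <- hbm_benchmark_config(seed = 17)
  tbl <- simulate_hbm_cohort(cfg, "pre", 60, 0, seed = 17)
  w <- published_weights
  cc <- 0.37
  expect_equal(cfaws_score(tbl, w + cc),
               cfaws_score(tbl, w) + cc * cfaws_score(tbl, rep(1, 22)),
               tolerance = 1e-12)
})

test_that("the pooled two-sample t-test matches the textbook computation", {
  cm <- compare_cohorts(c(1, 2, 3), c(4, 5, 6), method = "sss")
  expect_equal(cm$mean_difference, 3)
  expect_equal(cm$t_statistic, 3 / sqrt(1 * (1 / 3 + 1 / 3)),
               tolerance = 1e-10)
  expect_equal(cm$t_statistic, 3.674, tolerance = 1e-3)
  expect_equal(cm$df, 4)
  expect_true(cm$conf_int[1] <= cm$mean_difference &&
                cm$mean_difference <= cm$conf_int[2])
  expect_equal(diff(cm$conf_int) / 2, qt(0.975, 4) * sqrt(2 / 3),
               tolerance = 1e-10)

  # identical cohorts: zero difference, p = 1
  cm0 <- compare_cohorts(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(cm0$mean_difference, 0)
  expect_equal(cm0$p_value, 1)

  # Welch option changes the degrees of freedom under unequal variances
  pre <- draw_mvn(40, matrix(1), seed = 3)[, 1]
  post <- draw_mvn(25, matrix(9), seed = 4)[, 1] + 1
  cw <- compare_cohorts(pre, post, var_equal = FALSE)
  cp <- compare_cohorts(pre, post, var_equal = TRUE)
  expect_lt(cw$df, cp$df)
  expect_equal(cp$df, 63)

  expect_error(compare_cohorts(1, c(1, 2)), "at least 2")
  expect_error(compare_cohorts(c(2, 2, 2), c(3, 3, 3)), "degenerate")
})

test_that("rejection of the null matches closed-form power in continuous mode", {
  # population effect size of the SSS contrast under a latent shift delta
  cfg <- hbm_benchmark_config(response_scale = "continuous", delta = 0.5,
                              n_pre = 120, n_post = 150)
  pl <- list(lambda = cfg$lambda, gamma = cfg$gamma, beta = cfg$beta,
             psi = unname(cfg$psi), theta = cfg$theta)
  sigma <- implied_covariance(pl, cfg$spec)
  a <- ifelse(cfg$spec$factors[cfg$spec$factor_index] == "BAR", -1, 1)
  d <- cfg$delta * sum(a * hbm_total_effect_targets(cfg)) /
    sqrt(as.numeric(t(a) %*% sigma %*% a))
  ncp <- d / sqrt(1 / cfg$n_pre + 1 / cfg$n_post)
  df <- cfg$n_pre + cfg$n_post - 2
  tcrit <- qt(0.975, df)
  power <- 1 - pt(tcrit, df, ncp = ncp) + pt(-tcrit, df, ncp = ncp)

  reps <- 200
  rej <- vapply(seq_len(reps), function(i) {
    st <- simulate_hbm_study(hbm_benchmark_config(
      response_scale = "continuous", delta = 0.5,
      n_pre = 120, n_post = 150, seed = 40000 + i))
    compare_cohorts(sss_score(st$pre), sss_score(st$post))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - power),
            3 * sqrt(power * (1 - power) / reps) + 0.01)
})

test_that("score_study wires weights and methods together", {
  cfg <- hbm_benchmark_config(seed = 19, n_pre = 200, n_post = 250,
                              missing_rate = 0.02)
  study <- simulate_hbm_study(cfg)
  res <- score_study(study, weights = published_weights, method = "both")
  expect_named(res, c("cfaws", "sss"))
  expect_equal(unname(res$sss$n["pre"]),
               nrow(listwise_delete(study$pre)))
  expect_error(score_study(study, method = "cfaws"), "weight")
})
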
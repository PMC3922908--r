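#' Simulate one cohort of item responses
#'
#' Draws `n` respondents from the second-order latent model: the
#' health-belief factor is Normal(`mean_shift`, 1); each first-order factor
#' is its second-order loading times the health-belief factor plus any
#' structural inflow plus a disturbance; each item is its loading times its
#' factor plus measurement error. All variances are calibrated so that at
#' `mean_shift = 0` every latent variable and continuous item has population
#' mean 0 and variance 1. In ordinal mode responses are cut at
#' `config$thresholds` into the categories 1-5.
#'
#' @param config an [hbm_generator_config()].
#' @param cohort_label `"pre"` or `"post"` (stored in the `cohort` column).
#' @param n number of respondents.
#' @param mean_shift latent mean of the health-belief factor, in SD units.
#' @param seed integer seed for this cohort draw.
#'
#' @return A data frame with columns `respondent_id`, `cohort`, `age`,
#'   `gender`, then one column per item (`item_01` ... in Table-order).
#'   Ordinal mode yields integers in 1..5; continuous mode real values.
#' @export
#' @examples
#' cfg <- hbm_benchmark_config(seed = 7)
#' head(simulate_hbm_cohort(cfg, "pre", n = 5, mean_shift = 0, seed = 7))
simulate_hbm_cohort <- function(config, cohort_label, n,
                                mean_shift = 0, seed = config$seed) {
  stopifnot(inherits(config, "hbm_generator_config"), n >= 1)
  spec <- config$spec
  nf <- spec$n_factors
  p <- spec$n_items
  withr_seed(seed, {
    hb <- stats::rnorm(n, mean = mean_shift, sd = 1)
    A <- solve(diag(nf) - structural_matrix(spec, config$beta))
    zeta <- matrix(stats::rnorm(n * nf), n, nf) %*%
      diag(sqrt(unname(config$psi)), nf)
    eta <- (outer(hb, unname(config$gamma)) + zeta) %*% t(A)
    y <- eta[, spec$factor_index, drop = FALSE] %*% diag(config$lambda, p) +
      matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(config$theta), p)
    if (config$response_scale == "ordinal") {
      y <- matrix(
        1L + findInterval(y, config$thresholds),
        n, p
      )
    }
    colnames(y) <- spec$items
    tbl <- data.frame(
      respondent_id = sprintf("%s_%05d", cohort_label, seq_len(n)),
      cohort = cohort_label,
      age = sample(15:18, n, replace = TRUE),
      gender = sample(c("male", "female"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    cbind(tbl, as.data.frame(y))
  })
}

#' Simulate a pre/post intervention study
#'
#' Draws two independent cross-sectional cohorts: the pre cohort at latent
#' health-belief mean 0 and the post cohort shifted upward by
#' `config$delta` SD (the simulated intervention effect). Missing item cells
#' are injected completely at random at `config$missing_rate`.
#'
#' @param config an [hbm_generator_config()].
#' @return A list with elements `pre` and `post`, each an item-response
#'   data frame as returned by [simulate_hbm_cohort()].
#' @export
#' @examples
#' study <- simulate_hbm_study(hbm_benchmark_config(n_pre = 40, n_post = 60,
#'                                                  delta = 0.3, seed = 1))
#' nrow(study$pre); nrow(study$post)
simulate_hbm_study <- function(config) {
  stopifnot(inherits(config, "hbm_generator_config"))
  pre <- simulate_hbm_cohort(config, "pre", config$n_pre,
                             mean_shift = 0, seed = config$seed)
  post <- simulate_hbm_cohort(config, "post", config$n_post,
                              mean_shift = config$delta,
                              seed = config$seed + 1L)
  if (config$missing_rate > 0) {
    pre <- inject_missing(pre, config$missing_rate, seed = config$seed + 2L)
    post <- inject_missing(post, config$missing_rate, seed = config$seed + 3L)
  }
  list(pre = pre, post = post)
}

#' Inject missing-completely-at-random item cells
#'
#' Each item cell is independently set to `NA` with probability `rate`;
#' metadata columns (`respondent_id`, `cohort`, `age`, `gender`) are never
#' touched. Supports testing of listwise deletion.
#'
#' @param table an item-response data frame.
#' @param rate missingness probability in \[0, 1).
#' @param seed integer seed.
#' @return The table with `NA`s injected.
#' @export
inject_missing <- function(table, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(table)
  cols <- item_columns(table)
  withr_seed(seed, {
    m <- as.matrix(table[cols])
    mask <- matrix(stats::runif(length(m)) < rate, nrow(m), ncol(m))
    m[mask] <- NA
    table[cols] <- as.data.frame(m)
    table
  })
}

# run code with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# names of the item score columns of a study table, in order
item_columns <- function(table) {
  cols <- grep("^item_[0-9]+$", names(table), value = TRUE)
  if (length(cols) == 0) stop("no item_* columns found in table")
  cols[order(as.integer(sub("item_", "", cols)))]
}
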
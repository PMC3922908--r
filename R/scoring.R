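#' Listwise deletion
#'
#' Removes every respondent row containing at least one missing item score;
#' row order is preserved and metadata columns are kept.
#'
#' @param table an item-response data frame.
#' @return The table restricted to complete item rows.
#' @export
listwise_delete <- function(table) {
  cols <- item_columns(table)
  table[stats::complete.cases(table[cols]), , drop = FALSE]
}

#' CFA-weighted health-belief score (CFAWS)
#'
#' The weighted score `WHBS = sum_n W_n * IS_n`, where `IS_n` are the raw
#' 1-5 item scores and `W_n` the per-item weights -- the standardized total
#' effects of the health-belief factor produced by [total_effects()].
#' Barrier items enter with their raw scores; their negativity is carried by
#' the weights themselves.
#'
#' @param table an item-response data frame (or a single row).
#' @param weights numeric vector of 22 finite weights, or an `"hbm_cfa"` fit
#'   from which [total_effects()] is taken.
#' @return Numeric vector of per-respondent weighted scores (`NA` for rows
#'   with any missing item).
#' @export
#' @examples
#' cfg <- hbm_benchmark_config(n_pre = 30, n_post = 30, seed = 2)
#' tbl <- simulate_hbm_study(cfg)$post
#' head(cfaws_score(tbl, hbm_total_effect_targets(cfg)))
cfaws_score <- function(table, weights) {
  if (inherits(weights, "hbm_cfa")) weights <- total_effects(weights)
  weights <- as.numeric(weights)
  m <- extract_item_matrix(table, spec_for_width(length(weights)))
  if (ncol(m) != length(weights))
    stop("weight vector length does not match the number of items")
  if (any(!is.finite(weights))) stop("weights must be finite")
  as.numeric(m %*% weights)
}

#' Simple sum health-belief score (SSS)
#'
#' The unweighted score `HBS = sum IS_n`, with barrier items entered
#' negatively (their raw 1-5 score is subtracted): positively keyed
#' constructs add to the score, perceived barriers reduce it. With the
#' default 22-item structure the score ranges from -2 (all positive items
#' 1, all barrier items 5) to 70 (all items 5).
#'
#' @param table an item-response data frame.
#' @param spec an [hbm_model_spec()]; the `negate_factors` entries name the
#'   subscales entered negatively.
#' @param negate_factors factors whose items are subtracted; default `"BAR"`.
#' @return Numeric vector of per-respondent sum scores (`NA` for incomplete
#'   rows).
#' @export
sss_score <- function(table, spec = hbm_default_spec(),
                      negate_factors = "BAR") {
  m <- extract_item_matrix(table, spec)
  signs <- ifelse(spec$factors[spec$factor_index] %in% negate_factors, -1, 1)
  as.numeric(m %*% signs)
}

spec_for_width <- function(p) {
  if (p == 22L) return(hbm_default_spec())
  # generic placeholder spec so extract_item_matrix can locate item columns
  hbm_model_spec(stats::setNames(rep(c("F1", "F2"), length.out = p),
                                 sprintf("item_%02d", seq_len(p))),
                 second_order = FALSE)
}

#' Compare pre- and post-intervention score distributions
#'
#' Two-independent-sample t-test of per-respondent health-belief scores,
#' pooled-variance by default with a Welch option. The reported difference
#' is `mean(post) - mean(pre)` with its 95% confidence interval.
#'
#' @param pre_scores,post_scores numeric score vectors (missing values
#'   dropped; at least 2 per cohort).
#' @param method label stored in the result (`"cfaws"`, `"sss"`, ...).
#' @param var_equal pooled-variance test if `TRUE` (default), Welch if
#'   `FALSE`.
#' @param conf_level confidence level of the interval.
#' @return A list of class `"hbm_score_comparison"`: per-cohort `n`, `mean`,
#'   `sd`; `mean_difference`; `conf_int`; `t_statistic`; `df`; `p_value`.
#' @export
#' @examples
#' compare_cohorts(c(1, 2, 3), c(4, 5, 6), method = "sss")
compare_cohorts <- function(pre_scores, post_scores, method = "sss",
                            var_equal = TRUE, conf_level = 0.95) {
  pre <- pre_scores[!is.na(pre_scores)]
  post <- post_scores[!is.na(post_scores)]
  if (length(pre) < 2 || length(post) < 2)
    stop("need at least 2 scores per cohort")
  if (stats::sd(pre) == 0 && stats::sd(post) == 0)
    stop("both cohorts are degenerate (zero variance)")
  tt <- stats::t.test(post, pre, var.equal = var_equal,
                      conf.level = conf_level)
  structure(
    list(method = method,
         var_equal = var_equal,
         n = c(pre = length(pre), post = length(post)),
         mean = c(pre = mean(pre), post = mean(post)),
         sd = c(pre = stats::sd(pre), post = stats::sd(post)),
         mean_difference = unname(mean(post) - mean(pre)),
         conf_int = unname(sort(tt$conf.int)),
         conf_level = conf_level,
         t_statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value),
    class = "hbm_score_comparison")
}

#' @export
print.hbm_score_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Two-sample t-test (%s), %s method\n",
              if (x$var_equal) "pooled variance" else "Welch",
              toupper(x$method)))
  cat(sprintf("  pre : n = %d, mean = %.*f, sd = %.*f\n",
              x$n["pre"], digits, x$mean["pre"], digits, x$sd["pre"]))
  cat(sprintf("  post: n = %d, mean = %.*f, sd = %.*f\n",
              x$n["post"], digits, x$mean["post"], digits, x$sd["post"]))
  cat(sprintf("  difference (post - pre) = %.*f, %d%% CI (%.*f, %.*f)\n",
              digits, x$mean_difference, round(100 * x$conf_level),
              digits, x$conf_int[1], digits, x$conf_int[2]))
  cat(sprintf("  t = %.*f, df = %.4g, p = %.4g\n",
              digits, x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Score a study and compare cohorts
#'
#' Convenience wrapper: listwise-deletes both cohort tables, computes the
#' requested scores and runs the pre/post comparison.
#'
#' @param study a list with `pre` and `post` item-response tables.
#' @param weights CFAWS weight vector or `"hbm_cfa"` fit (required when
#'   `method` includes `"cfaws"`).
#' @param method `"cfaws"`, `"sss"` or `"both"`.
#' @param var_equal pooled (`TRUE`) or Welch (`FALSE`) t-test.
#' @param spec an [hbm_model_spec()].
#' @return A named list of `"hbm_score_comparison"` objects.
#' @export
score_study <- function(study, weights = NULL,
                        method = c("both", "cfaws", "sss"),
                        var_equal = TRUE, spec = hbm_default_spec()) {
  method <- match.arg(method)
  pre <- listwise_delete(study$pre)
  post <- listwise_delete(study$post)
  out <- list()
  if (method %in% c("cfaws", "both")) {
    if (is.null(weights)) stop("CFAWS scoring requires a weight vector")
    out$cfaws <- compare_cohorts(cfaws_score(pre, weights),
                                 cfaws_score(post, weights),
                                 method = "cfaws", var_equal = var_equal)
  }
  if (method %in% c("sss", "both")) {
    out$sss <- compare_cohorts(sss_score(pre, spec), sss_score(post, spec),
                               method = "sss", var_equal = var_equal)
  }
  out
}
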
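#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale,
#' `alpha = k/(k - 1) * (1 - sum(var(item_i)) / var(total))`, with
#' unbiased (n - 1 denominator) sample variances. Rows with any missing
#' item are dropped first.
#'
#' @param item_matrix numeric matrix or data frame, respondents in rows and
#'   the scale's items in columns (at least 2 items, 3 complete rows).
#' @return The alpha coefficient (a scalar, at most 1; can be negative for
#'   scales with negatively related items).
#' @export
#' @examples
#' x <- matrix(rnorm(300), 100, 3)
#' cronbach_alpha(cbind(x, x[, 1]))  # duplicated item raises alpha
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (ncol(m) < 2) stop("alpha needs at least 2 items")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("alpha needs at least 3 complete rows")
  k <- ncol(m)
  v_total <- stats::var(rowSums(m))
  if (v_total <= 0) stop("total-score variance is zero")
  item_vars <- apply(m, 2, stats::var)
  k / (k - 1) * (1 - sum(item_vars) / v_total)
}

#' Reliability report for a health-belief study table
#'
#' Cronbach's alpha for each of the five HBM subscales and for the full
#' 22-item scale, each computed after listwise deletion within the items
#' involved. Because the ambiguity of a single "average reliability" is
#' real -- it may denote the full-scale alpha or the mean of the subscale
#' alphas -- both are reported, clearly labelled. Barrier items enter with
#' their raw 1-5 scores: alpha is invariant to reflecting a consistently
#' keyed subscale, so no sign convention is needed within BAR.
#'
#' @param table an item-response data frame (see [simulate_hbm_study()]).
#' @param spec an [hbm_model_spec()].
#' @return A list of class `"hbm_reliability"`: `alpha` (named per-factor
#'   vector), `alpha_total`, `alpha_subscale_mean`, `n_used` (per
#'   computation) and `k` (items per scale).
#' @export
hbm_reliability <- function(table, spec = hbm_default_spec()) {
  m <- extract_item_matrix(table, spec)
  per_factor <- lapply(spec$factors, function(f) {
    cols <- which(spec$factor_index == match(f, spec$factors))
    sub <- m[, cols, drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    list(alpha = cronbach_alpha(sub), n = nrow(sub), k = ncol(sub))
  })
  total <- m[stats::complete.cases(m), , drop = FALSE]
  alpha <- stats::setNames(vapply(per_factor, `[[`, numeric(1), "alpha"),
                           spec$factors)
  structure(
    list(alpha = alpha,
         alpha_total = cronbach_alpha(total),
         alpha_subscale_mean = mean(alpha),
         n_used = c(stats::setNames(
           vapply(per_factor, `[[`, numeric(1), "n"), spec$factors),
           total = nrow(total)),
         k = stats::setNames(vapply(per_factor, `[[`, numeric(1), "k"),
                             spec$factors)),
    class = "hbm_reliability")
}

#' @export
print.hbm_reliability <- function(x, digits = 3, ...) {
  cat("Cronbach's alpha\n")
  for (f in names(x$alpha))
    cat(sprintf("  %-4s (k = %d, n = %d): %.*f\n", f, as.integer(x$k[f]),
                as.integer(x$n_used[f]), digits, x$alpha[f]))
  cat(sprintf("  full scale (n = %d): %.*f\n",
              as.integer(x$n_used["total"]), digits, x$alpha_total))
  cat(sprintf("  mean of subscale alphas: %.*f\n", digits,
              x$alpha_subscale_mean))
  invisible(x)
}
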
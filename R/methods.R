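#' @export
print.hbm_cfa <- function(x, digits = 3, ...) {
  cat("Second-order confirmatory factor model",
      if (!x$spec$second_order) "(correlated first-order factors)", "\n")
  cat(sprintf("  %d items, %d factors, n = %d (after listwise deletion)\n",
              x$spec$n_items, x$spec$n_factors, x$n_used))
  if (is.null(x$fit_indices))
    cat(sprintf("  chi-square = %.2f on %d df (saturated model)\n",
                x$chi_square, as.integer(x$df)))
  else
    cat(sprintf("  chi-square = %.2f on %d df; RMSEA = %.3f; CFI = %.3f\n",
                x$chi_square, as.integer(x$df), x$fit_indices$rmsea,
                x$fit_indices$cfi))
  if (x$spec$second_order) {
    cat("  standardized second-order coefficients:\n    ")
    cat(paste(sprintf("%s = %.2f", names(x$std$gamma), x$std$gamma),
              collapse = ", "), "\n")
    for (k in seq_along(x$spec$structural_paths)) {
      pth <- x$spec$structural_paths[[k]]
      cat(sprintf("  standardized %s -> %s = %.2f\n",
                  pth[1], pth[2], x$std$beta[k]))
    }
  }
  if (!x$converged)
    cat("  WARNING: optimizer did not meet the gradient criterion\n")
  if (x$heywood)
    cat("  WARNING: solution is boundary-adjacent (Heywood flag)\n")
  invisible(x)
}

#' Extract estimated coefficients
#'
#' @param object an `"hbm_cfa"` fit.
#' @param standardized return the fully standardized solution (default) or
#'   the raw marker-identified estimates.
#' @param ... unused.
#' @return Named vector of loadings, second-order coefficients and
#'   structural coefficients.
#' @export
coef.hbm_cfa <- function(object, standardized = TRUE, ...) {
  src <- if (standardized) object$std else object
  out <- stats::setNames(as.numeric(src$lambda),
                         paste0("lambda.", object$spec$items))
  if (object$spec$second_order) {
    out <- c(out, stats::setNames(as.numeric(src$gamma),
                                  paste0("gamma.", object$spec$factors)))
    if (length(object$spec$structural_paths)) {
      bn <- vapply(object$spec$structural_paths,
                   function(p) paste0("beta.", p[1], ".", p[2]), character(1))
      out <- c(out, stats::setNames(as.numeric(src$beta), bn))
    }
  }
  out
}

#' Model-implied covariance of a fitted model
#' @param object an `"hbm_cfa"` fit.
#' @param ... unused.
#' @return The implied covariance matrix at the estimates.
#' @export
fitted.hbm_cfa <- function(object, ...) object$sigma

#' Covariance residuals of a fitted model
#' @param object an `"hbm_cfa"` fit.
#' @param type `"raw"` (`S - Sigma`) or `"correlation"` (difference of the
#'   implied and observed correlation matrices).
#' @param ... unused.
#' @return Residual matrix.
#' @export
residuals.hbm_cfa <- function(object, type = c("raw", "correlation"), ...) {
  type <- match.arg(type)
  if (type == "raw") object$S - object$sigma
  else stats::cov2cor(object$S) - stats::cov2cor(object$sigma)
}

#' @export
summary.hbm_cfa <- function(object, ...) {
  structure(list(fit = object), class = "summary.hbm_cfa")
}

#' @export
print.summary.hbm_cfa <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$fit_indices)) {
    cat("\nFit indices:\n")
    print(f$fit_indices, digits = digits)
  }
  cat("\nStandardized loadings and total effects:\n")
  tab <- data.frame(item = f$spec$items,
                    factor = f$spec$factors[f$spec$factor_index],
                    loading = round(unname(f$std$lambda), digits))
  if (!is.null(f$total_effects))
    tab$total_effect <- round(unname(f$total_effects), digits)
  print(tab, row.names = FALSE)
  cat(sprintf("\nconverged: %s (|grad| = %.2e, %d function evaluations)\n",
              f$converged, f$final_gradient_norm, f$n_iterations))
  invisible(x)
}

#' Simulate item-response tables from a fitted model
#'
#' Draws `nsim` tables of `n` respondents from the fitted standardized
#' solution: the estimated standardized loadings and second-order and
#' structural coefficients are passed back into the latent-model generator.
#' Standardized loadings are capped just inside the unit interval in the
#' rare boundary case.
#'
#' @param object a converged second-order `"hbm_cfa"` fit.
#' @param nsim number of tables.
#' @param seed integer seed.
#' @param n respondents per table.
#' @param response_scale `"ordinal"` or `"continuous"`.
#' @param ... unused.
#' @return A list of `nsim` item-response data frames.
#' @export
simulate.hbm_cfa <- function(object, nsim = 1, seed = 1L,
                             n = object$n_used,
                             response_scale = "ordinal", ...) {
  stopifnot(object$spec$second_order)
  cfg <- hbm_generator_config(
    gamma = pmin(pmax(object$std$gamma, -0.99), 0.99),
    beta = object$std$beta,
    lambda = pmin(pmax(unname(object$std$lambda), -0.99), 0.99),
    n_pre = n, n_post = n,
    response_scale = response_scale,
    seed = as.integer(seed),
    spec = object$spec)
  lapply(seq_len(nsim), function(i)
    simulate_hbm_cohort(cfg, "sim", n, mean_shift = 0,
                        seed = as.integer(seed) + i - 1L))
}

#' Plot a fitted health-belief model
#'
#' Base-graphics dot chart of the standardized loadings (grouped by factor)
#' and, for second-order models, the per-item total effects that form the
#' CFAWS weight vector.
#'
#' @param x an `"hbm_cfa"` fit.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.hbm_cfa <- function(x, ...) {
  spec <- x$spec
  op <- graphics::par(mfrow = if (spec$second_order) c(1, 2) else c(1, 1))
  on.exit(graphics::par(op))
  grp <- factor(spec$factors[spec$factor_index], levels = spec$factors)
  graphics::dotchart(unname(x$std$lambda), labels = spec$items,
                     groups = grp, xlab = "standardized loading",
                     main = "Loadings", ...)
  graphics::abline(v = 0, lty = 3)
  if (spec$second_order) {
    graphics::dotchart(unname(x$total_effects), labels = spec$items,
                       groups = grp, xlab = "total effect (CFAWS weight)",
                       main = "Total effects", ...)
    graphics::abline(v = 0, lty = 3)
  }
  invisible(x)
}
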
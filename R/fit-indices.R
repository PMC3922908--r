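#' SEM fit-index battery
#'
#' Computes the conventional normal-theory fit summaries for a fitted
#' covariance-structure model: RMSEA with a 90% confidence interval, GFI,
#' AGFI, NFI, CFI and IFI. Conventional benchmarks: RMSEA at or below 0.08
#' and comparative indices at or above 0.90 indicate acceptable fit.
#'
#' Definitions used (p = number of items):
#' \itemize{
#'   \item `RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))`; the 90% CI
#'     bounds come from root-finding the noncentrality `ncp` at which the
#'     noncentral chi-square CDF evaluated at `chi2` equals 0.95 (lower
#'     bound) and 0.05 (upper bound), each bound mapped through
#'     `sqrt(ncp / (df (n - 1)))`.
#'   \item `GFI = 1 - tr[(Sigma^-1 S - I)^2] / tr[(Sigma^-1 S)^2]`;
#'     `AGFI = 1 - [p (p + 1) / (2 df)] (1 - GFI)`.
#'   \item `NFI = (chi2_null - chi2) / chi2_null`;
#'     `CFI = 1 - max(chi2 - df, 0) / max(chi2_null - df_null, chi2 - df, 0)`;
#'     `IFI = (chi2_null - chi2) / (chi2_null - df)`.
#' }
#'
#' @param chi_square,df model test statistic and its degrees of freedom.
#' @param n sample size used for the fit.
#' @param chi_square_null,df_null independence-model baseline, see
#'   [null_model()].
#' @param S,sigma sample and model-implied covariance matrices.
#' @return A list of class `"hbm_fit_indices"` with components `rmsea`,
#'   `rmsea_ci_lower`, `rmsea_ci_upper`, `gfi`, `agfi`, `nfi`, `cfi`, `ifi`,
#'   `chi_square`, `df`, `chi_square_null`, `df_null`, `n`.
#' @export
#' @examples
#' S <- diag(3); S[S == 0] <- 0.3
#' nm <- null_model(S, 200)
#' fit_indices(10, 5, 200, nm$chi_square_null, nm$df_null, S, diag(diag(S)))
fit_indices <- function(chi_square, df, n, chi_square_null, df_null,
                        S, sigma) {
  stopifnot(df > 0, n > 1)
  rmsea <- sqrt(max(chi_square - df, 0) / (df * (n - 1)))
  ci <- rmsea_ci(chi_square, df, n)

  W <- solve(sigma, S)                    # Sigma^-1 S
  p <- nrow(S)
  # tr(A^2) = sum(A * t(A)) for square A (A is not symmetric in general)
  R <- W - diag(p)
  gfi <- 1 - sum(R * t(R)) / sum(W * t(W))
  agfi <- 1 - (p * (p + 1) / (2 * df)) * (1 - gfi)

  if (chi_square_null <= 0)
    stop("null-model chi-square is zero; comparative indices undefined")
  nfi <- (chi_square_null - chi_square) / chi_square_null
  cfi <- 1 - max(chi_square - df, 0) /
    max(chi_square_null - df_null, chi_square - df, 0)
  ifi <- (chi_square_null - chi_square) / (chi_square_null - df)

  structure(list(rmsea = rmsea,
                 rmsea_ci_lower = ci[1], rmsea_ci_upper = ci[2],
                 gfi = gfi, agfi = agfi, nfi = nfi, cfi = cfi, ifi = ifi,
                 chi_square = chi_square, df = df,
                 chi_square_null = chi_square_null, df_null = df_null,
                 n = n),
            class = "hbm_fit_indices")
}

# 90% RMSEA confidence interval by root-finding the noncentrality parameter
rmsea_ci <- function(chi_square, df, n, level = 0.90) {
  lo_p <- (1 + level) / 2    # 0.95
  hi_p <- (1 - level) / 2    # 0.05
  find_ncp <- function(target) {
    # pchisq(chi_square, df, ncp) is decreasing in ncp
    if (stats::pchisq(chi_square, df, ncp = 0) < target) return(0)
    upper <- max(chi_square * 2, df * 2, 10)
    while (stats::pchisq(chi_square, df, ncp = upper) > target)
      upper <- upper * 2
    stats::uniroot(function(ncp)
      stats::pchisq(chi_square, df, ncp = ncp) - target,
      lower = 0, upper = upper, tol = 1e-9)$root
  }
  ncp_l <- find_ncp(lo_p)
  ncp_u <- find_ncp(hi_p)
  c(sqrt(ncp_l / (df * (n - 1))), sqrt(ncp_u / (df * (n - 1))))
}

#' @export
print.hbm_fit_indices <- function(x, digits = 3, ...) {
  cat(sprintf("chi-square = %.2f, df = %d (null: %.2f, df = %d), n = %d\n",
              x$chi_square, as.integer(x$df), x$chi_square_null,
              as.integer(x$df_null), as.integer(x$n)))
  cat(sprintf("RMSEA = %.*f (90%% CI %.3f, %.3f)\n", digits, x$rmsea,
              x$rmsea_ci_lower, x$rmsea_ci_upper))
  cat(sprintf("GFI = %.*f  AGFI = %.*f  NFI = %.*f  CFI = %.*f  IFI = %.*f\n",
              digits, x$gfi, digits, x$agfi, digits, x$nfi,
              digits, x$cfi, digits, x$ifi))
  invisible(x)
}
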
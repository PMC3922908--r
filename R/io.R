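#' Read and write item-response study tables
#'
#' Study tables travel as plain CSV with the header
#' `respondent_id,cohort,age,gender,item_01,...,item_22`; missing item
#' scores are empty fields; UTF-8 with LF line endings.
#'
#' @param path file path.
#' @param table an item-response data frame.
#' @param spec an [hbm_model_spec()] used to validate the schema.
#' @return `read_hbm_csv()` returns the validated data frame;
#'   `write_hbm_csv()` returns `path` invisibly.
#' @export
read_hbm_csv <- function(path, spec = hbm_default_spec()) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  meta <- c("respondent_id", "cohort", "age", "gender")
  missing_cols <- setdiff(c(meta, spec$items), names(tbl))
  if (length(missing_cols))
    stop("study CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (it in spec$items) {
    v <- tbl[[it]]
    if (!is.numeric(v))
      stop(sprintf("column %s is not numeric", it))
  }
  tbl[c(meta, spec$items)]
}

#' @rdname read_hbm_csv
#' @export
write_hbm_csv <- function(table, path, spec = hbm_default_spec()) {
  meta <- c("respondent_id", "cohort", "age", "gender")
  stopifnot(all(c(meta, spec$items) %in% names(table)))
  con <- file(path, open = "wb")   # binary mode forces LF on every platform
  on.exit(close(con))
  utils::write.csv(table[c(meta, spec$items)], con, row.names = FALSE,
                   na = "", quote = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a covariance matrix file
#'
#' Plain-text format: a first line `n=<sample size>` followed by a
#' whitespace-separated symmetric matrix, one row per line.
#'
#' @param path file path.
#' @return A list with `S` (matrix) and `n`.
#' @export
read_cov_file <- function(path) {
  lines <- readLines(path)
  if (!grepl("^n=\\d+$", trimws(lines[1])))
    stop("first line of a covariance file must be 'n=<sample size>'")
  n <- as.integer(sub("^n=", "", trimws(lines[1])))
  S <- as.matrix(utils::read.table(text = lines[-1]))
  dimnames(S) <- NULL
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8)
    stop("covariance matrix is not square symmetric")
  list(S = (S + t(S)) / 2, n = n)
}

#' Serialize a fitted model to JSON
#'
#' Writes raw and standardized parameters, the total-effect weight vector,
#' the test statistic and fit indices, and convergence diagnostics as
#' pretty-printed JSON (numbers at full precision). `read_fit_json()`
#' restores the parts needed downstream (notably the weight vector) as a
#' plain list.
#'
#' @param fit an `"hbm_cfa"` object.
#' @param path output file.
#' @param seed optional seed provenance to embed.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  spec <- fit$spec
  obj <- list(
    package = "hbmscore",
    version = as.character(utils::packageVersion("hbmscore")),
    seed = seed,
    spec = list(item_factor_map = unname(spec$item_factor_map),
                factors = spec$factors,
                second_order = spec$second_order,
                structural_paths = spec$structural_paths,
                markers = unname(spec$markers)),
    raw = list(lambda = unname(fit$lambda),
               gamma = unname(fit$gamma), beta = fit$beta,
               psi = unname(fit$psi), theta = unname(fit$theta)),
    standardized = list(lambda = unname(fit$std$lambda),
                        gamma = unname(fit$std$gamma),
                        beta = fit$std$beta,
                        psi = unname(fit$std$psi),
                        theta = unname(fit$std$theta)),
    total_effects = as.list(fit$total_effects),
    chi_square = fit$chi_square, df = fit$df, n_used = fit$n_used,
    fit_indices = unclass(fit$fit_indices),
    converged = fit$converged,
    heywood = fit$heywood,
    n_iterations = fit$n_iterations,
    final_gradient_norm = fit$final_gradient_norm)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a generator configuration from YAML
#'
#' The YAML keys mirror the [hbm_generator_config()] arguments
#' (`gamma`, `beta`, `lambda`, `delta`, `n_pre`, `n_post`, `thresholds`,
#' `response_scale`, `missing_rate`, `seed`). Omitted keys take the
#' benchmark-configuration values, so a minimal file may set only `delta`
#' and `seed`.
#'
#' @param path YAML file.
#' @return An `"hbm_generator_config"`.
#' @export
read_generator_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("gamma", "beta", "lambda", "delta", "n_pre", "n_post",
               "thresholds", "response_scale", "missing_rate", "seed")
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown generator config key(s): ", paste(bad, collapse = ", "))
  do.call(hbm_benchmark_config, raw)
}
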
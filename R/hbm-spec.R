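#' Model specification for a (second-order) confirmatory factor model
#'
#' Describes the measurement structure analysed by [hbm_cfa()]: which item
#' loads on which first-order factor (simple structure, one factor per item),
#' whether a single second-order factor drives the first-order factors, and
#' any directed structural paths among the first-order factors.
#'
#' Identification follows the usual marker-variable scheme: one loading per
#' first-order factor is fixed to 1 (by default the factor's first item) and
#' the second-order factor variance is fixed to 1, so every second-order
#' coefficient is free. Fully standardized estimates are derived after
#' fitting.
#'
#' @param item_factor_map character vector, one entry per item, naming the
#'   factor each item loads on. Names (if present) are used as item labels;
#'   otherwise items are labelled `item_01`, `item_02`, ...
#' @param factors factor names in display order; defaults to order of first
#'   appearance in `item_factor_map`.
#' @param second_order logical; if `TRUE` a single latent factor (named by
#'   `second_order_factor`) drives all first-order factors. If `FALSE` the
#'   first-order factors are freely correlated.
#' @param second_order_factor name of the second-order factor.
#' @param structural_paths list of length-2 character vectors
#'   `c(from, to)` of directed paths among first-order factors (acyclic).
#'   Only meaningful with `second_order = TRUE`.
#' @param markers optional named integer vector giving, for each factor, the
#'   (global) index of its marker item; defaults to each factor's first item.
#'
#' @return An object of class `"hbm_model_spec"`.
#' @seealso [hbm_default_spec()] for the 22-item injury-prevention health
#'   belief questionnaire structure.
#' @export
#' @examples
#' spec <- hbm_model_spec(c(a1 = "F1", a2 = "F1", b1 = "F2", b2 = "F2"),
#'                        second_order = FALSE)
#' spec$n_items
hbm_model_spec <- function(item_factor_map,
                           factors = NULL,
                           second_order = TRUE,
                           second_order_factor = "HB",
                           structural_paths = list(),
                           markers = NULL) {
  item_factor_map <- as.character(item_factor_map) |>
    stats::setNames(if (!is.null(names(item_factor_map))) names(item_factor_map)
                    else sprintf("item_%02d", seq_along(item_factor_map)))
  if (is.null(factors)) factors <- unique(unname(item_factor_map))
  if (!all(item_factor_map %in% factors))
    stop("item_factor_map contains factors not listed in 'factors'")
  counts <- table(factor(item_factor_map, levels = factors))
  if (any(counts < 2))
    stop("each factor needs at least 2 items; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  if (length(structural_paths) > 0) {
    for (pth in structural_paths) {
      if (length(pth) != 2 || !all(pth %in% factors))
        stop("each structural path must be c(from, to) over the factors")
    }
    if (!second_order)
      stop("structural paths require second_order = TRUE")
    check_acyclic(structural_paths, factors)
  }
  if (is.null(markers)) {
    markers <- vapply(factors, function(f) which(item_factor_map == f)[1L],
                      integer(1))
  } else {
    markers <- markers[factors]
    ok <- !is.na(markers) & item_factor_map[markers] == factors
    if (!all(ok)) stop("each marker must index an item of its own factor")
  }
  structure(
    list(item_factor_map = item_factor_map,
         items = names(item_factor_map),
         factors = factors,
         n_items = length(item_factor_map),
         n_factors = length(factors),
         second_order = second_order,
         second_order_factor = second_order_factor,
         structural_paths = structural_paths,
         markers = markers,
         factor_index = match(unname(item_factor_map), factors)),
    class = "hbm_model_spec"
  )
}

# simple DFS cycle check on the structural path graph
check_acyclic <- function(paths, factors) {
  adj <- lapply(factors, function(f)
    vapply(Filter(function(p) p[1] == f, paths), `[`, character(1), 2L))
  names(adj) <- factors
  state <- stats::setNames(rep(0L, length(factors)), factors) # 0 new 1 open 2 done
  visit <- function(f) {
    if (state[[f]] == 1L) stop("structural paths contain a cycle")
    if (state[[f]] == 2L) return(invisible())
    state[[f]] <<- 1L
    for (g in adj[[f]]) visit(g)
    state[[f]] <<- 2L
  }
  for (f in factors) visit(f)
  invisible(TRUE)
}

#' Default 22-item Health Belief Model questionnaire structure
#'
#' The measurement structure of the injury-prevention health-belief
#' questionnaire: 22 five-point Likert items mapped to the five HBM
#' constructs -- items 1-5 perceived susceptibility (SUS), 6-9 perceived
#' seriousness (SER), 10-14 perceived benefits (BEN), 15-18 barriers to
#' taking action (BAR), 19-22 cues to action (CTA) -- with one second-order
#' "health belief" factor and a structural BAR -> CTA path (respondents who
#' perceive more barriers are hypothesised to attend less to cues).
#'
#' @return An `"hbm_model_spec"` for the 22-item questionnaire.
#' @export
#' @examples
#' spec <- hbm_default_spec()
#' table(spec$item_factor_map)
hbm_default_spec <- function() {
  hbm_model_spec(
    item_factor_map = rep(c("SUS", "SER", "BEN", "BAR", "CTA"),
                          times = c(5L, 4L, 5L, 4L, 4L)),
    factors = c("SUS", "SER", "BEN", "BAR", "CTA"),
    second_order = TRUE,
    second_order_factor = "HB",
    structural_paths = list(c("BAR", "CTA"))
  )
}

#' @export
print.hbm_model_spec <- function(x, ...) {
  cat("Confirmatory factor model specification\n")
  cat(sprintf("  %d items, %d first-order factors (%s)\n",
              x$n_items, x$n_factors, paste(x$factors, collapse = ", ")))
  if (x$second_order)
    cat(sprintf("  second-order factor: %s (variance fixed to 1)\n",
                x$second_order_factor))
  else
    cat("  first-order factors freely correlated\n")
  for (pth in x$structural_paths)
    cat(sprintf("  structural path: %s -> %s\n", pth[1], pth[2]))
  cat("  markers:",
      paste(sprintf("%s=%s", x$factors, x$items[x$markers]), collapse = ", "),
      "\n")
  invisible(x)
}
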
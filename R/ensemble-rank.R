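#' Aggregate selector outputs into a per-feature rank table
#'
#' The aggregation statistic of the ensemble: for every feature in the
#' universe, count how many base selectors chose it. Features selected by no
#' selector get rank 0, so the table always covers the full universe.
#'
#' @param selections list of [selection_result()]s (or plain character
#'   vectors of feature identifiers).
#' @param universe ordered character vector of all feature identifiers.
#' @return An object of class `feature_rank_table`: list with `rank` (named
#'   integer vector over the universe, in universe order), `n_selectors`, and
#'   `universe`.
#' @export
aggregate_ranks <- function(selections, universe) {
  if (length(selections) < 1) stop("need at least one selection", call. = FALSE)
  universe <- as.character(universe)
  rank <- stats::setNames(integer(length(universe)), universe)
  for (sel in selections) {
    ids <- if (inherits(sel, "selection_result")) sel$selected
           else as.character(sel)
    unknown <- setdiff(ids, universe)
    if (length(unknown) > 0) {
      stop("selected feature(s) outside the universe: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    rank[ids] <- rank[ids] + 1L
  }
  structure(
    list(rank = rank, n_selectors = length(selections), universe = universe),
    class = "feature_rank_table"
  )
}

#' @export
print.feature_rank_table <- function(x, ...) {
  cat("<feature_rank_table> ", length(x$rank), " features, ",
      x$n_selectors, " selectors\n", sep = "")
  print(table(rank = x$rank))
  invisible(x)
}

#' Threshold a rank table into nested ensemble feature subsets
#'
#' `E_k = { feature i : R_i >= t_k }` for the three thresholds. Strictly
#' increasing thresholds guarantee the nesting `E3 <= E2 <= E1`. The default
#' (2, 3, 4) requires a feature to be chosen by at least two, three, and four
#' of five selectors respectively; (1, 2, 3) is the laxer variant in which E1
#' is the plain union of all selections.
#'
#' @param table a [aggregate_ranks()] result.
#' @param thresholds strictly increasing integer triple, each in
#'   `[1, n_selectors]`.
#' @return An object of class `ensemble_subsets`: list with `thresholds` and
#'   `E1`, `E2`, `E3` (character vectors in universe order).
#' @export
make_ensembles <- function(table, thresholds = c(2L, 3L, 4L)) {
  stopifnot(inherits(table, "feature_rank_table"))
  thresholds <- as.integer(thresholds)
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0)) {
    stop("thresholds must be three strictly increasing integers",
         call. = FALSE)
  }
  if (thresholds[1] < 1 || thresholds[3] > table$n_selectors) {
    stop("thresholds must lie in [1, n_selectors = ", table$n_selectors, "]",
         call. = FALSE)
  }
  subsets <- lapply(thresholds, function(t) {
    names(table$rank)[table$rank >= t]
  })
  structure(
    list(thresholds = thresholds,
         E1 = subsets[[1]], E2 = subsets[[2]], E3 = subsets[[3]]),
    class = "ensemble_subsets"
  )
}

#' @export
print.ensemble_subsets <- function(x, ...) {
  cat("<ensemble_subsets> thresholds (",
      paste(x$thresholds, collapse = ", "), "): |E1|=", length(x$E1),
      " |E2|=", length(x$E2), " |E3|=", length(x$E3), "\n", sep = "")
  invisible(x)
}
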
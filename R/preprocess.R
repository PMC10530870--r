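#' Clean a raw expression dataset
#'
#' Standard hygiene for tables that arrive from disk: drops index-like
#' columns (feature columns whose values are exactly the 0- or 1-based row
#' sequence, the usual exported-row-number artifact), removes rows containing
#' missing values, and removes duplicate sample rows (first occurrence kept,
#' duplicates compared on expression values and label together).
#'
#' @param ds an `expr_dataset`, possibly with missing cells or duplicate rows.
#' @param verbose log removal counts via [message()].
#' @return A cleaned `expr_dataset`. Errors if no rows survive.
#' @export
clean_dataset <- function(ds, verbose = FALSE) {
  stopifnot(inherits(ds, "expr_dataset"))
  X <- ds$X
  y <- ds$y
  n <- nrow(X)

  idx0 <- as.numeric(seq_len(n) - 1L)
  idx1 <- as.numeric(seq_len(n))
  index_like <- vapply(seq_len(ncol(X)), function(j) {
    col <- X[, j]
    !anyNA(col) && (isTRUE(all(col == idx0)) || isTRUE(all(col == idx1)))
  }, logical(1))
  # a 1-sample dataset makes every column trivially "index-like"; skip then
  if (n < 3) index_like[] <- FALSE
  n_cols_dropped <- sum(index_like)
  if (n_cols_dropped > 0) X <- X[, !index_like, drop = FALSE]

  has_na <- apply(X, 1, anyNA) | is.na(y)
  n_na <- sum(has_na)
  X <- X[!has_na, , drop = FALSE]
  y <- y[!has_na]

  dup <- duplicated(cbind(as.data.frame(X), .label = y))
  n_dup <- sum(dup)
  X <- X[!dup, , drop = FALSE]
  y <- y[!dup]

  if (nrow(X) == 0) stop("empty dataset after cleaning", call. = FALSE)
  if (verbose) {
    message(sprintf(
      "clean: dropped %d index-like column(s), %d row(s) with missing values, %d duplicate row(s)",
      n_cols_dropped, n_na, n_dup))
  }
  expr_dataset(X, y, colnames(X), ds$class_names)
}

#' Encode class labels as integers
#'
#' Classes are assigned indices `0..k-1` in order of first appearance, the
#' usual label-encoding convention (e.g. ALL=0, AML=1 for a leukemia table
#' whose first sample is ALL).
#'
#' @param labels vector of class names (character or factor).
#' @return A list with `y` (integer codes) and `class_names` (index-to-name
#'   mapping, `class_names[i + 1]` is the name of class `i`).
#' @export
encode_labels <- function(labels) {
  if (length(labels) < 1) stop("no labels to encode", call. = FALSE)
  labels <- as.character(labels)
  class_names <- unique(labels)
  y <- match(labels, class_names) - 1L
  list(y = y, class_names = class_names)
}

#' Encode the labels of a dataset in place
#'
#' @param ds an `expr_dataset` with raw string labels.
#' @return The dataset with integer labels and `class_names` filled in. A
#'   dataset already encoded is returned unchanged.
#' @export
encode_dataset <- function(ds) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!is.null(ds$class_names)) return(ds)
  enc <- encode_labels(ds$y)
  expr_dataset(ds$X, enc$y, ds$feature_ids, enc$class_names)
}

#' Scale expression features
#'
#' Per-feature scaling. `minmax` maps each feature to `[0, 1]` via
#' `(x - min) / (max - min)`; `zscore` centres and divides by the standard
#' deviation; `none` is the identity. Constant features map to 0 under both
#' non-trivial methods. When `params` is supplied, the stored ranges/moments
#' are applied instead of being re-learned — this is how the pipeline learns
#' scaling on the training split and applies it to the test split.
#'
#' @param ds an `expr_dataset`.
#' @param method one of `"minmax"`, `"zscore"`, `"none"`.
#' @param params optional scaling parameters from a previous call (the
#'   `"scaling"` attribute of its result).
#' @return The scaled `expr_dataset`, with the learned parameters in
#'   `attr(, "scaling")`.
#' @export
scale_features <- function(ds, method = c("minmax", "zscore", "none"),
                           params = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  method <- match.arg(method)
  X <- ds$X
  if (method == "none") {
    out <- ds
    attr(out, "scaling") <- list(method = "none")
    return(out)
  }
  if (is.null(params)) {
    if (method == "minmax") {
      lo <- apply(X, 2, min)
      hi <- apply(X, 2, max)
      params <- list(method = "minmax", lo = lo, hi = hi)
    } else {
      mu <- colMeans(X)
      sdv <- apply(X, 2, stats::sd)
      params <- list(method = "zscore", mu = mu, sd = sdv)
    }
  } else if (!identical(params$method, method)) {
    stop("scaling params were learned with method '", params$method, "'",
         call. = FALSE)
  }
  if (method == "minmax") {
    rng <- params$hi - params$lo
    rng[rng == 0] <- 1  # constant feature -> (x - lo)/1 = 0 on training data
    X <- sweep(sweep(X, 2, params$lo, "-"), 2, rng, "/")
  } else {
    sdv <- params$sd
    sdv[sdv == 0 | is.na(sdv)] <- 1
    X <- sweep(sweep(X, 2, params$mu, "-"), 2, sdv, "/")
  }
  out <- expr_dataset(X, ds$y, ds$feature_ids, ds$class_names)
  attr(out, "scaling") <- params
  out
}

## Run body with a locally-seeded RNG, restoring global state afterwards.
with_seed <- function(seed, body) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  body
}

#' Split a dataset into train and test partitions
#'
#' The training partition holds exactly `floor(ratio * n)` samples — the
#' rounding rule that reproduces the canonical 70:30 splits on the benchmark
#' microarray sizes (72 -> 50/22, 62 -> 43/19, 174 -> 121/53). Stratified
#' splitting allocates `floor(ratio * n_c)` training samples per class, then
#' tops up to the exact total by largest fractional remainder (ties broken by
#' class index). The permutation is driven only by `seed`.
#'
#' @param ds an encoded `expr_dataset` (see [encode_dataset()]).
#' @param ratio training fraction in (0, 1); default 0.7.
#' @param seed integer RNG seed for the permutation.
#' @param stratified preserve class proportions in both partitions (requires
#'   every class to have at least 2 samples).
#' @return An object of class `split_dataset`: list with `train`, `test`
#'   (both `expr_dataset`), `ratio`, `seed`, `stratified`, and the integer
#'   row indices `train_idx`, `test_idx`.
#' @export
split_train_test <- function(ds, ratio = 0.7, seed = 0L, stratified = TRUE) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0,1)", call. = FALSE)
  n <- n_samples(ds)
  if (n < 2) stop("need at least 2 samples to split", call. = FALSE)
  n_train <- floor(ratio * n)
  if (n_train < 1 || n_train >= n) {
    stop("split leaves an empty partition (n=", n, ", ratio=", ratio, ")",
         call. = FALSE)
  }

  if (stratified) {
    if (is.null(ds$class_names)) {
      stop("stratified split requires encoded labels", call. = FALSE)
    }
    counts <- table(ds$y)
    singles <- names(counts)[counts < 2]
    if (length(singles) > 0) {
      stop("stratified split impossible: class(es) with a single sample: ",
           paste(ds$class_names[as.integer(singles) + 1L], collapse = ", "),
           call. = FALSE)
    }
    classes <- sort(unique(ds$y))
    exact <- ratio * as.numeric(counts[as.character(classes)])
    base <- floor(exact)
    rem <- n_train - sum(base)
    if (rem > 0) {
      frac <- exact - base
      top_up <- order(-frac, seq_along(classes))[seq_len(rem)]
      base[top_up] <- base[top_up] + 1
    } else if (rem < 0) {
      frac <- exact - base
      cut_down <- order(frac, seq_along(classes))[seq_len(-rem)]
      base[cut_down] <- base[cut_down] - 1
    }
    train_idx <- with_seed(seed, {
      unlist(lapply(seq_along(classes), function(ci) {
        rows <- which(ds$y == classes[ci])
        take <- base[ci]
        if (take > length(rows)) take <- length(rows)
        sample(rows)[seq_len(take)]
      }), use.names = FALSE)
    })
  } else {
    train_idx <- with_seed(seed, sample.int(n)[seq_len(n_train)])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)

  mk <- function(idx) {
    expr_dataset(ds$X[idx, , drop = FALSE], ds$y[idx], ds$feature_ids,
                 ds$class_names)
  }
  structure(
    list(train = mk(train_idx), test = mk(test_idx),
         ratio = ratio, seed = seed, stratified = stratified,
         train_idx = train_idx, test_idx = test_idx),
    class = "split_dataset"
  )
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("<split_dataset> train ", n_samples(x$train), " / test ",
      n_samples(x$test), " (ratio ", x$ratio,
      if (x$stratified) ", stratified" else "", ", seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}
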
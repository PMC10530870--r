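#' Selection result container
#'
#' The common contract every base feature selector honours: the subset of
#' original feature identifiers it kept (in the dataset's column order), plus
#' the selector name and parameters.
#'
#' @param selector selector name, one of `"variance"`, `"pearson"`,
#'   `"ridge"`, `"rfe"`, `"pca"`.
#' @param selected character vector of selected feature identifiers.
#' @param params named list of the parameters used.
#' @return An object of class `selection_result` with fields `selector`,
#'   `selected`, `n_selected`, `params`.
#' @export
selection_result <- function(selector, selected, params = list()) {
  selector <- match.arg(selector, c("variance", "pearson", "ridge", "rfe", "pca"))
  selected <- as.character(selected)
  structure(
    list(selector = selector, selected = selected,
         n_selected = length(selected), params = params),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  pstr <- paste(names(x$params), unlist(lapply(x$params, format)),
                sep = "=", collapse = ", ")
  cat("<selection_result> ", x$selector, " (", pstr, "): ",
      x$n_selected, " features\n", sep = "")
  invisible(x)
}

## population variance (divisor n), per column
pop_var <- function(X) {
  mu <- colMeans(X)
  colMeans(X^2) - mu^2
}

#' Variance-threshold feature selection
#'
#' Keeps exactly the features whose population variance (divisor `n`) is at
#' least `t`. `t = 0` keeps everything including constants; any `t > 0`
#' removes zero-variance features.
#'
#' @param train training `expr_dataset` (typically scaled).
#' @param t variance threshold, `>= 0`.
#' @return A [selection_result()].
#' @export
select_variance <- function(train, t = 0.1) {
  stopifnot(inherits(train, "expr_dataset"))
  if (t < 0) stop("variance threshold must be >= 0", call. = FALSE)
  v <- pop_var(train$X)
  selection_result("variance", train$feature_ids[v >= t], list(t = t))
}

#' Pearson-correlation redundancy filter
#'
#' Computes pairwise Pearson correlation between features over the training
#' samples and scans pairs `(i, j)` with `i < j` in column order: whenever
#' `|r| > cutoff` the later feature `j` is dropped. Zero-variance features
#' are treated as uncorrelated with everything (`r = 0`). With
#' `mode = "relevance"` the filter instead keeps features whose absolute
#' correlation with the integer class label exceeds `cutoff` — the
#' feature-vs-class reading of the correlation coefficient.
#'
#' @param train training `expr_dataset` (encoded labels required for
#'   `mode = "relevance"`).
#' @param cutoff correlation cutoff in (0, 1); 0.9 is the usual default, 0.6
#'   for many-class data.
#' @param mode `"redundancy"` (default) or `"relevance"`.
#' @return A [selection_result()].
#' @export
select_pearson <- function(train, cutoff = 0.9,
                           mode = c("redundancy", "relevance")) {
  stopifnot(inherits(train, "expr_dataset"))
  mode <- match.arg(mode)
  if (!(cutoff > 0 && cutoff < 1)) {
    stop("correlation cutoff must be in (0,1)", call. = FALSE)
  }
  if (n_samples(train) < 2) stop("need >= 2 samples", call. = FALSE)
  X <- train$X
  if (mode == "relevance") {
    y <- as.numeric(train$y)
    r <- suppressWarnings(as.vector(stats::cor(X, y)))
    r[is.na(r)] <- 0
    keep <- abs(r) > cutoff
    return(selection_result("pearson", train$feature_ids[keep],
                            list(cutoff = cutoff, mode = mode)))
  }
  p <- ncol(X)
  r <- suppressWarnings(stats::cor(X))
  r[is.na(r)] <- 0
  dropped <- logical(p)
  for (j in seq_len(p)[-1]) {
    if (any(abs(r[seq_len(j - 1), j]) > cutoff)) dropped[j] <- TRUE
  }
  selection_result("pearson", train$feature_ids[!dropped],
                   list(cutoff = cutoff, mode = mode))
}

## Exact ridge solve for RSS + alpha * sum(beta^2), intercept unpenalised
## (handled by centring). Uses the dual identity when p > n.
ridge_coefficients <- function(X, y, alpha) {
  n <- nrow(X)
  p <- ncol(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm, "-")
  yc <- y - mean(y)
  if (p <= n) {
    beta <- solve(crossprod(Xc) + diag(alpha, p), crossprod(Xc, yc))
  } else {
    K <- tcrossprod(Xc)
    beta <- crossprod(Xc, solve(K + diag(alpha, n), yc))
  }
  as.vector(beta)
}

#' Ridge-regression coefficient feature selection
#'
#' Fits a ridge-penalised linear model of the integer-coded label on all
#' features, minimising `RSS + alpha * sum(beta^2)` (intercept unpenalised),
#' and keeps the features whose absolute coefficient is at least the mean
#' absolute coefficient. Ridge shrinks but never zeroes coefficients, so a
#' central threshold is what turns it into a selector. Multiclass problems
#' are handled one-vs-rest with the per-feature maximum absolute coefficient
#' across classes.
#'
#' @param train training `expr_dataset` with encoded labels.
#' @param alpha penalty weight, `> 0` (0.3 or 0.4 are typical).
#' @return A [selection_result()]. A degenerate all-zero fit yields an empty
#'   selection with a warning.
#' @export
select_ridge <- function(train, alpha = 0.3) {
  stopifnot(inherits(train, "expr_dataset"))
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (is.null(train$class_names)) stop("labels must be encoded", call. = FALSE)
  X <- train$X
  classes <- sort(unique(train$y))
  if (length(classes) <= 2) {
    beta <- abs(ridge_coefficients(X, as.numeric(train$y), alpha))
  } else {
    B <- vapply(classes, function(k) {
      abs(ridge_coefficients(X, as.numeric(train$y == k), alpha))
    }, numeric(ncol(X)))
    beta <- apply(B, 1, max)
  }
  if (all(beta == 0)) {
    warning("ridge fit degenerate (all coefficients zero); empty selection")
    return(selection_result("ridge", character(0), list(alpha = alpha)))
  }
  # tolerance absorbs float jitter when many coefficients sit exactly at
  # the mean (e.g. duplicated features)
  keep <- beta >= mean(beta) * (1 - 1e-8)
  selection_result("ridge", train$feature_ids[keep], list(alpha = alpha))
}

## Per-feature importance from linear SVM(s): squared weight magnitudes,
## summed one-vs-rest for multiclass.
linear_svm_importance <- function(X, y) {
  classes <- sort(unique(y))
  machines <- if (length(classes) == 2) {
    list(factor(y))
  } else {
    lapply(classes, function(k) factor(y == k))
  }
  imp <- numeric(ncol(X))
  for (f in machines) {
    fit <- e1071::svm(X, f, kernel = "linear", scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)  # 1 x p
    imp <- imp + as.vector(w)^2
  }
  imp
}

#' Recursive feature elimination with a linear support vector machine
#'
#' Iteratively fits a linear-kernel maximum-margin classifier, ranks features
#' by squared weight magnitude, removes the lowest-ranked `step` features,
#' and repeats until exactly `n_keep` remain. The margin weights require a
#' linear kernel; the radial kernel used for final classification exposes no
#' per-feature weights.
#'
#' @param train training `expr_dataset` with encoded labels and >= 2 classes.
#' @param n_keep target feature count, `1 <= n_keep <= p`.
#' @param step features removed per round: an integer `>= 1`, or a fraction
#'   in (0, 1) of the remaining features (rounded up). Default: 1 when
#'   `p <= 200`, otherwise 0.1.
#' @return A [selection_result()] with exactly `n_keep` features.
#' @export
select_rfe <- function(train, n_keep, step = NULL) {
  stopifnot(inherits(train, "expr_dataset"))
  p <- n_features(train)
  if (n_keep < 1 || n_keep > p) {
    stop("n_keep must be in [1, ", p, "]", call. = FALSE)
  }
  if (is.null(train$class_names)) stop("labels must be encoded", call. = FALSE)
  if (length(unique(train$y)) < 2) {
    stop("RFE requires >= 2 classes in the training data", call. = FALSE)
  }
  if (is.null(step)) step <- if (p <= 200) 1L else 0.1
  remaining <- train$feature_ids
  while (length(remaining) > n_keep) {
    drop_n <- if (step < 1) max(1L, ceiling(step * length(remaining)))
              else as.integer(step)
    drop_n <- min(drop_n, length(remaining) - n_keep)
    imp <- linear_svm_importance(train$X[, remaining, drop = FALSE], train$y)
    # lowest importance first; ties broken by later column position
    ord <- order(imp, -seq_along(remaining))
    remaining <- remaining[-ord[seq_len(drop_n)]]
  }
  selection_result("rfe", train$feature_ids[train$feature_ids %in% remaining],
                   list(n_keep = n_keep, step = step))
}

#' Principal-component loading feature selection
#'
#' Principal components are linear combinations, not genes; to let PCA
#' contribute gene identifiers to rank aggregation, each retained component
#' is mapped to its `m` original features with the largest absolute loading,
#' and the deduplicated union is returned.
#'
#' @param train training `expr_dataset`.
#' @param k number of components to retain (integer `>= 1`), or a fraction in
#'   (0, 1) of total variance to reach. `k` exceeding `min(n - 1, p)` is
#'   clipped with a warning.
#' @param m loadings taken per component, `>= 1`.
#' @return A [selection_result()] with at most `k * m` features.
#' @export
select_pca <- function(train, k = 0.95, m = 1) {
  stopifnot(inherits(train, "expr_dataset"))
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pc <- stats::prcomp(train$X, center = TRUE, scale. = FALSE)
  ncomp <- sum(pc$sdev > 1e-12)
  if (ncomp == 0) {
    warning("all features constant; PCA selects nothing")
    return(selection_result("pca", character(0), list(k = k, m = m)))
  }
  if (k < 1) {
    vfrac <- cumsum(pc$sdev[seq_len(ncomp)]^2) / sum(pc$sdev[seq_len(ncomp)]^2)
    use_k <- which(vfrac >= k)[1]
  } else {
    use_k <- as.integer(k)
    if (use_k > ncomp) {
      warning("k = ", use_k, " exceeds the ", ncomp,
              " available components; clipped")
      use_k <- ncomp
    }
  }
  picked <- unique(unlist(lapply(seq_len(use_k), function(ci) {
    load <- abs(pc$rotation[, ci])
    ord <- order(-load, seq_along(load))
    train$feature_ids[ord[seq_len(min(m, length(load)))]]
  })))
  selection_result("pca",
                   train$feature_ids[train$feature_ids %in% picked],
                   list(k = k, m = m))
}

#' Run all five base selectors on a training dataset
#'
#' @param train training `expr_dataset` (scaled, encoded).
#' @param params named list of per-selector parameters:
#'   `variance_t`, `pearson_cutoff`, `pearson_mode`, `ridge_alpha`,
#'   `rfe_n_keep` (default `ceiling(p / 2)`), `rfe_step`, `pca_k`, `pca_m`.
#' @param verbose log each selector's name, parameters and count.
#' @return Named list of five [selection_result()]s
#'   (`variance`, `pearson`, `ridge`, `rfe`, `pca`).
#' @export
run_selectors <- function(train, params = list(), verbose = FALSE) {
  p <- n_features(train)
  defaults <- list(variance_t = 0.1, pearson_cutoff = 0.9,
                   pearson_mode = "redundancy", ridge_alpha = 0.3,
                   rfe_n_keep = ceiling(p / 2), rfe_step = NULL,
                   pca_k = 0.95, pca_m = 1)
  prm <- utils::modifyList(defaults, params[!vapply(params, is.null, logical(1))])
  res <- list(
    variance = select_variance(train, t = prm$variance_t),
    pearson = select_pearson(train, cutoff = prm$pearson_cutoff,
                             mode = prm$pearson_mode),
    ridge = select_ridge(train, alpha = prm$ridge_alpha),
    rfe = select_rfe(train, n_keep = prm$rfe_n_keep, step = prm$rfe_step),
    pca = select_pca(train, k = prm$pca_k, m = prm$pca_m)
  )
  for (s in res) {
    if (s$n_selected == 0) {
      warning("selector '", s$selector, "' returned an empty feature set")
    }
    if (verbose) {
      message(sprintf("selector %s: %d features selected", s$selector,
                      s$n_selected))
    }
  }
  res
}
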
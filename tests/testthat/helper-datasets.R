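# Small fixture builders shared across the test files.

# dataset from an explicit matrix with encoded labels 0..k-1
make_ds <- function(X, y, ids = NULL) {
  if (is.null(ids)) ids <- paste0("g", seq_len(ncol(X)))
  k <- max(y) + 1L
  expr_dataset(as.matrix(X), as.integer(y), ids,
               class_names = paste0("c", seq_len(k) - 1L))
}

# seeded random dataset: pure noise plus optional mean-shifted block
random_ds <- function(n, p, k = 2, shift = 0, n_shifted = 0, seed = 1) {
  withr::with_seed(seed, {
    y <- rep_len(seq_len(k) - 1L, n)
    X <- matrix(rnorm(n * p), n, p)
    if (n_shifted > 0) {
      X[, seq_len(n_shifted)] <- X[, seq_len(n_shifted)] + shift * y
    }
    make_ds(X, y)
  })
}

# two well-separated axis-aligned Gaussian blobs (linearly separable)
blob_ds <- function(n = 40, p = 5, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * p, sd = 0.5), n, p)
    X[, 1] <- X[, 1] + gap * y
    make_ds(X, y)
  })
}

# A member that always predicts a fixed class: a 1-nearest-neighbour learner
# whose entire training set is that class. Only exported behaviour is used.
constant_member <- function(cls, classes = 0:2) {
  structure(
    list(kind = "knn", spec = list(kind = "knn", params = list(k = 1L)),
         fit = list(X = matrix(0, 1, 1), y = as.integer(cls)),
         classes = classes, train_X = matrix(0, 1, 1),
         train_y = as.integer(cls)),
    class = "base_member")
}

# voting model whose three members predict the fixed classes in `preds`
stub_model <- function(preds, weights, classes = 0:2) {
  members <- lapply(as.list(preds), constant_member, classes = classes)
  names(members) <- c("svm", "knn", "dt")
  voting_model(members, stats::setNames(as.integer(weights), names(members)),
               class_names = paste0("c", classes))
}

# brute-force weighted hard-vote oracle: independent of the implementation
oracle_vote <- function(preds, weights, classes) {
  score <- vapply(classes, function(cl) sum(weights[preds == cl]), numeric(1))
  tied <- classes[score == max(score)]
  if (length(tied) == 1) return(tied)
  for (mi in order(-weights)) {
    if (preds[mi] %in% tied) return(preds[mi])
  }
  min(tied)
}
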
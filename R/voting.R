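#' Base classifier specifications
#'
#' The three base learners of the voting ensemble: a radial-kernel support
#' vector machine, k-nearest neighbours with `k = 3`, and a depth-2 decision
#' tree. The declaration order (svm, knn, dt) is also the tie-break order for
#' weight assignment.
#'
#' @param knn_k neighbour count for KNN.
#' @param svm_kernel kernel for the SVM (`"radial"` is the RBF kernel).
#' @param dt_max_depth maximum tree depth.
#' @param dt_seed accepted for interface parity; tree fitting via rpart is
#'   deterministic, so it has no effect.
#' @return Named list of three `base_classifier_spec` objects.
#' @export
base_classifier_specs <- function(knn_k = 3L, svm_kernel = "radial",
                                  dt_max_depth = 2L, dt_seed = 0L) {
  list(
    svm = structure(list(kind = "svm", params = list(kernel = svm_kernel)),
                    class = "base_classifier_spec"),
    knn = structure(list(kind = "knn", params = list(k = as.integer(knn_k))),
                    class = "base_classifier_spec"),
    dt = structure(list(kind = "dt",
                        params = list(max_depth = as.integer(dt_max_depth),
                                      seed = as.integer(dt_seed))),
                   class = "base_classifier_spec")
  )
}

## Deterministic k-nearest-neighbour prediction: Euclidean distance, distance
## ties broken by training-sample order, vote ties by lowest class index.
knn_predict <- function(train_X, train_y, new_X, k) {
  k <- min(k, nrow(train_X))
  apply(new_X, 1, function(x) {
    d <- sqrt(colSums((t(train_X) - x)^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    votes <- table(train_y[nn])
    cls <- as.integer(names(votes))
    cls[order(-as.integer(votes), cls)][1]
  })
}

fit_base <- function(spec, X, y, classes) {
  fit <- switch(spec$kind,
    svm = e1071::svm(X, factor(y, levels = classes),
                     kernel = spec$params$kernel, scale = FALSE),
    knn = list(X = X, y = y),
    dt = {
      df <- as.data.frame(X)
      colnames(df) <- paste0("v", seq_len(ncol(X)))
      df$.class <- factor(y, levels = classes)
      rpart::rpart(.class ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = spec$params$max_depth, minsplit = 2,
                     minbucket = 1, cp = 0, xval = 0))
    },
    stop("unknown base classifier kind: ", spec$kind, call. = FALSE))
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 classes = classes, train_X = X, train_y = y),
            class = "base_member")
}

predict_base <- function(member, X) {
  switch(member$kind,
    svm = as.integer(as.character(stats::predict(member$fit, X))),
    knn = as.integer(knn_predict(member$fit$X, member$fit$y, X,
                                 member$spec$params$k)),
    dt = {
      df <- as.data.frame(X)
      colnames(df) <- paste0("v", seq_len(ncol(X)))
      as.integer(as.character(stats::predict(member$fit, df, type = "class")))
    })
}

#' Fit the three base classifiers on a feature subset
#'
#' @param train training `expr_dataset` with encoded labels and >= 2 classes.
#' @param features non-empty character vector of feature identifiers to train
#'   on (a subset of the training features).
#' @param specs output of [base_classifier_specs()].
#' @return Named list of fitted members (svm, knn, dt), each carrying its
#'   restricted training data for later cross-validated weighting.
#' @export
fit_bases <- function(train, features, specs = base_classifier_specs()) {
  stopifnot(inherits(train, "expr_dataset"))
  if (length(features) == 0) {
    stop("no features selected at this ensemble level", call. = FALSE)
  }
  if (!all(features %in% train$feature_ids)) {
    stop("features not present in the training data: ",
         paste(utils::head(setdiff(features, train$feature_ids), 5),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(train$class_names)) stop("labels must be encoded", call. = FALSE)
  classes <- seq_along(train$class_names) - 1L
  if (length(unique(train$y)) < 2) {
    stop("training data contain a single class", call. = FALSE)
  }
  tr <- restrict_features(train, features)
  members <- lapply(specs, function(s) fit_base(s, tr$X, tr$y, classes))
  attr(members, "features") <- tr$feature_ids
  members
}

## Seeded stratified k-fold assignment: per class, shuffle then deal
## round-robin. Returns an integer fold id per sample.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      rows <- which(y == cls)
      rows <- rows[sample.int(length(rows))]
      folds[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  folds
}

#' Assign integer voting weights by ranked accuracy
#'
#' Each member's accuracy is measured under the chosen policy, members are
#' sorted by accuracy (descending, ties broken by declaration order: svm,
#' knn, dt), and weights 3, 2, 1 are assigned from best to worst.
#'
#' Policies: `"cv"` — stratified 5-fold cross-validation on the members' own
#' training data (refitting per fold; pooled accuracy); `"holdout"` — refit
#' on 75% of the training data and score on the held-back 25%; `"test_leaky"`
#' — score the fitted members on `eval_data` directly. The last reproduces
#' weighting on a final test set and is kept only for replicating published
#' workflows that did so; it leaks test information into the ensemble.
#'
#' @param members fitted members from [fit_bases()].
#' @param eval_data `expr_dataset` restricted to the members' features;
#'   required for `policy = "test_leaky"`, ignored otherwise.
#' @param policy `"cv"`, `"holdout"` or `"test_leaky"`.
#' @param seed integer seed for fold/holdout assignment.
#' @return Named list with `weights` (named integer vector over members) and
#'   `accuracy` (the per-member accuracies used).
#' @export
assign_weights <- function(members, eval_data = NULL,
                           policy = c("cv", "holdout", "test_leaky"),
                           seed = 0L) {
  policy <- match.arg(policy)
  kinds <- names(members)
  acc <- switch(policy,
    cv = {
      X <- members[[1]]$train_X
      y <- members[[1]]$train_y
      k <- min(5L, min(table(y)))
      if (k < 2) {
        # too few samples per class to fold: fall back to training accuracy
        vapply(members, function(mem) {
          mean(predict_base(mem, X) == y)
        }, numeric(1))
      } else {
        folds <- stratified_folds(y, k, seed)
        vapply(members, function(mem) {
          pred <- integer(length(y))
          for (f in seq_len(k)) {
            tr <- folds != f
            refit <- fit_base(mem$spec, X[tr, , drop = FALSE], y[tr],
                              mem$classes)
            pred[!tr] <- predict_base(refit, X[!tr, , drop = FALSE])
          }
          mean(pred == y)
        }, numeric(1))
      }
    },
    holdout = {
      X <- members[[1]]$train_X
      y <- members[[1]]$train_y
      ds <- expr_dataset(X, y, colnames(X),
                         class_names = as.character(members[[1]]$classes))
      sp <- split_train_test(ds, ratio = 0.75, seed = seed,
                             stratified = min(table(y)) >= 2)
      vapply(members, function(mem) {
        refit <- fit_base(mem$spec, sp$train$X, sp$train$y, mem$classes)
        mean(predict_base(refit, sp$test$X) == sp$test$y)
      }, numeric(1))
    },
    test_leaky = {
      if (is.null(eval_data)) {
        stop("policy 'test_leaky' requires eval_data", call. = FALSE)
      }
      vapply(members, function(mem) {
        mean(predict_base(mem, eval_data$X) == eval_data$y)
      }, numeric(1))
    })
  names(acc) <- kinds
  ord <- order(-acc, seq_along(acc))  # ties -> declaration order
  weights <- integer(length(members))
  weights[ord] <- rev(seq_len(length(members)))  # best gets 3, then 2, 1
  names(weights) <- kinds
  list(weights = weights, accuracy = acc)
}

#' Construct a weighted hard-voting ensemble model
#'
#' @param members fitted members from [fit_bases()].
#' @param weights named positive integer vector, one weight per member (from
#'   [assign_weights()] or fixed).
#' @param class_names class index-to-name mapping from the training data.
#' @param eval_accuracy per-member accuracies used for the weighting.
#' @return An object of class `voting_model` with a [predict()][predict.voting_model]
#'   method.
#' @export
voting_model <- function(members, weights, class_names,
                         eval_accuracy = NULL) {
  if (length(weights) != length(members)) {
    stop("one weight per member required", call. = FALSE)
  }
  if (any(weights < 1)) stop("weights must be >= 1", call. = FALSE)
  structure(
    list(members = members, weights = as.integer(weights),
         classes = members[[1]]$classes, class_names = class_names,
         eval_accuracy = eval_accuracy, tie_break = "weight-then-index",
         features = attr(members, "features")),
    class = "voting_model"
  )
}

#' @export
print.voting_model <- function(x, ...) {
  cat("<voting_model> members:", paste(names(x$members), collapse = ", "),
      "\n  weights:", paste(sprintf("%s=%d", names(x$members), x$weights),
                            collapse = ", "), "\n")
  if (!is.null(x$eval_accuracy)) {
    cat("  eval accuracy:",
        paste(sprintf("%s=%.3f", names(x$eval_accuracy), x$eval_accuracy),
              collapse = ", "), "\n")
  }
  invisible(x)
}

## Weighted hard-vote tally for one matrix of member predictions
## (rows = members). Returns the winning class per column.
tally_votes <- function(pred_mat, weights, classes) {
  apply(pred_mat, 2, function(votes) {
    score <- vapply(classes, function(cl) sum(weights[votes == cl]),
                    numeric(1))
    top <- classes[score == max(score)]
    if (length(top) == 1) return(top)
    # tie: the class voted by the highest-weight member among the tied ones
    in_tie <- votes %in% top
    if (any(in_tie)) {
      by_weight <- order(-weights, seq_along(weights))
      for (mi in by_weight) {
        if (in_tie[mi]) return(votes[mi])
      }
    }
    min(top)  # residual tie: lowest class index
  })
}

#' Predict classes by weighted hard vote
#'
#' Each member casts its integer weight for its predicted class; the class
#' with the largest weight sum wins. Ties go to the class voted by the
#' highest-weight member among the tied classes, and any residual tie to the
#' lowest class index.
#'
#' @param object a [voting_model()].
#' @param newdata numeric matrix restricted to the model's training features,
#'   same column order (or an `expr_dataset`, restricted automatically).
#' @param ... unused.
#' @return Integer vector of predicted class indices.
#' @export
predict.voting_model <- function(object, newdata, ...) {
  X <- check_vote_input(object, newdata)
  pred <- vapply(object$members, function(mem) predict_base(mem, X),
                 integer(nrow(X)))
  pred <- matrix(as.integer(pred), nrow = nrow(X))
  as.integer(tally_votes(t(pred), object$weights, object$classes))
}

check_vote_input <- function(object, newdata) {
  if (inherits(newdata, "expr_dataset")) {
    newdata <- restrict_features(newdata, object$features)$X
  }
  X <- as.matrix(newdata)
  feats <- object$features
  if (!is.null(feats)) {
    if (ncol(X) != length(feats)) {
      stop("feature count mismatch: model expects ", length(feats),
           ", got ", ncol(X), call. = FALSE)
    }
    if (!is.null(colnames(X)) && !identical(colnames(X), feats)) {
      stop("feature order mismatch with the model's training features",
           call. = FALSE)
    }
  }
  X
}

#' Per-class vote-share scores
#'
#' `score(class) = (sum of weights of members predicting that class) / (total
#' weight)`; scores per sample sum to 1 and their argmax (under the same tie
#' rule) equals [predict.voting_model()]. These shares are the ranking scores
#' used to draw a ROC curve for a hard voter, which otherwise emits no
#' continuous score.
#'
#' @inheritParams predict.voting_model
#' @param model a [voting_model()].
#' @param newdata feature-restricted matrix or `expr_dataset`.
#' @return Numeric matrix, samples x classes, columns named by class index.
#' @export
vote_scores <- function(model, newdata) {
  X <- check_vote_input(model, newdata)
  pred <- vapply(model$members, function(mem) predict_base(mem, X),
                 integer(nrow(X)))
  pred <- matrix(as.integer(pred), nrow = nrow(X))
  total <- sum(model$weights)
  scores <- vapply(model$classes, function(cl) {
    rowSums(sweep(pred == cl, 2, model$weights, "*")) / total
  }, numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X),
                   dimnames = list(NULL, model$classes))
  scores
}
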
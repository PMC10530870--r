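#' Run the full ensemble feature-selection and voting pipeline
#'
#' The flagship fitting function. Cleans and label-encodes the data, makes a
#' stratified 70:30 split, learns scaling on the training split (applied to
#' the test split), fits the five base selectors on the training data,
#' aggregates their choices into a per-feature rank table, thresholds it into
#' the nested ensemble subsets E1/E2/E3, then — for the raw feature set, each
#' selector's set and each ensemble subset — trains the SVM/KNN/DT bases and
#' the weighted voting classifier and evaluates all four on the held-out
#' test split.
#'
#' Everything downstream of the split is driven only by `config$seed`, so
#' identical config and data give identical selections, predictions and
#' reports.
#'
#' @param data an `expr_dataset` (raw or encoded labels).
#' @param config a [run_config()].
#' @param verbose log selector sizes and voting weights.
#' @return An object of class `efs_pipeline` with `print`, `summary` and
#'   `predict` methods. Fields include `rank_table`, `ensembles`,
#'   `selections`, `feature_sets`, `reports` (feature set -> classifier ->
#'   [evaluate_predictions()] report), `models` (fitted [voting_model()]s),
#'   `weights`, `split`, `scaling` and `class_names`.
#' @seealso [write_report()] to persist the results;
#'   [predict.efs_pipeline()] to classify new samples.
#' @export
run_pipeline <- function(data, config = run_config(), verbose = FALSE) {
  stopifnot(inherits(data, "expr_dataset"), inherits(config, "run_config"))
  ds <- clean_dataset(data, verbose = verbose)
  ds <- encode_dataset(ds)
  if (length(unique(ds$y)) < 2) {
    stop("dataset has a single class; nothing to classify", call. = FALSE)
  }
  if (min(table(ds$y)) < 2) {
    stop("every class needs at least 2 samples", call. = FALSE)
  }

  split <- split_train_test(ds, ratio = config$split_ratio,
                            seed = config$seed,
                            stratified = config$stratified)
  if (length(unique(split$train$y)) < 2) {
    stop("training split contains a single class", call. = FALSE)
  }

  if (config$select_on_all) {
    all_scaled <- scale_features(ds, config$scaling)
    scaling <- attr(all_scaled, "scaling")
    train <- expr_dataset(all_scaled$X[split$train_idx, , drop = FALSE],
                          split$train$y, ds$feature_ids, ds$class_names)
    test <- expr_dataset(all_scaled$X[split$test_idx, , drop = FALSE],
                         split$test$y, ds$feature_ids, ds$class_names)
    select_data <- all_scaled
  } else {
    train <- scale_features(split$train, config$scaling)
    scaling <- attr(train, "scaling")
    test <- scale_features(split$test, config$scaling, params = scaling)
    select_data <- train
  }

  selections <- withCallingHandlers(
    run_selectors(select_data, config$selector_params, verbose = verbose),
    warning = function(w) {
      if (grepl("empty feature set", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  empty_selectors <- names(selections)[
    vapply(selections, function(s) s$n_selected == 0, logical(1))]
  if (length(empty_selectors) > 0) {
    warning("selector(s) returned an empty feature set: ",
            paste(empty_selectors, collapse = ", "),
            "; reported as empty and skipped in classification")
  }

  rank_table <- aggregate_ranks(selections, ds$feature_ids)
  ensembles <- make_ensembles(rank_table, config$ensemble_thresholds)

  feature_sets <- c(
    list(raw = ds$feature_ids),
    stats::setNames(lapply(selections, `[[`, "selected"), names(selections)),
    list(E1 = ensembles$E1, E2 = ensembles$E2, E3 = ensembles$E3)
  )

  specs <- do.call(base_classifier_specs, config$classifier_params)
  n_classes <- length(ds$class_names)
  reports <- list()
  models <- list()
  weight_log <- list()
  for (fs in names(feature_sets)) {
    feats <- feature_sets[[fs]]
    if (length(feats) == 0) {
      warning("feature set '", fs, "' is empty; skipped in classification")
      reports[[fs]] <- list()
      next
    }
    members <- fit_bases(train, feats, specs)
    if (is.null(config$fixed_weights)) {
      w <- assign_weights(members,
                          eval_data = if (config$weight_policy == "test_leaky")
                            restrict_features(test, feats) else NULL,
                          policy = config$weight_policy, seed = config$seed)
    } else {
      w <- list(weights = stats::setNames(as.integer(config$fixed_weights),
                                          names(members)),
                accuracy = rep(NA_real_, length(members)))
    }
    model <- voting_model(members, w$weights, ds$class_names,
                          eval_accuracy = w$accuracy)
    if (verbose) {
      message(sprintf("feature set %s (%d features): weights %s", fs,
                      length(feats),
                      paste(sprintf("%s=%d", names(members), w$weights),
                            collapse = " ")))
    }
    test_fs <- restrict_features(test, feats)
    rep_fs <- list()
    for (kind in names(members)) {
      pred <- predict_base(members[[kind]], test_fs$X)
      sc <- matrix(0, length(pred), n_classes)
      sc[cbind(seq_along(pred), pred + 1L)] <- 1  # hard one-hot scores
      rep_fs[[kind]] <- evaluate_predictions(test$y, pred, n_classes, sc)
    }
    vpred <- predict(model, test_fs$X)
    vscores <- vote_scores(model, test_fs$X)
    rep_fs$voting <- evaluate_predictions(test$y, vpred, n_classes, vscores)
    reports[[fs]] <- rep_fs
    models[[fs]] <- model
    weight_log[[fs]] <- w
  }

  structure(
    list(config = config, class_names = ds$class_names, split = split,
         scaling = scaling, selections = selections,
         rank_table = rank_table, ensembles = ensembles,
         feature_sets = feature_sets, reports = reports, models = models,
         weights = weight_log, n_features = length(ds$feature_ids)),
    class = "efs_pipeline"
  )
}

#' @export
print.efs_pipeline <- function(x, ...) {
  cat("<efs_pipeline> ", n_samples(x$split$train), " train / ",
      n_samples(x$split$test), " test samples, ", x$n_features,
      " features, ", length(x$class_names), " classes\n", sep = "")
  print(x$ensembles)
  cat("use summary() for the accuracy table\n")
  invisible(x)
}

#' Accuracy table of a fitted pipeline
#'
#' @param object an `efs_pipeline`.
#' @param ... unused.
#' @return Data frame of accuracy percentages: one row per feature set, one
#'   column per classifier, plus the feature count.
#' @export
summary.efs_pipeline <- function(object, ...) {
  sets <- names(object$feature_sets)
  classifiers <- c("svm", "knn", "dt", "voting")
  out <- data.frame(feature_set = sets,
                    n_features = vapply(object$feature_sets, length,
                                        integer(1)),
                    row.names = NULL)
  for (cl in classifiers) {
    out[[cl]] <- vapply(sets, function(fs) {
      r <- object$reports[[fs]][[cl]]
      if (is.null(r)) NA_real_ else r$accuracy_pct
    }, numeric(1))
  }
  class(out) <- c("summary.efs_pipeline", "data.frame")
  out
}

#' @export
print.summary.efs_pipeline <- function(x, ...) {
  cat("Test accuracy (%) by feature set and classifier:\n")
  y <- as.data.frame(x)
  for (cl in c("svm", "knn", "dt", "voting")) y[[cl]] <- round(y[[cl]], 2)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Classify new samples with a fitted pipeline
#'
#' Applies the stored scaling, restricts to the chosen feature set, and
#' predicts with that set's weighted voting model.
#'
#' @param object an `efs_pipeline`.
#' @param newdata numeric matrix (samples x genes, original feature
#'   identifiers as column names) or an `expr_dataset`.
#' @param feature_set which fitted feature set to use (default `"E2"`).
#' @param ... unused.
#' @return Character vector of predicted class names.
#' @export
predict.efs_pipeline <- function(object, newdata, feature_set = "E2", ...) {
  model <- object$models[[feature_set]]
  if (is.null(model)) {
    stop("no fitted model for feature set '", feature_set, "'",
         call. = FALSE)
  }
  if (!inherits(newdata, "expr_dataset")) {
    newdata <- expr_dataset(as.matrix(newdata),
                            y = rep(NA_character_, nrow(newdata)))
  }
  scaled <- scale_features(newdata, object$config$scaling,
                           params = if (object$config$scaling == "none")
                             NULL else object$scaling)
  restricted <- restrict_features(scaled, model$features)
  pred <- predict(model, restricted$X)
  object$class_names[pred + 1L]
}

#' Persist a pipeline run as machine-readable reports
#'
#' Writes three files into `out_dir`: `report.json` (configuration, selector
#' sizes, ensemble subsets, weights and all metrics), `metrics.csv` (flat
#' `feature_set, classifier, metric, value` table) and `features.csv`
#' (`feature_id, rank, in_E1, in_E2, in_E3`). Output is deterministic:
#' rerunning an identical pipeline reproduces the files byte for byte.
#'
#' @param pipeline an `efs_pipeline`.
#' @param out_dir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(pipeline, out_dir) {
  stopifnot(inherits(pipeline, "efs_pipeline"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  metrics <- do.call(rbind, lapply(names(pipeline$reports), function(fs) {
    do.call(rbind, lapply(names(pipeline$reports[[fs]]), function(cl) {
      r <- pipeline$reports[[fs]][[cl]]
      data.frame(feature_set = fs, classifier = cl,
                 metric = c("accuracy_pct", "macro_precision", "macro_recall",
                            "macro_f1", "auroc"),
                 value = c(r$accuracy_pct, unname(r$macro), r$auroc))
    }))
  }))
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(metrics, metrics_path, row.names = FALSE)

  rt <- pipeline$rank_table
  features <- data.frame(
    feature_id = names(rt$rank), rank = unname(rt$rank),
    in_E1 = names(rt$rank) %in% pipeline$ensembles$E1,
    in_E2 = names(rt$rank) %in% pipeline$ensembles$E2,
    in_E3 = names(rt$rank) %in% pipeline$ensembles$E3)
  features_path <- file.path(out_dir, "features.csv")
  utils::write.csv(features, features_path, row.names = FALSE)

  report <- list(
    config = unclass(pipeline$config),
    classes = pipeline$class_names,
    split = list(n_train = n_samples(pipeline$split$train),
                 n_test = n_samples(pipeline$split$test),
                 ratio = pipeline$split$ratio,
                 stratified = pipeline$split$stratified),
    selectors = lapply(pipeline$selections, function(s) {
      list(params = s$params, n_selected = s$n_selected)
    }),
    ensembles = list(thresholds = pipeline$ensembles$thresholds,
                     E1 = pipeline$ensembles$E1, E2 = pipeline$ensembles$E2,
                     E3 = pipeline$ensembles$E3),
    weights = lapply(pipeline$weights, function(w) {
      list(weights = as.list(w$weights), accuracy = as.list(w$accuracy))
    }),
    metrics = lapply(pipeline$reports, function(by_cl) {
      lapply(by_cl, function(r) {
        list(accuracy_pct = r$accuracy_pct,
             macro = as.list(r$macro), auroc = r$auroc,
             n_test = r$n_test,
             confusion = unname(r$confusion))
      })
    })
  )
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(c(report = json_path, metrics = metrics_path,
              features = features_path))
}
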
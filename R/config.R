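#' Run configuration
#'
#' Bundles every tunable of the pipeline with validation. Defaults follow the
#' conventional settings for microarray-scale tables: 70:30 stratified split,
#' min-max scaling, variance threshold 0.1, correlation cutoff 0.9, ridge
#' alpha 0.3, RFE keeping half the genes, PCA retaining 95% variance with one
#' loading per component, ensemble thresholds (2, 3, 4) of 5 selectors, and
#' cross-validated voting weights.
#'
#' @param label_column name of the class column in delimited input.
#' @param split_ratio training fraction in (0, 1).
#' @param seed integer RNG seed driving the split, folds and any sampling.
#' @param scaling `"minmax"`, `"zscore"` or `"none"`.
#' @param stratified stratify the train/test split by class.
#' @param select_on_all fit the selectors on the full dataset instead of the
#'   training split only. The default `FALSE` avoids selection leakage;
#'   `TRUE` reproduces workflows that select features before splitting.
#' @param selector_params named list overriding selector defaults:
#'   `variance_t`, `pearson_cutoff`, `pearson_mode`, `ridge_alpha`,
#'   `rfe_n_keep`, `rfe_step`, `pca_k`, `pca_m`.
#' @param ensemble_thresholds strictly increasing integer triple in `[1, 5]`.
#' @param weight_policy `"cv"`, `"holdout"` or `"test_leaky"` (see
#'   [assign_weights()]).
#' @param fixed_weights optional named integer vector (svm, knn, dt) to skip
#'   accuracy-based weighting entirely.
#' @param classifier_params named list: `knn_k`, `svm_kernel`,
#'   `dt_max_depth`, `dt_seed`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(label_column = "label", split_ratio = 0.7, seed = 0L,
                       scaling = c("minmax", "zscore", "none"),
                       stratified = TRUE, select_on_all = FALSE,
                       selector_params = list(),
                       ensemble_thresholds = c(2L, 3L, 4L),
                       weight_policy = c("cv", "holdout", "test_leaky"),
                       fixed_weights = NULL,
                       classifier_params = list()) {
  scaling <- match.arg(scaling)
  weight_policy <- match.arg(weight_policy)
  if (!(split_ratio > 0 && split_ratio < 1)) {
    stop("split_ratio must be in (0,1)", call. = FALSE)
  }
  ensemble_thresholds <- as.integer(ensemble_thresholds)
  if (length(ensemble_thresholds) != 3 || any(diff(ensemble_thresholds) <= 0) ||
      ensemble_thresholds[1] < 1 || ensemble_thresholds[3] > 5) {
    stop("ensemble_thresholds must be strictly increasing integers in [1, 5]",
         call. = FALSE)
  }
  sp <- selector_params
  if (!is.null(sp$variance_t) && sp$variance_t < 0) {
    stop("variance_t must be >= 0", call. = FALSE)
  }
  if (!is.null(sp$pearson_cutoff) &&
      !(sp$pearson_cutoff > 0 && sp$pearson_cutoff < 1)) {
    stop("pearson_cutoff must be in (0,1)", call. = FALSE)
  }
  if (!is.null(sp$ridge_alpha) && sp$ridge_alpha <= 0) {
    stop("ridge_alpha must be > 0", call. = FALSE)
  }
  if (!is.null(sp$pca_k) && sp$pca_k <= 0) {
    stop("pca_k must be positive", call. = FALSE)
  }
  if (!is.null(fixed_weights)) {
    if (length(fixed_weights) != 3 || any(fixed_weights < 1)) {
      stop("fixed_weights must be three integers >= 1", call. = FALSE)
    }
  }
  cp <- utils::modifyList(
    list(knn_k = 3L, svm_kernel = "radial", dt_max_depth = 2L, dt_seed = 0L),
    classifier_params)
  structure(
    list(label_column = label_column, split_ratio = split_ratio,
         seed = as.integer(seed), scaling = scaling, stratified = stratified,
         select_on_all = select_on_all, selector_params = sp,
         ensemble_thresholds = ensemble_thresholds,
         weight_policy = weight_policy, fixed_weights = fixed_weights,
         classifier_params = cp),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> split ", x$split_ratio, " (seed ", x$seed,
      if (x$stratified) ", stratified" else "", "), scaling ", x$scaling,
      ", thresholds (", paste(x$ensemble_thresholds, collapse = ","),
      "), weights ", x$weight_policy,
      if (x$select_on_all) ", select-on-all" else "", "\n", sep = "")
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `selector_params` and
#' `classifier_params` are nested mappings. `overrides` (e.g. parsed CLI
#' flags) take precedence over file values.
#'
#' @param path YAML file path, or `NULL` for pure defaults/overrides.
#' @param overrides named list of [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals <- utils::modifyList(vals, overrides)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}
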
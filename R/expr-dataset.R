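#' Expression dataset container
#'
#' The container every stage of the pipeline consumes and produces: a numeric
#' samples-by-genes matrix with unique feature identifiers, plus class labels.
#' Labels may be raw strings (fresh from disk) or integer codes `0..k-1` with
#' a `class_names` mapping (after [encode_labels()]).
#'
#' @param X numeric matrix, `n_samples x n_features`.
#' @param y labels, one per row of `X`: character (raw) or integer codes.
#' @param feature_ids character vector of unique feature identifiers, one per
#'   column of `X`. Defaults to `colnames(X)`.
#' @param class_names character vector mapping class index `i` (0-based) to
#'   its original name, i.e. `class_names[i + 1]`. `NULL` until labels are
#'   encoded.
#'
#' @return An object of class `expr_dataset`: a list with elements `X`,
#'   `y`, `feature_ids`, `class_names`.
#' @seealso [read_expression_table()], [encode_labels()], [clean_dataset()]
#' @export
expr_dataset <- function(X, y, feature_ids = colnames(X), class_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(feature_ids)) {
    feature_ids <- paste0("f", seq_len(ncol(X)))
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(X)) {
    stop("length(feature_ids) must equal ncol(X)", call. = FALSE)
  }
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup) > 0) {
    stop("duplicate feature identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (length(y) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  if (!is.null(class_names)) {
    y <- as.integer(y)
    if (any(y < 0L) || any(y >= length(class_names))) {
      stop("encoded labels out of range of class_names", call. = FALSE)
    }
  }
  colnames(X) <- feature_ids
  structure(
    list(X = X, y = y, feature_ids = feature_ids, class_names = class_names),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat("<expr_dataset> ", nrow(x$X), " samples x ", ncol(x$X), " features\n",
      sep = "")
  if (is.null(x$class_names)) {
    cat("  labels (raw): ", paste(utils::head(unique(x$y), 8), collapse = ", "),
        "\n", sep = "")
  } else {
    tab <- table(factor(x$y, levels = seq_along(x$class_names) - 1L))
    cat("  classes: ",
        paste(sprintf("%s=%d (n=%d)", x$class_names,
                      seq_along(x$class_names) - 1L, as.integer(tab)),
              collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of samples / features
#' @param ds an `expr_dataset`.
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$X)

#' @rdname n_samples
#' @export
n_features <- function(ds) ncol(ds$X)

#' Read a delimited expression table
#'
#' Reads a samples-by-genes table with a header row of feature identifiers and
#' one label column. Feature values must be numeric; empty cells become
#' missing values (removed later by [clean_dataset()]), while genuinely
#' non-numeric text in an expression cell is an error reported with its
#' row/column coordinates.
#'
#' @param path path to a delimited text file.
#' @param label_column name of the class-label column.
#' @param delimiter field delimiter, `","` or `"\t"`.
#' @return An [expr_dataset()] with raw (unencoded) string labels, sample
#'   order preserved.
#' @export
read_expression_table <- function(path, label_column = "label",
                                  delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "", na.strings = c("NA", ""))
  hdr <- colnames(df)
  if (sum(hdr == label_column) == 0) {
    stop("label column '", label_column, "' not found in header",
         call. = FALSE)
  }
  if (sum(hdr == label_column) > 1) {
    stop("label column '", label_column, "' appears more than once",
         call. = FALSE)
  }
  feat_names <- hdr[hdr != label_column]
  dup <- unique(feat_names[duplicated(feat_names)])
  if (length(dup) > 0) {
    stop("duplicate feature identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  y <- df[[label_column]]
  feats <- df[, hdr != label_column, drop = FALSE]
  X <- matrix(NA_real_, nrow(feats), ncol(feats),
              dimnames = list(NULL, feat_names))
  for (j in seq_len(ncol(feats))) {
    raw <- feats[[j]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric expression value '%s' at row %d, column '%s'",
                   raw[bad[1]], bad[1], feat_names[j]), call. = FALSE)
    }
    X[, j] <- val
  }
  expr_dataset(X, y = as.character(y), feature_ids = feat_names)
}

#' Write an expression dataset to delimited text
#'
#' Inverse of [read_expression_table()]: writes the expression matrix with a
#' header of feature identifiers plus one label column. Encoded labels are
#' written back as their original class names.
#'
#' @param ds an `expr_dataset`.
#' @param path output file path.
#' @param label_column name for the label column.
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(ds, path, label_column = "label",
                                   delimiter = ",") {
  labels <- if (is.null(ds$class_names)) ds$y else ds$class_names[ds$y + 1L]
  df <- as.data.frame(ds$X, check.names = FALSE)
  df[[label_column]] <- labels
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## Restrict a dataset to a feature subset (order taken from the dataset).
restrict_features <- function(ds, features) {
  keep <- ds$feature_ids[ds$feature_ids %in% features]
  if (length(keep) == 0) stop("no features selected", call. = FALSE)
  expr_dataset(ds$X[, keep, drop = FALSE], ds$y, keep, ds$class_names)
}
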
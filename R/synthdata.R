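#' Specification for a synthetic microarray-like dataset
#'
#' Describes a high-dimensional, low-sample-size expression table with known
#' ground truth: a small block of informative genes whose class-conditional
#' means are shifted, a block of redundant genes correlated with informative
#' sources, and a dominant majority of pure-noise genes.
#'
#' @param n_samples number of samples.
#' @param n_features total number of genes `p` (typically `p >> n`).
#' @param n_classes number of classes (2-11 emulates the benchmark range).
#' @param n_informative genes with class-dependent mean shifts.
#' @param effect mean shift per class step, in noise-SD units: informative
#'   gene values for class `c` are drawn from
#'   `Normal(c * effect * noise_sd, noise_sd)`.
#' @param n_redundant genes generated as `rho * source + sqrt(1 - rho^2) *
#'   noise`, sources cycling through the informative genes.
#' @param rho correlation of redundant genes with their source, in `[0, 1]`.
#' @param noise_sd standard deviation of the Gaussian noise.
#' @param class_proportions class mixing proportions (must sum to 1);
#'   uniform by default.
#' @param seed integer RNG seed; the dataset is fully reproducible from it.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 100L, n_features = 1000L, n_classes = 2L,
                       n_informative = 20L, effect = 3, n_redundant = 0L,
                       rho = 0.9, noise_sd = 1,
                       class_proportions = NULL, seed = 1L) {
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  if (length(class_proportions) != n_classes ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must have length n_classes and sum to 1",
         call. = FALSE)
  }
  if (n_informative + n_redundant > n_features) {
    stop("n_informative + n_redundant exceeds n_features", call. = FALSE)
  }
  if (n_redundant > 0 && n_informative == 0) {
    stop("redundant genes need informative sources", call. = FALSE)
  }
  if (effect < 0) stop("effect must be >= 0", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples),
         n_features = as.integer(n_features),
         n_classes = as.integer(n_classes),
         n_informative = as.integer(n_informative), effect = effect,
         n_redundant = as.integer(n_redundant), rho = rho,
         noise_sd = noise_sd, class_proportions = class_proportions,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Generate a synthetic expression dataset with ground truth
#'
#' Sample class sizes follow the proportions by largest remainder; informative
#' genes get class-shifted Gaussian values, redundant genes are correlated
#' copies of informative sources, all remaining genes are pure noise. Genes
#' are laid out informative-first (`inf0001...`), then redundant
#' (`red0001...`), then noise (`noi0001...`), and rows are shuffled. The
#' whole draw is reproducible from `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @return List with `dataset` (an encoded `expr_dataset`) and `truth`
#'   (class `synth_truth`: `informative` identifier set and `redundant_map`
#'   from redundant gene to its source).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_samples
  p <- spec$n_features
  k <- spec$n_classes
  exact <- spec$class_proportions * n
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    top <- order(-(exact - counts), seq_len(k))[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  if (any(counts == 0)) {
    stop("a class received zero samples; increase n_samples", call. = FALSE)
  }

  ni <- spec$n_informative
  nr <- spec$n_redundant
  nn <- p - ni - nr
  ids <- c(if (ni > 0) sprintf("inf%04d", seq_len(ni)),
           if (nr > 0) sprintf("red%04d", seq_len(nr)),
           if (nn > 0) sprintf("noi%04d", seq_len(nn)))

  out <- with_seed(spec$seed, {
    y <- rep(seq_len(k) - 1L, counts)
    y <- y[sample.int(n)]
    X <- matrix(0, n, p, dimnames = list(NULL, ids))
    if (ni > 0) {
      shift <- matrix(rep(y * spec$effect * spec$noise_sd, ni), n, ni)
      X[, seq_len(ni)] <- shift +
        matrix(stats::rnorm(n * ni, 0, spec$noise_sd), n, ni)
    }
    if (nr > 0) {
      src <- rep_len(seq_len(ni), nr)
      noise <- matrix(stats::rnorm(n * nr, 0, spec$noise_sd), n, nr)
      X[, ni + seq_len(nr)] <-
        spec$rho * X[, src, drop = FALSE] + sqrt(1 - spec$rho^2) * noise
    }
    if (nn > 0) {
      X[, ni + nr + seq_len(nn)] <-
        matrix(stats::rnorm(n * nn, 0, spec$noise_sd), n, nn)
    }
    list(X = X, y = y)
  })

  dataset <- expr_dataset(out$X, out$y, ids,
                          class_names = paste0("class", seq_len(k) - 1L))
  redundant_map <- if (nr > 0) {
    stats::setNames(ids[rep_len(seq_len(ni), nr)], ids[ni + seq_len(nr)])
  } else {
    stats::setNames(character(0), character(0))
  }
  truth <- structure(
    list(informative = if (ni > 0) ids[seq_len(ni)] else character(0),
         redundant_map = redundant_map),
    class = "synth_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' Fraction of the informative genes recovered by a feature subset
#'
#' @param truth a `synth_truth` from [generate_dataset()].
#' @param subset character vector of feature identifiers.
#' @return `|subset intersect informative| / |informative|` in `[0, 1]`.
#' @export
recovery_rate <- function(truth, subset) {
  stopifnot(inherits(truth, "synth_truth"))
  if (length(truth$informative) == 0) {
    stop("recovery rate undefined: no informative features in the truth",
         call. = FALSE)
  }
  length(intersect(subset, truth$informative)) / length(truth$informative)
}
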
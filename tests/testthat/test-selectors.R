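test_that("variance threshold keeps exactly the features with var >= t", {
  # population variance of (0,1) is 0.25
  ds <- make_ds(cbind(c(0, 1), c(5, 5)), c(0L, 1L))
  expect_equal(select_variance(ds, t = 0.2)$selected, "g1")
  expect_equal(select_variance(ds, t = 0.3)$selected, character(0))
  expect_setequal(select_variance(ds, t = 0)$selected, c("g1", "g2"))
  expect_equal(select_variance(ds, t = 1e-12)$selected, "g1")
})

test_that("variance selection matches a brute-force recomputation", {
  ds <- random_ds(30, 100, seed = 21)
  for (t in c(0.5, 0.9, 1.1)) {
    sel <- select_variance(ds, t)$selected
    v <- apply(ds$X, 2, function(col) mean((col - mean(col))^2))
    expect_setequal(sel, ds$feature_ids[v >= t])
  }
})

test_that("variance cardinality is monotone non-increasing in t and stable
          under sample permutation", {
  ds <- random_ds(25, 40, seed = 5)
  sizes <- vapply(c(0, 0.3, 0.6, 1, 2),
                  function(t) select_variance(ds, t)$n_selected, integer(1))
  expect_true(all(diff(sizes) <= 0))
  perm <- withr::with_seed(9, sample(25))
  ds_perm <- make_ds(ds$X[perm, ], ds$y[perm])
  expect_equal(select_variance(ds_perm, 0.5)$selected,
               select_variance(ds, 0.5)$selected)
})

test_that("correlation filter drops the later of highly correlated pairs", {
  x <- rnorm(20)
  z <- rnorm(20)
  ds <- make_ds(cbind(x, x, z), rep(0:1, 10), ids = c("f1", "f2", "f3"))
  expect_equal(select_pearson(ds, 0.9)$selected, c("f1", "f3"))

  # independent features survive any reasonable cutoff
  ds2 <- withr::with_seed(3, make_ds(matrix(rnorm(200 * 2), 200, 2),
                                     rep(0:1, 100)))
  expect_setequal(select_pearson(ds2, 0.9)$selected, c("g1", "g2"))

  # anti-correlated pairs are caught through |r|
  w <- rnorm(20)
  ds3 <- make_ds(cbind(x, x, z, w, -w), rep(0:1, 10),
                 ids = paste0("f", 1:5))
  expect_equal(select_pearson(ds3, 0.9)$selected, c("f1", "f3", "f4"))
})

test_that("correlation filter treats zero-variance features as uncorrelated
          and is monotone in the cutoff", {
  ds <- make_ds(cbind(rnorm(10), rep(1, 10), rep(2, 10)), rep(0:1, 5))
  expect_setequal(select_pearson(ds, 0.5)$selected, c("g1", "g2", "g3"))

  ds_rand <- random_ds(15, 30, seed = 12)
  sizes <- vapply(c(0.3, 0.5, 0.7, 0.9, 0.99),
                  function(cc) select_pearson(ds_rand, cc)$n_selected,
                  integer(1))
  expect_true(all(diff(sizes) >= 0))

  perm <- withr::with_seed(2, sample(15))
  ds_perm <- make_ds(ds_rand$X[perm, ], ds_rand$y[perm])
  expect_equal(select_pearson(ds_perm, 0.6)$selected,
               select_pearson(ds_rand, 0.6)$selected)
})

test_that("relevance mode keeps features correlated with the class", {
  y <- rep(0:1, each = 10)
  ds <- withr::with_seed(7, make_ds(cbind(y * 5 + rnorm(20, sd = 0.1),
                                          rnorm(20)), y))
  sel <- select_pearson(ds, 0.8, mode = "relevance")$selected
  expect_equal(sel, "g1")
})

test_that("ridge selection matches an independent closed-form solve", {
  withr::with_seed(40, {
    n <- 40; p <- 50; alpha <- 0.3
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(0:1, each = n / 2)
    ds <- make_ds(X, y)
    sel <- select_ridge(ds, alpha)$selected
    # independent primal oracle on centred data
    Xc <- scale(X, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    beta <- solve(t(Xc) %*% Xc + alpha * diag(p)) %*% (t(Xc) %*% yc)
    expect_setequal(sel, ds$feature_ids[abs(beta) >= mean(abs(beta))])
  })
})

test_that("ridge agrees between primal (p <= n) and dual (p > n) paths", {
  withr::with_seed(41, {
    X <- matrix(rnorm(30 * 28), 30, 28)
    y <- rep(0:1, 15)
    ds_small <- make_ds(X, y)
    # same columns plus two more: the shared coefficients must agree with a
    # dual-path fit on a p > n version built from the same generator
    Xbig <- cbind(X, matrix(rnorm(30 * 14), 30, 14))
    ds_big <- make_ds(Xbig, y)
    sel_big <- select_ridge(ds_big, 0.3)$selected
    Xc <- scale(Xbig, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    beta <- solve(t(Xc) %*% Xc + 0.3 * diag(ncol(Xbig))) %*% (t(Xc) %*% yc)
    expect_setequal(sel_big,
                    ds_big$feature_ids[abs(beta) >= mean(abs(beta))])
  })
})

test_that("ridge picks the feature that exactly determines the label", {
  withr::with_seed(42, {
    n <- 30; p <- 100
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * p, sd = 1), n, p)
    X[, 1] <- y  # f1 equals the label
    ds <- make_ds(X, y)
    expect_true("g1" %in% select_ridge(ds, 0.3)$selected)
  })
})

test_that("ridge on identical features selects all or none by symmetry", {
  x <- rnorm(12)
  ds <- make_ds(cbind(x, x, x), rep(0:1, 6))
  sel <- select_ridge(ds, 0.3)
  expect_true(sel$n_selected %in% c(0L, 3L))
  expect_equal(sel$n_selected, 3L)  # equal coefficients sit at the mean
})

test_that("ridge handles multiclass one-vs-rest", {
  withr::with_seed(43, {
    y <- rep(0:2, each = 10)
    X <- matrix(rnorm(30 * 40), 30, 40)
    X[, 1] <- (y == 1) * 4 + rnorm(30, sd = 0.1)
    X[, 2] <- (y == 2) * 4 + rnorm(30, sd = 0.1)
    ds <- make_ds(X, y)
    sel <- select_ridge(ds, 0.3)$selected
    expect_true(all(c("g1", "g2") %in% sel))
  })
})

test_that("RFE returns exactly n_keep features and honours the contract", {
  ds <- random_ds(20, 10, seed = 31)
  expect_setequal(select_rfe(ds, n_keep = 10)$selected, ds$feature_ids)
  for (n_keep in c(1L, 5L, 10L)) {
    expect_equal(select_rfe(ds, n_keep)$n_selected, n_keep)
  }
  expect_error(select_rfe(ds, 11), "n_keep")
  expect_error(select_rfe(ds, 0), "n_keep")
})

test_that("RFE keeps the single feature carrying the margin", {
  hits <- 0L
  for (seed in 1:20) {
    ds <- withr::with_seed(seed, {
      y <- rep(0:1, each = 15)
      X <- matrix(rnorm(30 * 10), 30, 10)
      X[, 1] <- 2 * y - 1 + rnorm(30, sd = 0.1)
      make_ds(X, y)
    })
    if (identical(select_rfe(ds, 1)$selected, "g1")) hits <- hits + 1L
  }
  expect_equal(hits, 20L)
})

test_that("fractional RFE steps reach n_keep on wider matrices", {
  ds <- random_ds(25, 300, seed = 32)
  sel <- select_rfe(ds, n_keep = 40)
  expect_equal(sel$n_selected, 40L)
  sel2 <- select_rfe(ds, n_keep = 40, step = 0.5)
  expect_equal(sel2$n_selected, 40L)
})

test_that("PCA loading selection finds the dominant-variance feature", {
  withr::with_seed(50, {
    X <- matrix(rnorm(30 * 10, sd = 0.1), 30, 10)
    X[, 3] <- rnorm(30, sd = 10)
    ds <- make_ds(X, rep(0:1, 15))
    expect_equal(select_pca(ds, k = 1, m = 1)$selected, "g3")
    # eigen-decomposition oracle: top loading of the first PC
    ev <- eigen(cov(scale(X, center = TRUE, scale = FALSE)))
    expect_equal(which.max(abs(ev$vectors[, 1])), 3L)
  })
})

test_that("PCA selection dedups repeated top features and clips k", {
  withr::with_seed(51, {
    # one dominant feature loads on the top of several components
    X <- matrix(rnorm(10 * 4, sd = 0.01), 10, 4)
    X[, 2] <- rnorm(10, sd = 5)
    ds <- make_ds(X, rep(0:1, 5))
    sel <- select_pca(ds, k = 2, m = 2)
    expect_lte(sel$n_selected, 4)
    expect_true("g2" %in% sel$selected)

    expect_warning(select_pca(ds, k = 50, m = 1), "clipped")
  })
})

test_that("k distinct variance carriers give k PCA selections", {
  withr::with_seed(52, {
    X <- matrix(rnorm(40 * 30, sd = 0.01), 40, 30)
    big <- c(4, 11, 23)
    for (j in big) X[, j] <- rnorm(40, sd = 10 + j)
    ds <- make_ds(X, rep(0:1, 20))
    sel <- select_pca(ds, k = 3, m = 1)
    expect_setequal(sel$selected, paste0("g", big))
  })
})

test_that("every selector returns a subset of the universe on fuzzed data", {
  for (seed in 1:5) {
    ds <- random_ds(20, 30, k = 2, shift = 2, n_shifted = 4, seed = seed)
    scaled <- scale_features(ds, "minmax")
    sels <- suppressWarnings(run_selectors(scaled, list(rfe_n_keep = 10L)))
    expect_named(sels, c("variance", "pearson", "ridge", "rfe", "pca"))
    for (s in sels) {
      expect_true(all(s$selected %in% ds$feature_ids))
      expect_equal(s$n_selected, length(s$selected))
    }
  }
})
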
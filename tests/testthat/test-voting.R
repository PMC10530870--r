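test_that("every base classifier fits separable blobs perfectly", {
  for (seed in 1:10) {
    ds <- blob_ds(n = 40, seed = seed)
    members <- fit_bases(ds, ds$feature_ids)
    for (kind in names(members)) {
      model <- voting_model(members[kind],
                            stats::setNames(1L, kind), ds$class_names)
      pred <- predict(model, ds$X)
      expect_equal(pred, ds$y,
                   label = sprintf("%s training accuracy (seed %d)",
                                   kind, seed))
    }
  }
})

test_that("refitting with the same inputs gives identical predictions", {
  ds <- blob_ds(n = 30, seed = 3)
  probe <- blob_ds(n = 20, seed = 4)
  m1 <- fit_bases(ds, ds$feature_ids)
  m2 <- fit_bases(ds, ds$feature_ids)
  w1 <- assign_weights(m1, policy = "cv", seed = 5)
  w2 <- assign_weights(m2, policy = "cv", seed = 5)
  expect_identical(w1, w2)
  v1 <- voting_model(m1, w1$weights, ds$class_names)
  v2 <- voting_model(m2, w2$weights, ds$class_names)
  expect_identical(predict(v1, probe$X), predict(v2, probe$X))
})

test_that("empty feature sets and single-class data fail before fitting", {
  ds <- blob_ds(n = 20, seed = 1)
  expect_error(fit_bases(ds, character(0)), "no features selected")
  single <- make_ds(ds$X, rep(0L, 20))
  expect_error(fit_bases(single, single$feature_ids), "single class")
  expect_error(fit_bases(ds, c("g1", "nope")), "not present")
})

test_that("weights rank members by accuracy with declaration-order ties", {
  rank_weights <- function(acc) {
    ord <- order(-acc, seq_along(acc))
    w <- integer(3)
    w[ord] <- 3:1
    stats::setNames(w, c("svm", "knn", "dt"))
  }
  expect_equal(rank_weights(c(svm = 0.70, knn = 0.80, dt = 0.90)),
               c(svm = 1L, knn = 2L, dt = 3L))
  expect_equal(rank_weights(c(svm = 0.80, knn = 0.80, dt = 0.90)),
               c(svm = 2L, knn = 1L, dt = 3L))
  expect_equal(rank_weights(c(svm = 0.5, knn = 0.5, dt = 0.5)),
               c(svm = 3L, knn = 2L, dt = 1L))

  # the exported path reproduces the rank rule on the leaky policy, where
  # accuracies are directly controllable
  ds <- blob_ds(n = 30, seed = 7)
  members <- fit_bases(ds, ds$feature_ids)
  w <- assign_weights(members, eval_data = ds, policy = "test_leaky")
  expect_equal(w$weights[order(-w$accuracy, seq_along(w$accuracy))],
               stats::setNames(3:1, names(w$weights)[
                 order(-w$accuracy, seq_along(w$accuracy))]))
  expect_setequal(as.integer(w$weights), 1:3)
})

test_that("weighted hard votes follow the stated tally and tie rules", {
  # (A, B, B) with weights (1, 2, 3): B wins 5 to 1
  expect_equal(predict(stub_model(c(0, 1, 1), c(1, 2, 3)),
                       matrix(0, 1, 1)), 1L)
  # (A, B, B) with weights (3, 2, 1): 3-3 tie; highest-weight member said A
  expect_equal(predict(stub_model(c(0, 1, 1), c(3, 2, 1)),
                       matrix(0, 1, 1)), 0L)
  # unanimity wins regardless of weights
  expect_equal(predict(stub_model(c(2, 2, 2), c(1, 2, 3)),
                       matrix(0, 1, 1)), 2L)
})

test_that("vote shares normalise to 1 and argmax matches the prediction", {
  m <- stub_model(c(0, 1, 1), c(1, 2, 3))
  sc <- vote_scores(m, matrix(0, 1, 1))
  expect_equal(unname(sc[1, ]), c(1 / 6, 5 / 6, 0))

  m2 <- stub_model(c(2, 2, 2), c(3, 1, 2))
  sc2 <- vote_scores(m2, matrix(0, 1, 1))
  expect_equal(unname(sc2[1, ]), c(0, 0, 1))
})

test_that("vote tallies match a brute-force oracle over all patterns,
          weights and dominance cases", {
  classes <- 0:2
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  patterns <- expand.grid(m1 = classes, m2 = classes, m3 = classes)
  for (w in perms) {
    for (i in seq_len(nrow(patterns))) {
      preds <- as.integer(patterns[i, ])
      model <- stub_model(preds, w)
      got <- predict(model, matrix(0, 1, 1))
      want <- oracle_vote(preds, w, classes)
      expect_equal(got, want,
                   label = sprintf("preds (%s), weights (%s)",
                                   paste(preds, collapse = ","),
                                   paste(w, collapse = ",")))
      sc <- vote_scores(model, matrix(0, 1, 1))
      expect_equal(sum(sc), 1)
      # argmax of scores under the same tie rule equals the prediction
      top <- classes[sc[1, ] == max(sc[1, ])]
      expect_true(got %in% top)
    }
  }
  # dominance: one weight above the sum of the others makes that member
  # the whole ensemble
  for (dom in 1:3) {
    w <- rep(1L, 3)
    w[dom] <- 3L
    for (i in seq_len(nrow(patterns))) {
      preds <- as.integer(patterns[i, ])
      got <- predict(stub_model(preds, w), matrix(0, 1, 1))
      expect_equal(got, preds[dom])
    }
  }
})

test_that("equal weights reduce to simple majority with the same tie rule", {
  classes <- 0:2
  patterns <- expand.grid(m1 = classes, m2 = classes, m3 = classes)
  for (i in seq_len(nrow(patterns))) {
    preds <- as.integer(patterns[i, ])
    got <- predict(stub_model(preds, c(1, 1, 1)), matrix(0, 1, 1))
    counts <- table(factor(preds, levels = classes))
    majority <- classes[counts == max(counts)]
    if (length(majority) == 1) {
      expect_equal(got, majority)
    } else {
      # all-distinct pattern: equal weights tie; first member is the
      # highest-weight one by declaration order
      expect_equal(got, preds[1])
    }
  }
})

test_that("feature mismatches are hard errors at prediction time", {
  ds <- blob_ds(n = 20, seed = 2)
  members <- fit_bases(ds, c("g1", "g2"))
  model <- voting_model(members, stats::setNames(1:3, names(members)),
                        ds$class_names)
  expect_error(predict(model, ds$X), "feature count mismatch")
  wrong_order <- ds$X[, c("g2", "g1")]
  expect_error(predict(model, wrong_order), "feature order")
})

test_that("cv and holdout weighting run without touching the test data", {
  ds <- blob_ds(n = 40, seed = 6)
  members <- fit_bases(ds, ds$feature_ids)
  for (policy in c("cv", "holdout")) {
    w <- assign_weights(members, policy = policy, seed = 1)
    expect_setequal(as.integer(w$weights), 1:3)
    expect_true(all(w$accuracy >= 0 & w$accuracy <= 1))
  }
  expect_error(assign_weights(members, policy = "test_leaky"), "eval_data")
})
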
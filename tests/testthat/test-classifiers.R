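sep_toy <- function(n = 60, seed = 2) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  f <- tibble::tibble(
    id = paste0("r", seq_len(n)),
    f1 = rnorm(n, mean = ifelse(y == 1, 3, -3), sd = 0.5),
    f2 = rnorm(n, mean = ifelse(y == 1, -3, 3), sd = 0.5))
  list(features = f, y = y)
}

test_that("the six default specs carry the published hyperparameters", {
  sp <- default_specs()
  expect_equal(sp$svm$hyper$cost, 19)
  expect_equal(sp$svm$hyper$gamma, 0.125)
  expect_equal(sp$knn$hyper$k, 9L)
  expect_equal(sp$knn$hyper$weight, "inverse_distance")
  expect_equal(sp$dt$hyper$confidence, 0.25)
  expect_equal(sp$rf$hyper$ntree, 300L)
  expect_equal(sp$et$hyper$ntree, 900L)
  expect_equal(sp$xgb$hyper$nrounds, 150L)
  expect_equal(sp$xgb$hyper$max_depth, 5L)
  expect_equal(sp$xgb$hyper$eta, 0.03)
  expect_equal(sp$xgb$hyper$subsample, 0.6)
  expect_true(sp$svm$scaling)
  expect_true(sp$knn$scaling)
  expect_false(sp$et$scaling)
})

test_that("every model separates a linearly separable toy and is seeded", {
  t <- sep_toy()
  for (kind in names(default_specs())) {
    m <- train_classifier(default_specs()[[kind]], t$features, t$y, seed = 4)
    p <- predict_classifier(m, t$features)
    expect_equal(p$label, t$y, info = kind)
    expect_true(all(p$score >= 0 & p$score <= 1), info = kind)
    m2 <- train_classifier(default_specs()[[kind]], t$features, t$y, seed = 4)
    expect_identical(predict_classifier(m2, t$features)$score, p$score,
                     info = kind)
  }
  expect_error(train_classifier(default_specs()$svm, t$features,
                                rep(1L, nrow(t$features)), seed = 1),
               "classes")
})

test_that("KNN follows inverse-distance weighting", {
  set.seed(12)
  f <- tibble::tibble(id = paste0("r", 1:18),
                      f1 = rnorm(18, rep(c(2, -2), each = 9)),
                      f2 = rnorm(18))
  y <- rep(c(0L, 1L), each = 9)
  m <- train_classifier(default_specs()$knn, f, y, seed = 1)
  probe <- tibble::tibble(id = "p", f1 = 0.3, f2 = -0.2)
  got <- predict_classifier(m, probe)
  # hand computation of the weighted vote on the standardized training scale
  X <- sweep(sweep(as.matrix(f[, c("f1", "f2")]), 2, m$center), 2, m$scale, "/")
  px <- (c(0.3, -0.2) - m$center) / m$scale
  d <- sqrt(colSums((t(X) - px)^2))
  nn <- order(d)[1:9]
  w <- 1 / d[nn]
  expect_equal(got$score, sum(w[y[nn] == 1]) / sum(w), tolerance = 1e-12)
  expect_equal(got$label, as.integer(got$score >= 0.5))
  # a probe deep inside one class's cluster scores for that class
  deep <- predict_classifier(m, tibble::tibble(id = "d", f1 = -2.2, f2 = 0))
  expect_gt(deep$score, 0.5)
})

test_that("tree models ignore monotone rescaling; SVM/KNN rely on the persisted standardizer", {
  t <- sep_toy(seed = 6)
  rescaled <- t$features
  rescaled$f1 <- rescaled$f1 * 1000 + 7
  rescaled$f2 <- rescaled$f2 / 50 - 2
  for (kind in c("dt", "rf", "et", "xgb")) {
    m1 <- train_classifier(default_specs()[[kind]], t$features, t$y, seed = 3)
    m2 <- train_classifier(default_specs()[[kind]], rescaled, t$y, seed = 3)
    expect_equal(predict_classifier(m1, t$features)$label,
                 predict_classifier(m2, rescaled)$label, info = kind)
  }
  for (kind in c("svm", "knn")) {
    m1 <- train_classifier(default_specs()[[kind]], t$features, t$y, seed = 3)
    m2 <- train_classifier(default_specs()[[kind]], rescaled, t$y, seed = 3)
    # the standardizer absorbs affine rescaling: scores match across scales
    expect_equal(predict_classifier(m1, t$features)$score,
                 predict_classifier(m2, rescaled)$score, tolerance = 1e-6,
                 info = kind)
  }
})

test_that("prediction refuses schema-mismatched input", {
  t <- sep_toy()
  m <- train_classifier(default_specs()$rf, t$features, t$y, seed = 1)
  bad <- t$features
  names(bad)[2] <- "other"
  expect_error(predict_classifier(m, bad), "schema mismatch")
  expect_error(predict_classifier(m, t$features[, 1:2]), "schema mismatch")
})

test_that("label permutation drives cross-validated accuracy to chance", {
  set.seed(31)
  n <- 60
  f <- tibble::tibble(id = paste0("r", 1:n),
                      f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
  y <- sample(rep(c(0L, 1L), n / 2))  # labels independent of features
  ds <- dplyr::bind_cols(tibble::tibble(sequence = NA_character_), f)
  ds <- f
  ds$label <- y
  ds$sequence <- rand_peptides(n, 8, 12, seed = 31)  # unused by the builder
  cv <- cross_validate(
    ds, k = 5,
    builder = function(train) {
      train_classifier(default_specs()$rf,
                       train[, c("id", "f1", "f2", "f3")], train$label,
                       seed = 7)
    },
    scorer = function(model, test) {
      predict_classifier(model, test[, c("id", "f1", "f2", "f3")])$score
    },
    seed = 8, n_boot = 0)
  expect_lt(abs(cv$metrics$ACC - 0.5), 0.15)
})

test_that("all six models clear the permutation null on synthetic signal", {
  ds <- generate_peptides(default_np_spec(n_pos = 60, n_neg = 60), seed = 41)
  feats <- featurize(ds)
  null_acc <- 0.5
  for (kind in names(default_specs())) {
    m <- train_classifier(default_specs()[[kind]], feats, ds$label, seed = 2)
    acc <- mean(predict_classifier(m, feats)$label == ds$label)
    expect_gte(acc, null_acc + 0.2)
  }
})
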
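test_that("metric formulas agree with hand evaluation on an exhaustive grid", {
  for (tp in 0:5) for (tn in 0:5) for (fp in 0:5) for (fn in 0:5) {
    if (tp + tn + fp + fn == 0) next
    m <- np_metrics(confusion_counts(
      truth = rep(c(1, 0, 0, 1), c(tp, tn, fp, fn)),
      predicted = rep(c(1, 0, 1, 0), c(tp, tn, fp, fn))))
    expect_equal(m$ACC, (tp + tn) / (tp + tn + fp + fn))
    if (tp + fn > 0) expect_equal(m$Sn, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$Sp, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$Precision, tp / (tp + fp))
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    if (den > 0) expect_equal(m$MCC, (tp * tn - fp * fn) / den)
  }
})

test_that("metric edge cases follow the stated conventions", {
  perfect <- np_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(perfect$ACC, 1)
  expect_equal(perfect$MCC, 1)
  expect_equal(perfect$F1, 1)
  allpos <- np_metrics(list(TP = 50, TN = 0, FP = 50, FN = 0))
  expect_equal(allpos$Sn, 1)
  expect_equal(allpos$Sp, 0)
  expect_equal(allpos$ACC, 0.5)
  expect_true("mcc" %in% attr(allpos, "undefined"))
  m <- np_metrics(list(TP = 45, TN = 40, FP = 10, FN = 5))
  expect_equal(m$MCC, 0.7035, tolerance = 1e-4)
  expect_error(np_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("AUC equals exhaustive pairwise concordance and pROC agrees", {
  set.seed(9)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(runif(n), 2)  # ties likely
    r <- roc_auc(scores, labels, n_boot = 0)
    expect_equal(r$auc, oracle_auc(scores, labels))
    expect_equal(r$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE,
                                                direction = "<"))))
  }
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1), n_boot = 0)$auc, 1)
  expect_error(roc_auc(1:4, rep(1, 4), n_boot = 0), "classes")
})

test_that("label-independent scores give AUC near one half", {
  set.seed(21)
  n <- 2000
  labels <- rbinom(n, 1, 0.5)
  scores <- runif(n)
  expect_equal(roc_auc(scores, labels, n_boot = 0)$auc, 0.5,
               tolerance = 0.03)
})

test_that("bootstrap CI is seeded, ordered and brackets the point estimate", {
  set.seed(4)
  labels <- rep(c(0, 1), each = 40)
  scores <- labels + rnorm(80, sd = 0.8)
  r1 <- roc_auc(scores, labels, n_boot = 300, seed = 5)
  r2 <- roc_auc(scores, labels, n_boot = 300, seed = 5)
  expect_identical(r1$ci, r2$ci)
  expect_lte(r1$ci[["lo"]], r1$auc)
  expect_gte(r1$ci[["hi"]], r1$auc)
})

test_that("stratified cross-validation predicts each record exactly once", {
  ds <- tibble::tibble(id = paste0("r", 1:10),
                       sequence = rand_peptides(10, 8, 15, seed = 2),
                       label = rep(c(0L, 1L), 5))
  builder <- function(train) {
    list(mu = mean(nchar(train$sequence[train$label == 1])))
  }
  scorer <- function(model, test) {
    as.numeric(nchar(test$sequence) >= model$mu)
  }
  cv <- cross_validate(ds, k = 5, builder, scorer, seed = 3, n_boot = 0)
  expect_equal(sort(cv$predictions$id), sort(ds$id))
  expect_equal(nrow(cv$predictions), 10)
  # reproducible fold assignment
  cv2 <- cross_validate(ds, k = 5, builder, scorer, seed = 3, n_boot = 0)
  expect_identical(cv$predictions, cv2$predictions)
  # stratification: each fold carries one record of each class
  tabs <- table(cv$predictions$fold, cv$predictions$label)
  expect_true(all(tabs == 1))
  expect_error(cross_validate(ds, k = 6, builder, scorer, seed = 1),
               "at least k")
})

test_that("cv aggregation pools fold predictions", {
  ds <- tibble::tibble(id = paste0("r", 1:20),
                       sequence = rand_peptides(20, 8, 15, seed = 4),
                       label = rep(c(0L, 1L), 10))
  builder <- function(train) NULL
  scorer <- function(model, test) rep(1, nrow(test))  # all-positive predictor
  cv <- cross_validate(ds, k = 5, builder, scorer, seed = 1, n_boot = 0)
  expect_equal(cv$metrics$Sn, 1)
  expect_equal(cv$metrics$Sp, 0)
  expect_equal(cv$metrics$ACC, 0.5)
  g <- glance(cv)
  expect_equal(g$ACC, 0.5)
  expect_equal(nrow(tidy(cv)), 5)
})
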
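# The six handcrafted-feature base classifiers with their published
# hyperparameters.

#' Default base-classifier specifications
#'
#' The six configurations with their published hyperparameters: SVM (RBF,
#' C = 19, gamma = 0.125), KNN (k = 9, inverse-distance weights), decision
#' tree (confidence factor 0.25, mapped to a cost-complexity prune), random
#' forest (300 trees), extra trees (900 trees), XGBoost (150 rounds, depth
#' 5, eta 0.03, subsample 0.6). Min-max feature normalization is applied
#' (and persisted) for the distance/kernel methods (SVM, KNN) only.
#'
#' @return Named list of `npp_classifier_spec` objects
#'   (`svm`, `knn`, `dt`, `rf`, `et`, `xgb`).
#' @export
default_specs <- function() {
  mk <- function(kind, hyper, scaling) {
    structure(list(kind = kind, hyper = hyper, scaling = scaling),
              class = "npp_classifier_spec")
  }
  list(
    svm = mk("svm", list(cost = 19, gamma = 0.125, kernel = "radial"), TRUE),
    knn = mk("knn", list(k = 9L, weight = "inverse_distance"), TRUE),
    dt  = mk("dt",  list(confidence = 0.25, cp = 0.01), FALSE),
    rf  = mk("rf",  list(ntree = 300L), FALSE),
    et  = mk("et",  list(ntree = 900L), FALSE),
    xgb = mk("xgb", list(nrounds = 150L, max_depth = 5L, eta = 0.03,
                         subsample = 0.6), FALSE)
  )
}

.feature_matrix <- function(features) {
  as.matrix(features[, setdiff(names(features), c("id", "label")),
                     drop = FALSE])
}

.svm_fit <- function(X, y, hyper, seed) {
  fit <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                    kernel = hyper$kernel, cost = hyper$cost,
                    gamma = hyper$gamma, scale = FALSE)
  dv_tr <- .svm_dv(fit, X)
  flip <- mean(dv_tr[y == 1]) < mean(dv_tr[y == 0])
  # Platt-style calibration on out-of-fold decision values (seeded folds)
  set.seed(seed)
  k <- 5L
  fold <- integer(length(y))
  for (cl in c(0, 1)) {
    i <- which(y == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  dv_cv <- numeric(length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- e1071::svm(x = X[tr, , drop = FALSE],
                    y = factor(y[tr], levels = c(0, 1)),
                    kernel = hyper$kernel, cost = hyper$cost,
                    gamma = hyper$gamma, scale = FALSE)
    dtr <- .svm_dv(m, X[tr, , drop = FALSE])
    d <- .svm_dv(m, X[!tr, , drop = FALSE])
    if (mean(dtr[y[tr] == 1]) < mean(dtr[y[tr] == 0])) d <- -d
    dv_cv[!tr] <- d
  }
  # separable folds give saturated fits; the sigmoid is still a valid
  # monotone calibration, so the glm warning is expected and silenced
  platt <- suppressWarnings(stats::glm(y ~ dv_cv, family = stats::binomial()))
  list(fit = fit, flip = flip, platt = stats::coef(platt))
}

.svm_dv <- function(fit, X) {
  as.numeric(attr(stats::predict(fit, X, decision.values = TRUE),
                  "decision.values"))
}

#' Train one base classifier
#'
#' For the distance/kernel methods (SVM, KNN) features are min-max
#' normalized to \[0, 1\] on the training ranges (the normalization the
#' published RBF hyperparameters presume; persisted with the model).
#' Tree-based models train on raw features. SVM probabilities come from a
#' Platt-style sigmoid fit on seeded out-of-fold decision values. All
#' stochastic learners are seeded.
#'
#' @param spec An `npp_classifier_spec` from [default_specs()].
#' @param features Feature tibble (`id` first).
#' @param labels 0/1 labels (1 = neuropeptide), both classes present.
#' @param seed Mandatory seed.
#' @return A list of class `npp_classifier`: `spec`, `fit`, `center`/`scale`
#'   (if scaled), `schema_names`.
#' @export
train_classifier <- function(spec, features, labels, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present",
                                   call. = FALSE)
  X <- .feature_matrix(features)
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  ctr <- scl <- NULL
  if (spec$scaling) {
    rng <- apply(X, 2, range)
    ctr <- rng[1, ]
    scl <- rng[2, ] - rng[1, ]
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  set.seed(seed)
  fit <- switch(spec$kind,
    svm = .svm_fit(X, y, spec$hyper, seed),
    knn = list(X = X, y = y, k = spec$hyper$k),
    dt = rpart::rpart(y ~ ., data = data.frame(y = factor(y), X,
                                               check.names = FALSE),
                      method = "class",
                      control = rpart::rpart.control(cp = spec$hyper$cp)),
    rf = randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                    ntree = spec$hyper$ntree),
    et = ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                        num.trees = spec$hyper$ntree,
                        splitrule = "extratrees", num.random.splits = 1L,
                        probability = TRUE, seed = seed, num.threads = 1L),
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = spec$hyper$max_depth,
                    eta = spec$hyper$eta,
                    subsample = spec$hyper$subsample,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = spec$hyper$nrounds, verbose = 0),
    stop("unknown classifier kind: ", spec$kind, call. = FALSE))
  structure(list(spec = spec, fit = fit, center = ctr, scale = scl,
                 schema_names = colnames(.feature_matrix(features)),
                 seed = seed),
            class = "npp_classifier")
}

#' Predict labels and scores with a trained base classifier
#'
#' Scores are class probabilities (trees, KNN, XGBoost) or Platt-calibrated
#' decision values (SVM), always in \[0, 1\]; the label is score >= 0.5.
#' Prediction refuses a feature tibble whose column set differs from the
#' training schema.
#'
#' @param model An `npp_classifier`.
#' @param features Feature tibble with the training columns.
#' @return Tibble with `score` (positive-class probability) and `label`.
#' @export
predict_classifier <- function(model, features) {
  nm <- colnames(.feature_matrix(features))
  if (!identical(nm, model$schema_names)) {
    stop("feature schema mismatch: expected ", length(model$schema_names),
         " columns (", paste(utils::head(model$schema_names, 3), collapse = ", "),
         ", ...), got ", length(nm), call. = FALSE)
  }
  X <- .feature_matrix(features)
  if (!is.null(model$center)) {
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  }
  score <- switch(model$spec$kind,
    svm = {
      dv <- .svm_dv(model$fit$fit, X)
      if (model$fit$flip) dv <- -dv
      as.numeric(stats::plogis(model$fit$platt[1] + model$fit$platt[2] * dv))
    },
    knn = {
      k <- model$fit$k
      apply(X, 1, function(row) {
        d <- sqrt(colSums((t(model$fit$X) - row)^2))
        nn <- order(d)[seq_len(k)]
        w <- 1 / pmax(d[nn], 1e-12)
        sum(w * (model$fit$y[nn] == 1)) / sum(w)
      })
    },
    dt = stats::predict(model$fit, data.frame(X, check.names = FALSE),
                        type = "prob")[, "1"],
    rf = stats::predict(model$fit, X, type = "prob")[, "1"],
    et = stats::predict(model$fit, data = X,
                        num.threads = 1L)$predictions[, "1"],
    xgb = stats::predict(model$fit, xgboost::xgb.DMatrix(X)))
  score <- pmin(pmax(as.numeric(score), 0), 1)
  tibble::tibble(score = score, label = as.integer(score >= 0.5))
}

#' @export
print.npp_classifier <- function(x, ...) {
  cat("Base classifier:", x$spec$kind, "(",
      paste(names(x$spec$hyper), unlist(x$spec$hyper), sep = "=",
            collapse = ", "), ")\n")
  invisible(x)
}
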
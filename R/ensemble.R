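# The shipped majority-vote ensemble: radial SVM + extra trees on the
# handcrafted descriptor matrix (plus composite logistic columns), and the
# CNN branch on skip-gram-embedded k-mer grids.

#' Ensemble training configuration
#'
#' @param descriptor A [descriptor_config()].
#' @param composites List of [composite_spec()]s fitted on the training fold
#'   and appended as feature columns (default: `logistic1` only).
#' @param n_select Optional ReliefF selection size applied to the
#'   handcrafted matrix before the SVM/ET (default `NULL` = keep all
#'   features; weights are then not computed).
#' @param relieff_k ReliefF neighbors when `n_select` is used (default 10).
#' @param embedding_k,embedding_window,embedding_epochs Skip-gram
#'   hyperparameters (k-mer size 3, window 5, epochs 5).
#' @param cnn A [cnn_spec()].
#' @param score_mode Continuous ensemble score for ROC: `"mean"` of the
#'   three calibrated voter scores (default) or `"vote"` fraction.
#' @return List of class `npp_ensemble_config`.
#' @export
ensemble_config <- function(descriptor = descriptor_config(),
                            composites = list(logistic1_spec()),
                            n_select = NULL, relieff_k = 10L,
                            embedding_k = 3L, embedding_window = 5L,
                            embedding_epochs = 5L,
                            cnn = cnn_spec(),
                            score_mode = c("mean", "vote")) {
  structure(list(descriptor = descriptor, composites = composites,
                 n_select = n_select, relieff_k = as.integer(relieff_k),
                 embedding_k = as.integer(embedding_k),
                 embedding_window = as.integer(embedding_window),
                 embedding_epochs = as.integer(embedding_epochs),
                 cnn = cnn, score_mode = match.arg(score_mode)),
            class = "npp_ensemble_config")
}

#' Hard majority vote of the three base labels
#'
#' With three voters and two classes a tie is impossible.
#'
#' @param l_svm,l_et,l_cnn 0/1 label vectors of equal length.
#' @return Tibble with `label` (majority) and `vote_fraction`
#'   (positives / 3, in 0, 1/3, 2/3, 1).
#' @export
vote <- function(l_svm, l_et, l_cnn) {
  stopifnot(length(l_svm) == length(l_et), length(l_et) == length(l_cnn))
  npos <- as.integer(l_svm) + as.integer(l_et) + as.integer(l_cnn)
  tibble::tibble(label = as.integer(npos >= 2L), vote_fraction = npos / 3)
}

#' Fit the SVM + extra-trees + CNN majority-vote ensemble
#'
#' Pipeline (all on the supplied training set): featurize; fit the
#' composite logistic features and append their columns; optionally reduce
#' to a ReliefF-selected subset; train the SVM and extra-trees voters; in
#' parallel train the skip-gram embedding and the CNN voter on the same
#' records. Every seed is derived from `seed` and recorded in the manifest.
#'
#' Raw descriptors are a pure per-record function of the sequence, so a
#' precomputed descriptor tibble may be passed via `features` (e.g. sliced
#' from a whole-dataset cache during cross-validation); everything that
#' learns from labels (composites, scaling, selection, the models) is always
#' fitted inside this call.
#'
#' @param train Labelled peptide dataset tibble (both classes).
#' @param config An [ensemble_config()].
#' @param seed Mandatory base seed.
#' @param features Optional precomputed raw descriptor tibble for exactly
#'   the records of `train` (same order), as returned by [featurize()] with
#'   `config$descriptor`.
#' @return A list of class `npp_ensemble` with components `svm`, `et`,
#'   `cnn`, `embedding`, `composites`, `feature_names`, `config`,
#'   `manifest`.
#' @export
fit_ensemble <- function(train, config = ensemble_config(), seed,
                         features = NULL) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  .assert_labelled(train)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("ensemble stage '", what, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  feats <- if (is.null(features)) {
    stage("featurize", featurize(train, config$descriptor))
  } else {
    stopifnot(identical(features$id, train$id))
    features
  }
  comps <- list()
  for (cs in config$composites) {
    cm <- stage(paste0("composite:", cs$name),
                fit_composite(feats, train$label, cs))
    feats <- apply_composite(cm, feats)
    comps[[cs$name]] <- cm
  }
  selected <- NULL
  if (!is.null(config$n_select)) {
    w <- stage("relieff",
               relieff_scores(feats, train$label,
                              k_neighbors = config$relieff_k, seed = seed + 1L))
    selected <- select_top(w, config$n_select)
    feats <- feats[, c("id", selected)]
  }
  svm <- stage("svm", train_classifier(default_specs()$svm, feats,
                                       train$label, seed = seed + 2L))
  et <- stage("et", train_classifier(default_specs()$et, feats,
                                     train$label, seed = seed + 3L))
  emb <- stage("embedding",
               train_embedding(train, k = config$embedding_k,
                               window = config$embedding_window,
                               epochs = config$embedding_epochs,
                               seed = seed + 4L))
  cnn <- stage("cnn", train_cnn(train, emb, config$cnn, seed = seed + 5L))
  manifest <- list(
    package = "nppred", version = as.character(utils::packageVersion("nppred")),
    n_train = nrow(train), n_pos = sum(train$label == 1L),
    seeds = list(base = seed, relieff = seed + 1L, svm = seed + 2L,
                 et = seed + 3L, embedding = seed + 4L, cnn = seed + 5L),
    score_mode = config$score_mode,
    n_features = length(setdiff(names(feats), "id")),
    composites = names(comps),
    cnn_max_len = cnn$spec$max_len
  )
  structure(list(svm = svm, et = et, cnn = cnn, embedding = emb,
                 composites = comps, selected = selected,
                 feature_names = setdiff(names(feats), "id"),
                 config = config, manifest = manifest),
            class = "npp_ensemble")
}

.ensemble_features <- function(model, ds, features = NULL) {
  feats <- if (is.null(features)) {
    featurize(ds, model$config$descriptor)
  } else {
    stopifnot(identical(features$id, ds$id))
    features
  }
  for (cm in model$composites) feats <- apply_composite(cm, feats)
  feats[, c("id", model$feature_names)]
}

#' Predict with a fitted ensemble
#'
#' One row per record: per-voter labels and scores, the hard-majority label,
#' the vote fraction, and the continuous ensemble score (mean of the three
#' voter scores by default, selectable to the vote fraction via the
#' config's `score_mode`).
#'
#' @param model An `npp_ensemble`.
#' @param ds Peptide dataset tibble.
#' @param features Optional precomputed raw descriptor tibble for the
#'   records of `ds` (same order).
#' @return Tibble `id`, `label`, `vote_fraction`, `score_svm`, `score_et`,
#'   `score_cnn`, `score_ensemble`.
#' @export
predict_ensemble <- function(model, ds, features = NULL) {
  feats <- .ensemble_features(model, ds, features)
  p_svm <- predict_classifier(model$svm, feats)
  p_et <- predict_classifier(model$et, feats)
  s_cnn <- cnn_predict(model$cnn, ds, model$embedding)
  l_cnn <- as.integer(s_cnn >= 0.5)
  v <- vote(p_svm$label, p_et$label, l_cnn)
  score <- if (model$config$score_mode == "mean") {
    (p_svm$score + p_et$score + s_cnn) / 3
  } else {
    v$vote_fraction
  }
  tibble::tibble(id = ds$id, label = v$label,
                 vote_fraction = v$vote_fraction,
                 score_svm = p_svm$score, score_et = p_et$score,
                 score_cnn = s_cnn, score_ensemble = score)
}

#' Save / load an ensemble bundle
#'
#' The bundle is a directory holding a JSON manifest (config summary and
#' seeds, human-readable) and the serialized model state.
#'
#' @param model An `npp_ensemble`.
#' @param path Bundle directory (created if needed).
#' @return `path` (save) or the restored `npp_ensemble` (load).
#' @export
save_ensemble <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(model$manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(model, file.path(path, "model.rds"))
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  m <- readRDS(file.path(path, "model.rds"))
  stopifnot(inherits(m, "npp_ensemble"))
  m
}

#' @export
print.npp_ensemble <- function(x, ...) {
  cat("Majority-vote ensemble (SVM + extra trees + CNN)\n")
  cat("  features:", length(x$feature_names),
      "| composites:", paste(names(x$composites), collapse = ", "), "\n")
  cat("  CNN stopped at epoch", x$cnn$log$best_epoch,
      "| embedding vocab", nrow(x$embedding$vectors), "\n")
  invisible(x)
}

#' Stratified cross-validation of the full ensemble
#'
#' Runs [cross_validate()] with [fit_ensemble()] as the builder and the
#' ensemble score as the pooled statistic. Raw descriptors are computed once
#' for the whole dataset (they are a label-free per-record function) and
#' sliced per fold; composites, scaling and all models are refitted inside
#' every training fold, and the embedding and CNN are retrained per fold.
#'
#' @param ds Labelled peptide dataset tibble.
#' @param k Folds (default 10).
#' @param config An [ensemble_config()].
#' @param seed Mandatory seed (fold assignment and all per-fold seeds).
#' @param n_boot Bootstrap replicates for the pooled AUC CI.
#' @return An `npp_cv` object (see [cross_validate()]).
#' @export
cv_ensemble <- function(ds, k = 10L, config = ensemble_config(), seed,
                        n_boot = 1000L) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  cache <- featurize(ds, config$descriptor)
  slice <- function(sub) cache[match(sub$id, cache$id), , drop = FALSE]
  cross_validate(
    ds, k = k,
    builder = function(train) {
      fit_ensemble(train, config, seed = seed + 100L, features = slice(train))
    },
    scorer = function(model, test) {
      predict_ensemble(model, test, features = slice(test))$score_ensemble
    },
    seed = seed, n_boot = n_boot)
}

#' @export
glance.npp_ensemble <- function(x, ...) {
  tibble::tibble(n_features = length(x$feature_names),
                 n_train = x$manifest$n_train,
                 n_pos = x$manifest$n_pos,
                 cnn_epoch = x$cnn$log$best_epoch,
                 score_mode = x$config$score_mode)
}
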
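# Confusion-matrix metrics, ROC/AUC and stratified cross-validation.

#' Confusion counts from labels and predictions
#'
#' @param truth 0/1 vector of reference labels (1 = positive class).
#' @param predicted 0/1 vector of predicted labels.
#' @return A named list `TP`, `TN`, `FP`, `FN` of class `npp_confusion`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  out <- list(
    TP = sum(truth == 1 & predicted == 1),
    TN = sum(truth == 0 & predicted == 0),
    FP = sum(truth == 0 & predicted == 1),
    FN = sum(truth == 1 & predicted == 0)
  )
  structure(out, class = "npp_confusion")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision, Matthews
#' correlation coefficient and F1, by their standard confusion-count
#' formulas. A metric whose denominator is zero is reported as 0 and listed
#' in the `undefined` field.
#'
#' @param counts An `npp_confusion` list (or anything with fields
#'   TP/TN/FP/FN).
#' @return A tibble row with the six metrics plus the counts; the
#'   `undefined` attribute names metrics with empty denominators.
#' @export
np_metrics <- function(counts) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  n <- tp + tn + fp + fn
  if (n == 0) stop("all confusion counts are zero", call. = FALSE)
  undef <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) {
      undef <<- c(undef, what)
      return(0)
    }
    num / den
  }
  acc <- (tp + tn) / n
  sn <- safe(tp, tp + fn, "sensitivity")
  sp <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) {
    undef <- c(undef, "mcc"); 0
  } else (tp * tn - fp * fn) / mcc_den
  f1 <- if (prec + sn == 0) {
    undef <- c(undef, "f1"); 0
  } else 2 * prec * sn / (prec + sn)
  out <- tibble::tibble(ACC = acc, Sn = sn, Sp = sp, Precision = prec,
                        MCC = mcc, F1 = f1,
                        TP = tp, TN = tn, FP = fp, FN = fn)
  attr(out, "undefined") <- undef
  out
}

.auc_rank <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' AUC is the rank statistic (equivalently the trapezoid over the full
#' threshold sweep, ties mid-ranked); the confidence interval is a seeded
#' percentile bootstrap over records.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels 0/1 reference labels, both classes present.
#' @param n_boot Bootstrap replicates (default 1000; 0 skips the CI).
#' @param seed Seed for the bootstrap (required when `n_boot > 0`).
#' @param conf Confidence level (default 0.95).
#' @return List of class `npp_roc`: `auc`, `ci` (lo/hi or NULL), and `roc`
#'   (tibble `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, labels, n_boot = 1000L, seed = NULL, conf = 0.95) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present",
                                        call. = FALSE)
  auc <- .auc_rank(scores, labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  roc <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores >= t & labels == 1) / np, numeric(1)),
    fpr = vapply(thr, function(t) sum(scores >= t & labels == 0) / nn, numeric(1))
  )
  ci <- NULL
  if (n_boot > 0) {
    if (is.null(seed)) stop("`seed` is required for the bootstrap CI",
                            call. = FALSE)
    set.seed(seed)
    n <- length(scores)
    reps <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[i])) < 2L) return(NA_real_)
      .auc_rank(scores[i], labels[i])
    }, numeric(1))
    qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    ci <- c(lo = qs[1], hi = qs[2])
  }
  structure(list(auc = auc, ci = ci, roc = roc), class = "npp_roc")
}

#' Stratified k-fold cross-validation
#'
#' Splits the labelled dataset into `k` stratified folds (seeded), calls
#' `builder(train)` to obtain a fitted model for each training fold, calls
#' `scorer(model, test)` for held-out scores, and pools the fold predictions
#' into one evaluation. All fitting (composites, scaling, selection,
#' sub-models) must happen inside `builder`.
#'
#' @param ds Labelled peptide dataset tibble (>= k records per class).
#' @param k Number of folds (default 10).
#' @param builder Function `train_ds -> model`.
#' @param scorer Function `(model, test_ds) -> numeric scores in [0, 1]`.
#' @param seed Seed controlling fold assignment (mandatory).
#' @param threshold Score threshold for the positive label (default 0.5).
#' @param n_boot Bootstrap replicates for the pooled AUC CI (default 1000).
#' @return List of class `npp_cv`: `metrics` (pooled tibble row), `auc`,
#'   `auc_ci`, `folds` (per-fold metric tibble), `predictions` (tibble with
#'   id, fold, label, score).
#' @export
cross_validate <- function(ds, k = 10L, builder, scorer, seed,
                           threshold = 0.5, n_boot = 1000L) {
  .assert_labelled(ds)
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  tab <- table(ds$label)
  if (any(tab < k)) stop("each class needs at least k = ", k, " records",
                         call. = FALSE)
  set.seed(seed)
  fold <- integer(nrow(ds))
  for (cl in unique(ds$label)) {
    i <- which(ds$label == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- ds[fold != f, , drop = FALSE]
    test <- ds[fold == f, , drop = FALSE]
    model <- builder(train)
    sc <- scorer(model, test)
    preds[[f]] <- tibble::tibble(id = test$id, fold = f, label = test$label,
                                 score = as.numeric(sc))
  }
  preds <- dplyr::bind_rows(preds)
  pred_lab <- as.integer(preds$score >= threshold)
  pooled <- np_metrics(confusion_counts(preds$label, pred_lab))
  roc <- roc_auc(preds$score, preds$label, n_boot = n_boot, seed = seed + 1L)
  folds <- dplyr::bind_rows(lapply(seq_len(k), function(f) {
    p <- preds[preds$fold == f, ]
    m <- np_metrics(confusion_counts(p$label, as.integer(p$score >= threshold)))
    dplyr::bind_cols(tibble::tibble(fold = f), m)
  }))
  structure(list(metrics = pooled, auc = roc$auc, auc_ci = roc$ci,
                 folds = folds, predictions = preds, roc = roc),
            class = "npp_cv")
}

#' @export
print.npp_cv <- function(x, ...) {
  cat("Stratified cross-validation (", max(x$predictions$fold), " folds, ",
      nrow(x$predictions), " pooled predictions)\n", sep = "")
  m <- x$metrics
  cat(sprintf("  ACC %.3f  Sn %.3f  Sp %.3f  MCC %.3f  F1 %.3f  AUC %.3f",
              m$ACC, m$Sn, m$Sp, m$MCC, m$F1, x$auc))
  if (!is.null(x$auc_ci)) {
    cat(sprintf("  [%.3f-%.3f]", x$auc_ci["lo"], x$auc_ci["hi"]))
  }
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.npp_cv <- function(x, ...) x$folds

#' @export
glance.npp_cv <- function(x, ...) {
  dplyr::bind_cols(x$metrics[, c("ACC", "Sn", "Sp", "Precision", "MCC", "F1")],
                   tibble::tibble(AUC = x$auc,
                                  AUC_lo = if (is.null(x$auc_ci)) NA_real_ else x$auc_ci[["lo"]],
                                  AUC_hi = if (is.null(x$auc_ci)) NA_real_ else x$auc_ci[["hi"]]))
}

#' @export
tidy.npp_roc <- function(x, ...) x$roc

#' @export
glance.npp_roc <- function(x, ...) {
  tibble::tibble(AUC = x$auc,
                 AUC_lo = if (is.null(x$ci)) NA_real_ else x$ci[["lo"]],
                 AUC_hi = if (is.null(x$ci)) NA_real_ else x$ci[["hi"]])
}
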
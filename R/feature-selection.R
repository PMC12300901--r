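# ReliefF relevance weighting and the Pearson redundancy screen.

#' ReliefF feature weights
#'
#' Standard ReliefF for binary (or multi-class) labels: features are min-max
#' scaled for the diff function, neighbors are found by Manhattan distance on
#' the scaled features, and each iteration penalizes separation from the k
#' nearest same-class neighbors ("hits") and rewards separation from the k
#' nearest neighbors of each other class ("misses", weighted by class
#' prior). Weights are averaged over iterations and neighbors.
#'
#' @param features Feature tibble (`id` first) or numeric matrix.
#' @param labels Class labels aligned to rows.
#' @param k_neighbors Neighbors per class (default 10).
#' @param n_iterations Instances sampled (default `NULL` = all records, in
#'   which case the result is deterministic and seed-independent).
#' @param seed Mandatory seed (used when sampling a subset of instances).
#' @return Tibble of class `npp_relief`: `feature`, `weight`, `rank`.
#' @export
relieff_scores <- function(features, labels, k_neighbors = 10L,
                           n_iterations = NULL, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  X <- if (is.data.frame(features)) {
    as.matrix(features[, setdiff(names(features), "id"), drop = FALSE])
  } else as.matrix(features)
  y <- as.vector(labels)
  n <- nrow(X)
  stopifnot(length(y) == n)
  tab <- table(y)
  if (length(tab) < 2L) stop("both classes must be present", call. = FALSE)
  if (any(tab < k_neighbors + 1L)) {
    stop("every class needs at least k_neighbors + 1 = ", k_neighbors + 1L,
         " records", call. = FALSE)
  }
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1  # constant features: diff is 0 everywhere
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  set.seed(seed)
  idx <- if (is.null(n_iterations) || n_iterations >= n) seq_len(n) else {
    sample.int(n, n_iterations)
  }
  m <- length(idx)
  prior <- as.numeric(tab) / n
  names(prior) <- names(tab)
  W <- numeric(ncol(X))
  D <- as.matrix(stats::dist(Xs, method = "manhattan"))
  for (i in idx) {
    same <- which(y == y[i]); same <- same[same != i]
    hits <- same[order(D[i, same])][seq_len(k_neighbors)]
    hit_diff <- colMeans(abs(Xs[hits, , drop = FALSE] -
                               matrix(Xs[i, ], k_neighbors, ncol(X), byrow = TRUE)))
    W <- W - hit_diff / m
    p_self <- prior[[as.character(y[i])]]
    for (cl in setdiff(names(tab), as.character(y[i]))) {
      other <- which(as.character(y) == cl)
      miss <- other[order(D[i, other])][seq_len(k_neighbors)]
      miss_diff <- colMeans(abs(Xs[miss, , drop = FALSE] -
                                  matrix(Xs[i, ], k_neighbors, ncol(X), byrow = TRUE)))
      W <- W + (prior[[cl]] / (1 - p_self)) * miss_diff / m
    }
  }
  out <- tibble::tibble(feature = colnames(X), weight = W)
  out$rank <- rank(-out$weight, ties.method = "first")
  class(out) <- c("npp_relief", class(out))
  out
}

#' Select the top-n features by ReliefF weight
#'
#' Ties are broken by schema (input) order.
#'
#' @param weights An `npp_relief` tibble from [relieff_scores()].
#' @param n Number of features to keep (1..number of features).
#' @return Character vector of n feature names, ordered by decreasing weight.
#' @export
select_top <- function(weights, n) {
  if (n < 1L || n > nrow(weights)) {
    stop("`n` must be in 1..", nrow(weights), call. = FALSE)
  }
  ord <- order(-weights$weight, seq_len(nrow(weights)))
  weights$feature[ord][seq_len(n)]
}

#' Pearson correlation redundancy screen
#'
#' Computes Pearson r over records for every feature pair and reports pairs
#' with `|r| >= threshold`. Constant features (undefined r) are reported
#' separately. The total pair count is n(n-1)/2 for n features.
#'
#' @param features Feature tibble (`id` first) or numeric matrix.
#' @param threshold Absolute correlation threshold (default 0.8).
#' @return List of class `npp_corr_screen`: `pairs` (tibble `feature_a`,
#'   `feature_b`, `r`), `n_features`, `total_pairs`, `high_pairs`,
#'   `constant_features`.
#' @export
correlation_screen <- function(features, threshold = 0.8) {
  X <- if (is.data.frame(features)) {
    as.matrix(features[, setdiff(names(features), "id"), drop = FALSE])
  } else as.matrix(features)
  if (nrow(X) < 2L) stop("need at least 2 records", call. = FALSE)
  p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  const <- colnames(X)[sds == 0]
  suppressWarnings(r <- stats::cor(X))
  r[!is.finite(r)] <- NA
  hit <- which(abs(r) >= threshold & upper.tri(r), arr.ind = TRUE)
  pairs <- tibble::tibble(
    feature_a = colnames(X)[hit[, 1]],
    feature_b = colnames(X)[hit[, 2]],
    r = r[hit]
  )
  structure(list(pairs = pairs, n_features = p,
                 total_pairs = p * (p - 1) / 2,
                 high_pairs = nrow(pairs),
                 constant_features = const,
                 threshold = threshold),
            class = "npp_corr_screen")
}

#' @export
print.npp_corr_screen <- function(x, ...) {
  cat("Correlation screen: ", x$n_features, " features, ", x$total_pairs,
      " pairs; ", x$high_pairs, " with |r| >= ", x$threshold, sep = "")
  if (length(x$constant_features)) {
    cat(" (", length(x$constant_features), " constant feature(s) excluded)",
        sep = "")
  }
  cat("\n")
  invisible(x)
}
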
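# Dataset algebra, identity-based redundancy filtering and train/test
# leakage screening.

# Global (Needleman-Wunsch) alignment identity with the shorter-sequence
# denominator (the convention of greedy identity-clustering tools).
.identity_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      a <- aa_alphabet()
      mm <- matrix(-1, 20, 20, dimnames = list(a, a))
      diag(mm) <- 2
      m <<- mm
    }
    m
  }
})

#' Pairwise global-alignment identity
#'
#' Identity = number of matched (identical) aligned positions of the optimal
#' global alignment, divided by the length of the shorter sequence.
#'
#' @param a,b Sequences (character).
#' @return Identity in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = .identity_matrix(), gapOpening = 5, gapExtension = 2)
  Biostrings::nmatch(aln) / min(nchar(a), nchar(b))
}

#' Combine training sets and subtract test sets (exact-sequence algebra)
#'
#' `result = (seqs(d1) u seqs(d2)) \ (seqs(t1) u seqs(t2))` with
#' exact-sequence set semantics: duplicate sequences within the union
#' collapse to one record (first id kept); a sequence carrying conflicting
#' labels is an error.
#'
#' @param d1,d2 Training peptide dataset tibbles.
#' @param t1,t2 Test peptide dataset tibbles (may be empty tibbles).
#' @return A peptide dataset tibble; provenance recorded in the
#'   `"provenance"` attribute.
#' @export
combine_and_subtract <- function(d1, d2, t1 = NULL, t2 = NULL) {
  d <- dplyr::bind_rows(d1, d2)
  if (nrow(d)) {
    conf <- d |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(n_lab = if ("label" %in% names(d)) {
        dplyr::n_distinct(.data$label)
      } else 1L, .groups = "drop") |>
      dplyr::filter(.data$n_lab > 1L)
    if (nrow(conf)) {
      stop("conflicting labels for ", nrow(conf), " sequence(s), e.g. '",
           substr(conf$sequence[1], 1, 20), "...'", call. = FALSE)
    }
    d <- d[!duplicated(d$sequence), , drop = FALSE]
  }
  test_seqs <- unique(c(if (!is.null(t1)) t1$sequence,
                        if (!is.null(t2)) t2$sequence))
  out <- d[!(d$sequence %in% test_seqs), , drop = FALSE]
  attr(out, "provenance") <- "combine_and_subtract"
  out
}

#' Greedy redundancy filtering at an identity threshold
#'
#' Incremental longest-first clustering: sequences are sorted by decreasing
#' length; each sequence joins the first existing representative with
#' global-alignment identity >= `threshold` (shorter-sequence denominator),
#' otherwise it founds a new cluster. The filter is idempotent.
#'
#' @param ds Peptide dataset tibble.
#' @param threshold Identity threshold (default 0.90).
#' @return List of class `npp_cluster`: `representatives` (peptide dataset),
#'   `map` (tibble `member_id`, `representative_id`, `identity`), and
#'   `threshold`.
#' @export
redundancy_filter <- function(ds, threshold = 0.90) {
  ord <- order(-nchar(ds$sequence), ds$id)
  reps <- integer(0)  # row indices of representatives, in founding order
  map <- vector("list", nrow(ds))
  for (i in ord) {
    joined <- FALSE
    for (r in reps) {
      idn <- pairwise_identity(ds$sequence[[i]], ds$sequence[[r]])
      if (idn >= threshold) {
        map[[i]] <- tibble::tibble(member_id = ds$id[[i]],
                                   representative_id = ds$id[[r]],
                                   identity = idn)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      map[[i]] <- tibble::tibble(member_id = ds$id[[i]],
                                 representative_id = ds$id[[i]],
                                 identity = 1)
    }
  }
  keep <- sort(reps)
  structure(list(representatives = ds[keep, , drop = FALSE],
                 map = dplyr::bind_rows(map),
                 threshold = threshold),
            class = "npp_cluster")
}

#' @export
print.npp_cluster <- function(x, ...) {
  cat("Redundancy filter at ", x$threshold * 100, "% identity: ",
      nrow(x$map), " sequences -> ", nrow(x$representatives),
      " representatives\n", sep = "")
  invisible(x)
}

# Karlin-Altschul parameters for gapped BLOSUM62 (gap open 11, extend 1),
# the standard protein-search setting.
.ka_lambda <- 0.267
.ka_k <- 0.041

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <<- env$BLOSUM62
    }
    m
  }
})

#' Best local-alignment hit of one query against a database
#'
#' Affine-gap Smith-Waterman (BLOSUM62, gap open 11 / extend 1) against
#' every database sequence; the E-value of the best hit uses the standard
#' Karlin-Altschul approximation `E = K m n exp(-lambda S)` with `m` the
#' total database residue count.
#'
#' @param query Query sequence.
#' @param db Character vector of database sequences.
#' @return List: `best_index`, `score`, `evalue`, `identity` (percent of
#'   aligned columns that match).
#' @export
best_local_hit <- function(query, db) {
  alns <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(db), Biostrings::AAString(query), type = "local",
    substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1)
  scores <- Biostrings::score(alns)
  best <- which.max(scores)
  s <- scores[best]
  width <- Biostrings::nchar(Biostrings::pattern(alns[best]))
  idn <- if (width > 0) {
    Biostrings::nmatch(alns[best]) / width * 100
  } else 0
  m <- sum(nchar(db))
  list(best_index = best, score = s,
       evalue = .ka_k * m * nchar(query) * exp(-.ka_lambda * s),
       identity = idn)
}

#' Train/test leakage screen
#'
#' Searches every test sequence against the training set with the built-in
#' local aligner and reports, per query, the best-hit identity and E-value,
#' plus the fraction of queries with a significant hit and the identity
#' range among significant hits.
#'
#' @param train,test Peptide dataset tibbles (both non-empty).
#' @param significance E-value cutoff (default 1e-5).
#' @return List of class `npp_leakage`: `hits` (tibble `id`, `best_train_id`,
#'   `score`, `evalue`, `identity`, `significant`), `fraction_significant`,
#'   `max_identity`.
#' @export
leakage_screen <- function(train, test, significance = 1e-5) {
  if (!nrow(train) || !nrow(test)) stop("both datasets must be non-empty",
                                        call. = FALSE)
  rows <- lapply(seq_len(nrow(test)), function(i) {
    h <- best_local_hit(test$sequence[[i]], train$sequence)
    tibble::tibble(id = test$id[[i]],
                   best_train_id = train$id[[h$best_index]],
                   score = h$score, evalue = h$evalue, identity = h$identity,
                   significant = h$evalue <= significance)
  })
  hits <- dplyr::bind_rows(rows)
  structure(list(hits = hits,
                 fraction_significant = mean(hits$significant),
                 max_identity = max(hits$identity),
                 significance = significance),
            class = "npp_leakage")
}

#' @export
print.npp_leakage <- function(x, ...) {
  cat(sprintf(
    "Leakage screen: %.1f%% of %d queries significant at E <= %g; max identity %.1f%%\n",
    x$fraction_significant * 100, nrow(x$hits), x$significance,
    x$max_identity))
  invisible(x)
}
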
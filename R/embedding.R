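# K-mer tokenization, skip-gram embedding and sequence encoding for the
# deep-learning branch.

#' Tokenize a sequence into overlapping k-mers
#'
#' @param seq Canonical sequence of length >= k.
#' @param k K-mer size (default 3).
#' @return Character vector of L - k + 1 tokens in sequence order.
#' @export
tokenize_kmers <- function(seq, k = 3L) {
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k = ", k, call. = FALSE)
  substring(seq, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

#' Train a skip-gram k-mer embedding
#'
#' Word2vec-style skip-gram with negative sampling over the k-mer token
#' streams of a corpus. Every k-mer observed in the corpus receives a
#' `dim`-dimensional vector; unseen k-mers map to the zero vector at
#' encoding time.
#'
#' @param corpus Peptide dataset tibble (non-empty).
#' @param k K-mer size (default 3).
#' @param dim Embedding dimension (default 120).
#' @param window Maximum context window (default 5).
#' @param epochs Training epochs (default 5).
#' @param negative Negative samples per positive pair (default 5).
#' @param lr Initial learning rate (default 0.025, linearly decayed).
#' @param seed Mandatory seed.
#' @return List of class `npp_embedding`: `k`, `dim`, `vectors` (vocab x dim
#'   matrix with k-mer rownames), and the training hyperparameters.
#' @export
train_embedding <- function(corpus, k = 3L, dim = 120L, window = 5L,
                            epochs = 5L, negative = 5L, lr = 0.025, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (!nrow(corpus)) stop("empty corpus", call. = FALSE)
  toks <- lapply(corpus$sequence, tokenize_kmers, k = k)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  ids <- lapply(toks, function(t) match(t, vocab) - 1L)
  vec <- .cpp_sg_train(ids, length(vocab), as.integer(dim),
                       as.integer(window), as.integer(epochs), lr,
                       as.integer(negative), as.integer(seed))
  rownames(vec) <- vocab
  structure(list(k = as.integer(k), dim = as.integer(dim), vectors = vec,
                 window = as.integer(window), epochs = as.integer(epochs),
                 negative = as.integer(negative), lr = lr, seed = seed),
            class = "npp_embedding")
}

#' @export
print.npp_embedding <- function(x, ...) {
  cat("Skip-gram k-mer embedding: k =", x$k, ", dim =", x$dim,
      ", vocabulary", nrow(x$vectors), "\n")
  invisible(x)
}

#' Encode a sequence as an embedded token grid
#'
#' Rows 1..(L-k+1) hold the embedding vectors of the sequence's k-mers;
#' remaining rows are zero padding. Sequences with more than `max_len`
#' tokens are truncated from the C-terminal end. Out-of-vocabulary tokens
#' become zero rows.
#'
#' @param seq Canonical sequence.
#' @param emb An `npp_embedding`.
#' @param max_len Number of grid rows.
#' @return A `max_len` x `dim` numeric matrix.
#' @export
encode_sequence <- function(seq, emb, max_len = 100L) {
  toks <- tokenize_kmers(seq, emb$k)
  if (length(toks) > max_len) toks <- toks[seq_len(max_len)]
  grid <- matrix(0, nrow = max_len, ncol = emb$dim)
  hit <- match(toks, rownames(emb$vectors))
  ok <- !is.na(hit)
  if (any(ok)) grid[which(ok), ] <- emb$vectors[hit[ok], , drop = FALSE]
  grid
}

.encode_dataset <- function(ds, emb, max_len) {
  lapply(ds$sequence, encode_sequence, emb = emb, max_len = max_len)
}

#' CNN architecture and training specification
#'
#' Defaults follow the published configuration: two convolutional layers
#' (64 then 32 filters, kernel size 3), max pooling (size 2) after each, a
#' 32-unit dense layer with ReLU, dropout 0.3, a single sigmoid output,
#' Adam with learning rate 1e-4, up to 100 epochs with early stopping.
#'
#' @param filters1,filters2 Convolution filters (64, 32).
#' @param dense Dense units (32).
#' @param dropout Dropout rate (0.3).
#' @param lr Adam learning rate (1e-4).
#' @param max_epochs Epoch cap (100).
#' @param patience Early-stopping patience in epochs (10).
#' @param batch_size Mini-batch size (16).
#' @param max_len Token grid rows; `NULL` (default) adapts to the training
#'   corpus (its maximum token count, capped at 100).
#' @param val_fraction Stratified validation split for early stopping (0.1).
#' @return A list of class `npp_cnn_spec`.
#' @export
cnn_spec <- function(filters1 = 64L, filters2 = 32L, dense = 32L,
                     dropout = 0.3, lr = 1e-4, max_epochs = 100L,
                     patience = 10L, batch_size = 16L, max_len = NULL,
                     val_fraction = 0.1) {
  structure(list(filters1 = as.integer(filters1),
                 filters2 = as.integer(filters2), kernel = 3L,
                 dense = as.integer(dense), dropout = dropout, lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 max_len = if (is.null(max_len)) NULL else as.integer(max_len),
                 val_fraction = val_fraction),
            class = "npp_cnn_spec")
}

#' Train the CNN branch on embedded sequences
#'
#' Splits the training records into a stratified train/validation partition
#' (for early stopping), trains with Adam on binary cross-entropy, and
#' restores the weights of the best validation epoch.
#'
#' @param ds Labelled peptide dataset tibble (>= 2 records per class).
#' @param emb An `npp_embedding` trained on the same training partition.
#' @param spec A [cnn_spec()].
#' @param seed Mandatory seed (weight init, shuffling, dropout, split).
#' @return List of class `npp_cnn`: `spec` (with resolved `max_len`),
#'   `weights`, `embedding_k`, `log` (per-epoch train/validation loss and
#'   stopping epoch).
#' @export
train_cnn <- function(ds, emb, spec = cnn_spec(), seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  .assert_labelled(ds)
  if (any(table(ds$label) < 2L)) stop(">= 2 records per class required",
                                      call. = FALSE)
  max_len <- spec$max_len
  if (is.null(max_len)) {
    max_len <- min(100L, max(nchar(ds$sequence)) - emb$k + 1L)
  }
  max_len <- max(max_len, 12L)  # two conv/pool stages need >= 12 rows
  set.seed(seed)
  val_idx <- unlist(lapply(split(seq_len(nrow(ds)), ds$label), function(i) {
    sample(i, max(1L, round(length(i) * spec$val_fraction)))
  }), use.names = FALSE)
  tr <- setdiff(seq_len(nrow(ds)), val_idx)
  Xtr <- .encode_dataset(ds[tr, ], emb, max_len)
  Xva <- .encode_dataset(ds[val_idx, ], emb, max_len)
  fit <- .cpp_cnn_train(Xtr, as.numeric(ds$label[tr]), Xva,
                        as.numeric(ds$label[val_idx]),
                        emb$dim, spec$filters1, spec$filters2, spec$dense,
                        spec$dropout, spec$lr, spec$max_epochs,
                        spec$patience, spec$batch_size, as.integer(seed))
  spec$max_len <- as.integer(max_len)
  structure(list(spec = spec, weights = fit$weights,
                 embedding_k = emb$k, emb_dim = emb$dim,
                 log = list(train_loss = fit$train_loss,
                            val_loss = fit$val_loss,
                            best_epoch = fit$best_epoch),
                 seed = seed),
            class = "npp_cnn")
}

#' Predict class probabilities with a trained CNN
#'
#' Inference is deterministic (dropout inactive).
#'
#' @param model An `npp_cnn`.
#' @param ds Peptide dataset tibble.
#' @param emb The `npp_embedding` the model was trained with.
#' @return Numeric vector of probabilities in \[0, 1\] (positive class).
#' @export
cnn_predict <- function(model, ds, emb) {
  if (emb$dim != model$emb_dim || emb$k != model$embedding_k) {
    stop("embedding mismatch: model expects k = ", model$embedding_k,
         ", dim = ", model$emb_dim, call. = FALSE)
  }
  X <- .encode_dataset(ds, emb, model$spec$max_len)
  as.numeric(.cpp_cnn_predict(model$weights, X, model$emb_dim,
                              model$spec$filters1, model$spec$filters2,
                              model$spec$dense))
}

#' @export
print.npp_cnn <- function(x, ...) {
  cat("CNN branch: conv(", x$spec$filters1, ") -> pool -> conv(",
      x$spec$filters2, ") -> pool -> dense(", x$spec$dense,
      "), dropout ", x$spec$dropout, "; stopped at epoch ",
      x$log$best_epoch, "\n", sep = "")
  invisible(x)
}

#' @export
glance.npp_cnn <- function(x, ...) {
  tibble::tibble(filters1 = x$spec$filters1, filters2 = x$spec$filters2,
                 kernel = x$spec$kernel, dense = x$spec$dense,
                 dropout = x$spec$dropout, lr = x$spec$lr,
                 max_len = x$spec$max_len, best_epoch = x$log$best_epoch,
                 final_val_loss = min(unlist(x$log$val_loss)))
}
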
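test_that("k-mer tokenization is an overlapping stride-1 window", {
  expect_equal(tokenize_kmers("ACDEF", 3), c("ACD", "CDE", "DEF"))
  expect_equal(tokenize_kmers("ACD", 3), "ACD")
  expect_error(tokenize_kmers("AC", 3), "shorter than k")
  for (s in rand_peptides(5, 6, 30, seed = 8)) {
    expect_length(tokenize_kmers(s, 3), nchar(s) - 2)
    expect_length(tokenize_kmers(s, 2), nchar(s) - 1)
  }
})

test_that("skip-gram training covers the vocabulary with 120-vectors", {
  ds <- generate_peptides(default_np_spec(n_pos = 15, n_neg = 15), seed = 3)
  emb <- train_embedding(ds, seed = 5)
  expect_equal(ncol(emb$vectors), 120)
  seen <- unique(unlist(lapply(ds$sequence, tokenize_kmers, k = 3)))
  expect_setequal(rownames(emb$vectors), seen)
  # one repeated sequence: vocabulary is its distinct k-mers only
  one <- tibble::tibble(id = c("a", "b"), sequence = rep("ACDEFGH", 2))
  emb1 <- train_embedding(one, seed = 1)
  expect_setequal(rownames(emb1$vectors), tokenize_kmers("ACDEFGH", 3))
  # reproducibility under a fixed seed
  emb2 <- train_embedding(ds, seed = 5)
  expect_identical(emb$vectors, emb2$vectors)
  expect_error(train_embedding(ds[0, ], seed = 1), "empty")
  expect_error(train_embedding(ds), "seed")
})

test_that("co-occurring k-mers embed closer than never-co-occurring ones", {
  # planted context: AAA always flanked by CCC; WWW only ever beside YYY
  set.seed(9)
  mk <- function(core, n) {
    vapply(seq_len(n), function(i) {
      paste0(paste(sample(aa_alphabet(), 6, TRUE), collapse = ""), core,
             paste(sample(aa_alphabet(), 6, TRUE), collapse = ""))
    }, character(1))
  }
  corpus <- tibble::tibble(
    id = paste0("c", 1:80),
    sequence = c(mk("AAACCC", 40), mk("WWWYYY", 40)))
  emb <- train_embedding(corpus, epochs = 20, seed = 13)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  v <- emb$vectors
  expect_gt(cosine(v["AAA", ], v["CCC", ]), cosine(v["AAA", ], v["YYY", ]))
})

test_that("sequence encoding pads, truncates and looks up correctly", {
  ds <- tibble::tibble(id = "x", sequence = "ACDEFGHIKL")
  emb <- train_embedding(ds, seed = 2)
  g <- encode_sequence("ACDEFGHIKL", emb, max_len = 12)
  expect_equal(dim(g), c(12, 120))
  toks <- tokenize_kmers("ACDEFGHIKL", 3)
  for (i in seq_along(toks)) {
    expect_equal(g[i, ], unname(emb$vectors[toks[i], ]))
  }
  expect_equal(g[(length(toks) + 1):12, ], matrix(0, 12 - length(toks), 120))
  # exact fit: no padding, no truncation
  g2 <- encode_sequence("ACDEFGHIKL", emb, max_len = length(toks))
  expect_equal(nrow(g2), length(toks))
  expect_false(any(rowSums(abs(g2)) == 0))
  # truncation keeps the N-terminal tokens
  g3 <- encode_sequence("ACDEFGHIKL", emb, max_len = 4)
  expect_equal(g3, g[1:4, ])
  # out-of-vocabulary tokens become zero rows
  g4 <- encode_sequence("WWWWWW", emb, max_len = 6)
  expect_equal(g4, matrix(0, 6, 120))
})

test_that("the CNN echoes its published architecture and overfits a planted toy", {
  spec <- cnn_spec()
  expect_equal(spec$filters1, 64L)
  expect_equal(spec$filters2, 32L)
  expect_equal(spec$kernel, 3L)
  expect_equal(spec$dense, 32L)
  expect_equal(spec$dropout, 0.3)
  expect_equal(spec$lr, 1e-4)
  expect_equal(spec$max_epochs, 100L)
  set.seed(15)
  mk <- function(core, n, prefix) {
    tibble::tibble(
      id = paste0(prefix, seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        paste0(paste(sample(aa_alphabet(), 8, TRUE), collapse = ""), core,
               paste(sample(aa_alphabet(), 8, TRUE), collapse = ""))
      }, character(1)))
  }
  ds <- dplyr::bind_rows(
    dplyr::mutate(mk("WWWWWW", 30, "p"), label = 1L),
    dplyr::mutate(mk("DDDDDD", 30, "n"), label = 0L))
  emb <- train_embedding(ds, epochs = 10, seed = 7)
  # higher learning rate for the overfit check so it converges in few epochs
  cnn <- train_cnn(ds, emb, cnn_spec(lr = 3e-3, patience = 100L), seed = 7)
  p <- cnn_predict(cnn, ds, emb)
  expect_gte(mean((p >= 0.5) == (ds$label == 1)), 0.95)
  expect_true(all(p >= 0 & p <= 1))
  # inference determinism
  expect_identical(p, cnn_predict(cnn, ds, emb))
  # training log reports the stopping epoch
  expect_gte(cnn$log$best_epoch, 1)
  expect_error(cnn_predict(cnn, ds, train_embedding(ds, k = 2, seed = 1)),
               "mismatch")
})

test_that("early stopping halts when validation loss stops improving", {
  set.seed(16)
  ds <- tibble::tibble(
    id = paste0("r", 1:40),
    sequence = rand_peptides(40, 15, 25, seed = 16),
    label = rep(c(0L, 1L), 20))  # pure noise: nothing to learn
  emb <- train_embedding(ds, seed = 4)
  cnn <- train_cnn(ds, emb, cnn_spec(patience = 3L, max_epochs = 100L),
                   seed = 4)
  n_epochs <- length(unlist(cnn$log$val_loss))
  expect_lt(n_epochs, 100)
  expect_equal(n_epochs, cnn$log$best_epoch + 3)
})

test_that("CNN training is reproducible for a fixed seed", {
  ds <- generate_peptides(default_np_spec(n_pos = 20, n_neg = 20), seed = 21)
  emb <- train_embedding(ds, seed = 9)
  c1 <- train_cnn(ds, emb, cnn_spec(max_epochs = 5L), seed = 9)
  c2 <- train_cnn(ds, emb, cnn_spec(max_epochs = 5L), seed = 9)
  expect_identical(cnn_predict(c1, ds, emb), cnn_predict(c2, ds, emb))
})
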
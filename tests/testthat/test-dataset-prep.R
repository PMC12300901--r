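mk_ds <- function(seqs, prefix = "q", label = NULL) {
  out <- tibble::tibble(id = paste0(prefix, seq_along(seqs)),
                        sequence = seqs)
  if (!is.null(label)) out$label <- label
  out
}

test_that("set algebra: union, dedup, subtraction, conflict detection", {
  d1 <- mk_ds(c("AAAAC", "CCCCA"), "a")
  d2 <- mk_ds(c("CCCCA", "GGGGA"), "b")
  t1 <- mk_ds("GGGGA", "t")
  out <- combine_and_subtract(d1, d2, t1)
  expect_setequal(out$sequence, c("AAAAC", "CCCCA"))
  # disjoint test set: result is the deduplicated union
  out2 <- combine_and_subtract(d1, d2, mk_ds("WWWWW", "t"))
  expect_setequal(out2$sequence, c("AAAAC", "CCCCA", "GGGGA"))
  # conflicting labels on a collapsing sequence
  expect_error(combine_and_subtract(mk_ds("AAAAC", "a", 1L),
                                    mk_ds("AAAAC", "b", 0L)),
               "conflicting labels")
})

test_that("set algebra equals a brute-force oracle on random collections", {
  pool <- rand_peptides(120, 5, 12, seed = 31)
  set.seed(32)
  for (rep in 1:3) {
    d1 <- mk_ds(sample(pool, 80, replace = TRUE), "a")
    d2 <- mk_ds(sample(pool, 80, replace = TRUE), "b")
    t1 <- mk_ds(sample(pool, 30, replace = TRUE), "t")
    t2 <- mk_ds(sample(pool, 30, replace = TRUE), "u")
    out <- combine_and_subtract(d1, d2, t1, t2)
    expected <- setdiff(union(d1$sequence, d2$sequence),
                        union(t1$sequence, t2$sequence))
    expect_setequal(out$sequence, expected)
    expect_false(anyDuplicated(out$sequence) > 0)
    # audit: no test sequence survives
    expect_length(intersect(out$sequence, c(t1$sequence, t2$sequence)), 0)
  }
})

test_that("pairwise identity matches hand checks and the DP oracle", {
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL"), 1)
  # two substitutions in ten positions: 80% identity
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIWW"), 0.8)
  set.seed(33)
  for (rep in 1:10) {
    a <- rand_peptides(1, 8, 30, seed = 100 + rep)
    b <- a
    if (rep %% 2 == 0) {
      # random point mutations
      pos <- sample(nchar(a), 2)
      for (p in pos) substr(b, p, p) <- sample(aa_alphabet(), 1)
    } else {
      b <- rand_peptides(1, 8, 30, seed = 200 + rep)
    }
    got <- pairwise_identity(a, b)
    want <- oracle_nw_matches(a, b) / min(nchar(a), nchar(b))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("redundancy filter: dedup, retention below threshold, postcondition, idempotence", {
  # identical sequences collapse to one representative
  two <- mk_ds(c("ACDEFGHIKLMNP", "ACDEFGHIKLMNP"))
  expect_equal(nrow(redundancy_filter(two)$representatives), 1)
  # 80% identical pair is retained at a 90% threshold
  pair <- mk_ds(c("ACDEFGHIKL", "ACDEFGHIWW"))
  expect_equal(nrow(redundancy_filter(pair, 0.9)$representatives), 2)
  # mixed set with planted near-duplicates
  base <- rand_peptides(40, 10, 30, seed = 41)
  near <- vapply(base[1:20], function(s) {
    p <- sample(nchar(s), 1)
    substr(s, p, p) <- sample(aa_alphabet(), 1)
    s
  }, character(1))
  ds <- mk_ds(unique(c(base, near)))
  cl <- redundancy_filter(ds, 0.9)
  # every input id appears exactly once in the map
  expect_setequal(cl$map$member_id, ds$id)
  expect_equal(nrow(cl$map), nrow(ds))
  # postcondition: no representative pair at or above the threshold
  reps <- cl$representatives$sequence
  for (i in seq_along(reps)) {
    for (j in seq_len(i - 1)) {
      expect_lt(pairwise_identity(reps[i], reps[j]), 0.9)
    }
  }
  # idempotence
  cl2 <- redundancy_filter(cl$representatives, 0.9)
  expect_identical(cl2$representatives, cl$representatives)
})

test_that("local aligner scores match the affine-gap DP oracle", {
  set.seed(51)
  for (rep in 1:8) {
    a <- rand_peptides(1, 10, 30, seed = 300 + rep)
    b <- if (rep %% 2) rand_peptides(1, 10, 30, seed = 400 + rep) else {
      paste0(substr(a, 3, nchar(a) - 2), "WY")
    }
    h <- best_local_hit(a, b)
    expect_equal(h$score, oracle_sw_score(a, b), tolerance = 1e-9)
  }
})

test_that("leakage screen flags identity and passes the shuffled negative control", {
  train <- mk_ds(rand_peptides(25, 20, 40, seed = 61), "tr")
  # a test sequence identical to a training sequence is flagged at 100%
  test1 <- mk_ds(train$sequence[1], "te")
  lk <- leakage_screen(train, test1)
  expect_equal(lk$max_identity, 100)
  expect_true(lk$hits$significant[1])
  # residue-shuffled queries rarely hit
  set.seed(62)
  shuffled <- vapply(train$sequence[1:10], function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1))
  lk2 <- leakage_screen(train, mk_ds(shuffled, "sh"))
  expect_lte(lk2$fraction_significant, 0.2)
  expect_error(leakage_screen(train[0, ], test1), "non-empty")
})

test_that("E-values decrease monotonically in alignment score at fixed lengths", {
  train <- mk_ds(rand_peptides(15, 25, 25, seed = 71), "tr")
  q1 <- train$sequence[1]                        # perfect self-hit
  q2 <- paste0(substr(q1, 1, 15), strrep("G", 10))  # partial hit
  h1 <- best_local_hit(q1, train$sequence)
  h2 <- best_local_hit(q2, train$sequence)
  expect_gt(h1$score, h2$score)
  expect_lt(h1$evalue, h2$evalue)
})
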
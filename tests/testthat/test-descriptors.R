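test_that("amino acid composition matches hand counts", {
  v <- compute_aac("AAAA")
  expect_equal(unname(v[1]), 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(compute_aac("ACDE")[1:4]), rep(0.25, 4))
  s <- rand_peptides(1, 30, 30, seed = 9)
  expect_equal(unname(compute_aac(s)), oracle_aac(s))
})

test_that("every descriptor family matches its direct-formula oracle", {
  seqs <- rand_peptides(25, 5, 40, seed = 11)
  cfg <- descriptor_config()
  for (s in seqs) {
    expect_equal(unname(compute_aac(s)), oracle_aac(s), tolerance = 1e-8)
    expect_equal(unname(compute_pseaac(s, cfg)), oracle_pseaac(s),
                 tolerance = 1e-8)
    expect_equal(unname(compute_ctd(s)), oracle_ctd(s), tolerance = 1e-8)
    expect_equal(unname(compute_qso(s, cfg)), oracle_qso(s), tolerance = 1e-8)
    expect_equal(unname(compute_physchem(s, cfg)), oracle_physchem(s),
                 tolerance = 1e-8)
    expect_equal(unname(compute_kmers(s)), oracle_kmers(s), tolerance = 1e-8)
    expect_equal(unname(compute_conformation(s)), oracle_conformation(s),
                 tolerance = 1e-8)
  }
})

test_that("homopolymers hit their closed-form degenerate values", {
  lib <- scale_library()
  for (a in aa_alphabet()) {
    s <- strrep(a, 8)
    aac <- compute_aac(s)
    expect_equal(unname(aac[match(a, aa_alphabet())]), 1)
    # PseAAC: zero property differences -> correlation terms vanish
    p <- compute_pseaac(s)
    expect_equal(unname(p[21:23]), rep(0, 3))
    expect_equal(unname(p[1:20]), unname(aac))
    # QSO: zero self-distance -> tau = 0, composition part = AAC
    q <- compute_qso(s)
    expect_equal(unname(q[1:6]), rep(0, 6))
    expect_equal(unname(q[7:26]), unname(aac))
    # CTD: single group per property -> compositions 0/1, no transitions
    ct <- compute_ctd(s)
    expect_true(all(ct[1:21] %in% c(0, 1)))
    expect_equal(unname(ct[22:42]), rep(0, 21))
    # scale means equal the residue's scale entry
    pc <- compute_physchem(s)
    expect_equal(unname(pc["zscales1"]), unname(lib$zscales[a, 1]))
    expect_equal(unname(pc[paste0("geary", 1:12)]), rep(0, 12))
    # conformational surrogate equals the residue's scale entries
    expect_equal(unname(compute_conformation(s)),
                 unname(lib$conformation[a, ]))
  }
})

test_that("composition blocks are unit-sum and weight limits recover AAC", {
  seqs <- rand_peptides(10, 6, 35, seed = 3)
  for (s in seqs) {
    expect_equal(sum(compute_aac(s)), 1, tolerance = 1e-9)
    k <- compute_kmers(s)
    expect_equal(sum(k[1:400]), 1, tolerance = 1e-9)
    ct <- compute_ctd(s)
    for (p in 0:6) expect_equal(sum(ct[p * 3 + 1:3]), 1, tolerance = 1e-9)
    # weight -> 0: PseAAC and QSO composition parts converge to AAC
    tiny <- descriptor_config(pseaac_weight = 1e-12, qso_weight = 1e-12)
    expect_equal(unname(compute_pseaac(s, tiny)[1:20]),
                 unname(compute_aac(s)), tolerance = 1e-8)
    expect_equal(unname(compute_qso(s, tiny)[7:26]),
                 unname(compute_aac(s)), tolerance = 1e-8)
  }
})

test_that("stated example values hold", {
  lib <- scale_library()
  # pure alanine: aliphatic index 100
  expect_equal(unname(compute_physchem("AAAA")["aIndex"]), 100)
  # GL dipeptide: instability = 10/2 * DIWV(G, L)
  expect_equal(unname(compute_physchem("GLGL")["Instaindex"]),
               10 / 4 * (2 * lib$diwv["G", "L"] + lib$diwv["L", "G"]))
  # A (neutral) and V (hydrophobic) alternate: every adjacent pair is a
  # group-2/group-3 transition of the hydrophobicity property
  ct <- compute_ctd("AVAV")
  expect_equal(unname(ct["CTDT3"]), 1)
  expect_equal(unname(ct["CTDT1"]), 0)
  # GFLG 2-mers each 1/3
  k <- compute_kmers("GFLG")
  expect_equal(unname(k[paste0("kmer", dipeptide_index(c("GF", "FL", "LG")))]),
               rep(1 / 3, 3))
  # overlapping motif occurrences are counted raw
  k2 <- compute_kmers("ALPALP")
  expect_equal(unname(k2["motif_ALP"]), 2)
  expect_equal(sum(k2[grep("motif_", names(k2))]), 2)  # LPA/PAL are not motifs
  # QSO coupling numbers match direct summation on a short sequence
  expect_equal(unname(compute_qso("ACDEG")), oracle_qso("ACDEG"),
               tolerance = 1e-10)
})

test_that("conformation modes behave per contract", {
  expect_equal(unname(compute_conformation("ACDEF", mode = "zero")), rep(0, 6))
  tab <- data.frame(id = "x1", t(stats::setNames(1:6, paste0("tango", 1:6))))
  names(tab)[2:7] <- paste0("tango", 1:6)
  expect_equal(unname(compute_conformation("ACDEF", mode = "external",
                                           id = "x1", table = tab)),
               as.numeric(1:6))
  expect_error(compute_conformation("ACDEF", mode = "external", id = "zz",
                                    table = tab), "zz")
})

test_that("featurize is deterministic, order-equivariant and label-blind", {
  ds <- peptide_dataset(paste0("r", 1:6),
                        rand_peptides(6, 8, 25, seed = 21))
  f1 <- featurize(ds)
  f2 <- featurize(ds)
  expect_identical(as.matrix(f1[, -1]), as.matrix(f2[, -1]))
  perm <- c(4, 2, 6, 1, 3, 5)
  f3 <- featurize(ds[perm, ])
  expect_equal(as.matrix(f3[, -1]), as.matrix(f1[perm, -1]),
               ignore_attr = TRUE)
  ds_lab <- ds
  ds_lab$label <- rep(c(0L, 1L), 3)
  f4 <- featurize(ds_lab)
  expect_equal(as.matrix(f4[, -1]), as.matrix(f1[, -1]), ignore_attr = TRUE)
  # schema covers every column, once
  sc <- feature_schema(f1)
  expect_equal(sc$name, setdiff(names(f1), "id"))
  expect_false(anyDuplicated(sc$name) > 0)
  expect_true(all(is.finite(as.matrix(f1[, -1]))))
})

test_that("per-record failures are aggregated with ids", {
  ds <- tibble::tibble(id = c("ok", "bad"), sequence = c("ACDEFGH", "ACD"))
  expect_error(featurize(ds), "bad")
})
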
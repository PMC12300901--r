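# Handcrafted descriptor families.
#
# Family blocks, in the canonical schema order:
#   aac          mer1..mer20
#   pseaac       PAAC1..23, PsePC1..22, PseSC1..26, APAAC1..46
#   ctd          CTDC1..21, CTDT1..21, CTDD1..105
#   qso          SOCN1..6, QSO1..46
#   physchem     scale means, indices, correlations (76 values)
#   kmer         kmer1..kmer400 (dipeptide frequencies), motif_* counts (57)
#   conformation tango1..tango6
# Composite logistic columns are appended by the composite-feature module.

#' Descriptor configuration
#'
#' @param lambda Sequence-order depth of the pseudo amino acid composition
#'   (default 3).
#' @param pseaac_weight Weight of the sequence-order terms in PseAAC
#'   (default 0.05).
#' @param qso_lag Maximum lag of the sequence-order-coupling numbers
#'   (default 3).
#' @param qso_weight Weight of the coupling terms in the quasi-sequence-order
#'   descriptors (default 0.1).
#' @param families Character vector of enabled family tags, a subset of
#'   `c("aac","pseaac","ctd","qso","physchem","kmer","conformation")`.
#' @param conformation_mode `"surrogate"` (scale-average propensities,
#'   default), `"zero"`, or `"external"` (per-record table).
#' @param conformation_table For `"external"` mode: data frame with columns
#'   `id`, `tango1`..`tango6`.
#' @param pk_set `"bjellqvist"` (default) or `"emboss"` pK set for charge and
#'   isoelectric point.
#' @param geary_properties Scale names used for Geary autocorrelation
#'   (default hydrophobicity, hydrophilicity, side-chain mass, polarity).
#' @param geary_lags Lags for Geary autocorrelation (default 1:3).
#'
#' @return A list of class `npp_descriptor_config`.
#' @export
descriptor_config <- function(lambda = 3L, pseaac_weight = 0.05,
                              qso_lag = 3L, qso_weight = 0.1,
                              families = c("aac", "pseaac", "ctd", "qso",
                                           "physchem", "kmer", "conformation"),
                              conformation_mode = c("surrogate", "zero", "external"),
                              conformation_table = NULL,
                              pk_set = c("bjellqvist", "emboss"),
                              geary_properties = c("hydrophobicity",
                                                   "hydrophilicity",
                                                   "sidechain_mass", "polarity"),
                              geary_lags = 1:3) {
  stopifnot(lambda >= 1L, pseaac_weight > 0, qso_lag >= 1L, qso_weight > 0)
  cfg <- list(lambda = as.integer(lambda), pseaac_weight = pseaac_weight,
              qso_lag = as.integer(qso_lag), qso_weight = qso_weight,
              families = match.arg(families, several.ok = TRUE),
              conformation_mode = match.arg(conformation_mode),
              conformation_table = conformation_table,
              pk_set = match.arg(pk_set),
              geary_properties = geary_properties,
              geary_lags = as.integer(geary_lags))
  class(cfg) <- "npp_descriptor_config"
  cfg
}

.seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Amino acid composition
#'
#' @param seq A canonical peptide sequence.
#' @return Named 20-vector of residue fractions (`mer1`..`mer20`,
#'   alphabetical residue order); components sum to 1.
#' @export
compute_aac <- function(seq) {
  ch <- .seq_chars(seq)
  f <- table(factor(ch, levels = aa_alphabet()))
  out <- as.numeric(f) / length(ch)
  names(out) <- paste0("mer", 1:20)
  out
}

# Type-1 ("parallel") pseudo composition: theta_j is the mean squared
# property difference at lag j, averaged over the supplied property scales.
.pseaac_type1 <- function(ch, props, lambda, w) {
  L <- length(ch)
  if (L <= lambda) stop("sequence length must exceed lambda = ", lambda,
                        call. = FALSE)
  f <- as.numeric(table(factor(ch, levels = aa_alphabet()))) / L
  H <- vapply(props, function(p) p[ch], numeric(L))  # L x nprop
  theta <- vapply(seq_len(lambda), function(j) {
    d <- (H[seq_len(L - j) + j, , drop = FALSE] -
            H[seq_len(L - j), , drop = FALSE])^2
    mean(rowMeans(d))
  }, numeric(1))
  denom <- 1 + w * sum(theta)
  c(f / denom, w * theta / denom)
}

# Type-2 ("series") pseudo composition: one product-correlation term per
# property and lag (the amphiphilic correlation functions).
.pseaac_type2 <- function(ch, props, lambda, w) {
  L <- length(ch)
  if (L <= lambda) stop("sequence length must exceed lambda = ", lambda,
                        call. = FALSE)
  f <- as.numeric(table(factor(ch, levels = aa_alphabet()))) / L
  H <- vapply(props, function(p) p[ch], numeric(L))
  tau <- numeric(0)
  for (j in seq_len(lambda)) {
    for (p in seq_along(props)) {
      tau <- c(tau, mean(H[seq_len(L - j), p] * H[seq_len(L - j) + j, p]))
    }
  }
  denom <- 1 + w * sum(tau)
  c(f / denom, w * tau / denom)
}

#' Pseudo amino acid composition blocks
#'
#' Computes four pseudo-composition blocks over Chou-standardized property
#' scales: `PAAC1..23` (type 1, three properties, lambda), `PsePC1..22`
#' (type 1 parallel correlations, hydrophobicity + hydrophilicity,
#' lambda = 2), `PseSC1..26` (type 2 series correlations, two properties,
#' lambda) and `APAAC1..46` (amphiphilic product correlations, one 23-block
#' per property).
#'
#' @param seq Canonical sequence of length > lambda.
#' @param cfg A [descriptor_config()].
#' @return Named numeric vector of 117 values.
#' @export
compute_pseaac <- function(seq, cfg = descriptor_config()) {
  lib <- scale_library()
  ch <- .seq_chars(seq)
  h1 <- .norm_scale(lib$hydrophobicity)
  h2 <- .norm_scale(lib$hydrophilicity)
  h3 <- .norm_scale(lib$sidechain_mass)
  w <- cfg$pseaac_weight
  paac <- .pseaac_type1(ch, list(h1, h2, h3), cfg$lambda, w)
  psepc <- .pseaac_type1(ch, list(h1, h2), 2L, w)
  psesc <- .pseaac_type2(ch, list(h1, h2), cfg$lambda, w)
  ap_h <- .pseaac_type2(ch, list(h1), cfg$lambda, w)
  ap_w <- .pseaac_type2(ch, list(h2), cfg$lambda, w)
  out <- c(paac, psepc, psesc, ap_h, ap_w)
  names(out) <- c(paste0("PAAC", seq_along(paac)),
                  paste0("PsePC", seq_along(psepc)),
                  paste0("PseSC", seq_along(psesc)),
                  paste0("APAAC", seq_len(length(ap_h) + length(ap_w))))
  out
}

.ctd_encode <- function(ch, groups) {
  g <- integer(length(ch))
  for (k in 1:3) {
    g[ch %in% strsplit(groups[k], "")[[1]]] <- k
  }
  g
}

#' Composition/Transition/Distribution descriptors
#'
#' Seven physicochemical properties, each recoding the sequence into three
#' groups: per property the three group compositions (sum 1), the three
#' between-group transition frequencies, and per group five distribution
#' percentiles (position of the first, 25%, 50%, 75% and last occurrence, as
#' percent of sequence length; 0 for absent groups).
#'
#' @param seq Canonical sequence.
#' @return Named vector `CTDC1..21`, `CTDT1..21`, `CTDD1..105`.
#' @export
compute_ctd <- function(seq) {
  lib <- scale_library()
  ch <- .seq_chars(seq)
  L <- length(ch)
  comp <- trans <- distr <- numeric(0)
  for (prop in lib$ctd_groups) {
    g <- .ctd_encode(ch, prop)
    comp <- c(comp, vapply(1:3, function(k) mean(g == k), numeric(1)))
    pairs <- cbind(g[-L], g[-1])
    tr <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ab) {
      sum((pairs[, 1] == ab[1] & pairs[, 2] == ab[2]) |
            (pairs[, 1] == ab[2] & pairs[, 2] == ab[1]))
    }, numeric(1))
    trans <- c(trans, tr / (L - 1))
    for (k in 1:3) {
      pos <- which(g == k)
      if (!length(pos)) {
        distr <- c(distr, rep(0, 5))
      } else {
        n <- length(pos)
        qpos <- pos[pmax(1L, ceiling(c(0.0001, 0.25, 0.5, 0.75, 1) * n))]
        distr <- c(distr, qpos / L * 100)
      }
    }
  }
  out <- c(comp, trans, distr)
  names(out) <- c(paste0("CTDC", 1:21), paste0("CTDT", 1:21),
                  paste0("CTDD", 1:105))
  out
}

#' Quasi-sequence-order descriptors
#'
#' Sequence-order-coupling numbers `tau_d` (sum of squared residue-pair
#' distances at lag d) and quasi-sequence-order values for two 20x20
#' residue distance matrices: the constructed physicochemical matrix (the
#' Schneider-Wrede slot of the original definition) followed by the Grantham
#' matrix.
#'
#' @param seq Canonical sequence with length greater than `qso_lag`.
#' @param cfg A [descriptor_config()].
#' @return Named vector `SOCN1..6` then `QSO1..46`.
#' @export
compute_qso <- function(seq, cfg = descriptor_config()) {
  lib <- scale_library()
  ch <- .seq_chars(seq)
  L <- length(ch)
  lag <- cfg$qso_lag
  if (L <= lag) stop("sequence length must exceed lag = ", lag, call. = FALSE)
  f <- as.numeric(table(factor(ch, levels = aa_alphabet()))) / L
  socn <- qso <- numeric(0)
  for (m in list(lib$qso_physchem, lib$qso_grantham)) {
    tau <- vapply(seq_len(lag), function(d) {
      sum(m[cbind(ch[seq_len(L - d)], ch[seq_len(L - d) + d])]^2)
    }, numeric(1))
    socn <- c(socn, tau)
    denom <- sum(f) + cfg$qso_weight * sum(tau)
    qso <- c(qso, f / denom, cfg$qso_weight * tau / denom)
  }
  out <- c(socn, qso)
  names(out) <- c(paste0("SOCN", seq_along(socn)), paste0("QSO", seq_along(qso)))
  out
}

.hh_charge <- function(ch, pH, pk) {
  npos <- c(sum(ch == "K"), sum(ch == "R"), sum(ch == "H"))
  pos <- sum(c(1, npos) / (1 + 10^(pH - pk[c("Nterm", "K", "R", "H")])))
  nneg <- c(sum(ch == "D"), sum(ch == "E"), sum(ch == "C"), sum(ch == "Y"))
  neg <- sum(c(1, nneg) / (1 + 10^(pk[c("Cterm", "D", "E", "C", "Y")] - pH)))
  pos - neg
}

.isoelectric_point <- function(ch, pk) {
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (.hh_charge(ch, mid, pk) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

.geary <- function(x, d) {
  n <- length(x)
  if (n - d < 1L) return(0)
  den <- sum((x - mean(x))^2)
  if (den == 0) return(0)
  (n - 1) / (2 * (n - d)) * sum((x[seq_len(n - d)] - x[seq_len(n - d) + d])^2) / den
}

#' Scale-based physicochemical and topological descriptors
#'
#' Sequence means of the multidimensional residue scale sets (Cruciani-style
#' 3, Z 5, FASGAI-style 6, T 5, VHSE 8, ProtFP-style 8, ST-style 8, MS-WHIM
#' 3, BLOSUM62-derived 8), plus the aliphatic index, Geary autocorrelations
#' (4 properties x lags 1..3), lag-1 autocovariance of hydrophobicity, the
#' Boman interaction index, two lag-1 cross-covariances
#' (hydrophobicity/hydrophilicity in both orders), net charge at pH 7,
#' the Guruprasad instability index, hydrophobic moments for the alpha-helix
#' (100 degrees) and beta-sheet (160 degrees) geometries, and the
#' isoelectric point.
#'
#' @param seq Canonical sequence (length >= 2 for the instability index).
#' @param cfg A [descriptor_config()].
#' @return Named numeric vector of 76 values.
#' @export
compute_physchem <- function(seq, cfg = descriptor_config()) {
  lib <- scale_library()
  ch <- .seq_chars(seq)
  L <- length(ch)
  scale_means <- function(m, prefix, k) {
    v <- colMeans(m[ch, , drop = FALSE])
    names(v) <- paste0(prefix, seq_len(k))
    v
  }
  out <- c(
    scale_means(lib$cruciani, "crucian", 3),
    scale_means(lib$zscales, "zscales", 5),
    scale_means(lib$fasgai, "fasgai", 6),
    scale_means(lib$tscales, "tscales", 5),
    scale_means(lib$vhse, "vhsescales", 8),
    scale_means(lib$protfp, "protFP", 8),
    scale_means(lib$stscales, "stscales", 8),
    scale_means(lib$mswhim, "mswhimscore", 3),
    scale_means(lib$blosum_idx, "Blosum", 8)
  )
  aac <- compute_aac(seq)
  names(aac) <- aa_alphabet()
  out["aIndex"] <- 100 * (aac["A"] + 2.9 * aac["V"] + 3.9 * (aac["I"] + aac["L"]))
  g <- numeric(0)
  for (p in cfg$geary_properties) {
    x <- lib[[p]][ch]
    for (d in cfg$geary_lags) g <- c(g, .geary(x, d))
  }
  names(g) <- paste0("geary", seq_along(g))
  out <- c(out, g)
  h <- .norm_scale(lib$hydrophobicity)[ch]
  w <- .norm_scale(lib$hydrophilicity)[ch]
  acov <- function(x, y) {
    if (L < 2L) return(0)
    sum((x[-L] - mean(x)) * (y[-1] - mean(y))) / (L - 1)
  }
  out["autocov"] <- acov(h, h)
  out["Boman"] <- -sum(lib$boman[ch]) / L
  out["Crosscov1"] <- acov(h, w)
  out["Crosscov2"] <- acov(w, h)
  pk <- lib$pk[[cfg$pk_set]]
  out["Charge"] <- .hh_charge(ch, 7.0, pk)
  out["Instaindex"] <- if (L >= 2L) {
    10 / L * sum(lib$diwv[cbind(ch[-L], ch[-1])])
  } else 0
  he <- lib$hydrophobicity[ch]
  moment <- function(delta_deg) {
    ang <- (seq_len(L)) * delta_deg * pi / 180
    sqrt(sum(he * cos(ang))^2 + sum(he * sin(ang))^2) / L
  }
  out["Hmoment1"] <- moment(100)
  out["Hmoment2"] <- moment(160)
  out["pI"] <- .isoelectric_point(ch, pk)
  out
}

#' Dipeptide frequencies and curated motif counts
#'
#' The dipeptide block is the 400 overlapping 2-mer counts divided by L-1
#' (first residue major, `kmer1..kmer400`); the motif block is the raw
#' overlapping occurrence count of each curated 3-mer.
#'
#' @param seq Canonical sequence.
#' @param motifs Motif list (default [np_motifs()]).
#' @return Named vector of 400 + `length(motifs)` values.
#' @export
compute_kmers <- function(seq, motifs = np_motifs()) {
  ch <- .seq_chars(seq)
  L <- length(ch)
  di <- paste0(ch[-L], ch[-1])
  counts <- table(factor(di, levels = {
    a <- aa_alphabet()
    as.vector(t(outer(a, a, paste0)))
  }))
  kmer <- as.numeric(counts) / (L - 1)
  names(kmer) <- paste0("kmer", 1:400)
  mot <- vapply(motifs, function(m) {
    hits <- gregexpr(paste0("(?=", m, ")"), seq, perl = TRUE)[[1]]
    if (hits[1] == -1L) 0 else length(hits)
  }, numeric(1))
  names(mot) <- paste0("motif_", motifs)
  c(kmer, mot)
}

#' Conformational propensity features
#'
#' Six per-sequence propensities (aggregation, amyloid, turn, helix, helical
#' aggregation, beta-strand). The default `"surrogate"` mode averages
#' documented per-residue propensity scales over the sequence (Chou-Fasman
#' turn/helix/sheet plus constructed aggregation combinations; see the
#' methods vignette). `"zero"` returns six zeros; `"external"` looks up a
#' user-supplied per-record table.
#'
#' @param seq Canonical sequence.
#' @param mode `"surrogate"`, `"zero"` or `"external"`.
#' @param id Record id (external mode lookup key).
#' @param table External table with columns `id`, `tango1`..`tango6`.
#' @return Named vector `tango1..tango6`.
#' @export
compute_conformation <- function(seq, mode = c("surrogate", "zero", "external"),
                                 id = NULL, table = NULL) {
  mode <- match.arg(mode)
  out <- switch(mode,
    zero = rep(0, 6),
    surrogate = {
      lib <- scale_library()
      as.numeric(colMeans(lib$conformation[.seq_chars(seq), , drop = FALSE]))
    },
    external = {
      if (is.null(table) || is.null(id)) {
        stop("external conformation mode needs `table` and `id`", call. = FALSE)
      }
      row <- table[table$id == id, , drop = FALSE]
      if (nrow(row) != 1L) {
        stop("no conformation table entry for id '", id, "'", call. = FALSE)
      }
      as.numeric(row[1, paste0("tango", 1:6)])
    })
  names(out) <- paste0("tango", 1:6)
  out
}

.featurize_one <- function(seq, cfg, motifs, id = NULL) {
  fams <- cfg$families
  parts <- list()
  if ("aac" %in% fams) parts$aac <- compute_aac(seq)
  if ("pseaac" %in% fams) parts$pseaac <- compute_pseaac(seq, cfg)
  if ("ctd" %in% fams) parts$ctd <- compute_ctd(seq)
  if ("qso" %in% fams) parts$qso <- compute_qso(seq, cfg)
  if ("physchem" %in% fams) parts$physchem <- compute_physchem(seq, cfg)
  if ("kmer" %in% fams) parts$kmer <- compute_kmers(seq, motifs)
  if ("conformation" %in% fams) {
    parts$conformation <- compute_conformation(
      seq, mode = cfg$conformation_mode, id = id,
      table = cfg$conformation_table)
  }
  parts
}

#' Compute the full descriptor matrix for a peptide dataset
#'
#' Applies every enabled descriptor family to each record and returns a wide
#' tibble (`id` first, then one column per descriptor, in the canonical block
#' order). The feature schema (name + family per column) is attached as the
#' `"schema"` attribute and can be read with [feature_schema()].
#'
#' @param ds Peptide dataset tibble.
#' @param cfg A [descriptor_config()].
#' @param motifs Curated motif list (default [np_motifs()]).
#' @return A tibble of class `npp_features`.
#' @export
featurize <- function(ds, cfg = descriptor_config(), motifs = np_motifs()) {
  errs <- character(0)
  rows <- vector("list", nrow(ds))
  for (i in seq_len(nrow(ds))) {
    r <- tryCatch(
      unlist(.featurize_one(ds$sequence[[i]], cfg, motifs, id = ds$id[[i]]),
             use.names = TRUE),
      error = function(e) e)
    if (inherits(r, "error")) {
      errs <- c(errs, paste0(ds$id[[i]], ": ", conditionMessage(r)))
    } else {
      rows[[i]] <- r
    }
  }
  if (length(errs)) {
    stop("featurization failed for ", length(errs), " record(s):\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  if (!nrow(ds)) stop("empty dataset", call. = FALSE)
  parts <- .featurize_one(ds$sequence[[1]], cfg, motifs, id = ds$id[[1]])
  schema <- tibble::tibble(
    name = unlist(lapply(parts, names), use.names = FALSE),
    family = rep(names(parts), vapply(parts, length, integer(1)))
  )
  mat <- do.call(rbind, rows)
  colnames(mat) <- schema$name
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(id = ds$id), out)
  attr(out, "schema") <- schema
  class(out) <- c("npp_features", class(out))
  out
}

#' Read the feature schema of a feature tibble
#'
#' @param features An `npp_features` tibble (or any tibble with `id` first;
#'   families are then inferred from the column-name prefixes).
#' @return Tibble with columns `name` and `family`.
#' @export
feature_schema <- function(features) {
  sc <- attr(features, "schema")
  if (!is.null(sc)) return(sc)
  nm <- setdiff(names(features), "id")
  fam <- dplyr::case_when(
    grepl("^mer\\d+$", nm) ~ "aac",
    grepl("^(PAAC|PsePC|PseSC|APAAC)", nm) ~ "pseaac",
    grepl("^CTD", nm) ~ "ctd",
    grepl("^(SOCN|QSO)", nm) ~ "qso",
    grepl("^(kmer\\d+|motif_)", nm) ~ "kmer",
    grepl("^tango", nm) ~ "conformation",
    grepl("^logistic", nm) ~ "composite",
    TRUE ~ "physchem"
  )
  tibble::tibble(name = nm, family = fam)
}
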
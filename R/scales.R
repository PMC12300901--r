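# Residue property tables backing the descriptor engine.
#
# Single-scale values are transcribed from the primary literature (sources in
# the roxygen blocks).  Multidimensional scale sets that we could not source
# as published tables (Cruciani-style, FASGAI-style, ProtFP-style, ST-style,
# BLOSUM-derived) are *reconstructions*: principal-component style summaries
# recomputed from the AAindex collection (via bio3d) or from BLOSUM62 (via
# Biostrings), with the dimensionality of the original publications.  They are
# documented as such and must not be read as the published factor values.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues in alphabetical single-letter order. Every
#' descriptor table in the package indexes this order.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.aa <- function(...) {
  x <- c(...)
  stopifnot(length(x) == 20L)
  names(x) <- aa_alphabet()
  x
}

# Eisenberg consensus hydrophobicity (Eisenberg et al. 1984); also the
# hydrophobicity component of Chou's pseudo amino acid composition.
.scale_hydrophobicity <- .aa(
  0.62, 0.29, -0.90, -0.74, 1.19, 0.48, -0.40, 1.38, -1.50, 1.06,
  0.64, -0.78, 0.12, -0.85, -2.53, -0.18, -0.05, 1.08, 0.81, 0.26)

# Hopp-Woods hydrophilicity (Hopp & Woods 1981).
.scale_hydrophilicity <- .aa(
  -0.5, -1.0, 3.0, 3.0, -2.5, 0.0, -0.5, -1.8, 3.0, -1.8,
  -1.3, 0.2, 0.0, 0.2, 3.0, 0.3, -0.4, -1.5, -3.4, -2.3)

# Side-chain mass (Da), the third component of Chou's property triplet.
.scale_sidechain_mass <- .aa(
  15, 47, 59, 73, 91, 1, 82, 57, 73, 57,
  75, 58, 42, 72, 101, 31, 45, 43, 130, 107)

# Kyte-Doolittle hydropathy (Kyte & Doolittle 1982).
.scale_kd <- .aa(
  1.8, 2.5, -3.5, -3.5, 2.8, -0.4, -3.2, 4.5, -3.9, 3.8,
  1.9, -3.5, -1.6, -3.5, -4.5, -0.8, -0.7, 4.2, -0.9, -1.3)

# Grantham (1974) side-chain composition / polarity / volume components.
.grantham_c <- .aa(
  0, 2.75, 1.38, 0.92, 0, 0.74, 0.58, 0, 0.33, 0,
  0, 1.33, 0.39, 0.89, 0.65, 1.42, 0.71, 0, 0.13, 0.20)
.grantham_p <- .aa(
  8.1, 5.5, 13.0, 12.3, 5.2, 9.0, 10.4, 5.2, 11.3, 4.9,
  5.7, 11.6, 8.0, 10.5, 10.5, 9.2, 8.6, 5.9, 5.4, 6.2)
.grantham_v <- .aa(
  31, 55, 54, 83, 132, 3, 96, 111, 119, 111,
  105, 56, 32.5, 85, 124, 32, 61, 84, 170, 136)

# Chou-Fasman conformational propensities (Chou & Fasman 1978).
.scale_helix <- .aa(
  1.42, 0.70, 1.01, 1.51, 1.13, 0.57, 1.00, 1.08, 1.16, 1.21,
  1.45, 0.67, 0.57, 1.11, 0.98, 0.77, 0.83, 1.06, 1.08, 0.69)
.scale_sheet <- .aa(
  0.83, 1.19, 0.54, 0.37, 1.38, 0.75, 0.87, 1.60, 0.74, 1.30,
  1.05, 0.89, 0.55, 1.10, 0.93, 0.75, 1.19, 1.70, 1.37, 1.47)
.scale_turn <- .aa(
  0.66, 1.19, 1.46, 0.74, 0.60, 1.56, 0.95, 0.47, 1.01, 0.59,
  0.60, 1.56, 1.52, 0.98, 0.95, 1.43, 0.96, 0.50, 0.96, 1.14)

# Radzicka-Wolfenden transfer free energies used by the Boman (1993)
# interaction index; proline is undetermined in the source and set to 0.
.scale_boman <- .aa(
  1.81, 1.28, -8.72, -6.81, 2.98, 0.94, -4.66, 4.92, -5.55, 4.92,
  2.35, -6.64, 0.00, -5.54, -14.92, -3.40, -2.57, 4.04, 2.33, -0.14)

.mat20 <- function(values_by_row, k) {
  m <- matrix(unlist(values_by_row), nrow = 20, ncol = k, byrow = TRUE)
  rownames(m) <- aa_alphabet()
  colnames(m) <- paste0("d", seq_len(k))
  m
}

# Z-scales (Sandberg et al. 1998), rows in alphabetical residue order.
.scale_zscales <- .mat20(list(
  c(0.24, -2.32, 0.60, -0.14, 1.30),   # A
  c(0.84, -1.67, 3.71, 0.18, -2.65),   # C
  c(3.98, 0.93, 1.93, -2.46, 0.75),    # D
  c(3.11, 0.26, -0.11, -3.04, -0.25),  # E
  c(-4.22, 1.94, 1.06, 0.54, -0.62),   # F
  c(2.05, -4.06, 0.36, -0.82, -0.38),  # G
  c(2.47, 1.95, 0.26, 3.90, 0.09),     # H
  c(-3.89, -1.73, -1.71, -0.84, 0.26), # I
  c(2.29, 0.89, -2.49, 1.49, 0.31),    # K
  c(-4.28, -1.30, -1.49, -0.72, 0.84), # L
  c(-2.85, -0.22, 0.47, 1.94, -0.98),  # M
  c(3.05, 1.62, 1.04, -1.15, 1.61),    # N
  c(-1.66, 0.27, 1.84, 0.70, 2.00),    # P
  c(1.75, 0.50, -1.44, -1.34, 0.66),   # Q
  c(3.52, 2.50, -3.50, 1.99, -0.17),   # R
  c(2.39, -1.07, 1.15, -1.39, 0.67),   # S
  c(0.75, -2.18, -1.12, -1.46, -0.40), # T
  c(-2.59, -2.64, -1.54, -0.85, -0.02),# V
  c(-4.36, 3.94, 0.59, 3.44, -1.59),   # W
  c(-2.54, 2.44, 0.43, 0.04, -1.47)    # Y
), 5)

# VHSE scales (Mei et al. 2005).
.scale_vhse <- .mat20(list(
  c(0.15, -1.11, -1.35, -0.92, 0.02, -0.91, 0.36, -0.48),
  c(0.18, -1.67, -0.46, -0.21, 0.00, 1.20, -1.61, -0.19),
  c(-1.15, 0.67, -0.41, -0.01, -2.68, 1.31, 0.03, 0.56),
  c(-1.18, 0.40, 0.10, 0.36, -2.16, -0.17, 0.91, 0.02),
  c(1.52, 0.61, 0.96, -0.16, 0.25, 0.28, -1.33, -0.20),
  c(-0.20, -1.53, -2.63, 2.28, -0.53, -1.18, 2.01, -1.34),
  c(-0.43, -0.25, 0.37, 0.19, 0.51, 1.28, 0.93, 0.65),
  c(1.27, -0.14, 0.30, -1.80, 0.30, -1.61, -0.16, -0.13),
  c(-1.17, 0.70, 0.70, 0.80, 1.64, 0.67, 1.63, 0.13),
  c(1.36, 0.07, 0.26, -0.80, 0.22, -1.37, 0.08, -0.62),
  c(1.01, -0.53, 0.43, 0.00, 0.23, 0.10, -0.86, -0.68),
  c(-0.99, 0.00, -0.37, 0.69, -0.55, 0.85, 0.73, -0.80),
  c(0.22, -0.17, -0.50, 0.05, -0.01, -1.34, -0.19, 3.56),
  c(-0.96, 0.12, 0.18, 0.16, 0.09, 0.42, -0.20, -0.41),
  c(-1.47, 1.45, 1.24, 1.27, 1.55, 1.47, 1.30, 0.83),
  c(-0.67, -0.86, -1.07, -0.41, -0.32, 0.27, -0.64, 0.11),
  c(-0.34, -0.51, -0.55, -1.06, -0.06, -0.01, -0.79, 0.39),
  c(0.76, -0.92, -0.17, -1.91, 0.22, -1.40, -0.24, -0.03),
  c(1.50, 2.06, 1.79, 0.75, 0.75, -0.13, -1.01, -0.85),
  c(0.61, 1.60, 1.17, 0.73, 0.53, 0.25, -0.96, -0.52)
), 8)

# MS-WHIM scores (Zaliani & Gancia 1999).
.scale_mswhim <- .mat20(list(
  c(-0.73, 0.20, -0.62),
  c(-0.66, 0.26, -0.27),
  c(0.11, -1.00, -0.96),
  c(0.24, -0.39, -0.04),
  c(0.76, 0.85, -0.34),
  c(-0.31, -0.28, -0.75),
  c(0.84, 0.67, -0.78),
  c(-0.91, 0.83, -0.25),
  c(-0.51, 0.08, 0.70),
  c(-0.74, 0.72, -0.16),
  c(-0.70, 1.00, -0.32),
  c(0.14, 0.20, -0.66),
  c(-0.43, 0.73, -0.60),
  c(0.30, 1.00, -0.30),
  c(-0.22, 0.27, 1.00),
  c(-0.80, 0.61, -1.00),
  c(-0.58, 0.85, -0.89),
  c(-1.00, 0.79, -0.58),
  c(1.00, 0.98, -0.47),
  c(0.97, 0.66, -0.16)
), 3)

# T-scales (Tian et al. 2007).
.scale_tscales <- .mat20(list(
  c(-9.11, -1.63, 0.63, 1.04, 2.26),
  c(-7.35, -0.86, -0.33, 0.80, 0.98),
  c(-4.65, 0.75, 1.39, -0.40, 1.05),
  c(-3.03, 1.82, 0.51, -0.58, 0.43),
  c(0.49, -0.94, -0.63, -1.27, -0.44),
  c(-10.61, -1.21, -0.12, 0.75, 3.25),
  c(-1.01, -1.31, 0.01, -1.81, -0.21),
  c(-4.25, -0.28, -0.15, 1.40, -0.21),
  c(-2.59, 2.34, -1.69, 0.41, -0.21),
  c(-4.38, 0.28, -0.49, 1.45, 0.02),
  c(-4.08, 0.98, -2.34, 1.64, -0.79),
  c(-4.62, 0.66, 1.16, -0.22, 0.93),
  c(-5.11, -3.54, -0.53, -0.36, -0.29),
  c(-3.00, 1.72, 0.28, -0.39, 0.33),
  c(0.23, 3.89, -1.16, -0.39, -0.06),
  c(-7.44, -0.65, 0.68, -0.17, 1.58),
  c(-5.97, -0.62, 1.11, 0.31, 0.95),
  c(-5.87, -0.94, 0.28, 1.10, 0.48),
  c(5.73, -2.67, -0.07, -1.96, -0.54),
  c(2.08, -0.47, 0.07, -1.67, -0.35)
), 5)

# Guruprasad et al. (1990) dipeptide instability weights (DIWV).
# Rows: first residue of the dipeptide; columns: second residue.
.diwv <- local({
  v <- c(
    1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
    1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
    1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
    1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
    1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
    -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
    1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
    1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
    1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
    1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
    13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
    1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
    20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
    1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
    1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
    1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
    1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
    1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
    -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
    24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34)
  m <- matrix(v, nrow = 20, byrow = TRUE,
              dimnames = list(aa_alphabet(), aa_alphabet()))
  m
})

# pK sets for charge / isoelectric point. Bjellqvist et al. (1993) is the
# default; the EMBOSS iep set is selectable.
.pk_sets <- list(
  bjellqvist = c(Nterm = 7.50, Cterm = 3.55, K = 10.00, R = 12.00, H = 5.98,
                 D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
  emboss     = c(Nterm = 8.60, Cterm = 3.60, K = 10.80, R = 12.50, H = 6.50,
                 D = 3.90, E = 4.10, C = 8.50, Y = 10.10)
)

# Three-group residue partitions for the CTD descriptors (Dubchak et al. 1995
# convention; seven properties, the seventh being polarizability).
.ctd_groups <- list(
  hydrophobicity = c("RKEDQN", "GASTPHY", "CLVIMFW"),
  vdw_volume     = c("GASTPDC", "NVEQIL", "MHKFRYW"),
  polarity       = c("LIFWCMVY", "PATGS", "HQRKNED"),
  polarizability = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge         = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  secondary      = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  solvent_access = c("ALFCGIVW", "RKQEND", "MPSTHY")
)

.fix_pc_sign <- function(scores) {
  for (j in seq_len(ncol(scores))) {
    s <- scores[, j]
    if (s[which.max(abs(s))] < 0) scores[, j] <- -s
  }
  scores
}

# Property-pool matrix from the AAindex collection: complete entries only,
# residues as rows (alphabetical order), standardized columns.
.aaindex_matrix <- function(pattern = NULL) {
  env <- new.env()
  utils::data("aa.index", package = "bio3d", envir = env)
  idx <- env$aa.index
  if (!is.null(pattern)) {
    keep <- vapply(idx, function(e) grepl(pattern, e$D, ignore.case = TRUE),
                   logical(1))
    idx <- idx[keep]
  }
  vals <- vapply(idx, function(e) as.numeric(e$I[aa_alphabet()]), numeric(20))
  vals <- vals[, colSums(is.na(vals)) == 0, drop = FALSE]
  scale(vals)
}

.pca_scale_set <- function(X, k, prefix, rotate = FALSE) {
  pr <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  sc <- pr$x[, seq_len(k), drop = FALSE]
  if (rotate) {
    rot <- stats::varimax(pr$rotation[, seq_len(k), drop = FALSE] %*%
                            diag(pr$sdev[seq_len(k)]))
    sc <- pr$x[, seq_len(k), drop = FALSE] %*% rot$rotmat
  }
  sc <- scale(sc)
  sc <- .fix_pc_sign(sc)
  rownames(sc) <- aa_alphabet()
  colnames(sc) <- paste0(prefix, seq_len(k))
  sc
}

.grantham_matrix <- function() {
  a <- aa_alphabet()
  d2 <- outer(.grantham_c, .grantham_c, "-")^2 * 1.833 +
    outer(.grantham_p, .grantham_p, "-")^2 * 0.1018 +
    outer(.grantham_v, .grantham_v, "-")^2 * 0.000399
  d <- sqrt(d2)
  off <- d[upper.tri(d)]
  d <- d * (100 / mean(off))  # normalize mean pairwise distance to 100
  dimnames(d) <- list(a, a)
  d
}

# Constructed physicochemical distance matrix occupying the slot the original
# quasi-sequence-order definition fills with the Schneider-Wrede matrix:
# euclidean distance over the standardized Chou property triplet
# (hydrophobicity, hydrophilicity, side-chain mass). A reconstruction, not
# the published Schneider-Wrede values.
.physchem_matrix <- function() {
  p <- cbind(.norm_scale(.scale_hydrophobicity),
             .norm_scale(.scale_hydrophilicity),
             .norm_scale(.scale_sidechain_mass))
  d <- as.matrix(stats::dist(p)) / sqrt(3)
  dimnames(d) <- list(aa_alphabet(), aa_alphabet())
  d
}

# Chou's standardization over the 20 residues: centre, divide by the
# root-mean-square deviation (denominator 20, not 19).
.norm_scale <- function(x) {
  x <- x[aa_alphabet()]
  (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
}

.scales_cache <- new.env(parent = emptyenv())

#' Residue property library used by the descriptor engine
#'
#' Collects every per-residue table the descriptors need: the Chou property
#' triplet (hydrophobicity, hydrophilicity, side-chain mass), Kyte-Doolittle
#' hydropathy, Grantham polarity, CTD three-group partitions, two 20x20
#' residue distance matrices for quasi-sequence-order descriptors, the
#' multidimensional scale sets (Z, VHSE, MS-WHIM, T, plus reconstructed
#' Cruciani-, FASGAI-, ProtFP-, ST-style and BLOSUM62-derived sets), the
#' Chou-Fasman conformational propensities, Guruprasad instability weights,
#' Boman transfer energies and pK sets.
#'
#' The Grantham matrix is computed from the published composition, polarity
#' and volume components with the mean pairwise distance normalized to 100.
#' The second distance matrix (`qso_physchem`) and the Cruciani-, FASGAI-,
#' ProtFP-, ST-style and BLOSUM-derived scale sets are reconstructions
#' (documented in their source), not transcriptions of the original tables.
#'
#' @return A named list of scale vectors and matrices, cached per session.
#' @export
scale_library <- function() {
  if (!is.null(.scales_cache$lib)) return(.scales_cache$lib)
  aaix <- .aaindex_matrix()
  lib <- list(
    hydrophobicity = .scale_hydrophobicity,
    hydrophilicity = .scale_hydrophilicity,
    sidechain_mass = .scale_sidechain_mass,
    kd             = .scale_kd,
    polarity       = .grantham_p,
    helix          = .scale_helix,
    sheet          = .scale_sheet,
    turn           = .scale_turn,
    boman          = .scale_boman,
    diwv           = .diwv,
    pk             = .pk_sets,
    ctd_groups     = .ctd_groups,
    qso_physchem   = .physchem_matrix(),
    qso_grantham   = .grantham_matrix(),
    zscales        = .scale_zscales,
    vhse           = .scale_vhse,
    mswhim         = .scale_mswhim,
    tscales        = .scale_tscales,
    cruciani       = .pca_scale_set(
      .aaindex_matrix("hydrophob|polar|hydration|partition|solvation"),
      3, "pc"),
    fasgai         = .pca_scale_set(aaix, 6, "f", rotate = TRUE),
    protfp         = .pca_scale_set(aaix, 8, "pc"),
    stscales       = .pca_scale_set(
      .aaindex_matrix("structur|conformat|volume|steric|flexib|shape|turn|helix|sheet|coil"),
      8, "pc"),
    blosum_idx     = local({
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      b <- env$BLOSUM62[aa_alphabet(), aa_alphabet()]
      .pca_scale_set(scale(b), 8, "pc")
    })
  )
  # surrogate conformational propensity scales (constructed; see vignette)
  z <- function(x) as.numeric(scale(x[aa_alphabet()]))
  conf <- cbind(
    aggregation = (z(.scale_kd) + z(.scale_sheet)) / 2,
    amyloid     = (z(.scale_sheet) - z(.scale_turn)) / 2,
    turn        = .scale_turn,
    helix       = .scale_helix,
    helagg      = (z(.scale_kd) + z(.scale_helix)) / 2,
    beta        = .scale_sheet
  )
  rownames(conf) <- aa_alphabet()
  lib$conformation <- conf
  .scales_cache$lib <- lib
  lib
}
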
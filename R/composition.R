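# Class-conditional sequence composition analytics.

.residue_groups <- list(
  charged     = "DEKHR",
  aliphatic   = "ILV",
  aromatic    = "FHWY",
  polar       = "DERKQN",
  neutral     = "AGHPSTY",
  hydrophobic = "CVLIMFW",
  positive    = "HKR",
  negative    = "DE",
  tiny        = "ACDGST",
  small       = "EHILKMNPQV",
  large       = "FRWY"
)

.pooled_group_pct <- function(seqs) {
  ch <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  total <- length(ch)
  vapply(.residue_groups, function(g) {
    sum(ch %in% strsplit(g, "")[[1]]) / total * 100
  }, numeric(1))
}

#' Physicochemical group composition by class
#'
#' Average sequence length and the pooled percent composition of eleven
#' physicochemical residue groups (charged DEKHR, aliphatic ILV, aromatic
#' FHWY, polar DERKQN, neutral AGHPSTY, hydrophobic CVLIMFW, positively
#' charged HKR, negatively charged DE, tiny ACDGST, small EHILKMNPQV, large
#' FRWY), per class. Percentages are residue-weighted (pooled counts over
#' all residues of the class), under which positive% + negative% = charged%
#' holds exactly.
#'
#' @param pos,neg Peptide dataset tibbles for the two classes.
#' @return A tibble with columns `property`, `positive`, `negative`.
#' @export
group_composition <- function(pos, neg) {
  if (!nrow(pos) || !nrow(neg)) stop("both classes must be non-empty",
                                     call. = FALSE)
  p <- c(avg_length = mean(nchar(pos$sequence)), .pooled_group_pct(pos$sequence))
  n <- c(avg_length = mean(nchar(neg$sequence)), .pooled_group_pct(neg$sequence))
  tibble::tibble(property = names(p), positive = unname(p), negative = unname(n))
}

#' Positional residue frequencies at a terminus
#'
#' Residue frequency at positions 1..`positions` counted from the N- or
#' C-terminus, plus the per-residue average over those positions. Records
#' shorter than `positions` are excluded (with a message).
#'
#' @param ds Peptide dataset tibble.
#' @param terminus `"N"` or `"C"`.
#' @param positions Number of terminal positions (default 5).
#' @return List with `freq` (20 x positions matrix, columns sum to 1) and
#'   `average` (named 20-vector, percent).
#' @export
positional_frequencies <- function(ds, terminus = c("N", "C"), positions = 5L) {
  terminus <- match.arg(terminus)
  keep <- nchar(ds$sequence) >= positions
  if (any(!keep)) {
    message(sum(!keep), " record(s) shorter than ", positions, " excluded")
  }
  seqs <- ds$sequence[keep]
  if (!length(seqs)) stop("no records long enough", call. = FALSE)
  m <- matrix(0, nrow = 20, ncol = positions,
              dimnames = list(aa_alphabet(), paste0("p", seq_len(positions))))
  for (j in seq_len(positions)) {
    ch <- if (terminus == "N") substr(seqs, j, j) else {
      L <- nchar(seqs)
      substr(seqs, L - j + 1L, L - j + 1L)
    }
    tab <- table(factor(ch, levels = aa_alphabet()))
    m[, j] <- as.numeric(tab) / length(ch)
  }
  list(freq = m, average = rowMeans(m) * 100)
}

.kmer_counts <- function(seqs, k) {
  ch <- strsplit(seqs, "", fixed = TRUE)
  kmers <- unlist(lapply(ch, function(x) {
    L <- length(x)
    if (L < k) return(character(0))
    vapply(seq_len(L - k + 1L), function(i) paste(x[i:(i + k - 1L)], collapse = ""),
           character(1))
  }), use.names = FALSE)
  table(kmers)
}

#' Dipeptide log-odds matrix (positive vs negative class)
#'
#' `M[x, y] = log((c_pos(xy) + a) / (N_pos + 400 a)) -
#'            log((c_neg(xy) + a) / (N_neg + 400 a))`
#' over overlapping dipeptide counts `c`, class totals `N` and pseudocount
#' `a`.
#'
#' @param pos,neg Peptide dataset tibbles.
#' @param pseudocount Pseudocount `a` (default 0.5).
#' @param base Logarithm base (default `exp(1)`).
#' @return A 20 x 20 matrix of class `npp_logodds` (first residue in rows),
#'   with attributes `pseudocount` and `base`.
#' @export
dipeptide_logodds <- function(pos, neg, pseudocount = 0.5, base = exp(1)) {
  stopifnot(pseudocount > 0)
  a <- aa_alphabet()
  all_di <- as.vector(t(outer(a, a, paste0)))
  cp <- .kmer_counts(pos$sequence, 2L)
  cn <- .kmer_counts(neg$sequence, 2L)
  get <- function(tab, keys) {
    v <- as.numeric(tab[keys]); v[is.na(v)] <- 0; v
  }
  np <- sum(cp); nn <- sum(cn)
  lo <- log((get(cp, all_di) + pseudocount) / (np + 400 * pseudocount), base) -
    log((get(cn, all_di) + pseudocount) / (nn + 400 * pseudocount), base)
  m <- matrix(lo, nrow = 20, byrow = TRUE, dimnames = list(a, a))
  structure(m, pseudocount = pseudocount, base = base, class = "npp_logodds")
}

#' Ranked k-mer enrichment screen
#'
#' Log-odds enrichment of every observed k-mer in the positive class over the
#' negative class (same pseudocount formula as [dipeptide_logodds()] with the
#' k-mer space size as denominator multiplier), ranked by decreasing
#' log-odds with lexicographic tie-break.
#'
#' @param pos,neg Peptide dataset tibbles.
#' @param k K-mer size (default 3).
#' @param top_n Number of rows to return (default all observed k-mers).
#' @param pseudocount Pseudocount (default 0.5).
#' @return Tibble `kmer`, `count_pos`, `count_neg`, `log_odds`, ranked.
#' @export
kmer_enrichment <- function(pos, neg, k = 3L, top_n = Inf, pseudocount = 0.5) {
  cp <- .kmer_counts(pos$sequence, k)
  cn <- .kmer_counts(neg$sequence, k)
  keys <- sort(union(names(cp), names(cn)))
  get <- function(tab) {
    v <- as.numeric(tab[keys]); v[is.na(v)] <- 0; v
  }
  xp <- get(cp); xn <- get(cn)
  vocab <- 20^k
  lo <- log((xp + pseudocount) / (sum(xp) + vocab * pseudocount)) -
    log((xn + pseudocount) / (sum(xn) + vocab * pseudocount))
  out <- tibble::tibble(kmer = keys, count_pos = xp, count_neg = xn,
                        log_odds = lo)
  out <- out[order(-out$log_odds, out$kmer), ]
  utils::head(out, top_n)
}
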
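# Synthetic labelled peptide fixtures.
#
# The generator emulates the class-conditional structure observed in curated
# neuropeptide training data: neuropeptides are shorter on average and
# enriched in G, P, F, S, R; non-neuropeptides are longer and enriched in
# V, T, M, C, K, I, L; a fraction of positives carries one curated 3-mer
# motif spliced at a random position. Sequences are i.i.d. residue draws,
# so the fixtures carry composition and motif signal but no grammar.

#' Default synthetic neuropeptide generation spec
#'
#' Class-conditional residue distributions are Dirichlet-style perturbed
#' uniform distributions: the enriched residues of each class get a
#' multiplier (default 2) before renormalization. Lengths are Poisson with
#' class means 24 (positives) and 27 (negatives), shifted to a minimum of 4.
#' Positives splice one curated motif with probability 0.3.
#'
#' @param n_pos,n_neg Class sizes (default 400 each).
#' @param enrich Multiplier applied to each class's enriched residues
#'   (default 2).
#' @param motif_prob Probability a positive record carries a planted motif
#'   (default 0.3).
#' @param null_control If TRUE both classes share the positive-class length
#'   and residue distributions and no motifs are planted, giving a dataset
#'   with no class signal.
#' @return A list of class `npp_synthetic_spec`.
#' @export
default_np_spec <- function(n_pos = 400L, n_neg = 400L, enrich = 2,
                            motif_prob = 0.3, null_control = FALSE) {
  a <- aa_alphabet()
  base <- stats::setNames(rep(1, 20), a)
  pos <- base; pos[c("G", "P", "F", "S", "R")] <- enrich
  neg <- base; neg[c("V", "T", "M", "C", "K", "I", "L")] <- enrich
  pos <- pos / sum(pos); neg <- neg / sum(neg)
  spec <- list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    residue_pos = pos, residue_neg = if (null_control) pos else neg,
    mean_len_pos = 24, mean_len_neg = if (null_control) 24 else 27,
    min_len = 4L,
    motifs = np_motifs(),
    motif_prob = if (null_control) 0 else motif_prob
  )
  class(spec) <- "npp_synthetic_spec"
  spec
}

.rlen <- function(n, mean_len, min_len) {
  pmax(min_len, stats::rpois(n, mean_len))
}

.rseq <- function(len, dist) {
  paste(sample(names(dist), len, replace = TRUE, prob = dist), collapse = "")
}

#' Generate a labelled synthetic peptide dataset
#'
#' @param spec A spec from [default_np_spec()].
#' @param seed Mandatory integer seed; identical seeds give identical
#'   datasets.
#' @return A labelled peptide dataset tibble (label 1 = neuropeptide).
#' @export
generate_peptides <- function(spec = default_np_spec(), seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  gen_class <- function(n, dist, mean_len, label, prefix) {
    if (!n) return(NULL)
    lens <- .rlen(n, mean_len, spec$min_len)
    seqs <- vapply(lens, .rseq, character(1), dist = dist)
    if (label == 1L && spec$motif_prob > 0) {
      plant <- stats::runif(n) < spec$motif_prob
      for (i in which(plant)) {
        m <- sample(spec$motifs, 1)
        s <- seqs[[i]]
        pos <- sample.int(max(1L, nchar(s) - 2L), 1)
        substr(s, pos, pos + 2L) <- m
        seqs[[i]] <- s
      }
    }
    tibble::tibble(id = paste0(prefix, seq_len(n)), sequence = seqs,
                   label = label)
  }
  out <- dplyr::bind_rows(
    gen_class(spec$n_pos, spec$residue_pos, spec$mean_len_pos, 1L, "pos"),
    gen_class(spec$n_neg, spec$residue_neg, spec$mean_len_neg, 0L, "neg")
  )
  out
}
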
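#' Curated neuropeptide-associated 3-mer motifs
#'
#' The fixed list of 57 tripeptide motifs retained by log-odds/MERCI
#' enrichment screening of neuropeptides against non-neuropeptides. The list
#' is canonical for featurization: motif occurrence counts form one feature
#' block regardless of any re-screening.
#'
#' @return Character vector of 57 unique 3-mers, in canonical order.
#' @export
np_motifs <- function() {
  c("ALP", "DFI", "DTD", "ENL", "ETI", "FLP", "FYP", "GLQ", "GPF", "HLP",
    "HPF", "IAW", "IFP", "IKW", "IPA", "IPP", "IYP", "KDQ", "KRI", "KVL",
    "LAV", "LHL", "LLE", "LMR", "MFL", "NPC", "NVP", "NWN", "PAG", "PEV",
    "PFP", "PGA", "PIP", "PIT", "PKH", "PLP", "PSE", "PTH", "PVP", "PYP",
    "QTP", "RLN", "RND", "STC", "TKE", "TLE", "TLV", "TST", "VKE", "VLP",
    "VPP", "VPQ", "VRP", "VYP", "WLP", "YNP", "YST")
}

#' Dipeptide feature index
#'
#' Maps a dipeptide such as `"LR"` to its position in the 400-column
#' dipeptide block (first residue major, alphabetical order), so that e.g.
#' `LR` is feature `kmer195`.
#'
#' @param dipep Character vector of 2-letter dipeptides.
#' @return Integer vector of indices in 1..400.
#' @export
dipeptide_index <- function(dipep) {
  a <- aa_alphabet()
  i <- match(substr(dipep, 1, 1), a)
  j <- match(substr(dipep, 2, 2), a)
  if (anyNA(i) || anyNA(j)) stop("non-canonical dipeptide", call. = FALSE)
  (i - 1L) * 20L + j
}
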
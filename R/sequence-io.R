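# Peptide dataset I/O and the alphabet contract.
#
# A peptide dataset is an ordinary tibble with columns `id` (unique,
# non-empty), `sequence` (upper-case, canonical 20-letter alphabet) and an
# optional `label` column (integer, 1 = neuropeptide, 0 = non-neuropeptide;
# present for every record or for none). All downstream modules take and
# return these tibbles.

.label_pos_token <- "NP"
.label_neg_token <- "nonNP"

#' Assemble and validate a peptide dataset tibble
#'
#' @param id Character vector of unique, non-empty record identifiers.
#' @param sequence Character vector of peptide sequences (upper-cased here).
#' @param label Optional numeric/integer vector of 0/1 class labels
#'   (1 = neuropeptide). Either full length or `NULL`.
#' @param policy Non-canonical residue policy passed to
#'   [validate_sequence()]: `"strict"` (default), `"map"` or `"drop"`.
#' @param min_length Minimum accepted sequence length (default 4, required by
#'   the lambda = 3 / lag = 3 sequence-order descriptors).
#'
#' @return A tibble with columns `id`, `sequence` and (if given) `label`.
#'   Records removed under `policy = "drop"` are reported via a message and
#'   recorded in the `"dropped"` attribute.
#' @export
peptide_dataset <- function(id, sequence, label = NULL,
                            policy = c("strict", "map", "drop"),
                            min_length = 4L) {
  policy <- match.arg(policy)
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("`id` and `sequence` must have equal length", call. = FALSE)
  }
  if (any(!nzchar(id))) stop("record ids must be non-empty", call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(label)) {
    label <- as.integer(label)
    if (length(label) != length(id) || anyNA(label) ||
        !all(label %in% c(0L, 1L))) {
      stop("`label` must be 0/1 for every record, or NULL", call. = FALSE)
    }
  }
  dropped <- character(0)
  out_seq <- character(length(sequence))
  keep <- rep(TRUE, length(sequence))
  for (i in seq_along(sequence)) {
    res <- tryCatch(
      validate_sequence(sequence[[i]], policy = if (policy == "drop") "strict" else policy,
                        min_length = min_length),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (policy == "drop") {
        keep[i] <- FALSE
        dropped <- c(dropped, paste0(id[[i]], ": ", conditionMessage(res)))
      } else {
        stop("record '", id[[i]], "': ", conditionMessage(res), call. = FALSE)
      }
    } else {
      out_seq[[i]] <- res
    }
  }
  if (length(dropped)) {
    message(length(dropped), " record(s) dropped during validation")
  }
  out <- tibble::tibble(id = id[keep], sequence = out_seq[keep])
  if (!is.null(label)) out$label <- label[keep]
  attr(out, "dropped") <- dropped
  out
}

#' Canonicalize one peptide sequence
#'
#' Enforces the 20-letter amino-acid alphabet. Under `"strict"` any other
#' character is an error. Under `"map"` the common ambiguity/rare codes are
#' substituted by their nearest canonical residue (B to N, Z to Q, U to C,
#' O to K, J to L); `X` and gap characters are always rejected.
#'
#' @param seq A single sequence string.
#' @param policy `"strict"` (default) or `"map"`.
#' @param min_length Minimum accepted length after mapping (default 4).
#' @return The canonical upper-case sequence.
#' @export
validate_sequence <- function(seq, policy = c("strict", "map"),
                              min_length = 4L) {
  policy <- match.arg(policy)
  if (length(seq) != 1L || is.na(seq)) {
    stop("`seq` must be a single string", call. = FALSE)
  }
  s <- toupper(gsub("[[:space:]*]", "", seq))
  if (policy == "map") {
    s <- chartr("BZUOJ", "NQCKL", s)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), aa_alphabet())
  if (length(bad)) {
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nchar(s) < min_length) {
    stop("sequence too short for lambda = 3 descriptors (length ",
         nchar(s), " < ", min_length, ")", call. = FALSE)
  }
  s
}

.parse_header_label <- function(headers) {
  token <- sub("^.*\\|", "", headers)
  lab <- ifelse(toupper(token) == toupper(.label_pos_token), 1L,
                ifelse(toupper(token) %in% c("NONNP", "NON-NP"), 0L, NA_integer_))
  lab
}

#' Read peptide sequences from FASTA
#'
#' Labels can be encoded as a trailing `|NP` / `|nonNP` token on the FASTA
#' header (`label_policy = "header"`), supplied as a two-column table
#' (`labels`, columns `id` and `label`), or omitted. With
#' `label_policy = "auto"` headers are used when every record carries a
#' recognizable token.
#'
#' @param path FASTA file path.
#' @param label_policy One of `"auto"`, `"header"`, `"none"`.
#' @param labels Optional data frame (or TSV path) with columns `id`,
#'   `label` (0/1 or NP/nonNP strings).
#' @param policy,min_length Passed to [peptide_dataset()].
#' @return A peptide dataset tibble.
#' @export
read_fasta <- function(path, label_policy = c("auto", "header", "none"),
                       labels = NULL, policy = "strict", min_length = 4L) {
  label_policy <- match.arg(label_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  headers <- names(set)
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    bad <- which(!nzchar(seqs))[1]
    stop("empty sequence at entry ", bad, " ('", headers[bad], "')",
         call. = FALSE)
  }
  header_lab <- .parse_header_label(headers)
  use_header <- label_policy == "header" ||
    (label_policy == "auto" && length(headers) > 0 && !anyNA(header_lab) &&
       is.null(labels))
  ids <- if (any(!is.na(header_lab))) sub("\\|[^|]*$", "", headers) else headers
  ids <- sub("\\s.*$", "", ids)  # first token of the header
  lab <- NULL
  if (use_header) {
    if (anyNA(header_lab)) {
      stop("label_policy = 'header' but unrecognized label token on entries: ",
           paste(utils::head(which(is.na(header_lab)), 5), collapse = ", "),
           call. = FALSE)
    }
    lab <- header_lab
  } else if (!is.null(labels)) {
    if (is.character(labels) && length(labels) == 1L) {
      labels <- utils::read.delim(labels, stringsAsFactors = FALSE)
    }
    if (!all(c("id", "label") %in% names(labels))) {
      stop("label table must have columns `id` and `label`", call. = FALSE)
    }
    m <- match(ids, labels$id)
    if (anyNA(m)) {
      stop("no label for id(s): ",
           paste(utils::head(ids[is.na(m)], 5), collapse = ", "),
           call. = FALSE)
    }
    lv <- labels$label[m]
    if (is.character(lv)) lv <- ifelse(toupper(lv) == "NP", 1L, 0L)
    lab <- as.integer(lv)
  } else if (!any(!is.na(header_lab))) {
    ids <- sub("\\s.*$", "", headers)
  }
  peptide_dataset(ids, seqs, label = lab, policy = policy,
                  min_length = min_length)
}

#' Write a peptide dataset to FASTA
#'
#' If labels are present they are appended to the header as `|NP` / `|nonNP`.
#'
#' @param ds Peptide dataset tibble.
#' @param path Output path.
#' @param label_in_header Append the label token when labels exist (default
#'   TRUE).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path, label_in_header = TRUE) {
  headers <- ds$id
  if (label_in_header && "label" %in% names(ds)) {
    headers <- paste0(ds$id, "|",
                      ifelse(ds$label == 1L, .label_pos_token, .label_neg_token))
  }
  lines <- as.vector(rbind(paste0(">", headers), ds$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Write a feature table to CSV/TSV
#'
#' Header row is `id` followed by the schema names; values are printed with
#' six significant digits. Non-finite values are refused with a row/column
#' report.
#'
#' @param features Feature tibble from [featurize()] (column `id` first).
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  stopifnot(names(features)[1] == "id")
  num <- as.matrix(features[, -1, drop = FALSE])
  if (nrow(num) && !all(is.finite(num))) {
    bad <- which(!is.finite(num), arr.ind = TRUE)[1, ]
    stop("non-finite value at row ", bad[1], " (id '", features$id[bad[1]],
         "'), column '", colnames(num)[bad[2]], "'", call. = FALSE)
  }
  out <- features
  out[-1] <- lapply(out[-1], function(x) signif(x, 6))
  utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"csv"`; guessed from the extension by default.
#' @return A tibble with `id` first and numeric feature columns.
#' @export
read_feature_table <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  df <- utils::read.table(path, header = TRUE, sep = if (format == "tsv") "\t" else ",",
                          stringsAsFactors = FALSE, check.names = FALSE)
  tibble::as_tibble(df)
}

.has_labels <- function(ds) "label" %in% names(ds)

.assert_labelled <- function(ds, both_classes = TRUE) {
  if (!.has_labels(ds)) stop("dataset has no `label` column", call. = FALSE)
  if (both_classes && length(unique(ds$label)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  invisible(ds)
}
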
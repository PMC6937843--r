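#' Read an aligned FASTA file
#'
#' Reads a multi-record FASTA file into a [multiple_alignment()]. Record
#' order is preserved, wrapped sequence lines are concatenated and sequences
#' are uppercased. Validation is strict: unequal row lengths, duplicate
#' labels and characters outside the permitted alphabet are errors.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param type Alphabet to validate against, `"nucleotide"` (default) or
#'   `"amino"`.
#' @return A `multiple_alignment`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, type = c("nucleotide", "amino")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  # labels are everything up to the first whitespace, as most tools emit them
  labels <- sub("\\s.*$", "", names(set))
  multiple_alignment(labels, as.character(set), type = type)
}

#' Write an alignment as FASTA
#'
#' @param aln A `multiple_alignment`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(aln, path, width = 60L) {
  stopifnot(inherits(aln, "multiple_alignment"))
  if (n_taxa(aln) == 0L) stop("empty alignment", call. = FALSE)
  set <- Biostrings::BStringSet(stats::setNames(aln$rows, aln$taxa))
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}
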
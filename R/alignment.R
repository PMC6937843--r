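#' Multiple sequence alignment container
#'
#' A minimal value type for an aligned set of sequences: an ordered vector of
#' unique taxon labels and one row string per taxon, all of equal length.
#' Nucleotide alignments are restricted to the IUPAC nucleotide alphabet
#' (`A C G T U R Y S W K M B D H V N`) plus gap `-` and missing `?`;
#' amino-acid alignments (as produced by [translate_alignment()]) use the
#' 20 standard residue letters plus `X`, `*`, `-` and `?`.
#'
#' @param taxa Character vector of unique sequence labels.
#' @param rows Character vector of aligned sequences, one per taxon, all the
#'   same length. Stored uppercase.
#' @param type `"nucleotide"` (default) or `"amino"`; selects the permitted
#'   alphabet.
#' @return An object of class `multiple_alignment` with fields `taxa`,
#'   `rows` and `type`.
#' @examples
#' aln <- multiple_alignment(c("t1", "t2"), c("ACGT", "AC-T"))
#' n_taxa(aln)
#' n_sites(aln)
#' @export
multiple_alignment <- function(taxa, rows, type = c("nucleotide", "amino")) {
  type <- match.arg(type)
  taxa <- as.character(taxa)
  rows <- toupper(as.character(rows))
  if (length(taxa) == 0L) {
    stop("alignment must contain at least one sequence", call. = FALSE)
  }
  if (length(taxa) != length(rows)) {
    stop("'taxa' and 'rows' must have equal length", call. = FALSE)
  }
  if (anyDuplicated(taxa)) {
    dup <- unique(taxa[duplicated(taxa)])
    stop("duplicate taxon label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  widths <- nchar(rows)
  if (length(unique(widths)) > 1L) {
    stop("alignment rows differ in length (",
         paste(unique(widths), collapse = ", "), ")", call. = FALSE)
  }
  alphabet <- if (type == "nucleotide") .nt_alphabet else .aa_alphabet
  for (i in seq_along(rows)) {
    chars <- strsplit(rows[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!(chars %in% alphabet))
    if (length(bad)) {
      stop(sprintf("illegal character '%s' at position %d of sequence '%s'",
                   chars[bad[1L]], bad[1L], taxa[[i]]), call. = FALSE)
    }
  }
  structure(list(taxa = taxa, rows = rows, type = type),
            class = "multiple_alignment")
}

.nt_alphabet <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-", "?")
.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                  "X", "*", "-", "?")

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("multiple_alignment: %d %s sequences, %d columns\n",
              n_taxa(x), x$type, n_sites(x)))
  show <- utils::head(seq_along(x$taxa), 6L)
  for (i in show) {
    row <- x$rows[[i]]
    if (nchar(row) > 50L) row <- paste0(substr(row, 1L, 50L), "...")
    cat(sprintf("  %-12s %s\n", x$taxa[[i]], row))
  }
  if (n_taxa(x) > 6L) cat(sprintf("  ... and %d more\n", n_taxa(x) - 6L))
  invisible(x)
}

#' @rdname multiple_alignment
#' @param aln A `multiple_alignment`.
#' @export
n_taxa <- function(aln) length(aln$taxa)

#' @rdname multiple_alignment
#' @export
n_sites <- function(aln) if (length(aln$rows)) nchar(aln$rows[[1L]]) else 0L

#' Alignment as a character matrix
#'
#' @param aln A `multiple_alignment`.
#' @return Character matrix, one row per taxon, one column per site, with
#'   taxa as row names.
#' @keywords internal
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- aln$taxa
  m
}

.aln_from_matrix <- function(m, type = "nucleotide") {
  multiple_alignment(rownames(m), apply(m, 1L, paste, collapse = ""),
                     type = type)
}

#' Reorder alignment rows to a reference taxa order
#'
#' Working with many alignments of the same gene (one per estimation
#' strategy) is much easier when every alignment lists its taxa in the same
#' order; this permutes rows only, columns are untouched.
#'
#' @param alns A single `multiple_alignment` or a list of them.
#' @param reference Character vector giving the required taxa order. Every
#'   alignment's taxon set must equal this set.
#' @return Input alignment(s) with rows permuted into `reference` order; a
#'   list in, a list out.
#' @export
normalize_taxa_order <- function(alns, reference) {
  single <- inherits(alns, "multiple_alignment")
  if (single) alns <- list(alns)
  reference <- as.character(reference)
  out <- lapply(alns, function(a) {
    missing <- setdiff(reference, a$taxa)
    extra <- setdiff(a$taxa, reference)
    if (length(missing) || length(extra)) {
      stop("taxon set mismatch",
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; extra: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    }
    idx <- match(reference, a$taxa)
    multiple_alignment(a$taxa[idx], a$rows[idx], type = a$type)
  })
  if (single) out[[1L]] else out
}
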
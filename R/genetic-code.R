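#' Genetic code tables
#'
#' Wraps an NCBI translation table (via Biostrings) as a plain codon-to-
#' amino-acid map over the 64 `ACGT` codons, with `*` marking stops. The
#' table id follows the NCBI numbering (1 = standard, 2 = vertebrate
#' mitochondrial, 5 = invertebrate mitochondrial, ...). A custom code can
#' be supplied directly as a named character vector of 64 codons.
#'
#' @param table_id NCBI translation table identifier (default 1, the
#'   standard code), or ignored when `codon_to_aa` is given.
#' @param codon_to_aa Optional named character vector mapping all 64 ACGT
#'   codons to single amino-acid letters (`*` for stop).
#' @return An object of class `genetic_code` with fields `table_id` and
#'   `codon_to_aa`.
#' @examples
#' gc <- genetic_code(1)
#' gc$codon_to_aa[["ATG"]]
#' @export
genetic_code <- function(table_id = 1, codon_to_aa = NULL) {
  if (is.null(codon_to_aa)) {
    codon_to_aa <- Biostrings::getGeneticCode(as.character(table_id))
  }
  codon_to_aa <- codon_to_aa[order(names(codon_to_aa))]
  if (length(codon_to_aa) != 64L ||
      !setequal(names(codon_to_aa), all_codons())) {
    stop("genetic code must map exactly the 64 ACGT codons", call. = FALSE)
  }
  if (!any(codon_to_aa == "*")) {
    stop("genetic code must contain at least one stop codon", call. = FALSE)
  }
  structure(list(table_id = table_id,
                 codon_to_aa = unclass(codon_to_aa)),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("genetic_code: table %s (%d stop codons)\n", x$table_id,
              sum(x$codon_to_aa == "*")))
  invisible(x)
}

#' All 64 ACGT codons, alphabetically
#' @keywords internal
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

# IUPAC code for a set of nucleotides; key is the sorted, deduplicated
# concatenation of the bases present.
.iupac_union_table <- c(
  A = "A", C = "C", G = "G", T = "T",
  AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
  CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
)

#' IUPAC code for a union of nucleotides
#'
#' @param bases Character vector of bases drawn from A, C, G, T.
#' @return Single IUPAC nucleotide code covering exactly those bases.
#' @keywords internal
iupac_union <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- .iupac_union_table[[key]]
  if (is.null(code)) stop("not a nucleotide set: ", key, call. = FALSE)
  code
}
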
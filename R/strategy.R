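#' Strategy identifiers
#'
#' A "strategy" is the chain of algorithms applied to one gene on its way to
#' a phylogeny: the alignment estimator (AE), an optional alignment
#' refinement/consensus step (ARC), the character coding or phylogeny
#' estimation method (CC/PE), and an optional tree-editing/bootstrap suffix
#' (ED). File names encode the chain as underscore-separated codes,
#' `GENE_AE[_ARC][_CC][_ED]`, e.g. `ATP8_MAFFTF2_TRIMALS_DNA_UB`.
#'
#' Because gene names may themselves contain underscores while stage codes
#' may not, names are parsed right-to-left against per-stage code
#' vocabularies: the rightmost tokens are matched (optionally) to the ED,
#' CC, ARC and AE vocabularies in that order, and whatever remains is the
#' gene name.
#'
#' @param gene Gene name (may contain underscores).
#' @param ae Stage-2 alignment-estimator code.
#' @param arc Stage-4 refinement code, or `""` when absent.
#' @param cc Stage-5 character-coding / estimation code (e.g. `DNA`, `RY`,
#'   `DEG`, `CDN`, `NT2AA`), or `""` when absent.
#' @param ed Stage-7 / bootstrap suffix code, or `""` when absent.
#' @return `strategy_id()` returns an object of class `strategy_id`;
#'   `render_strategy()` returns the underscore-joined name string.
#' @examples
#' s <- parse_strategy_id("ATP8_MAFFTF2_TRIMALS_DNA_UB")
#' s$gene
#' render_strategy(s)
#' @export
strategy_id <- function(gene, ae = "", arc = "", cc = "", ed = "") {
  stopifnot(is.character(gene), nchar(gene) > 0L)
  structure(list(gene = gene, ae = ae, arc = arc, cc = cc, ed = ed),
            class = "strategy_id")
}

#' @rdname strategy_id
#' @param id A `strategy_id`.
#' @export
render_strategy <- function(id) {
  stopifnot(inherits(id, "strategy_id"))
  parts <- c(id$gene, id$ae, id$arc, id$cc, id$ed)
  paste(parts[nzchar(parts)], collapse = "_")
}

#' @export
format.strategy_id <- function(x, ...) render_strategy(x)

#' @export
print.strategy_id <- function(x, ...) {
  cat("strategy_id:", render_strategy(x), "\n")
  cat(sprintf("  gene=%s ae=%s arc=%s cc=%s ed=%s\n",
              x$gene, x$ae, x$arc, x$cc, x$ed))
  invisible(x)
}

#' Default per-stage code vocabulary
#'
#' The vocabulary lists, per pipeline stage, the codes that may appear in a
#' strategy name. The defaults cover the common alignment estimators
#' (Clustal, MAFFT variants, MUSCLE, Prank variants, ...), refinement tools
#' (Gblocks, TrimAl modes, MaxAlign, ...), character-coding / estimation
#' methods and bootstrap suffixes. Extend or replace any component to match
#' a local naming scheme.
#'
#' @return Named list with character-vector components `ae`, `arc`, `cc`
#'   and `ed`.
#' @export
default_strategy_vocab <- function() {
  list(
    ae = c("CLUSTALO", "CLUSTALW", "DIALIGNTX", "DIALIGNTXD", "DIALIGNTXT",
           "FSA", "FSANP", "GRAMALIGN", "KALIGN", "MACSE", "MACSEPG",
           "MAFFT", "MAFFTA", "MAFFTEI", "MAFFTF1", "MAFFTF2", "MAFFTFI",
           "MAFFTGI", "MAFFTLI", "MUSCLE", "OPAL", "PRANK", "PRANKF",
           "PRANKO", "PRANKCD", "PRANKCDF", "PRANKCDO", "PROBALIGN",
           "PROBCONS", "TCOFFEE", "TCOFFEEK", "TCOFFEEP", "TCOFFEEL"),
    arc = c("GBLOCKSD", "GBLOCKSC", "MAXALIGN", "MERGEALIGN", "NOISY",
            "PSAR", "TCS", "TCSO", "TCSFM", "TRIMAL", "TRIMALA1",
            "TRIMALG", "TRIMALS", "TRIMALSP", "TRIMALC", "WEAVEALIGN"),
    cc = c("DNA", "DNA12", "DNA3", "RY", "RY3", "DEG", "CDN", "NT2AA",
           "MPB", "NJ", "SMSAN", "SMSAS", "SMSBN", "SMSBS"),
    ed = c("UB", "SB")
  )
}

#' @rdname strategy_id
#' @param filename File name (or path) whose stem encodes a strategy.
#' @param vocab Per-stage code vocabulary, as from
#'   [default_strategy_vocab()].
#' @export
parse_strategy_id <- function(filename, vocab = default_strategy_vocab()) {
  stem <- sub("\\.[A-Za-z0-9]+$", "", basename(filename))
  toks <- strsplit(stem, "_", fixed = TRUE)[[1L]]
  if (length(toks) < 2L) {
    stop("unparseable strategy name '", stem,
         "': expected underscore-separated stage codes", call. = FALSE)
  }
  i <- length(toks)
  take <- function(stage) {
    if (i >= 1L && toks[i] %in% vocab[[stage]]) {
      tok <- toks[i]
      i <<- i - 1L
      tok
    } else ""
  }
  ed <- take("ed")
  cc <- take("cc")
  arc <- take("arc")
  ae <- take("ae")
  if (!nzchar(ed) && !nzchar(cc) && !nzchar(arc) && !nzchar(ae)) {
    stop("unparseable strategy name '", stem,
         "': no token matches any stage vocabulary", call. = FALSE)
  }
  if (i < 1L) {
    stop("unparseable strategy name '", stem, "': empty gene name",
         call. = FALSE)
  }
  strategy_id(paste(toks[seq_len(i)], collapse = "_"),
              ae = ae, arc = arc, cc = cc, ed = ed)
}
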
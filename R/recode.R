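#' RY-code a nucleotide alignment
#'
#' Collapses nucleotides to their purine/pyrimidine class: `A`,`G`,`R` map
#' to `R` and `C`,`T`,`U`,`Y` map to `Y`. Ambiguity codes that mix the two
#' classes (`S`, `W`, `K`, `M`, `B`, `D`, `H`, `V`, `N`) become `N`; gaps
#' `-` and missing `?` pass through. RY coding removes the (frequently
#' saturated and compositionally biased) transition signal while keeping
#' transversions, and is commonly restricted to third codon positions.
#'
#' @param aln A nucleotide `multiple_alignment`.
#' @param positions `"all"` (default) to recode every column, or `"third"`
#'   to recode only third codon positions.
#' @param frame 1-based reading-frame offset (1, 2 or 3); with `frame = 1`
#'   third positions are columns 3, 6, 9, ...
#' @return A `multiple_alignment` of the same shape; recoded columns use
#'   only `R`, `Y`, `N`, `-`, `?`.
#' @examples
#' aln <- multiple_alignment("t1", "ACGT")
#' ry_encode(aln)$rows
#' @export
ry_encode <- function(aln, positions = c("all", "third"), frame = 1L) {
  stopifnot(inherits(aln, "multiple_alignment"))
  positions <- match.arg(positions)
  frame <- .check_frame(frame)
  map <- c(A = "R", G = "R", R = "R",
           C = "Y", T = "Y", U = "Y", Y = "Y",
           "-" = "-", "?" = "?")
  m <- aln_matrix(aln)
  cols <- if (positions == "all") seq_len(ncol(m)) else
    which(((seq_len(ncol(m)) - frame) %% 3L) == 2L)
  if (length(cols)) {
    sub <- m[, cols, drop = FALSE]
    rec <- map[sub]
    rec[is.na(rec)] <- "N"
    m[, cols] <- rec
  }
  .aln_from_matrix(m)
}

.check_frame <- function(frame) {
  frame <- as.integer(frame)
  if (length(frame) != 1L || is.na(frame) || !(frame %in% 1:3)) {
    stop("'frame' must be 1, 2 or 3", call. = FALSE)
  }
  frame
}

#' Build a degeneracy-coding table from a genetic code
#'
#' Degeneracy coding erases synonymous variation: every codon in a group of
#' codons that are interconvertible by synonymous single-nucleotide
#' substitutions is replaced by one degenerate codon whose IUPAC letters
#' cover, at each position, exactly the nucleotides seen across the group.
#' Under the standard code the leucine codons \{TTA, TTG, CTT, CTC, CTA,
#' CTG\} all become `YTN`, while the two serine groups stay apart (`AGY`
#' vs `TCN`) because no single synonymous substitution connects them.
#'
#' The table is derived algorithmically from the genetic code: build a
#' graph on the 64 codons with an edge between codons that differ at
#' exactly one position and encode the same amino acid, take connected
#' components, and for each component form the positionwise IUPAC union.
#' Stop-codon components are handled like any other. This works for any
#' translation table, not just the standard one.
#'
#' @param code A [genetic_code()].
#' @return An object of class `degen_table`: list with `codon_to_degen`
#'   (named character vector over the 64 codons) and `table_id`.
#' @examples
#' dt <- build_degen_table(genetic_code(1))
#' dt$codon_to_degen[["CTA"]]  # "YTN"
#' @export
build_degen_table <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  codons <- all_codons()
  aa <- code$codon_to_aa[codons]
  n <- length(codons)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  bases <- c("A", "C", "G", "T")
  idx <- stats::setNames(seq_len(n), codons)
  for (i in seq_len(n)) {
    cs <- strsplit(codons[i], "")[[1L]]
    for (p in 1:3) {
      for (b in bases) {
        if (b == cs[p]) next
        alt <- cs
        alt[p] <- b
        j <- idx[[paste(alt, collapse = "")]]
        if (j > i && aa[j] == aa[i]) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  degen <- character(n)
  for (r in unique(comp)) {
    members <- codons[comp == r]
    chars <- do.call(rbind, strsplit(members, ""))
    dg <- paste(vapply(1:3, function(p) iupac_union(chars[, p]),
                       character(1L)), collapse = "")
    degen[comp == r] <- dg
  }
  structure(list(codon_to_degen = stats::setNames(degen, codons),
                 table_id = code$table_id),
            class = "degen_table")
}

#' @export
print.degen_table <- function(x, ...) {
  cat(sprintf("degen_table: table %s, %d degenerate codon groups\n",
              x$table_id, length(unique(x$codon_to_degen))))
  invisible(x)
}

#' Apply degeneracy coding to an alignment
#'
#' Replaces every in-frame codon consisting solely of `A`/`C`/`G`/`T`
#' (`U` read as `T`) by its degenerate image from `table`. Codons
#' containing gaps, `?` or ambiguity codes, and trailing partial codons,
#' are copied through unchanged. Alignment length is preserved.
#'
#' @param aln A nucleotide `multiple_alignment` of aligned coding sequence.
#' @param table A [build_degen_table()] result.
#' @param frame 1-based reading-frame offset (1, 2 or 3).
#' @return Recoded `multiple_alignment` of identical shape.
#' @export
degen_encode <- function(aln, table, frame = 1L) {
  stopifnot(inherits(aln, "multiple_alignment"), inherits(table, "degen_table"))
  frame <- .check_frame(frame)
  tab <- table$codon_to_degen
  rows <- vapply(aln$rows, function(row) {
    L <- nchar(row)
    i <- frame
    while (i + 2L <= L) {
      codon <- substr(row, i, i + 2L)
      key <- chartr("U", "T", codon)
      if (grepl("^[ACGT]{3}$", key)) {
        substr(row, i, i + 2L) <- tab[[key]]
      }
      i <- i + 3L
    }
    row
  }, character(1L), USE.NAMES = FALSE)
  multiple_alignment(aln$taxa, rows)
}

#' Extract codon-position columns
#'
#' Restricting an alignment to first+second codon positions (or to third
#' positions alone) is a standard response to substitution saturation at
#' synonymous sites. Columns are assigned positions cyclically from
#' `frame`; the selected columns are kept in their original order.
#'
#' @param aln A `multiple_alignment`.
#' @param keep Subset of `c(1, 2, 3)`: codon positions to keep.
#' @param frame 1-based reading-frame offset (1, 2 or 3).
#' @return `multiple_alignment` holding only the selected columns.
#' @export
extract_codon_positions <- function(aln, keep, frame = 1L) {
  stopifnot(inherits(aln, "multiple_alignment"))
  frame <- .check_frame(frame)
  keep <- as.integer(keep)
  if (length(keep) == 0L || !all(keep %in% 1:3)) {
    stop("'keep' must be a non-empty subset of 1:3", call. = FALSE)
  }
  L <- n_sites(aln)
  pos <- ((seq_len(L) - frame) %% 3L) + 1L
  cols <- which(pos %in% keep)
  m <- aln_matrix(aln)[, cols, drop = FALSE]
  multiple_alignment(aln$taxa, apply(m, 1L, function(r)
    paste(r, collapse = "")), type = aln$type)
}

#' Translate a nucleotide alignment to amino acids
#'
#' In-frame codons of pure `A`/`C`/`G`/`T` (`U` as `T`) are translated
#' through `code`; an all-gap codon becomes `-`; stop codons become `*`.
#' A codon made of IUPAC ambiguity codes is resolved in two steps: if
#' every nucleotide combination it covers encodes one amino acid, that
#' amino acid is emitted; failing that, if the codon is the degeneracy
#' image of a synonym group of `code` (e.g. `YTN` for leucine, `MGN` for
#' arginine under the standard code, whose IUPAC unions overcover the
#' group) the group's amino acid is emitted; otherwise `X`. Codons
#' containing gaps or `?` alongside bases become `X`. The leading
#' `frame - 1` columns and any trailing partial codon are dropped.
#'
#' @param aln A nucleotide `multiple_alignment`.
#' @param code A [genetic_code()].
#' @param frame 1-based reading-frame offset (1, 2 or 3).
#' @param strip_final_stop If `TRUE`, remove the final amino-acid column
#'   when every row ends in `*` (gap/missing rows ignored); rows that
#'   disagree (some stop, some residue) raise an error.
#' @return An amino-acid `multiple_alignment`.
#' @examples
#' translate_alignment(multiple_alignment("t1", "ATGTGG"), genetic_code(1))$rows
#' @export
translate_alignment <- function(aln, code = genetic_code(1), frame = 1L,
                                strip_final_stop = FALSE) {
  stopifnot(inherits(aln, "multiple_alignment"), inherits(code, "genetic_code"))
  frame <- .check_frame(frame)
  tab <- code$codon_to_aa
  expand <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
              R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
              B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  # degenerate images can overcover their synonym group (YTN spans TTY
  # phenylalanine as well as the leucine codons), so expansion alone
  # cannot decode them: fall back to the code's own degeneracy table
  img2aa <- tapply(tab, build_degen_table(code)$codon_to_degen[names(tab)],
                   function(x) unique(x))
  resolve <- function(key) {
    parts <- strsplit(expand[strsplit(key, "")[[1L]]], "")
    combos <- expand.grid(parts, stringsAsFactors = FALSE)
    aa <- unique(tab[paste0(combos[[1L]], combos[[2L]], combos[[3L]])])
    if (length(aa) == 1L) return(aa)
    byimg <- img2aa[[key]]
    if (!is.null(byimg) && length(byimg) == 1L) byimg else "X"
  }
  rows <- vapply(aln$rows, function(row) {
    L <- nchar(row)
    n_codons <- max(0L, (L - frame + 1L) %/% 3L)
    if (n_codons == 0L) return("")
    starts <- frame + 3L * (seq_len(n_codons) - 1L)
    aa <- vapply(starts, function(i) {
      codon <- substr(row, i, i + 2L)
      key <- chartr("U", "T", codon)
      if (grepl("^[ACGT]{3}$", key)) tab[[key]]
      else if (codon == "---") "-"
      else if (grepl("^[ACGTRYSWKMBDHVN]{3}$", key)) resolve(key)
      else "X"
    }, character(1L))
    paste(aa, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  out <- multiple_alignment(aln$taxa, rows, type = "amino")
  if (strip_final_stop && n_sites(out) > 0L) {
    last <- substr(out$rows, n_sites(out), n_sites(out))
    informative <- !(last %in% c("-", "?", "X"))
    if (any(last[informative] == "*")) {
      if (!all(last[informative] == "*")) {
        stop("ragged final stop: some sequences end in a stop codon, ",
             "others do not", call. = FALSE)
      }
      out <- multiple_alignment(
        out$taxa, substr(out$rows, 1L, n_sites(out) - 1L), type = "amino")
    }
  }
  out
}

#' Remove or mask stop codons
#'
#' Coding-sequence inputs routinely carry their terminal stop codon, which
#' alignment and tree software does not expect. `mode = "final-only"`
#' removes the last complete in-frame codon triple when it is a stop codon
#' in every row whose final codon is gap-free (an error is raised when rows
#' disagree); `mode = "mask-internal"` replaces internal stop codons with
#' `NNN` and leaves the final codon alone.
#'
#' @param aln A nucleotide `multiple_alignment`.
#' @param code A [genetic_code()].
#' @param frame 1-based reading-frame offset (1, 2 or 3).
#' @param mode `"final-only"` or `"mask-internal"`.
#' @return A `multiple_alignment`.
#' @export
strip_stop_codons <- function(aln, code = genetic_code(1), frame = 1L,
                              mode = c("final-only", "mask-internal")) {
  stopifnot(inherits(aln, "multiple_alignment"), inherits(code, "genetic_code"))
  frame <- .check_frame(frame)
  mode <- match.arg(mode)
  stops <- names(code$codon_to_aa)[code$codon_to_aa == "*"]
  L <- n_sites(aln)
  n_codons <- max(0L, (L - frame + 1L) %/% 3L)
  if (n_codons == 0L) return(aln)
  starts <- frame + 3L * (seq_len(n_codons) - 1L)

  if (mode == "final-only") {
    i <- starts[n_codons]
    final <- chartr("U", "T", substr(aln$rows, i, i + 2L))
    considered <- grepl("^[ACGT]{3}$", final)
    is_stop <- final %in% stops
    if (!any(is_stop)) return(aln)
    if (any(considered & !is_stop)) {
      stop("ragged final stop: some sequences end in a stop codon, ",
           "others do not", call. = FALSE)
    }
    keep <- setdiff(seq_len(L), i:(i + 2L))
    m <- aln_matrix(aln)[, keep, drop = FALSE]
    return(multiple_alignment(aln$taxa, apply(m, 1L, paste, collapse = "")))
  }

  internal <- starts[-n_codons]
  rows <- vapply(aln$rows, function(row) {
    for (i in internal) {
      if (chartr("U", "T", substr(row, i, i + 2L)) %in% stops) {
        substr(row, i, i + 2L) <- "NNN"
      }
    }
    row
  }, character(1L), USE.NAMES = FALSE)
  multiple_alignment(aln$taxa, rows)
}
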
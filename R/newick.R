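#' Read and write Newick tree files
#'
#' Thin, validating wrappers around ape's Newick support. Branch lengths
#' and support values are parsed and retained, but all topology metrics in
#' this package ignore them. Multi-tree files (one tree per line) yield a
#' list of `phylo` objects; trees are validated for duplicate leaf labels,
#' which ape itself tolerates.
#'
#' @param path Path to a Newick file.
#' @return `read_newick()`: a single `phylo` when the file holds one tree,
#'   otherwise a plain list of `phylo` objects (named after the `multiPhylo`
#'   names when present).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  trees <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) stop("Newick parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(trees)) {
    stop("Newick parse error in ", path, ": no tree could be read",
         call. = FALSE)
  }
  check <- function(tr) {
    if (anyDuplicated(tr$tip.label)) {
      dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
      stop("duplicate leaf label(s) in ", path, ": ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    tr
  }
  if (inherits(trees, "multiPhylo")) {
    out <- lapply(trees, check)
    names(out) <- names(trees)
    out
  } else {
    check(trees)
  }
}

#' @rdname read_newick
#' @param trees A `phylo` or a (possibly named) list of `phylo` objects;
#'   lists are written one tree per line.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  lines <- vapply(trees, function(tr) {
    stopifnot(inherits(tr, "phylo"))
    ape::write.tree(tr)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
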
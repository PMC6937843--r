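#' Site-wise log-likelihood tables
#'
#' Phylogeny estimators such as TREE-PUZZLE and IQ-TREE can print, for each
#' evaluated tree, the log-likelihood of every alignment column. The text
#' format is a header line `n_trees n_sites` followed by one record per
#' tree: a name token and then `n_sites` numeric values (line wrapping
#' within a record is permitted). These per-site values are the input to
#' the RELL bootstrap and AU test (see [rell_bp()], [au_pvalue()]).
#'
#' @param names Character vector of tree/strategy labels, one per row.
#' @param loglik Numeric matrix of per-site log-likelihoods,
#'   `length(names)` rows.
#' @return An object of class `sitelh` with fields `n_trees`, `n_sites`,
#'   `names` and `loglik`.
#' @export
sitelh <- function(names, loglik) {
  loglik <- as.matrix(loglik)
  names <- as.character(names)
  if (nrow(loglik) != length(names)) {
    stop("'names' must have one entry per row of 'loglik'", call. = FALSE)
  }
  if (!is.numeric(loglik) || anyNA(loglik)) {
    stop("'loglik' must be numeric with no missing values", call. = FALSE)
  }
  rownames(loglik) <- names
  structure(list(n_trees = nrow(loglik), n_sites = ncol(loglik),
                 names = names, loglik = loglik),
            class = "sitelh")
}

#' @export
print.sitelh <- function(x, ...) {
  cat(sprintf("sitelh: %d tree(s) x %d sites\n", x$n_trees, x$n_sites))
  invisible(x)
}

#' @rdname sitelh
#' @param path Path to a site-wise log-likelihood file.
#' @export
read_sitelh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  toks <- scan(path, what = character(), quiet = TRUE)
  if (length(toks) < 2L) stop("empty sitelh file: ", path, call. = FALSE)
  n_trees <- suppressWarnings(as.integer(toks[1L]))
  n_sites <- suppressWarnings(as.integer(toks[2L]))
  if (is.na(n_trees) || is.na(n_sites) || n_trees < 1L || n_sites < 1L) {
    stop("sitelh header must be two positive integers, got '",
         toks[1L], " ", toks[2L], "'", call. = FALSE)
  }
  expected <- 2L + n_trees * (n_sites + 1L)
  if (length(toks) != expected) {
    stop(sprintf(
      "truncated or overlong sitelh file '%s': expected %d tokens for %d tree(s) x %d sites, found %d",
      path, expected, n_trees, n_sites, length(toks)), call. = FALSE)
  }
  body <- toks[-(1:2)]
  nm <- character(n_trees)
  ll <- matrix(NA_real_, n_trees, n_sites)
  for (i in seq_len(n_trees)) {
    off <- (i - 1L) * (n_sites + 1L)
    nm[i] <- body[off + 1L]
    vals <- suppressWarnings(as.numeric(body[off + 1L + seq_len(n_sites)]))
    if (anyNA(vals)) {
      stop("non-numeric log-likelihood value in record '", nm[i], "' of ",
           path, call. = FALSE)
    }
    ll[i, ] <- vals
  }
  sitelh(nm, ll)
}

#' @rdname sitelh
#' @param s A `sitelh` object.
#' @param precision Significant digits used when writing values (default 6).
#' @export
write_sitelh <- function(s, path, precision = 6L) {
  stopifnot(inherits(s, "sitelh"))
  lines <- c(
    paste(s$n_trees, s$n_sites),
    vapply(seq_len(s$n_trees), function(i) {
      paste(s$names[i],
            paste(formatC(s$loglik[i, ], digits = as.integer(precision),
                          format = "g"), collapse = " "))
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}
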
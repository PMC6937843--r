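# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the package's own split_system / cost-matrix /
# Hungarian code paths: splits come from phangorn, costs are recomputed
# from first principles, and the assignment optimum is found by exhaustive
# enumeration over all permutations.

# all permutations of a vector as a matrix, one permutation per row
perms <- function(v) {
  if (length(v) <= 1L) return(matrix(v, nrow = 1L))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- perms(v[-i])
    out <- rbind(out, cbind(v[i], rest, deparse.level = 0))
  }
  out
}

# nontrivial splits of an unrooted tree as canonical label sets (the side
# not containing the alphabetically first leaf), via phangorn
oracle_splits <- function(tree) {
  tree <- ape::unroot(tree)
  leaves <- sort(tree$tip.label)
  n <- length(leaves)
  sp <- phangorn::as.splits(tree)
  m <- as.matrix(sp)
  sets <- list()
  for (i in seq_len(nrow(m))) {
    side <- sort(colnames(m)[m[i, ] == 1])
    if (leaves[1L] %in% side) side <- sort(setdiff(leaves, side))
    if (length(side) >= 2L && length(side) <= n - 2L) {
      sets[[length(sets) + 1L]] <- side
    }
  }
  unique(sets)
}

oracle_rf <- function(t1, t2) {
  k1 <- vapply(oracle_splits(t1), paste, character(1L), collapse = "|")
  k2 <- vapply(oracle_splits(t2), paste, character(1L), collapse = "|")
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# matching distance by exhaustive enumeration over perfect matchings of
# the padded split systems (unrooted semantics)
oracle_matching <- function(t1, t2) {
  s1 <- oracle_splits(t1)
  s2 <- oracle_splits(t2)
  n <- length(t1$tip.label)
  a <- length(s1)
  b <- length(s2)
  k <- max(a, b)
  if (k == 0L) return(0)
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i <= a && j <= b) {
        h <- length(union(s1[[i]], s2[[j]])) -
             length(intersect(s1[[i]], s2[[j]]))
        cost[i, j] <- min(h, n - h)
      } else if (i <= a) {
        cost[i, j] <- min(length(s1[[i]]), n - length(s1[[i]]))
      } else if (j <= b) {
        cost[i, j] <- min(length(s2[[j]]), n - length(s2[[j]]))
      }
    }
  }
  p <- perms(seq_len(k))
  min(apply(p, 1L, function(pr) sum(cost[cbind(seq_len(k), pr)])))
}

# brute-force degeneracy table: breadth-first synonym components over
# single-substitution neighbors, positionwise nucleotide-union coding
oracle_degen_table <- function(code) {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(p1 = bases, p2 = bases, p3 = bases,
                   stringsAsFactors = FALSE)
  codons <- sort(paste0(g$p1, g$p2, g$p3))
  aa <- code$codon_to_aa[codons]
  iupac <- c(A = "A", C = "C", G = "G", T = "T", AG = "R", CT = "Y",
             CG = "S", AT = "W", GT = "K", AC = "M", CGT = "B",
             AGT = "D", ACT = "H", ACG = "V", ACGT = "N")
  neighbors <- function(c1) {
    out <- character(0L)
    for (p in 1:3) for (b in bases) {
      alt <- c1
      substr(alt, p, p) <- b
      if (alt != c1) out <- c(out, alt)
    }
    out
  }
  assigned <- setNames(rep(NA_character_, 64L), codons)
  for (start in codons) {
    if (!is.na(assigned[[start]])) next
    comp <- start
    frontier <- start
    while (length(frontier)) {
      nxt <- character(0L)
      for (c1 in frontier) {
        for (c2 in neighbors(c1)) {
          if (aa[[c2]] == aa[[c1]] && !(c2 %in% comp)) {
            comp <- c(comp, c2)
            nxt <- c(nxt, c2)
          }
        }
      }
      frontier <- nxt
    }
    chars <- do.call(rbind, strsplit(comp, ""))
    dg <- paste(vapply(1:3, function(p)
      iupac[[paste(sort(unique(chars[, p])), collapse = "")]],
      character(1L)), collapse = "")
    assigned[comp] <- dg
  }
  assigned
}

# random pure-coding row (no gaps/ambiguity) of n_codons codons
random_coding_row <- function(n_codons) {
  paste(sample(c("A", "C", "G", "T"), 3L * n_codons, replace = TRUE),
        collapse = "")
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")

cli_path <- function() {
  p <- system.file("exec", "phylopcc.R", package = "phylopcc")
  stopifnot(nzchar(p))
  p
}
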
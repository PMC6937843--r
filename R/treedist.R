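#' Split / cluster system of a tree
#'
#' The topology of a tree is captured by its nontrivial bipartitions: for
#' an unrooted tree, each internal edge splits the leaves in two (splits);
#' for a rooted tree, each internal node below the root defines the leaf
#' subset beneath it (clusters). Splits are stored canonically as the side
#' not containing the alphabetically first leaf; clusters as the leaf
#' subset itself. Trivial entries (singleton or full-set sides) are
#' excluded, so a star tree has an empty system.
#'
#' @param tree A `phylo` object with unique leaf labels.
#' @param mode `"unrooted"` for splits (default; a degree-2 root is
#'   collapsed first) or `"rooted"` for clusters.
#' @return An object of class `split_system`: list with `leaves` (sorted
#'   labels), `mode`, `sets` (list of sorted character vectors) and `keys`
#'   (canonical string per set).
#' @export
split_system <- function(tree, mode = c("unrooted", "rooted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  leaves <- sort(tree$tip.label)
  n <- length(leaves)
  if (anyDuplicated(leaves)) stop("duplicate leaf labels", call. = FALSE)
  if (n < if (mode == "unrooted") 3L else 2L) {
    stop("too few leaves for a ", mode, " split system", call. = FALSE)
  }
  if (mode == "unrooted" && ape::is.rooted(tree) && n >= 3L) {
    tree <- ape::unroot(tree)
  }
  sets <- list()
  if (tree$Nnode >= 2L) {
    pp <- ape::prop.part(tree)
    labs <- attr(pp, "labels")
    # entry 1 is the root (all leaves); the rest are internal nodes below it
    for (k in seq_along(pp)[-1L]) {
      side <- sort(labs[pp[[k]]])
      size <- length(side)
      ok <- if (mode == "unrooted") size >= 2L && size <= n - 2L
            else size >= 2L && size <= n - 1L
      if (!ok) next
      if (mode == "unrooted" && leaves[1L] %in% side) {
        side <- sort(setdiff(leaves, side))
      }
      sets[[length(sets) + 1L]] <- side
    }
  }
  keys <- vapply(sets, paste, character(1L), collapse = "\r")
  dedup <- !duplicated(keys)  # polytomy-safe; identical entries collapse
  structure(list(leaves = leaves, mode = mode,
                 sets = sets[dedup], keys = keys[dedup]),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  cat(sprintf("split_system (%s): %d leaves, %d nontrivial %s\n",
              x$mode, length(x$leaves), length(x$sets),
              if (x$mode == "unrooted") "splits" else "clusters"))
  invisible(x)
}

.check_same_leaves <- function(t1, t2) {
  l1 <- sort(t1$tip.label)
  l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    stop("leaf-set mismatch; only in first tree: ",
         paste(setdiff(l1, l2), collapse = ", "),
         "; only in second tree: ",
         paste(setdiff(l2, l1), collapse = ", "), call. = FALSE)
  }
}

.resolve_mode <- function(mode, t1, t2 = NULL) {
  if (mode != "auto") return(mode)
  rooted <- ape::is.rooted(t1) && (is.null(t2) || ape::is.rooted(t2))
  if (rooted) "rooted" else "unrooted"
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the two trees' nontrivial
#' split (or cluster) systems: the number of bipartitions present in one
#' tree but not the other. Zero if and only if the two systems are equal.
#' Branch lengths are ignored.
#'
#' @param t1,t2 `phylo` objects over the same leaf set.
#' @param mode `"unrooted"` (splits), `"rooted"` (clusters, the R-F
#'   variant computed on rooted trees), or `"auto"` (rooted when both
#'   inputs are rooted).
#' @param normalized If `TRUE`, divide by the maximum attainable for the
#'   leaf count (`2(n-3)` unrooted, `2(n-2)` rooted).
#' @return Non-negative integer (or a value in \[0, 1\] when normalized).
#' @export
rf_distance <- function(t1, t2, mode = c("unrooted", "rooted", "auto"),
                        normalized = FALSE) {
  mode <- .resolve_mode(match.arg(mode), t1, t2)
  .check_same_leaves(t1, t2)
  s1 <- split_system(t1, mode)
  s2 <- split_system(t2, mode)
  d <- length(setdiff(s1$keys, s2$keys)) + length(setdiff(s2$keys, s1$keys))
  if (normalized) {
    n <- length(s1$leaves)
    dmax <- if (mode == "unrooted") 2L * (n - 3L) else 2L * (n - 2L)
    if (dmax <= 0L) return(0)
    return(d / dmax)
  }
  d
}

#' Matching-based topological distance
#'
#' A refinement of Robinson-Foulds: instead of scoring unmatched splits
#' all-or-nothing, the two split systems are put in minimum-cost
#' one-to-one correspondence. The smaller system is padded with null
#' entries; the cost of pairing two splits is the smaller symmetric
#' difference over the two orientations of their sides, the cost of
#' pairing a split `A|B` with a null entry is `min(|A|, |B|)` (for rooted
#' clusters: the plain symmetric difference, and the cluster size). The
#' distance is the total cost of the optimal assignment, found with the
#' Hungarian algorithm; it is 0 exactly when the systems are equal.
#'
#' @inheritParams rf_distance
#' @return Non-negative integer.
#' @export
matching_distance <- function(t1, t2, mode = c("unrooted", "rooted", "auto")) {
  mode <- .resolve_mode(match.arg(mode), t1, t2)
  .check_same_leaves(t1, t2)
  s1 <- split_system(t1, mode)
  s2 <- split_system(t2, mode)
  cost <- matching_cost_matrix(s1, s2)
  assignment_cost(cost)
}

#' Padded cost matrix between two split systems
#'
#' @param s1,s2 `split_system` objects over the same leaf set and mode.
#' @return Square numeric cost matrix (possibly 0 x 0), rows indexing
#'   `s1`'s entries (then padding), columns `s2`'s.
#' @keywords internal
matching_cost_matrix <- function(s1, s2) {
  stopifnot(identical(s1$leaves, s2$leaves), identical(s1$mode, s2$mode))
  n <- length(s1$leaves)
  a <- length(s1$sets)
  b <- length(s2$sets)
  k <- max(a, b)
  if (k == 0L) return(matrix(0, 0L, 0L))
  unrooted <- s1$mode == "unrooted"
  null_w <- function(side) {
    if (unrooted) min(length(side), n - length(side)) else length(side)
  }
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i <= a && j <= b) {
        h <- length(setdiff(s1$sets[[i]], s2$sets[[j]])) +
             length(setdiff(s2$sets[[j]], s1$sets[[i]]))
        cost[i, j] <- if (unrooted) min(h, n - h) else h
      } else if (i <= a) {
        cost[i, j] <- null_w(s1$sets[[i]])
      } else if (j <= b) {
        cost[i, j] <- null_w(s2$sets[[j]])
      }
    }
  }
  cost
}

#' Minimum-cost perfect assignment
#'
#' Solves the square assignment problem exactly (Hungarian algorithm, via
#' igraph's maximum-weight bipartite matching on the complemented costs).
#'
#' @param cost Square numeric cost matrix.
#' @return Total cost of the optimal assignment.
#' @keywords internal
assignment_cost <- function(cost) {
  k <- nrow(cost)
  if (k == 0L) return(0)
  if (k == 1L) return(cost[1L, 1L])
  wmax <- max(cost)
  g <- igraph::make_full_bipartite_graph(k, k)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- (wmax + 1) - cost[cbind(el[, 1L], el[, 2L] - k)]
  m <- igraph::max_bipartite_match(g, weights = w)
  k * (wmax + 1) - m$matching_weight
}

#' Pairwise tree-distance matrix
#'
#' Computes the full symmetric matrix of pairwise topological distances
#' over a labelled set of trees of one gene (typically one tree per
#' estimation strategy, labelled by strategy name).
#'
#' @param trees Named list of `phylo` objects sharing one leaf set
#'   (length at least 2).
#' @param metric `"rf"` or `"matching"`.
#' @param mode `"unrooted"`, `"rooted"` or `"auto"` (rooted only when all
#'   trees are rooted).
#' @return Symmetric numeric matrix with zero diagonal; row/column names
#'   are the tree labels in input order.
#' @export
distance_matrix <- function(trees, metric = c("rf", "matching"),
                            mode = c("unrooted", "rooted", "auto")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (length(trees) < 2L) stop("need at least 2 trees", call. = FALSE)
  labels <- names(trees)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels)) {
    stop("'trees' must be a list with unique non-empty names", call. = FALSE)
  }
  if (mode == "auto") {
    mode <- if (all(vapply(trees, ape::is.rooted, logical(1L))))
      "rooted" else "unrooted"
  }
  ref <- sort(trees[[1L]]$tip.label)
  for (lab in labels) {
    if (!identical(sort(trees[[lab]]$tip.label), ref)) {
      stop("tree '", lab, "' has a different leaf set", call. = FALSE)
    }
  }
  systems <- lapply(trees, split_system, mode = mode)
  k <- length(trees)
  d <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s1 <- systems[[i]]
      s2 <- systems[[j]]
      d[i, j] <- d[j, i] <- if (metric == "rf") {
        length(setdiff(s1$keys, s2$keys)) + length(setdiff(s2$keys, s1$keys))
      } else {
        assignment_cost(matching_cost_matrix(s1, s2))
      }
    }
  }
  d
}
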
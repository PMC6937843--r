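#' Simulation configuration for planted-structure fixtures
#'
#' Describes a synthetic per-gene comparison: `n_strategies` strategy
#' chains partitioned into identical-topology clusters (so the planted
#' zero-distance structure of the distance matrix is known exactly), and a
#' site-wise log-likelihood matrix in which one planted strategy enjoys a
#' constant per-site mean advantage.
#'
#' The site log-likelihood model is i.i.d. normal per site and strategy:
#' baseline mean `mu0` (default -2, a typical per-site log-likelihood for
#' a protein-coding nucleotide alignment), standard deviation `sigma`
#' (default 1), with the planted best strategy's mean raised by `delta`.
#' This generates the matrix the resampling machinery actually consumes,
#' with exact control over the effect size, rather than simulating
#' sequences under a substitution model.
#'
#' @param n_taxa Number of leaves per tree (at least 3 unrooted).
#' @param cluster_sizes Integer partition of the strategy count into
#'   identical-topology clusters, e.g. `c(3, 1)`.
#' @param n_sites Alignment columns for the log-likelihood matrix.
#' @param delta Per-site mean log-likelihood advantage of the planted best
#'   strategy (non-negative).
#' @param sigma Per-site noise standard deviation (positive).
#' @param seed Integer seed; all generation is deterministic given it.
#' @param gene Gene name used in the synthetic strategy ids.
#' @param cc Character-coding code used in the synthetic strategy ids.
#' @param mu0 Baseline per-site mean log-likelihood.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 10L, cluster_sizes = c(3L, 1L),
                       n_sites = 1000L, delta = 0.05, sigma = 1,
                       seed = 1L, gene = "COX1", cc = "DNA", mu0 = -2) {
  cluster_sizes <- as.integer(cluster_sizes)
  stopifnot(n_taxa >= 3L, length(cluster_sizes) >= 1L,
            all(cluster_sizes >= 1L), n_sites >= 1L,
            delta >= 0, sigma > 0)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_strategies = sum(cluster_sizes),
                 cluster_sizes = cluster_sizes,
                 n_sites = as.integer(n_sites),
                 delta = delta, sigma = sigma, seed = as.integer(seed),
                 gene = gene, cc = cc, mu0 = mu0),
            class = "sim_config")
}

#' Random binary tree by sequential leaf attachment
#'
#' Grows a binary tree by attaching leaves one at a time to a uniformly
#' chosen edge (for rooted trees, the position above the current root is a
#' candidate too). This yields the uniform distribution over labelled
#' binary topologies. Leaves are labelled `t1 ... tn`.
#'
#' @param n_taxa Number of leaves (at least 3).
#' @param seed Optional integer seed.
#' @param rooted Grow a rooted tree (default `FALSE`).
#' @return A `phylo` object.
#' @export
random_tree <- function(n_taxa, seed = NULL, rooted = FALSE) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 3L) stop("'n_taxa' must be at least 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # tips are nodes 1..n; internal nodes get fresh ids; edges are rows (u, v)
  if (!rooted) {
    root <- n_taxa + 1L
    edges <- rbind(c(root, 1L), c(root, 2L), c(root, 3L))
    nn <- n_taxa + 2L
    first_new <- 4L
  } else {
    root <- n_taxa + 1L
    edges <- rbind(c(root, 1L), c(root, 2L))
    nn <- n_taxa + 2L
    first_new <- 3L
  }
  if (first_new <= n_taxa) {
    for (k in first_new:n_taxa) {
      n_choices <- nrow(edges) + if (rooted) 1L else 0L
      e <- sample.int(n_choices, 1L)
      w <- nn
      nn <- nn + 1L
      if (e > nrow(edges)) {        # rooted only: new root above the old one
        edges <- rbind(edges, c(w, root), c(w, k))
        root <- w
      } else {
        uv <- edges[e, ]
        edges[e, ] <- c(uv[1L], w)
        edges <- rbind(edges, c(w, uv[2L]), c(w, k))
      }
    }
  }
  build <- function(v) {
    kids <- edges[edges[, 1L] == v, 2L]
    if (length(kids) == 0L) return(paste0("t", v))
    paste0("(", paste(vapply(kids, build, character(1L)), collapse = ","),
           ")")
  }
  ape::read.tree(text = paste0(build(root), ";"))
}

# deterministic strategy labels for m synthetic strategies of one gene:
# real-looking estimator/refiner code pairs drawn from the default
# vocabulary, in a fixed order
.synth_strategy_labels <- function(m, gene, cc) {
  vocab <- default_strategy_vocab()
  combos <- expand.grid(arc = vocab$arc, ae = vocab$ae,
                        stringsAsFactors = FALSE)
  if (m > nrow(combos)) stop("too many strategies requested", call. = FALSE)
  vapply(seq_len(m), function(i) {
    render_strategy(strategy_id(gene, ae = combos$ae[i],
                                arc = combos$arc[i], cc = cc, ed = "UB"))
  }, character(1L))
}

#' Strategy-labelled tree set with planted topology clusters
#'
#' Draws one distinct random topology per cluster (distinctness enforced
#' by rejection on a positive Robinson-Foulds distance) and assigns all
#' members of a cluster the same topology. The strategies are named with
#' the underscore code scheme ([parse_strategy_id()]), so the output can
#' drive the whole pipeline as if it came from real estimation runs.
#'
#' @param cfg A [sim_config()].
#' @param rooted Generate rooted trees (default `FALSE`).
#' @return Named list of `phylo` objects, one per strategy, in cluster
#'   order; attribute `cluster` gives each strategy's cluster index.
#' @export
planted_tree_set <- function(cfg, rooted = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  k <- length(cfg$cluster_sizes)
  mode <- if (rooted) "rooted" else "unrooted"
  topologies <- list()
  attempts <- 0L
  while (length(topologies) < k) {
    if (attempts >= 100L * k) {
      stop("could not generate ", k, " distinct topologies on ",
           cfg$n_taxa, " leaves; infeasible configuration", call. = FALSE)
    }
    attempts <- attempts + 1L
    cand <- random_tree(cfg$n_taxa, rooted = rooted)
    distinct <- all(vapply(topologies, function(t)
      rf_distance(t, cand, mode = mode) > 0, logical(1L)))
    if (distinct) topologies[[length(topologies) + 1L]] <- cand
  }
  labels <- .synth_strategy_labels(cfg$n_strategies, cfg$gene, cfg$cc)
  cluster <- rep(seq_len(k), cfg$cluster_sizes)
  trees <- lapply(cluster, function(ci) topologies[[ci]])
  names(trees) <- labels
  attr(trees, "cluster") <- stats::setNames(cluster, labels)
  trees
}

#' Simulate a site-wise log-likelihood group
#'
#' @param cfg A [sim_config()].
#' @param planted_best Index (or label) of the advantaged strategy
#'   (default 1).
#' @return An [swlh_group()] whose rows follow the synthetic strategy
#'   naming of [planted_tree_set()]; attribute `planted_best` records the
#'   advantaged label.
#' @export
simulate_swlh <- function(cfg, planted_best = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  labels <- .synth_strategy_labels(cfg$n_strategies, cfg$gene, cfg$cc)
  if (is.character(planted_best)) planted_best <- match(planted_best, labels)
  stopifnot(!is.na(planted_best), planted_best >= 1L,
            planted_best <= cfg$n_strategies)
  set.seed(cfg$seed)
  m <- cfg$n_strategies
  ll <- matrix(stats::rnorm(m * cfg$n_sites, mean = cfg$mu0,
                            sd = cfg$sigma), m, cfg$n_sites)
  ll[planted_best, ] <- ll[planted_best, ] + cfg$delta
  rownames(ll) <- labels
  g <- swlh_group(cfg$gene, cfg$cc, ll)
  attr(g, "planted_best") <- labels[planted_best]
  g
}

#' Write a complete synthetic fixture set to disk
#'
#' Materializes a [sim_config()] as the on-disk inputs the command-line
#' interface consumes: one Newick file per strategy under `trees/`, one
#' single-tree site-likelihood file per strategy under `sitelh/`, and a
#' combined multi-tree Newick file `all_trees.nwk` with one tree per line.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory, created if needed.
#' @param planted_best Advantaged strategy passed to [simulate_swlh()].
#' @return Invisibly, a list with the tree set and the swlh group.
#' @export
write_fixtures <- function(cfg, outdir, planted_best = 1L) {
  trees <- planted_tree_set(cfg)
  swlh <- simulate_swlh(cfg, planted_best)
  tdir <- file.path(outdir, "trees")
  sdir <- file.path(outdir, "sitelh")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  for (lab in names(trees)) {
    write_newick(trees[[lab]], file.path(tdir, paste0(lab, ".nwk")))
    write_sitelh(sitelh(lab, swlh$loglik[lab, , drop = FALSE]),
                 file.path(sdir, paste0(lab, ".sitelh")))
  }
  write_newick(unname(trees), file.path(outdir, "all_trees.nwk"))
  invisible(list(trees = trees, swlh = swlh))
}
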
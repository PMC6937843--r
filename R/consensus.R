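#' Cross-mark statistical winners against topological matches
#'
#' The consensus step of the pipeline combines the two comparison routes
#' for one gene. Each (gene, character-coding) group contributes a seed:
#' its top-ranking statistical strategy (rank 1 of [stat_report()]). The
#' seed receives a statistical mark, and its row of the distance matrix is
#' searched for zero scores: every strategy whose topological distance to
#' some seed is zero (the seed itself included, since the diagonal is
#' zero) receives a topological mark. Any marked strategy is a consensus
#' strategy -- it carries, directly or through an identical topology, the
#' support of a top-ranking statistical strategy. A seed is thereby
#' "doubly marked" (both routes agree on it); its zero-distance partners
#' are marked once; unmarked strategies are discarded by the condensed
#' report.
#'
#' Seeds whose label is missing from the distance matrix are skipped with
#' a warning.
#'
#' @param stat_reports A [stat_report()] data frame, or several such
#'   frames row-bound together (one per character coding), all for the
#'   same gene.
#' @param topo Symmetric per-gene distance matrix with strategy labels as
#'   dimnames (typically the matching-metric matrix from
#'   [distance_matrix()]).
#' @return A `data.frame` of class `consensus_table` with columns `gene`,
#'   `strategy`, `stat_mark`, `topo_mark`, `consensus`, one row per matrix
#'   strategy in matrix order.
#' @export
mark_consensus <- function(stat_reports, topo) {
  labels <- rownames(topo)
  if (is.null(labels) || nrow(topo) == 0L || is.null(stat_reports) ||
      nrow(stat_reports) == 0L) {
    warning("empty statistical report or distance matrix; ",
            "no consensus can be formed", call. = FALSE)
    out <- data.frame(gene = character(0L), strategy = character(0L),
                      stat_mark = logical(0L), topo_mark = logical(0L),
                      consensus = logical(0L), stringsAsFactors = FALSE)
    class(out) <- c("consensus_table", "data.frame")
    return(out)
  }
  gene <- unique(stat_reports$gene)
  if (length(gene) != 1L) {
    stop("'stat_reports' must cover exactly one gene, found: ",
         paste(gene, collapse = ", "), call. = FALSE)
  }
  seeds <- character(0L)
  for (cc in unique(stat_reports$cc)) {
    sub <- stat_reports[stat_reports$cc == cc, ]
    # several rank-1 rows can occur when a coding was split by site count
    for (s in sub$strategy[sub$rank == 1L]) {
      if (!(s %in% labels)) {
        warning("seed strategy '", s,
                "' not present in the distance matrix; skipped",
                call. = FALSE)
      } else {
        seeds <- c(seeds, s)
      }
    }
  }
  stat_mark <- labels %in% seeds
  topo_mark <- if (length(seeds)) {
    apply(topo[seeds, , drop = FALSE] == 0, 2L, any)
  } else rep(FALSE, length(labels))
  out <- data.frame(gene = gene, strategy = labels,
                    stat_mark = stat_mark,
                    topo_mark = unname(topo_mark),
                    consensus = stat_mark | topo_mark,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("consensus_table", "data.frame")
  out
}

#' Condense a distance matrix to the marked strategies
#'
#' Drops every strategy that carries neither a statistical nor a
#' topological mark, keeping the remaining submatrix in its original
#' label order.
#'
#' @param table A `consensus_table` from [mark_consensus()].
#' @param topo The distance matrix the table was built against.
#' @return Submatrix of `topo` (possibly 0 x 0).
#' @export
condense <- function(table, topo) {
  keep <- table$strategy[table$stat_mark | table$topo_mark]
  keep <- intersect(rownames(topo), keep)
  topo[keep, keep, drop = FALSE]
}

#' Total topological scores of the consensus strategies
#'
#' The total topological score (TTS) of a consensus strategy is the
#' number of other strategies of the gene whose topological distance to
#' it is zero -- the off-diagonal zeros of its matrix row. The optimal
#' strategies for the gene are the consensus strategies attaining the
#' maximum TTS; a tree with maximal TTS represents the topology most
#' widely reproduced across the competing strategy chains.
#'
#' @param table A `consensus_table` from [mark_consensus()].
#' @param topo The gene's distance matrix.
#' @return `data.frame` of class `tts_report` with columns `gene`,
#'   `strategy`, `tts`, `optimal`, one row per consensus strategy;
#'   attribute `n_total` records the total strategy count of the gene
#'   (the denominator of the optimal-fraction summary).
#' @export
tts_scores <- function(table, topo) {
  cons <- table$strategy[table$consensus]
  gene <- if (nrow(table)) unique(table$gene) else character(0L)
  if (length(cons) == 0L) {
    out <- data.frame(gene = character(0L), strategy = character(0L),
                      tts = integer(0L), optimal = logical(0L),
                      stringsAsFactors = FALSE)
  } else {
    tts <- vapply(cons, function(s) {
      row <- topo[s, ]
      sum(row[setdiff(names(row), s)] == 0)
    }, numeric(1L))
    out <- data.frame(gene = gene, strategy = cons, tts = as.integer(tts),
                      optimal = tts == max(tts),
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  attr(out, "n_total") <- ncol(topo)
  class(out) <- c("tts_report", "data.frame")
  out
}

.write_matrix_csv <- function(m, path) {
  df <- if (length(m)) {
    cbind(data.frame(strategy = rownames(m), stringsAsFactors = FALSE),
          as.data.frame(m))
  } else data.frame(strategy = character(0L))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Write the six consensus reports for one gene
#'
#' Emits the full report set of the comparison-and-consensus step as CSV:
#' the ranked statistical report, the matching-metric and Robinson-Foulds
#' distance matrices, the consensus (marking) table, the condensed matrix
#' restricted to marked strategies, and the TTS histogram with the
#' optimal-strategy flags. Output is deterministic given the inputs.
#'
#' @param stat_reports Row-bound [stat_report()] frames for the gene.
#' @param mp Matching-metric distance matrix (used for the consensus).
#' @param rf Robinson-Foulds distance matrix.
#' @param table [mark_consensus()] result.
#' @param tts [tts_scores()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the six file paths.
#' @export
write_reports <- function(stat_reports, mp, rf, table, tts, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  paths <- file.path(outdir, c("stat_report.csv", "mp_matrix.csv",
                               "rf_matrix.csv", "consensus.csv",
                               "condensed_matrix.csv",
                               "tts_histogram.csv"))
  utils::write.csv(stat_reports, paths[1L], row.names = FALSE)
  .write_matrix_csv(mp, paths[2L])
  .write_matrix_csv(rf, paths[3L])
  utils::write.csv(table, paths[4L], row.names = FALSE)
  .write_matrix_csv(condense(table, mp), paths[5L])
  hist_df <- as.data.frame(tts)
  hist_df$max_tts <- if (nrow(hist_df)) max(hist_df$tts) else integer(0L)
  hist_df$n_strategies <- if (nrow(hist_df)) attr(tts, "n_total")
                          else integer(0L)
  utils::write.csv(hist_df, paths[6L], row.names = FALSE)
  invisible(paths)
}

#' Run the full comparison-and-consensus pipeline for one gene
#'
#' Chains the three analysis layers: per-gene topology matrices (matching
#' and Robinson-Foulds metrics) from the strategies' trees, per-coding
#' statistical ranking from their site-wise log-likelihoods, and the
#' consensus marking with TTS scoring; optionally writes the six CSV
#' reports.
#'
#' @param trees Named list of `phylo` objects, one per strategy; names
#'   must be renderable strategy ids (see [parse_strategy_id()]).
#' @param entries Site-likelihood entries as for [group_swlh()].
#' @param outdir Optional output directory for [write_reports()].
#' @param n_rep RELL replicates per scale.
#' @param scales AU bootstrap scale factors.
#' @param seed Integer seed controlling all resampling.
#' @param mode Tree mode passed to [distance_matrix()].
#' @return List with components `stat` (combined report), `mp`, `rf`,
#'   `consensus`, `tts`.
#' @export
run_pcc <- function(trees, entries, outdir = NULL, n_rep = 10000L,
                    scales = seq(0.5, 1.4, by = 0.1), seed = 1L,
                    mode = "unrooted") {
  mp <- distance_matrix(trees, metric = "matching", mode = mode)
  rf <- distance_matrix(trees, metric = "rf", mode = mode)
  groups <- group_swlh(entries)
  reports <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    reports[[i]] <- stat_report(groups[[i]], n_rep = n_rep,
                                scales = scales, seed = seed + i - 1L)
  }
  stat <- do.call(rbind, reports)
  table <- mark_consensus(stat, mp)
  tts <- tts_scores(table, mp)
  if (!is.null(outdir)) {
    write_reports(stat, mp, rf, table, tts, outdir)
  }
  list(stat = stat, mp = mp, rf = rf, consensus = table, tts = tts)
}
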
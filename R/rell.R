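#' Group of competing strategies' site-wise log-likelihoods
#'
#' Strategy comparison by RELL resampling is only meaningful when every
#' competing strategy scores the same sites: the same gene, under the same
#' character coding, with the same number of alignment columns. An
#' `swlh_group` is the merged per-site log-likelihood matrix of one such
#' comparable set, one row per strategy.
#'
#' @param gene Gene name shared by all strategies in the group.
#' @param cc Character-coding code shared by all strategies.
#' @param loglik Numeric matrix of per-site log-likelihoods with one named
#'   row per strategy.
#' @return Object of class `swlh_group` with fields `gene`, `cc`,
#'   `n_sites`, `strategies` and `loglik`.
#' @export
swlh_group <- function(gene, cc, loglik) {
  loglik <- as.matrix(loglik)
  if (is.null(rownames(loglik)) || anyDuplicated(rownames(loglik))) {
    stop("'loglik' needs unique row names (strategy labels)", call. = FALSE)
  }
  if (nrow(loglik) < 1L || ncol(loglik) < 1L || anyNA(loglik)) {
    stop("'loglik' must be a non-empty numeric matrix", call. = FALSE)
  }
  structure(list(gene = gene, cc = cc, n_sites = ncol(loglik),
                 strategies = rownames(loglik), loglik = loglik),
            class = "swlh_group")
}

#' @export
print.swlh_group <- function(x, ...) {
  cat(sprintf("swlh_group: gene %s, cc %s, %d strategies x %d sites\n",
              x$gene, x$cc, length(x$strategies), x$n_sites))
  invisible(x)
}

#' Agglutinate per-strategy site-likelihood files into comparable groups
#'
#' Partitions per-strategy site-wise log-likelihood rows by (gene,
#' character coding, site count). Strategies of the same gene and coding
#' whose site count differs from the majority for that (gene, coding) pair
#' cannot be resampled jointly; they are placed in their own groups and
#' listed in the `skipped` attribute with a warning.
#'
#' @param entries List of entries, each a list with components `id` (a
#'   [strategy_id()]) and either `loglik` (numeric vector) or `sitelh` (a
#'   single-tree [sitelh()] object).
#' @return List of [swlh_group()] objects, each with strategies in sorted
#'   label order; attribute `skipped` names the minority-length strategies.
#' @export
group_swlh <- function(entries) {
  recs <- lapply(entries, function(e) {
    stopifnot(inherits(e$id, "strategy_id"))
    ll <- if (!is.null(e$loglik)) as.numeric(e$loglik) else {
      stopifnot(inherits(e$sitelh, "sitelh"))
      if (e$sitelh$n_trees != 1L) {
        stop("sitelh for strategy '", render_strategy(e$id),
             "' holds ", e$sitelh$n_trees,
             " trees; one strategy id per tree row is required",
             call. = FALSE)
      }
      as.numeric(e$sitelh$loglik[1L, ])
    }
    list(label = render_strategy(e$id), gene = e$id$gene, cc = e$id$cc,
         n_sites = length(ll), loglik = ll)
  })
  labels <- vapply(recs, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) {
    stop("duplicate strategy id(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  gene_cc <- vapply(recs, function(r) paste(r$gene, r$cc, sep = "\r"),
                    character(1L))
  skipped <- character(0L)
  groups <- list()
  for (gc in sort(unique(gene_cc))) {
    sub <- recs[gene_cc == gc]
    lens <- vapply(sub, `[[`, integer(1L), "n_sites")
    tab <- sort(table(lens), decreasing = TRUE)
    majority <- as.integer(names(tab)[1L])
    if (length(tab) > 1L) {
      off <- vapply(sub[lens != majority], `[[`, character(1L), "label")
      skipped <- c(skipped, off)
      warning("site-count mismatch for gene ", sub[[1L]]$gene, " / cc ",
              sub[[1L]]$cc, ": strategies ", paste(off, collapse = ", "),
              " differ from the majority length ", majority,
              " and are grouped separately", call. = FALSE)
    }
    for (len in sort(unique(lens))) {
      members <- sub[lens == len]
      ord <- order(vapply(members, `[[`, character(1L), "label"))
      members <- members[ord]
      mat <- do.call(rbind, lapply(members, `[[`, "loglik"))
      rownames(mat) <- vapply(members, `[[`, character(1L), "label")
      groups[[length(groups) + 1L]] <-
        swlh_group(members[[1L]]$gene, members[[1L]]$cc, mat)
    }
  }
  attr(groups, "skipped") <- skipped
  groups
}

# Bootstrap-proportion core. For each requested scale r, draws n_rep RELL
# replicates of round(r * n_sites) sites (multinomial site weights), sums
# each strategy's log-likelihood, and awards each replicate to the argmax,
# splitting ties equally. Returns a strategies x scales matrix of win
# proportions. Chunked so memory stays modest at large n_rep.
.multiscale_bp <- function(loglik, scales, n_rep, seed = NULL,
                           block = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(loglik)
  S <- ncol(loglik)
  bp <- matrix(NA_real_, m, length(scales),
               dimnames = list(rownames(loglik), NULL))
  for (si in seq_along(scales)) {
    size <- max(1L, as.integer(round(scales[si] * S)))
    wins <- numeric(m)
    done <- 0L
    while (done < n_rep) {
      b <- min(block, n_rep - done)
      W <- stats::rmultinom(b, size, rep.int(1, S))
      tot <- loglik %*% W
      cmax <- apply(tot, 2L, max)
      is_max <- tot == matrix(cmax, m, b, byrow = TRUE)
      nmax <- colSums(is_max)
      wins <- wins + rowSums(is_max / matrix(nmax, m, b, byrow = TRUE))
      done <- done + b
    }
    bp[, si] <- wins / n_rep
  }
  bp
}

#' RELL bootstrap proportions
#'
#' Resampling of estimated log-likelihoods: instead of re-estimating trees
#' on bootstrap alignments, site log-likelihood columns are resampled with
#' replacement and summed. Each replicate is awarded to the strategy with
#' the highest resampled total (ties split equally among the maxima); a
#' strategy's bootstrap proportion (BP) is its share of the replicates.
#'
#' @param group An [swlh_group()].
#' @param n_rep Number of bootstrap replicates (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return Named numeric vector of bootstrap proportions summing to 1.
#' @export
rell_bp <- function(group, n_rep = 10000L, seed = NULL) {
  stopifnot(inherits(group, "swlh_group"), n_rep >= 1L)
  drop(.multiscale_bp(group$loglik, 1, n_rep, seed))
}

# Weighted least-squares multiscale fit for one strategy's bp-per-scale
# curve. Returns list(au, d, c, usable, degraded).
.au_fit <- function(bp, scales, n_rep) {
  usable <- bp > 0 & bp < 1
  if (!any(usable)) {
    return(list(au = if (all(bp == 1)) 1 else 0, d = NA_real_, c = NA_real_,
                usable = usable, degraded = FALSE))
  }
  if (sum(usable) < 2L) {
    near1 <- which.min(abs(scales - 1))
    return(list(au = bp[near1], d = NA_real_, c = NA_real_,
                usable = usable, degraded = TRUE))
  }
  r <- scales[usable]
  p <- bp[usable]
  z <- stats::qnorm(1 - p)
  X <- cbind(sqrt(r), 1 / sqrt(r))
  w <- n_rep * stats::dnorm(z)^2 / (p * (1 - p))
  fit <- stats::lm.wfit(X, z, w)
  d <- fit$coefficients[[1L]]
  cc <- fit$coefficients[[2L]]
  list(au = min(1, max(0, 1 - stats::pnorm(d - cc))), d = d, c = cc,
       usable = usable, degraded = FALSE)
}

#' Approximately unbiased (AU) p-value by multiscale bootstrap
#'
#' The naive bootstrap proportion of a strategy is biased by selection.
#' The AU correction resamples at several replicate sizes (scales `r` of
#' the original site count), converts each scale's bootstrap proportion to
#' a normal quantile `z(r) = qnorm(1 - BP(r))`, and fits
#' `z(r) = d * sqrt(r) + c / sqrt(r)` by weighted least squares, where `d`
#' estimates a signed distance and `c` a boundary curvature. The AU
#' p-value is `1 - pnorm(d - c)`.
#'
#' Degenerate cases: scales with BP of exactly 0 or 1 carry no quantile
#' information and are dropped; if every scale is degenerate the p-value
#' is 1 for a strategy that wins all replicates at all scales and 0
#' otherwise, and with fewer than two usable scales the scale-1 BP is
#' returned with a warning.
#'
#' @param group An [swlh_group()].
#' @param index Strategy of interest: row index or label.
#' @param scales Positive bootstrap scale factors (default 0.5 to 1.4 in
#'   steps of 0.1).
#' @param n_rep Replicates per scale (default 10000, minimum 100).
#' @param seed Optional integer seed.
#' @return List with elements `au` (the p-value) and `fit` (an `au_fit`
#'   list: `scales`, `bp_per_scale`, `d`, `c`).
#' @export
au_pvalue <- function(group, index, scales = seq(0.5, 1.4, by = 0.1),
                      n_rep = 10000L, seed = NULL) {
  stopifnot(inherits(group, "swlh_group"), all(scales > 0), n_rep >= 100L)
  if (is.character(index)) index <- match(index, group$strategies)
  stopifnot(!is.na(index), index >= 1L, index <= length(group$strategies))
  bp <- .multiscale_bp(group$loglik, scales, n_rep, seed)
  fit <- .au_fit(bp[index, ], scales, n_rep)
  if (fit$degraded) {
    warning("fewer than 2 non-degenerate scales for strategy '",
            group$strategies[index],
            "'; falling back to the scale-1 bootstrap proportion",
            call. = FALSE)
  }
  list(au = fit$au,
       fit = structure(list(scales = scales, bp_per_scale = bp[index, ],
                            d = fit$d, c = fit$c), class = "au_fit"))
}

#' Ranked statistical report for one strategy group
#'
#' Computes, for every strategy of a comparable group, the observed total
#' log-likelihood, its deficit to the best strategy, the RELL bootstrap
#' proportion at scale 1 and the multiscale AU p-value, then ranks the
#' strategies by AU (descending), breaking ties by observed log-likelihood
#' and then by label. The rank-1 strategy is the group's top-ranking
#' statistical strategy, the seed used by the consensus step.
#'
#' @inheritParams au_pvalue
#' @return `data.frame` with columns `gene`, `cc`, `strategy`, `n_sites`,
#'   `obs_lnl`, `delta_lnl`, `bp`, `au`, `rank`, one row per strategy in
#'   group (label-sorted) order.
#' @export
stat_report <- function(group, n_rep = 10000L,
                        scales = seq(0.5, 1.4, by = 0.1), seed = NULL) {
  stopifnot(inherits(group, "swlh_group"), all(scales > 0), n_rep >= 100L)
  m <- length(group$strategies)
  obs <- rowSums(group$loglik)
  # always resample scale 1 (last, so the fit scales see a fixed stream)
  has1 <- any(scales == 1)
  all_scales <- if (has1) scales else c(scales, 1)
  bp_mat <- .multiscale_bp(group$loglik, all_scales, n_rep, seed)
  bp1 <- bp_mat[, which(all_scales == 1)[1L]]
  au <- numeric(m)
  degraded <- character(0L)
  for (i in seq_len(m)) {
    fit <- .au_fit(bp_mat[i, seq_along(scales)], scales, n_rep)
    au[i] <- fit$au
    if (fit$degraded) degraded <- c(degraded, group$strategies[i])
  }
  if (length(degraded)) {
    warning("fewer than 2 non-degenerate scales for strategy(ies) ",
            paste(degraded, collapse = ", "),
            "; using the scale-1 bootstrap proportion", call. = FALSE)
  }
  ord <- order(-au, -obs, group$strategies)
  rank <- integer(m)
  rank[ord] <- seq_len(m)
  data.frame(gene = group$gene, cc = group$cc,
             strategy = group$strategies, n_sites = group$n_sites,
             obs_lnl = obs, delta_lnl = max(obs) - obs,
             bp = unname(bp1), au = au, rank = rank,
             row.names = NULL, stringsAsFactors = FALSE)
}
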
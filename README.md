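# phylopcc

Per-gene selection of optimal phylogeny-estimation strategies by
phylogeny comparison and consensus (PCC).

## The problem

A "strategy" is the chain of algorithms that turns a gene's sequences
into a tree: alignment estimator → optional refinement filter → character
coding → tree estimator, encoded in file names such as
`ATP8_MAFFTF2_TRIMALS_DNA_UB`. Different strategies routinely produce
different trees for the same gene, and the best chain differs from gene
to gene. phylopcc compares all competing strategies of a gene along two
independent routes and reports the strategies on which both agree:

* **Statistical route.** From each strategy's site-wise log-likelihoods
  (the `sitelh` tables written by ML tree software), strategies sharing a
  gene, character coding and site count are compared by the RELL
  bootstrap — resample site columns, award each replicate to the highest
  resampled total log-likelihood — giving bootstrap proportions *BP*, and
  by the approximately unbiased (AU) test: at scale factors
  *r* ∈ {0.5, …, 1.4} of the sequence length, fit
  *z(r) = qnorm(1 − BP(r)) ≈ d·√r + c/√r* by weighted least squares and
  report *AU = 1 − pnorm(d − c)*. Strategies are ranked by AU.
* **Topological route.** All trees of the gene are reduced to their
  nontrivial splits (or clusters, when rooted) and compared pairwise by
  the Robinson-Foulds distance (symmetric difference of split systems)
  and a matching-based distance (minimum-cost perfect assignment between
  padded split systems, solved by the Hungarian algorithm). Both are zero
  exactly when two topologies are identical.

The **consensus** marks each coding group's AU-rank-1 strategy (the
*seed*) and every strategy at matching-distance zero from a seed; marked
strategies are the gene's consensus strategies. Each is scored by its
**total topological score (TTS)** — the number of other strategies with
an identical topology — and the maximum-TTS strategies are reported as
optimal for the gene: the topology they carry is both statistically
preferred and the most widely reproduced across strategy chains.

The package also provides the surrounding toolkit: validating FASTA /
Newick / site-log-likelihood IO, strategy-name parsing, taxa-order
normalization, and the character-coding transforms (RY coding,
algorithmically derived degeneracy coding for any NCBI translation table,
codon-position extraction, translation, stop-codon handling), plus a
synthetic-data module that plants known topology clusters and
log-likelihood advantages so the whole pipeline runs without any external
estimation software.

## Worked example

Simulate a gene with four strategies, three of which share a topology,
and a planted statistical advantage for one member of that cluster; then
run the full pipeline:

```r
library(phylopcc)

cfg   <- sim_config(n_taxa = 8, cluster_sizes = c(3, 1), n_sites = 500,
                    delta = 0.4, seed = 42)
trees <- planted_tree_set(cfg)
swlh  <- simulate_swlh(cfg, planted_best = 1)
entries <- lapply(swlh$strategies, function(lab)
  list(id = parse_strategy_id(lab), loglik = swlh$loglik[lab, ]))

res <- run_pcc(trees, entries, n_rep = 2000, seed = 7)
res$stat[, c("strategy", "obs_lnl", "delta_lnl", "bp", "au", "rank")]
#>                          strategy obs_lnl delta_lnl bp au rank
#> 1   COX1_CLUSTALO_GBLOCKSC_DNA_UB  -996.2     194.1  0  0    2
#> 2   COX1_CLUSTALO_GBLOCKSD_DNA_UB  -802.1       0.0  1  1    1
#> 3   COX1_CLUSTALO_MAXALIGN_DNA_UB -1015.5     213.4  0  0    3
#> 4 COX1_CLUSTALO_MERGEALIGN_DNA_UB -1017.3     215.2  0  0    4
res$tts
#>   gene                      strategy tts optimal
#> 1 COX1 COX1_CLUSTALO_GBLOCKSD_DNA_UB   2    TRUE
#> 2 COX1 COX1_CLUSTALO_GBLOCKSC_DNA_UB   2    TRUE
#> 3 COX1 COX1_CLUSTALO_MAXALIGN_DNA_UB   2    TRUE
```

The planted strategy (`..._GBLOCKSD_...`, with the +0.4 per-site
advantage) wins the statistical ranking outright (`bp = au = 1`,
`delta_lnl = 0` means it is the ML-best). Its two topological twins join
it in the consensus; all three share the maximal TTS of 2 (two
zero-distance partners each), so the optimal fraction for this gene is
3/4 — any of the three may be taken as the optimal strategy, and the
fourth (topologically isolated, statistically worse) is discarded.
Passing `outdir =` to `run_pcc()` writes the six CSV reports
(statistical report, both distance matrices, marking table, condensed
matrix, TTS histogram).

A command-line interface with subcommands `simulate`, `recode`,
`compare-topo`, `compare-stat`, `consensus` and `run-pcc` is installed at
`system.file("exec", "phylopcc.R", package = "phylopcc")`.

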
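---
title: "Comparing and reconciling per-gene phylogeny-estimation strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and reconciling per-gene phylogeny-estimation strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylopcc)
```

## The problem

For a single gene, a practitioner can choose among dozens of multiple
sequence alignment programs, alignment refinement filters, character
codings and tree estimators. Each chain of choices -- a *strategy* -- can
yield a different tree, and there is good evidence that no single chain is
best for every gene. phylopcc treats the strategies of one gene as
competitors and asks which of them deserve to be called optimal, by
requiring agreement between two independent lines of evidence:

* a **statistical** comparison of the strategies' site-wise
  log-likelihoods (RELL bootstrap proportions and multiscale AU p-values),
  which is only valid within groups that score the same sites -- the same
  gene, character coding and alignment length; and
* a **topological** comparison of the strategies' trees (Robinson-Foulds
  and matching-based distance matrices), which is valid across the whole
  gene.

The consensus step cross-marks the statistical winners against their
zero-distance topological matches and scores each consensus strategy by
its *total topological score* (TTS): the number of other strategies that
reproduce exactly the same topology. Strategies with maximal TTS are
reported as optimal for the gene.

## Strategy names

File names carry the strategy identity as underscore-separated codes,
`GENE_AE[_ARC][_CC][_ED]`, e.g. `ATP8_MAFFTF2_TRIMALS_DNA_UB`. Gene names
may contain underscores while stage codes may not, so names are parsed
right-to-left against per-stage vocabularies (`default_strategy_vocab()`),
each stage optional from the right. `render_strategy()` inverts
`parse_strategy_id()` exactly for any vocabulary, a property the test
suite checks on randomly assembled names.

## Character codings

Saturation at synonymous positions motivates recoding the data before
tree estimation; the package implements the transforms as pure functions
on alignments.

**RY coding** collapses each selected column to purine/pyrimidine:
`A,G,R -> R`, `C,T,U,Y -> Y`. Ambiguity codes that span both classes
(`S,W,K,M,B,D,H,V,N`) become `N`, class-pure codes keep their class, and
`-`/`?` pass through. This is a committed decision: it retains exactly
the transversion information the recoding is meant to keep, and nothing
else. The default recodes all columns; `positions = "third"` restricts to
third codon positions, the common practice for saturation control.
Positions are assigned cyclically from the `frame` offset, so with
`frame = 2` column 1 is a third position (it closes the codon that began
before the window) -- the same convention `extract_codon_positions()`
uses, which makes the position sets a partition of the columns for every
frame.

**Degeneracy coding** replaces each codon by an IUPAC-degenerate codon
that erases all synonymous variation within its synonymous codon group.
The table is *derived*, not hard-coded: build a graph over the 64 codons
with an edge wherever two codons differ at exactly one position and
encode the same amino acid, take connected components, and give each
component the positionwise IUPAC union of its members. Under the standard
code this yields `YTN` for the six leucine codons and keeps the two
serine groups (`TCN`, `AGY`) apart, because no single synonymous
substitution connects them. Deriving the table makes every NCBI
translation table (and user-supplied codes) work unchanged; the standard
code result is verified against a brute-force component finder in the
tests. Codons containing any non-`ACGT` symbol are copied through
untouched -- partial degeneration would require inventing semantics for
ambiguous inputs that have no agreed definition.

**Translation** maps clean in-frame codons through the genetic code,
all-gap codons to `-` and gap-contaminated codons to `X`. Pure-IUPAC
ambiguous codons are resolved in two steps: by expansion when every
covered codon agrees on one amino acid, and otherwise through the code's
own degeneracy table (the image `YTN` *is* leucine even though its
expansion also covers `TTY` phenylalanine, because IUPAC unions can
overcover their synonym group). The second step is what makes
`translate(degen(x)) == translate(x)` hold on stop-free coding rows, a
property the tests check on 1000 random rows; without it degeneracy-coded
leucine and arginine codons would decode as `X`.

**Stop handling**: terminal stop codons are removed only when every
gap-free final codon is a stop (disagreement is an error rather than a
silent ragged trim); internal stops can be masked to `NNN`.

## Topological comparison

Trees are reduced to their nontrivial bipartitions: *splits* across
internal edges for unrooted trees (a degree-2 root is collapsed first),
*clusters* below internal nodes for rooted trees. Splits are stored
canonically as the side not containing the alphabetically first leaf.
Polytomies simply contribute fewer entries; a star tree has an empty
system.

The **Robinson-Foulds distance** is the size of the symmetric difference
of the two systems, reported as a raw integer count (a normalized variant
divides by `2(n-3)` / `2(n-2)`). The **matching distance** refines it:
pad the smaller system with null entries, price a split pair at the
smaller symmetric difference over the two orientations of their sides,
price a split `A|B` against a null at `min(|A|,|B|)` (for clusters: the
plain symmetric difference and the cluster size), and take the
minimum-cost perfect assignment, solved exactly by the Hungarian
algorithm. Both metrics are zero exactly when the split systems are
equal, which is the only property the consensus logic relies on; the test
suite nevertheless verifies both metrics against exhaustive oracles
(direct set arithmetic, and enumeration over all perfect matchings) on
hundreds of random small trees, along with symmetry, the triangle
inequality and invariance under re-rooting. Branch lengths and support
values are parsed but never used.

## Statistical comparison

Strategies are grouped for resampling by `(gene, coding, site count)`.
When strategies of one gene and coding disagree on the site count they
cannot be resampled jointly; rather than pad or truncate log-likelihood
rows (which would fabricate data), the minority lengths form their own
groups and are listed in a skip log. Within a group, rows are ordered by
label so all downstream output is deterministic.

**RELL bootstrap.** Each replicate draws `n_sites` sites with replacement
(equivalently, multinomial site weights), sums each strategy's
log-likelihoods over the draw, and awards the replicate to the strategy
with the maximal total. Exact ties are split equally among the maxima, so
proportions sum to one exactly and a pair of identical rows yields
exactly `0.5/0.5`.

**AU p-value.** The naive bootstrap proportion is selection-biased. The
multiscale correction resamples at scales `r` of the original length
(default `0.5, 0.6, ..., 1.4`, ten scales), converts each scale's
proportion to `z(r) = qnorm(1 - BP(r))` and fits

```
z(r) = d * sqrt(r) + c / sqrt(r)
```

by weighted least squares with weights `n_rep * dnorm(z)^2 / (BP(1-BP))`
(the delta-method variance of the probit-transformed proportion); the
p-value is `1 - pnorm(d - c)`, clamped to `[0, 1]`. Degenerate scales
with `BP` of exactly 0 or 1 carry no quantile information and are
dropped; a strategy that wins everything everywhere gets `au = 1`, one
that never wins gets 0, and with fewer than two informative scales the
scale-1 proportion is returned with a warning. A flat `BP = 0.5` across
scales gives `d = c = 0` and hence `au = 0.5` in closed form.

The report ranks by AU descending, breaking ties by observed
log-likelihood and then by label -- the consensus step needs a single
top strategy per group, so a committed total order is required. Defaults
are 10 scales x 10,000 replicates; both are configurable, and all
resampling is reproducible from one integer seed.

## Consensus and TTS

For each `(gene, coding)` group the rank-1 strategy is a *seed*. The seed
carries the statistical mark, and its row of the (matching-metric)
distance matrix is searched for zeros: every strategy at distance zero
from some seed -- the seed itself included, via the diagonal -- carries
the topological mark. Any marked strategy is a *consensus strategy*: the
seed is doubly marked, its exact topological matches singly. This is a
deliberate reading of an ambiguous rule: restricting the consensus to
doubly-marked seeds alone would make the reported "number of consensus
strategies with equal highest TTS over the total number of strategies"
collapse to `1/n` whenever a gene has a single coding group, whereas
under this reading a topology reproduced by `k` strategies yields `k`
consensus strategies, which is the structure the condensed and histogram
reports are built to show.

The row/column ambiguity of "searching the matrix row/column" is moot:
the matrix is symmetric, and the implementation commits to the row.

The **TTS** of a consensus strategy counts the off-diagonal zeros of its
full matrix row -- the diagonal is excluded so that `tts = 0` is
meaningful for an isolated strategy, and the count runs over all of the
gene's strategies, not only marked ones. Optimal strategies are the
argmax of TTS among consensus strategies; ties produce several optimal
strategies, all reported. Six CSV reports are written per gene: the
ranked statistical report, both distance matrices, the marking table, the
condensed matrix restricted to marked strategies, and the TTS histogram
with `max_tts` and the total strategy count (the numerator and
denominator of the optimal fraction).

## Synthetic data

The generator plants known structure so every stage is testable without
external estimation software:

* `random_tree()` grows binary trees by uniform sequential leaf
  attachment (each new leaf joins a uniformly chosen edge; for rooted
  trees the position above the root is also a candidate), which samples
  labelled topologies uniformly and is deterministic per seed.
* `planted_tree_set()` draws one distinct topology per cluster
  (distinctness enforced by rejection on a positive Robinson-Foulds
  distance) and assigns cluster members identical topologies, so the
  planted clusters are exactly the zero-distance classes of the resulting
  matrix. Strategies are named with realistic estimator/refiner codes so
  the fixtures drive the name-parsing path too.
* `simulate_swlh()` draws site log-likelihoods i.i.d. normal with
  baseline mean `mu0 = -2` (a typical per-site log-likelihood for a
  protein-coding nucleotide alignment), noise `sigma = 1`, and a planted
  per-site advantage `delta` for one strategy. Generating the matrix the
  resampling machinery actually consumes, instead of simulating sequences
  under a substitution model, gives exact control of the effect size.

What the generator does *not* emulate: site-to-site rate heterogeneity,
correlation between sites, correlation between strategies' likelihoods
beyond the shared planted mean, or any dependence of the log-likelihoods
on the generated topologies. Passing tests therefore demonstrate the
correctness of the machinery, not the field behaviour of any particular
estimator chain on real data.

With the default planted advantage (`delta = 0.05`, `sigma = 1`,
`n_sites = 2000`, five strategies) the planted strategy's expected total
advantage over each rival is `delta * n_sites = 100` log-likelihood units
against a noise standard deviation of `sqrt(2 * n_sites) * sigma ~ 63`,
so recovery is good but not certain: the probability that the planted
strategy is even the maximum-likelihood winner is
`E[pnorm(Z + delta * sqrt(n_sites) / (sigma * sqrt(2)))^(m-1)] ~ 0.84`
(accounting for the shared-noise correlation of 0.5 between rival
differences), and AU-rank recovery cannot systematically exceed that
bound. Within a `delta = 0` group, the realised likelihood differences
are of the same order as the resampling noise, so single-dataset
bootstrap proportions concentrate on the lucky strategy; exchangeability
shows up across datasets, as equal rank-1 frequencies.

## Numerical and formatting choices

* Site-likelihood files are written with 6 significant digits by default
  (round-trips are exact to that precision; readers accept wrapped rows
  and arbitrary name tokens).
* All stochastic functions take an explicit integer seed; identical seeds
  give byte-identical CSV reports.
* Assignment ties in the Hungarian step do not affect the total cost,
  which is the only quantity used.
* Sequences are uppercased on read; `U` is preserved in storage and
  treated as `T` by the coding operations.
* Degenerate inputs fail loudly: empty alignments, mismatched taxon sets,
  mixed leaf sets, truncated site-likelihood files and duplicate strategy
  ids are all errors that name the offending item.

The test suite exercises the tree-metric oracles on 200 random pairs of
up-to-7-leaf trees and 100 random 8-leaf triples, the translation
invariance on 1000 random 15-codon rows, the RELL/AU analytic cases at
10,000 replicates, planted-best recovery on 50 simulated datasets of
2000 sites, and the consensus recovery on cluster layouts {3,1} and
{5,2,1}; these sizes keep the default run comfortably fast on one CPU
while leaving the stochastic assertions well inside their tolerances.

## Known limitations

* The matching metric follows the matching-split/matching-cluster
  construction; only its zero set (identical topology) is load-bearing
  for the consensus, and other published "matching" variants may differ
  away from zero.
* Statistical groups are formed by exact site-count equality; no attempt
  is made to reconcile strategies whose refinement steps changed the
  alignment length.
* Codon-model (CDN) likelihood computation and amino-acid recoding
  schemes beyond translation are out of scope, as are consensus *trees*:
  the package selects optimal strategies, it does not merge topologies.
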
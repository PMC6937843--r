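Package: phylopcc
Title: Phylogeny Comparison and Consensus for Alignment-Strategy Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for choosing, per gene, an optimal chain of alignment and
    phylogeny-estimation algorithms (a "strategy") from competing analyses of
    the same gene. Provides readers and writers for FASTA alignments, Newick
    trees and site-wise log-likelihood tables; nucleotide character-coding
    transforms (RY coding, algorithmically derived degeneracy coding, codon
    position extraction, translation, stop-codon handling); topology-only tree
    distances (Robinson-Foulds and a matching-based metric) with per-gene
    distance matrices; statistical strategy ranking by RELL bootstrap
    proportions and multiscale approximately-unbiased (AU) p-values computed
    from site-wise log-likelihoods; and a phylogeny comparison and consensus
    (PCC) procedure that cross-marks top-ranked statistical strategies against
    zero-distance topological matches and scores each consensus strategy by its
    total topological score (TTS). A synthetic-data module generates
    strategy-named tree sets and site-wise log-likelihood matrices with planted
    structure so the whole pipeline can be exercised without external
    estimation software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    optparse,
    jsonlite
Config/testthat/edition: 3
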
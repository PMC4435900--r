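Package: motiftrace
Title: Tracing Gain and Loss of Short Conserved Motifs in Disordered
    Protein Regions Across a Species Tree
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A phylogenomic pipeline for reconstructing the evolutionary
    history of short conserved sequence motifs ("microdomains") embedded in
    the intrinsically disordered noncatalytic region of a bacterial protein
    family. Starting from per-genome protein FASTA files and a rooted
    species tree, the package infers orthologs by reciprocal best hits over
    exact Smith-Waterman scores, extracts protein families with the Markov
    Cluster Algorithm, annotates composition-biased segments, tandem
    repeats, amphipathic-helix candidates and a disorder heuristic in the
    noncatalytic region, discovers motifs of width 10-25 under a
    zero-or-one-occurrence-per-sequence (ZOOPS) expectation-maximization
    model, encodes per-species motif presence/absence, and estimates
    ancestral states under a two-state continuous-time Markov chain with
    unequal gain and loss rates by maximum likelihood (Felsenstein
    pruning), yielding a per-motif gain/loss report. A synthetic-evolution
    simulator generates species trees, binary characters and proteomes
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
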
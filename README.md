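# motiftrace

Bacterial RNase E carries, downstream of its conserved catalytic core, a
large intrinsically disordered (ID) region that scaffolds the RNA
degradosome. Short conserved segments inside that region — "microdomains"
such as the membrane targeting sequence and the helicase-, enolase- and
PNPase-binding sites — are the functional units, and their presence or
absence across species records how the degradosome was assembled during
evolution. `motiftrace` implements the complete phylogenomic workflow that
reconstructs this history for any protein family with a comparable
architecture, from per-genome protein FASTA files and a rooted species
tree to a per-motif gain/loss report:

1. **Orthology.** All protein pairs between genomes are scored with exact
   Smith–Waterman (BLOSUM62, affine gaps 11/1) and classified by the
   reciprocal-best-hit rules: *(a, b)* are **orthologs** when each is the
   other's best hit, and **one-to-one orthologs** when additionally no
   within-genome paralog scores higher than the pair.
2. **Families.** The unweighted graph of one-to-one pairs is clustered
   with the Markov Cluster Algorithm (expansion/inflation of a
   column-stochastic matrix); granularity is set by the inflation
   exponent.
3. **Noncatalytic features.** The region downstream of the catalytic core
   is annotated for single-residue composition bias (exact binomial tails,
   stringent threshold 1e-15), tandem repeats, amphipathic-helix
   candidates (hydrophobic moment, δ = 100°), and a transparent
   charge-hydropathy disorder heuristic.
4. **Motifs.** Up to 30 motifs of width 10–25 are discovered in the
   unaligned noncatalytic regions by ZOOPS (zero-or-one occurrence per
   sequence) expectation–maximization, then used to annotate every
   sequence by best-window log-odds scanning, yielding a binary
   motifs × species presence matrix.
5. **Ancestral states.** Each motif's presence/absence is modelled as a
   two-state continuous-time Markov chain with unequal gain (*a*) and
   loss (*b*) rates. With `s = a + b`,
   `P01(t) = a(1 − e^{−st})/s` and `P10(t) = b(1 − e^{−st})/s`;
   the likelihood over the species tree is computed by Felsenstein
   pruning, rates are fitted by maximum likelihood, and exact marginal
   presence probabilities at every ancestral node follow from a combined
   post-order/pre-order pass. Gains are presence onsets at confidence
   τ = 0.92; each motif is called acquired once, multiply, ancestral, or
   absent, with a scaled likelihood of gain.

A synthetic-evolution module (`simulate_dataset()`) generates Yule species
trees, binary characters evolving under the same gain/loss process, and
proteomes with a conserved core, an RNQ-rich/AEPV-rich disordered region,
REE/AEVP tandem repeats and planted motif instances — with a full truth
bundle, so every stage of the pipeline is validated against known ground
truth.

## Worked example

```r
library(motiftrace)

p <- evol_params(n_taxa = 16)                      # study-scale defaults
tree <- sample_tree(16, 1, seed = motiftrace:::derive_seed(15, 1))
cl <- pick_scenario_clades(tree, min_leaves = 6, max_leaves = 9)
chars <- matrix(0L, 2, 16, dimnames = list(c("m1", "m2"), tree$tip.label))
chars[1, cl$leaves_a] <- 1L                        # motif 1 in clade A
chars[2, cl$leaves_b] <- 1L                        # motif 2 in clade B

cfg <- pipeline_config(outdir = "run", seed = 15, simulate = p,
                       simulate_characters = chars,
                       motifs = list(n_motifs = 6))
res <- run_pipeline(cfg)
res$report[1:4, c("rank", "width", "consensus", "gain", "gain_nodes", "call")]
```

```
  rank width        consensus gain gain_nodes      call
1    1    16 AEVPAEVPAEVPAEVP 1.00            ancestral
2    2    15  REEREEREEREEREE 1.00            ancestral
3    3    15  WQKPYTVGSNHEAFM 1.00       n003      once
4    4    16 LRDLFSQAGIRELHER 0.95       n010      once
```

Ranks 1–2 are the simulated AEVP/REE repeat tracks, correctly recognized
as ancestral low-complexity motifs present in every species. Ranks 3–4 are
the two planted microdomains: each is recovered at (within one residue of)
its true width, assigned exactly the species of its true clade, and called
acquired **once** at the true clade stem (`gain_nodes`), with the scaled
likelihood of gain (`gain`, the marginal presence probability at the gain
node) printed the way gain confidence is usually reported, e.g. 0.95.
Intermediate artifacts — hit tables, clusters, feature tables, MEME-format
motifs, the presence matrix, per-node marginals — are checkpointed under
`run/` and are byte-identical when the pipeline is rerun with the same
config and seed.

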
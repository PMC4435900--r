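---
title: "Tracing microdomain gain and loss in disordered protein regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing microdomain gain and loss in disordered protein regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(motiftrace)
```

# The problem

Intrinsically disordered (ID) regions of scaffold proteins such as
bacterial RNase E carry short conserved segments — microdomains, or SLiMs —
that mediate binding to membranes, RNA and partner proteins. Because the
surrounding ID sequence drifts quickly while functional microdomains are
conserved, the presence or absence of each microdomain across a set of
species is a phylogenetically informative binary character. `motiftrace`
turns a collection of per-genome proteomes plus a rooted species tree into
a per-motif account of where on the tree each microdomain was acquired or
lost.

This vignette explains the models and algorithms behind each stage, the
parameters that matter, what the synthetic data generator does and does
not emulate, and the numerical and design choices a user should know
about.

# The gain/loss model

Presence (1) / absence (0) of a motif evolves along each branch as a
two-state continuous-time Markov chain with gain rate $a$ ($0 \to 1$) and
loss rate $b$ ($1 \to 0$) per unit branch length. With $s = a + b$ the
transition probabilities have the closed form

$$P_{00}(t) = \frac{b + a e^{-st}}{s},\qquad
  P_{01}(t) = \frac{a(1 - e^{-st})}{s},$$

and symmetrically for rows starting in state 1 (`transition_matrix()`).
The likelihood of the observed leaf states is computed by Felsenstein
pruning with per-node rescaling (`pruning_loglik()`); `fit_rates()`
maximizes it over $(\log a, \log b)$ with box constraints
$[10^{-8}, 10^3]$, starting L-BFGS-B from the best cells of a $5 \times 5$
log-spaced grid. Exact marginal presence probabilities at every ancestral
node come from combining the post-order pass with a pre-order "outside"
pass (`marginal_ancestral()`); both are verified in the test suite against
brute-force enumeration over all internal state assignments on small
trees, to $10^{-8}$ (likelihood) and $10^{-10}$ (marginals).

**Root prior.** The default is the stationary distribution
$(b, a)/(a+b)$; a flat prior and arbitrary numeric priors are available.
With the flat prior the fitted rates agree with `ape::ace(model = "ARD")`
to high precision (ace's log likelihood differs by exactly $\log 2$, the
flat prior mass it leaves out; its non-root `lik.anc` values are scaled
conditional likelihoods rather than full marginals, so only the root entry
is comparable).

**Gains and losses.** `infer_gains()` hard-calls a node *present* when its
marginal $P(1) \ge \tau$ (default $\tau = 0.92$) and *absent* when
$P(1) \le 1 - \tau$. A **gain** is a presence onset: a present node whose
parent marginal is below $\tau$ (the root counts when its prior favours
absence). Each maximal present subtree therefore contributes exactly one
gain at its stem, and a motif is called acquired **once** (single gain),
**multiple** (two or more), **ancestral** (present root), or **absent**.
The *scaled likelihood of gain* reported per motif is the marginal
presence probability at the gain node. An earlier formulation we explored
— requiring the parent to be confidently *absent* ($P(1) \le 1-\tau$)
before accepting a gain — proved far too conservative at desk scale:
under per-character maximum likelihood the parent of a genuine gain node
typically retains residual presence probability in the 0.1–0.3 range, and
nearly every true clade gain was left uncalled. Scoring confidence at the
gain node itself matches how single-acquisition confidence is usually
reported and recovers the true gain branch for ~98–99% of simulated
single-gain characters on 32–64-taxon trees.

**Why per-character fits are soft.** A single binary character carries
little information about two free rates; for small presence patterns the
likelihood surface often has a high-turnover ridge ($b$ fitted large).
`fit_rates(fix_b = )` profiles one rate with the other pinned (useful for
irreversible-gain analyses), and a matrix of characters can be fitted
jointly with shared rates for calibration studies.

# Orthology and families

Genome pairs are scored with exact Smith–Waterman local alignment
(BLOSUM62, gap open 11, extension 1 — a gap of length $L$ costs
$11 + L$), implemented via `Biostrings::pairwiseAlignment` and verified
against an independent dynamic-programming oracle. Raw scores are used
throughout because the classification rules only compare scores. Per
query, the best hit in each subject genome is the top score with
lexicographic tie-break; *(a, b)* reciprocal best hits are orthologs, and
one-to-one orthologs when no within-genome score involving either protein
exceeds the pair's own score. The unweighted graph of one-to-one pairs is
clustered with a dense-matrix Markov Cluster implementation
(`mcl_cluster()`): expansion (matrix square), inflation (entrywise power
then column normalization, default 2.0), pruning below $10^{-8}$,
self-loops of weight 1 to damp bipartite oscillation; clusters are the
attractor systems of the converged matrix, with strict partitioning by
largest incoming value on the rare overlaps.

# Noncatalytic-region features

All coordinates are 1-based inclusive. `lps_scan()` computes, for every
residue type and window, the exact binomial tail $P(X \ge k)$ of the
observed count under background frequencies, in log space (so a run of 30
arginines at background 0.05 is reported at its exact
$\log_{10} p = 30\log_{10} 0.05 \approx -39.03$); maximal windows at or
below the stringent default threshold $10^{-15}$ are merged per residue.
Only single-residue signatures are scanned — the null model stays exact —
and joint signatures are obtained afterwards by merging overlapping
segments. The window cap (`max_len = 500`) bounds the quadratic
enumeration; composition-biased regions of this family are well under 500
residues. `find_tandem_repeats()` detects maximal regions where positions
one period apart agree at a configurable identity; calls are resolved
greedily by matching-column count and agree with a brute-force scanner on
short sequences. `hydrophobic_moment()` uses the Eisenberg consensus scale
with $\delta = 100^\circ$ for helices. `disorder_index()` is a
transparent charge–hydropathy heuristic
($2.785\,\langle H_{norm}\rangle - |\langle q\rangle| - 1.151$ in a
sliding window; negative = predicted disordered). It is a sequence-only
screen devised for this package and is labelled as such in all outputs —
it is not a trained disorder predictor and should not be interpreted as
one.

# Motif discovery

`discover_motifs()` implements sequential ZOOPS
expectation–maximization: per sequence the latent variable is "no site"
or a site at one of the $L - w + 1$ windows (prior $\gamma/m$ per window);
the M-step re-estimates the PWM from expected site counts with a Dirichlet
pseudocount of 0.01 per residue per column, and $\gamma$ from the expected
number of sites. The full-data log likelihood is tracked and is
non-decreasing across iterations (asserted in the tests). Seeding uses the
most frequent exact words plus random windows, a few EM iterations each.

**Width selection.** The raw ZOOPS likelihood always grows with width, so
widths (coarse grid 10, 13, 16, 19, 22, 25, then a hill-climb of $\pm 1$
steps until no neighbour improves) are compared by a BIC-penalized log
likelihood with an *effective* parameter count of 15 per column. The
nominal 19 free frequencies per column overshoot for the near-sparse
columns of real motifs and truncate genuine motifs with few sites, while
15 still dominates the ~9.5 nat expected overfitting gain of a background
column. The hill-climb (rather than a single $\pm 1$ probe) is needed
because the best coarse width can sit two residues away from the true
width. Discovered occurrences are erased by masking with a neutral symbol
(coordinates preserved) before the next motif is sought; motifs are
ranked in discovery order and carry a significance surrogate
(information content × expected site count, floor 10 by default) in place
of a full E-value computation.

**Annotation.** `scan_sequences()` reports at most one occurrence per
sequence — the best-scoring window, leftmost on ties — when the log-odds
score reaches `min_bits` (default 60% of the motif's maximum attainable
score). The presence matrix keeps one strain per species
(lexicographically first genome id).

**Detection limits.** With few input sequences, conserved low-complexity
segments (composition-driven) legitimately outrank specific motifs
present in only a handful of species — the same behaviour that places
R-rich and AEPV-rich motifs among real discovery results. Planted motifs
below ~6 occurrences sit near the detection limit of the penalized
likelihood and may be truncated or missed; the pipeline therefore defaults
to 30 discovery rounds so that specific motifs surface after
low-complexity signal has been erased.

# The synthetic-evolution generator

`simulate_dataset()` draws a Yule tree (`sample_tree()`: while $k$
lineages exist the next split is Exponential($k\lambda$); a final
Exponential($n\lambda$) epoch gives terminal branches positive length, so
the expected root-to-tip height is $\sum_{k=2}^{n} 1/(k\lambda)$),
simulates one binary character per motif by exact Gillespie simulation of
the gain/loss process (`simulate_binary_character()`; the root state can
be fixed or drawn from the stationary distribution — the latter is the
consistent choice for parameter-recovery studies fitted with a stationary
root prior), and emits proteomes with full ground truth.

Each focal protein is a conserved core (default 200 residues, slow
substitution at 0.05/residue/unit) followed by a disordered region
(default ~250 residues) built from an RNQ-rich profile (R 0.214, N 0.101,
Q 0.091) and an AEPV-rich profile (A 0.208, E 0.138, P 0.106, V 0.127),
with REE and AEVP tandem repeat tracks. Key generator design choices:

* **Fast background drift.** The disordered background substitutes at
  3/residue/unit — faster than the shallowest species splits — so that
  across the tree it conserves only its composition, never its sequence.
  This emulates one-strain-per-species sampling of deeply diverged taxa;
  with slow background drift, discovery correctly (but uselessly) reports
  conserved background everywhere. Substitutions draw replacements from
  the local composition profile, so composition bias survives saturation.
* **Slippage-maintained repeats.** Repeat tracks are re-stamped at the
  leaves, mimicking the expansion/contraction dynamics that keep tandem
  repeats recognizable despite point-mutation saturation, and keeping
  truth coordinates valid.
* **Replacement, not insertion.** Motif instances overwrite background
  residues at their anchor, so sequence length is independent of
  character state and motif presence is a sequence signal only.
* **Indels.** Optional single-residue indels are confined to the
  disordered region, with all truth coordinates (motif anchors, repeat
  and composition-segment intervals) shifted accordingly; the default
  rate is 0, which keeps coordinates identical across taxa.
* **Paralogy.** One protein per family per genome by default; paralogs
  only when configured, matching the near-absence of species paralogs in
  the target family. Decoy families evolve independently and give the
  orthology graph and MCL stage realistic multi-family structure.

What the generator does **not** emulate: realistic indel length
distributions, rate heterogeneity across sites, gene gain/loss, horizontal
transfer, or non-ultrametric rate variation beyond what the Yule tree
induces. Passing tests on synthetic data therefore demonstrate the
correctness of the inference machinery under the model's own assumptions,
not robustness to every feature of real proteomes.

# Pipeline and scenario choices

`run_pipeline()` chains simulate/load → orthology → MCL → noncatalytic
features → motif discovery → presence matrix → ancestral reconstruction →
report, each stage checkpointed in a numbered directory with a config-hash
marker: reruns with the same config and seed are skipped or byte-identical.
The focal family is the cluster with the widest species coverage, ties
broken by mean protein length (the focal family is the long one) — a
coverage-only rule is ambiguous when decoy families also span all genomes.

Validation scenarios plant motifs on the two disjoint clades (4–8 or 6–9
leaves) with the longest stem branches (`pick_scenario_clades()`):
acquisitions on long stems are the statistically identifiable regime, just
as confidently dated acquisitions in real analyses sit on deep inter-order
stems. Problem sizes used by the tests and the acceptance script — 16
taxa end-to-end, 64 taxa with 300 characters for rate recovery, 200
single-gain characters for gain-branch recovery, 60 sequences of length
300 for motif discovery — were chosen as the smallest sizes at which each
statistical claim is comfortably testable.

# Known limitations

* Per-motif rate estimates from a single character are weakly constrained;
  gain calls inherit that softness on small trees (the uncertainty is
  visible in the per-node marginals written by the pipeline).
* The MCL implementation is dense and intended for desk-scale graphs.
* The significance surrogate for motifs is not an E-value; ranking is
  reliable, absolute significance calibration is not claimed.
* The disorder index is a heuristic screen, not a predictor.
* Trees are consumed, not inferred; polytomies are rejected.
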
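---
title: "Clade-aware specificity analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clade-aware specificity analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpnet)
```

## The problem

When a protein family splits into subfamilies with different activities —
for instance an acid protease family whose fungal members diverged into
endopeptidases and tripeptidyl exopeptidases — the sequence record of that
functional diversification takes two forms. First, *cluster-determining
positions* (CDPs): alignment columns whose residue composition separates
the two clades. Second, larger architectural differences:
*cluster-specific inserts* (CSIs), alignment regions present in one clade
and absent in the others.

A CDP on its own is weak evidence of functional relevance: clade-specific
residues also arise from drift and from phylogenetic reconstruction
artifacts. The analysis implemented here therefore corroborates CDPs
through coevolution. Positions that changed *together* during a
diversification leave a signature of elevated mutual information (MI)
within each clade. A CDP with at least two high-MI connections to other
CDPs is promoted to *specificity-determining position* (SDP); one with a
single connection is a putative SDP (pSDP); connected groups of such
positions form *specificity-determining networks* (SDNs). Running the MI
analysis independently on each clade and intersecting the SDP sets yields
*key SDPs* — positions supported by two statistically independent
datasets, the strongest evidence the method produces.

## The statistics

**Sequence weighting.** Database-derived alignments are phylogenetically
redundant. Every statistic therefore weights sequence $s$ by
$1/|c(s)|$ where $c(s)$ is its identity cluster: greedy single-pass
clustering in input order, joining a sequence to the first cluster whose
*founding* representative shares aligned identity $\ge t$ (default
$t = 0.62$, the convention of the weighted-MI literature this follows).
Identity is computed on the aligned rows over positions where both rows
are non-gap. Weights sum to the number of clusters, which also acts as the
effective sample size $N_c$.

**CDP scan.** For a column $X$ and clade label $G$ the statistic is the
weighted mutual information
$I(X;G)=\sum_{a,g} p(a,g)\,\ln\frac{p(a,g)}{p(a)p(g)}$ in nats, with
frequencies from identity-cluster weights over the sequences that are
non-gap at the column. Significance comes from a label-permutation null
(default 999 permutations): labels are permuted at the identity-cluster
level — whole clusters swap together — because permuting near-identical
sequences independently would make the null anti-conservative. One
permutation per replicate is applied to all columns, preserving
between-column dependence, and $p = (1 + \#\{I^{null} \ge I\})/(B+1)$,
Benjamini–Hochberg adjusted at $\alpha = 0.05$ by default.

**Covariation.** For columns $i<j$, weighted joint counts are taken over
sequences non-gap at both, a flat pseudocount with total mass
$0.05 \times N_c$ is spread over the $20\times20$ joint table (a
low-count correction in the Buslje style; the rate is exposed as
`pseudocount`), and raw MI is computed in nats. The average-product
correction removes the background share of MI that reflects conservation
and shared phylogeny rather than coevolution:
$\mathrm{APC}(i,j) = \bar m_i \bar m_j / \bar m$, subtracted from raw MI.
Each pair is then calibrated against a shuffle null (default 100
replicates) in which every column's residues are independently permuted
among its non-gap positions — destroying covariation while preserving
per-column composition and gap structure — and reported as
$z = (\mathrm{obs} - \mu_{null})/\sigma_{null}$. Pairs whose null is
degenerate (both columns near-conserved, $\sigma_{null}=0$) are flagged
and given $z = 0$ rather than an infinite score.

**Network and promotion.** Nodes are CDP columns; edges join CDP pairs
with $z \ge 6.5$, the conventional cut-off calibrated for datasets of
roughly 400 sequence clusters. Degree $\ge 2$ makes an SDP, degree 1 a
pSDP, degree 0 leaves the CDP unsupported. A "direct connection" is an
edge between two CDPs; non-CDP columns never enter the graph. Because
z-scores grow with cluster count, `build_network()` warns when the
dataset exceeds ~400 clusters; no automatic rescaling is attempted since
no principled rule for it exists — `threshold_sweep()` reports how edges,
classes and SDN structure respond to the cut-off instead. Key SDPs are
positions classified SDP (pSDPs excluded by default; promotion of a pSDP
requires evidence the network cannot supply) in the networks of *both*
independently analysed clades, intersected in a common reference
numbering.

**CSI calling.** Per clade, a column is marked when its weighted in-clade
occupancy is $\ge \theta_{in}$ (default 0.5) while every other clade
stays $\le \theta_{out}$ (default 0.1); marked columns merge into runs
tolerating up to `max_gap_run` (default 2) unmarked columns, and runs
shorter than `min_len` (default 5) are discarded. The defaults are
deliberately permissive on the focal clade (inserts may be restricted to
a subclade) and strict on the others. A known limitation follows from the
definition: an insert shared by all clades but *longer* in one is called
only over its clade-exclusive portion.

## The trimmer

Columns with gap fraction above `g` (default 0.3) or normalised Shannon
entropy above `h` (default 0.8; entropy over residue frequencies, gaps
excluded, divided by $\ln 20$) are removed before tree- and MI-oriented
analyses. This is a BMGE-like criterion, not bit-compatible with BMGE's
BLOSUM-smoothed entropy, so downstream column counts are treated as
approximate. All-gap columns are always removed. `'X'` residues are kept
in the rows but count as gaps in every statistic, since they carry no
residue identity.

## Coordinate frames

All reports use a single frame: the original alignment's 1-based columns,
optionally translated to the numbering of a nominated reference sequence
(e.g. a crystal structure's chain numbering) through `build_column_map()`.
The pipeline trims internally but remaps every result back to original
coordinates. CSI calling always runs on the *untrimmed* alignment —
trimming removes exactly the gap-dominated regions inserts live in. SDP
columns where the reference is gapped cannot be numbered and are reported
in a side list, never silently dropped.

## The synthetic generator

`synthetic_truth()` + `generate_msa()` emulate what the analysis assumes:

* background columns with per-column residue distributions drawn from a
  symmetric Dirichlet (concentration 0.5; a 25% share of near-conserved
  columns at concentration 0.02, mimicking the strong conservation
  gradient of real families);
* CDP columns emitting a clade-specific dominant residue with probability
  `q` (0.9 in the recovery experiments — a strongly diagnostic position
  with realistic impurity);
* coupled column groups sharing one latent residue through fixed
  per-column bijections with probability `rho`; unless the group is also
  clade-diagnostic, the marginal of each coupled column equals a
  background law, so coupling is invisible to single-column statistics —
  this separation is what lets the CDP and MI stages be validated
  independently;
* CSI blocks occupied only in their clade, with per-sequence presence and
  right-truncation length noise;
* a caterpillar tree consistent with the clade partition.

The recovery and calibration experiments use two clades of 100 sequences
over 60–100 columns with 999 label permutations (199 inside the
replicated end-to-end runs) and 100 MI shuffles (50 in the replicated
runs) — sizes at which the permutation nulls are already stable and an
entire ten-replicate study runs in about a minute.

What the generator does *not* emulate: phylogenetic autocorrelation
beyond the clade split (star topology within clades, so every sequence is
exchangeable), realistic substitution processes along branches, and
alignment error. Identity-cluster weighting — the mechanism that
compensates relatedness on real data — is therefore exercised only
mildly by the synthetic tests; passing them demonstrates correctness of
the statistics and the promotion logic, not robustness to deep
phylogenetic structure.

## Structure mapping

`read_structure()` parses the first model of a PDB file via bio3d,
resolving alternate locations to the highest-occupancy conformer and
keeping HETATM records flagged (metal ions can mediate dimer interfaces).
Distance queries default to heavy atoms — hydrogens are absent from
typical crystal structures, and published inter-residue distances rarely
state an atom convention, which is the main tolerance source when
reproducing them. `proximity_report()` answers the standard question
"which candidate positions sit within 5 Å of the catalytic site".

## Numerical and design choices

* MI is computed in nats everywhere; negative values from floating-point
  cancellation (magnitude below $10^{-12}$) are clamped to 0.
* The permutation p-value uses the add-one estimator, so its attainable
  minimum is $1/(B+1)$; with the default $B = 999$ and BH adjustment this
  resolves single-column signals down to adjusted $p \approx 0.05$ over a
  few hundred columns.
* The greedy identity clustering is order-dependent by construction
  (CD-HIT-style); file order is always used, making runs deterministic.
* Midpoint rooting delegates to phangorn; MRCA clade extraction errors on
  overlapping groups rather than guessing.
* The combined-clades MI run is computed and reported, but key-SDP
  determination uses only the two single-clade networks: combined sets
  exceed the cluster count the 6.5 cut-off is calibrated for, and in
  practice every CDP connects to every CDP there.
* Every stochastic stage refuses to run without a seed, and a pipeline
  run archives its full configuration next to its outputs; rerunning with
  the archived seed reproduces every table byte for byte.

## Limitations

The CDP statistic is a reimplementation of the idea, not of any specific
published tool, and dataset-level counts from such tools are comparable
only in order of magnitude. Sensitivity of the whole chain is bounded by
its weakest link — a true SDP whose partner positions were trimmed, or
whose MI fails the 6.5 cut-off in one clade, is reported as pSDP or
missed; the method is deliberately specific rather than sensitive. CSI
calls are descriptive interval calls, not evolutionary event
reconstructions.
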
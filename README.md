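# sdpnet

Clade-aware analysis of functional diversification in protein families:
specificity-determining positions (SDPs), coevolution networks, and
cluster-specific inserts (CSIs), from a multiple sequence alignment and a
clade partition.

## The problem and the method

When a family splits into subfamilies with different activities — e.g. an
acid protease family whose members diverged into endopeptidases and
tripeptidyl peptidases — the columns of the family alignment record that
split. `sdpnet` implements the full chain of inference:

1. **CDP scan.** A *cluster-determining position* is a column whose
   residue composition separates two clades. The statistic is the
   weighted mutual information between residue and clade label,
   `I(X;G) = Σ p(a,g) ln[p(a,g) / (p(a)p(g))]` (nats), with
   identity-cluster sequence weights and a cluster-level
   label-permutation null (BH-adjusted).
2. **Covariation.** Pairwise column MI with a flat low-count pseudocount,
   the average-product correction
   `MI_APC(i,j) = MI(i,j) − m̄(i)·m̄(j)/m̄`, and a z-score against a
   within-column shuffle null that preserves composition and gap
   structure while destroying covariation.
3. **SDP promotion.** CDPs with ≥ 2 direct connections to other CDPs at
   `z ≥ 6.5` are SDPs; exactly one connection makes a putative SDP
   (pSDP). Connected components are *specificity-determining networks*
   (SDNs).
4. **Key SDPs.** The MI analysis runs independently per clade; positions
   classified SDP in *both* single-clade networks — intersected in a
   common reference numbering — are the method's strongest calls.
5. **CSI calling.** Intervals occupied (weighted occupancy ≥ 0.5) in one
   clade and essentially gapped (≤ 0.1) in all others, with per-sequence
   insert lengths, logo frequency matrices and tree-annotation export.
6. **Structure mapping.** Reference-numbered positions against a PDB
   structure: minimum heavy-atom distances and catalytic-site proximity
   reports.

A synthetic-alignment generator plants all three signal types (diagnostic
columns, coupled column groups, clade-exclusive inserts) on disjoint
columns with recorded truth, so every stage — and the pipeline end to
end — is validated by recovery of known signal. See the methods vignette
(`vignettes/specificity-analysis.Rmd`) for the model, parameter defaults
and design rationale.

## Worked example

Generate a two-clade alignment (100 sequences each, 60 columns) with two
planted coupled CDP groups and one planted insert, and run the full
pipeline:

```r
library(sdpnet)

truth <- synthetic_truth(
  60, clades = c(Endo = 100, TPP = 100),
  pair_columns = list(c(10, 20, 25), c(30, 40, 45)),
  rho = 1, q = 0.9, pairs_are_cdp = TRUE,
  csis = list(list(clade = "Endo", col_start = 50, col_end = 58)))
data <- generate_msa(truth, seed = 42)

res <- run_two_clade_analysis(data$alignment, data$groups, "Endo", "TPP",
                              seed = 7, n_perm = 199, n_shuffles = 50)

res$cdps[res$cdps$is_cdp, c("column", "statistic", "p_adjusted", "z")]
#>    column  statistic p_adjusted         z
#> 10     10 0.65291123 0.03071429 81.580269
#> 13     14 0.08574517 0.03071429  3.334088
#> 18     20 0.65291123 0.03071429 81.580269
#> 23     25 0.65291123 0.03071429 81.580269
#> 27     30 0.60791890 0.03071429 64.462752
#> 33     40 0.60791890 0.03071429 64.462752
#> 38     45 0.60791890 0.03071429 64.462752
```

The scan finds the six planted diagnostic columns (statistics near
`ln 2 ≈ 0.69`, the maximum for a perfectly diagnostic column with equal
clades) plus one background column (14) with a weak statistic. The
covariation network sorts that out — column 14 has no coevolution
support and stays unsupported, while the planted coupled groups form two
SDNs:

```r
res$networks$a
#> sdp_network: 7 CDP nodes (6 SDP, 0 pSDP, 1 unsupported), 6 edges at z >= 6.5, 2 SDN(s)

res$key_sdps   # SDP in both single-clade networks
#> [1] 10 20 25 30 40 45

res$csis
#> csi_calls: 1 insert(s)
#>   clade col_start col_end length occupancy_in occupancy_out_max median_seq_length
#> 1  Endo        50      58      9            1                 0                 9
```

The planted insert is recovered with exact boundaries. On real data the
entry points are `read_alignment()` (aligned FASTA), `groups_from_table()`
or `groups_from_tree()` (exemplar-defined MRCA clades, midpoint rooting),
and `build_column_map()` to report positions in a reference structure's
numbering; `out_dir =` makes the pipeline write every table (TSV/JSON,
GraphML networks) with full config and seed provenance.

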
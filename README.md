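# afphylo

Alignment-free (AF) phylogenomics for whole microbial genomes: simulate
genome evolution with known ground truth, compute nine AF distances,
build neighbour-joining trees, score them with the normalized
Robinson–Foulds distance, and attach fragment-deletion jackknife support
to AF trees.

## Why

Microbial genomes recombine, rearrange and exchange genes laterally —
processes that violate the positional-homology assumption behind
multiple sequence alignment, and that make alignment-based phylogenomics
both biased and expensive at genome scale. AF methods sidestep alignment
by comparing k-mer statistics or common substring lengths between whole
genomes. Two questions then matter to a practitioner: *how sensitive is
each AF method to divergence, lateral genetic transfer (LGT) and
rearrangement*, and *how can an AF tree — produced by an exact
computation with no resampling — carry node support*? This package
implements the full evaluation loop for the first question and a
jackknife for the second.

## What is inside

| module | contents |
| --- | --- |
| simulator | birth–death trees on an iteration axis; gene-structured genomes; GTR+Γ substitution (defaults a=0.987, b=0.11, c=0.218, d=0.243, e=0.395, α=1 with 8 categories); Poisson LGT with receptivity and a divergence-factor constraint; inverted-translocation rearrangement (≤20 genes/event, rate r calibrated so r=1 moves ≈20% of genome length); full event logs; FASTA/Newick/TSV/JSON output |
| distances | `d2` (cosine on k-mer counts), `cvt` (composition vectors, Markov k−2 background), `ffp` (Jensen–Shannon divergence), `spaced` (spaced-word frequency vectors, mean Euclidean over patterns), `cophylog` (context/object mismatch fraction), `acs`, `kmacs` (greedy ≤ mm mismatches), `gram` (LZ76 cross-complexity), `kr` (shulen-based, Jukes–Cantor transformed), plus shared k-mer (Jaccard) fractions; PHYLIP matrix I/O |
| trees | neighbour-joining (Saitou–Nei), canonical bipartitions, raw and normalized Robinson–Foulds `RF = |B1 Δ B2| / 2(N−3)`, Newick I/O |
| jackknife | delete 40% of each genome as 100-nt fragments, rebuild trees over B pseudo-replicates, annotate the test tree with per-split support percentages |
| bench | scenario sweeps (divergence m, LGT rate l, divergence factor d, rearrangement rate r) with replicate management, the smallest-grand-mean-RF parameter selection rule, empirical mode against a user reference tree, TSV reports |

A thin command-line front end lives in `exec/afphylo`
(`simulate`, `dist`, `nj`, `rf`, `jackknife` subcommands).

## Worked example

Simulate 8 genomes with moderate divergence and a little LGT, infer a
co-phylog tree, score it against the truth, and attach jackknife support:

```r
library(afphylo)

cfg <- sim_config(taxa_range = c(8, 10), genes_range = c(60, 70),
                  gene_length_range = c(200, 400), iterations = 500,
                  mutation_rate = c(0.4, 0.6), lgt_rate = 0.5, seed = 11)
gs <- evolve(cfg)
gs
#> genome_set: 8 genomes, 70 genes in genome 1; 42 LGT attempts, 0 rearrangement events

seqs <- genome_strings(gs)           # ~20.6 kb per genome
m <- distance_matrix(seqs, af_params("cophylog", K = 8))
round(m[1:4, 1:4], 4)
#>        t4     t5     t6     t7
#> t4 0.0000 0.1293 0.1186 0.1283
#> t5 0.1293 0.0000 0.0386 0.0924
#> t6 0.1186 0.0386 0.0000 0.0848
#> t7 0.1283 0.0924 0.0848 0.0000

tree <- neighbor_joining(m)
rf_normalized(tree, gs$tree)
#> [1] 0
```

Each matrix entry is the fraction of shared 17-nt context windows whose
middle nucleotide differs — for example genomes `t5` and `t6` disagree at
3.9% of their shared contexts, and the inferred tree reproduces the true
topology exactly (`RF = 0`; an RF of 1 would mean no shared bipartition).

```r
jk <- jackknife_pipeline(seqs, af_params("cophylog", K = 8),
                         jackknife_config(replicates = 50, seed = 1))
ape::write.tree(jk)
#> (t4:0.0615,((t2:0.0328,t3:0.0613)98:0.0447,t1:0.0578)92:0.0335,
#>  ((t5:0.0184,t6:0.0201)100:0.0246,(t7:0.0048,t8:0.0028)100:0.0414)72:0.0183);
```

The integer labels are jackknife supports: each is the percentage of 50
pseudo-replicate trees (40% of every genome deleted as random 100-nt
fragments) that contain that split — both cherries here are recovered in
every replicate (100), the deeper groupings in 72–98% of them.

Scenario sweeps wrap this loop over a parameter grid:

```r
sweep <- run_scenario("lgt", grid = c(0, 5, 25, 125),
                      methods = list(cophylog_K8 = af_params("cophylog", K = 8),
                                     cvt_k8 = af_params("cvt", k = 8)),
                      replicates = 10, seed = 1)
sweep$summary   # mean and sd of RF per grid value and method
```

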
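---
title: "Alignment-free phylogenomics under divergence, LGT and rearrangement: models and methods"
author: "afphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{afphylo methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`afphylo` is a test bench for alignment-free (AF) phylogenomics on whole
microbial genomes. It answers a methodological question: how sensitive are
AF distance methods — which infer trees from k-mer statistics or common
substring lengths, without multiple sequence alignment — to the three
genome-scale processes that most violate alignment assumptions in
microbes: sequence divergence, lateral genetic transfer (LGT), and genome
rearrangement? The package provides (i) a genome evolution simulator with
known ground truth, (ii) nine AF distances, (iii) neighbour-joining and
Robinson–Foulds machinery, (iv) a fragment-deletion jackknife that gives
AF trees node support, and (v) a scenario-sweep layer that ties them
together.

## The simulator

A genome is an ordered list of genes; each gene has an identifier, a
homology-family label, an orientation, and a nucleotide sequence. The set
evolves along a birth–death tree on a discrete "iteration" time axis of
length `iterations`.

**Tree process.** We run a continuous-time Gillespie birth–death process
with per-lineage rates `speciation_rate * s` and `extinction_rate * s`,
where the scale `s` (`tree_event_scale`) is auto-calibrated so the
expected number of extant lineages at the end of the run is near the
middle of `taxa_range`: `s = log(target)/((b - e) * iterations)` for
supercritical settings and `target/(b * iterations)` at criticality. Runs
are rejection-sampled until the extant count falls in `taxa_range`; runs
that die out or explode are discarded. The returned reference tree is the
reconstructed tree of the extant taxa (extinct side branches are pruned
but counted). Sequence evolution, LGT and rearrangement act on the
reconstructed tree only; extinct lineages never donate genes. This is a
deliberate simplification: transfers from extinct donors would add
sequence material with no bearing on the leaf-set topology that the
Robinson–Foulds comparison scores.

**Substitution.** GTR with exchangeabilities `a = 0.987` (A–C),
`b = 0.11` (A–G), `c = 0.218` (A–T), `d = 0.243` (C–G), `e = 0.395`
(C–T) and the G–T rate fixed at 1 as reference; base frequencies default
to uniform since no others are specified anywhere upstream. Among-site
rate variation uses a discrete gamma model (`alpha = 1`, 8
equal-probability categories with conditional-mean rates); each site
keeps its category for the whole run, through transfers. Transition
probabilities come from the eigendecomposition of the symmetrized rate
matrix.

**The meaning of `m`.** The mutation-rate dial `m` in `[0, 1]` is
calibrated in units of root-to-tip expected substitutions per site: the
per-iteration intensity is `m * mutation_calibration / depth`, with
`depth` the time from the extant MRCA to the leaves. Two choices deserve
justification:

* *Anchoring to the extant MRCA.* In (near-)critical birth–death runs the
  MRCA can fall anywhere in the run; anchoring the clock to the realized
  depth makes `m` mean the same thing in every replicate instead of
  silently varying with tree age.
* *`mutation_calibration = 0.25`.* The sweeps compare word statistics of
  length 8–16 (12-mers, 16-nt co-phylog contexts, weight-8 spaced words).
  The calibration places the three sweep levels `m = 0.1, 0.5, 0.9`
  (sampled as ranges 0.01–0.2, 0.4–0.6, 0.8–0.99) at roughly 0.05, 0.25
  and 0.45 expected substitutions per site between the most divergent
  leaves: exact 16-mer statistics are fully informative at the low end,
  degraded but usable in the middle, and heavily eroded at the top. A
  calibration of 1.0 would saturate every such statistic already at
  `m = 0.5` and turn the sweep into a comparison of noise. A single `m`
  is drawn per run when a range is given; we chose run-level rather than
  lineage-level draws so that pairwise divergence stays consistent with
  the tree.

**LGT.** Attempts arrive as a Poisson process at `lgt_rate` per iteration
while at least two lineages exist. Each attempt draws an ordered
donor–recipient pair uniformly among the lineages alive at that moment
and succeeds only if (1) the pair's divergence — iterations since their
most recent common ancestor — does not exceed the divergence factor `d`,
and (2) a uniform draw falls below the recipient's receptivity, itself
drawn at lineage birth from a scaled Beta matched to the configured
minimum 0.2 / mean 0.5 / maximum 0.8. An accepted event copies one
uniformly chosen donor gene; it replaces the recipient's gene of the same
family when present and is inserted at a random position otherwise (with
no gene loss in the model, replacement is the path actually exercised).
Every attempt is logged with its outcome and rejection reason.

Genes are evolved lazily: each carries a last-updated time, whole genomes
are brought up to date at speciation nodes (so that shared history stays
shared) and at the leaves, and in between only genes touched by LGT are
advanced. This makes runs with tens of thousands of attempts cheap
without approximating the process.

**Rearrangement.** An event is an inverted translocation: a contiguous
block of `Uniform{1..20}` genes is excised, its gene order reversed and
every orientation flipped, and the block reinserted at a uniform
position. Event counts are Poisson with intensity
`r * 0.2 * n_genes / E[block]` per root-to-tip path, so that `r = 1`
moves blocks covering about 20% of the genome length over a run (and
0.01/0.10 about 0.2%/2%) — a calibration that is itself asserted by a
property test rather than hidden. Rearrangement permutes gene order and
strand but never changes the family multiset, which is also tested.

**Desk-scale analogs.** The full protocol this emulates runs ~30 genomes
of 2000–3000 genes over 5000 iterations; the package's reduced template
(`reduced_sim_config()`) uses 12 taxa, ~150 genes of 200–400 nt and 500
iterations so that a 40-replicate sweep finishes in minutes on one CPU.
Sweeps are specified on the full-protocol scale and translated:
`lgt_rate_analog()` preserves accepted transfers per gene over the run,
anchored at "about one transfer per gene at l = 250";
`divergence_factor_analog()` rescales `d` proportionally to the iteration
count. The reduced trees have 9 internal edges, so one mis-resolved split
costs RF ≈ 0.056 — mean-RF values at this scale are coarser than at full
scale, which matters when comparing against bounds like 0.03 (see
Limitations).

## The nine distances

Word-count methods (all counting the sequence and its reverse complement
by default; `both_strands = FALSE` disables this):

* **d2** — cosine dissimilarity of raw k-mer count vectors.
* **ffp** — Jensen–Shannon divergence (base 2, hence in `[0, 1]`) between
  normalized k-mer frequency profiles.
* **cvt** — composition vectors: each word's frequency minus its
  Markov-order `k - 2` expectation `p(prefix) p(suffix) / p(middle)`,
  relative to that expectation; distance `(1 - cosine)/2`. For
  `k <= 10` the vectors are dense over all `4^k` words — exact, including
  the `-1` components of absent-but-expected words; above that the
  computation restricts to observed words, a standard sparse
  approximation.
* **spaced** — for each of `n` binary patterns (length 14, weight 8,
  first and last positions fixed matches, generated from a recorded
  seed), the Euclidean distance between frequency-normalized spaced-word
  vectors, averaged over patterns.
* **co-phylog** — every position contributes a context (K nt each side)
  and an object (the middle nt); contexts that map to more than one
  object within a genome are discarded; the distance is the fraction of
  shared contexts with differing objects. A pair sharing no context has
  no defined distance and raises an error rather than returning a number.

Match-length methods (searching the target and its reverse complement):

* **acs** — mean longest-prefix match lengths into the partner, entered
  into the score `log|y|/L(x,y) - 2 log|x|/|x|`, symmetrized and floored
  at zero.
* **kmacs** — as acs, with each match extended greedily across up to `mm`
  mismatches. The extension anchor is pinned, deliberately: the
  *rightmost* occurrence in the target of the longest exact match (the
  occurrence the reversed-target suffix automaton identifies at no extra
  cost). `mm = 0` reduces exactly to acs, which is tested.
* **gram** — LZ76 cross-complexity: with `c(s)` the exhaustive-history
  phrase count, the distance is `(c(x|y) + c(y|x)) / (c(x) + c(y))`,
  where `c(x|y) = c(y'x) - c(y')` and `y'` is `y` plus its reverse
  complement. Note `d(x, x) > 0` by construction — describing a string
  given itself still costs a few phrases — so gram is exempt from the
  zero-self-distance contract the other eight obey.
* **kr** — per-position shortest-absent-substring lengths (shulens); the
  mean shulen is inverted against its expectation under a model where
  each position's match is the longer of a uniform-background match
  (`P(len >= l) = 1 - (1 - 4^-l)^|y|`) and a homologous run
  (`P(len >= l) = (1 - pi)^l`), solved for `pi` by root finding, then
  mapped through the Jukes–Cantor transform `-3/4 log(1 - 4 pi / 3)`.
  Estimates at or beyond the JC pole (`pi >= 3/4`) raise a saturation
  error. When a sequence is wholly contained in the partner the capped
  shulens hit their ceiling and `pi = 0` is returned directly.

All suffix machinery (matching statistics, occurrence positions, shulens,
LZ76 parsing) runs on a suffix automaton with first-occurrence positions,
built in C++; every kernel is checked against a quadratic brute-force
oracle in the test suite. Windows containing non-ACGT characters are
skipped by the counting methods, and match extension stops at them.

## Trees and comparison

`neighbor_joining()` validates the matrix (symmetry, zero diagonal, no
non-finite entries) and delegates to the standard Saitou–Nei algorithm;
an all-zero matrix returns a star tree rather than an arbitrary
resolution. Negative branch lengths are kept by default with an optional
clamp. `bipartitions()` extracts canonical non-trivial splits (the block
containing the lexicographically smallest leaf, sorted); `rf_raw()` is
the symmetric difference of split sets, compared against an independent
implementation in the tests, and `rf_normalized()` divides by
`2(N - 3)`, the maximum for two unrooted trees on N leaves — so 0 means
identical topologies and 1 means no shared split. Multifurcations are
compared by their split sets directly, with the same denominator.

## Jackknife support

From each genome, `floor(L * rate / fragment_length)` fragments of
`fragment_length` nt (defaults: rate 0.4, 100 nt) are deleted at
uniformly random positions, sequentially, each deletion shortening the
sequence before the next draw — overlap with earlier deletion sites is
allowed, which is the simplest reading of fragment deletion and keeps
the deleted fraction exact up to the floor. A tree is built per
pseudo-replicate with the same AF method, and each internal edge of the
test tree is labelled with the percentage of replicate trees containing
its split. Support is reported on the test tree's own splits only; no
consensus tree is formed. With the default 40% rate each replicate keeps
60% of every genome, so supports reflect how redundantly the genome
encodes each split: they rise toward 100 as genomes grow at fixed
divergence (a property test), and they are invariant under replicate
reordering.

## Scenario sweeps and the selection rule

`run_scenario()` crosses a parameter grid (divergence level, LGT rate,
divergence factor, or rearrangement rate) with replicates: each cell
simulates a set, computes the requested AF distance matrices, builds NJ
trees and scores them against the true tree. Replicate failures (e.g. a
co-phylog pair without shared contexts at extreme divergence) are
recorded and excluded from means, never imputed. The whole sweep is a
deterministic function of the master seed. `select_optimal_params()`
implements the optimal-parameter rule used throughout: per method, the
candidate setting with the smallest grand mean of per-grid mean RF wins,
ties going to the smaller key parameter. `run_empirical()` runs the same
distance → NJ → jackknife → RF chain on user-supplied FASTA genomes
against a user-supplied reference tree, and `shared_kmer_table()`
reports pairwise Jaccard fractions of distinct k-mers (k = 12 being the
conventional choice for closely related genomes).

## What the generator does and does not emulate

It emulates: genome-scale gene-structured evolution with known ground
truth; GTR+Γ substitution; uniformly random LGT with receptivity and
relatedness constraints; inverted-translocation rearrangement with the
20-gene block cap; and the published rate grids via per-gene-load
analogs. It does not emulate: gene duplication and loss, pseudogenes,
intergenic DNA, compositional (G+C) heterogeneity across lineages,
habitat-structured transfer preferences, or assembly artifacts. Passing
sweeps therefore demonstrate method behaviour under controlled,
homogeneous-composition genomes — not performance on real assemblies,
where composition bias and repeats are known additional failure modes
for word statistics.

## Known limitations

* At the desk scale (12 taxa), RF granularity is 1/18 per tree and some
  replicates contain internal edges of near-zero length that no distance
  method resolves; mean-RF floors of 0.01–0.1 at zero event rates are
  expected and method-dependent.
* The co-phylog estimator conditions on conserved contexts; under strong
  site-rate heterogeneity those oversample slow regions, compressing
  large distances. At moderate divergence this occasionally costs a deep
  split even with several-fold more genes — a bias of the statistic at
  this scale, not a sampling artifact.
* The Euclidean spaced-words statistic, by contrast, resolves the small
  reduced-scale trees essentially perfectly; its published weakness on
  sets several times deeper and larger does not transfer to this scale.
* kmacs uses the greedy mismatch extension with a pinned anchor, not the
  exact mismatch-LCS; kr's background model assumes i.i.d. uniform
  nucleotides (no GC correction).
* Simulated receptivity is inherited at birth and constant per lineage;
  real transfer barriers evolve.
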
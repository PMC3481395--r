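---
title: "Sifting families: iterative de novo protein family clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sifting families: iterative de novo protein family clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfams)
```

## The problem and the model

De novo protein family construction by all-vs-all comparison scales with
the square of the database, which makes refreshing a family resource from
scratch prohibitively expensive every time new genomes arrive. The
approach implemented here amortises that cost by *sifting*: an initial set
of families is built once from a phylogenetically diverse core of
genomes, profile models are trained for each family, and every subsequent
batch of sequences is first screened against the existing profiles. Only
the sequences that no profile recruits enter a fresh all-vs-all
clustering round, so the quadratic step shrinks with every iteration
while the family database only ever grows.

Families are intended to be sets of *globally* homologous proteins:
membership requires that alignments cover most of both sequences, not
merely that they share a domain. Concretely, two proteins are treated as
homologous when their best local alignment has an e-value at most a
threshold and spans at least 80% of the lengths of **both** sequences;
pairs failing either condition contribute zero similarity. The retained
pairs are weighted by percent identity (0–100) and the resulting sparse
graph is partitioned with Markov clustering (MCL) at inflation 2.
Single-sequence clusters are not families.

The pipeline in `initialize_database()` is then:

1. All-vs-all comparison of the representative-genome proteins under a
   stringent e-value gate (`1e-10`, coverage 0.8 both ways), MCL,
   and a *universality score* per cluster — the fraction of representative
   genomes with at least one member. Clusters at or above 50% become the
   widely distributed seed families (construction id 1).
2. Profiles trained on the seed families recruit members from the whole
   corpus at the general gate (`1e-5`, coverage rule "both").
3. Whatever no profile recruited is clustered de novo at the general
   gate; multi-member clusters become construction id 2 families, the
   rest is recorded as unclustered.

`update_database()` repeats steps 2–3 for new sequences, pooling the
residual with the previously unclustered sequences (which therefore get a
fresh chance in every round) and labelling each round's new families with
the next construction id.

## Components and numerical choices

**Local aligner.** Pairwise comparison is Smith–Waterman under BLOSUM62
with affine gaps (open 11, extend 1; a gap of length $k$ costs
$11 + k$), computing the single best-scoring HSP. Percent identity
follows the `pident` convention: identical columns divided by all
alignment columns, gaps included. Significance uses the Karlin–Altschul
form $E = Kmn\,e^{-\lambda S}$ with the standard gapped-BLOSUM62
constants $\lambda = 0.267$, $K = 0.041$; $n$ is the total residue count
of the record set, $m$ the shorter sequence of the pair (which of the two
symmetric directions yields the lower e-value). Pre-computed hits in the
conventional 12-column tabular format can be imported instead via
`parse_tabular_hits()`. A shared-5-mer prefilter skips hopeless pairs;
it is exact in practice for anything able to pass the coverage/e-value
gate and can be disabled.

**MCL.** A dense implementation of the standard process: self-loops at
each node's maximum incident weight, column normalisation, then repeated
expansion (matrix squaring) and inflation (entrywise power, default 2)
with pruning at $10^{-10}$ per round, until the maximum entrywise change
drops below $10^{-8}$ (at most 200 iterations; non-convergence is an
error). Clusters are read from the attractor structure; a node with equal
mass on two attractor systems joins the larger cluster, remaining ties go
to the system whose smallest attractor id sorts first.

**Profiles.** Per-family profile models are trained from trimmed
alignments: match states are columns with gap fraction at most 0.5,
match emissions are `(counts + background) / (n + 1)` (one
background-distributed pseudocount), transitions get +1 smoothing, insert
states emit at the background (BLOSUM62 marginal frequencies). Scoring is
best local Viterbi with uniform entry over match states (cost
$\log_2(1/L)$) and free exit; flanking residues are emitted by the null
model, so scores are log2-odds in bits. Coverages come from the alignment
envelope: spanned sequence residues over sequence length, and spanned
match states over $L$. E-value calibration scores seeded random sequences
(background composition, lengths resampled from the member lengths) and
fits a Gumbel by the method of moments
($\hat\lambda = \pi/(\sigma\sqrt 6)$,
$\hat\mu = \bar x - \gamma/\hat\lambda$). The default of 100 shuffles is
plenty for pipeline decisions, where true hits sit dozens to hundreds of
bits above the null; distribution-level checks in the test suite use
1000 shuffles, below which the method-of-moments parameter noise (of
order $1/\sqrt{n_\text{shuffles}}$) dominates a Kolmogorov–Smirnov
comparison. The number of comparisons multiplying the per-comparison tail
probability defaults to the number of profiled families in the database.

**Alignments and trees.** The progressive aligner builds a guide tree by
average-linkage clustering of shared-3-mer distances and merges
alignments by profile–profile global alignment under the same scoring
matrix and gap costs; ungapping any output row reproduces its input.
Columns with strictly more than 80% gaps are excised before profile
training (a column at exactly 80% is kept). Family trees are
neighbor-joining on p-distances with pairwise deletion. Families with
more than 250 members are aligned from diverse representatives: members
are sub-clustered by MCL on the similarity graph restricted to edges at
or below an 80% identity ceiling, one representative drawn (seeded) per
sub-cluster, and the remaining members folded into the training
alignment afterwards. If 200 or more sub-clusters appear, the ceiling is
lowered in 5-point steps to a floor of 5%. Note that removing edges can
only fragment the sub-clustering further, so the schedule exists to
bound the loop; reaching the floor returns one representative per
sub-cluster with a warning rather than failing.

**Genome ranking.** `select_representative_genomes()` ranks the leaves
of a genome phylogeny by greedy phylogenetic-diversity contribution:
the first pick is an endpoint of a maximum-distance leaf pair (the one
with the larger total distance, ties by label), and each later pick
maximises the gain in spanned branch length. Greedy selection is optimal
for PD, so the first $k$ picks attain the maximum achievable PD.

**Fragment triage.** Sequences that remain unclustered are compared to
every profile at the general gate with coverage rule "either". A
sequence is *truncated* if some hit's profile is at least 1.2 times its
length while the alignment covers at least 80% of the sequence —
evidence of a gene fragment; otherwise *extended* if it is longer than
every profile it hits; otherwise *novel or diverged* (including no
hits). Truncated takes precedence, keeping the categories disjoint.

**Quality metrics, networks, clans.** A family profile's *precision* is
the fraction of the sequences it recruits (gate `1e-5`, coverage rule
"both") that are members; *recall* is the fraction of members recruited.
A profile that recruits nothing has undefined precision; it is reported
as 1 with a `vacuous` flag. Leave-one-out recall retrains the profile
without each tested member (with a per-member seed offset) and asks
whether it still recruits it. The family network connects two families
when their profile consensus sequences align with e-value at most `1e-5`
covering at least 80% of the shorter consensus; node statistics are
degree, unnormalised betweenness, local transitivity (0 where
undefined), and within-component closeness
$(n_c - 1)/\sum d$. Clans come in two constructions: connected
components of the consensus network, and single-linkage closure of pairs
that reciprocally recruit at least 80% of one another's members. In both
cases only multi-family components are called clans.

**Annotation and enrichment.** A family inherits a term carried by a
strict majority of members; families with annotated members but no
majority term are flagged partially annotated. Enrichment scans build a
2×2 table per term over a family partition — inclusive upper quartile
for size and degree, precision strictly below 0.75 for the low-precision
set — and apply a one-sided Fisher exact test with Bonferroni correction
over the number of terms observed in at least one family.

## The synthetic benchmark

`simulate_families()` plants ground truth for every property the test
suite checks. Its defaults are the study conditions used throughout: 20
families of 10 members, each family an independent random ancestor of
180–240 residues (background composition) whose members are mutated to a
70% identity target (substitutions drawn from BLOSUM62-conditional
probabilities, indels at 0.01/site with geometric lengths of mean 2);
4 genomes with half the families occupying all of them and half confined
to one; fragments equal to 10% of the member count, each a 30–60%
prefix or suffix of a member (at most one per family, so fragment pairs
cannot form spurious two-member families); 20 ORFans; and one annotation
term per family carried by 90% of its members. At these settings,
between-family identity stays near background and the coverage filter
leaves no cross-family edges, so the planted partition is recoverable
exactly — the benchmark verifies the machinery, not the hard cases.

The optional superfamily mode plants pairs of families built around a
common 80-residue domain with 5-residue family-specific flanks, members
at an 85% identity target. The shared domain then makes up roughly 89%
of each sequence, deliberately above the 80% coverage gates so that
cross-family recruitment, consensus-network edges and both clan
constructions actually fire; with long family-specific flanks the
coverage filter would (correctly) keep such families fully separate,
which is the uninteresting case. The flank/domain proportions and the
identity targets are the generator's definition of this fixture.

What the generator does *not* emulate: phylogenetic correlation among
members (every member is an independent draw from the ancestor),
among-site rate variation, domain shuffling beyond simple fusions, and
corpus-scale family-size distributions. Passing tests therefore show
that the operators implement their contracts, not that the thresholds
are optimal for real proteomes.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline on the
240-sequence benchmark (about 29k candidate pairs before the k-mer
prefilter), a 48-sequence superfamily fixture, 100 random 25-node graphs
against the reference MCL, and exhaustive-oracle comparisons for the
aligner (all pairs of 50 sequences up to 40 residues), the Viterbi
scorer (profiles up to 4 states), the network statistics (graphs up to
12 nodes) and Fisher tests (200 random tables) — sizes chosen so a
desk-scale run completes in minutes while the oracles stay exhaustive.
All randomness flows through explicit integer seeds: the generator, the
representative draw, profile calibration, and the leave-one-out member
sampling are reproducible bit-for-bit for a given seed.

## Known limitations

* The aligner reports one HSP; multi-domain proteins whose homology is
  split across several HSPs can fail the coverage gate that a
  tiling-aware aligner would pass.
* E-values from the built-in aligner and profiles are calibrated
  approximations (fixed Karlin–Altschul constants; moment-fitted
  Gumbel), adequate for gating decisions but not comparable to BLAST or
  HMMER numbers digit-for-digit.
* Viterbi (best-path) scoring replaces full forward scoring; scores for
  marginal hits are slightly conservative.
* The dense MCL implementation targets desk-scale graphs (thousands of
  nodes); corpus-scale runs should import external clustering via the
  ABC/cluster formats instead.
* Reciprocal-recruitment clans reuse the recruitment sets of the
  precision/recall evaluation; on databases whose profiles were built
  from representatives, those sets reflect the trained profile, not a
  hypothetical full-membership profile.
```{r session}
sessionInfo()
```
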
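---
title: "Pan-genome trees: model, weights and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-genome trees: model, weights and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pantree)
```

## The problem

For many bacterial species several complete genomes are available, and the
interesting variation between close relatives is often not sequence
divergence but gene content: which gene families a strain carries and
which it lacks. A *pan-genome tree* clusters genomes by their gene-family
presence/absence profiles. Unlike classical phylogenies it is not meant to
reconstruct evolutionary history — horizontally transferred genes are
signal here, not noise — but to display the functional relationships
within a "snapshot" collection of genomes of a species or genus.

## Gene families from alignment hits

The unit of comparison is the gene family. Protein sequences from all
genomes are compared all-vs-all (e.g. BLASTP with tabular output); hits
with E-value above a significance cutoff (default `1e-5`) are discarded.
Two distinct sequences are linked when **both** query directions qualify:
the alignment with that sequence as query spans at least 50% of the query
length and has at least 50% identity over the aligned region. Families are
the connected components of this link graph.

Choices worth making explicit:

* **Transitive closure.** The 50/50 rule is pairwise, but families must
  partition the sequences, so the relation is closed transitively (single
  linkage). Two members of one family need not be directly linked.
* **Coverage denominator.** Coverage of the direction a→b is the
  alignment length divided by the length of *a* (that direction's query).
  A short sequence aligning fully inside a long one can therefore qualify
  in one direction and fail in the other — and then the pair fails.
* **Multiple HSPs.** A direction qualifies if any single hit qualifies;
  HSPs are never tiled into a combined alignment.
* **Identity.** The percent-identity field of the hit is used as the
  aligner reports it, i.e. measured over the aligned region.
* **Determinism.** Families are labelled `F0001, F0002, ...` in order of
  their lexicographically smallest member, so outputs are reproducible
  regardless of hit order.

## The pan-matrix and occupancy weights

Presence/absence is collected in the binary pan-matrix $M$ (genomes ×
families); $M_{ij} = 1$ iff family $j$ has at least one member in genome
$i$ — in-paralogs do not count twice. The *occupancy* $k_j$ of a family is
the number of genomes carrying it, and the occupancy spectrum typically
shows a U shape: a *core* present in all $G$ genomes, a *shell* present in
a majority, and a *cloud* of rare, strain-specific families (*ORFans* when
$k_j = 1$).

Distances can weight families by occupancy class:

| scheme        | $w_j$                 | emphasis                          |
|---------------|-----------------------|-----------------------------------|
| `uniform`     | $1$                   | none (default)                    |
| `drop_orfans` | $0$ if $k_j=1$ else 1 | robustness to gene-calling noise  |
| `shell`       | $(k_j-1)/(G-1)$       | conserved ("stabilome") families  |
| `cloud`       | $(G-k_j)/(G-1)$       | rare ("mobilome") families        |

The shell and cloud ramps are *linear* in occupancy. Only the qualitative
shape of these weighting strategies is prescribed by the procedure
("gradually higher weight" toward one end); linear ramps are the simplest
monotone choice, they are complementary ($w^{shell}_j + w^{cloud}_j = 1$),
and alternative ramps can be added behind the same `scheme` interface
without touching anything downstream. Families with equal occupancy always
receive equal weights under every scheme. The boolean flags `dropOrfans`
and `dropCore` compose with any scheme and are applied afterwards, so
e.g. a shell tree with ORFans discarded is `makeWeights(P, "shell",
dropOrfans = TRUE)`. Core families are kept by default: they contribute no
presence difference to any pair, so they only enter through the total
weight $W$ (a pure rescaling), and `dropCore` exists for users who prefer
distances relative to the variable part of the pan-genome.

## Distances

The distance between genomes $i$ and $k$ is the weighted relative
Manhattan distance between their profiles,

$$D(i,k) \;=\; \frac{1}{W} \sum_{j=1}^{n} w_j \, \lvert M_{ij} - M_{kj}
\rvert, \qquad W = \sum_j w_j ,$$

the (weighted) proportion of the pan-genome in which the two genomes
differ. With uniform weights this is $(b+c)/n$ where $b$ and $c$ count the
families private to either genome. The classical Jaccard distance
$1 - a/(a+b+c)$ (with $a$ the shared families) is provided for comparison;
the essential difference is that the Manhattan distance also counts
*shared absence* as similarity: appending families absent from both
genomes of a pair (but present elsewhere in the pan-genome) lowers their
Manhattan distance and leaves their Jaccard distance unchanged. Inside a
pan-genome, where every family could in principle be present, lacking the
same machinery is meaningful similarity.

One wording issue deserves a note: verbal definitions of the Jaccard
distance sometimes divide the shared count by the *discordant* classes
only. This package implements the standard form, dividing by the union
$a+b+c$, which is the definition with the metric properties users expect.

Both distances are true metrics on profiles (non-negativity, symmetry,
triangle inequality); the test suite verifies this on random matrices.

## UPGMA and bootstrap supports

Trees are built by average-linkage hierarchical clustering (UPGMA):
repeatedly merge the two clusters at minimal distance, place the new node
at half the merge distance, and set the merged cluster's distance to every
other cluster to the size-weighted mean of its parts' distances (which
equals the plain mean over all leaf pairs). The result is a rooted
ultrametric tree; branch lengths are height differences. UPGMA is used
deliberately: the height of a node is directly readable as half the
average profile distance between the two clades, which suits the
descriptive purpose of these trees (it is not a consistent estimator of
phylogeny, and is not meant to be).

Numerical and tie-handling choices:

* Among minimal-distance pairs, the pair whose (smaller, larger) cluster
  labels — each cluster labelled by its smallest member genome id, byte
  order — is lexicographically least is merged. Ties are detected with a
  relative tolerance of $10^{-12}$ so that floating-point noise in the
  running average cannot hide a genuine tie; this makes the output
  identical to a from-scratch average-linkage reference implementation,
  which the tests assert.
* Newick output quotes labels containing reserved characters and prints
  branch lengths with 10 significant digits by default.

Branch stability is assessed by resampling *columns* of the pan-matrix:
each replicate draws $n$ column indices with replacement, each sampled
column keeping its weight, recomputes $W$, the distances and the UPGMA
tree. The support of an internal node is the percentage of replicate trees
containing a node with the *identical two child leaf sets* — stricter than
asking for the combined clade only. Resampling is performed over id-sorted
columns with a single seeded generator, so supports are reproducible given
the seed and invariant to the column order of the input. When a weighting
scheme is active the sampled columns carry their precomputed weights;
recomputing scheme weights from the resampled occupancies would be a
coherent alternative, but occupancies are invariant under column
resampling, so the two agree for all occupancy-based schemes and the
simpler rule is used.

## What the simulator emulates — and what it does not

The package ships three generators used throughout the tests:

* `simulatePanMatrix()` plants an occupancy spectrum: `nCore` families at
  occupancy $G$, `nShell` and `nCloud` families with occupancies drawn
  uniformly from their class ranges (defaults: majority range for shell,
  minority for cloud), assigned to uniformly random genome subsets. The
  defaults ($G = 14$, 1500/700/500 families) mimic the scale of a
  single-species pan-genome of a dozen-odd strains.
* `simulateGainLoss()` evolves presence/absence along a known rooted tree
  under the simplest independent-events model: per branch of length $t$
  each family is lost with probability $1-e^{-\lambda t}$ and
  $\mathrm{Poisson}(\gamma t)$ novel families are gained. It exists to
  provide matrices with a known true tree for recovery experiments, not
  as a realistic model of genome evolution: there is no rate
  heterogeneity across families, no transfer between lineages, and gains
  are always novel families.
* `simulateAlignmentTable()` inverts the family-building step: for a
  planted partition it emits reciprocal qualifying hits (coverage 0.8 of
  the query, identity 60–99%, E-value $\le 10^{-11}$) plus decoys that
  each fail exactly one clause of the 50/50 rule — coverage only,
  identity only, or reciprocity only — on disjoint cross-family pairs,
  plus full-length self-hits. Recovering the planted partition exactly
  therefore exercises every clause of the rule.

Because random genome subsets carry no phylogenetic signal,
`simulatePanMatrix()` output is appropriate for distance/weight properties
but not for topology benchmarks; that is what the gain/loss generator is
for. Passing tests on these simulations show the procedure is implemented
correctly and behaves as designed under its own model; they cannot show
that the 50/50 rule is a good family definition for any particular real
data set, nor that UPGMA resolves any particular genus.

## Study conditions frozen in the tests

The acceptance-style tests run at fixed, documented problem sizes chosen
to give stable results at interactive runtimes: 1000 random matrices
($G \le 10$, $n \le 200$) for the distance brute-force comparison; 100
random matrices ($G \le 8$) for the UPGMA reference comparison; a balanced
4-leaf guide tree (pendant branches 0.5, internal 0.3), 500 root families,
gain 20 and loss 0.1 per unit branch length, 50 seeds for topology
recovery, with a frozen regression bound of 45/50 exact recoveries; and a
support-versus-separation grid with internal branch lengths
$\{0.05, 0.2, 0.8\}$ (200 root families, gain 15, loss 0.3, $B = 50$,
50 seeds), where mean support of the true cherries must be non-decreasing.
These values were fixed by a calibration run before the package was
assembled and are not tuned afterwards.

## Known limitations

* All-vs-all alignment input scales quadratically in the number of
  proteomes; the package consumes the tabular output but does not run or
  parallelise the aligner.
* HSP tiling is not implemented; proteins with fragmented alignments can
  fail the coverage clause in one direction.
* Single-linkage closure can chain families together through promiscuous
  domains; database-driven family definitions (e.g. orthology databases)
  are out of scope.
* The Jaccard tree is unweighted by design; weights are only defined for
  the Manhattan distance.
* UPGMA assumes a roughly clock-like accumulation of profile differences;
  strongly uneven gene turnover across lineages will distort the tree,
  which is one reason bootstrap supports are reported.
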
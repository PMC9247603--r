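---
title: "Inferring polyploid origins by deep-coalescence minimization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring polyploid origins by deep-coalescence minimization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

polycoal implements a complete workflow for reconstructing the reticulate
history of auto- and allopolyploid plants from multi-locus amplicon data:
allele calling from reads, assignment of polyploid alleles to diploid
subgenomes, multi-labeled (MUL) species trees and their folded networks,
scenario ranking for species delimitation, and plastid haplotype networks.
This vignette explains the models behind each stage, the tunable parameters
and their defaults, what the bundled simulator does and does not emulate,
and the numerical choices a maintainer should know about.

## The inference problem

A polyploid of ploidy $p$ carries $p/2$ diploid subgenomes.  In an
allopolyploid each subgenome descends from a different progenitor species;
in an autopolyploid all descend from one.  Sequencing a single-copy nuclear
locus in a polyploid yields up to $p$ alleles, but nothing in the sequence
says which subgenome an allele belongs to.  Recovering that partition — the
*allele co-ancestry* — is the central estimation problem: once alleles are
binned into subgenomes, the polyploid can be placed in a species phylogeny
once per subgenome (a MUL tree), and merging those placements yields a
network in which each allopolyploid is a reticulation node joining its
parent lineages.

## Deep-coalescence scoring

For a rooted gene tree $G$ and rooted species tree $S$ with a mapping of
alleles to species, the number of *extra lineages* is the classical
cluster-based count: for every cluster $A$ of $S$ (the leaf set under one
branch), the minimum number of gene lineages exiting $A$ equals the number
of maximal clades of $G$ whose leaves all map into $A$, written $k_G(A)$,
and

$$ XL(G, S) \;=\; \sum_{A \in \mathrm{clusters}(S)} \big(k_G(A) - 1\big). $$

$XL$ is zero exactly when $G$ can be embedded in $S$ with every
coalescence inside its branch.  The minimize-deep-coalescence (MDC)
criterion chooses the species tree (or, here, the allele partition)
minimizing $XL$ summed over all sampled gene trees and loci, each tree
weighted $1/n$ within its locus.

### Exact search by dynamic programming over clusters

Because $XL$ is additive over clusters, the optimal rooted species tree on
$L$ lineage labels satisfies

$$ \mathrm{best}(A) \;=\; K(A) + \min_{A = B \,\dot\cup\, C}
   \big[\mathrm{best}(B) + \mathrm{best}(C)\big], $$

where $K(A) = \sum_{G} w_G \, (k_G(A) - 1)$ is precomputed for all $2^L$
lineage subsets.  Evaluating $\mathrm{best}$ over all subsets costs
$O(3^L)$ and visits every cluster of every rooted binary topology exactly
once, so the optimum is exact.  The package uses this exact mode up to 12
labels (the compiled kernel computes all $K(A)$ per gene tree with one
subset-sum transform of counts keyed by node bitmasks) and falls back to a
rooted-NNI hill climb above that; the study scale (4–8 lineages) never
leaves the exact regime.  The unit tests cross-check both $XL$ and the
optimum against a brute-force enumerator built on plain set operations and
phangorn's topology enumeration.

### Assignment search

`hill_climb_assignment()` searches the space of valid partitions (at most
two alleles per subgenome bin per locus).  Moves are: move one allele to a
bin with spare capacity, swap two alleles between bins, and — one deliberate
extension of the single-swap neighbourhood — relabel a whole bin pair at one
locus.  The extension exists because subgenome bin indices are arbitrary
per locus: a locus whose bins are internally coherent but permuted relative
to the other loci can only be repaired by two coupled swaps whose
intermediate state scores worse, a local optimum a single-swap
neighbourhood cannot leave; with the composite move the search reliably
reaches the global optimum on planted hexaploids.  The climb accepts the
first strictly improving move (random scan order), reinitializes from a
fresh random assignment at local optima, spends 1000 hill-climbing steps
per run by default, and returns the best of 10 independent runs.  All
randomness is governed by one seed.

Scoring an assignment reduces to relabeling the polyploid alleles by their
bins and rerunning the species-tree DP; per-locus $K$ vectors and move
lists are cached by bin configuration, which makes a full search on 10
loci of 100 gene trees a matter of seconds.

### Tie-breaking by gene-tree probability

Two assignments can tie on extra lineages (a symptom the original protocol
associates with autopolyploidy).  `gene_tree_prob_tiebreak()` then computes
the probability of every sampled gene-tree topology under each assignment's
species tree by enumerating coalescent histories: each assignment of gene
coalescences to species branches contributes
$\prod_b (w_b/d_b)\, g_{u_b v_b}(T_b)$, with $g$ the Tavaré pure-death
probability, $d_b$ the number of coalescent sequences from $u_b$ to $v_b$
lineages and $w_b$ the number of event orderings compatible with the gene
tree (hook-length formula on the event forest).  The enumeration is
validated against the three-taxon closed form
$P(\text{concordant}) = 1 - \tfrac{2}{3}e^{-T}$.  MDC provides no branch
lengths, so they are estimated by inverting that same identity on observed
triplet concordance frequencies (terminal branches: allele monophyly
frequencies), clamped to $[0.02, 8]$ coalescent units — a documented
approximation.  Beyond 8 lineage labels or 12-leaf gene trees the function
falls back to lexicographic order with a warning rather than enumerate
intractably many histories.

## Allele calling

The calling pipeline mirrors an amplicon workflow for 454-era data:

* **Quality filter** — a read is discarded when strictly more than 10% of
  its positions have Phred < 20 (both constants exposed in `qc_params()`).
* **Clustering** — average-linkage agglomeration on pairwise Hamming
  distance, cut at `cluster_cut_factor` (default 1.5) times the expected
  within-allele pairwise distance $2eL$, with $e$ the mean per-base error
  probability implied by the quality strings.  This replaces an external
  Bayesian clustering tool; the contract downstream needs is only a
  partition of reads.  Reads are assumed equal-length (no-indel amplicons).
* **Retention** — a cluster is an allele candidate only with at least
  $\lceil 0.5 \times \text{total}/p \rceil$ reads (`min_read_factor`
  default 0.5, a declared stand-in for a companion method whose formula is
  not printed; exposed as a parameter).
* **Chimera removal** — a read is flagged when some breakpoint and ordered
  allele pair make the recombinant strictly closer to the read than any
  single candidate allele.
* **Consensus** — per column, bases reaching 20% frequency are retained and
  encoded as IUPAC ambiguities (ties at the majority likewise).

Utility calculators cover the wet-lab design numbers: the
inclusion–exclusion (coupon-collector) probability that $n$ clones recover
all $k$ equally frequent alleles — 27 clones give probability 0.957 for a
hexaploid's six alleles, 26 give 0.948, so 27 is the smallest design
reaching 0.95 — and ploidy classification from flow-cytometric fluorescence
ratios against the per-ploidy reference ranges observed in the study system.

## Alignment post-processing

`simple_gap_code()` implements simple indel coding: one binary character
per distinct (start, end) gap event; sequences whose own gap strictly
contains a shorter event are inapplicable (`NA`) for that character.
`mask_region()` removes a 1-based inclusive column range (used for a
microsatellite motif producing homoplastic length variation).
`flag_paralogs()` operationalizes the paralog screen on gene trees rather
than splits graphs — the exclusion rule, not the visualization, is what
matters: a clade is dropped when support ≥ 0.95, its stem is ≥ 3× the
median internal branch length (the source gives no number; both are
parameters), it spans ≥ 2 a-priori taxa, and no sample would lose its last
sequence.  No minimum clade size is imposed.

## Networks and ages

`collapse_low_support()` contracts internal branches with posterior
support strictly below 0.7 (a branch at exactly 0.70 is kept), preserving
node heights.  `join_subgenome_leaves()` folds a MUL tree by merging each
polyploid's subgenome leaves into one node with an incoming edge per former
position; sister subgenome leaves (autopolyploids) collapse to a single
annotated edge, so only true hybrids appear as reticulations.  Hexaploids
yield in-degree-3 nodes.  The age of a polyploid is the covering interval
of the 95% HPD intervals of its subgenome divergence nodes
(`merge_hpd()`, `polyploid_age()`); dated, annotated trees are read with
`read_annotated_tree()`.  Both orders of collapsing and folding are
available; they commute unless a weak branch is adjacent to a reticulation,
a case the source protocol leaves open.

`rank_scenarios()` scores species-delimitation scenarios (partitions of
the polyploid samples into putative lineages, samples of one lineage
sharing subgenome labels) by the best assignment score under each
grouping.  This is a surrogate for path-sampling marginal likelihoods —
reimplementing a full Bayesian dating stack is out of scope — and its
output is labeled accordingly; ties are reported, not broken silently.

## Plastid haplotype networks

`parsimony_limit()` computes the statistical-parsimony connection limit:
the largest step count $j$ whose parsimony probability still reaches 95%.
The probability is reconstructed as
$P(H = j \mid j \text{ distinct differing sites})$ under a geometric
(coalescent) prior on the true mutation count $H$ with moment estimate
$\theta = j$, and uniform multiple-hit collisions over the $m$ sites
(occupancy probabilities via Stirling numbers, evaluated in log space).
Published implementations of this calculation differ subtly among
themselves; the tests therefore validate against an independent Monte-Carlo
evaluation of the same series rather than against any one tool's output.
`build_network()` then connects haplotype pairs in increasing step distance
(substitutions plus one step per contiguous indel run, or with gapped
columns excluded), round by round: a pair is linked unless already
connected within its distance, multi-step links insert hypothetical
intermediate nodes, and all equal-cost alternatives of a round are
retained, so reticulations survive — a reproducible, conservative reduction
of the original heuristic's frequency-based choices.  Components further
apart than the limit stay separate.

## The synthetic-data generator

Everything above is testable without any sequencing download because the
generator plants a known history:

* **Species tree** — either user-fixed or a random coalescent shape
  rescaled to the crown age, default 4.39 Ma (sd 0.91 Ma carried as
  metadata), with 3-year generations and a substitution rate of
  $5\times10^{-9}$/site/year — standard plant values matching the study
  system.  The preset scenarios use a fixed four-species tree
  `((spA:3.5,spB:3.5):0.89,(spC:3.2,spD:3.2):1.19)` and polyploid origins
  at 1.5 Ma, inside the age interval reported for the study's polyploids;
  with the default $N_e$ the preset parent lineages are separated by more
  than 2 coalescent units.
* **Population sizes** — the source states none; the default
  $N_e = 2.5\times10^5$ makes the crown span ≈ 2.9 coalescent units,
  producing visible but not overwhelming incomplete lineage sorting.  An
  allopolyploid subgenome is an isolated disomic population from its origin
  (no homoeologous exchange); an autopolyploid is one tetrasomic population
  holding all $p$ copies at proportionally larger size; the plastid is a
  single maternally inherited lineage per sample at half the nuclear
  effective size.
* **Gene trees** — independent multispecies-coalescent genealogies per
  locus (default 5 nuclear + 1 plastid).  The first genealogy is the true
  allele genealogy used for HKY sequence simulation (phangorn's simulator,
  $\kappa = 3$); the remaining draws stand in for the topological spread of
  a Bayesian posterior sample.  That is a deliberate simplification: real
  posterior trees are correlated estimates of one genealogy, whereas these
  draws are independent, which if anything *overstates* gene-tree conflict
  and makes recovery tests conservative.  Monte-Carlo concordance
  frequencies are checked against the closed-form three-taxon probability.
* **Reads** — uniform allele sampling with a quality-first error model:
  per-base Phred scores are drawn (a low-quality fraction tuned so the mean
  implied error equals `error_rate`) and bases err with the probability
  their score implies, so qualities are calibrated as on a real instrument;
  a configurable fraction of uniformly low-quality reads exercises the
  quality filter.  PCR chimeras are prefix+suffix recombinants of two
  alleles with a uniform breakpoint; a recombinant identical to an existing
  allele is emitted as an ordinary read of that allele, because no
  information could distinguish it — chimera truth labels mark only
  recombinants distinct from every input allele.  No indels, no
  platform-specific homopolymer errors, no selection.

What passing tests show, and what they do not: recovery rates measured on
these simulations certify the estimator under the stated coalescent
conditions (deep parent divergence, single-copy loci, calibrated errors);
they do not certify robustness to alignment error, paralogy missed by the
screen, homoeologous exchange after polyploid formation, or posterior
correlation structure, none of which the generator emulates.

## Numerical choices and limitations

* Scores are compared with a $10^{-9}$ tolerance; ties at that tolerance
  are genuine ties and routed to the tie-break.
* Subset DP and bitmask kernels limit the exact engine to 30 lineage
  labels (masks) and 12 labels (DP); the NNI fallback handles more but
  without optimality guarantees.
* Problem sizes in the tests — 10 loci × 100 gene trees × 20 seeds for
  recovery, 100 random instances for oracle equivalence — were chosen as
  the smallest sets at which the Monte-Carlo margins are comfortably
  resolved.
* `subsample_gene_trees()` roots on the declared outgroup and prunes it;
  gene-tree samples are deduplicated by canonical topology before scoring,
  which is exact because $XL$ depends only on topology.
* Degenerate inputs: empty read sets warn and pass through; masking an
  entire alignment warns and returns zero-length sequences; a polyploid
  with fewer called alleles than $p$ is handled by bins of unequal size;
  scenario groups must partition the polyploid samples exactly.
* The scenario criterion compares total extra lineages across groupings
  with different label counts; like the original's marginal-likelihood
  comparison it is a relative, not absolute, measure, and equal scores are
  reported as ties.
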
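---
title: "Methods: transcriptomic and fitness analysis of facultative intraguild predation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptomic and fitness analysis of facultative intraguild predation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facpred)
```

## The scientific problem

The blow fly *Chrysomya rufifacies* is an invasive carrion breeder whose
second- and third-instar larvae facultatively prey on larvae of native blow
flies such as *Cochliomyia macellaria*, an example of intraguild predation
inside a normally detritivorous guild.  Two complementary kinds of evidence
bear on this behavior:

* **Fitness assays.** No-choice laboratory arenas (one *C. rufifacies*
  larva, with or without a single prey larva as the only supplemental food)
  scored for survival to eclosion, repeated over three trial generations,
  analyzed as stratified 2x2 contingency tables.
* **Transcriptomics.** Twelve RNA-seq libraries from six sibling pairs
  (three per sex), each pair contributing one actively predating and one
  nonpredating larva collected simultaneously, analyzed for differential
  expression between the behaviors.  Because no genome is available for
  this species, expression is measured on de novo splicing-graph assemblies
  built under a sweep of assembly stringencies, and gene identities come
  from protein homology.

`facpred` implements both analysis arms end to end, together with a seeded
synthetic-data generator so that every stage is testable without the
original sequence archives.

## Read quality control

Raw reads are filtered by two rules applied in order of severity:

1. **Adapter filter.** A read is dropped if any of four screened Illumina
   adapter/contaminant 50-mers — or any of their reverse complements —
   occurs as an *exact substring*.  Exact matching (rather than alignment
   with mismatches) is deliberate: the filter is then a pure set-membership
   predicate, reproducible bit for bit.
2. **Quality truncation.** Each read is cut immediately before the first
   base whose Phred score is less than or equal to 15 (the comparison is
   inclusive); the quality string is truncated in lockstep.

Pairs are the QC unit: if either mate is adapter-flagged or falls below the
minimum post-trim length (default 20 bp, so that a typical assembly k-mer
still fits), the whole pair is dropped.  This keeps mate files
record-aligned for downstream bookkeeping.  QC is idempotent: running it on
its own output changes nothing.

## Splicing-graph assembly

An assembly setting is a pair (k, c): k-mer length and k-mer coverage
cutoff, named `"k_c"` (for example `25_50`).  For each setting:

1. Every length-k window of every read is counted.  Counts are aggregated
   under the **canonical** form of each k-mer (the lexicographically
   smaller of the k-mer and its reverse complement), because the protocol
   is unstranded.  `k` must be odd, so no k-mer can equal its own reverse
   complement and the palindrome special case disappears.
2. K-mers whose canonical count is below `c` are discarded.  `c` is the
   sweep's stringency knob; everything else is fixed.
3. The de Bruijn graph is built over the surviving k-mer strings **in read
   orientation**, with an edge wherever the (k-1)-suffix of one vertex
   equals the (k-1)-prefix of another.  Maximal non-branching paths (each
   internal step leaves a vertex of out-degree 1 and enters one of
   in-degree 1, and no vertex repeats) are compressed into unitig nodes;
   isolated cycles are broken deterministically at their lexicographically
   smallest vertex.  Node sequences are reported in canonical spelling
   (minimum of the spelling and its reverse complement), which merges the
   two mirror-image unitigs that arise when both strands of a locus were
   read.  Edges join unitigs at branch points, and the weakly connected
   components are the *splicing graphs*: a node is analogous to an exon or
   a group of exons transcribed together, and a component collects the
   nodes of one gene-like locus.

Using read-orientation strings (rather than one vertex per canonical
k-mer) as graph vertices is a deliberate design decision.  A canonical
vertex set must conflate a k-mer with its reverse complement, which
creates spurious hairpin adjacencies wherever a sequence contains both
orientations of the same k-mer (`ACGT...` contains `ACG` and its reverse
complement `CGT` for k = 3), and these conflations fragment or overextend
unitigs in ways that have no analogue in the underlying transcripts.  With
read-orientation vertices the compaction is exactly the classic
single-strand unitig construction, the coverage cutoff still acts on
strand-collapsed counts, and strand symmetry is restored at the node level
by canonical spelling.  The package ships an independent brute-force
enumerator (`unitigs_bruteforce()`) implementing the same definition by
exhaustive path search; the test suite and the acceptance script verify
node-set equality on hundreds of random micro read sets.

**Quantification.**  Reads are assigned to nodes by plurality vote: each
surviving k-mer of a read (looked up in either orientation) votes for the
node that owns it, and the read counts toward the winning node.  Ties and
reads with no surviving k-mer are left unassigned, so counts stay integral
(as the count model downstream requires) and per-library node counts never
exceed the library size.

The default sweep is k in {25, 31, 41, 49} times c in {2, 5, 10, 25, 50,
100} — 24 settings, fully configurable.

## Annotation

Nodes receive gene labels by best-hit homology.  Hits can be ingested from
the standard 12-column tabular alignment format, or produced by the
built-in miniature six-frame translated search, which exists so the
synthetic pipeline is closed-world; real database searches are out of
scope.  The mini search translates each node in all six frames, aligns
locally (Smith–Waterman, BLOSUM62, gap open 11 / extend 1), and converts
scores with the ungapped Karlin–Altschul constants for BLOSUM62
(lambda = 0.3176, K = 0.134):

$$E = K \, m \, n \, e^{-\lambda S}.$$

Using ungapped constants with gapped alignment scores slightly
underestimates E; for the self-vs-decoy separation the synthetic tests
need (true hits at E below 1e-15, random 40-mers near E of 0.1) this bias
is immaterial.  Per query only the top hit is retained — minimal E-value,
ties broken by maximal bitscore then lexicographically smallest subject —
and the query is annotated only if that hit reaches E <= 1e-7.  A splicing
graph's gene set is the union over its nodes; empty sets (unannotated
graphs) and multi-gene graphs are both expected outcomes.

## Nested differential expression

Counts for node $i$ in library $j$ are modeled as negative binomial with
mean $s_j \mu_{ij}$ and variance $\mu + \alpha_i \mu^2$, where $s_j$ are
median-of-ratios size factors (rescaled to geometric mean 1) entering as
fixed offsets, never by pre-dividing counts — pre-division would distort
the NB variance structure.

The test is a two-stage nested likelihood-ratio procedure under the
sibling-pair design:

* **Stage 1 (relatedness screen).** Per node, `~ behavior + pair` against
  `~ behavior` (df = pairs − 1 = 5).  Nodes significant after BH
  adjustment at FDR < 0.1 are flagged and removed: their expression tracks
  shared rearing environment/relatedness, not behavior.
* **Stage 2 (behavior).** On the survivors, `~ behavior` against the
  intercept-only model (df = 1), BH within the assembly (each assembly is
  analyzed independently), and classes at FDR < 0.1:
  predator-biased (log2 fold change > 0) or nonpredator-biased (< 0).

The stage-2 reduced model and the stage-1 significance threshold are design
choices (both configurable): the nested structure fixes only the stage-1
model pair, and mirroring the stated stage-2 FDR rule at stage 1 keeps the
two screens symmetric.  Sex is recorded but never modeled, as both sexes
express the phenotype.

**Fitting.**  GLMs are fit by iteratively reweighted least squares with
log link, offsets `log(s_j)`, and fixed dispersion, converged when the
relative change in deviance falls below 1e-8 (at most 100 iterations);
non-converging nodes are excluded with a warning, and all-zero nodes are
untestable and skipped.

**Dispersion.**  Each node's $\alpha_i$ is estimated *once under the full
design* and shared by every fit of that node, so the LRTs compare means
only.  The per-node estimate solves the Pearson moment equation
$\sum_j (y_j - \hat\mu_j)^2 / (\hat\mu_j + \alpha \hat\mu_j^2) = n - p$
with $\hat\mu$ from the full-design fit (fit and solve are iterated once).
Estimating dispersion from residuals around the fitted design — rather
than from raw cross-library variance — matters: raw moments would absorb
genuine pair and behavior signal into the noise term and destroy the
stage-1 screen's power entirely.  A hyperbolic mean–dispersion trend
$\alpha(\mu) = a_0 + a_1/\mu$ is then fit by least squares across nodes,
and the final value is the geometric mean of the node estimate and the
trend prediction, floored at 1e-8.  With twelve libraries the residual
degrees of freedom are few (5 under the full design), so the plug-in LRT
is moderately anticonservative; in the package's calibration simulations
the empirical FDR at nominal 0.1 is about 0.2, which the acceptance
bounds account for.

For the expression heatmap, DE-node counts are transformed to row-z-scored
`log2(normalized + 1)` and rows and columns are each ordered by
agglomerative hierarchical clustering (average linkage, Euclidean
distance) — the reciprocal clustering presentation.  In the shipped
synthetic analysis this ordering cleanly separates the six predator from
the six nonpredator libraries.

## Cross-assembly consensus

A gene is *detected in assembly A* iff at least one node annotated to it
has a non-`ns` class in A.  Detection is counted **once per assembly**
regardless of how many splicing graphs within A hit the gene — this is
what makes counts comparable across assemblies in which a gene's locus may
be assembled in one or several graphs.  The consensus direction is
`up-in-predator` or `down-in-predator` when all detections agree and
`mixed` otherwise; a mixed flag is safer than a silent majority vote.
Differentially expressed nodes with no annotation are reported separately,
keyed by assembly, component and a node-sequence signature, so they can be
revisited after later annotation rounds.

The tiered report uses detection thresholds of 10 (headline) and 7
(secondary) assemblies by default — the study-scale conventions for a
24-setting sweep.  These absolute thresholds are kept even for small
sweeps: with a 4-setting grid nothing can reach tier 1, and the per-gene
detection counts and directions carry the evidence.  This is intentional.
Because all assemblies of a sweep are built from the same reads, a
FDR-level false discovery (a null gene whose twelve count draws happen to
fall in a behavior-like pattern) replicates across *every* assembly in
which its nodes survive; replication across assemblies therefore guards
against assembly artifacts, not against sampling noise, and no
proportionally scaled-down tier threshold could suppress such a gene.

## Predation-assay statistics

The published assay table reports group sizes with rounded percent
survival.  `reconstruct_count(N, pct)` inverts that presentation exactly:
it returns the unique integer `s` with `round(100 s / N) = pct` under
half-up rounding, and refuses (with the candidate list) when the inversion
is ambiguous.  All six per-trial inversions of the shipped table are
unique, and the reconstructed tables reproduce the published test results
to all printed digits.

* **Fisher exact, two-sided** by point-probability summation (the p-value
  sums all margin-consistent tables whose probability does not exceed the
  observed one) — the convention under which trial 1 gives 0.6111.
* **Cochran–Mantel–Haenszel** across trials with no continuity correction;
  the common odds ratio is the Mantel–Haenszel estimator.  For a single
  stratum the statistic equals $(n-1)/n$ times the uncorrected chi-square
  statistic — the hypergeometric variance carries the $n-1$.
* **Breslow–Day** homogeneity of the per-trial odds ratios, expected cells
  from the margin-constrained quadratic at the MH common odds ratio, no
  Tarone adjustment.
* **Proportion z-test** without continuity correction, for the field
  predator sex-ratio question (8 males of 10 predators vs 0.5).

Survival-by-consumption-level analyses (R x 2 tables) are supported via
`fisher_exact_rx2()` on arena-level records; the package ships no fixture
for them because the underlying raw counts are not part of the published
summary.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes, not
sequencing reality:

* **Gene models**: 2–4 exons of 50–300 bp, 1–3 isoforms, first isoform
  always the full exon chain; gene bodies are drawn from sense codons so
  the full-length transcript reads through in frame 1 like a
  protein-coding sequence (this gives every gene a translatable protein
  for the closed-world annotation tests).  Exon sequences are globally
  distinct.
* **Counts**: NB draws with mean
  `size_factor x baseline x 2^(lfc x predator) x 2^(pair offset)`, the
  per-gene, per-pair offsets Normal(0, sd) on the log2 scale and shared by
  the two siblings of a pair — multiplicative effects, exactly the
  structure the GLM assumes.  Default dispersion 0.05; default size
  factors log-uniform in [0.5, 2].
* **Reads**: one fragment per count unit, uniform start, fragment length
  equal to the read length, mate 2 the reverse complement of mate 1, roles
  swapped with probability 0.5 (unstranded); per-base substitution errors;
  a configurable fraction of reads has a full adapter overwritten at a
  random offset; qualities constant Q40.

Known departures from real data, and their consequences: the two mates of
a fragment cover the same span, so every k-mer (including every error
k-mer) arrives in pairs and coverage cutoffs below about 4 are
ineffective against singleton errors; there is no insert-size model, no
indels, no PCR duplicates, no quality decay along the read, no intron
retention, and library depth is about three orders of magnitude below a
real HiSeq library.  Passing tests therefore demonstrate correctness of
the algorithms under the assumed generative model, not robustness to
artifacts the generator does not produce.

## Problem sizes and numerical choices

The shipped analysis and the test suite run at deliberately modest sizes
chosen so the whole battery completes in minutes on one core: 20-gene
transcriptomes at baseline 60 with a 4-setting sweep for the end-to-end
runs; 2,000-node count matrices over 20 seeded replicates for the DE
operating characteristics (5% true behavior effects at |log2fc| in [2, 4],
baselines 100–500, dispersion 0.05, plus 5% pure pair-effect nodes at
sd 1.5); 200 random micro read sets for assembler–oracle equivalence.
Numerical conventions worth knowing: IRLS convergence at relative deviance
change < 1e-8 with the linear predictor capped at 30; dispersion floor
1e-8; LRT statistics clamped at 0; BH adjustment capped at 1; assembly
tie-breaks (canonical k-mers, cycle break points, read-assignment ties)
all resolved lexicographically or by discarding, never randomly, so every
stage is deterministic given its seed.

## Limitations

The package reproduces the published analysis *procedure*, not the
published gene list: that would require the original 66-library archive, a
real fly proteome, and the original 24 parameter settings.  The DE stage
is a plain plug-in-dispersion LRT; it does not implement shrinkage
estimators, outlier refitting, or independent filtering, and its moderate
anticonservativeness at n = 12 is documented above.  The mini translated
search is a testing device, not a BLAST replacement.  Consumption-level
fitness analyses are implemented generically but unvalidated against
published numbers, which do not include the underlying counts.
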
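---
title: "Methods: peak annotation, motif statistics and consensus network inference in stmgrn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak annotation, motif statistics and consensus network inference in stmgrn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmgrn)
```

stmgrn implements the downstream computational analysis of a ChIP-seq
study of the Arabidopsis KNOX transcription factor SHOOT MERISTEMLESS
(STM): from filtered binding-site intervals to annotated target loci,
from peak sequences to TGAC/TGAT-core binding motifs, and from an
STM-responsive gene set to a consensus Bayesian gene-regulatory
network. This vignette records the models, the tunable parameters and
the numerical choices, in enough detail that a reader can judge what a
passing test suite does and does not establish.

## Coordinate conventions and peak-to-locus assignment

All internal coordinates are 0-based half-open; GFF3 input (1-based
inclusive) is converted on ingest and converted back on export, so
write/read round trips are identities. A peak's *reference point* is
its summit when one is recorded, else the floor midpoint of its
interval — the summit is the natural proxy for the binding position,
and the source data do not define an alternative.

Consensus filtering keeps a peak only when an independent comparison
also calls an overlapping peak (`consensus_peaks()`, minimum overlap 1
bp by default), and every peak overlapping a no-epitope control peak by
at least 1 bp is discarded (`subtract_control_peaks()`). Both
operations are backed by `IRanges` interval trees and are
property-tested against an all-pairs quadratic oracle.

Each surviving peak is assigned to the gene whose interval lies nearest
to the reference point, with distance 0 inside the gene body. Distance
is measured to the gene interval, not the TSS, matching the behaviour
of nearest-feature annotation tools; the signed TSS distance is then
reported for the chosen gene (negative = upstream in the gene's
orientation, 0 when the peak interval spans the TSS). When the two
nearest genes are approximately equidistant the transcriptionally
responsive one wins; if both or neither are responsive the peak is
assigned to both loci. "Approximately equidistant" is operationalised
as a difference of at most 10% of the larger distance (configurable,
or an absolute bp tolerance), since no numeric threshold is given in
the source material.

Location categories follow a fixed precedence: gene body when the
reference point falls inside the gene; otherwise upstream bins at
|TSS distance| in (0, 1000], (1000, 2000] and (2000, 5000] bp (bins are
half-open, so exactly 2000 bp falls in the 1–2 kb bin); then downstream
within 3000 bp past the strand-aware 3' end; everything else is distal
intergenic. TSS overlap is a flag, not a category, because
TSS-spanning peaks are a sub-statistic of the upstream/body classes.
`distribution_summary()` reports fractions per peak or per locus; the
per-locus denominator is what a one-row-per-locus annotation table
yields, and it is the denominator under which the published location
percentages are mutually consistent.

## Word, dyad and positional statistics

Oligomer analysis counts overlapping occurrences of all 4^k words
(k = 6, 7 in the discovery protocol) with N-containing windows
skipped; both-strand runs pool each word with its reverse complement
under the lexicographically smaller key, so pooled counts equal the
sum of the two per-strand counts. Significance is the upper binomial
tail P(X ≥ observed) with the number of countable windows as the trial
count and the background word probability as the success probability;
E-values multiply by the number of distinct words tested in the run,
and `sig = -log10(E)`. Only positively enriched words are reported, at
most three per run by default, mirroring the hits-per-algorithm cap of
the discovery protocol. Dyads are pairs of short cores (3 bp
canonically) at an exact spacing of 0–20 bp; their expectation
multiplies the two monad probabilities (independence under the
background), with the same tail and E-value machinery, and strand
pooling maps a dyad to its reverse complement at the same spacing.
Because overlapping occurrences are counted rather than clumped, null
tails for self-overlapping words are slightly miscalibrated; the null
property the suite asserts is the one E-values actually provide — about
one dyad per null run reaches E < 1, while E < 0.05 essentially never
occurs.

Positional analysis bins word-occurrence offsets around the summit
(100 bp window, 10 bp bins by default) and applies a chi-square test
against a homogeneous expectation on bins − 1 degrees of freedom:
binding-associated words concentrate centrally, background words do
not.

Backgrounds are Bernoulli (order 0) or Markov (order 1–2) models with
strictly positive probabilities; word probabilities under a Markov
model start the first m positions from the mononucleotide marginal.
The default synthetic composition is AT-rich (A/T 0.32, C/G 0.18),
approximating the Arabidopsis nuclear genome. The "matrix-based"
motif representation is a position count matrix with a pseudocount
(default 1, distributed by background frequencies) — profile-HMM state
machinery is deliberately out of scope, since the discovery protocol
rests on word/dyad statistics over Markov backgrounds.

## Exact PWM scan p-values

Count matrices are converted to log2 likelihood-ratio weights against
the background mononucleotide composition. For the hit p-value —
the probability that a background-drawn word scores at least as high —
the weights are first quantised onto an integer lattice of 10^4 steps
spanning the full score range, and the null score distribution is then
computed *exactly* for the quantised weights by dynamic-programming
convolution across positions. Because scoring and null distribution
use the same lattice, reported p-values are exact for the scoring
scheme actually applied; quantisation perturbs any single weight by at
most half a lattice step (the full score by at most w/2 steps, about
0.05% of the score range for an 8-column matrix). The suite verifies
the DP tail against complete enumeration of all 4^w words for widths
up to 8.

One floor is worth knowing: a scan p-value can never be smaller than
the background probability of the single best-scoring word, so the
stringent 1e-5 hit threshold is unreachable for short or AT-balanced
motifs under an AT-rich background (for example, an 8-mer with four
A/T bases bottoms out at 0.32^4 × 0.18^4 ≈ 1.1e-5). This is a real
property of exact p-values — the published observation that known
binding sites in the *CUC1* promoter fail the same threshold is the
same phenomenon — and the recall tests therefore plant GC-enriched
motifs when exercising the 1e-5 cut-off.

Motif enrichment against control sequences is a two-sided Fisher exact
test on the per-sequence hit indicator, with a Haldane half-count
odds-ratio correction when a cell is zero. Matrix clustering uses the
maximum Pearson correlation of aligned frequency columns over all
offsets (at least 4 aligned columns) and both orientations, with
single-linkage grouping at a similarity threshold.

## Early/late response classification

Differential-expression evidence lives on a closed vocabulary of
channels: the 3 h direct-target experiment, the 8 h, 24 h, 72 h and
9-day time-course timepoints, and the meta-analysis. A gene is
*early*-responding if any evidence exists at 3 h, 8 h, 24 h or meta;
*late* if evidence exists only at 72 h or 9 d; *none* otherwise. The
"24" in the source text is read as the 24 h timepoint, the only
reading consistent with the enumerated time course. Direction of
change is carried but unused: the rule keys only on when differential
expression first appears. The integration with a bound-gene set
partitions it exactly (early + late + none = bound), and the ΔΔCt
utility computes 2^−ΔΔCt fold changes for qPCR validation.

## Discretisation and the BDeu score

Expression matrices are discretised per gene into equal-frequency
bins (3 levels by default — the conventional choice for the search
tool family this pipeline follows; the level count is configurable).
Ties are broken stably by sample order; constant genes are assigned
state 0 with a warning.

Network structures are scored with the BDeu marginal likelihood
(equivalent sample size 1, uniform structure prior): for each child
with q parent configurations and r states,

score = Σ_j [ lnΓ(α_j) − lnΓ(α_j + N_j) + Σ_k ( lnΓ(α_jk + N_jk) −
lnΓ(α_jk) ) ],  α_jk = ess/(q·r).

The score is decomposable (the network score is the sum of family
scores) and score-equivalent (Markov-equivalent DAGs score equally);
both properties are verified numerically to 1e-8 against a direct
Gamma-formula oracle, the latter via covered-edge reversals. The
original study names only its search tool; BDeu is that tool family's
default Bayesian Dirichlet score and is the standard desk-verifiable
choice.

## Simulated-annealing search and the consensus network

The structure search proposes adding, deleting or reversing a random
edge, rejects proposals that would create a cycle or exceed the
10-parent cap, and accepts score-decreasing moves with probability
exp(Δ/T). The temperature schedule follows the published
configuration: T starts at 10,000 and is multiplied by 0.7 whenever
2,500 proposals are accepted or 10,000 proposed since the last update;
if fewer than 500 were accepted in that window the search *reanneals*
to T = 800 instead, and when a reannealing cycle brings no improvement
of the incumbent it restarts from a random DAG (up to 10,000
restarts). The published wall-clock budget (1 h per run) is replaced
by a deterministic proposal budget — 100,000 proposals by default —
so results are exactly reproducible from a seed; family scores are
memoised, making the search core (implemented in C++) fast enough
that the full 50-run protocol on an 8-node problem takes seconds.
At near-zero temperature the acceptance rule degenerates to greedy
hill climbing, which the suite verifies by checking local optimality
of the result.

Fifty independent searches feed the consensus: each directed edge's
frequency is its share of the 50 result DAGs, and edges at or
**at least** the 30% threshold are retained — the inclusive reading
reconciles "> 30% confidence" with the gloss "predicted in 30–100% of
iterations". Node pairs retained in both directions are flagged as
feedback with their combined frequency reported, and node order is
breadth-first distance from the root regulator (STM) over the
undirected skeleton. The published "influence score" terminology is
conflated in the source with edge frequency; frequency is what the
text's own numerical gloss describes, so frequency is what is
implemented, and signed CPD-derived influence magnitudes are left as
an extension.

`exhaustive_search_oracle()` enumerates all DAGs on up to five nodes
(3, 25, 543, 29281 structures for 2–5 nodes) and anchors the
correctness of the annealing search: on 4-node data sampled at CPD
strength 0.8 with n = 2000, the default-budget search attains the
enumerated optimum in essentially every seeded run.

## The synthetic-data generators

Every generator is a pure function of its seed and records its ground
truth alongside the data, so downstream tests check recovery against
bookkeeping rather than re-deriving truth from output.

* `random_dag()` samples a topological order and includes forward
  edges independently; `ground_truth_cpds()` gives each parent
  configuration a random target state and mixes a one-hot on that
  target with the uniform distribution at weight `strength`. Targets
  are resampled until the map depends on every parent, so no edge of
  the truth is statistically vacuous — without this, a "strong" CPD
  can still render an edge unrecoverable in principle, which is a
  property of the truth, not of the search. Root nodes keep uniform
  marginals at every strength so ancestral samples stay diverse.
* `toy_genome_fixture()` builds a 17-gene annotation with peaks
  planted in every location category on both strands, a TSS-spanning
  peak, and the two equidistance cases (responsive vs not; neither).
* `planted_motif_sequences()` samples Bernoulli/Markov background
  sequences and plants a motif (dyad spacers filled from the
  background) at a uniform position and strand in a `rate` fraction.
* `synthetic_study_annotation()` and `synthetic_study_de()` are
  study-scale stand-ins: the original per-peak and per-gene
  supplementary tables are not redistributable, so these generators
  plant the *published composition* — 858 peaks over 859 loci, 854
  single-peak loci, six dual-assigned peaks, five two-peak loci, 257
  TSS-spanning peaks, the printed location fractions, and the
  74 early / 358 late / 432 responsive split with 428 genes carrying
  time-course or meta evidence. Tests against them establish that the
  assignment, binning and integration machinery reproduces a known
  composition end-to-end from files; they cannot establish anything
  about the original raw data, which is exactly why they are labelled
  synthetic.

What the generators do not emulate: read-level noise, peak-calling
uncertainty, irregular gene sizes and overlapping gene models,
linkage between motif occurrence and binding strength, and real
microarray correlation structure. Passing tests demonstrate correct
statistics and bookkeeping on data satisfying each stage's
assumptions, not robustness to violations of them.

## Problem sizes and numerical notes

The suite and the acceptance script use desk-scale problem sizes
chosen to exercise each claim meaningfully: 4-node exhaustive
comparisons over 20 seeds, 8-node / n = 2000 / 50-run consensus
recovery over 5 seeds, complete 4^w enumerations up to w = 8, and
20-seed planted-dyad recovery at 200 sequences of 100 bp. Binomial
tails use `pbinom` upper tails and are cross-checked against log-space
summation at 1e-10 relative tolerance. Degenerate inputs are defined
behaviour: zero-sample data score 0 for every family, a flat count
matrix scores every word identically with p-value 1 (so no hits at
any threshold below 1), a word with zero occurrences gives a
positional chi-square of 0 with p = 1, and constant genes discretise
to a single state with a warning.
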
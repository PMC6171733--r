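---
title: "Predicting promoter evolution in a transcriptionally rewired phage"
author: "promoterEvo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting promoter evolution in a transcriptionally rewired phage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterEvo)
```

## The system and the question

Bacteriophage T7 drives most of its gene expression with its own single-subunit
RNA polymerase (RNAP), which recognises a highly conserved 23-nt promoter. The
polymerase's promoter specificity is governed largely by three bases at
promoter positions −11..−9: fifteen of the seventeen wild-type promoters carry
`GAC` there, two (including the genome-entry promoter phiOL) carry `AAC`. An
engineered polymerase whose optimal promoter carries `CGG` at those positions
— three substitutions from the canonical triplet — can be supplied in trans to
a phage deleted of its own RNAP gene (here called the T7Δ1 background, which
also lost the phi1.1A promoter in the deletion). Serial passage of such a
phage selects for promoter mutations that restore transcription, and because
every promoter in the genome faces the same selective pressure, the outcome is
a replicated natural experiment in evolutionary prediction.

promoterEvo implements that analysis end to end:

1. **sequence space** — combinatorics of the 64-triplet genotype space:
   Hamming distances, direct intermediates, all `d!` shortest mutational paths.
2. **landscape** — measured transcription activities attached to genotypes;
   the single-step prediction matrix; a greedy trajectory DAG; accessible
   (monotonically increasing) path counts; origin-fixation (SSWM) step
   probabilities; classification of observed triplets as predicted or
   unanticipated.
3. **passage simulation** — a forward stochastic serial-passage model of a
   multi-promoter genome with selection, mutation, promoter duplication,
   bottleneck transfer and sequencing sampling.
4. **observed data** — promoter annotations (as `GRanges`), variant tables
   from population sequencing, and the predicted-versus-actual comparison.
5. **phenotype** — lysis time from OD600 curves and plate-growth doublings
   per hour.
6. **synthetic data** — seeded generators for every input, so the entire
   pipeline is testable without any external data.

## The prediction model

A *direct path* between the ancestral triplet `GAC` and the target `CGG`
changes one of the three differing sites per step; the six genotypes reachable
this way (three single mutants, three double mutants) are the *direct
intermediates*. The prediction matrix layers them by distance from the
ancestor:

```{r}
ls <- landscapeFromMeans(defaultActivityTruth())
buildPredictionMatrix(ls, "GAC", "CGG")
```

The greedy DAG formalises arrow placement between layers: from every retained
node, edges go to each adjacent next-layer genotype whose activity is at
least `(1 - tieTol)` times the best adjacent candidate. `tieTol` defaults to
0.15: the qualitative structure being encoded keeps two near-tied strong
double mutants (`CAG` and `GGG`) while dropping the clearly weaker `CGC`, but
no numeric criterion for "substantially higher" exists in the underlying
assay descriptions, so the tolerance is an explicit, recorded parameter
rather than a hidden constant. Setting `tieTol = 0` retains only exact ties.

Two further prediction-layer tools:

* `accessibleDirectPaths()` counts the direct paths along which activity
  increases *strictly* at every step — the classic accessibility criterion
  for monotonic path counting on empirical fitness landscapes (for five
  differing sites there are 120 orderings; here, 6).
* `sswmStepProbabilities()` converts relative activity gains into
  origin-fixation step weights, `s_h = max(0, a(h)/a(g) - 1)`, normalised
  over the candidate set. When no candidate is beneficial the distribution
  falls back to uniform and is flagged, rather than silently pretending a
  preference exists.

Missing measurements are never imputed: any operation that needs an
unmeasured genotype fails with a condition listing the gaps. That behaviour
is itself part of the scientific story — the observed off-path triplets
(`GCC`, `CCC`, `AAG`) were exactly the ones outside the initially assayed
set.

## The serial-passage simulator

The simulator tracks a population of phage genotypes — per-promoter triplet
plus copy number — in frequency space. Each passage comprises
`generationsPerPassage` rounds of fitness-weighted multinomial resampling
with mutation and duplication, then a multinomial bottleneck; records are
emitted at the sampled passages (default 50 and 100 of 100).

**Fitness.** Each locus contributes `weight_l * x_l / (K + x_l)` with
`x_l = expressionLevel * sum over copies of a(triplet)`, activities on the
percent scale. The saturating form captures diminishing returns of
transcription on growth; `K = 50` (percent units) puts the half-saturation
point mid-scale so that both low-activity rescue and high-activity
fine-tuning are selectively visible. Locus weights are exposed but default to
1: no measured per-promoter importance exists, and exploring heterogeneous
weights is exactly what the parameter is for.

**Scale.** The experiment transfers roughly 1e7–1e8 phage per passage; the
simulator represents that census with multinomial sampling at an effective
size of 1e5 (configurable). This preserves the qualitative drift/selection
balance at desk scale without per-virion bookkeeping; absolute fixation
probabilities of very rare mutants are therefore compressed relative to the
true census, which matters only for analyses that lean on the exact mutation
supply rate.

**Free parameters.** Burst size, generations per passage and mutation rate
are not reported for this system. Defaults: 5 generations per passage (a
lysis cycle amplifies ~1e2–1e3-fold), substitution rate 1e-5 per base per
replication, duplication rate 1e-6 per locus per replication — all
configurable, all echoed into every run manifest. The polymerase expression
switch (induced first half, uninduced second half) is modelled as a scalar
multiplier on all activities, default `c(1.0, 0.2)` switching after passage
50; the two values are fixtures, not measurements.

**Mutation model.** Substitutions are uniform over the three alternative
bases at each of the three motif positions; no transition/transversion bias
is imposed because none is documented for this assay. Duplication raises a
locus from one to two tandem copies (capped, default 2); copies thereafter
mutate independently and are collapsed into the per-locus allele set when
frequencies are reported.

**Determinism.** All randomness flows from the master seed in the
configuration; per-line streams are derived deterministically, so runs are
reproducible byte for byte.

## Observed data and the comparison

Promoter annotations load into a `GRanges` under a fixed window convention:
the annotated promoter spans 23 nt with transcription start at +1, so the
variable motif occupies offsets 6–8 from the annotated start (closed
interval, 1-based). Only two promoter coordinates are reported for this
genome (phi1.5 at 7761, phi2.5 at 9090); the bundled fixtures mark every
other coordinate as a placeholder in a `coord_source` column, and nothing in
the analysis depends on the placeholder values.

`summarizeObservations()` counts promoters with at least one non-ancestral
triplet and calls per-line fixation; `compareToPrediction()` labels every
observed triplet (`ancestral`, `predicted_single`, `predicted_double`,
`target`, `unanticipated`) against its own locus background. The
`AAC`-background promoter phiOL is classified against `AAC`, not `GAC`, and
every phiOL observation carries a "no measured landscape" caveat — there are
no activity measurements in that background, so the machinery exposes the
classification but refuses to dress it up as a prediction.

**Fixation threshold.** "Fixed" means the top allele reaches 0.95 of the
population at the final sampled passage (configurable, recorded in output).
The underlying reports use "fixed" qualitatively and describe a 25.6% allele
as not fixed; any threshold in (0.256, 1] reproduces those calls, and 0.95
leaves room for sequencing-sampling noise around true fixation.

**Observation fixture.** `makeObservedFixture()` encodes only the
text-reported outcomes: printed frequencies are used verbatim (46.6/25.6 for
phi2.5:GAG; 39/3.2 for phiOL:AGC), fixation is encoded as 100%, and entries
reported only as present get a sentinel 20% with an `unquantified` flag so
that no count-based result depends on an invented number.

## Synthetic generators: what they emulate, and what they do not

`makeActivityTable()` draws triplicate measurements as
`truth * (1 + N(0, cv))`, floored at zero, with `cv = 0.05` — the underlying
assays report triplicate standard errors but not a dispersion model, so the
noise level is a fixture choice. The default truth table encodes only the
qualitative activity ordering of the system (GAG the strongest single
mutant; CAG and GGG near-tied strong double mutants well above CGC; CGG
maximal; GAC minimal; the off-path GCC/CCC/AAG at least as strong as the
single mutants); the numeric values are arbitrary within those constraints
and the generator rejects any truth table violating them, naming the broken
constraint. Consequently, passing tests demonstrate that the pipeline
recovers structure *implied by the ordering*, not that it reproduces the
actual (figure-only) percentages.

OD600 curves are logistic growth times logistic collapse with the collapse
midpoint as ground truth; real lysis curves have multi-burst shoulders and
baseline drift that this deliberately omits. Sequencing sampling is
multinomial at fixed depth (default 360000 reads), which models counting
noise but not alignment error or strand bias.

## Numerical choices and degenerate inputs

* Genotypes are uppercase `A/C/G/T` only; IUPAC codes are rejected, because
  the analysis is defined on concrete motifs.
* Path and intermediate enumeration returns deterministic lexicographic
  order; equal-activity ties in the greedy DAG are both retained (never
  broken by order of appearance).
* `src == dst` yields a single-node matrix and one zero-step path; adjacent
  genotypes have no intermediates. Both are valid inputs, not errors.
* Frequencies are conserved to 1e-9 at every simulator step; a population
  whose total fitness is zero is a hard error rather than a silent
  renormalisation.
* Fixation calls use the final sampled passage only; earlier passages inform
  the fixation-passage estimate but never the call itself, so summaries are
  invariant to row order of the input.

## Problem sizes

The test suite and the bundled reproduction script run entirely on generated
data: combinatorial checks cover the full 4^L spaces for L ≤ 3 (and
length-5 endpoints for the 120-path count), the accessible-path oracle
comparison uses 1000 random landscapes on the 8-node subspace, and the
simulator checks use single- to four-locus genomes at effective sizes of
300–20000 with 200 seeded replicates for the sweep property. These sizes
were chosen to make the stochastic assertions sharp (3-sigma margins) while
keeping a full run in the tens of seconds on one core; the simulator scales
linearly in passages, lines and segregating classes.

## Known limitations

* No recombination between phage genomes, although the passaging protocol
  deliberately allowed co-infection; observed duplication dynamics may
  partly reflect recombination this model cannot produce.
* Non-promoter mutations (e.g. capsid substitutions observed alongside the
  promoter changes) are outside the model; variants are only assigned
  promoter/non-promoter status.
* Fitness is a static function of promoter activity; infection-cycle timing,
  transcript length limits and host physiology are not modelled.
* Why most promoters never evolved is not explained by this machinery — the
  per-locus weights let a user explore hypotheses, but no measured weights
  exist to plug in.
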
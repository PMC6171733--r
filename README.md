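# promoterEvo

Predicting and analysing promoter evolution in a transcriptionally rewired
bacteriophage.

## The problem

Bacteriophage T7 expresses most of its genome through its own RNA polymerase
(RNAP), whose promoter specificity hinges on three bases at promoter
positions −11..−9 (`GAC` in 15 of 17 wild-type promoters). When a phage
deleted of its RNAP gene is forced to grow on an engineered polymerase whose
optimal promoter reads `CGG` at those positions — a three-step Hamming
distance — every promoter in the genome comes under selection to mutate
toward the new specificity. Given in vitro transcription activities for the
genotypes between `GAC` and `CGG`, can the mutational trajectory be
predicted before running the evolution experiment?

promoterEvo is for molecular-evolution and synthetic-biology researchers who
want to build, simulate and score such predictions. It provides:

* **Genotype-space combinatorics** — the 64-triplet space, Hamming metrics,
  the 6 direct intermediates between `GAC` and `CGG`, all `d!` direct
  mutational paths (120 for five differing sites).
* **Prediction objects** — activity landscapes normalised as
  percent-of-reference (mean ± SEM of replicates), the layered single-step
  prediction matrix, a greedy trajectory DAG with an explicit near-tie
  tolerance, accessible-path counts (strict monotonic increase along a
  direct path), and origin–fixation (SSWM) step probabilities
  `s_h = max(0, a(h)/a(g) − 1)` normalised over candidates.
* **A serial-passage simulator** — multi-promoter phage genomes under a
  saturating activity-to-fitness map `w = Σ_l w_l · x_l/(K + x_l)`, with
  per-base mutation, per-locus duplication, bottleneck transfer, an
  induction-phase expression switch, and multinomial sequencing sampling.
* **Observed-data scoring** — promoter annotations as `GRanges`, variant
  tables from population sequencing, fixation calls, and classification of
  every observed triplet as ancestral / predicted (single or double step) /
  target / unanticipated.
* **Seeded synthetic generators** for every input, so the full pipeline runs
  and is tested without any external data.

## Worked example

Build the prediction from a (synthetic, ordering-constrained) activity
table, then score the bundled observation fixture against it:

```r
library(promoterEvo)

tab <- makeActivityTable(cv = 0.05, seed = 1)      # triplicates with 5% CV
landscape <- normalizeActivity(tab, reference = "CGG")
pm <- buildPredictionMatrix(landscape, "GAC", "CGG")
pm
#> PredictionMatrix: GAC -> CGG (distance 3, 8 nodes, 5 greedy edges, tieTol 0.15)
#>   layer 0: GAC (5%)
#>   layer 1: CAC (21%), GAG (58%), GGC (19%)
#>   layer 2: CAG (83%), CGC (15%), GGG (83%)
#>   layer 3: CGG (100%)
#>   edges: CAG -> CGG; GAC -> GAG; GAG -> CAG; GAG -> GGG; GGG -> CGG
```

The matrix layers the six intermediates by distance from the ancestor; the
greedy DAG says the most likely first step is `GAC → GAG` (the strongest
single mutant), then either near-tied strong double mutant (`CAG`, `GGG`),
then the target.

```r
loci <- makeAnnotationFixture("T7_delta1")   # 16 promoters, GRanges
obs  <- makeObservedFixture()                # passages 50 and 100, 4 lines
report <- compareToPrediction(obs, landscape, loci)
report
#> ComparisonReport: 40 observation(s)
#>   evolved promoters: 5 of 16 (phi1.5, phi2.5, phi6.5, phiOL, phiOR)
#>   predicted triplets: GAG, GGG
#>   unanticipated triplets: AAG, CCC, GCC
#>   duplicated promoters: phi6.5, phiOL
```

Five of the sixteen promoters carry substitutions; `GAG` and `GGG` fall on
the predicted direct paths, while `AAG`, `CCC` and `GCC` lie off every
direct path — the unanticipated changes. The phiOL promoter (ancestral
triplet `AAC`, no measured landscape in that background) is classified
against its own background and flagged accordingly.

Simulate the 100-passage experiment itself:

```r
cfg <- passageConfig(seed = 1)               # 100 passages, sample at 50/100
files <- simulateAndExport(cfg, loci, landscape, "run1",
                           defaultActivity = 10)
summarizeTrajectory(read.delim(files[["trajectory"]]))
```

A thin command-line dispatcher with `synth`, `predict`, `simulate`,
`compare` and `phenotype` subcommands lives at
`inst/scripts/promoterEvo.R`.

## Package layout

* `R/sequence-space.R` — genotype space combinatorics and motif I/O
* `R/landscape.R`, `R/prediction.R` — activity landscapes and prediction
  objects
* `R/passage-sim.R` — the serial-passage simulator
* `R/observed-data.R` — annotations, variant tables, comparison reports
* `R/phenotype.R` — lysis time, doublings/hour, endpoint activity
* `R/synthetic-data.R` — seeded generators for every input
* `R/pipeline.R` — stage orchestration (`runPredict`, `runCompare`,
  `runSimulate`)
* `vignettes/predicting-promoter-evolution.Rmd` — the methods vignette

See the vignette for the model assumptions, parameter defaults and the
design decisions behind them.
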
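#' PromoterLandscape: measured activities over a motif genotype space
#'
#' A partial mapping from promoter-motif genotypes to transcription activity,
#' expressed as a percentage of a reference polymerase/promoter combination
#' (mean of replicate endpoint measurements, with standard error of the mean
#' propagated on the same scale). The mapping may cover only a measured
#' subset of the full genotype space.
#'
#' @slot activities data.frame with columns \code{genotype}, \code{mean_pct},
#'   \code{sem_pct}, \code{n_replicates}.
#' @slot reference Genotype string of the normalisation reference.
#' @slot referenceLabel Free-text label of the reference measurement
#'   (e.g. the polymerase assayed on its cognate promoter).
#' @exportClass PromoterLandscape
setClass("PromoterLandscape",
  representation(activities = "data.frame",
                 reference = "character",
                 referenceLabel = "character"))

setValidity("PromoterLandscape", function(object) {
  a <- object@activities
  need <- c("genotype", "mean_pct", "sem_pct", "n_replicates")
  if (!all(need %in% names(a)))
    return(paste("activities must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(a$genotype))
    return("duplicate genotypes in activities")
  if (any(a$mean_pct < 0))
    return("mean_pct must be non-negative")
  if (nrow(a) && length(unique(nchar(a$genotype))) != 1L)
    return("all genotypes must share one motif length")
  TRUE
})

#' PredictionMatrix: layered single-step prediction graph
#'
#' The ancestral genotype, its direct intermediates grouped by mutational
#' distance, and the target genotype, annotated with measured activities,
#' plus the greedy trajectory DAG (hypothesised most likely steps).
#'
#' @slot src,dst Ancestral and target genotype strings.
#' @slot layers List of character vectors: layer k holds genotypes at
#'   Hamming distance k from \code{src} on direct paths.
#' @slot edges data.frame (\code{from}, \code{to}) of greedy DAG edges
#'   between adjacent layers.
#' @slot activities Named numeric vector of mean percent activities for every
#'   node.
#' @slot tieTol Relative tolerance used to retain near-tied next steps.
#' @exportClass PredictionMatrix
setClass("PredictionMatrix",
  representation(src = "character", dst = "character", layers = "list",
                 edges = "data.frame", activities = "numeric",
                 tieTol = "numeric"))

setValidity("PredictionMatrix", function(object) {
  nodes <- unlist(object@layers, use.names = FALSE)
  if (!all(c(object@src, object@dst) %in% nodes))
    return("layers must contain src and dst")
  if (nrow(object@edges)) {
    layerOf <- rep(seq_along(object@layers) - 1L,
                   lengths(object@layers))
    names(layerOf) <- nodes
    dl <- layerOf[object@edges$to] - layerOf[object@edges$from]
    if (any(dl != 1L))
      return("edges must connect adjacent layers (k to k+1)")
  }
  if (!all(nodes %in% names(object@activities)))
    return("every node needs an activity")
  TRUE
})

#' PassageConfig: serial-passage simulator parameters
#'
#' All knobs of the forward serial-passage simulation: passage count,
#' bottleneck, multiplicity of infection, per-base substitution and per-locus
#' duplication rates, the polymerase expression level in each induction phase,
#' and the master seed. The census population (1e7-1e8 phage per transfer) is
#' represented in genotype-frequency space with an effective multinomial
#' sample size.
#'
#' @slot nPassages Number of serial transfers (default 100).
#' @slot bottleneckSize Phage transferred per passage (default 1e7).
#' @slot moi Multiplicity of infection at each transfer (default 0.01).
#' @slot generationsPerPassage Lysis cycles per passage (default 5).
#' @slot mutationRate Per-base substitution probability per replication.
#' @slot duplicationRate Per-locus duplication probability per replication.
#' @slot expressionLevel Numeric of length 1 or 2: polymerase expression
#'   multiplier; with two values the second applies after
#'   \code{switchPassage} (induced then uninduced phases).
#' @slot switchPassage Passage after which the second expression level
#'   applies (default 50).
#' @slot samplePassages Passages at which sequencing records are emitted
#'   (default 50 and 100).
#' @slot seed Master seed; all per-line random streams derive from it.
#' @slot effectiveSize Multinomial sample size standing in for the census
#'   (default 1e5).
#' @slot fitnessK Half-saturation constant of the activity-to-fitness map,
#'   on the percent-activity scale.
#' @slot maxCopyNumber Cap on per-locus tandem copies (default 2).
#' @exportClass PassageConfig
setClass("PassageConfig",
  representation(nPassages = "integer", bottleneckSize = "numeric",
                 moi = "numeric", generationsPerPassage = "integer",
                 mutationRate = "numeric", duplicationRate = "numeric",
                 expressionLevel = "numeric", switchPassage = "integer",
                 samplePassages = "integer", seed = "integer",
                 effectiveSize = "integer", fitnessK = "numeric",
                 maxCopyNumber = "integer"))

setValidity("PassageConfig", function(object) {
  if (object@nPassages < 1L) return("nPassages must be >= 1")
  rates <- c(object@mutationRate, object@duplicationRate)
  if (any(rates < 0 | rates > 1)) return("rates must lie in [0, 1]")
  if (object@effectiveSize < 1L) return("effectiveSize must be positive")
  if (object@bottleneckSize < 1) return("bottleneckSize must be positive")
  if (!length(object@expressionLevel) %in% 1:2 ||
      any(object@expressionLevel < 0))
    return("expressionLevel must be 1 or 2 non-negative values")
  if (any(object@samplePassages < 1L) ||
      any(object@samplePassages > object@nPassages))
    return("samplePassages must lie within 1..nPassages")
  TRUE
})

#' ComparisonReport: observed promoter changes scored against the prediction
#'
#' Per-observation labels from \code{\link{classifyTriplet}} together with the
#' aggregate counts of the predicted-versus-actual comparison.
#'
#' @slot observations data.frame of variant observations with a \code{label}
#'   column (and a \code{caveat} column for loci without a measured
#'   landscape).
#' @slot counts Named list of aggregate counts (evolved promoters, distinct
#'   observed triplets, predicted and unanticipated triplet sets, fixed loci
#'   per line).
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  representation(observations = "data.frame", counts = "list"))
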
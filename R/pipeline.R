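passageConfigAsList <- function(config) {
  list(n_passages = config@nPassages,
       bottleneck_size = config@bottleneckSize,
       moi = config@moi,
       generations_per_passage = config@generationsPerPassage,
       mutation_rate = config@mutationRate,
       duplication_rate = config@duplicationRate,
       expression_level = config@expressionLevel,
       switch_passage = config@switchPassage,
       sample_passages = config@samplePassages,
       seed = config@seed,
       effective_size = config@effectiveSize,
       fitness_k = config@fitnessK,
       max_copy_number = config@maxCopyNumber)
}

#' Read and write a simulator configuration as YAML
#'
#' Keys mirror the \linkS4class{PassageConfig} slots in snake_case; missing
#' keys fall back to the defaults of \code{\link{passageConfig}}.
#'
#' @param path YAML file path.
#' @param config A \linkS4class{PassageConfig}.
#' @return \code{readPassageConfig} returns a \linkS4class{PassageConfig};
#'   \code{writePassageConfig} returns \code{path} invisibly.
#' @name configIO
NULL

#' @rdname configIO
#' @export
readPassageConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- passageConfigAsList(passageConfig())
  take <- function(key) vals[[key]] %||% defaults[[key]]
  passageConfig(nPassages = take("n_passages"),
                bottleneckSize = take("bottleneck_size"),
                moi = take("moi"),
                generationsPerPassage = take("generations_per_passage"),
                mutationRate = take("mutation_rate"),
                duplicationRate = take("duplication_rate"),
                expressionLevel = unlist(take("expression_level")),
                switchPassage = take("switch_passage"),
                samplePassages = unlist(take("sample_passages")),
                seed = take("seed"),
                effectiveSize = take("effective_size"),
                fitnessK = take("fitness_k"),
                maxCopyNumber = take("max_copy_number"))
}

#' @rdname configIO
#' @export
writePassageConfig <- function(config, path) {
  yaml::write_yaml(passageConfigAsList(config), path)
  invisible(path)
}

#' Prediction stage: activity table to prediction-matrix files
#'
#' Reads a replicate activity table, normalises it against the target
#' genotype, builds the single-step prediction matrix and greedy DAG, counts
#' accessible direct paths, and writes the landscape table, edge list, DOT
#' graph, an accessible-path report and a run manifest into \code{outdir}.
#'
#' @param activityTable Path to an activity TSV, or an activity data.frame.
#' @param src,dst Ancestral and target genotypes.
#' @param outdir Output directory.
#' @param reference Normalisation reference genotype (default \code{dst},
#'   the engineered polymerase's cognate promoter).
#' @param tieTol Near-tie tolerance for the greedy DAG.
#' @param seed Seed echoed to the manifest (the stage itself is
#'   deterministic).
#' @return The \linkS4class{PredictionMatrix}, invisibly; files are written
#'   as a side effect.
#' @export
runPredict <- function(activityTable, src = "GAC", dst = "CGG",
                       outdir = ".", reference = dst, tieTol = 0.15,
                       seed = 1L) {
  records <- if (is.character(activityTable)) readActivityTable(activityTable)
             else activityTable
  landscape <- normalizeActivity(records, reference = reference,
                                 referenceLabel = paste0(
                                   records$rnap_id[1L], " on ", reference))
  pm <- buildPredictionMatrix(landscape, src, dst, tieTol = tieTol)
  acc <- accessibleDirectPaths(landscape, src, dst)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeLandscapeTable(landscape, file.path(outdir, "landscape.tsv"))
  writePredictionEdges(pm, file.path(outdir, "prediction_edges.tsv"))
  writePredictionDot(pm, file.path(outdir, "prediction.dot"))
  writeLines(c(
    sprintf("src\t%s", src), sprintf("dst\t%s", dst),
    sprintf("direct_paths\t%d", factorial(hammingDistance(src, dst))),
    sprintf("accessible_paths\t%d", acc$count),
    vapply(acc$paths, paste, "", collapse = " -> ")),
    file.path(outdir, "accessible_paths.tsv"))
  yaml::write_yaml(list(stage = "predict", src = src, dst = dst,
                        reference = reference, tie_tol = tieTol,
                        seed = seed),
                   file.path(outdir, "run_config.yaml"))
  invisible(pm)
}

#' Comparison stage: observations scored against the prediction
#'
#' Loads the promoter annotation, observed variant table and activity table,
#' scores every observation with \code{\link{compareToPrediction}}, and
#' writes the labelled table, text summary and run manifest.
#'
#' @param annotation Annotation TSV path or \code{GRanges}.
#' @param observations Variant TSV path or data.frame.
#' @param activityTable Activity TSV path or data.frame.
#' @param outdir Output directory.
#' @param src,dst Canonical ancestral and target genotypes.
#' @param reference Normalisation reference for the activity table.
#' @param fixationThreshold Fixation call threshold.
#' @return The \linkS4class{ComparisonReport}, invisibly.
#' @export
runCompare <- function(annotation, observations, activityTable,
                       outdir = ".", src = "GAC", dst = "CGG",
                       reference = dst, fixationThreshold = 0.95) {
  loci <- if (is.character(annotation)) loadPromoterAnnotation(annotation)
          else annotation
  obs <- if (is.character(observations)) loadVariantTable(observations, loci)
         else observations
  records <- if (is.character(activityTable)) readActivityTable(activityTable)
             else activityTable
  landscape <- normalizeActivity(records, reference = reference)
  report <- compareToPrediction(obs, landscape, loci, src = src, dst = dst,
                                fixationThreshold = fixationThreshold)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeComparisonReport(report, file.path(outdir, "comparison.tsv"))
  yaml::write_yaml(list(stage = "compare", src = src, dst = dst,
                        reference = reference,
                        fixation_threshold = fixationThreshold),
                   file.path(outdir, "run_config.yaml"))
  invisible(report)
}

#' Simulation stage: serial-passage run to trajectory and observation files
#'
#' Thin orchestration over \code{\link{simulateAndExport}} that accepts file
#' paths, echoes the configuration, and returns the written file set.
#'
#' @param config \linkS4class{PassageConfig} or YAML path.
#' @param annotation Annotation TSV path or \code{GRanges}.
#' @param activityTable Activity TSV path or data.frame.
#' @param outdir Output directory.
#' @param nLines Replicate lines.
#' @param depth Sequencing depth.
#' @param reference Normalisation reference for the activity table.
#' @param defaultActivity Activity for triplets outside the measured set
#'   (default 10, a weak-promoter baseline, so that mutational exploration
#'   off the assayed set is possible).
#' @return Named character vector of written files, invisibly.
#' @export
runSimulate <- function(config, annotation, activityTable, outdir = ".",
                        nLines = 4L, depth = 360000L, reference = "CGG",
                        defaultActivity = 10) {
  if (is.character(config)) config <- readPassageConfig(config)
  loci <- if (is.character(annotation)) loadPromoterAnnotation(annotation)
          else annotation
  records <- if (is.character(activityTable)) readActivityTable(activityTable)
             else activityTable
  landscape <- normalizeActivity(records, reference = reference)
  simulateAndExport(config, loci, landscape, outdir, nLines = nLines,
                    depth = depth, defaultActivity = defaultActivity)
}
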
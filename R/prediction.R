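intermediate_layers <- function(src, dst) {
  d <- hammingDistance(src, dst)
  inter <- directIntermediates(src, dst)
  layers <- vector("list", d + 1L)
  layers[[1L]] <- src
  if (d >= 1L) layers[[d + 1L]] <- dst
  if (d >= 2L) {
    for (k in seq_len(d - 1L)) {
      layers[[k + 1L]] <- sort(inter[vapply(inter, hammingDistance, 0L,
                                            b = src) == k])
    }
  }
  if (src == dst) layers <- list(src)
  layers
}

#' Build the single-step prediction matrix between two promoter genotypes
#'
#' Arranges the ancestral genotype, its direct intermediates grouped by
#' mutational distance, and the target genotype into layers, attaches measured
#' activities, and computes the greedy trajectory DAG (the hypothesised most
#' likely steps through mutational space). Requires every node to be measured;
#' unmeasured intermediates are reported by name, never imputed.
#'
#' @param landscape A \linkS4class{PromoterLandscape} covering \code{src},
#'   \code{dst} and all direct intermediates.
#' @param src,dst Ancestral and target genotype strings.
#' @param tieTol Relative tolerance for retaining near-tied next steps
#'   (default 0.15): a candidate is kept when its activity is at least
#'   \code{(1 - tieTol)} times the best next-layer candidate's.
#' @return A \linkS4class{PredictionMatrix}.
#' @examples
#' ls <- landscapeFromMeans(c(GAC = 5, GAG = 55, CAC = 20, GGC = 18,
#'                            CAG = 80, GGG = 78, CGC = 15, CGG = 100))
#' buildPredictionMatrix(ls, "GAC", "CGG")
#' @export
buildPredictionMatrix <- function(landscape, src, dst, tieTol = 0.15) {
  src <- asGenotype(src); dst <- asGenotype(dst)
  layers <- intermediate_layers(src, dst)
  nodes <- unique(unlist(layers, use.names = FALSE))
  act <- activityOf(landscape, nodes)  # errors listing any unmeasured node
  edges <- greedyPredictionDag(landscape, src, dst, tieTol = tieTol)
  new("PredictionMatrix", src = src, dst = dst, layers = layers,
      edges = edges, activities = act, tieTol = tieTol)
}

#' Greedy trajectory DAG over the direct intermediates
#'
#' From the ancestral genotype outward, each retained node sends edges to
#' every adjacent next-layer intermediate whose measured activity is within
#' the tie tolerance of the best adjacent candidate; the target genotype is
#' always terminal. This formalises arrow placement in a single-step
#' prediction matrix: the strictly best next step is kept, and near-ties
#' (two double mutants with comparable activity, say) keep both branches.
#'
#' @inheritParams buildPredictionMatrix
#' @return data.frame of directed edges with columns \code{from}, \code{to}.
#' @export
greedyPredictionDag <- function(landscape, src, dst, tieTol = 0.15) {
  src <- asGenotype(src); dst <- asGenotype(dst)
  if (tieTol < 0) stop_input("tieTol must be non-negative")
  layers <- intermediate_layers(src, dst)
  nodes <- unique(unlist(layers, use.names = FALSE))
  act <- activityOf(landscape, nodes)
  edges <- data.frame(from = character(0L), to = character(0L))
  if (length(layers) == 1L) return(edges)
  frontier <- src
  for (k in seq_len(length(layers) - 1L)) {
    nextLayer <- layers[[k + 1L]]
    newFrontier <- character(0L)
    for (node in frontier) {
      cand <- nextLayer[vapply(nextLayer, hammingDistance, 0L, b = node) == 1L]
      if (length(cand) == 0L) next
      best <- max(act[cand])
      keep <- cand[act[cand] >= (1 - tieTol) * best]
      edges <- rbind(edges, data.frame(from = node, to = keep))
      newFrontier <- union(newFrontier, keep)
    }
    frontier <- sort(newFrontier)
  }
  edges <- unique(edges)
  rownames(edges) <- NULL
  edges[order(edges$from, edges$to), , drop = FALSE]
}

#' Count and list accessible direct paths
#'
#' An accessible path is a direct (shortest) mutational path along which
#' measured activity increases strictly at every step — the selective
#' accessibility criterion used for monotonic path counting on empirical
#' fitness landscapes.
#'
#' @inheritParams buildPredictionMatrix
#' @return List with \code{count} (integer in \code{[0, d!]}) and
#'   \code{paths} (list of accessible paths, each a character vector).
#' @export
accessibleDirectPaths <- function(landscape, src, dst) {
  paths <- directPaths(src, dst)
  allNodes <- unique(unlist(paths, use.names = FALSE))
  act <- activityOf(landscape, allNodes)
  ok <- vapply(paths, function(p) all(diff(act[p]) > 0), NA)
  list(count = sum(ok), paths = paths[ok])
}

#' Origin-fixation (SSWM) step probabilities
#'
#' Under strong-selection weak-mutation dynamics each beneficial mutation
#' fixes or is lost before the next arises, and the relative fixation
#' probability of candidate steps scales with their selection coefficients.
#' Selection coefficients are taken proportional to relative activity gain,
#' \code{s_h = max(0, a(h)/a(g) - 1)}; probabilities are \code{s_h / sum(s)}.
#' When no candidate is beneficial the distribution falls back to uniform and
#' the result carries attribute \code{allNeutral = TRUE}.
#'
#' @param landscape A \linkS4class{PromoterLandscape}.
#' @param g Current genotype (measured, activity > 0).
#' @param candidates Candidate next genotypes (measured).
#' @return Named numeric probability vector over \code{candidates}.
#' @export
sswmStepProbabilities <- function(landscape, g, candidates) {
  g <- asGenotype(g)
  candidates <- asGenotype(candidates)
  ag <- activityOf(landscape, g)
  if (ag <= 0)
    stop_compute("current genotype ", g, " has non-positive activity")
  s <- pmax(0, activityOf(landscape, candidates) / ag - 1)
  if (sum(s) == 0) {
    p <- setNames(rep(1 / length(candidates), length(candidates)), candidates)
    attr(p, "allNeutral") <- TRUE
    return(p)
  }
  p <- s / sum(s)
  attr(p, "allNeutral") <- FALSE
  p
}

#' Classify an observed triplet against the prediction
#'
#' Labels a genotype by its position relative to the ancestral and target
#' motifs: \code{ancestral}, \code{target}, \code{predicted_single} (first
#' layer of direct intermediates), \code{predicted_double} (deeper
#' intermediate layers), or \code{unanticipated} (off every direct path).
#' For a triplet three steps from its target this partitions the 64-genotype
#' space as 1/1/3/3/56.
#'
#' @param observed Observed genotype string (vectorised).
#' @param src,dst Ancestral and target genotype strings.
#' @return Character vector of labels.
#' @examples
#' classifyTriplet(c("GAG", "GCC"), "GAC", "CGG")
#' @export
classifyTriplet <- function(observed, src, dst) {
  src <- asGenotype(src); dst <- asGenotype(dst)
  observed <- asGenotype(observed)
  if (any(nchar(c(observed, dst)) != nchar(src)))
    stop_input("genotype length mismatch")
  inter <- directIntermediates(src, dst)
  vapply(observed, function(g) {
    if (g == src) return("ancestral")
    if (g == dst) return("target")
    if (g %in% inter) {
      if (hammingDistance(src, g) == 1L) "predicted_single" else "predicted_double"
    } else "unanticipated"
  }, "", USE.NAMES = FALSE)
}

#' @export
setMethod("show", "PredictionMatrix", function(object) {
  d <- length(object@layers) - 1L
  cat("PredictionMatrix:", object@src, "->", object@dst,
      sprintf("(distance %d, %d nodes, %d greedy edges, tieTol %.2f)\n",
              d, length(object@activities), nrow(object@edges),
              object@tieTol))
  for (k in seq_along(object@layers)) {
    g <- object@layers[[k]]
    cat(sprintf("  layer %d: %s\n", k - 1L,
                paste(sprintf("%s (%.0f%%)", g, object@activities[g]),
                      collapse = ", ")))
  }
  if (nrow(object@edges))
    cat("  edges:", paste(object@edges$from, "->", object@edges$to,
                          collapse = "; "), "\n")
})

#' Export a prediction matrix
#'
#' \code{writePredictionEdges} writes the greedy DAG as an edge-list TSV with
#' node activities; \code{writePredictionDot} writes Graphviz DOT text.
#'
#' @param pm A \linkS4class{PredictionMatrix}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @name predictionIO
NULL

#' @rdname predictionIO
#' @export
writePredictionEdges <- function(pm, path) {
  e <- pm@edges
  e$from_pct <- unname(pm@activities[e$from])
  e$to_pct <- unname(pm@activities[e$to])
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname predictionIO
#' @export
writePredictionDot <- function(pm, path) {
  lines <- c("digraph prediction {", "  rankdir=BT;")
  for (g in names(pm@activities))
    lines <- c(lines, sprintf("  \"%s\" [label=\"%s\\n%.1f%%\"];", g, g,
                              pm@activities[g]))
  for (i in seq_len(nrow(pm@edges)))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", pm@edges$from[i],
                              pm@edges$to[i]))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
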
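#' Construct a serial-passage simulator configuration
#'
#' Defaults mirror the passaging regime being modelled: 100 transfers with
#' sequencing at passages 50 and 100, a 1e7-phage bottleneck at MOI 0.01, and
#' a polymerase expression drop after passage 50 (induced then uninduced
#' phases). Burst-scale growth within a passage is modelled as a fixed number
#' of fitness-weighted multinomial generations. The census is tracked in
#' genotype-frequency space at an effective multinomial size
#' (\code{effectiveSize}) rather than per virion.
#'
#' @param nPassages,bottleneckSize,moi,generationsPerPassage See slots of
#'   \linkS4class{PassageConfig}.
#' @param mutationRate Per-base substitution probability per replication.
#' @param duplicationRate Per-locus duplication probability per replication.
#' @param expressionLevel Length-1 or length-2 expression multiplier(s); the
#'   second value applies after \code{switchPassage}.
#' @param switchPassage Passage after which the second expression level
#'   applies.
#' @param samplePassages Passages at which records are emitted.
#' @param seed Master seed for all randomness.
#' @param effectiveSize Multinomial sample size representing the census.
#' @param fitnessK Half-saturation constant (percent-activity scale) of the
#'   activity-to-fitness map.
#' @param maxCopyNumber Per-locus tandem copy cap.
#' @return A validated \linkS4class{PassageConfig}.
#' @export
passageConfig <- function(nPassages = 100L, bottleneckSize = 1e7, moi = 0.01,
                          generationsPerPassage = 5L, mutationRate = 1e-5,
                          duplicationRate = 1e-6,
                          expressionLevel = c(1.0, 0.2), switchPassage = 50L,
                          samplePassages = c(50L, 100L), seed = 1L,
                          effectiveSize = 1e5L, fitnessK = 50,
                          maxCopyNumber = 2L) {
  new("PassageConfig", nPassages = as.integer(nPassages),
      bottleneckSize = bottleneckSize, moi = moi,
      generationsPerPassage = as.integer(generationsPerPassage),
      mutationRate = mutationRate, duplicationRate = duplicationRate,
      expressionLevel = expressionLevel,
      switchPassage = as.integer(switchPassage),
      samplePassages = as.integer(samplePassages), seed = as.integer(seed),
      effectiveSize = as.integer(effectiveSize), fitnessK = fitnessK,
      maxCopyNumber = as.integer(maxCopyNumber))
}

#' @export
setMethod("show", "PassageConfig", function(object) {
  cat("PassageConfig:", object@nPassages, "passages,",
      object@generationsPerPassage, "generations/passage\n")
  cat(sprintf("  bottleneck %g (effective %d), MOI %g\n",
              object@bottleneckSize, object@effectiveSize, object@moi))
  cat(sprintf("  mutation %g /base/replication, duplication %g /locus, copy cap %d\n",
              object@mutationRate, object@duplicationRate,
              object@maxCopyNumber))
  cat(sprintf("  expression %s (switch after passage %d), fitness K %g\n",
              paste(object@expressionLevel, collapse = " -> "),
              object@switchPassage, object@fitnessK))
  cat("  sampled passages:", paste(object@samplePassages, collapse = ", "),
      "| seed:", object@seed, "\n")
})

# Normalise a promoter annotation (GRanges or data.frame) to a data.frame
# with columns name, triplet, weight.
loci_info <- function(loci) {
  if (is(loci, "GRanges")) {
    m <- as.data.frame(S4Vectors::mcols(loci))
    df <- data.frame(name = m$name, triplet = m$triplet, weight = m$weight,
                     stringsAsFactors = FALSE)
  } else if (is.data.frame(loci)) {
    df <- loci[, c("name", "triplet", "weight")]
  } else stop_input("loci must be a GRanges or data.frame promoter annotation")
  if (anyDuplicated(df$name)) stop_input("duplicate locus names")
  if (any(df$weight < 0)) stop_input("locus weights must be non-negative")
  df$triplet <- asGenotype(df$triplet)
  df
}

locus_activity <- function(triplets, landscape, defaultActivity = NULL) {
  a <- landscape@activities
  idx <- match(triplets, a$genotype)
  if (anyNA(idx)) {
    if (is.null(defaultActivity))
      stop_gap(paste0("unmeasured triplet(s) with no default activity: ",
                      paste(sort(unique(triplets[is.na(idx)])), collapse = ", ")),
               missing = sort(unique(triplets[is.na(idx)])))
    out <- a$mean_pct[idx]
    out[is.na(idx)] <- defaultActivity
    return(out)
  }
  a$mean_pct[idx]
}

#' Relative fitness of a phage genotype over its promoter network
#'
#' Each promoter locus contributes its weight times a saturating function of
#' its total expression-scaled activity, summed over tandem copies:
#' \code{w = sum_l weight_l * x_l / (K + x_l)} with
#' \code{x_l = expressionLevel * sum_copies a(triplet)}. The saturating map
#' captures diminishing returns of transcription on growth; \code{w} is
#' strictly increasing in every locus activity with positive weight.
#'
#' @param states Named list: locus name -> character vector of per-copy
#'   triplets (length = copy number).
#' @param landscape A \linkS4class{PromoterLandscape} of percent activities.
#' @param loci Promoter annotation (GRanges or data.frame with \code{name},
#'   \code{triplet}, \code{weight}).
#' @param K Half-saturation constant on the percent-activity scale.
#' @param expressionLevel Scalar multiplier on all activities (polymerase
#'   supply).
#' @param defaultActivity Activity assigned to unmeasured triplets; when
#'   \code{NULL} (default) unmeasured triplets are an error.
#' @return Positive real relative fitness.
#' @export
phageFitness <- function(states, landscape, loci, K = 50,
                         expressionLevel = 1, defaultActivity = NULL) {
  info <- loci_info(loci)
  w <- 0
  for (i in seq_len(nrow(info))) {
    trips <- states[[info$name[i]]]
    if (is.null(trips))
      stop_input("phage genotype missing locus ", info$name[i])
    if (info$weight[i] == 0) next
    x <- expressionLevel *
      sum(locus_activity(trips, landscape, defaultActivity))
    w <- w + info$weight[i] * x / (K + x)
  }
  w
}

pop_key <- function(states) {
  paste(vapply(states, paste, "", collapse = ","), collapse = ";")
}

# One line's forward simulation; pop is a list(states=list of state lists,
# freq=numeric). Returns records data.frame at sampled passages.
simulate_one_line <- function(config, info, landscape, lineId,
                              defaultActivity, initialPop = NULL) {
  N <- config@effectiveSize
  nLoci <- nrow(info)
  ancestral <- lapply(seq_len(nLoci), function(i) info$triplet[i])
  names(ancestral) <- info$name
  if (is.null(initialPop)) {
    pop <- list(states = list(ancestral), freq = 1)
  } else pop <- initialPop

  fitCache <- new.env(parent = emptyenv())
  fitness_of <- function(states, exprLevel) {
    key <- paste0(pop_key(states), "@", exprLevel)
    if (!is.null(fitCache[[key]])) return(fitCache[[key]])
    w <- phageFitness(states, landscape, info, K = config@fitnessK,
                      expressionLevel = exprLevel,
                      defaultActivity = defaultActivity)
    fitCache[[key]] <- w
    w
  }

  records <- list()
  for (passage in seq_len(config@nPassages)) {
    exprLevel <- if (length(config@expressionLevel) == 2L &&
                     passage > config@switchPassage)
      config@expressionLevel[2L] else config@expressionLevel[1L]

    for (gen in seq_len(config@generationsPerPassage)) {
      w <- vapply(pop$states, fitness_of, 0, exprLevel = exprLevel)
      sel <- pop$freq * w
      if (sum(sel) <= 0)
        stop_compute("degenerate population: total fitness is zero")
      counts <- as.vector(rmultinom(1L, N, sel))

      # per-class substitution events over all motif bases of all copies
      if (config@mutationRate > 0) {
        for (ci in seq_along(counts)) {
          if (counts[ci] == 0L) next
          copies <- lengths(pop$states[[ci]])
          totBases <- 3L * sum(copies)
          pAny <- 1 - (1 - config@mutationRate)^totBases
          nMut <- rbinom(1L, counts[ci], pAny)
          if (nMut == 0L) next
          counts[ci] <- counts[ci] - nMut
          for (m in seq_len(nMut)) {
            st <- pop$states[[ci]]
            li <- sample.int(nLoci, 1L, prob = copies)
            cp <- sample.int(copies[li], 1L)
            pos <- sample.int(3L, 1L)
            cur <- split1(st[[li]][cp])
            cur[pos] <- sample(setdiff(DNA_ALPHABET, cur[pos]), 1L)
            st[[li]][cp] <- paste(cur, collapse = "")
            pop$states <- c(pop$states, list(st))
            counts <- c(counts, 1L)
          }
        }
      }
      # per-class duplication events (copy number 1 -> 2, capped)
      if (config@duplicationRate > 0) {
        for (ci in seq_along(counts)) {
          if (counts[ci] == 0L) next
          open <- which(lengths(pop$states[[ci]]) < config@maxCopyNumber)
          if (length(open) == 0L) next
          pAny <- 1 - (1 - config@duplicationRate)^length(open)
          nDup <- rbinom(1L, counts[ci], pAny)
          if (nDup == 0L) next
          counts[ci] <- counts[ci] - nDup
          for (m in seq_len(nDup)) {
            st <- pop$states[[ci]]
            li <- open[sample.int(length(open), 1L)]
            cp <- sample.int(length(st[[li]]), 1L)
            st[[li]] <- c(st[[li]], st[[li]][cp])
            pop$states <- c(pop$states, list(st))
            counts <- c(counts, 1L)
          }
        }
      }
      pop <- collapse_pop(pop$states, counts / sum(counts))
    }

    # bottleneck transfer: multinomial at the effective size
    counts <- as.vector(rmultinom(1L, N, pop$freq))
    pop <- collapse_pop(pop$states, counts / sum(counts))

    if (passage %in% config@samplePassages)
      records[[length(records) + 1L]] <-
        trajectory_record(pop, info, lineId, passage)
  }
  do.call(rbind, records)
}

collapse_pop <- function(states, freq) {
  keep <- freq > 0
  states <- states[keep]; freq <- freq[keep]
  keys <- vapply(states, pop_key, "")
  if (anyDuplicated(keys)) {
    agg <- rowsum(freq, keys)
    states <- states[match(rownames(agg), keys)]
    freq <- as.vector(agg)
  }
  list(states = states, freq = freq)
}

trajectory_record <- function(pop, info, lineId, passage) {
  out <- list()
  for (li in seq_len(nrow(info))) {
    locus <- info$name[li]
    alleleFreq <- list()
    dupFreq <- 0
    for (ci in seq_along(pop$freq)) {
      trips <- pop$states[[ci]][[locus]]
      ncp <- length(trips)
      if (ncp > 1L) dupFreq <- dupFreq + pop$freq[ci]
      for (tr in trips) {
        alleleFreq[[tr]] <- (alleleFreq[[tr]] %||% 0) +
          pop$freq[ci] / ncp
      }
    }
    out[[li]] <- data.frame(
      line_id = lineId, passage = passage, locus = locus,
      allele = names(alleleFreq),
      frequency = unname(unlist(alleleFreq)),
      dup_frequency = dupFreq, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate serial-passage evolution of replicate phage lines
#'
#' Forward stochastic simulation in genotype-frequency space. Each passage
#' runs \code{generationsPerPassage} rounds of fitness-weighted multinomial
#' resampling with per-base substitution and per-locus duplication, followed
#' by a multinomial bottleneck; allele-frequency records are emitted at the
#' sampled passages. All randomness derives from the master seed; each line
#' gets its own deterministic stream.
#'
#' @param config A \linkS4class{PassageConfig}.
#' @param loci Promoter annotation (GRanges or data.frame).
#' @param landscape A \linkS4class{PromoterLandscape}.
#' @param nLines Number of replicate lines (default 4).
#' @param defaultActivity Activity for unmeasured triplets (see
#'   \code{\link{phageFitness}}). Unmeasured triplets arise as soon as
#'   mutation explores beyond the assayed set, so simulations with nonzero
#'   mutation rates need a default.
#' @param initialPop Optional starting population, a list with elements
#'   \code{states} (list of per-class locus-state lists) and \code{freq}.
#' @return data.frame of trajectory records: \code{line_id}, \code{passage},
#'   \code{locus}, \code{allele}, \code{frequency}, \code{dup_frequency}.
#' @export
simulatePassages <- function(config, loci, landscape, nLines = 4L,
                             defaultActivity = NULL, initialPop = NULL) {
  info <- loci_info(loci)
  set.seed(config@seed)
  lineSeeds <- sample.int(.Machine$integer.max, nLines)
  out <- vector("list", nLines)
  for (ln in seq_len(nLines)) {
    set.seed(lineSeeds[ln])
    out[[ln]] <- simulate_one_line(config, info, landscape,
                                   lineId = paste0("line", ln),
                                   defaultActivity = defaultActivity,
                                   initialPop = initialPop)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resample trajectory records at finite sequencing depth
#'
#' Emulates population sequencing: per line, passage and locus, allele counts
#' are drawn multinomially at the given read depth and frequencies
#' recomputed; duplication frequencies are binomially resampled.
#'
#' @param records Trajectory data.frame from \code{\link{simulatePassages}}.
#' @param depth Reads per sample (default 360000).
#' @param seed Seed for the sampling stream.
#' @return Trajectory data.frame with sampled frequencies (zero-count alleles
#'   dropped).
#' @export
sequencingSample <- function(records, depth = 360000L, seed = 1L) {
  if (depth < 1) stop_input("depth must be >= 1")
  set.seed(seed)
  groups <- split(records,
                  interaction(records$line_id, records$passage,
                              records$locus, drop = TRUE))
  out <- lapply(groups, function(g) {
    p <- g$frequency
    counts <- as.vector(rmultinom(1L, depth, p))
    g$frequency <- counts / depth
    g$dup_frequency <- rbinom(1L, depth, min(1, g$dup_frequency[1L])) / depth
    g[g$frequency > 0, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$line_id, res$passage, res$locus, res$allele), , drop = FALSE]
}

#' Summarise allele trajectories into fixation calls
#'
#' Per line and locus, the allele with maximal frequency at the final sampled
#' passage is called \code{fixed} when it reaches the fixation threshold;
#' otherwise the locus is reported \code{heterogeneous} with its allele set
#' above the reporting floor. The fixation passage is the earliest sampled
#' passage at which the finally-fixed allele already met the threshold.
#'
#' @param records Trajectory data.frame (as from
#'   \code{\link{simulatePassages}} or loaded observations converted with
#'   frequencies in \code{[0, 1]}).
#' @param fixationThreshold Frequency required to call fixation
#'   (default 0.95).
#' @param reportingFloor Minimum frequency for an allele to be reported in a
#'   heterogeneous set (default 0.02).
#' @return data.frame with columns \code{line_id}, \code{locus},
#'   \code{status}, \code{alleles} (comma-separated, by descending final
#'   frequency), \code{top_allele}, \code{top_frequency},
#'   \code{fixation_passage} (NA unless fixed).
#' @export
summarizeTrajectory <- function(records, fixationThreshold = 0.95,
                                reportingFloor = 0.02) {
  if (nrow(records) == 0L)
    return(data.frame(line_id = character(0L), locus = character(0L),
                      status = character(0L), alleles = character(0L),
                      top_allele = character(0L), top_frequency = numeric(0L),
                      fixation_passage = integer(0L)))
  records <- records[order(records$passage), , drop = FALSE]
  groups <- split(records, interaction(records$line_id, records$locus,
                                       drop = TRUE))
  out <- lapply(groups, function(g) {
    finalP <- max(g$passage)
    fin <- g[g$passage == finalP, , drop = FALSE]
    fin <- fin[order(-fin$frequency), , drop = FALSE]
    top <- fin[1L, ]
    fixed <- top$frequency >= fixationThreshold
    fixPassage <- NA_integer_
    if (fixed) {
      hit <- g[g$allele == top$allele &
                 g$frequency >= fixationThreshold, "passage"]
      fixPassage <- min(hit)
    }
    reported <- fin$allele[fin$frequency >= reportingFloor]
    data.frame(line_id = top$line_id, locus = top$locus,
               status = if (fixed) "fixed" else "heterogeneous",
               alleles = paste(reported, collapse = ","),
               top_allele = top$allele, top_frequency = top$frequency,
               fixation_passage = fixPassage, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$line_id, res$locus), , drop = FALSE]
}
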
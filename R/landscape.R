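#' Normalise replicate activity measurements into a landscape
#'
#' Converts raw replicate endpoint measurements (e.g. fluorescence after 1 h
#' of in vitro transcription) into percent-of-reference activities:
#' \code{mean_pct = 100 * mean(replicates) / mean(reference replicates)} and
#' \code{sem_pct = 100 * sem(replicates) / mean(reference replicates)}.
#'
#' @param records data.frame in long format with columns \code{genotype},
#'   \code{rnap_id}, \code{replicate}, \code{value} (one row per replicate
#'   measurement, values non-negative).
#' @param reference Genotype string naming the reference rows in
#'   \code{records}, or a data.frame of reference rows in the same format.
#' @param referenceLabel Label recorded for the normalisation basis.
#' @return A \linkS4class{PromoterLandscape}.
#' @examples
#' tab <- data.frame(genotype = rep(c("GAC", "CGG"), each = 3),
#'                   rnap_id = "G78-KIRV", replicate = rep(1:3, 2),
#'                   value = c(0.5, 0.5, 0.5, 1, 1, 1))
#' normalizeActivity(tab, reference = "CGG")
#' @export
normalizeActivity <- function(records, reference,
                              referenceLabel = "reference") {
  need <- c("genotype", "rnap_id", "replicate", "value")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_input("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$value < 0))
    stop_input("replicate values must be non-negative")
  records$genotype <- asGenotype(records$genotype)

  if (is.character(reference)) {
    reference <- asGenotype(reference)
    refRows <- records[records$genotype == reference, , drop = FALSE]
    refGenotype <- reference
  } else {
    refRows <- reference
    refRows$genotype <- asGenotype(refRows$genotype)
    refGenotype <- unique(refRows$genotype)
    if (length(refGenotype) != 1L)
      stop_input("reference rows must carry a single genotype")
  }
  if (nrow(refRows) == 0L)
    stop_input("no replicate rows found for reference genotype")
  refMean <- mean(refRows$value)
  if (refMean <= 0)
    stop_compute("reference mean activity must be positive, got ", refMean)

  per <- split(records, records$genotype)
  activities <- data.frame(
    genotype = names(per),
    mean_pct = vapply(per, function(d) 100 * mean(d$value) / refMean, 0),
    sem_pct = vapply(per, function(d) {
      n <- nrow(d)
      if (n < 2L) return(0)
      100 * (sd(d$value) / sqrt(n)) / refMean
    }, 0),
    n_replicates = vapply(per, nrow, 0L),
    row.names = NULL)
  new("PromoterLandscape", activities = activities,
      reference = refGenotype, referenceLabel = referenceLabel)
}

#' Construct a landscape directly from mean activities
#'
#' Convenience constructor for landscapes whose genotype activities are
#' already on the percent scale (one value per genotype, no replicates).
#'
#' @param means Named numeric vector: genotype -> mean percent activity.
#' @param reference Reference genotype string (defaults to the maximal
#'   activity genotype).
#' @param sem Named numeric vector of standard errors (defaults to 0).
#' @param referenceLabel Label recorded for the normalisation basis.
#' @return A \linkS4class{PromoterLandscape}.
#' @export
landscapeFromMeans <- function(means, reference = names(means)[which.max(means)],
                               sem = NULL, referenceLabel = "reference") {
  if (is.null(names(means)))
    stop_input("means must be a named numeric vector")
  g <- asGenotype(names(means))
  semv <- if (is.null(sem)) rep(0, length(means)) else sem[names(means)]
  new("PromoterLandscape",
      activities = data.frame(genotype = g, mean_pct = unname(means),
                              sem_pct = unname(semv),
                              n_replicates = 1L, row.names = NULL),
      reference = asGenotype(reference), referenceLabel = referenceLabel)
}

#' @describeIn landscapeGenotypes Mean percent activity for given genotypes;
#'   fails loudly, listing every unmeasured genotype, rather than imputing.
#' @export
activityOf <- function(landscape, genotypes) {
  genotypes <- asGenotype(genotypes)
  a <- landscape@activities
  idx <- match(genotypes, a$genotype)
  if (anyNA(idx)) {
    missing <- genotypes[is.na(idx)]
    stop_gap(paste0("unmeasured genotype(s): ",
                    paste(sort(unique(missing)), collapse = ", ")),
             missing = sort(unique(missing)))
  }
  setNames(a$mean_pct[idx], genotypes)
}

#' Genotypes measured in a landscape
#'
#' @param landscape A \linkS4class{PromoterLandscape}.
#' @param genotypes Character vector of genotypes to look up
#'   (\code{activityOf}).
#' @return \code{landscapeGenotypes}: character vector of measured genotypes;
#'   \code{activityOf}: named numeric vector of mean percent activities.
#' @export
landscapeGenotypes <- function(landscape) landscape@activities$genotype

#' @export
setMethod("show", "PromoterLandscape", function(object) {
  a <- object@activities
  cat("PromoterLandscape:", nrow(a), "measured genotype(s)\n")
  cat("  reference:", object@reference,
      paste0("(", object@referenceLabel, ")"), "\n")
  if (nrow(a)) {
    ord <- order(-a$mean_pct)
    shown <- head(a[ord, ], 8L)
    cat(sprintf("  %s %6.1f%% +/- %.1f\n", shown$genotype, shown$mean_pct,
                shown$sem_pct), sep = "")
    if (nrow(a) > 8L) cat("  ...", nrow(a) - 8L, "more\n")
  }
})

#' Read and write activity tables and landscape exports
#'
#' Activity tables are TSV with columns \code{genotype}, \code{rnap_id},
#' \code{replicate}, \code{value}; landscape exports are TSV with columns
#' \code{genotype}, \code{mean_pct}, \code{sem_pct}.
#'
#' @param path File path.
#' @param records Activity data.frame to write.
#' @param landscape A \linkS4class{PromoterLandscape} to export.
#' @return Readers return a data.frame; writers return \code{path} invisibly.
#' @name activityIO
NULL

#' @rdname activityIO
#' @export
readActivityTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("genotype", "rnap_id", "replicate", "value")
  if (!all(need %in% names(tab)))
    stop_input("activity table must have columns: ",
               paste(need, collapse = ", "), " (file: ", path, ")")
  tab$genotype <- asGenotype(tab$genotype)
  tab
}

#' @rdname activityIO
#' @export
writeActivityTable <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname activityIO
#' @export
writeLandscapeTable <- function(landscape, path) {
  write.table(landscape@activities[, c("genotype", "mean_pct", "sem_pct")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
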
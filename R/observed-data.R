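# Promoter window convention: the annotated 23-nt promoter spans positions
# -17..+6 around the transcription start (+1), so the variable motif
# (-11..-9) occupies offsets 6..8 from the annotated start; closed interval,
# 1-based genome coordinates.
PROMOTER_LEN <- 23L
MOTIF_OFFSET <- 6L

#' Load a promoter annotation into a GRanges
#'
#' Reads a BED-like TSV (columns \code{name}, \code{start}, \code{strand},
#' \code{triplet}, \code{weight}; 1-based promoter start, \code{#} comments
#' ignored) and returns a \code{GRanges} spanning each 23-nt promoter, with
#' the variable-motif window, ancestral triplet and fitness weight in the
#' metadata columns.
#'
#' @param path TSV file path.
#' @param genome Seqname used for the ranges (default \code{"T7"}).
#' @return \code{GRanges} with mcols \code{name}, \code{triplet},
#'   \code{weight}, \code{motif_start}, \code{motif_end}. An empty file
#'   yields an empty \code{GRanges} with a warning.
#' @export
loadPromoterAnnotation <- function(path, genome = "T7") {
  tab <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop_input("malformed annotation file ", path, ": ",
                                   conditionMessage(e)))
  if (nrow(tab) == 0L) {
    warning("empty promoter annotation: ", path)
    return(GenomicRanges::GRanges())
  }
  need <- c("name", "start", "strand", "triplet", "weight")
  if (!all(need %in% names(tab)))
    stop_input("annotation must have columns: ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (is.na(row$start) || row$start < 1)
      stop_input("annotation line ", i + 1L, ": start must be >= 1")
    if (!row$strand %in% c("+", "-"))
      stop_input("annotation line ", i + 1L, ": strand must be + or -")
    ok <- tryCatch({asGenotype(row$triplet, length = 3L); TRUE},
                   error = function(e) FALSE)
    if (!ok)
      stop_input("annotation line ", i + 1L, ": invalid triplet '",
                 row$triplet, "'")
  }
  if (anyDuplicated(tab$name))
    stop_input("duplicate promoter names: ",
               paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  promoterGRanges(tab, genome)
}

promoterGRanges <- function(tab, genome = "T7") {
  gr <- GenomicRanges::GRanges(
    seqnames = genome,
    ranges = IRanges::IRanges(start = tab$start,
                              width = PROMOTER_LEN),
    strand = tab$strand)
  S4Vectors::mcols(gr)$name <- tab$name
  S4Vectors::mcols(gr)$triplet <- asGenotype(tab$triplet, length = 3L)
  S4Vectors::mcols(gr)$weight <- tab$weight
  S4Vectors::mcols(gr)$motif_start <- tab$start + MOTIF_OFFSET
  S4Vectors::mcols(gr)$motif_end <- tab$start + MOTIF_OFFSET + 2L
  names(gr) <- tab$name
  gr
}

#' Load a promoter annotation from GFF3
#'
#' GFF3 alternative to \code{\link{loadPromoterAnnotation}}: promoter
#' features with \code{Name}, \code{triplet} and \code{weight} attributes.
#' Requires \pkg{rtracklayer}.
#'
#' @inheritParams loadPromoterAnnotation
#' @return As \code{\link{loadPromoterAnnotation}}.
#' @export
loadPromoterAnnotationGFF3 <- function(path, genome = "T7") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_input("rtracklayer is required to read GFF3 annotations")
  gff <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gff)
  tab <- data.frame(name = as.character(m$Name),
                    start = GenomicRanges::start(gff),
                    strand = as.character(GenomicRanges::strand(gff)),
                    triplet = as.character(m$triplet),
                    weight = as.numeric(m$weight),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab$name)) stop_input("duplicate promoter names in GFF3")
  promoterGRanges(tab, genome)
}

#' Write a promoter annotation as BED-like TSV
#'
#' @param loci \code{GRanges} promoter annotation.
#' @param path Output file.
#' @param header Optional comment lines (without leading \code{#}) written
#'   before the column header.
#' @return \code{path}, invisibly.
#' @export
writePromoterAnnotation <- function(loci, path, header = character(0L)) {
  m <- S4Vectors::mcols(loci)
  tab <- data.frame(name = m$name, start = GenomicRanges::start(loci),
                    strand = as.character(GenomicRanges::strand(loci)),
                    triplet = m$triplet, weight = m$weight)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(tab), collapse = "\t"), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Assign a genomic position to a promoter motif window
#'
#' Returns the name of the promoter whose variable-motif window (promoter
#' positions -11..-9; closed interval) contains the 1-based position, or
#' \code{"non-promoter"}. Overlapping motif windows raise an ambiguity error.
#'
#' @param position 1-based nucleotide position (vectorised).
#' @param loci \code{GRanges} promoter annotation.
#' @return Character vector of locus names or \code{"non-promoter"}.
#' @export
assignVariantToPromoter <- function(position, loci) {
  if (any(position < 1)) stop_input("positions must be >= 1")
  m <- S4Vectors::mcols(loci)
  vapply(position, function(p) {
    hits <- which(p >= m$motif_start & p <= m$motif_end)
    if (length(hits) > 1L)
      stop_input("position ", p, " falls in overlapping motif windows: ",
                 paste(m$name[hits], collapse = ", "))
    if (length(hits) == 0L) "non-promoter" else m$name[hits]
  }, "")
}

#' Read and write observed variant tables
#'
#' Variant tables are TSV with columns \code{line_id}, \code{passage},
#' \code{promoter} (name, or a 1-based genome position to be resolved
#' against the annotation), \code{triplet}, \code{frequency_pct},
#' \code{is_duplication}; an optional \code{flag} column carries
#' \code{unquantified}-style markers. \code{#} comment lines are ignored.
#'
#' @param path File path.
#' @param observations Observation data.frame to write.
#' @param loci Optional \code{GRanges} annotation used to resolve numeric
#'   \code{promoter} values to locus names.
#' @param header Optional comment lines written before the data.
#' @return Readers return a validated data.frame; writers return \code{path}
#'   invisibly.
#' @name variantIO
NULL

#' @rdname variantIO
#' @export
loadVariantTable <- function(path, loci = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("line_id", "passage", "promoter", "triplet", "frequency_pct",
            "is_duplication")
  if (!all(need %in% names(tab)))
    stop_input("variant table must have columns: ",
               paste(need, collapse = ", "), " (file: ", path, ")")
  if (nrow(tab) == 0L) return(tab)
  tab$triplet <- asGenotype(tab$triplet, length = 3L)
  if (any(tab$frequency_pct < 0 | tab$frequency_pct > 100))
    stop_input("frequency_pct must lie in [0, 100]")
  tab$is_duplication <- as.logical(tab$is_duplication)
  numeric_pos <- grepl("^[0-9]+$", tab$promoter)
  if (any(numeric_pos)) {
    if (is.null(loci))
      stop_input("variant table uses genome positions; supply the annotation")
    tab$promoter[numeric_pos] <-
      assignVariantToPromoter(as.integer(tab$promoter[numeric_pos]), loci)
  }
  if (!"flag" %in% names(tab)) tab$flag <- ""
  tab
}

#' @rdname variantIO
#' @export
writeVariantTable <- function(observations, path, header = character(0L)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(observations), collapse = "\t"), con)
  write.table(observations, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

resolve_ancestral <- function(promoters, loci) {
  info <- loci_info(loci)
  idx <- match(promoters, info$name)
  if (anyNA(idx))
    stop_input("unknown promoter name(s): ",
               paste(sort(unique(promoters[is.na(idx)])), collapse = ", "))
  info$triplet[idx]
}

#' Summarise observed promoter evolution
#'
#' Counts, across all lines and passages, the promoters carrying at least one
#' substitution (a non-ancestral triplet), the distinct triplets observed per
#' promoter, and per-line fixation status at the final sampled passage.
#'
#' @param observations Observation data.frame (see
#'   \code{\link{loadVariantTable}}).
#' @param loci \code{GRanges} (or data.frame) promoter annotation.
#' @param fixationThreshold Fraction of the population required to call
#'   fixation (default 0.95).
#' @return Named list: \code{n_promoters} (annotated), \code{evolved_promoters}
#'   (character vector), \code{n_evolved}, \code{triplets_by_promoter}
#'   (list), \code{fixation} (data.frame from
#'   \code{\link{summarizeTrajectory}} over substituted loci),
#'   \code{duplicated_promoters}.
#' @export
summarizeObservations <- function(observations, loci,
                                  fixationThreshold = 0.95) {
  info <- loci_info(loci)
  if (nrow(observations) == 0L)
    return(list(n_promoters = nrow(info), evolved_promoters = character(0L),
                n_evolved = 0L, triplets_by_promoter = list(),
                fixation = summarizeTrajectory(data.frame(
                  line_id = character(0L), passage = integer(0L),
                  locus = character(0L), allele = character(0L),
                  frequency = numeric(0L))),
                duplicated_promoters = character(0L)))
  obs <- observations
  obs$ancestral <- resolve_ancestral(obs$promoter, info)
  subst <- obs[obs$triplet != obs$ancestral & !obs$is_duplication, ,
               drop = FALSE]
  evolved <- sort(unique(subst$promoter))
  triplets <- lapply(split(subst$triplet, subst$promoter),
                     function(x) sort(unique(x)))
  # fixation per line over substituted loci, on the 0..1 frequency scale
  traj <- data.frame(line_id = subst$line_id, passage = subst$passage,
                     locus = subst$promoter, allele = subst$triplet,
                     frequency = subst$frequency_pct / 100,
                     stringsAsFactors = FALSE)
  fixation <- summarizeTrajectory(traj, fixationThreshold = fixationThreshold)
  dup <- sort(unique(obs$promoter[obs$is_duplication]))
  list(n_promoters = nrow(info), evolved_promoters = evolved,
       n_evolved = length(evolved), triplets_by_promoter = triplets,
       fixation = fixation, duplicated_promoters = dup)
}

#' Score observed promoter changes against the prediction
#'
#' Labels every observed triplet via \code{\link{classifyTriplet}} against the
#' ancestral triplet of its own locus and the common target, and aggregates
#' the predicted-versus-unanticipated comparison. Loci whose ancestral
#' triplet differs from \code{src} (the noncanonical AAC-background promoter)
#' are classified against their own background and flagged: with no measured
#' activity landscape for that background there is no basis for a
#' prediction there.
#'
#' @param observations Observation data.frame.
#' @param landscape \linkS4class{PromoterLandscape} used to flag measured vs
#'   unmeasured observed triplets.
#' @param src Canonical ancestral triplet (default \code{"GAC"}).
#' @param dst Target triplet (default \code{"CGG"}).
#' @param loci \code{GRanges} (or data.frame) promoter annotation.
#' @param fixationThreshold Passed to \code{\link{summarizeObservations}}.
#' @return A \linkS4class{ComparisonReport}.
#' @export
compareToPrediction <- function(observations, landscape, loci,
                                src = "GAC", dst = "CGG",
                                fixationThreshold = 0.95) {
  src <- asGenotype(src); dst <- asGenotype(dst)
  info <- loci_info(loci)
  obs <- observations
  if (nrow(obs)) {
    obs$ancestral <- resolve_ancestral(obs$promoter, info)
    obs$label <- vapply(seq_len(nrow(obs)), function(i) {
      classifyTriplet(obs$triplet[i], obs$ancestral[i], dst)
    }, "")
    obs$caveat <- ifelse(obs$ancestral != src, "no measured landscape", "")
    obs$measured <- obs$triplet %in% landscapeGenotypes(landscape)
  } else {
    obs$ancestral <- character(0L); obs$label <- character(0L)
    obs$caveat <- character(0L); obs$measured <- logical(0L)
  }
  summary <- summarizeObservations(observations, info,
                                   fixationThreshold = fixationThreshold)
  canon <- obs[obs$ancestral == src & !obs$is_duplication, , drop = FALSE]
  canonTriplets <- unique(canon[, c("triplet", "label")])
  counts <- list(
    n_promoters = summary$n_promoters,
    n_evolved = summary$n_evolved,
    evolved_promoters = summary$evolved_promoters,
    n_distinct_triplets = length(unique(
      obs$triplet[!obs$is_duplication & obs$triplet != obs$ancestral])),
    predicted_triplets = sort(canonTriplets$triplet[
      canonTriplets$label %in% c("predicted_single", "predicted_double",
                                 "target")]),
    unanticipated_triplets = sort(canonTriplets$triplet[
      canonTriplets$label == "unanticipated"]),
    label_counts = table(obs$label[!obs$is_duplication]),
    fixation = summary$fixation,
    duplicated_promoters = summary$duplicated_promoters)
  new("ComparisonReport", observations = obs, counts = counts)
}

#' @describeIn compareToPrediction Aggregate counts of a report.
#' @param report A \linkS4class{ComparisonReport}.
#' @export
reportCounts <- function(report) report@counts

#' @describeIn compareToPrediction Per-observation labelled table.
#' @export
reportObservations <- function(report) report@observations

#' @export
setMethod("show", "ComparisonReport", function(object) {
  ct <- object@counts
  cat("ComparisonReport:", nrow(object@observations), "observation(s)\n")
  cat(sprintf("  evolved promoters: %d of %d (%s)\n", ct$n_evolved,
              ct$n_promoters, paste(ct$evolved_promoters, collapse = ", ")))
  cat("  predicted triplets:",
      paste(ct$predicted_triplets, collapse = ", "), "\n")
  cat("  unanticipated triplets:",
      paste(ct$unanticipated_triplets, collapse = ", "), "\n")
  if (length(ct$duplicated_promoters))
    cat("  duplicated promoters:",
        paste(ct$duplicated_promoters, collapse = ", "), "\n")
})

#' Write a comparison report
#'
#' Writes the labelled observation table as TSV and, alongside it, a
#' human-readable text summary (same path with extension \code{.txt}).
#'
#' @param report A \linkS4class{ComparisonReport}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeComparisonReport <- function(report, path) {
  write.table(report@observations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ct <- report@counts
  txt <- c(
    sprintf("Evolved promoters: %d of %d", ct$n_evolved, ct$n_promoters),
    sprintf("  %s", paste(ct$evolved_promoters, collapse = ", ")),
    sprintf("Distinct substituted triplets: %d", ct$n_distinct_triplets),
    sprintf("Predicted triplets (canonical background): %s",
            paste(ct$predicted_triplets, collapse = ", ")),
    sprintf("Unanticipated triplets (canonical background): %s",
            paste(ct$unanticipated_triplets, collapse = ", ")),
    sprintf("Duplicated promoters: %s",
            paste(ct$duplicated_promoters, collapse = ", ")))
  writeLines(txt, sub("\\.tsv$", ".txt", path))
  invisible(path)
}
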
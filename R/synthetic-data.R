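#' Default true activity table for the synthetic generator
#'
#' Percent activities for the ancestral (GAC) and target (CGG) triplets, the
#' six direct intermediates, and the three off-path triplets later observed
#' in evolved lines (GCC, CCC, AAG). The numeric values are arbitrary
#' synthetic choices; only the qualitative ordering they encode is
#' meaningful: GAG is the strongest single mutant, CAG and GGG are near-tied
#' strong double mutants well above CGC, CGG is maximal, GAC minimal, and the
#' off-path triplets are at least as active as the single-mutant
#' intermediates.
#'
#' @return Named numeric vector of percent activities.
#' @export
defaultActivityTruth <- function() {
  c(GAC = 5, CAC = 20, GGC = 18, GAG = 55,
    CGC = 15, CAG = 80, GGG = 78, CGG = 100,
    GCC = 60, CCC = 65, AAG = 58)
}

check_activity_ordering <- function(truth, src = "GAC", dst = "CGG") {
  need <- c(src, dst, directIntermediates(src, dst))
  missing <- setdiff(need, names(truth))
  if (length(missing))
    stop_input("activity truth must cover src, dst and all direct ",
               "intermediates; missing: ", paste(missing, collapse = ", "))
  fail <- character(0L)
  if (!(truth["GAG"] > truth["CAC"] && truth["GAG"] > truth["GGC"]))
    fail <- c(fail, "GAG must exceed the other single mutants (CAC, GGC)")
  singles <- truth[c("GAG", "CAC", "GGC")]
  for (g in c("CAG", "GGG")) {
    if (!(truth[g] > max(singles) && truth[g] > truth["CGC"]))
      fail <- c(fail, paste0(g, " must exceed all single mutants and CGC"))
  }
  if (truth[dst] < max(truth[need]))
    fail <- c(fail, paste0(dst, " must be maximal"))
  if (truth[src] > min(truth[need]))
    fail <- c(fail, paste0(src, " must be minimal among measured"))
  if (length(fail))
    stop_input("activity ordering constraint violated: ",
               paste(fail, collapse = "; "))
  invisible(TRUE)
}

#' Generate a replicate activity table with measurement noise
#'
#' Simulates triplicate endpoint transcription measurements: replicate values
#' are \code{truth * (1 + N(0, cv))}, floored at zero. The truth table must
#' satisfy the qualitative ordering constraints of the system (checked, with
#' the violated constraint named on failure). Deterministic given the seed.
#'
#' @param truth Named numeric vector of true percent activities
#'   (default \code{\link{defaultActivityTruth}}).
#' @param cv Replicate coefficient of variation (default 0.05).
#' @param nReplicates Replicates per genotype (default 3).
#' @param seed Seed.
#' @param rnapId Polymerase label recorded in the table.
#' @param src,dst Endpoints used for the ordering check.
#' @return Long-format data.frame with columns \code{genotype},
#'   \code{rnap_id}, \code{replicate}, \code{value}.
#' @export
makeActivityTable <- function(truth = defaultActivityTruth(), cv = 0.05,
                              nReplicates = 3L, seed = 1L,
                              rnapId = "G78-KIRV", src = "GAC", dst = "CGG") {
  if (cv < 0) stop_input("cv must be non-negative")
  if (nReplicates < 1L) stop_input("nReplicates must be >= 1")
  check_activity_ordering(truth, src, dst)
  set.seed(seed)
  g <- rep(names(truth), each = nReplicates)
  vals <- pmax(0, rep(unname(truth), each = nReplicates) *
                 (1 + rnorm(length(g), 0, cv)))
  data.frame(genotype = asGenotype(g), rnap_id = rnapId,
             replicate = rep(seq_len(nReplicates), length(truth)),
             value = vals, stringsAsFactors = FALSE)
}

# Promoter coordinates: phi1.5 (7761) and phi2.5 (9090) are reported genome
# positions; all others are plausible placeholders on the ~40-kb genome and
# are flagged as such in the annotation.
T7_PROMOTER_TABLE <- function() {
  data.frame(
    name = c("phiOL", "phi1.1A", "phi1.1B", "phi1.3", "phi1.5", "phi1.6",
             "phi2.5", "phi3.8", "phi4c", "phi4.3", "phi4.7", "phi6.5",
             "phi9", "phi10", "phi13", "phi17", "phiOR"),
    start = c(405L, 5848L, 5950L, 6409L, 7761L, 7990L, 9090L, 11180L,
              12671L, 12900L, 13341L, 18545L, 21004L, 22904L, 27274L,
              34566L, 39229L),
    strand = "+",
    triplet = c("AAC", "AAC", rep("GAC", 15L)),
    weight = 1,
    coord_source = c("placeholder", "placeholder", "placeholder",
                     "placeholder", "reported", "placeholder", "reported",
                     rep("placeholder", 10L)),
    stringsAsFactors = FALSE)
}

#' Promoter annotation fixtures for the wild-type and RNAP-deleted genomes
#'
#' The wild-type fixture has 17 promoters, 15 with the canonical GAC triplet
#' and 2 with the noncanonical AAC; the RNAP-deletion fixture drops
#' phi1.1A (removed together with the polymerase gene), leaving 16. Only the
#' phi1.5 (7761) and phi2.5 (9090) genome starts are reported coordinates;
#' all other positions are synthetic placeholders, flagged in the
#' \code{coord_source} metadata column.
#'
#' @param variant \code{"T7_delta1"} (default) or \code{"T7_wildtype"}.
#' @return \code{GRanges} promoter annotation (see
#'   \code{\link{loadPromoterAnnotation}}) with an extra \code{coord_source}
#'   column.
#' @export
makeAnnotationFixture <- function(variant = c("T7_delta1", "T7_wildtype")) {
  variant <- match.arg(variant)
  tab <- T7_PROMOTER_TABLE()
  if (variant == "T7_delta1")
    tab <- tab[tab$name != "phi1.1A", , drop = FALSE]
  gr <- promoterGRanges(tab)
  S4Vectors::mcols(gr)$coord_source <- tab$coord_source
  gr
}

#' Observation fixture encoding the reported passaging outcomes
#'
#' Variant-frequency table reproducing the text-reported promoter evolution
#' across four replicate lines at passages 50 and 100: phi1.5 fixed at GAG in
#' all four lines by passage 50; phi2.5 GAG in line 3 at 46.6% then 25.6%;
#' phiOL AGC in line 4 at 39% then 3.2% and ACC in lines 1-3; phiOR GCC in
#' all lines then a heterogeneous GCC/GGG/AAG/GAG/CCC mixture; phi6.5
#' heterogeneous at both passages; phiOL duplicated in all lines and phi6.5
#' in lines 2-4 by passage 100. Entries reported only as present (without a
#' printed frequency) are encoded at a sentinel 20% and flagged
#' \code{unquantified}; fixed entries are encoded at 100%.
#'
#' @return Observation data.frame (see \code{\link{loadVariantTable}} for
#'   columns).
#' @export
makeObservedFixture <- function() {
  row <- function(line, passage, promoter, triplet, freq, dup = FALSE,
                  flag = "unquantified") {
    data.frame(line_id = paste0("line", line), passage = as.integer(passage),
               promoter = promoter, triplet = triplet, frequency_pct = freq,
               is_duplication = dup, flag = flag, stringsAsFactors = FALSE)
  }
  obs <- rbind(
    # phi1.5 -> GAG, fixed in all four lines at both sampled passages
    do.call(rbind, lapply(1:4, function(l)
      rbind(row(l, 50, "phi1.5", "GAG", 100, flag = "fixed"),
            row(l, 100, "phi1.5", "GAG", 100, flag = "fixed")))),
    # phi2.5 -> GAG in line 3 only; printed frequencies
    row(3, 50, "phi2.5", "GAG", 46.6, flag = "printed"),
    row(3, 100, "phi2.5", "GAG", 25.6, flag = "printed"),
    # phiOL (AAC background): AGC in line 4 (printed), ACC in lines 1-3
    row(4, 50, "phiOL", "AGC", 39, flag = "printed"),
    row(4, 100, "phiOL", "AGC", 3.2, flag = "printed"),
    do.call(rbind, lapply(1:3, function(l)
      row(l, 100, "phiOL", "ACC", 20))),
    # phiOR: GCC in all lines at passage 50, heterogeneous mixture at 100
    do.call(rbind, lapply(1:4, function(l)
      row(l, 50, "phiOR", "GCC", 20))),
    row(1, 100, "phiOR", "GCC", 20),
    row(2, 100, "phiOR", "GGG", 20),
    row(3, 100, "phiOR", "AAG", 20),
    row(4, 100, "phiOR", "GAG", 20),
    row(1, 100, "phiOR", "CCC", 20),
    # phi6.5: heterogeneous at both passages (ancestral GAC still present
    # at passage 50)
    row(1, 50, "phi6.5", "GAC", 20),
    row(2, 50, "phi6.5", "GAG", 20),
    row(3, 50, "phi6.5", "CCC", 20),
    row(4, 50, "phi6.5", "GCC", 20),
    row(1, 100, "phi6.5", "GAG", 20),
    row(2, 100, "phi6.5", "CCC", 20),
    row(3, 100, "phi6.5", "GCC", 20),
    row(4, 100, "phi6.5", "GGG", 20),
    row(2, 100, "phi6.5", "AAG", 20),
    # duplications by passage 100: phiOL in all lines, phi6.5 in lines 2-4
    do.call(rbind, lapply(1:4, function(l)
      row(l, 100, "phiOL", "AAC", 20, dup = TRUE, flag = "duplication"))),
    do.call(rbind, lapply(2:4, function(l)
      row(l, 100, "phi6.5", "GAC", 20, dup = TRUE, flag = "duplication"))))
  rownames(obs) <- NULL
  obs
}

#' Synthetic OD600 lysis curve
#'
#' Logistic growth to a carrying OD followed (optionally) by a logistic
#' collapse centred at the lysis midpoint; sampled every minute over the
#' assay window. The generator's midpoint is ground truth for
#' \code{\link{lysisTime}} recovery tests.
#'
#' @param times Sampling times in minutes (default 0..120, 1-min sampling).
#' @param growthRate Logistic growth rate per minute.
#' @param growthMidpoint Time of half-maximal growth (minutes).
#' @param carryingOd Plateau OD600.
#' @param od0 Baseline OD600.
#' @param lysisMidpoint Centre of the lysis collapse (minutes).
#' @param dropSteepness Logistic steepness of the collapse per minute.
#' @param lyse When \code{FALSE} the curve grows monotonically (no lysis).
#' @return data.frame with columns \code{time}, \code{od600}, \code{label}.
#' @export
makeOdCurve <- function(times = 0:120, growthRate = 0.5, growthMidpoint = 15,
                        carryingOd = 1.0, od0 = 0.05, lysisMidpoint = 90,
                        dropSteepness = 1.0, lyse = TRUE) {
  if (lyse && (lysisMidpoint < min(times) || lysisMidpoint > max(times)))
    stop_input("lysisMidpoint outside the sampled time range")
  growth <- 1 / (1 + exp(-growthRate * (times - growthMidpoint)))
  decline <- if (lyse)
    1 / (1 + exp(dropSteepness * (times - lysisMidpoint))) else 1
  data.frame(time = times,
             od600 = od0 + (carryingOd - od0) * growth * decline,
             label = if (lyse) sprintf("lysis_mid_%g", lysisMidpoint)
                     else "no_lysis")
}

#' Run the simulator and export pipeline-consumable tables
#'
#' Runs \code{\link{simulatePassages}}, applies
#' \code{\link{sequencingSample}} at the given depth, and writes (i) the raw
#' trajectory TSV, (ii) a sequencing-sampled observation table in the variant
#' format consumed by \code{\link{loadVariantTable}} (substituted alleles
#' above the reporting floor plus duplication rows), and (iii) a YAML
#' manifest echoing the configuration and seed.
#'
#' @param config A \linkS4class{PassageConfig}.
#' @param loci \code{GRanges} (or data.frame) promoter annotation.
#' @param landscape A \linkS4class{PromoterLandscape}.
#' @param outdir Output directory (created if needed).
#' @param nLines Replicate lines.
#' @param depth Sequencing depth (reads per sample).
#' @param defaultActivity Activity for unmeasured triplets.
#' @param reportingFloor Minimum sampled frequency exported to the
#'   observation table (default 0.02).
#' @return Named character vector of the files written, invisibly; the
#'   sampled observation data.frame as attribute \code{"observations"}.
#' @export
simulateAndExport <- function(config, loci, landscape, outdir,
                              nLines = 4L, depth = 360000L,
                              defaultActivity = NULL,
                              reportingFloor = 0.02) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  info <- loci_info(loci)
  traj <- simulatePassages(config, loci, landscape, nLines = nLines,
                           defaultActivity = defaultActivity)
  sampled <- sequencingSample(traj, depth = depth, seed = config@seed + 1L)

  trajPath <- file.path(outdir, "trajectory.tsv")
  write.table(traj, trajPath, sep = "\t", quote = FALSE, row.names = FALSE)

  anc <- setNames(info$triplet, info$name)
  keep <- sampled$allele != anc[sampled$locus] &
    sampled$frequency >= reportingFloor
  subst <- sampled[keep, , drop = FALSE]
  obs <- data.frame(line_id = subst$line_id, passage = subst$passage,
                    promoter = subst$locus, triplet = subst$allele,
                    frequency_pct = 100 * subst$frequency,
                    is_duplication = rep(FALSE, nrow(subst)),
                    flag = rep("simulated", nrow(subst)),
                    stringsAsFactors = FALSE)
  dup <- sampled[sampled$dup_frequency >= reportingFloor, , drop = FALSE]
  if (nrow(dup)) {
    dup <- unique(dup[, c("line_id", "passage", "locus", "dup_frequency")])
    obs <- rbind(obs, data.frame(
      line_id = dup$line_id, passage = dup$passage, promoter = dup$locus,
      triplet = anc[dup$locus], frequency_pct = 100 * dup$dup_frequency,
      is_duplication = TRUE, flag = "simulated", stringsAsFactors = FALSE))
  }
  obs <- obs[order(obs$line_id, obs$passage, obs$promoter, obs$triplet), ,
             drop = FALSE]
  rownames(obs) <- NULL
  obsPath <- file.path(outdir, "observations.tsv")
  writeVariantTable(obs, obsPath,
                    header = "simulated sequencing-sampled observations")

  manifestPath <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(c(passageConfigAsList(config),
                     list(n_lines = nLines, depth = depth,
                          reporting_floor = reportingFloor,
                          default_activity = defaultActivity)),
                   manifestPath)
  files <- c(trajectory = trajPath, observations = obsPath,
             manifest = manifestPath)
  attr(files, "observations") <- obs
  invisible(files)
}
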
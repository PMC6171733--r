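test_that("activity generator is exact at zero noise and seeded", {
  truth <- defaultActivityTruth()
  tab0 <- makeActivityTable(truth, cv = 0, seed = 1)
  expect_equal(tab0$value, rep(unname(truth), each = 3))

  tabA <- makeActivityTable(truth, cv = 0.05, seed = 42)
  tabB <- makeActivityTable(truth, cv = 0.05, seed = 42)
  tabC <- makeActivityTable(truth, cv = 0.05, seed = 43)
  expect_identical(tabA, tabB)
  expect_false(identical(tabA$value, tabC$value))
})

test_that("ordering-constraint violations are named", {
  truth <- defaultActivityTruth()
  truth["GAG"] <- 10  # now below CAC
  expect_error(makeActivityTable(truth), "GAG")

  short <- defaultActivityTruth()
  short <- short[names(short) != "GGG"]
  expect_error(makeActivityTable(short), "missing: GGG")
})

test_that("noisy tables reproduce the greedy DAG edge structure", {
  for (seed in 1:5) {
    tab <- makeActivityTable(cv = 0.05, seed = seed)
    ls <- normalizeActivity(tab, reference = "CGG")
    edges <- greedyPredictionDag(ls, "GAC", "CGG", tieTol = 0.15)
    expect_identical(paste(edges$from, edges$to, sep = ">"),
                     c("CAG>CGG", "GAC>GAG", "GAG>CAG", "GAG>GGG", "GGG>CGG"))
  }
})

test_that("normalised means are unbiased for the truth across seeds", {
  truth <- defaultActivityTruth()
  means <- sapply(1:200, function(s) {
    ls <- normalizeActivity(makeActivityTable(truth, cv = 0.05, seed = s),
                            reference = "CGG")
    activityOf(ls, names(truth))
  })
  mcMean <- rowMeans(means)
  mcSem <- apply(means, 1, sd) / sqrt(ncol(means))
  # every genotype's Monte-Carlo mean within 3 MC standard errors of truth
  ok <- abs(mcMean - unname(truth)) <= 3 * mcSem
  expect_gte(mean(ok), 0.99)
})

test_that("annotation fixtures differ only in the promoter lost to the deletion", {
  d1 <- makeAnnotationFixture("T7_delta1")
  wt <- makeAnnotationFixture("T7_wildtype")
  expect_length(d1, 16L)
  expect_length(wt, 17L)
  expect_identical(setdiff(names(wt), names(d1)), "phi1.1A")
  expect_identical(sum(S4Vectors::mcols(wt)$triplet == "GAC"), 15L)
  # the two reported coordinates are marked as such
  m <- S4Vectors::mcols(d1)
  expect_setequal(m$name[m$coord_source == "reported"],
                  c("phi1.5", "phi2.5"))
  expect_identical(GenomicRanges::start(d1[names(d1) == "phi1.5"]), 7761L)
  expect_identical(GenomicRanges::start(d1[names(d1) == "phi2.5"]), 9090L)
})

test_that("observed fixture encodes the printed frequencies and flags the rest", {
  obs <- makeObservedFixture()
  p25 <- obs[obs$promoter == "phi2.5", ]
  expect_equal(sort(p25$frequency_pct), c(25.6, 46.6))
  agc <- obs[obs$promoter == "phiOL" & obs$triplet == "AGC", ]
  expect_equal(sort(agc$frequency_pct), c(3.2, 39))
  expect_true(all(obs$flag[obs$frequency_pct == 20] %in%
                    c("unquantified", "duplication")))
  # phi2.5 GAG is below the fixation threshold at the final passage
  expect_lt(max(p25$frequency_pct[p25$passage == 100]), 95)
})

test_that("OD curve generator ground truth is recovered by lysisTime", {
  for (mid in c(30, 60, 90)) {
    curve <- makeOdCurve(lysisMidpoint = mid)
    expect_lte(abs(lysisTime(curve$time, curve$od600) - mid), 1)
  }
  expect_identical(unique(makeOdCurve(lyse = FALSE)$label), "no_lysis")
  expect_error(makeOdCurve(lysisMidpoint = 500), "outside")
})

test_that("simulate-and-export writes tables that close the loop", {
  loci <- makeAnnotationFixture("T7_delta1")[1:4]
  ls <- truth_landscape()
  out <- withr::local_tempdir()

  # zero rates: no substituted alleles are exported
  cfg0 <- passageConfig(nPassages = 4L, mutationRate = 0,
                        duplicationRate = 0, samplePassages = 4L,
                        effectiveSize = 2000L, seed = 2L)
  f0 <- simulateAndExport(cfg0, loci, ls, file.path(out, "zero"),
                          nLines = 1, depth = 10000L, defaultActivity = 10)
  expect_identical(nrow(loadVariantTable(f0[["observations"]], loci)), 0L)

  # strong selection from a seeded sweep: exported tables show fixation
  lsStrong <- landscapeFromMeans(c(GAC = 5, CGG = 100))
  lociA <- single_locus()
  fixedRuns <- vapply(1:20, function(s) {
    cfg <- passageConfig(nPassages = 20L, mutationRate = 0,
                         duplicationRate = 0, samplePassages = 20L,
                         effectiveSize = 10000L, seed = s)
    tr <- simulatePassages(cfg, lociA, lsStrong, nLines = 1,
                           initialPop = seeded_population("CGG", 0.5))
    any(tr$allele == "CGG" & tr$frequency > 0.95)
  }, NA)
  expect_gte(mean(fixedRuns), 0.95)

  # exported files round-trip through the variant loader unchanged
  cfg <- passageConfig(nPassages = 6L, mutationRate = 1e-3,
                       samplePassages = c(3L, 6L), effectiveSize = 5000L,
                       seed = 9L)
  f <- simulateAndExport(cfg, loci, ls, file.path(out, "run"),
                         nLines = 2, depth = 50000L, defaultActivity = 10)
  exported <- attr(f, "observations")
  reloaded <- loadVariantTable(f[["observations"]], loci)
  expect_equal(reloaded$frequency_pct, exported$frequency_pct)
  expect_identical(reloaded$triplet, exported$triplet)
  expect_true(file.exists(f[["manifest"]]))
})

test_that("landscape ordering propagates through simulation to the comparison", {
  # closed loop: simulate under the default truth, then classify what fixed;
  # alleles favoured by the greedy DAG must be scored as predicted
  loci <- makeAnnotationFixture("T7_delta1")[c("phi1.5", "phi2.5")]
  cfg <- passageConfig(nPassages = 40L, mutationRate = 2e-4,
                       duplicationRate = 0, samplePassages = 40L,
                       effectiveSize = 20000L, seed = 4L)
  truth <- defaultActivityTruth()
  onPath <- truth[c("GAC", "CGG", directIntermediates("GAC", "CGG"))]
  tr <- simulatePassages(cfg, loci, landscapeFromMeans(onPath), nLines = 2,
                         defaultActivity = 2)
  subst <- tr[tr$allele != "GAC" & tr$frequency > 0.5, ]
  expect_gt(nrow(subst), 0)
  labels <- classifyTriplet(subst$allele, "GAC", "CGG")
  # with off-path activity suppressed, sweeps follow the predicted steps
  expect_true(all(labels %in% c("predicted_single", "predicted_double",
                                "target")))
})
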
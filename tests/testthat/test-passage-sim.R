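test_that("phage fitness is a weighted saturating function of activity", {
  ls <- landscapeFromMeans(c(GAC = 40, GAG = 80, CGG = 100))
  loci <- data.frame(name = c("p1", "p2"), triplet = "GAC",
                     weight = c(0.5, 0.5))
  st <- list(p1 = "GAC", p2 = "GAC")
  # all loci at activity a, weights summing to 1, single copies: w = a/(K+a)
  expect_equal(phageFitness(st, ls, loci, K = 50), 40 / (50 + 40))

  # raising one locus activity strictly increases w
  up <- list(p1 = "GAG", p2 = "GAC")
  expect_gt(phageFitness(up, ls, loci, K = 50),
            phageFitness(st, ls, loci, K = 50))

  # a zero-weight locus has no effect
  loci0 <- data.frame(name = c("p1", "p2"), triplet = "GAC",
                      weight = c(1, 0))
  expect_equal(phageFitness(list(p1 = "GAC", p2 = "GAG"), ls, loci0, K = 50),
               phageFitness(list(p1 = "GAC", p2 = "GAC"), ls, loci0, K = 50))

  # a duplicated copy doubles the locus activity input
  dup <- list(p1 = c("GAC", "GAC"), p2 = "GAC")
  expect_equal(phageFitness(dup, ls, loci, K = 50),
               0.5 * (80 / 130) + 0.5 * (40 / 90))

  # unmeasured triplet without a default activity fails loudly
  expect_error(phageFitness(list(p1 = "AAA", p2 = "GAC"), ls, loci),
               "unmeasured")
  expect_equal(phageFitness(list(p1 = "AAA", p2 = "GAC"), ls, loci,
                            K = 50, defaultActivity = 40),
               2 * 0.5 * (40 / 90))
})

test_that("config validity rejects degenerate parameters", {
  expect_error(passageConfig(nPassages = 0), "nPassages")
  expect_error(passageConfig(mutationRate = 2), "rates")
  expect_error(passageConfig(samplePassages = 200), "samplePassages")
  expect_s4_class(passageConfig(), "PassageConfig")
})

test_that("zero mutation and duplication rates leave composition unchanged", {
  cfg <- passageConfig(nPassages = 20L, mutationRate = 0,
                       duplicationRate = 0, samplePassages = c(10L, 20L),
                       effectiveSize = 5000L, seed = 5L)
  tr <- simulatePassages(cfg, single_locus(), truth_landscape(), nLines = 2)
  expect_true(all(tr$allele == "GAC"))
  expect_true(all(tr$frequency == 1))
  expect_true(all(tr$dup_frequency == 0))
})

test_that("per-locus allele frequencies are conserved at every record", {
  cfg <- passageConfig(nPassages = 10L, mutationRate = 1e-3,
                       duplicationRate = 1e-4,
                       samplePassages = c(5L, 10L),
                       effectiveSize = 5000L, seed = 8L)
  loci <- makeAnnotationFixture("T7_delta1")[1:4]
  tr <- simulatePassages(cfg, loci, truth_landscape(), nLines = 2,
                         defaultActivity = 10)
  sums <- aggregate(frequency ~ line_id + passage + locus, tr, sum)
  expect_true(all(abs(sums$frequency - 1) < 1e-9))
})

test_that("a strongly beneficial mutant seeded at 50% sweeps by passage 50", {
  # selection only: ancestral activity 5%, mutant 100%; no new mutations
  ls <- landscapeFromMeans(c(GAC = 5, CGG = 100))
  fixed <- vapply(1:40, function(s) {
    cfg <- passageConfig(nPassages = 50L, mutationRate = 0,
                         duplicationRate = 0, samplePassages = 50L,
                         effectiveSize = 10000L, seed = s)
    tr <- simulatePassages(cfg, single_locus(), ls, nLines = 1,
                           initialPop = seeded_population("CGG", 0.5))
    tr$frequency[tr$allele == "CGG"] > 0.99
  }, NA)
  expect_gte(mean(fixed), 0.95)
})

test_that("a flat landscape drifts with zero mean frequency change", {
  ls <- landscapeFromMeans(c(GAC = 50, CGG = 50))
  delta <- vapply(1:60, function(s) {
    cfg <- passageConfig(nPassages = 20L, mutationRate = 0,
                         duplicationRate = 0, samplePassages = 20L,
                         effectiveSize = 20000L, seed = 1000L + s)
    tr <- simulatePassages(cfg, single_locus(), ls, nLines = 1,
                           initialPop = seeded_population("CGG", 0.5))
    f <- tr$frequency[tr$allele == "CGG"]
    (if (length(f)) f else 0) - 0.5
  }, 0)
  # mean change consistent with 0 at the 3-sigma level
  expect_lt(abs(mean(delta)), 3 * sd(delta) / sqrt(length(delta)))
})

test_that("fixation probability rises with the selection coefficient", {
  # weak drift regime: small effective size, rare mutant
  sweep_rate <- function(mutantActivity) {
    ls <- landscapeFromMeans(c(GAC = 20, CGG = mutantActivity))
    mean(vapply(1:40, function(s) {
      cfg <- passageConfig(nPassages = 15L, mutationRate = 0,
                           duplicationRate = 0, samplePassages = 15L,
                           effectiveSize = 300L, seed = 5000L + s)
      tr <- simulatePassages(cfg, single_locus(), ls, nLines = 1,
                             initialPop = seeded_population("CGG", 0.05))
      f <- tr$frequency[tr$allele == "CGG"]
      length(f) > 0 && f > 0.5
    }, NA))
  }
  rates <- c(sweep_rate(20), sweep_rate(40), sweep_rate(200))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("sequencing sampling is multinomial at the stated depth", {
  rec <- data.frame(line_id = "line1", passage = 50L, locus = "locusA",
                    allele = c("GAC", "GAG"), frequency = c(0.534, 0.466),
                    dup_frequency = 0)
  # an absent allele can never be sampled
  rec0 <- rbind(rec, data.frame(line_id = "line1", passage = 50L,
                                locus = "locusA", allele = "CGG",
                                frequency = 0, dup_frequency = 0))
  out0 <- sequencingSample(rec0, depth = 1000L, seed = 2L)
  expect_false("CGG" %in% out0$allele)

  # law of large numbers: huge depth recovers the true frequencies
  big <- sequencingSample(rec, depth = 1e7L, seed = 3L)
  expect_lt(max(abs(big$frequency - rec$frequency)), 1e-3)

  # at depth 360000 the sampled frequency sits within 3 binomial SEs
  se <- sqrt(0.466 * 0.534 / 360000)
  hits <- vapply(1:200, function(s) {
    out <- sequencingSample(rec, depth = 360000L, seed = s)
    abs(out$frequency[out$allele == "GAG"] - 0.466) <= 3 * se
  }, NA)
  expect_gte(mean(hits), 0.99)
})

test_that("trajectory summaries call fixation and heterogeneity", {
  rec <- data.frame(line_id = "line1", passage = c(50L, 100L),
                    locus = "phi1.5", allele = "GAG", frequency = 1,
                    stringsAsFactors = FALSE)
  s <- summarizeTrajectory(rec)
  expect_identical(s$status, "fixed")
  expect_identical(s$fixation_passage, 50L)

  # 25.6% at the final passage: not fixed, reported in the allele set
  rec2 <- data.frame(line_id = "line3", passage = c(50L, 50L, 100L, 100L),
                     locus = "phi2.5", allele = c("GAG", "GAC", "GAG", "GAC"),
                     frequency = c(0.466, 0.534, 0.256, 0.744))
  s2 <- summarizeTrajectory(rec2)
  expect_identical(s2$status, "heterogeneous")
  expect_true(grepl("GAG", s2$alleles))

  expect_identical(nrow(summarizeTrajectory(rec[0, ])), 0L)
})
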
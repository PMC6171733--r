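test_that("activity normalisation is percent-of-reference with propagated sem", {
  tab <- data.frame(genotype = rep(c("GAC", "CGG"), each = 3),
                    rnap_id = "G78-KIRV", replicate = rep(1:3, 2),
                    value = c(0.5, 0.5, 0.5, 1, 1, 1))
  ls <- normalizeActivity(tab, reference = "CGG")
  expect_equal(unname(activityOf(ls, "GAC")), 50)
  expect_equal(unname(activityOf(ls, "CGG")), 100)  # reference against itself
  a <- ls@activities
  expect_equal(a$sem_pct[a$genotype == "GAC"], 0)

  # replicates (1,2,3) against reference mean 2: mean 100%, sem = 100*(sd/sqrt(3))/2
  tab2 <- data.frame(genotype = c(rep("GAG", 3), rep("CGG", 2)),
                     rnap_id = "G78-KIRV", replicate = c(1:3, 1:2),
                     value = c(1, 2, 3, 2, 2))
  ls2 <- normalizeActivity(tab2, reference = "CGG")
  expect_equal(unname(activityOf(ls2, "GAG")), 100)
  expect_equal(ls2@activities$sem_pct[ls2@activities$genotype == "GAG"],
               100 * (sd(1:3) / sqrt(3)) / 2)

  zero <- data.frame(genotype = rep("CGG", 3), rnap_id = "x",
                     replicate = 1:3, value = 0)
  expect_error(normalizeActivity(zero, reference = "CGG"), "positive")
})

test_that("prediction matrix has distance layers and loud gaps", {
  pm <- buildPredictionMatrix(truth_landscape(), "GAC", "CGG")
  expect_length(pm@layers, 4L)                      # distances 0..3
  expect_length(unlist(pm@layers), 8L)              # 2 endpoints + 6 intermediates
  expect_identical(pm@layers[[2]], sort(c("CAC", "GAG", "GGC")))
  expect_identical(pm@layers[[3]], sort(c("CAG", "CGC", "GGG")))

  # single-node matrix when src == dst
  pm0 <- buildPredictionMatrix(truth_landscape(), "GAC", "GAC")
  expect_length(unlist(pm0@layers), 1L)
  expect_identical(nrow(pm0@edges), 0L)

  # a missing intermediate is reported by name, never imputed
  truth <- defaultActivityTruth()
  gap <- landscapeFromMeans(truth[names(truth) != "CGC"])
  err <- tryCatch(buildPredictionMatrix(gap, "GAC", "CGG"),
                  error = function(e) e)
  expect_s3_class(err, "promoterEvo_landscape_gap")
  expect_identical(err$missing, "CGC")
})

test_that("greedy DAG keeps the best next step and near-ties", {
  edges <- greedyPredictionDag(truth_landscape(), "GAC", "CGG",
                               tieTol = 0.15)
  expect_identical(
    paste(edges$from, edges$to, sep = ">"),
    c("CAG>CGG", "GAC>GAG", "GAG>CAG", "GAG>GGG", "GGG>CGG"))

  # strictly increasing chain: unique path of d edges
  chain <- landscapeFromMeans(c(AA = 1, CA = 10, AC = 2, CC = 20))
  e <- greedyPredictionDag(chain, "AA", "CC", tieTol = 0)
  expect_identical(paste(e$from, e$to, sep = ">"), c("AA>CA", "CA>CC"))

  # exact tie at tieTol = 0 keeps both branches
  tie <- landscapeFromMeans(c(AA = 1, CA = 10, AC = 10, CC = 20))
  e2 <- greedyPredictionDag(tie, "AA", "CC", tieTol = 0)
  expect_setequal(paste(e2$from, e2$to, sep = ">"),
                  c("AA>CA", "AA>AC", "CA>CC", "AC>CC"))

  # every DAG edge connects adjacent layers; every DAG path is a direct path
  pm <- buildPredictionMatrix(truth_landscape(), "GAC", "CGG")
  expect_true(validObject(pm))
})

test_that("accessible paths are the strictly monotone direct paths", {
  # strictly increasing with distance from src: all 3! accessible
  mono <- landscapeFromMeans(c(GAC = 1, CAC = 10, GGC = 11, GAG = 12,
                               CAG = 20, CGC = 21, GGG = 22, CGG = 30))
  acc <- accessibleDirectPaths(mono, "GAC", "CGG")
  expect_identical(acc$count, 6L)

  # all intermediates below the ancestor: none accessible
  sunk <- landscapeFromMeans(c(GAC = 50, CAC = 1, GGC = 2, GAG = 3,
                               CAG = 4, CGC = 5, GGG = 6, CGG = 90))
  expect_identical(accessibleDirectPaths(sunk, "GAC", "CGG")$count, 0L)

  # random landscapes agree with a per-path brute-force monotonicity check
  set.seed(7)
  nodes <- c("GAC", "CGG", directIntermediates("GAC", "CGG"))
  for (i in 1:50) {
    ls <- random_landscape(nodes)
    acc <- accessibleDirectPaths(ls, "GAC", "CGG")
    oracle <- sum(vapply(oracle_paths("GAC", "CGG"), function(p) {
      a <- vapply(p, function(g) unname(activityOf(ls, g)), 0)
      all(a[-1] > a[-length(a)])
    }, NA))
    expect_identical(acc$count, oracle)
    expect_true(acc$count >= 0 && acc$count <= 6)
  }
})

test_that("SSWM step probabilities normalise and weight activity gains", {
  ls <- landscapeFromMeans(c(GAC = 10, GAG = 12, CAC = 11, GGC = 5))
  # s = 0.2 and 0.1 -> probabilities 2/3, 1/3; deleterious gets 0
  p <- sswmStepProbabilities(ls, "GAC", c("GAG", "CAC", "GGC"))
  expect_equal(as.numeric(p), c(2 / 3, 1 / 3, 0))
  expect_false(attr(p, "allNeutral"))

  # equal positive gains split evenly
  eq <- landscapeFromMeans(c(GAC = 10, GAG = 15, CAC = 15))
  expect_equal(as.numeric(sswmStepProbabilities(eq, "GAC", c("GAG", "CAC"))),
               c(0.5, 0.5))

  # single beneficial candidate takes all the probability
  one <- landscapeFromMeans(c(GAC = 10, GAG = 20, CAC = 3, GGC = 1))
  p1 <- sswmStepProbabilities(one, "GAC", c("GAG", "CAC", "GGC"))
  expect_equal(as.numeric(p1), c(1, 0, 0))

  # all-deleterious: uniform fallback with the neutral flag raised
  down <- landscapeFromMeans(c(GAC = 10, GAG = 2, CAC = 3))
  pd <- sswmStepProbabilities(down, "GAC", c("GAG", "CAC"))
  expect_equal(as.numeric(pd), c(0.5, 0.5))
  expect_true(attr(pd, "allNeutral"))

  expect_error(sswmStepProbabilities(
    landscapeFromMeans(c(GAC = 0, GAG = 1)), "GAC", "GAG"), "non-positive")

  # probabilities sum to 1 on random landscapes
  set.seed(12)
  for (i in 1:20) {
    nodes <- unique(c("GAC", oneStepNeighbors("GAC")))
    ls <- random_landscape(nodes)
    p <- sswmStepProbabilities(ls, "GAC", oneStepNeighbors("GAC"))
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
})

test_that("triplet classification partitions the 64-genotype space 1/1/3/3/56", {
  expect_identical(classifyTriplet("GAG", "GAC", "CGG"), "predicted_single")
  expect_identical(classifyTriplet("GCC", "GAC", "CGG"), "unanticipated")
  expect_identical(classifyTriplet("GAC", "GAC", "CGG"), "ancestral")
  expect_identical(classifyTriplet("CGG", "GAC", "CGG"), "target")
  labels <- classifyTriplet(enumerateGenotypes(3), "GAC", "CGG")
  expect_equal(as.vector(table(labels)[c("ancestral", "target",
                                         "predicted_single",
                                         "predicted_double",
                                         "unanticipated")]),
               c(1, 1, 3, 3, 56))
})
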
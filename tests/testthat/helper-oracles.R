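# Independent brute-force oracles over the full 4^L genotype space.
# These deliberately avoid the package's combinatorial shortcuts: they
# enumerate and filter exhaustively.

# All genotypes g (excluding endpoints) with d(src,g) + d(g,dst) = d(src,dst),
# filtered from the full space.
oracle_intermediates <- function(src, dst) {
  space <- enumerateGenotypes(nchar(src))
  d <- hammingDistance(src, dst)
  keep <- vapply(space, function(g)
    hammingDistance(src, g) + hammingDistance(g, dst) == d, NA)
  sort(setdiff(space[keep], c(src, dst)))
}

# All shortest src->dst paths by depth-first search over one-step neighbours
# in the full space, pruned to non-increasing distance-to-go.
oracle_paths <- function(src, dst) {
  d <- hammingDistance(src, dst)
  recurse <- function(path) {
    cur <- path[length(path)]
    if (cur == dst) return(list(path))
    out <- list()
    for (n in oneStepNeighbors(cur)) {
      if (hammingDistance(n, dst) == hammingDistance(cur, dst) - 1L)
        out <- c(out, recurse(c(path, n)))
    }
    out
  }
  paths <- recurse(src)
  paths[order(vapply(paths, paste, "", collapse = ">"))]
}

# Random genotype of length L under the current RNG stream.
random_genotype <- function(L = 3L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Landscape with i.i.d. uniform activities over the given genotypes.
random_landscape <- function(genotypes) {
  landscapeFromMeans(setNames(runif(length(genotypes), 1, 100), genotypes))
}

# Shared small fixtures.
truth_landscape <- function() landscapeFromMeans(defaultActivityTruth())

single_locus <- function(triplet = "GAC", weight = 1) {
  data.frame(name = "locusA", triplet = triplet, weight = weight,
             stringsAsFactors = FALSE)
}

# Two-class starting population for a single locus: ancestral vs mutant.
seeded_population <- function(mutant, freq, locus = "locusA",
                              ancestral = "GAC") {
  list(states = list(setNames(list(ancestral), locus),
                     setNames(list(mutant), locus)),
       freq = c(1 - freq, freq))
}
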
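#' Hamming distance between two motif genotypes
#'
#' Number of positions at which two equal-length motifs differ. The engineered
#' CGG promoter triplet is three steps from the wild-type GAC triplet.
#'
#' @param a,b Genotype strings of equal length.
#' @return Non-negative integer count of differing positions.
#' @examples
#' hammingDistance("GAC", "CGG")  # 3
#' @export
hammingDistance <- function(a, b) {
  a <- asGenotype(a)
  b <- asGenotype(b)
  if (length(a) != 1L || length(b) != 1L)
    stop_input("hammingDistance compares two single genotypes")
  if (nchar(a) != nchar(b))
    stop_input("genotype length mismatch: ", nchar(a), " vs ", nchar(b))
  sum(split1(a) != split1(b))
}

#' Enumerate the full motif genotype space
#'
#' All \code{|alphabet|^length} motifs of a given length; 64 triplets for the
#' default DNA alphabet at length 3. Order is lexicographic.
#'
#' @param length Motif length (>= 1), default 3 (promoter positions -11..-9).
#' @param alphabet Character vector of allowed residues.
#' @return Character vector of all genotypes, each exactly once.
#' @examples
#' length(enumerateGenotypes(3))  # 64
#' @export
enumerateGenotypes <- function(length = 3L, alphabet = DNA_ALPHABET) {
  if (!is.numeric(length) || length(length) != 1L || length < 1 ||
      length != as.integer(length))
    stop_input("length must be a single integer >= 1")
  if (!is.character(alphabet) || length(alphabet) == 0L)
    stop_input("alphabet must be a non-empty character vector")
  alphabet <- sort(unique(alphabet))
  grid <- expand.grid(rep(list(alphabet), length),
                      stringsAsFactors = FALSE)[, seq_len(length), drop = FALSE]
  # expand.grid varies the first factor fastest; reverse columns for
  # lexicographic order on the concatenated string
  out <- do.call(paste0, rev(grid))
  sort(out)
}

differing_sites <- function(a, b) which(split1(a) != split1(b))

#' Direct intermediates between two genotypes
#'
#' All genotypes lying on some shortest (direct) mutational path between
#' \code{src} and \code{dst}: every position matches either endpoint, and the
#' genotype is neither endpoint. For the GAC -> CGG pair these are the three
#' single- and three double-mutant promoter triplets.
#'
#' @param src,dst Genotype strings of equal length.
#' @return Character vector of intermediate genotypes (lexicographic order);
#'   empty for identical or adjacent endpoints.
#' @examples
#' directIntermediates("GAC", "CGG")  # 6 triplets
#' @export
directIntermediates <- function(src, dst) {
  src <- asGenotype(src); dst <- asGenotype(dst)
  if (nchar(src) != nchar(dst))
    stop_input("genotype length mismatch")
  sites <- differing_sites(src, dst)
  d <- length(sites)
  if (d < 2L) return(character(0L))
  sc <- split1(src); dc <- split1(dst)
  # each differing site independently takes the src or dst residue
  choices <- expand.grid(rep(list(c(FALSE, TRUE)), d))
  out <- apply(choices, 1L, function(useDst) {
    g <- sc
    g[sites[as.logical(useDst)]] <- dc[sites[as.logical(useDst)]]
    paste(g, collapse = "")
  })
  sort(setdiff(out, c(src, dst)))
}

#' All direct (shortest) mutational paths between two genotypes
#'
#' A direct path changes one not-yet-changed differing site per step, so
#' \code{d} differing sites give \code{d!} paths (120 for five sites, the
#' classic count for a five-mutation landscape). Paths are returned in a
#' deterministic lexicographic order of their step sequences.
#'
#' @param src,dst Genotype strings of equal length.
#' @return List of character vectors; each path runs \code{src} to \code{dst}
#'   inclusive. Identical endpoints give one zero-step path.
#' @examples
#' length(directPaths("GAC", "CGG"))  # 6 = 3!
#' @export
directPaths <- function(src, dst) {
  src <- asGenotype(src); dst <- asGenotype(dst)
  if (nchar(src) != nchar(dst))
    stop_input("genotype length mismatch")
  sites <- differing_sites(src, dst)
  dc <- split1(dst)
  recurse <- function(cur, remaining) {
    if (length(remaining) == 0L) return(list(cur))
    paths <- list()
    for (s in remaining) {
      g <- split1(cur[length(cur)])
      g[s] <- dc[s]
      nxt <- paste(g, collapse = "")
      paths <- c(paths, recurse(c(cur, nxt), setdiff(remaining, s)))
    }
    paths
  }
  paths <- recurse(src, sites)
  keys <- vapply(paths, paste, "", collapse = ">")
  paths[order(keys)]
}

#' One-step mutational neighbours of a genotype
#'
#' All genotypes at Hamming distance exactly 1: \code{L * (|alphabet| - 1)}
#' neighbours (9 for a DNA triplet).
#'
#' @param g Genotype string.
#' @param alphabet Residue alphabet, default DNA.
#' @return Character vector of neighbours in lexicographic order.
#' @examples
#' length(oneStepNeighbors("GAC"))  # 9
#' @export
oneStepNeighbors <- function(g, alphabet = DNA_ALPHABET) {
  g <- asGenotype(g)
  gc <- split1(g)
  out <- character(0L)
  for (i in seq_along(gc)) {
    for (res in setdiff(alphabet, gc[i])) {
      n <- gc
      n[i] <- res
      out <- c(out, paste(n, collapse = ""))
    }
  }
  sort(out)
}

#' Read and write motif genotype sets
#'
#' Plain-text lists carry one motif per line (blank lines and \code{#}
#' comments ignored); FASTA files carry one motif per record via
#' \pkg{Biostrings}.
#'
#' @param path File to read or write.
#' @param genotypes Character vector of motifs to write.
#' @param names Optional FASTA record names; defaults to the motifs.
#' @return Readers return a character vector of validated motifs (named for
#'   FASTA); writers return \code{path} invisibly.
#' @name genotypeIO
NULL

#' @rdname genotypeIO
#' @export
readGenotypeList <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  asGenotype(lines)
}

#' @rdname genotypeIO
#' @export
writeGenotypeList <- function(genotypes, path) {
  writeLines(asGenotype(genotypes), path)
  invisible(path)
}

#' @rdname genotypeIO
#' @export
readGenotypeFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- asGenotype(as.character(seqs))
  names(out) <- names(seqs)
  out
}

#' @rdname genotypeIO
#' @export
writeGenotypeFasta <- function(genotypes, path, names = genotypes) {
  genotypes <- asGenotype(genotypes)
  set <- Biostrings::DNAStringSet(genotypes)
  names(set) <- names
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
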
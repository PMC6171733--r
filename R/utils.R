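#' @importFrom methods new validObject is show slot setValidity
#' @importFrom stats rnorm rbinom rmultinom sd setNames
#' @importFrom utils read.delim write.table head
#' @import methods
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("promoterEvo_input_error", "error")))
}

stop_compute <- function(...) {
  stop(errorCondition(paste0(...), class = c("promoterEvo_compute_error", "error")))
}

stop_gap <- function(msg, missing) {
  stop(errorCondition(msg, missing = missing,
                      class = c("promoterEvo_landscape_gap", "error")))
}

#' Validate and normalise a promoter motif genotype
#'
#' Genotypes are fixed-length DNA strings over \{A, C, G, T\}. Input is
#' case-normalised to uppercase; IUPAC ambiguity codes and gaps are rejected
#' because the analysis operates on concrete motifs only.
#'
#' @param x Character vector of motif strings.
#' @param length Optional required length; if supplied every element must
#'   have exactly this number of characters.
#' @return The uppercased character vector, invisibly validated.
#' @examples
#' asGenotype(c("gac", "CGG"))
#' @export
asGenotype <- function(x, length = NULL) {
  if (!is.character(x) || anyNA(x))
    stop_input("genotypes must be a character vector without NA")
  x <- toupper(x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop_input("invalid genotype character(s) in: ",
               paste(unique(x[bad]), collapse = ", "),
               " (alphabet is A/C/G/T, no IUPAC ambiguity)")
  if (!is.null(length) && any(nchar(x) != length))
    stop_input("genotype length must be ", length, "; offending: ",
               paste(unique(x[nchar(x) != length]), collapse = ", "))
  x
}

split1 <- function(g) strsplit(g, "", fixed = TRUE)[[1L]]
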
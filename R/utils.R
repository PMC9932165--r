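#' @keywords internal
"_PACKAGE"

#' @import Biostrings
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
#' @importFrom GenomicRanges seqnames start end strand
#' @importFrom methods is
#' @importFrom stats rlnorm runif setNames cor
#' @importFrom utils data
NULL

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_AMBIG <- c("B", "Z", "X")
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Validate a protein sequence
#'
#' Accepts the 20 standard residues plus the ambiguity codes B, Z, X and,
#' optionally, the translation stop `*` (needed when scanning six-frame
#' translations). Any other character is an error naming the offender.
#' @param x single character string
#' @param allow_stop logical; admit `*`
#' @param what label used in error messages
#' @return invisibly, the uppercased sequence
#' @keywords internal
check_protein <- function(x, allow_stop = FALSE, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- toupper(x)
  ok <- c(AA_STANDARD, AA_AMBIG, if (allow_stop) "*")
  bad <- setdiff(unique(seq_chars(x)), ok)
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue character '%s' in %s", bad[[1L]], what),
         call. = FALSE)
  }
  invisible(x)
}

check_dna <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  x <- toupper(x)
  bad <- setdiff(unique(seq_chars(x)), DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("invalid base character '%s' in %s", bad[[1L]], what),
         call. = FALSE)
  }
  invisible(x)
}

# Run code under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric as 1:x; this never does.
sample1 <- function(x, prob = NULL) {
  if (length(x) == 1L) x else sample(x, 1L, prob = prob)
}

# BLOSUM62 fetched once from Biostrings' datasets.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
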
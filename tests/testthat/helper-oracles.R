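# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Three-state (Gotoh) affine local-alignment DP, plain R loops.
# Gap of length L costs gap_open + L * gap_extend.
sw_oracle <- function(a, b, gap_open = 11, gap_extend = 1) {
  mat <- oracle_blosum62()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[A[i], B[j]]
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  best
}

oracle_blosum62 <- local({
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

# Manual left-to-right maximal non-overlapping motif scan (no regex).
motif_oracle <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  res <- list(polyA_runs = 0L, polyA_residues = 0L, ga_arrays = 0L,
              ggx = 0L, gpgxx = 0L, xqq = 0L)
  covered <- rep(FALSE, L)
  # poly-A runs of length >= 4
  i <- 1L
  while (i <= L) {
    if (x[i] == "A") {
      j <- i
      while (j < L && x[j + 1L] == "A") j <- j + 1L
      if (j - i + 1L >= 4L) {
        res$polyA_runs <- res$polyA_runs + 1L
        res$polyA_residues <- res$polyA_residues + (j - i + 1L)
        covered[i:j] <- TRUE
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  # (GA)n arrays of >= 2 dyads, maximal, left to right
  i <- 1L
  while (i <= L - 1L) {
    d <- 0L
    j <- i
    while (j <= L - 1L && x[j] == "G" && x[j + 1L] == "A") {
      d <- d + 1L
      j <- j + 2L
    }
    if (d >= 2L) {
      res$ga_arrays <- res$ga_arrays + 1L
      covered[i:(i + 2L * d - 1L)] <- TRUE
      i <- i + 2L * d
    } else {
      i <- i + 1L
    }
  }
  # fixed-width scans, non-overlapping within class
  fixed_scan <- function(width, pred, field) {
    i <- 1L
    while (i <= L - width + 1L) {
      if (pred(i)) {
        res[[field]] <<- res[[field]] + 1L
        covered[i:(i + width - 1L)] <<- TRUE
        i <- i + width
      } else {
        i <- i + 1L
      }
    }
  }
  fixed_scan(3L, function(i) x[i] == "G" && x[i + 1L] == "G", "ggx")
  fixed_scan(5L, function(i) x[i] == "G" && x[i + 1L] == "P" &&
               x[i + 2L] == "G", "gpgxx")
  fixed_scan(3L, function(i) x[i + 1L] == "Q" && x[i + 2L] == "Q", "xqq")
  res$coverage <- if (L == 0L) 0 else mean(covered)
  res
}

random_protein <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                           "G", "H", "I", "L", "K", "M", "F",
                                           "P", "S", "T", "W", "Y", "V"),
                           prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# Alphabet biased towards silk motif characters, to exercise every class.
silk_alphabet <- function() {
  list(alphabet = c("G", "A", "P", "Q", "S", "Y", "L", "W"),
       prob = c(.3, .25, .1, .15, .08, .05, .04, .03))
}
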
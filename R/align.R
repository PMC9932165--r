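#' Protein local-alignment scoring scheme
#'
#' BLOSUM62 with affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`, the BLAST convention) and Karlin-Altschul
#' parameters for converting raw scores to bit scores and E-values. The
#' default lambda/K pair are the canonical gapped-BLOSUM62 constants, so
#' E-values are reproducible without an empirical calibration step.
#'
#' @param gap_open gap opening penalty (> 0)
#' @param gap_extend gap extension penalty per residue (> 0)
#' @param lambda Karlin-Altschul lambda, nats per raw-score unit (> 0)
#' @param K Karlin-Altschul K (> 0)
#' @return an object of class `scoring_scheme`
#' @export
scoring_scheme <- function(gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  structure(list(matrix = blosum62(), gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw score `S`, query length `m`
#' and database length `n` (summed reference lengths).
#'
#' @param S raw alignment score
#' @param m query length (> 0)
#' @param n database length (> 0)
#' @param scheme a [scoring_scheme()]
#' @return numeric E-value
#' @export
evalue <- function(S, m, n, scheme = scoring_scheme()) {
  stopifnot(m > 0, n > 0)
  scheme$K * m * n * exp(-scheme$lambda * S)
}

bit_score <- function(S, scheme) {
  (scheme$lambda * S - log(scheme$K)) / log(2)
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman with affine gaps under the scheme's BLOSUM62 scoring
#' (computed by `Biostrings::pairwiseAlignment`). When no pair of segments
#' scores positively the result is the empty alignment with score 0 and
#' `NA` spans. Residues B/Z/X are scored via their matrix rows; `*`
#' (translation stop) is admitted so six-frame translations can be scanned.
#'
#' @param a,b protein sequences (query, reference)
#' @param scheme a [scoring_scheme()]
#' @return list with `score` (raw), `bits`, `pident` (percent identity over
#'   aligned columns), 1-based closed spans `q_start`, `q_end`, `r_start`,
#'   `r_end`, and `evalue` (`NA` here; filled in by [search_termini()])
#' @export
align_local <- function(a, b, scheme = scoring_scheme()) {
  a <- check_protein(a, allow_stop = TRUE, what = "query")
  b <- check_protein(b, allow_stop = TRUE, what = "reference")
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  pa <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  as_local_hit(pa, scheme)
}

# Convert one element of a PairwiseAlignments object into the hit record.
as_local_hit <- function(pa, scheme, i = 1L) {
  s <- Biostrings::score(pa)[i]
  if (s <= 0) {
    return(list(score = 0, bits = bit_score(0, scheme), pident = NA_real_,
                q_start = NA_integer_, q_end = NA_integer_,
                r_start = NA_integer_, r_end = NA_integer_,
                evalue = NA_real_))
  }
  pat <- Biostrings::pattern(pa)
  sub <- Biostrings::subject(pa)
  list(score = s, bits = bit_score(s, scheme),
       pident = Biostrings::pid(pa)[i],
       q_start = IRanges::start(pat)[i], q_end = IRanges::end(pat)[i],
       r_start = IRanges::start(sub)[i], r_end = IRanges::end(sub)[i],
       evalue = NA_real_)
}

#' Search a proteome against a terminal-domain reference database
#'
#' Every protein is locally aligned against every reference domain; hits
#' with `E < e_max` are kept. The database length used in the E-value is
#' the summed reference length, the common search-tool convention. The
#' default cutoff 1e-10 is the spidroin-discovery setting; 1e-5 is the
#' ortholog-search setting.
#'
#' @param proteome named character vector (or `AAStringSet`) of proteins
#' @param refdb data.frame with `id`, `type`, `terminus`, `seq`
#'   (see [read_termini_fasta()])
#' @param scheme a [scoring_scheme()]
#' @param e_max E-value cutoff (> 0)
#' @return data.frame of hits sorted by (query, ascending E) with columns
#'   `query`, `ref`, `type`, `terminus`, `pident`, `score`, `bits`,
#'   `evalue`, `q_start`, `q_end`, `r_start`, `r_end`
#' @export
search_termini <- function(proteome, refdb, scheme = scoring_scheme(),
                           e_max = 1e-10) {
  stopifnot(e_max > 0)
  if (is.null(nrow(refdb)) || nrow(refdb) == 0L) {
    stop("empty reference database", call. = FALSE)
  }
  if (methods::is(proteome, "XStringSet")) {
    proteome <- setNames(as.character(proteome), names(proteome))
  }
  stopifnot(length(proteome) > 0, !is.null(names(proteome)))
  for (i in seq_along(proteome)) {
    proteome[[i]] <- check_protein(proteome[[i]], allow_stop = TRUE,
                                   what = names(proteome)[i])
  }
  n_db <- sum(nchar(refdb$seq))
  qset <- Biostrings::AAStringSet(proteome)
  rows <- vector("list", nrow(refdb))
  for (j in seq_len(nrow(refdb))) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = qset, subject = refdb$seq[j], type = "local",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
    sc <- Biostrings::score(pa)
    ev <- evalue(sc, nchar(proteome), n_db, scheme)
    keep <- which(sc > 0 & ev < e_max)
    if (length(keep) == 0L) next
    pat <- Biostrings::pattern(pa)
    sub <- Biostrings::subject(pa)
    rows[[j]] <- data.frame(
      query = names(proteome)[keep], ref = refdb$id[j],
      type = refdb$type[j], terminus = refdb$terminus[j],
      pident = Biostrings::pid(pa)[keep],
      score = sc[keep], bits = bit_score(sc[keep], scheme),
      evalue = ev[keep],
      q_start = IRanges::start(pat)[keep], q_end = IRanges::end(pat)[keep],
      r_start = IRanges::start(sub)[keep], r_end = IRanges::end(sub)[keep],
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(query = character(), ref = character(),
                       type = character(), terminus = character(),
                       pident = numeric(), score = numeric(),
                       bits = numeric(), evalue = numeric(),
                       q_start = integer(), q_end = integer(),
                       r_start = integer(), r_end = integer(),
                       stringsAsFactors = FALSE)
  }
  hits <- hits[order(hits$query, hits$evalue), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Collapse hits to one best hit per query gene
#'
#' The paper-style "nonrepetitive" deduplication: per distinct query, keep
#' the hit with the smallest E-value (ties: larger bit score, then
#' lexicographically smallest reference id).
#'
#' @param hits data.frame as from [search_termini()]
#' @return data.frame with exactly one row per distinct query
#' @export
collapse_nonredundant <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query, hits$evalue, -hits$bits, hits$ref)
  hits <- hits[ord, , drop = FALSE]
  out <- hits[!duplicated(hits$query), , drop = FALSE]
  rownames(out) <- NULL
  out
}
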
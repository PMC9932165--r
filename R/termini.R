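#' Synthetic terminal-domain reference library
#'
#' Spidroin discovery anchors on the conserved, nonrepetitive ~100-150
#' residue N- and C-terminal domains. This library is fully synthetic: one
#' globular-composition random domain per (type, terminus), generated from a
#' fixed internal seed so the shipped FASTA fixture and this function agree
#' byte-for-byte. It plays the role of a curated terminal-domain reference
#' set without shipping any real sequence data.
#'
#' @param types spidroin types to cover
#' @param len_range integer min/max domain length
#' @param seed integer seed (default fixed, so the library is a constant)
#' @return data.frame with columns `id`, `type`, `terminus`, `seq`
#' @export
make_termini_library <- function(types = spidroin_types(),
                                 len_range = c(100L, 150L),
                                 seed = 733001L) {
  # Typical globular amino-acid frequencies (Robinson-Robinson-like), so
  # domains look protein-like rather than low-complexity.
  freqs <- c(A = .078, R = .051, N = .045, D = .054, C = .019, Q = .043,
             E = .063, G = .074, H = .022, I = .051, L = .090, K = .057,
             M = .022, F = .039, P = .052, S = .071, T = .058, W = .013,
             Y = .032, V = .065)
  with_seed(seed, {
    rows <- lapply(types, function(tp) {
      one <- function(term) {
        len <- sample1(seq.int(len_range[1], len_range[2]))
        data.frame(
          id = sprintf("%s_%sTD", tp, term),
          type = tp, terminus = term,
          seq = paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
                      collapse = ""),
          stringsAsFactors = FALSE)
      }
      rbind(one("N"), one("C"))
    })
    do.call(rbind, rows)
  })
}

#' Write a terminal-domain library as FASTA
#'
#' Headers carry `type=` and `terminus=` tokens, the on-disk contract of the
#' reference database (`>id type=MaSp1 terminus=N`).
#' @param lib data.frame as from [make_termini_library()]
#' @param path output file
#' @export
write_termini_fasta <- function(lib, path) {
  seqs <- Biostrings::AAStringSet(lib$seq)
  names(seqs) <- sprintf("%s type=%s terminus=%s", lib$id, lib$type, lib$terminus)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a terminal-domain reference FASTA
#'
#' @param path FASTA whose headers carry `type=` and `terminus=` tokens;
#'   terminus must be `N`, `C` or `complete`
#' @return data.frame with columns `id`, `type`, `terminus`, `seq`
#' @export
read_termini_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  tok <- function(key) {
    m <- regmatches(hdr, regexpr(sprintf("%s=[^ ]+", key), hdr))
    sub(sprintf("^%s=", key), "", m)
  }
  type <- tok("type")
  terminus <- tok("terminus")
  if (length(type) != length(hdr) || length(terminus) != length(hdr)) {
    stop("reference FASTA headers must carry 'type=' and 'terminus=' tokens",
         call. = FALSE)
  }
  if (!all(terminus %in% c("N", "C", "complete"))) {
    stop("terminus token must be one of N, C, complete", call. = FALSE)
  }
  data.frame(id = sub(" .*$", "", hdr), type = type, terminus = terminus,
             seq = as.character(seqs), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' The bundled terminal-domain reference library
#'
#' Loads the synthetic reference FASTA shipped with the package (identical
#' to `make_termini_library()` at its default seed).
#' @return data.frame with columns `id`, `type`, `terminus`, `seq`
#' @export
default_termini_library <- function() {
  read_termini_fasta(system.file("extdata", "terminal_domains_synthetic.fasta",
                                 package = "spidroinr", mustWork = TRUE))
}
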
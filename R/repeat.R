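#' Self-alignment periodicity profile
#'
#' For each lag `l`, the fraction of positions whose residue matches the
#' residue `l` positions downstream: `m(l) = #{i : s[i] == s[i+l]} / (L-l)`.
#' A tandem array of unit length `u` drives `m(u)` (and its multiples)
#' towards 1, which is what [find_repeat_region()] exploits.
#'
#' @param seq protein sequence
#' @param min_lag,max_lag lag range; `max_lag` is capped at `floor(L/2)`
#'   so at least two unit copies fit
#' @return data.frame of class `periodicity_profile` with columns
#'   `lag`, `match`
#' @export
periodicity <- function(seq, min_lag = 5L, max_lag = 200L) {
  seq <- check_protein(seq, allow_stop = TRUE, what = "sequence")
  L <- nchar(seq)
  if (L <= 2L * min_lag) {
    stop("sequence too short for periodicity analysis", call. = FALSE)
  }
  x <- seq_chars(seq)
  lags <- seq.int(min_lag, min(max_lag, L %/% 2L))
  m <- vapply(lags, function(l) {
    mean(x[seq_len(L - l)] == x[seq.int(1L + l, L)])
  }, numeric(1))
  structure(data.frame(lag = lags, match = m),
            class = c("periodicity_profile", "data.frame"))
}

#' Locate the tandem-repeat region of a protein
#'
#' The unit length is the smallest lag whose match fraction is within
#' `tol` (relative) of the profile maximum — preferring the fundamental
#' period over its multiples. A coarse region is the maximal run of
#' positions whose windowed (window `2*unit`) shifted-match fraction is at
#' least `theta`; boundaries are then refined to the first/last pair of
#' consecutive exact self-matches, so noiseless arrays are recovered to
#' within a residue or two.
#'
#' @param seq protein sequence
#' @param profile optional precomputed [periodicity()] profile
#' @param theta windowed match-fraction threshold in (0, 1]
#' @param tol relative tolerance for "within reach of the maximum"
#' @param min_lag,max_lag passed to [periodicity()] when `profile` is NULL
#' @return an object of class `repeat_region` (fields `start`, `end`
#'   1-based closed, `unit_length`, `copy_number`, `consensus`,
#'   `harmonics` = other lags within tolerance of the maximum), or `NULL`
#'   when no region qualifies
#' @export
find_repeat_region <- function(seq, profile = NULL, theta = 0.5, tol = 0.05,
                               min_lag = 5L, max_lag = 200L) {
  seq <- check_protein(seq, allow_stop = TRUE, what = "sequence")
  L <- nchar(seq)
  if (is.null(profile)) {
    if (L <= 2L * min_lag) return(NULL)
    profile <- periodicity(seq, min_lag, max_lag)
  }
  mmax <- max(profile$match)
  if (mmax <= 0) return(NULL)
  near <- profile$lag[profile$match >= (1 - tol) * mmax]
  u <- min(near)
  x <- seq_chars(seq)
  n_ind <- L - u
  if (n_ind < 2L * u) return(NULL)
  ind <- as.integer(x[seq_len(n_ind)] == x[seq.int(1L + u, L)])
  # windowed mean over 2u consecutive indicators
  w <- 2L * u
  cs <- c(0, cumsum(ind))
  starts <- seq_len(n_ind - w + 1L)
  wm <- (cs[starts + w] - cs[starts]) / w
  qual <- wm >= theta
  if (!any(qual)) return(NULL)
  # maximal (longest) run of qualifying window starts
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  z1 <- begs[best]
  z2 <- ends[best] + w - 1L   # last indicator index covered by the run
  # refine: seed each boundary on a run of >= 4 consecutive exact
  # self-matches (random flank coincidences of that length are ~20^-4
  # likely), then extend through any adjacent consecutive matches
  zone <- seq.int(max(1L, z1 - u), min(n_ind, z2 + u))
  seed_len <- min(4L, max(2L, n_ind %/% 2L))
  runs4 <- zone[vapply(zone, function(j) {
    j + seed_len - 1L <= n_ind && all(ind[j:(j + seed_len - 1L)] == 1L)
  }, logical(1))]
  if (length(runs4) == 0L) return(NULL)
  start <- min(runs4)
  while (start > 1L && ind[start - 1L] == 1L) start <- start - 1L
  jend <- max(runs4) + seed_len - 1L
  while (jend < n_ind && ind[jend + 1L] == 1L) jend <- jend + 1L
  end <- jend + u   # indicator j covers positions j and j+u
  span <- end - start + 1L
  if (span < 2L * u) return(NULL)
  units <- substring(seq, seq.int(start, end - u + 1L, by = u),
                     pmin(seq.int(start + u - 1L, end, by = u), end))
  units <- units[nchar(units) == u]
  consensus <- paste(vapply(seq_len(u), function(k) {
    col <- substr(units, k, k)
    names(which.max(table(col)))
  }, character(1)), collapse = "")
  structure(list(start = start, end = end, unit_length = u,
                 copy_number = span / u, consensus = consensus,
                 harmonics = setdiff(near, u)),
            class = "repeat_region")
}

#' Count silk motifs
#'
#' Quantifies the canonical silk repeat motifs: maximal poly-alanine runs
#' `(A)n` with `n >= 4` (runs and total residues), maximal `(GA)n` arrays
#' of at least 2 dyads, and left-to-right maximal non-overlapping matches
#' of `GGX`, `GPGXX` and `XQQ` (`X` = any residue). Classes are counted
#' independently of one another; `coverage` is the fraction of the sequence
#' covered by at least one motif of any class.
#'
#' @param seq protein sequence (may be empty)
#' @return list of class `motif_counts`: `polyA_runs`, `polyA_residues`,
#'   `ga_arrays`, `ggx`, `gpgxx`, `xqq`, `coverage`
#' @export
count_motifs <- function(seq) {
  seq <- check_protein(seq, allow_stop = TRUE, what = "sequence")
  L <- nchar(seq)
  scan <- function(pattern) {
    if (L == 0L) return(list(n = 0L, cov = integer(0)))
    m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) return(list(n = 0L, cov = integer(0)))
    len <- attr(m, "match.length")
    cov <- unlist(mapply(function(s, l) seq.int(s, s + l - 1L),
                         as.integer(m), len, SIMPLIFY = FALSE))
    list(n = length(m), lengths = len, cov = cov)
  }
  pa <- scan("A{4,}")
  ga <- scan("(?:GA){2,}")
  ggx <- scan("GG.")
  gpgxx <- scan("GPG..")
  xqq <- scan(".QQ")
  cov <- unique(c(pa$cov, ga$cov, ggx$cov, gpgxx$cov, xqq$cov))
  structure(list(
    polyA_runs = pa$n,
    polyA_residues = if (pa$n) sum(pa$lengths) else 0L,
    ga_arrays = ga$n,
    ggx = ggx$n,
    gpgxx = gpgxx$n,
    xqq = xqq$n,
    coverage = if (L == 0L) 0 else length(cov) / L
  ), class = "motif_counts")
}

#' Amino-acid composition
#'
#' Per-residue fractions over the 20 standard amino acids (counts / length;
#' ambiguity codes contribute to the denominator only).
#'
#' @param seq non-empty protein sequence
#' @return named numeric vector of length 20 summing to <= 1
#' @export
composition <- function(seq) {
  seq <- check_protein(seq, allow_stop = TRUE, what = "sequence")
  if (nchar(seq) == 0L) stop("empty input", call. = FALSE)
  x <- seq_chars(seq)
  counts <- table(factor(x, levels = AA_STANDARD))
  setNames(as.numeric(counts) / length(x), AA_STANDARD)
}

#' Call the tri-partite spidroin architecture
#'
#' A spidroin is full-length when an N-terminal domain, a tandem-repeat
#' array and a C-terminal domain are all present; partial when the repeat
#' plus exactly one terminus is present; otherwise non-spidroin. Terminal
#' hits count only when they fall within `terminal_window` residues of the
#' respective end of the protein.
#'
#' @param protein the candidate protein sequence
#' @param hits data.frame of this protein's hits (see [search_termini()])
#' @param repeat_region a [find_repeat_region()] result or `NULL`
#' @param terminal_window residues from each end within which a terminal
#'   domain hit must start (N) or end (C)
#' @return list of class `architecture_call`: `has_N`, `has_C`,
#'   `has_repeat`, `classification`, `evidence`
#' @export
call_architecture <- function(protein, hits, repeat_region = NULL,
                              terminal_window = 250L) {
  protein <- check_protein(protein, allow_stop = TRUE, what = "protein")
  L <- nchar(protein)
  has_N <- FALSE
  has_C <- FALSE
  ev <- character(0)
  if (!is.null(hits) && nrow(hits) > 0L) {
    n_hits <- hits$terminus %in% c("N", "complete") &
      hits$q_start <= terminal_window
    c_hits <- hits$terminus %in% c("C", "complete") &
      hits$q_end >= L - terminal_window + 1L
    has_N <- any(n_hits)
    has_C <- any(c_hits)
    ev <- unique(hits$ref[n_hits | c_hits])
  }
  has_repeat <- !is.null(repeat_region)
  classification <- if (has_N && has_C && has_repeat) {
    "full-length"
  } else if (has_repeat && xor(has_N, has_C)) {
    "partial"
  } else {
    "non-spidroin"
  }
  structure(list(has_N = has_N, has_C = has_C, has_repeat = has_repeat,
                 classification = classification,
                 evidence = list(hits = ev, repeat_region = repeat_region)),
            class = "architecture_call")
}
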
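#' Six-frame translation of a chromosome
#'
#' Frames 0/1/2 on both strands. Codons containing N translate to X; stops
#' are retained as `*` so translated-frame local alignment can run directly.
#'
#' @param chrom_seq chromosome nucleotide sequence (ACGTN)
#' @return list of class `six_frames` with one entry per frame
#'   (`strand`, `frame`, `protein`) and attribute `chrom_length`
#' @export
six_frame_translate <- function(chrom_seq) {
  chrom_seq <- check_dna(chrom_seq, what = "chromosome")
  L <- nchar(chrom_seq)
  rc <- revcomp(chrom_seq)
  frames <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") chrom_seq else rc
    for (f in 0:2) {
      frames[[length(frames) + 1L]] <- list(
        strand = strand, frame = f,
        protein = translate_cds(substr(s, f + 1L, L)))
    }
  }
  structure(frames, class = "six_frames", chrom_length = L)
}

#' Map a protein span in a translation frame back to genomic coordinates
#'
#' @param strand `+` or `-`
#' @param frame 0, 1 or 2
#' @param p_start,p_end 1-based closed protein positions in the frame
#' @param chrom_length chromosome length (nt)
#' @return integer genomic span `c(start, end)`, 1-based closed
#' @export
map_frame_span <- function(strand, frame, p_start, p_end, chrom_length) {
  if (strand == "+") {
    c(frame + 3L * (p_start - 1L) + 1L, frame + 3L * p_end)
  } else {
    c(chrom_length - frame - 3L * p_end + 1L,
      chrom_length - frame - 3L * (p_start - 1L))
  }
}

#' Search terminal domains against a genome (translated search)
#'
#' Each reference terminal domain is locally aligned against all six
#' translation frames of every chromosome. A frame can harbour several
#' genes, so after each hit the aligned segment is masked (with X) and the
#' search repeats until the E-value cutoff is no longer met. Hits become
#' genomic anchors carrying strand, frame and the codon-projected span.
#'
#' @param refdb terminal-domain reference data.frame (`id`, `type`,
#'   `terminus`, `seq`)
#' @param genome named character vector of chromosome sequences
#' @param scheme a [scoring_scheme()]
#' @param e_max E-value cutoff
#' @param max_hits_per_frame safety cap on masked re-search rounds
#' @return data.frame of anchors: `chromosome`, `strand`, `frame`,
#'   `g_start`, `g_end`, `terminus`, `type`, `ref`, `score`, `evalue`,
#'   `pident`
#' @export
anchor_search <- function(refdb, genome, scheme = scoring_scheme(),
                          e_max = 1e-10, max_hits_per_frame = 10L) {
  if (length(genome) == 0L || sum(nchar(genome)) == 0L) {
    stop("empty genome", call. = FALSE)
  }
  if (is.null(nrow(refdb)) || nrow(refdb) == 0L) {
    stop("empty reference database", call. = FALSE)
  }
  n_db <- 2 * sum(nchar(genome)) %/% 3   # total translated residues
  rows <- list()
  for (chrom in names(genome)) {
    frames <- six_frame_translate(genome[[chrom]])
    L <- attr(frames, "chrom_length")
    for (fr in frames) {
      if (nchar(fr$protein) == 0L) next
      for (j in seq_len(nrow(refdb))) {
        subj <- fr$protein
        m <- nchar(refdb$seq[j])
        for (k in seq_len(max_hits_per_frame)) {
          pa <- Biostrings::pairwiseAlignment(
            pattern = refdb$seq[j], subject = subj, type = "local",
            substitutionMatrix = scheme$matrix,
            gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
          s <- Biostrings::score(pa)
          if (s <= 0) break
          ev <- evalue(s, m, n_db, scheme)
          if (ev >= e_max) break
          sp <- c(IRanges::start(Biostrings::subject(pa)),
                  IRanges::end(Biostrings::subject(pa)))
          gs <- map_frame_span(fr$strand, fr$frame, sp[1], sp[2], L)
          rows[[length(rows) + 1L]] <- data.frame(
            chromosome = chrom, strand = fr$strand, frame = fr$frame,
            g_start = gs[1], g_end = gs[2],
            terminus = refdb$terminus[j], type = refdb$type[j],
            ref = refdb$id[j], score = s, evalue = ev,
            pident = Biostrings::pid(pa), stringsAsFactors = FALSE)
          # mask the hit and look for further copies in this frame
          substr(subj, sp[1], sp[2]) <- strrep("X", sp[2] - sp[1] + 1L)
        }
      }
    }
  }
  anchors <- do.call(rbind, rows)
  if (is.null(anchors)) {
    anchors <- data.frame(chromosome = character(), strand = character(),
                          frame = integer(), g_start = integer(),
                          g_end = integer(), terminus = character(),
                          type = character(), ref = character(),
                          score = numeric(), evalue = numeric(),
                          pident = numeric(), stringsAsFactors = FALSE)
  }
  anchors <- anchors[order(anchors$chromosome, anchors$g_start), ,
                     drop = FALSE]
  rownames(anchors) <- NULL
  anchors
}

#' Pair N and C anchors into candidate loci
#'
#' Greedy nearest pairing per chromosome and strand: walking the N anchors
#' in transcription order, each takes the nearest unused C anchor downstream
#' (in transcription orientation) within `max_span`, provided no other N
#' anchor lies between them — a lone N (C-truncated locus) must not capture
#' the C terminus of the next gene. Unpaired anchors become partial loci
#' flagged with the missing terminus.
#'
#' @param anchors data.frame from [anchor_search()]
#' @param max_span maximum genomic extent of a paired locus (nt)
#' @return data.frame of candidate loci: `chromosome`, `strand`, `start`,
#'   `end`, `frame` (reading frame of the 5' anchor), `type`, `n_ref`,
#'   `c_ref`, `missing` (`"none"`, `"missing C"` or `"missing N"`)
#' @export
pair_anchors <- function(anchors, max_span = 50000L) {
  loci <- list()
  used <- rep(FALSE, nrow(anchors))
  for (chrom in unique(anchors$chromosome)) {
    for (strand in c("+", "-")) {
      idx <- which(anchors$chromosome == chrom & anchors$strand == strand)
      if (length(idx) == 0L) next
      ns <- idx[anchors$terminus[idx] == "N"]
      cs <- idx[anchors$terminus[idx] == "C"]
      # transcription order: ascending coordinates on +, descending on -
      ns <- ns[order(anchors$g_start[ns],
                     decreasing = (strand == "-"))]
      for (ni in ns) {
        if (strand == "+") {
          cand <- cs[!used[cs] & anchors$g_start[cs] > anchors$g_end[ni] &
                       anchors$g_end[cs] - anchors$g_start[ni] + 1L <= max_span]
          cand <- cand[!vapply(cand, function(ci) {
            any(anchors$g_start[setdiff(ns, ni)] > anchors$g_end[ni] &
                  anchors$g_start[setdiff(ns, ni)] < anchors$g_start[ci])
          }, logical(1))]
          if (length(cand) > 0L) {
            ci <- cand[which.min(anchors$g_start[cand])]
            loci[[length(loci) + 1L]] <- data.frame(
              chromosome = chrom, strand = strand,
              start = anchors$g_start[ni], end = anchors$g_end[ci],
              frame = anchors$frame[ni], type = anchors$type[ni],
              n_ref = anchors$ref[ni], c_ref = anchors$ref[ci],
              missing = "none", stringsAsFactors = FALSE)
            used[c(ni, ci)] <- TRUE
          }
        } else {
          cand <- cs[!used[cs] & anchors$g_end[cs] < anchors$g_start[ni] &
                       anchors$g_end[ni] - anchors$g_start[cs] + 1L <= max_span]
          cand <- cand[!vapply(cand, function(ci) {
            any(anchors$g_end[setdiff(ns, ni)] < anchors$g_start[ni] &
                  anchors$g_end[setdiff(ns, ni)] > anchors$g_end[ci])
          }, logical(1))]
          if (length(cand) > 0L) {
            ci <- cand[which.max(anchors$g_end[cand])]
            loci[[length(loci) + 1L]] <- data.frame(
              chromosome = chrom, strand = strand,
              start = anchors$g_start[ci], end = anchors$g_end[ni],
              frame = anchors$frame[ni], type = anchors$type[ni],
              n_ref = anchors$ref[ni], c_ref = anchors$ref[ci],
              missing = "none", stringsAsFactors = FALSE)
            used[c(ni, ci)] <- TRUE
          }
        }
      }
      for (ai in c(ns, cs[!used[cs]])) {
        if (used[ai]) next
        term <- anchors$terminus[ai]
        loci[[length(loci) + 1L]] <- data.frame(
          chromosome = chrom, strand = strand,
          start = anchors$g_start[ai], end = anchors$g_end[ai],
          frame = anchors$frame[ai], type = anchors$type[ai],
          n_ref = if (term == "N") anchors$ref[ai] else NA_character_,
          c_ref = if (term == "C") anchors$ref[ai] else NA_character_,
          missing = if (term == "N") "missing C" else "missing N",
          stringsAsFactors = FALSE)
        used[ai] <- TRUE
      }
    }
  }
  out <- do.call(rbind, loci)
  if (is.null(out)) {
    out <- data.frame(chromosome = character(), strand = character(),
                      start = integer(), end = integer(), frame = integer(),
                      type = character(), n_ref = character(),
                      c_ref = character(), missing = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$chromosome, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract and translate a candidate locus
#'
#' Reads the locus CDS in the 5' (N-side) anchor's frame. Partial loci
#' missing their C terminus are extended downstream (in transcription
#' orientation, codon-aligned) and the translation is cut at the first
#' stop, emulating ORF extension from a lone anchor. Internal stops are
#' reported with protein and genomic positions.
#'
#' @param locus one row of [pair_anchors()] output (as list or data.frame)
#' @param genome named character vector of chromosomes
#' @param extend downstream extension (nt) for loci missing a C anchor
#' @return list: `cds`, `protein`, `stops` (protein positions of internal
#'   stops), `stop_genomic` (genomic start of each stop codon), `start`,
#'   `end` (possibly extended span)
#' @export
extract_and_translate <- function(locus, genome, extend = 20000L) {
  chrom <- genome[[locus$chromosome]]
  if (is.null(chrom)) stop("unknown chromosome", call. = FALSE)
  L <- nchar(chrom)
  start <- locus$start
  end <- locus$end
  if (start < 1L || end > L) stop("locus span out of chromosome bounds",
                                  call. = FALSE)
  if (identical(locus$missing, "missing C")) {
    ext <- 3L * (extend %/% 3L)
    if (locus$strand == "+") end <- min(L, end + ext)
    else start <- max(1L, start - ext)
  }
  cds <- substr(chrom, start, end)
  if (locus$strand == "-") cds <- revcomp(cds)
  prot <- translate_cds(cds)
  if (identical(locus$missing, "missing C")) {
    stop_at <- regexpr("*", prot, fixed = TRUE)
    if (stop_at > 0L) {
      prot <- substr(prot, 1L, stop_at - 1L)
      cds <- substr(cds, 1L, 3L * (stop_at - 1L))
      if (locus$strand == "+") end <- start + nchar(cds) - 1L
      else start <- end - nchar(cds) + 1L
    }
  }
  stops <- which(seq_chars(prot) == "*")
  stops <- stops[stops < nchar(prot)]
  stop_genomic <- vapply(stops, function(p) {
    q <- 3L * (p - 1L) + 1L
    if (locus$strand == "+") start + q - 1L else end - q + 1L
  }, integer(1))
  list(cds = cds, protein = prot, stops = stops,
       stop_genomic = stop_genomic, start = start, end = end)
}

#' Repair frameshifts in a candidate locus
#'
#' Scans the translated CDS 5' to 3'. An internal stop signals a frame
#' break somewhere upstream: silk-repeat codons are thymine-poor, so the
#' shifted frame can run well past the true indel before the first stop
#' appears. The breakpoint is therefore searched, not assumed: every
#' codon-aligned position within `back_search` codons upstream of the stop
#' is tried with both one-nucleotide shifts (`-1` deletes the base at the
#' breakpoint, `+1` duplicates it), and the candidate maximising the silk
#' motif coverage (see [count_motifs()]) of the upstream window in the
#' current frame plus the downstream window in the shifted frame — which
#' peaks at the true breakpoint — wins, provided the shift clears the stop.
#' Repair stops after `max_edits` edits, or flags the locus unresolved when
#' no candidate clears the stop with at least `min_coverage` downstream
#' motif coverage (e.g. a corruption inside a terminal domain, which the
#' repeat grammar cannot vouch for).
#'
#' @param locus one row of [pair_anchors()] output
#' @param genome named character vector of chromosomes
#' @param max_edits maximum number of single-nt edits
#' @param lookahead window (codons) translated on each side to score a
#'   candidate breakpoint
#' @param back_search how far upstream of a stop (codons) breakpoints are
#'   considered
#' @param min_coverage minimum downstream motif coverage for an acceptable
#'   shift
#' @param extend passed to [extract_and_translate()]
#' @return a `locus_model` list: locus fields plus `cds`, `protein`,
#'   `completeness`, `repair_log` (data.frame of edits), `unresolved`
#' @export
repair_frameshifts <- function(locus, genome, max_edits = 3L,
                               lookahead = 60L, back_search = 400L,
                               min_coverage = 0.3, extend = 20000L) {
  ex <- extract_and_translate(locus, genome, extend = extend)
  cds <- ex$cds
  log_rows <- list()
  unresolved <- FALSE
  adj <- 0L       # cumulative genomic-offset correction from applied edits
  q_floor <- 1L   # edits proceed strictly left to right
  for (edit in seq_len(max_edits + 1L)) {
    prot <- translate_cds(cds)
    stops <- which(seq_chars(prot) == "*")
    stops <- stops[stops < nchar(prot)]
    if (length(stops) == 0L) break
    if (edit > max_edits) {
      unresolved <- TRUE
      break
    }
    q_stop <- 3L * (stops[1L] - 1L) + 1L
    q_min <- max(q_floor, q_stop - 3L * back_search)
    apply_shift <- function(q, shift) {
      if (shift == -1L) {
        paste0(substr(cds, 1L, q - 1L), substr(cds, q + 1L, nchar(cds)))
      } else {
        paste0(substr(cds, 1L, q), substr(cds, q, q),
               substr(cds, q + 1L, nchar(cds)))
      }
    }
    best <- NULL
    best_score <- -Inf
    best_cov <- -Inf
    for (q in seq.int(q_stop, q_min, by = -3L)) {
      up <- translate_cds(substr(cds, max(1L, q - 3L * lookahead), q - 1L))
      up_cov <- if (nchar(up) > 0L) count_motifs(up)$coverage else 0
      for (shift in c(-1L, 1L)) {
        cds2 <- apply_shift(q, shift)
        down <- translate_cds(substr(cds2, q,
                                     min(nchar(cds2),
                                         q_stop + 3L * lookahead)))
        if (grepl("*", down, fixed = TRUE)) next   # stop not cleared
        down_cov <- count_motifs(down)$coverage
        score <- up_cov + down_cov
        if (score > best_score + 1e-12) {
          best <- list(q = q, shift = shift, cds = cds2)
          best_score <- score
          best_cov <- down_cov
        }
      }
    }
    if (is.null(best) || best_cov < min_coverage) {
      unresolved <- TRUE
      break
    }
    orig_pos <- best$q + adj
    genomic <- if (locus$strand == "+") ex$start + orig_pos - 1L
               else ex$end - orig_pos + 1L
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      cds_pos = best$q, genomic_pos = genomic, shift = best$shift,
      score = best_cov, stringsAsFactors = FALSE)
    adj <- adj - best$shift   # +1 shift inserts a base, -1 removes one
    q_floor <- best$q + 3L
    cds <- best$cds
  }
  prot <- sub("\\*$", "", translate_cds(cds))
  repair_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(cds_pos = integer(), genomic_pos = integer(),
               shift = integer(), score = numeric())
  structure(list(
    chromosome = locus$chromosome, strand = locus$strand,
    start = ex$start, end = ex$end, frame = locus$frame, type = locus$type,
    n_ref = locus$n_ref, c_ref = locus$c_ref,
    cds = cds, protein = prot,
    completeness = if (identical(locus$missing, "none")) "full-length"
                   else "partial",
    repair_log = repair_log, unresolved = unresolved),
    class = "locus_model")
}

#' Reconstruct all spidroin gene models from a genome
#'
#' Convenience wrapper: translated anchor search, greedy N/C pairing,
#' extraction and frameshift repair for every candidate locus.
#'
#' @param genome named character vector of chromosomes
#' @param refdb terminal-domain reference data.frame
#' @param scheme a [scoring_scheme()]
#' @param e_max anchor E-value cutoff
#' @param max_span maximum paired-locus extent (nt)
#' @param ... passed to [repair_frameshifts()]
#' @return list with `anchors`, `loci` and `models`
#'   (a list of `locus_model`s)
#' @export
assemble_gene_models <- function(genome, refdb, scheme = scoring_scheme(),
                                 e_max = 1e-10, max_span = 50000L, ...) {
  anchors <- anchor_search(refdb, genome, scheme, e_max)
  loci <- pair_anchors(anchors, max_span)
  models <- lapply(seq_len(nrow(loci)), function(i) {
    repair_frameshifts(as.list(loci[i, ]), genome, ...)
  })
  list(anchors = anchors, loci = loci, models = models)
}

#' Emit reconstructed loci as GFF3
#'
#' gene/mRNA/CDS features, 1-based closed, strand-correct; completeness,
#' repair edits and the unresolved flag are serialized in the attribute
#' column.
#'
#' @param models list of `locus_model`s (see [repair_frameshifts()])
#' @param path optional file to write
#' @return the GFF3 document as a character vector of lines
#' @export
emit_gff3 <- function(models, path = NULL) {
  lines <- "##gff-version 3"
  for (i in seq_along(models)) {
    m <- models[[i]]
    gid <- sprintf("locus%03d", i)
    edits <- if (nrow(m$repair_log) > 0L) {
      paste(sprintf("%+d@%d", m$repair_log$shift, m$repair_log$genomic_pos),
            collapse = ",")
    } else "none"
    base <- sprintf("%s\tspidroinr\t%%s\t%d\t%d\t.\t%s\t%%s\t%%s",
                    m$chromosome, m$start, m$end, m$strand)
    lines <- c(
      lines,
      sprintf(base, "gene", ".",
              sprintf("ID=%s;completeness=%s;repair=%s;unresolved=%s",
                      gid, m$completeness, edits, tolower(m$unresolved))),
      sprintf(base, "mRNA", ".", sprintf("ID=%s.t1;Parent=%s", gid, gid)),
      sprintf(base, "CDS", "0", sprintf("ID=%s.cds;Parent=%s.t1", gid, gid)))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
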
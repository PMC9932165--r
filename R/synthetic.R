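#' Simulate one spidroin protein
#'
#' A spidroin is a long tandem-repeat array sandwiched between nonrepetitive
#' N- and C-terminal domains. One master repeat unit is drawn from the
#' grammar and tandem-copied `n_units` times with per-residue substitution
#' noise (`unit_noise`) — real spidroin arrays are homogenised, which is
#' exactly what self-alignment periodicity detection relies on. Termini are
#' the library domains for the type, mutated at `substitution_rate`.
#' Uses the current RNG stream.
#'
#' @param type spidroin type (must have N and C entries in `termini`)
#' @param n_units number of repeat-unit copies (>= 0)
#' @param termini terminal-domain library data.frame
#' @param grammar repeat-unit [motif_grammar()]
#' @param substitution_rate per-residue substitution probability applied to
#'   the terminal domains
#' @param unit_noise per-residue substitution probability applied to each
#'   repeat-unit copy
#' @return list with `protein` and `truth` (type, unit_length, n_units,
#'   1-based closed `repeat_start`/`repeat_end`, `NA` when `n_units == 0`)
#' @export
make_spidroin <- function(type, n_units = 12L,
                          termini = make_termini_library(),
                          grammar = default_grammar(type),
                          substitution_rate = 0.05, unit_noise = 0.02) {
  ndom <- termini$seq[termini$type == type & termini$terminus == "N"]
  cdom <- termini$seq[termini$type == type & termini$terminus == "C"]
  if (length(ndom) != 1L || length(cdom) != 1L) {
    stop(sprintf("unknown spidroin type '%s' (no unique N/C domain in library)",
                 type), call. = FALSE)
  }
  stopifnot(n_units >= 0L)
  mutate <- function(s, rate) {
    if (rate <= 0 || nchar(s) == 0L) return(s)
    x <- seq_chars(s)
    hit <- which(runif(length(x)) < rate)
    for (i in hit) {
      x[i] <- sample(setdiff(AA_STANDARD, x[i]), 1L)
    }
    paste(x, collapse = "")
  }
  n_mut <- mutate(ndom, substitution_rate)
  c_mut <- mutate(cdom, substitution_rate)
  if (n_units > 0L) {
    master <- make_repeat_unit(grammar)
    units <- vapply(seq_len(n_units), function(i) mutate(master, unit_noise),
                    character(1))
    rep_seq <- paste(units, collapse = "")
    repeat_start <- nchar(n_mut) + 1L
    repeat_end <- nchar(n_mut) + nchar(rep_seq)
    unit_length <- nchar(master)
  } else {
    rep_seq <- ""
    repeat_start <- NA_integer_
    repeat_end <- NA_integer_
    unit_length <- NA_integer_
  }
  list(protein = paste0(n_mut, rep_seq, c_mut),
       truth = list(type = type, unit_length = unit_length,
                    n_units = as.integer(n_units),
                    repeat_start = repeat_start, repeat_end = repeat_end))
}

#' Simulate a decoy (non-spidroin) protein
#'
#' Decoys stress discovery specificity: a contiguous low-complexity block of
#' collagen-like GXY triplets embedded in otherwise uniform-random sequence.
#' Candidates sharing > 40% identity over at least half a reference terminal
#' domain are rejection-sampled away, so decoys carry no terminal-domain
#' signal. Uses the current RNG stream.
#'
#' @param length protein length (> 0)
#' @param low_complexity_fraction fraction of the sequence occupied by the
#'   GXY block (0 disables it; residues then uniform over the 20 standard)
#' @param termini optional terminal-domain library for rejection sampling
#' @param scheme scoring scheme for the rejection alignments
#' @param max_tries resampling attempts before giving up the rejection
#' @return a protein string of exactly `length` residues
#' @export
make_decoy <- function(length, low_complexity_fraction = 0.3,
                       termini = NULL, scheme = scoring_scheme(),
                       max_tries = 20L) {
  stopifnot(length > 0)
  draw <- function() {
    x <- sample(AA_STANDARD, length, replace = TRUE)
    lc <- floor(low_complexity_fraction * length)
    if (lc >= 3L) {
      n_trip <- lc %/% 3L
      gxy <- as.vector(rbind("G",
                             sample(c("P", "A", "S", "Q"), n_trip, TRUE),
                             sample(c("P", "A", "G", "S"), n_trip, TRUE)))
      at <- sample.int(length - 3L * n_trip + 1L, 1L)
      x[seq.int(at, at + 3L * n_trip - 1L)] <- gxy
    }
    paste(x, collapse = "")
  }
  for (i in seq_len(max_tries)) {
    cand <- draw()
    if (is.null(termini)) return(cand)
    clash <- FALSE
    for (j in seq_len(nrow(termini))) {
      al <- align_local(cand, termini$seq[j], scheme)
      if (al$score > 0 && !is.na(al$pident) && al$pident > 40 &&
          (al$r_end - al$r_start + 1L) >= 0.5 * nchar(termini$seq[j])) {
        clash <- TRUE
        break
      }
    }
    if (!clash) return(cand)
  }
  cand
}

# codon table: list residue -> codons (standard genetic code)
codons_by_aa <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

# Reverse-translate a protein, sampling uniformly over synonymous codons.
reverse_translate <- function(protein) {
  tab <- codons_by_aa()
  x <- seq_chars(protein)
  paste(vapply(x, function(aa) {
    cs <- tab[[aa]]
    if (is.null(cs)) stop(sprintf("cannot reverse-translate residue '%s'", aa),
                          call. = FALSE)
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1)), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Embed genes into synthetic chromosomes
#'
#' Reverse-translates each protein (uniform synonymous codons, plus a stop
#' codon), lays the CDSs out on their chromosomes in plan order separated by
#' random intergenic flanks, and applies the corruption plan: a single-nt
#' deletion or insertion inside the repeat span (central 80%, so the
#' frameshift provably lies within the truth repeat), or truncation of a
#' terminus. Genes are single-exon CDSs. Uses the current RNG stream.
#'
#' @param genes data.frame with columns `gene_id`, `protein`, `chromosome`,
#'   `strand`, and (for spidroins) `repeat_start`, `repeat_end` in protein
#'   coordinates; an optional `start` column fixes genomic starts, which
#'   must then be non-overlapping (overlap is an invalid-plan error)
#' @param corruption optional data.frame with `gene_id` and `kind` in
#'   `del`, `ins`, `truncate_N`, `truncate_C`
#' @param gap_range min/max intergenic flank length (nt)
#' @return list with `genome` (named character per chromosome) and `genes`
#'   (the input plus genomic `start`, `end` 1-based closed and a
#'   `corruption` record string)
#' @export
embed_genes <- function(genes, corruption = NULL,
                        gap_range = c(800L, 2000L)) {
  stopifnot(all(c("gene_id", "protein", "chromosome", "strand") %in%
                  names(genes)))
  stopifnot(all(genes$strand %in% c("+", "-")))
  genes$corruption <- "none"
  genes$start <- genes$start %||% NA_integer_
  genes$end <- NA_integer_
  fixed_plan <- !all(is.na(genes$start))
  out_genome <- character(0)
  for (chrom in unique(genes$chromosome)) {
    idx <- which(genes$chromosome == chrom)
    if (fixed_plan) idx <- idx[order(genes$start[idx])]
    parts <- character(0)
    pos <- 0L
    prev_end <- 0L
    for (i in idx) {
      cds <- paste0(reverse_translate(genes$protein[i]),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      rec <- "none"
      if (!is.null(corruption) && genes$gene_id[i] %in% corruption$gene_id) {
        kind <- corruption$kind[match(genes$gene_id[i], corruption$gene_id)]
        rs <- genes$repeat_start[i]
        re <- genes$repeat_end[i]
        if (kind %in% c("del", "ins")) {
          if (is.na(rs)) stop("cannot corrupt a gene without a repeat span",
                              call. = FALSE)
          lo <- (rs - 1L) * 3L + 1L
          hi <- re * 3L
          width <- hi - lo
          at <- sample1(seq.int(lo + ceiling(0.1 * width),
                                hi - ceiling(0.1 * width)))
          if (kind == "del") {
            cds <- paste0(substr(cds, 1L, at - 1L),
                          substr(cds, at + 1L, nchar(cds)))
          } else {
            cds <- paste0(substr(cds, 1L, at),
                          sample(c("A", "C", "G", "T"), 1L),
                          substr(cds, at + 1L, nchar(cds)))
          }
          rec <- sprintf("%s@cds:%d", kind, at)
        } else if (kind == "truncate_C") {
          cut <- re * 3L   # keep N domain + repeat, drop C domain and stop
          cds <- substr(cds, 1L, cut)
          rec <- "truncate_C"
        } else if (kind == "truncate_N") {
          cut <- (rs - 1L) * 3L   # drop N domain, keep repeat onwards
          cds <- substr(cds, cut + 1L, nchar(cds))
          rec <- "truncate_N"
        } else {
          stop(sprintf("unknown corruption kind '%s'", kind), call. = FALSE)
        }
      }
      if (genes$strand[i] == "-") cds <- revcomp(cds)
      if (fixed_plan) {
        if (genes$start[i] <= prev_end) {
          stop(sprintf("invalid plan: gene %s overlaps the previous gene",
                       genes$gene_id[i]), call. = FALSE)
        }
        gap <- genes$start[i] - pos - 1L
      } else {
        gap <- sample1(seq.int(gap_range[1], gap_range[2]))
      }
      parts <- c(parts, random_dna(gap), cds)
      genes$start[i] <- pos + gap + 1L
      genes$end[i] <- pos + gap + nchar(cds)
      genes$corruption[i] <- rec
      pos <- genes$end[i]
      prev_end <- pos
    }
    parts <- c(parts, random_dna(sample1(seq.int(gap_range[1], gap_range[2]))))
    out_genome[[chrom]] <- paste(parts, collapse = "")
  }
  list(genome = out_genome, genes = genes)
}

#' Multi-gland expression design
#'
#' Samples cover the seven silk gland types, with the major ampullate (Ma)
#' gland split into its Tail/Sac/Duct segments. Baseline expression is
#' log-normal; each silk gene is multiplied by `fold` in its cognate gland
#' samples (major-ampullate spidroins: Tail and Sac — the synthesis and
#' storage segments; the Duct only spins the fiber).
#'
#' @param tissues sample tissue/segment labels
#' @param replicates replicates per tissue
#' @param mu0,sigma log-normal baseline parameters (meanlog, sdlog);
#'   `sigma > 0`
#' @param fold cognate-gland fold factor, >= 1
#' @return object of class `expression_design`
#' @export
expression_design <- function(tissues = c("Tail", "Sac", "Duct", "Mi", "Fl",
                                          "Tu", "Ag", "Ac", "Py"),
                              replicates = 3L, mu0 = 1, sigma = 1,
                              fold = 1000) {
  stopifnot(fold >= 1, sigma > 0, replicates >= 1, length(tissues) >= 2)
  samples <- data.frame(
    sample = paste0(rep(tissues, each = replicates), "_r",
                    seq_len(replicates)),
    tissue = rep(tissues, each = replicates),
    stringsAsFactors = FALSE)
  structure(list(samples = samples, mu0 = mu0, sigma = sigma, fold = fold),
            class = "expression_design")
}

#' Cognate gland segments of a spidroin type
#' @param type spidroin type
#' @return character vector of tissue labels
#' @export
cognate_tissues <- function(type) {
  switch(type,
         MaSp1 = , MaSp2 = , other = c("Tail", "Sac"),
         MiSp = "Mi", FlSp = "Fl", TuSp = "Tu",
         AgSp = "Ag", AcSp = "Ac", PySp = "Py",
         character(0))
}

#' Simulate a gland expression matrix
#'
#' FPKM-scale values: baseline `LogNormal(mu0, sigma)` for every gene and
#' sample, with each spidroin's values multiplied by `design$fold` in its
#' cognate gland samples. Uses the current RNG stream.
#'
#' @param truth truth table with `gene_id`, `class` and `type` columns
#' @param design an [expression_design()]
#' @return list with `values` (genes x samples matrix) and `samples`
#'   (sample/tissue data.frame)
#' @export
make_expression <- function(truth, design = expression_design()) {
  stopifnot(inherits(design, "expression_design"))
  ns <- nrow(design$samples)
  ng <- nrow(truth)
  vals <- matrix(rlnorm(ng * ns, meanlog = design$mu0, sdlog = design$sigma),
                 nrow = ng, ncol = ns,
                 dimnames = list(truth$gene_id, design$samples$sample))
  for (i in which(truth$class == "spidroin")) {
    cg <- cognate_tissues(truth$type[i])
    cols <- design$samples$tissue %in% cg
    vals[i, cols] <- vals[i, cols] * design$fold
  }
  list(values = vals, samples = design$samples)
}

#' Default synthetic bundle configuration
#'
#' Thirteen spidroins arranged as three chromosome groups mirroring the
#' classic orb-weaver layout — MaSp1a-c plus MaSp2e on chr4, MaSp2a-d on
#' chr7, MiSp-a-e on chr6 — with two corrupted loci (one single-nt deletion
#' inside a repeat, one C-terminal truncation) and 50 decoys interleaved
#' across the three chromosomes.
#'
#' @param n_decoys number of decoy genes
#' @param decoy_len_range decoy length range (residues)
#' @param substitution_rate terminal-domain substitution rate
#' @param unit_noise repeat-unit copy substitution rate
#' @param gap_range intergenic flank range (nt)
#' @param design an [expression_design()]
#' @return a config list consumed by [make_bundle()]
#' @export
default_bundle_config <- function(n_decoys = 50L,
                                  decoy_len_range = c(200L, 400L),
                                  substitution_rate = 0.05,
                                  unit_noise = 0.02,
                                  gap_range = c(800L, 2000L),
                                  design = expression_design()) {
  spidroins <- data.frame(
    gene_id = c("MaSp1a", "MaSp1b", "MaSp1c", "MaSp2e",
                "MaSp2a", "MaSp2b", "MaSp2c", "MaSp2d",
                "MiSp-a", "MiSp-b", "MiSp-c", "MiSp-d", "MiSp-e"),
    type = c("MaSp1", "MaSp1", "MaSp1", "MaSp2",
             "MaSp2", "MaSp2", "MaSp2", "MaSp2",
             rep("MiSp", 5L)),
    chromosome = c(rep("chr4", 4L), rep("chr7", 4L), rep("chr6", 5L)),
    strand = c("+", "+", "-", "+", "+", "-", "+", "+",
               "+", "-", "+", "+", "-"),
    n_units = c(12L, 14L, 11L, 12L, 12L, 13L, 11L, 12L,
                10L, 12L, 14L, 11L, 13L),
    stringsAsFactors = FALSE)
  corruption <- data.frame(gene_id = c("MaSp1b", "MaSp2c"),
                           kind = c("del", "truncate_C"),
                           stringsAsFactors = FALSE)
  list(spidroins = spidroins, corruption = corruption,
       n_decoys = as.integer(n_decoys), decoy_len_range = decoy_len_range,
       substitution_rate = substitution_rate, unit_noise = unit_noise,
       gap_range = gap_range, design = design)
}

#' Generate a complete synthetic genome bundle
#'
#' Chromosomes, gene models, proteome, expression matrix and a ground-truth
#' table, deterministically from `(config, seed)`. The proteome entry of
#' each gene is the translation of its (possibly corrupted) genomic CDS up
#' to the first stop, emulating what an ORF-based annotator would report.
#'
#' @param config a [default_bundle_config()]-shaped list
#' @param seed integer seed; the bundle is a pure function of
#'   `(config, seed)`
#' @return object of class `silk_bundle`: `genome`, `genes`, `proteome`,
#'   `truth`, `expression`, `termini`, `config`, `seed`
#' @export
make_bundle <- function(config = default_bundle_config(), seed = 1L) {
  termini <- make_termini_library()
  with_seed(seed, {
    sp <- config$spidroins
    made <- lapply(seq_len(nrow(sp)), function(i) {
      make_spidroin(sp$type[i], n_units = sp$n_units[i], termini = termini,
                    substitution_rate = config$substitution_rate,
                    unit_noise = config$unit_noise)
    })
    sp_genes <- data.frame(
      gene_id = sp$gene_id, class = "spidroin", type = sp$type,
      chromosome = sp$chromosome, strand = sp$strand,
      protein = vapply(made, function(m) m$protein, character(1)),
      repeat_start = vapply(made, function(m) m$truth$repeat_start, integer(1)),
      repeat_end = vapply(made, function(m) m$truth$repeat_end, integer(1)),
      unit_length = vapply(made, function(m) m$truth$unit_length, integer(1)),
      n_units = vapply(made, function(m) m$truth$n_units, integer(1)),
      stringsAsFactors = FALSE)
    chroms <- unique(sp$chromosome)
    n_dec <- config$n_decoys
    dec_genes <- if (n_dec > 0L) {
      data.frame(
        gene_id = sprintf("decoy%03d", seq_len(n_dec)),
        class = "decoy", type = NA_character_,
        chromosome = sample(rep_len(chroms, n_dec)),
        strand = sample(c("+", "-"), n_dec, replace = TRUE),
        protein = vapply(seq_len(n_dec), function(i) {
          len <- sample1(seq.int(config$decoy_len_range[1],
                                 config$decoy_len_range[2]))
          make_decoy(len, low_complexity_fraction = runif(1, 0, 0.4),
                     termini = termini)
        }, character(1)),
        repeat_start = NA_integer_, repeat_end = NA_integer_,
        unit_length = NA_integer_, n_units = NA_integer_,
        stringsAsFactors = FALSE)
    } else {
      sp_genes[0, ]
    }
    genes <- rbind(sp_genes, dec_genes)
    # shuffle layout order within chromosomes so decoys interleave spidroins
    genes <- genes[sample.int(nrow(genes)), , drop = FALSE]
    emb <- embed_genes(genes, corruption = config$corruption,
                       gap_range = config$gap_range)
    truth <- emb$genes
    truth$completeness <- ifelse(
      truth$class == "spidroin",
      ifelse(grepl("^truncate", truth$corruption), "partial", "full-length"),
      NA_character_)
    truth <- truth[order(truth$chromosome, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
    proteome <- vapply(seq_len(nrow(truth)), function(i) {
      cds <- substr(emb$genome[[truth$chromosome[i]]], truth$start[i],
                    truth$end[i])
      if (truth$strand[i] == "-") cds <- revcomp(cds)
      translate_cds(cds, to_first_stop = TRUE)
    }, character(1))
    names(proteome) <- truth$gene_id
    expr <- make_expression(truth, config$design)
    structure(list(genome = emb$genome,
                   genes = truth[, c("gene_id", "chromosome", "start", "end",
                                     "strand")],
                   proteome = proteome, truth = truth, expression = expr,
                   termini = termini, config = config,
                   seed = as.integer(seed)),
              class = "silk_bundle")
  })
}

# Translate a CDS string; optionally stop at the first internal stop.
translate_cds <- function(cds, to_first_stop = FALSE) {
  n <- (nchar(cds) %/% 3L) * 3L
  if (n == 0L) return("")
  p <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
  if (to_first_stop) {
    stop_at <- regexpr("*", p, fixed = TRUE)
    if (stop_at > 0L) p <- substr(p, 1L, stop_at - 1L)
  } else {
    p <- sub("\\*$", "", p)
  }
  p
}

#' @export
print.silk_bundle <- function(x, ...) {
  cat(sprintf(
    "silk_bundle: %d chromosome(s) (%s nt), %d spidroins, %d decoys, seed %d\n",
    length(x$genome), format(sum(nchar(x$genome)), big.mark = ","),
    sum(x$truth$class == "spidroin"), sum(x$truth$class == "decoy"),
    x$seed))
  invisible(x)
}
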
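test_that("six-frame translation honours the codon table on both strands", {
  fr <- six_frame_translate("ATGAAA")
  fwd0 <- Filter(function(f) f$strand == "+" && f$frame == 0, fr)[[1]]
  expect_identical(fwd0$protein, "MK")
  fr2 <- six_frame_translate("TTTCAT")
  rev0 <- Filter(function(f) f$strand == "-" && f$frame == 0, fr2)[[1]]
  expect_identical(rev0$protein, "MK")
  expect_error(six_frame_translate("ACGU"), "'U'")
})

test_that("frame coordinate maps round-trip on random sequence", {
  set.seed(23)
  dna <- paste(sample(c("A", "C", "G", "T"), 999, TRUE), collapse = "")
  frames <- six_frame_translate(dna)
  L <- attr(frames, "chrom_length")
  for (fr in frames) {
    np <- nchar(fr$protein)
    for (p in sort(sample.int(np, 5))) {
      gs <- map_frame_span(fr$strand, fr$frame, p, p, L)
      codon <- substr(dna, gs[1], gs[2])
      if (fr$strand == "-") {
        codon <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(codon)))
      }
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(codon)))
      expect_identical(aa, substr(fr$protein, p, p))
    }
  }
})

test_that("anchor search recovers termini at truth coordinates and is clean on decoys", {
  b <- shared_mini()
  refdb <- shared_refdb()
  anchors <- anchor_search(refdb, b$genome)
  truth_sp <- b$truth[b$truth$class == "spidroin", ]
  lib <- b$termini
  for (i in seq_len(nrow(truth_sp))) {
    tr <- truth_sp[i, ]
    near <- anchors$chromosome == tr$chromosome &
      anchors$g_start >= tr$start - 30 & anchors$g_end <= tr$end + 30
    expect_identical(sort(anchors$terminus[near]), c("C", "N"))
    expect_true(all(anchors$type[near] == tr$type))
    expect_true(all(anchors$strand[near] == tr$strand))
    # noise-free bundle: anchors sit exactly on the domain boundaries
    ndom_len <- nchar(lib$seq[lib$type == tr$type & lib$terminus == "N"])
    n_anchor <- anchors[near & anchors$terminus == "N", ]
    if (tr$strand == "+") {
      expect_identical(n_anchor$g_start, tr$start)
      expect_identical(n_anchor$g_end, tr$start + 3L * ndom_len - 1L)
    } else {
      expect_identical(n_anchor$g_end, tr$end)
    }
  }
  # every anchor lies inside a true spidroin gene: decoys attract none
  in_gene <- vapply(seq_len(nrow(anchors)), function(j) {
    any(truth_sp$chromosome == anchors$chromosome[j] &
          truth_sp$start <= anchors$g_start[j] &
          truth_sp$end >= anchors$g_end[j])
  }, logical(1))
  expect_true(all(in_gene))
  expect_error(anchor_search(refdb, character(0)), "empty genome")
})

test_that("anchor count grows monotonically with e_max", {
  b <- shared_mini()
  refdb <- shared_refdb()
  n_strict <- nrow(anchor_search(refdb, b$genome, e_max = 1e-30))
  n_default <- nrow(anchor_search(refdb, b$genome, e_max = 1e-10))
  expect_lte(n_strict, n_default)
})

test_that("anchor pairing follows orientation and span rules", {
  mk <- function(term, s, e, strand = "+", frame = 0L) {
    data.frame(chromosome = "chr1", strand = strand, frame = frame,
               g_start = s, g_end = e, terminus = term, type = "MaSp1",
               ref = paste0("r", term), score = 500, evalue = 1e-40,
               pident = 99, stringsAsFactors = FALSE)
  }
  # plain pairing
  loci <- pair_anchors(rbind(mk("N", 1000L, 1300L), mk("C", 9000L, 9200L)))
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$start, 1000L)
  expect_identical(loci$end, 9200L)
  expect_identical(loci$missing, "none")
  # lone N anchor becomes a partial locus
  lone <- pair_anchors(mk("N", 1000L, 1300L))
  expect_identical(lone$missing, "missing C")
  # N downstream of C on + strand is not paired
  wrong <- pair_anchors(rbind(mk("N", 9000L, 9300L), mk("C", 1000L, 1200L)))
  expect_setequal(wrong$missing, c("missing C", "missing N"))
  # gap beyond max_span is not paired
  far <- pair_anchors(rbind(mk("N", 1000L, 1300L), mk("C", 90000L, 90200L)),
                      max_span = 50000L)
  expect_setequal(far$missing, c("missing C", "missing N"))
  # an intervening N blocks capture of the next gene's C terminus
  three <- pair_anchors(rbind(mk("N", 1000L, 1300L), mk("N", 5000L, 5300L),
                              mk("C", 9000L, 9200L)))
  expect_identical(three$missing[three$start == 1000L], "missing C")
  expect_identical(three$missing[three$start == 5000L], "none")
})

test_that("extraction reproduces uncorrupted proteins exactly", {
  b <- shared_mini()
  asm <- shared_mini_assembly()
  expect_identical(nrow(asm$loci), 3L)
  for (m in asm$models) {
    tr <- b$truth[b$truth$chromosome == m$chromosome &
                    b$truth$start <= m$start + 2 &
                    b$truth$end >= m$end - 2 &
                    b$truth$class == "spidroin", ]
    expect_identical(nrow(tr), 1L)
    expect_identical(m$protein, tr$protein)
    expect_identical(m$completeness, "full-length")
    expect_identical(nrow(m$repair_log), 0L)
    expect_false(m$unresolved)
    expect_identical(nchar(m$cds) %% 3L, 0L)
  }
  bad <- asm$loci[1, ]
  bad$end <- nchar(b$genome[[bad$chromosome]]) + 10L
  expect_error(extract_and_translate(as.list(bad), b$genome), "out of")
})

test_that("a single-nucleotide deletion is detected and repaired", {
  b <- shared_bundle()
  asm <- shared_assembly()
  tr <- b$truth[b$truth$corruption != "none" &
                  grepl("^del", b$truth$corruption), ]
  li <- which(vapply(asm$models, function(m) {
    m$chromosome == tr$chromosome && m$start >= tr$start - 50 &&
      m$start <= tr$start + 50
  }, logical(1)))
  expect_identical(length(li), 1L)
  m <- asm$models[[li]]
  # extraction before repair reports at least one internal stop
  ex <- extract_and_translate(as.list(asm$loci[li, ]), b$genome)
  expect_gt(length(ex$stops), 0)
  expect_identical(m$completeness, "full-length")
  expect_false(m$unresolved)
  expect_gte(nrow(m$repair_log), 1L)
  # repaired protein is >= 95% identical to the truth protein
  pa <- Biostrings::pairwiseAlignment(m$protein, tr$protein,
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 11, gapExtension = 1,
                                      type = "global")
  expect_gte(Biostrings::pid(pa), 95)
  # every applied edit lies inside the truth repeat span (genomic)
  rep_nt <- c(tr$start + (tr$repeat_start - 1L) * 3L,
              tr$start + tr$repeat_end * 3L - 1L)
  expect_true(all(m$repair_log$genomic_pos >= rep_nt[1] &
                    m$repair_log$genomic_pos <= rep_nt[2]))
})

test_that("loci without internal stops come back unchanged from repair", {
  b <- shared_bundle()
  asm <- shared_assembly()
  clean <- Filter(function(m) nrow(m$repair_log) == 0L, asm$models)
  expect_gt(length(clean), 5)
  expect_true(all(!vapply(clean, function(m) m$unresolved, logical(1))))
})

test_that("a frameshift inside a terminal domain is flagged unresolved", {
  b <- shared_mini()
  tr <- b$truth[b$truth$gene_id == "MaSp1a", ]
  # inject a 1-nt deletion into the C-terminal domain on the genome
  cut <- tr$start + tr$repeat_end * 3L + 30L   # inside the C domain
  chrom <- b$genome[[tr$chromosome]]
  genome2 <- b$genome
  genome2[[tr$chromosome]] <- paste0(substr(chrom, 1, cut - 1),
                                     substr(chrom, cut + 1, nchar(chrom)))
  asm2 <- assemble_gene_models(genome2, shared_refdb())
  li <- which(vapply(asm2$models, function(m) {
    m$chromosome == tr$chromosome && abs(m$start - tr$start) < 50
  }, logical(1)))
  m <- asm2$models[[li[1]]]
  expect_true(m$unresolved || m$completeness == "partial")
})

test_that("GFF3 emission round-trips through rtracklayer and keeps strands", {
  asm <- shared_assembly()
  path <- withr::local_tempfile(fileext = ".gff3")
  emit_gff3(asm$models, path)
  gr <- rtracklayer::import(path)
  genes <- gr[gr$type == "gene"]
  expect_identical(length(genes), length(asm$models))
  for (i in seq_along(asm$models)) {
    m <- asm$models[[i]]
    expect_identical(GenomicRanges::start(genes)[i], m$start)
    expect_identical(GenomicRanges::end(genes)[i], m$end)
    expect_identical(as.character(GenomicRanges::strand(genes)[i]), m$strand)
    expect_true(GenomicRanges::start(genes)[i] <=
                  GenomicRanges::end(genes)[i])
  }
  expect_setequal(unique(genes$completeness),
                  unique(vapply(asm$models, function(m) m$completeness,
                                character(1))))
})
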
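test_that("make_spidroin handles the zero-unit and zero-noise cases", {
  lib <- make_termini_library()
  set.seed(3)
  sp0 <- make_spidroin("MaSp1", n_units = 0L, termini = lib)
  ndom <- lib$seq[lib$type == "MaSp1" & lib$terminus == "N"]
  cdom <- lib$seq[lib$type == "MaSp1" & lib$terminus == "C"]
  expect_true(is.na(sp0$truth$repeat_start))
  set.seed(3)
  sp_exact <- make_spidroin("MaSp1", n_units = 0L, termini = lib,
                            substitution_rate = 0)
  expect_identical(sp_exact$protein, paste0(ndom, cdom))
  expect_error(make_spidroin("NoSuchSp", termini = lib), "unknown spidroin type")
})

test_that("make_spidroin records exact repeat spans", {
  lib <- make_termini_library()
  set.seed(11)
  sp <- make_spidroin("MiSp", n_units = 8L, termini = lib, unit_noise = 0)
  tr <- sp$truth
  span <- substr(sp$protein, tr$repeat_start, tr$repeat_end)
  expect_identical(nchar(span), tr$unit_length * tr$n_units)
  # noiseless: the span is the master unit tandem-repeated
  unit <- substr(span, 1, tr$unit_length)
  expect_identical(span, strrep(unit, tr$n_units))
})

test_that("decoys have the requested length and uniform composition at zero low-complexity", {
  set.seed(22)
  expect_identical(nchar(make_decoy(50L)), 50L)
  d <- make_decoy(5000L, low_complexity_fraction = 0)
  counts <- table(factor(strsplit(d, "")[[1]],
                         levels = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]))
  # oracle: direct counting + chi-square against the uniform distribution
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("uncorrupted embedded genes round-trip genome -> CDS -> protein", {
  b <- shared_mini()
  for (i in which(b$truth$class == "spidroin")) {
    cds <- substr(b$genome[[b$truth$chromosome[i]]],
                  b$truth$start[i], b$truth$end[i])
    if (b$truth$strand[i] == "-") {
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    }
    prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cds, 1, nchar(cds) - 3)),
      no.init.codon = TRUE))
    expect_identical(prot, b$truth$protein[i])
    expect_identical((b$truth$end[i] - b$truth$start[i] + 1L) %% 3L, 0L)
  }
  # minus-strand gene models carry strand "-"
  expect_true(any(b$genes$strand == "-"))
})

test_that("an explicit overlapping chromosome plan is rejected", {
  genes <- data.frame(gene_id = c("g1", "g2"), protein = c("MKV", "MKV"),
                      chromosome = "chr1", strand = "+",
                      start = c(100L, 105L))
  set.seed(1)
  expect_error(embed_genes(genes), "invalid plan")
})

test_that("corruption kinds are validated and recorded", {
  genes <- data.frame(gene_id = "g1", protein = strrep("MKV", 50),
                      chromosome = "chr1", strand = "+",
                      repeat_start = 10L, repeat_end = 100L)
  set.seed(2)
  expect_error(embed_genes(genes, corruption = data.frame(gene_id = "g1",
                                                          kind = "explode")),
               "unknown corruption kind")
  set.seed(2)
  emb <- embed_genes(genes, corruption = data.frame(gene_id = "g1",
                                                    kind = "del"))
  expect_match(emb$genes$corruption, "^del@cds:")
  # a deletion shortens the CDS by one base
  expect_identical(emb$genes$end - emb$genes$start + 1L, 150L * 3L + 3L - 1L)
})

test_that("expression design places cognate-gland signal where configured", {
  truth <- data.frame(gene_id = c(sprintf("sp%02d", 1:5),
                                  sprintf("d%02d", 1:50)),
                      class = rep(c("spidroin", "decoy"), c(5, 50)),
                      type = c("MaSp1", "MaSp2", "MiSp", "FlSp", "TuSp",
                               rep(NA, 50)))
  des <- expression_design(fold = 1000)
  set.seed(31)
  ex <- make_expression(truth, des)
  argmax <- des$samples$tissue[apply(ex$values, 1, which.max)]
  # at fold 1000 every silk gene peaks in a cognate gland sample
  expect_true(all(argmax[1:2] %in% c("Tail", "Sac")))
  expect_identical(argmax[3:5], c("Mi", "Fl", "Tu"))
})

test_that("at fold 1 silk genes are indistinguishable from decoys", {
  truth <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      class = rep(c("spidroin", "decoy"), each = 50),
                      type = c(rep("MaSp1", 50), rep(NA, 50)))
  set.seed(17)
  ex <- make_expression(truth, expression_design(fold = 1))
  cols <- ex$samples$tissue %in% c("Tail", "Sac")
  p <- stats::wilcox.test(as.vector(ex$values[1:50, cols]),
                          as.vector(ex$values[51:100, cols]))$p.value
  expect_gt(p, 0.01)
})

test_that("expression regeneration under the same seed is bitwise identical", {
  truth <- data.frame(gene_id = c("a", "b"), class = c("spidroin", "decoy"),
                      type = c("MiSp", NA))
  set.seed(5)
  e1 <- make_expression(truth)
  set.seed(5)
  e2 <- make_expression(truth)
  expect_identical(e1$values, e2$values)
})

test_that("bundle writers and readers round-trip the bundle", {
  b <- shared_mini()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  rb <- read_bundle(dir)
  expect_identical(rb$genome, b$genome)
  expect_identical(rb$proteome, b$proteome)
  expect_equal(rb$genes, b$genes)
  expect_equal(rb$truth, b$truth)
  expect_identical(rb$expression$values, b$expression$values)
  expect_equal(rb$expression$samples, b$expression$samples)
  expect_equal(rb$termini, b$termini)
  expect_identical(rb$seed, b$seed)
})

test_that("every gene model id is exactly one of spidroin or decoy", {
  b <- shared_bundle()
  expect_setequal(b$genes$gene_id, b$truth$gene_id)
  expect_true(all(b$truth$class %in% c("spidroin", "decoy")))
  expect_identical(anyDuplicated(b$truth$gene_id), 0L)
})
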
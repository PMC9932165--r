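#' Write a synthetic bundle to a directory
#'
#' Plain-text formats throughout: genome and proteome FASTA (60-column
#' wrap), gene models as GFF3 (1-based closed, `ID=` attributes), truth and
#' expression as TSV (expression column headers are `sample:tissue`), the
#' terminal-domain library FASTA, and a flat key=value config file carrying
#' the seed. Numeric expression values are written with 17 significant
#' digits so the write/read round trip is exact.
#'
#' @param bundle a [make_bundle()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "silk_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(bundle$genome)
  Biostrings::writeXStringSet(g, file.path(dir, "genome.fa"), width = 60L)
  p <- Biostrings::AAStringSet(bundle$proteome)
  Biostrings::writeXStringSet(p, file.path(dir, "proteome.fa"), width = 60L)
  write_gff3_genes(bundle$genes, file.path(dir, "genes.gff3"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expr <- bundle$expression
  hdr <- paste(c("gene", paste(expr$samples$sample, expr$samples$tissue,
                               sep = ":")), collapse = "\t")
  lines <- vapply(seq_len(nrow(expr$values)), function(i) {
    paste(c(rownames(expr$values)[i], sprintf("%.17g", expr$values[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), file.path(dir, "expression.tsv"))
  write_termini_fasta(bundle$termini, file.path(dir, "termini.fasta"))
  cfg <- bundle$config
  writeLines(c(
    sprintf("seed=%d", bundle$seed),
    sprintf("n_decoys=%d", cfg$n_decoys),
    sprintf("substitution_rate=%g", cfg$substitution_rate),
    sprintf("unit_noise=%g", cfg$unit_noise),
    sprintf("gap_range=%d,%d", cfg$gap_range[1], cfg$gap_range[2]),
    sprintf("decoy_len_range=%d,%d", cfg$decoy_len_range[1],
            cfg$decoy_len_range[2])
  ), file.path(dir, "config.txt"))
  invisible(dir)
}

# Minimal GFF3 emitter for the bundle's single-exon gene annotation.
write_gff3_genes <- function(genes, path) {
  rows <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    gid <- genes$gene_id[i]
    base <- sprintf("%s\tspidroinr\t%%s\t%d\t%d\t.\t%s\t%%s\t%%s",
                    genes$chromosome[i], genes$start[i], genes$end[i],
                    genes$strand[i])
    c(sprintf(base, "gene", ".", sprintf("ID=%s", gid)),
      sprintf(base, "mRNA", ".", sprintf("ID=%s.t1;Parent=%s", gid, gid)),
      sprintf(base, "CDS", "0", sprintf("ID=%s.cds;Parent=%s.t1", gid, gid)))
  }))
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read a synthetic bundle back from a directory
#'
#' Inverse of [write_bundle()] for the data components (genome, gene
#' models, proteome, truth, expression, termini). Gene models are parsed
#' with `rtracklayer`.
#'
#' @param dir directory written by [write_bundle()]
#' @return a list of class `silk_bundle` (config reduced to the flat
#'   key=value fields)
#' @export
read_bundle <- function(dir) {
  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  genome <- setNames(as.character(g), names(g))
  p <- Biostrings::readAAStringSet(file.path(dir, "proteome.fa"))
  proteome <- setNames(as.character(p), names(p))
  gr <- rtracklayer::import(file.path(dir, "genes.gff3"))
  is_gene <- as.character(gr$type) == "gene"
  genes <- data.frame(
    gene_id = as.character(gr$ID[is_gene]),
    chromosome = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    stringsAsFactors = FALSE)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  expr_raw <- utils::read.delim(file.path(dir, "expression.tsv"),
                                check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(expr_raw[, -1, drop = FALSE])
  rownames(vals) <- expr_raw[[1]]
  hdr <- colnames(vals)
  samples <- data.frame(sample = sub(":.*$", "", hdr),
                        tissue = sub("^.*:", "", hdr),
                        stringsAsFactors = FALSE)
  colnames(vals) <- samples$sample
  termini <- read_termini_fasta(file.path(dir, "termini.fasta"))
  cfg_lines <- readLines(file.path(dir, "config.txt"))
  cfg <- setNames(sub("^[^=]*=", "", cfg_lines), sub("=.*$", "", cfg_lines))
  structure(list(genome = genome, genes = genes, proteome = proteome,
                 truth = truth,
                 expression = list(values = vals, samples = samples),
                 termini = termini, config = as.list(cfg),
                 seed = as.integer(cfg[["seed"]])),
            class = "silk_bundle")
}
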
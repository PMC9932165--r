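#' Tryptic digest of a protein
#'
#' Cleaves after K or R except when the next residue is P; zero missed
#' cleavages. The peptides tile the protein exactly.
#'
#' @param protein protein sequence
#' @return data.frame of class `peptide_digest`: `peptide`, `start`, `end`
#'   (1-based closed spans in the parent protein)
#' @export
tryptic_digest <- function(protein) {
  protein <- check_protein(protein, what = "protein")
  x <- seq_chars(protein)
  L <- length(x)
  if (L == 0L) {
    return(structure(data.frame(peptide = character(), start = integer(),
                                end = integer(), stringsAsFactors = FALSE),
                     class = c("peptide_digest", "data.frame")))
  }
  cut <- which(x %in% c("K", "R"))
  cut <- cut[cut < L & x[pmin(cut + 1L, L)] != "P"]
  ends <- unique(c(cut, L))
  starts <- c(1L, head(ends, -1L) + 1L)
  structure(data.frame(peptide = substring(protein, starts, ends),
                       start = starts, end = ends, stringsAsFactors = FALSE),
            class = c("peptide_digest", "data.frame"))
}

#' Count theoretically observable peptides
#'
#' Peptides within the mass-spectrometric length window; this count is the
#' iBAQ denominator.
#'
#' @param digest a [tryptic_digest()] result (or any data.frame with a
#'   `peptide` column)
#' @param min_len,max_len inclusive length window (residues)
#' @return integer count
#' @export
count_theoretical_peptides <- function(digest, min_len = 7L, max_len = 30L) {
  len <- nchar(digest$peptide)
  sum(len >= min_len & len <= max_len)
}

#' iBAQ quantification of a protein catalog
#'
#' iBAQ = summed intensity / max(1, theoretical peptide count); the share
#' of each record is its iBAQ as a percentage of the catalog total. Peptide
#' counts are taken from a `peptides` column, or computed by tryptic digest
#' of a `protein` column.
#'
#' @param records data.frame with `id`, `class`, `intensity` (>= 0, at
#'   least one positive), and `peptides` or `protein`
#' @param min_len,max_len peptide length window for the digest-based count
#' @return object of class `silk_proteome_catalog`: the records with
#'   `peptides`, `ibaq` and `share` (% of total, summing to 100)
#' @export
ibaq_quantify <- function(records, min_len = 7L, max_len = 30L) {
  stopifnot(all(c("id", "class", "intensity") %in% names(records)))
  if (any(records$intensity < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  if (all(records$intensity == 0)) {
    stop("all intensities are zero", call. = FALSE)
  }
  if (!"peptides" %in% names(records)) {
    if (!"protein" %in% names(records)) {
      stop("records need a 'peptides' count or a 'protein' sequence column",
           call. = FALSE)
    }
    records$peptides <- vapply(records$protein, function(p) {
      count_theoretical_peptides(tryptic_digest(p), min_len, max_len)
    }, integer(1), USE.NAMES = FALSE)
  }
  records$ibaq <- records$intensity / pmax(1L, records$peptides)
  records$share <- 100 * records$ibaq / sum(records$ibaq)
  structure(records, class = c("silk_proteome_catalog", "data.frame"))
}

#' Cumulative share of the k most abundant proteins
#'
#' @param catalog an [ibaq_quantify()] catalog
#' @param k number of top records (<= record count)
#' @return percentage in `[0, 100]`
#' @export
topk_cumulative_share <- function(catalog, k) {
  stopifnot(k >= 0, k <= nrow(catalog))
  sum(sort(catalog$share, decreasing = TRUE)[seq_len(k)])
}

#' Tally a silk proteome catalog by class
#'
#' Spidroin classes are MaSp and MiSp; everything else counts as
#' nonspidroin.
#'
#' @param catalog a data.frame with a `class` column
#' @return list: `by_class` (named counts), `spidroin`, `nonspidroin`,
#'   `total`
#' @export
tally_proteome <- function(catalog) {
  by_class <- table(catalog$class)
  spid <- sum(catalog$class %in% c("MaSp", "MiSp"))
  list(by_class = setNames(as.integer(by_class), names(by_class)),
       spidroin = spid, nonspidroin = nrow(catalog) - spid,
       total = nrow(catalog))
}

#' Tally a metabolite catalog by category
#'
#' Unclassified records (empty or `NA` category) count toward the overall
#' total only.
#'
#' @param catalog data.frame with `name` and `category` columns
#' @return list: `by_category` (named counts), `classified`, `categories`,
#'   `total`
#' @export
tally_metabolites <- function(catalog) {
  cat_ok <- !is.na(catalog$category) & nzchar(catalog$category)
  by_cat <- table(catalog$category[cat_ok])
  list(by_category = setNames(as.integer(by_cat), names(by_cat)),
       classified = sum(cat_ok), categories = length(by_cat),
       total = nrow(catalog))
}

#' Bundled dragline-silk proteome table
#'
#' A synthetic stand-in table (ids and intensities constructed, not
#' measured) whose iBAQ shares reproduce the published dragline-silk
#' composition pattern: 28 proteins, 10 spidroins (9 MaSp + 1 MiSp) and 18
#' nonspidroin components, with the five dominant records at
#' 37.7/12.2/11.9/10.4/7.2% of total iBAQ.
#'
#' @return data.frame with `id`, `class`, `intensity`, `peptides`
#' @export
dragline_proteome_table <- function() {
  utils::read.delim(system.file("extdata", "dragline_proteome_synthetic.tsv",
                                package = "spidroinr", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Bundled dragline-silk metabolite table
#'
#' A synthetic stand-in table (names constructed) reproducing the published
#' category structure: 180 metabolites, 109 of them classified into ten
#' categories.
#'
#' @return data.frame with `name`, `category`, `intensity`
#' @export
dragline_metabolite_table <- function() {
  utils::read.delim(system.file("extdata", "dragline_metabolites_synthetic.tsv",
                                package = "spidroinr", mustWork = TRUE),
                    stringsAsFactors = FALSE, na.strings = "")
}

#' Bundled spidroin gene catalog table
#'
#' The reference orb-weaver spidroin catalog used for worked examples:
#' 28 genes, 26 full-length (9 MaSp, 5 MiSp, 2 FlSp, 1 TuSp, 2 AgSp,
#' 1 AcSp, 1 PySp, 5 other) plus 2 partial entries. Gene ids are synthetic
#' placeholders.
#'
#' @return a `spidroin_catalog`
#' @export
reference_catalog <- function() {
  calls <- utils::read.delim(
    system.file("extdata", "spidroin_catalog_reference.tsv",
                package = "spidroinr", mustWork = TRUE),
    stringsAsFactors = FALSE)
  structure(list(calls = calls, species = "T_clavata_like"),
            class = "spidroin_catalog")
}
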
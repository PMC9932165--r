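#' Assign a spidroin type from terminal-domain hits
#'
#' Bit-score-weighted vote: the type with the largest summed bit score over
#' the gene's hits wins. Ties break by the highest single bit score, then
#' by C-terminus evidence, then lexicographically. Confidence is the
#' winner's share of the total bit score.
#'
#' @param hits data.frame of one gene's hits (see [search_termini()])
#' @return list of class `spidroin_call`: `type`, `confidence`,
#'   `evidence` (hit reference ids)
#' @export
assign_type <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) {
    stop("cannot classify a gene without hits", call. = FALSE)
  }
  sums <- tapply(hits$bits, hits$type, sum)
  best <- max(sums)
  cand <- names(sums)[sums == best]
  if (length(cand) > 1L) {
    top_single <- vapply(cand, function(tp) max(hits$bits[hits$type == tp]),
                         numeric(1))
    cand <- cand[top_single == max(top_single)]
  }
  if (length(cand) > 1L) {
    has_c <- vapply(cand, function(tp) {
      any(hits$type == tp & hits$terminus %in% c("C", "complete"))
    }, logical(1))
    if (any(has_c)) cand <- cand[has_c]
  }
  type <- sort(cand)[1L]
  structure(list(type = type, confidence = unname(best / sum(sums)),
                 evidence = unique(hits$ref[hits$type == type])),
            class = "spidroin_call")
}

#' Build a typed spidroin catalog from search hits
#'
#' One call per distinct query gene with hits, combining [assign_type()]
#' with per-gene completeness (from architecture calls, when given).
#'
#' @param hits data.frame of hits for all genes
#' @param completeness optional named character vector (per gene) of
#'   architecture classifications
#' @param species species label for the catalog
#' @return object of class `spidroin_catalog` with a `calls` data.frame
#'   (`gene_id`, `type`, `confidence`, `completeness`) and `species`
#' @export
build_catalog <- function(hits, completeness = NULL, species = "synthetic") {
  genes <- unique(hits$query)
  calls <- do.call(rbind, lapply(genes, function(g) {
    a <- assign_type(hits[hits$query == g, , drop = FALSE])
    data.frame(gene_id = g, type = a$type, confidence = a$confidence,
               completeness = if (is.null(completeness)) NA_character_
                              else unname(completeness[g]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(calls)) {
    calls <- data.frame(gene_id = character(), type = character(),
                        confidence = numeric(), completeness = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(calls = calls, species = species),
            class = "spidroin_catalog")
}

#' Tally a spidroin catalog
#'
#' @param catalog a `spidroin_catalog` (or any list with a `calls`
#'   data.frame carrying `type` and `completeness`)
#' @return list: `by_type` (named counts), `full_length`, `partial`,
#'   `total`
#' @export
tally_catalog <- function(catalog) {
  calls <- catalog$calls
  by_type <- table(calls$type)
  list(by_type = setNames(as.integer(by_type), names(by_type)),
       full_length = sum(calls$completeness == "full-length", na.rm = TRUE),
       partial = sum(calls$completeness == "partial", na.rm = TRUE),
       total = nrow(calls))
}

# Superfamily of a type: MaSp1/MaSp2 -> MaSp; everything else is itself.
superfamily <- function(type) sub("^(MaSp)[0-9].*$", "\\1", type)

#' Detect chromosomal groups of spidroin genes
#'
#' Single-linkage clustering per chromosome: adjacent genes (by span) join
#' one group when the gap between their spans is at most `max_gap`. Groups
#' of at least `min_size` members are reported, labelled by the majority
#' superfamily (mixed membership allowed).
#'
#' @param calls data.frame with `gene_id`, `type`, `chromosome`, `start`,
#'   `end`
#' @param max_gap maximum gap (nt) between adjacent member spans
#' @param min_size minimum group size
#' @return data.frame: `group`, `chromosome`, `label`, `size`, `start`,
#'   `end`, `members` (comma-separated gene ids)
#' @export
detect_groups <- function(calls, max_gap = 1e6, min_size = 3L) {
  need <- c("gene_id", "type", "chromosome", "start", "end")
  stopifnot(all(need %in% names(calls)))
  miss <- calls$gene_id[is.na(calls$start) | is.na(calls$end) |
                          is.na(calls$chromosome)]
  if (length(miss) > 0L) {
    stop(sprintf("missing coordinates for gene %s", miss[[1L]]),
         call. = FALSE)
  }
  out <- list()
  for (chrom in unique(calls$chromosome)) {
    d <- calls[calls$chromosome == chrom, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    gap <- d$start[-1L] - d$end[-nrow(d)]
    grp <- cumsum(c(1L, as.integer(gap > max_gap)))
    for (g in unique(grp)) {
      m <- d[grp == g, , drop = FALSE]
      if (nrow(m) < min_size) next
      fams <- table(superfamily(m$type))
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom,
        label = names(fams)[which.max(fams)],
        size = nrow(m), start = min(m$start), end = max(m$end),
        members = paste(m$gene_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chromosome = character(), label = character(),
                      size = integer(), start = integer(), end = integer(),
                      members = character(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$chromosome, res$start), , drop = FALSE]
  res$group <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("group", "chromosome", "label", "size", "start", "end", "members")]
}

#' Compare spidroin catalogs across species
#'
#' @param catalogs list of `spidroin_catalog`s
#' @return integer matrix, species (rows, input order) by type (columns);
#'   row sums equal catalog sizes
#' @export
compare_catalogs <- function(catalogs) {
  stopifnot(length(catalogs) >= 1L)
  types <- sort(unique(unlist(lapply(catalogs, function(ct) ct$calls$type))))
  mat <- t(vapply(catalogs, function(ct) {
    counts <- table(factor(ct$calls$type, levels = types))
    setNames(as.integer(counts), types)
  }, setNames(integer(length(types)), types)))
  rownames(mat) <- vapply(catalogs, function(ct) ct$species, character(1))
  mat
}
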
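#' FPKM from raw counts
#'
#' `FPKM = counts * 1e9 / (length * library_size)` — fragments per kilobase
#' of transcript per million mapped fragments.
#'
#' @param counts genes x samples matrix of fragment counts
#' @param lengths effective transcript lengths (nt), one per gene, all > 0
#' @param lib_sizes library sizes (mapped fragments), one per sample, > 0
#' @return FPKM matrix of the same shape
#' @export
fpkm <- function(counts, lengths, lib_sizes) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts),
            length(lib_sizes) == ncol(counts))
  if (any(lengths <= 0)) stop("transcript lengths must be > 0", call. = FALSE)
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0", call. = FALSE)
  counts * 1e9 / outer(lengths, lib_sizes)
}

# Per-tissue mean profile of an expression matrix.
tissue_means <- function(values, tissues) {
  stopifnot(length(tissues) == ncol(values))
  groups <- unique(tissues)
  out <- vapply(groups, function(tt) {
    rowMeans(values[, tissues == tt, drop = FALSE])
  }, numeric(nrow(values)))
  if (nrow(values) == 1L) out <- matrix(out, nrow = 1L,
                                        dimnames = list(rownames(values),
                                                        groups))
  out
}

#' Tissue specificity index tau
#'
#' `tau = sum(1 - x_i / x_max) / (N - 1)` over tissue-mean expression:
#' 0 for a uniform profile, 1 for single-tissue expression.
#'
#' @param values genes x samples FPKM matrix
#' @param tissues tissue label per sample
#' @param threshold tau at or above which a gene is flagged specific
#' @return data.frame: `gene_id`, `tau`, `argmax_tissue`, `specific`
#' @export
tau_specificity <- function(values, tissues, threshold = 0.8) {
  means <- tissue_means(values, tissues)
  if (ncol(means) < 2L) stop("need at least two tissues", call. = FALSE)
  xmax <- apply(means, 1L, max)
  if (any(xmax <= 0)) stop("every gene needs a positive maximum",
                           call. = FALSE)
  tau <- rowSums(1 - means / xmax) / (ncol(means) - 1L)
  data.frame(gene_id = rownames(values) %||% seq_len(nrow(values)),
             tau = unname(tau),
             argmax_tissue = colnames(means)[apply(means, 1L, which.max)],
             specific = unname(tau >= threshold),
             stringsAsFactors = FALSE)
}

#' Silk transcriptional load of a gland segment
#'
#' The fraction of a segment's total FPKM contributed by the silk genes:
#' sum of silk-gene FPKM over the segment's samples divided by the total
#' FPKM over those samples.
#'
#' @param values genes x samples FPKM matrix (rownames = gene ids)
#' @param silk_ids silk gene ids (must all be rows of `values`)
#' @param segment focal segment/tissue label
#' @param tissues tissue label per sample
#' @return fraction in `[0, 1]`
#' @export
silk_load <- function(values, silk_ids, segment, tissues) {
  stopifnot(all(silk_ids %in% rownames(values)))
  cols <- tissues == segment
  if (!any(cols)) stop(sprintf("no samples for segment '%s'", segment),
                       call. = FALSE)
  sum(values[silk_ids, cols, drop = FALSE]) / sum(values[, cols, drop = FALSE])
}

#' Screen segment-specific genes
#'
#' A gene is specific to a segment when its mean FPKM there is at least
#' `min_fpkm` and at least `min_fold` times its mean FPKM in every other
#' segment.
#'
#' @param values genes x samples FPKM matrix
#' @param tissues tissue label per sample (>= 2 distinct)
#' @param min_fpkm minimum mean FPKM in the focal segment
#' @param min_fold minimum fold over every other segment
#' @return named list of gene-id vectors, one per segment
#' @export
segment_specific_genes <- function(values, tissues, min_fpkm = 1,
                                   min_fold = 4) {
  means <- tissue_means(values, tissues)
  if (ncol(means) < 2L) stop("need at least two segments", call. = FALSE)
  ids <- rownames(values) %||% as.character(seq_len(nrow(values)))
  out <- lapply(colnames(means), function(seg) {
    focal <- means[, seg]
    others <- means[, colnames(means) != seg, drop = FALSE]
    ids[focal >= min_fpkm & apply(others * min_fold <= focal, 1L, all)]
  })
  setNames(out, colnames(means))
}

#' Annotation-integration filter
#'
#' Keep a gene model iff its repeat-sequence proportion is below 0.5, its
#' protein is longer than 50 aa, it has FPKM > 0.1 in at least
#' `min_support` samples, and it is supported by Iso-seq (identity > 95%)
#' or by a homolog (E < 1e-5 and identity > 50%). Inequalities are strict
#' except the support-sample count; each dropped gene carries the first
#' failing reason among `repeat`, `length`, `expression`, `evidence`.
#'
#' @param evidence data.frame with columns `gene_id`, `repeat_prop`,
#'   `length_aa`, `n_expressed`, `isoseq_identity`, `homolog_evalue`,
#'   `homolog_identity` (use `NA` identities/E-values for "no evidence")
#' @param max_repeat,min_length,min_support,min_isoseq,max_homolog_e,min_homolog_id
#'   the five thresholds (defaults as described)
#' @return the input with logical `keep` and character `reason`
#'   (`NA` for kept genes) appended
#' @export
integration_filter <- function(evidence, max_repeat = 0.5, min_length = 50,
                               min_support = 10, min_isoseq = 95,
                               max_homolog_e = 1e-5, min_homolog_id = 50) {
  need <- c("gene_id", "repeat_prop", "length_aa", "n_expressed",
            "isoseq_identity", "homolog_evalue", "homolog_identity")
  for (f in need) {
    if (!f %in% names(evidence)) {
      stop(sprintf("evidence table lacks field '%s'", f), call. = FALSE)
    }
  }
  for (f in setdiff(need, c("gene_id", "isoseq_identity", "homolog_evalue",
                            "homolog_identity"))) {
    bad <- which(is.na(evidence[[f]]))
    if (length(bad) > 0L) {
      stop(sprintf("missing field '%s' for gene %s", f,
                   evidence$gene_id[bad[1L]]), call. = FALSE)
    }
  }
  iso_ok <- !is.na(evidence$isoseq_identity) &
    evidence$isoseq_identity > min_isoseq
  hom_ok <- !is.na(evidence$homolog_evalue) &
    !is.na(evidence$homolog_identity) &
    evidence$homolog_evalue < max_homolog_e &
    evidence$homolog_identity > min_homolog_id
  pass_repeat <- evidence$repeat_prop < max_repeat
  pass_length <- evidence$length_aa > min_length
  pass_expr <- evidence$n_expressed >= min_support
  pass_evid <- iso_ok | hom_ok
  keep <- pass_repeat & pass_length & pass_expr & pass_evid
  reason <- rep(NA_character_, nrow(evidence))
  reason[!pass_evid] <- "evidence"
  reason[!pass_expr] <- "expression"
  reason[!pass_length] <- "length"
  reason[!pass_repeat] <- "repeat"
  reason[keep] <- NA_character_
  evidence$keep <- keep
  evidence$reason <- reason
  evidence
}

#' Pearson correlation between segment mean profiles
#'
#' @param values genes x samples FPKM matrix (>= 2 genes)
#' @param tissues tissue label per sample
#' @return symmetric correlation matrix (diagonal 1) over segments
#' @export
segment_correlation <- function(values, tissues) {
  if (nrow(values) < 2L) stop("need at least two genes", call. = FALSE)
  stats::cor(tissue_means(values, tissues))
}
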
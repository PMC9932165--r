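#' Silk repeat motif grammar
#'
#' A generative model of a spidroin repeat unit. Units are built by drawing
#' motif emissions — poly-alanine runs `(A)n`, glycine-alanine dyad arrays
#' `(GA)n`, `GGX`, `GPGXX`, `XQQ`, and single spacer residues — with the
#' given class weights until the unit length falls inside `unit_len`.
#' The same five motif classes are what [count_motifs()] quantifies, so a
#' grammar doubles as the analytic expectation model for repeat composition.
#'
#' @param weights named non-negative numeric weights for classes
#'   `polyA`, `GA`, `GGX`, `GPGXX`, `XQQ`, `spacer`; at least one > 0.
#' @param polyA_len list with integer `values` (all >= 4) and `probs`
#'   for the poly-alanine run length.
#' @param ga_dyads list with integer `values` (all >= 2) and `probs`
#'   for the number of GA dyads in a `(GA)n` array.
#' @param spacer_freqs named probabilities over residues used for spacers
#'   and for the `X` positions of GGX/GPGXX/XQQ.
#' @param unit_len integer length-2 vector, min/max unit length (residues).
#' @return an object of class `motif_grammar`
#' @export
motif_grammar <- function(weights = c(polyA = 0.2, GA = 0.1, GGX = 0.4,
                                      GPGXX = 0.05, XQQ = 0.05, spacer = 0.2),
                          polyA_len = list(values = 4:8,
                                           probs = c(.15, .3, .3, .15, .1)),
                          ga_dyads = list(values = 2:5,
                                          probs = c(.4, .3, .2, .1)),
                          spacer_freqs = c(G = .25, A = .2, S = .2, Q = .15,
                                           Y = .1, L = .1),
                          unit_len = c(24L, 40L)) {
  classes <- c("polyA", "GA", "GGX", "GPGXX", "XQQ", "spacer")
  w <- setNames(numeric(6), classes)
  w[names(weights)] <- weights
  if (any(w < 0) || all(w == 0)) {
    stop("invalid grammar configuration: weights must be >= 0 with at least one > 0",
         call. = FALSE)
  }
  if (any(polyA_len$values < 4L)) {
    stop("invalid grammar configuration: poly-A run lengths must be >= 4",
         call. = FALSE)
  }
  if (any(ga_dyads$values < 2L)) {
    stop("invalid grammar configuration: GA dyad counts must be >= 2",
         call. = FALSE)
  }
  stopifnot(length(polyA_len$values) == length(polyA_len$probs),
            length(ga_dyads$values) == length(ga_dyads$probs),
            all(polyA_len$probs >= 0), sum(polyA_len$probs) > 0,
            all(ga_dyads$probs >= 0), sum(ga_dyads$probs) > 0,
            all(spacer_freqs >= 0), sum(spacer_freqs) > 0,
            length(unit_len) == 2L, unit_len[1] >= 1L,
            unit_len[2] >= unit_len[1])
  structure(list(
    weights = w / sum(w),
    polyA_len = list(values = as.integer(polyA_len$values),
                     probs = polyA_len$probs / sum(polyA_len$probs)),
    ga_dyads = list(values = as.integer(ga_dyads$values),
                    probs = ga_dyads$probs / sum(ga_dyads$probs)),
    spacer_freqs = spacer_freqs / sum(spacer_freqs),
    unit_len = as.integer(unit_len)
  ), class = "motif_grammar")
}

#' Preset grammars for the spidroin families
#'
#' Weights follow the families' characteristic repeat chemistry: MaSp1 is
#' GGX/poly-A dominated, MaSp2 carries GPGXX and XQQ (proline/glutamine
#' rich), MiSp is (GA)n-heavy, FlSp is GPGXX-dominated, and the
#' tubuliform/aggregate/aciniform/pyriform/other families are spacer-rich
#' with modest motif content.
#'
#' @param type spidroin family, one of `MaSp1`, `MaSp2`, `MiSp`, `FlSp`,
#'   `TuSp`, `AgSp`, `AcSp`, `PySp`, `other`
#' @return a `motif_grammar`
#' @export
default_grammar <- function(type = "MaSp1") {
  type <- match.arg(type, spidroin_types())
  w <- switch(type,
    MaSp1 = c(polyA = .25, GA = .15, GGX = .40, GPGXX = .02, XQQ = .03, spacer = .15),
    MaSp2 = c(polyA = .25, GA = .05, GGX = .10, GPGXX = .35, XQQ = .15, spacer = .10),
    MiSp  = c(polyA = .10, GA = .40, GGX = .30, GPGXX = .02, XQQ = .03, spacer = .15),
    FlSp  = c(polyA = .02, GA = .05, GGX = .25, GPGXX = .50, XQQ = .03, spacer = .15),
    TuSp  = c(polyA = .15, GA = .05, GGX = .10, GPGXX = .05, XQQ = .15, spacer = .50),
    AgSp  = c(polyA = .05, GA = .05, GGX = .15, GPGXX = .10, XQQ = .20, spacer = .45),
    AcSp  = c(polyA = .10, GA = .05, GGX = .15, GPGXX = .05, XQQ = .10, spacer = .55),
    PySp  = c(polyA = .08, GA = .05, GGX = .12, GPGXX = .05, XQQ = .25, spacer = .45),
    other = c(polyA = .15, GA = .10, GGX = .25, GPGXX = .10, XQQ = .10, spacer = .30)
  )
  motif_grammar(weights = w)
}

#' Canonical spidroin type vocabulary
#' @return character vector of the recognised spidroin types
#' @export
spidroin_types <- function() {
  c("MaSp1", "MaSp2", "MiSp", "FlSp", "TuSp", "AgSp", "AcSp", "PySp", "other")
}

# One emission from a motif class, using the caller's RNG stream.
emit_motif <- function(grammar, class) {
  sf <- grammar$spacer_freqs
  draw_x <- function(n) sample(names(sf), n, replace = TRUE, prob = sf)
  switch(class,
    polyA = strrep("A", sample1(grammar$polyA_len$values,
                                prob = grammar$polyA_len$probs)),
    GA = strrep("GA", sample1(grammar$ga_dyads$values,
                              prob = grammar$ga_dyads$probs)),
    GGX = paste0("GG", draw_x(1L)),
    GPGXX = paste0("GPG", paste(draw_x(2L), collapse = "")),
    XQQ = paste0(draw_x(1L), "QQ"),
    spacer = draw_x(1L)
  )
}

#' Draw one repeat unit from a motif grammar
#'
#' Emissions are appended until the unit reaches the grammar's minimum
#' length; the unit is truncated at the maximum length. Uses the current
#' RNG stream: seed the session (or call from a seeded generator) for
#' reproducible units.
#'
#' @param grammar a [motif_grammar()]
#' @return a single protein string
#' @export
make_repeat_unit <- function(grammar) {
  stopifnot(inherits(grammar, "motif_grammar"))
  classes <- names(grammar$weights)
  out <- character(0)
  len <- 0L
  while (len < grammar$unit_len[1]) {
    cl <- sample(classes, 1L, prob = grammar$weights)
    em <- emit_motif(grammar, cl)
    out <- c(out, em)
    len <- len + nchar(em)
  }
  unit <- paste(out, collapse = "")
  if (nchar(unit) > grammar$unit_len[2]) {
    unit <- substr(unit, 1L, grammar$unit_len[2])
  }
  unit
}

#' Expected residue composition of a grammar
#'
#' Ratio-of-expectations composition: expected residue counts per emission,
#' averaged over the class weights, divided by the expected emission length.
#' This is the analytic target that long runs of [make_repeat_unit()]
#' approach (up to the small bias introduced by length truncation).
#'
#' @param grammar a [motif_grammar()]
#' @return named numeric vector of expected fractions over residues
#' @export
expected_composition <- function(grammar) {
  stopifnot(inherits(grammar, "motif_grammar"))
  sf <- grammar$spacer_freqs
  res <- union(c("A", "G", "P", "Q"), names(sf))
  counts <- setNames(numeric(length(res)), res)
  add <- function(counts, w, contrib) {
    counts[names(contrib)] <- counts[names(contrib)] + w * contrib
    counts
  }
  w <- grammar$weights
  e_polyA <- sum(grammar$polyA_len$values * grammar$polyA_len$probs)
  e_dyads <- sum(grammar$ga_dyads$values * grammar$ga_dyads$probs)
  counts <- add(counts, w[["polyA"]], c(A = e_polyA))
  counts <- add(counts, w[["GA"]], c(G = e_dyads, A = e_dyads))
  counts <- add(counts, w[["GGX"]], c(G = 2))
  counts <- add(counts, w[["GGX"]], setNames(as.numeric(sf), names(sf)))
  counts <- add(counts, w[["GPGXX"]], c(G = 2, P = 1))
  counts <- add(counts, w[["GPGXX"]], setNames(2 * as.numeric(sf), names(sf)))
  counts <- add(counts, w[["XQQ"]], c(Q = 2))
  counts <- add(counts, w[["XQQ"]], setNames(as.numeric(sf), names(sf)))
  counts <- add(counts, w[["spacer"]], setNames(as.numeric(sf), names(sf)))
  e_len <- w[["polyA"]] * e_polyA + w[["GA"]] * 2 * e_dyads +
    w[["GGX"]] * 3 + w[["GPGXX"]] * 5 + w[["XQQ"]] * 3 + w[["spacer"]] * 1
  counts / e_len
}
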
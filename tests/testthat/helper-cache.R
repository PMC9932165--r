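# Expensive shared objects, computed once per test session.
.test_cache <- new.env(parent = emptyenv())

shared_refdb <- function() {
  if (is.null(.test_cache$refdb)) {
    .test_cache$refdb <- default_termini_library()
  }
  .test_cache$refdb
}

shared_bundle <- function() {
  if (is.null(.test_cache$bundle)) {
    .test_cache$bundle <- make_bundle(seed = 101L)
  }
  .test_cache$bundle
}

shared_hits <- function() {
  if (is.null(.test_cache$hits)) {
    b <- shared_bundle()
    .test_cache$hits <- search_termini(b$proteome, shared_refdb())
  }
  .test_cache$hits
}

shared_assembly <- function() {
  if (is.null(.test_cache$assembly)) {
    b <- shared_bundle()
    .test_cache$assembly <- assemble_gene_models(b$genome, shared_refdb())
  }
  .test_cache$assembly
}

# A small, noise-free bundle: exact round trips through the genome.
mini_config <- function() {
  cfg <- default_bundle_config(n_decoys = 5L,
                               substitution_rate = 0,
                               unit_noise = 0,
                               gap_range = c(300L, 600L))
  cfg$spidroins <- cfg$spidroins[c(1L, 3L, 9L), ]   # MaSp1a, MaSp1c(-), MiSp-a
  cfg$corruption <- NULL
  cfg
}

shared_mini <- function() {
  if (is.null(.test_cache$mini)) {
    .test_cache$mini <- make_bundle(mini_config(), seed = 7L)
  }
  .test_cache$mini
}

shared_mini_assembly <- function() {
  if (is.null(.test_cache$mini_assembly)) {
    .test_cache$mini_assembly <-
      assemble_gene_models(shared_mini()$genome, shared_refdb())
  }
  .test_cache$mini_assembly
}
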
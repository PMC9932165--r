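test_that("FPKM follows the definition", {
  counts <- matrix(c(0, 100), nrow = 2,
                   dimnames = list(c("g0", "g1"), "s1"))
  out <- fpkm(counts, lengths = c(500, 1000), lib_sizes = 1e6)
  expect_identical(out["g0", 1], 0)
  expect_identical(out["g1", 1], 100)
  # doubling the library size halves FPKM
  out2 <- fpkm(counts, lengths = c(500, 1000), lib_sizes = 2e6)
  expect_equal(out2, out / 2)
  expect_error(fpkm(counts, lengths = c(0, 1000), lib_sizes = 1e6), "> 0")
})

test_that("tau spans uniform to single-tissue expression", {
  tissues <- c("a", "b", "c")
  m <- rbind(uniform = c(5, 5, 5), single = c(9, 0, 0), mixed = c(10, 5, 0))
  out <- tau_specificity(m, tissues)
  expect_equal(out$tau, c(0, 1, 0.75))
  expect_identical(out$argmax_tissue, c("a", "a", "a"))
  expect_identical(out$specific, c(FALSE, TRUE, FALSE))
  expect_error(tau_specificity(m[, 1, drop = FALSE], "a"), "two tissues")
})

test_that("silk load is a fraction of segment FPKM and partitions to one", {
  m <- matrix(c(80, 20, 10, 30), nrow = 2,
              dimnames = list(c("silk", "bg"), c("T1", "T2")))
  tissues <- c("Tail", "Duct")
  expect_equal(silk_load(m, "silk", "Tail", tissues), 0.8)
  expect_equal(silk_load(m, c("silk", "bg"), "Tail", tissues), 1.0)
  expect_equal(silk_load(m, "silk", "Tail", tissues) +
                 silk_load(m, "bg", "Tail", tissues), 1.0)
  expect_error(silk_load(m, "silk", "Sac", tissues), "no samples")
})

test_that("synthetic Tail/Sac silk loads dominate the Duct", {
  b <- shared_bundle()
  ex <- b$expression
  silk <- b$truth$gene_id[b$truth$class == "spidroin" &
                            b$truth$type %in% c("MaSp1", "MaSp2")]
  tail_load <- silk_load(ex$values, silk, "Tail", ex$samples$tissue)
  sac_load <- silk_load(ex$values, silk, "Sac", ex$samples$tissue)
  duct_load <- silk_load(ex$values, silk, "Duct", ex$samples$tissue)
  # in the Duct the silk genes sit at baseline, so their load there is
  # bounded by their share of the gene count (~13%), far below Tail/Sac
  expect_gt(tail_load, 0.3)
  expect_gt(sac_load, 0.3)
  expect_lt(duct_load, 0.2)
  expect_gt(tail_load, 5 * duct_load)
  expect_gt(sac_load, 5 * duct_load)
})

test_that("segment-specific screening applies the fpkm and fold rules", {
  m <- rbind(tailspec = c(100, 100, 1, 1, 1, 1),
             uniform = c(5, 5, 5, 5, 5, 5),
             weak = c(0.5, 0.5, 0.1, 0.1, 0.1, 0.1))
  tissues <- rep(c("Tail", "Sac", "Duct"), each = 2)
  sets <- segment_specific_genes(m, tissues)
  expect_identical(sets$Tail, "tailspec")
  expect_identical(sets$Sac, character(0))
  expect_identical(sets$Duct, character(0))
  # lowering min_fold never shrinks a set
  sets2 <- segment_specific_genes(m, tissues, min_fold = 2)
  expect_true(all(sets$Tail %in% sets2$Tail))
})

test_that("integration filter drops by the first failing rule", {
  row <- function(...) {
    d <- data.frame(gene_id = "g", repeat_prop = 0.1, length_aa = 300,
                    n_expressed = 20, isoseq_identity = 99,
                    homolog_evalue = NA, homolog_identity = NA,
                    stringsAsFactors = FALSE)
    mod <- list(...)
    for (f in names(mod)) d[[f]] <- mod[[f]]
    d
  }
  expect_true(integration_filter(row())$keep)
  out <- integration_filter(row(repeat_prop = 0.6))
  expect_false(out$keep)
  expect_identical(out$reason, "repeat")
  # boundary values drop under strict inequalities
  expect_false(integration_filter(row(repeat_prop = 0.5))$keep)
  expect_false(integration_filter(row(length_aa = 50))$keep)
  expect_false(integration_filter(row(isoseq_identity = 95))$keep)
  # support-sample rule is >= 10
  expect_true(integration_filter(row(n_expressed = 10))$keep)
  expect_false(integration_filter(row(n_expressed = 9))$keep)
  # homolog evidence can replace Iso-seq support
  hom <- row(isoseq_identity = NA, homolog_evalue = 1e-8,
             homolog_identity = 70)
  expect_true(integration_filter(hom)$keep)
  expect_error(integration_filter(row()[, -2]), "repeat_prop")
})

test_that("segment correlations match the textbook formula", {
  set.seed(41)
  m <- matrix(rlnorm(300), nrow = 50)
  tissues <- rep(c("Tail", "Sac", "Duct"), each = 2)
  out <- segment_correlation(m, tissues)
  expect_equal(diag(out), setNames(rep(1, 3), c("Tail", "Sac", "Duct")))
  expect_equal(out, t(out))
  # textbook covariance-based recomputation for one pair
  a <- rowMeans(m[, 1:2]); b <- rowMeans(m[, 3:4])
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(out["Tail", "Sac"], r)
  # identical and anti-ordered profiles
  m2 <- rbind(c(1, 5), c(2, 4))
  expect_equal(segment_correlation(m2, c("x", "y"))["x", "y"], -1)
  m3 <- rbind(c(1, 1), c(2, 2))
  expect_equal(segment_correlation(m3, c("x", "y"))["x", "y"], 1)
})
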
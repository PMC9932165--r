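#!/usr/bin/env Rscript
# Gland expression analytics on the synthetic matrix: tau specificity,
# silk transcriptional load of the Ma segments, segment-specific gene
# screens, and segment correlations.

suppressMessages(library(spidroinr))

bundle <- read_bundle("results/bundle")
ex <- bundle$expression
tissues <- ex$samples$tissue
truth <- bundle$truth

tau <- tau_specificity(ex$values, tissues)
write.table(tau, "results/tau_specificity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
silk_all <- truth$gene_id[truth$class == "spidroin"]
cat(sprintf("gland-specific genes (tau >= 0.8): %d of %d; spidroins among them: %d/%d\n",
            sum(tau$specific), nrow(tau),
            sum(tau$specific & tau$gene_id %in% silk_all),
            length(silk_all)))

ma_silk <- truth$gene_id[truth$class == "spidroin" &
                           truth$type %in% c("MaSp1", "MaSp2")]
loads <- vapply(c("Tail", "Sac", "Duct"), function(seg) {
  silk_load(ex$values, ma_silk, seg, tissues)
}, numeric(1))
cat(sprintf("dragline silk transcriptional load: Tail %.1f%%, Sac %.1f%%, Duct %.1f%%\n",
            100 * loads[1], 100 * loads[2], 100 * loads[3]))

sets <- segment_specific_genes(ex$values, tissues)
cat(sprintf("segment-specific genes: %s\n",
            paste(sprintf("%s=%d", names(sets), lengths(sets)),
                  collapse = ", ")))

corr <- segment_correlation(ex$values[, tissues %in% c("Tail", "Sac", "Duct")],
                            tissues[tissues %in% c("Tail", "Sac", "Duct")])
cat("\nMa segment correlation (Pearson, segment means):\n")
print(round(corr, 3))

summary <- data.frame(segment = names(loads),
                      silk_load_pct = round(100 * loads, 2),
                      specific_genes = lengths(sets)[names(loads)])
write.table(summary, "results/expression_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/tau_specificity.tsv and results/expression_summary.tsv\n")
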
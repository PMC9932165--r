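#!/usr/bin/env Rscript
# Generate the synthetic study system: three chromosomes carrying 13
# spidroin genes in the classic three-group layout (MaSp1a-c + MaSp2e,
# MaSp2a-d, MiSp-a-e) plus 50 decoys, with two corrupted loci, a proteome,
# and a seven-gland expression matrix. Everything downstream reads from
# results/bundle/.

suppressMessages(library(spidroinr))

seed <- 42L
bundle <- make_bundle(seed = seed)
print(bundle)

dir.create("results", showWarnings = FALSE)
write_bundle(bundle, "results/bundle")

truth_sp <- bundle$truth[bundle$truth$class == "spidroin", ]
cat(sprintf("\n%d spidroins on %s; corrupted: %s\n",
            nrow(truth_sp),
            paste(unique(truth_sp$chromosome), collapse = ", "),
            paste(truth_sp$gene_id[truth_sp$corruption != "none"],
                  collapse = ", ")))
cat("bundle written to results/bundle/\n")
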
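#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-condition study.
#
# The real study contrasted two glioma methylation subtypes (234 vs 16
# tumours) with controlled-access TCGA RNA-seq; here we emulate its
# statistical structure at desk scale: NB counts for 800 mRNAs + 80 lncRNAs,
# 60 miRNAs on a log2-RPM-like scale, 100 samples per condition, 60 planted
# differential features (|log2FC| = 2), 10 fully mediated sponge triplets
# and 20 confounder-driven decoy pairs.

library(spongelnc)

seed <- 2026
out <- "results/dataset"

sim <- simulate_sponge_dataset(sim_config(seed = seed))
paths <- write_dataset(sim, out)

cat("Synthetic dataset written to", out, "\n")
cat(sprintf("  genes: %d x %d samples; miRNAs: %d\n",
            nrow(sim$counts), ncol(sim$counts), nrow(sim$mirna)))
cat(sprintf("  planted: %d DE features, %d sponge triplets, %d decoy pairs\n",
            nrow(sim$truth$de_features), nrow(sim$truth$sponge_triplets),
            nrow(sim$truth$decoy_pairs)))
cat(sprintf("  target map: %d miRNAs with predicted targets\n",
            length(sim$targets$forward)))
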
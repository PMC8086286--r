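#!/usr/bin/env Rscript
# Stage 2: low-expression filtering (mean CPM >= 1 in at least one condition)
# and TMM between-sample normalization of the count matrix.

library(spongelnc)

counts <- read_expression_matrix("results/dataset/counts.tsv", "counts")
groups <- read_sample_groups("results/dataset/samples.tsv")

flt <- filter_low_expression(counts, groups, cpm_threshold = 1)
cat(sprintf("CPM filter: %d of %d features retained (%d removed)\n",
            nrow(flt$counts), nrow(counts), length(flt$removed_ids)))

f <- tmm_factors(flt$counts)
cat(sprintf("TMM reference sample: %s; factor range %.3f-%.3f\n",
            attr(f, "reference_sample_id"), min(f), max(f)))

norm <- normalize_counts(flt$counts, f)
dir.create("results/preprocess", showWarnings = FALSE, recursive = TRUE)
write_expression_matrix(norm, "results/preprocess/normalized.tsv",
                        id_column = "gene_id")
write.table(data.frame(sample_id = names(f), tmm_factor = as.vector(f),
                       effective_scale = as.vector(attr(f, "effective_scale"))),
            "results/preprocess/tmm_factors.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Normalized matrix and factors written to results/preprocess/\n")
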
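#!/usr/bin/env Rscript
# Stage 2: MAD-based QC per sample, then log-normalization of kept cells.

suppressPackageStartupMessages(library(tlscape))
inp <- readRDS("scratch/analysis/01_simulated.rds")
cohort <- inp$cohort

qc <- mad_filter(cohort$matrix, qc_config(), sample = cohort$cells$sample)
cat(sprintf("QC kept %d / %d cells (%.1f%%)\n", length(qc$kept),
            nrow(qc$qc_table), 100 * mean(qc$qc_table$keep)))
by_rule <- colSums(qc$qc_table[, c("fail_mito", "fail_umi", "fail_gene")])
cat("removals by rule:", paste(names(by_rule), by_rule, collapse = ", "), "\n")

keep_idx <- match(qc$kept, cohort$matrix$entity_ids)
kept_counts <- expression_matrix(cohort$matrix$values[, keep_idx],
                                 cohort$matrix$gene_ids, qc$kept)
lognorm <- lognormalize(kept_counts)
cells <- cohort$cells[match(qc$kept, cohort$cells$cell_id), ]

write.table(qc$qc_table, "results/qc_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(list(lognorm = lognorm, cells = cells), "scratch/analysis/02_qc.rds")
cat("wrote results/qc_table.tsv and scratch/analysis/02_qc.rds\n")
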
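#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# One cohort-style single-cell dataset (responders / non-responders, pre and
# post treatment, NB counts with subtype markers, bimodal Tex pseudotime,
# planted pre->post shift of the TLS genes) and one binned spatial sample
# with three planted TLS discs. Ground truth is kept alongside for the later
# stages. Bulky intermediates go to scratch/, summaries to results/.

suppressPackageStartupMessages(library(tlscape))
dir.create("scratch/analysis", showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

seed <- 20260919L

cfg <- sim_config(treatment_genes = 301:340, treatment_lfc = 1, seed = seed)
cohort <- simulate_cohort(cfg)
cat(sprintf("cohort: %d genes x %d cells, %d Tex cells with pseudotime\n",
            nrow(cohort$matrix$values), ncol(cohort$matrix$values),
            sum(!is.na(cohort$cells$pseudotime))))

t_sig <- gene_signature("Tcell", cfg$marker_map$Tcell$genes, "panel")
b_sig <- gene_signature("Bcell", cfg$marker_map$Bcell$genes, "panel")
spatial <- simulate_spatial(cfg, t_sig, b_sig, sample_label = "CR1")
cat(sprintf("spatial: %d bins, %.1f%% planted TLS\n",
            length(spatial$sample$matrix$entity_ids),
            100 * spatial$truth$planted_fraction))

saveRDS(list(cfg = cfg, cohort = cohort, spatial = spatial,
             t_sig = t_sig, b_sig = b_sig),
        "scratch/analysis/01_simulated.rds")

# the cohort also goes out in interchange formats for external tools
write_expression(cohort$matrix, "scratch/analysis/cohort_mtx", format = "mtx")
write.table(cohort$cells, "scratch/analysis/cell_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote scratch/analysis/01_simulated.rds\n")
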
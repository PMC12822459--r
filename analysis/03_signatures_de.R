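#!/usr/bin/env Rscript
# Stage 3: signature scoring, pre-vs-post differential expression, and
# derivation of the treatment-associated TLS signature.

suppressPackageStartupMessages(library(tlscape))
inp <- readRDS("scratch/analysis/01_simulated.rds")
qc <- readRDS("scratch/analysis/02_qc.rds")
ln <- qc$lognorm; cells <- qc$cells
seed <- 20260919L

# module scores of the subtype marker panels, summarized per subtype
for (nm in names(inp$cfg$marker_map)) {
  sig <- gene_signature(nm, inp$cfg$marker_map[[nm]]$genes, "panel")
  sc <- module_score(ln, sig, seed = seed)
  mu <- tapply(sc$score, cells$subtype, mean)
  cat(sprintf("%s panel: mean module score in %s = %.2f, elsewhere = %.2f\n",
              nm, nm, mu[[nm]], mean(sc$score[cells$subtype != nm])))
}

# DE pre vs post in responders
r_pre <- cells$cell_id[cells$group == "R" & cells$timepoint == "pre"]
r_post <- cells$cell_id[cells$group == "R" & cells$timepoint == "post"]
de <- wilcoxon_de(ln, r_post, r_pre)
cat(sprintf("pre-vs-post DE (responders): %d significant genes\n",
            sum(de$significant)))
write.table(de[order(de$padj), ], "results/de_pre_post.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# published TLS list = planted treatment genes plus decoys; keep the
# significantly shifted ones
planted <- names(inp$cohort$truth$de_gene_mask)[inp$cohort$truth$de_gene_mask]
published <- gene_signature("TLS_published",
                            c(planted, inp$cfg$gene_ids[501:520]),
                            "literature")
derived <- derive_treatment_signature(published, de)
cat(sprintf("derived TLS signature: %d / %d published genes retained\n",
            length(derived$genes), length(published$genes)))
write.table(data.frame(set_name = derived$name, gene = derived$genes),
            "results/derived_tls_signature.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# top-ratio markers of the planted Tex subtype vs other T/B populations
tex_cells <- cells$cell_id[cells$subtype == "Tex"]
rest <- cells$cell_id[cells$subtype %in% c("Tcell", "Bcell")]
mk <- top_ratio_markers(ln, tex_cells, rest, k = 20, name = "Tex_markers")
truth_markers <- inp$cfg$marker_map$Tex$genes
cat(sprintf("top-20 Tex markers: %d / 20 from the planted marker set\n",
            length(intersect(mk$genes, truth_markers))))

saveRDS(list(de = de, derived = derived, markers = mk),
        "scratch/analysis/03_signatures.rds")
cat("wrote results/de_pre_post.tsv, results/derived_tls_signature.tsv\n")
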
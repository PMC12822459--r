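# tlscape

Tertiary lymphoid structures (TLS) — organized aggregates of T and B cells
arising in tumor tissue — are a strong correlate of response to neoadjuvant
chemoradiotherapy (neoCRT) in rectal cancer. Studying them computationally
means stitching together several bespoke procedures that are usually buried
in per-paper scripts: outlier-based quality control of single-cell RNA-seq,
signature scoring against expression-matched controls, deriving a
treatment-responsive TLS gene signature, splitting exhausted T cells (Tex)
into early and terminal stages at the antimode of a bimodal pseudotime
distribution, and calling TLS regions in binned spatial transcriptomics
with thresholds calibrated from matched single-cell data. `tlscape`
implements that pipeline as a tested R package, together with a
synthetic-data generator that plants ground truth for every stage, so each
procedure's recovery behavior is verifiable without controlled-access
patient data.

## Methods at a glance

* **QC** — a cell is removed iff mito% > median + 5·MAD (one-sided), or
  |UMI − median| > 3·MAD, or |genes − median| > 3·MAD, with the raw MAD
  (no consistency constant), per sample. Normalization:
  `ln(1 + count/total · 10⁴)`.
* **Module score** — mean over signature genes minus mean over control genes
  drawn from 25 mean-expression rank bins (100 controls per gene);
  **summed score** — plain sum of signature genes per spatial bin.
* **DE** — two-sided Wilcoxon rank-sum per gene, BH adjustment;
  significant iff log₂FC > 0.5 and p_adj < 0.05, with
  log₂FC = log₂(mean expm1 A + ε) − log₂(mean expm1 B + ε).
* **Treatment TLS signature** — published TLS genes ∩ genes significantly
  DE pre vs post treatment.
* **Tex staging** — Gaussian KDE (Silverman bandwidth) on pseudotime; split
  at the antimode between the two highest peaks; `early` ≤ split <
  `terminal`.
* **Spatial TLS calling** — bin is TLS iff its summed T score is in the top
  23.9% *and* its summed B score is in the top 5.4% (single-cell-calibrated
  defaults, configurable or derivable from cell fractions); 8-connected
  components of called bins, minimum 2 bins; validation by rank-statistic
  ROC/AUC.
* **Statistics** — Pearson correlation (t-transform p), Wilcoxon/t
  two-group tests, BH adjustment, stratified composition tables with
  pre→post changes. MSI status: MSI iff score > 3.5.

## Worked example

Simulate a 60×60 spatial sample with three planted TLS discs, call TLS
bins with the default calibrated thresholds, and validate against the
planted mask:

```r
library(tlscape)
cfg   <- sim_config(seed = 1)
t_sig <- gene_signature("Tcell", cfg$marker_map$Tcell$genes)
b_sig <- gene_signature("Bcell", cfg$marker_map$Bcell$genes)
sp    <- simulate_spatial(cfg, t_sig, b_sig, sample_label = "CR1")
samp  <- spatial_sample(lognormalize(sp$sample$matrix), sp$sample$coords, "CR1")
calls <- label_regions(call_tls_bins(samp, t_sig, b_sig,
                                     p_t = 0.239, p_b = 0.054),
                       connectivity = 8, min_size = 2)
head(calls[calls$is_tls, ], 3)
#>        bin_id  x  y  t_score  b_score is_tls region_id
#> 555 bin_15_10 15 10 87.00761 95.97250   TRUE         1
#> 612 bin_12_11 12 11 99.18207 95.31813   TRUE         1
#> 613 bin_13_11 13 11 91.44453 86.53215   TRUE         1

length(attr(calls, "region_sizes"))   # connected TLS regions found
#> 3
tls_proportion(calls)                  # fraction of bins called TLS
#> 0.054  (planted fraction: 0.055)

roc <- validate_roc(summed_score(samp$matrix,
                    gene_signature("TLS", c(t_sig$genes, b_sig$genes))),
                    sp$truth$tls_bin_mask)
roc$auc
#> 1
```

Each called bin reports its T and B summed scores and its region label;
the three planted discs come back as exactly three 8-connected regions,
the called TLS proportion (5.4% of bins) tracks the planted fraction
(5.5%), and the summed TLS-signature score separates TLS from non-TLS
bins perfectly (AUC 1.0) at this planted effect size (+2 log₂-fold).

## Analysis workflow

The `analysis/` directory holds the numbered drivers that run the study
end-to-end on the synthetic cohort: `01_simulate.R` (cohort + spatial
generation), `02_qc_normalize.R`, `03_signatures_de.R` (scores, DE,
derived TLS signature, marker selection), `04_tex_staging.R`,
`05_tls_spatial.R`, `06_group_stats.R`. Run them in order from the
repository root; summary tables land in `results/`, bulky intermediates in
`scratch/`.

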
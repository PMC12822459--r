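test_that("module score vanishes when the signature equals the background", {
  # 100 genes, 4 bins of 25, n_ctrl = bin size: control draws cover each bin
  # exhaustively, so signature mean and pooled control mean coincide
  m <- null_matrix(n_genes = 100, n_cells = 50, seed = 2)
  all_genes <- gene_signature("all", m$gene_ids)
  sc <- module_score(m, all_genes, n_bins = 4, n_ctrl = 25, seed = 1)
  expect_lt(max(abs(sc$score)), 1e-6)
})

test_that("module score is near zero for a random signature on null data", {
  m <- null_matrix(n_genes = 500, n_cells = 1000, seed = 9)
  set.seed(21)
  sig <- gene_signature("rand", sample(m$gene_ids, 50))
  sc <- module_score(m, sig, seed = 3)
  expect_lt(abs(mean(sc$score)), 0.05)
})

test_that("module score recovers a planted subtype elevation", {
  sim <- tiny_cohort(seed = 31)
  ln <- lognormalize(sim$matrix)
  cfg_markers <- sim_config(n_genes = 300, n_cells = 600, seed = 31)$marker_map
  sig <- gene_signature("Tex_markers", cfg_markers$Tex$genes)
  sc <- module_score(ln, sig, seed = 4)
  in_tex <- sim$cells$subtype == "Tex"
  expect_gt(mean(sc$score[in_tex]), mean(sc$score[!in_tex]))
  expect_lt(wilcox.test(sc$score[in_tex], sc$score[!in_tex])$p.value, 0.01)
  # deterministic under seed
  sc2 <- module_score(ln, sig, seed = 4)
  expect_identical(sc, sc2)
})

test_that("summed score is the plain sum and is additive over signatures", {
  m <- null_matrix(n_genes = 30, n_cells = 10, seed = 4)
  one <- summed_score(m, gene_signature("one", "g7"))
  expect_equal(one$score, unname(as.matrix(m$values)["g7", ]))
  s1 <- gene_signature("s1", c("g1", "g2"))
  s2 <- gene_signature("s2", c("g10", "g11", "g12"))
  both <- gene_signature("both", c(s1$genes, s2$genes))
  expect_equal(summed_score(m, both)$score,
               summed_score(m, s1)$score + summed_score(m, s2)$score)
  expect_warning(w <- summed_score(m, gene_signature("x", c("g1", "nope"))),
                 "absent")
  expect_equal(w$score, unname(as.matrix(m$values)["g1", ]))
  expect_error(summed_score(m, gene_signature("none", "absent_gene")),
               "no gene")
})

test_that("wilcoxon_de: null, planted signal, and the significance rule", {
  # identical groups: zero fold changes, nothing significant
  m <- null_matrix(n_genes = 50, n_cells = 40, seed = 6)
  de0 <- wilcoxon_de(m, m$entity_ids[1:20], m$entity_ids[1:20])
  expect_true(all(de0$log2fc == 0))
  expect_false(any(de0$significant))

  # planted log2fc = 1 on 40 genes, 200 vs 200 cells
  cfg <- sim_config(n_genes = 400, n_cells = 800, treatment_genes = 31:70,
                    treatment_lfc = 1, marker_map = list(), seed = 17)
  sim <- simulate_cohort(cfg)
  ln <- lognormalize(sim$matrix)
  pre <- sim$cells$cell_id[sim$cells$timepoint == "pre"][1:200]
  post <- sim$cells$cell_id[sim$cells$timepoint == "post"][1:200]
  de <- wilcoxon_de(ln, post, pre)
  planted <- sim$truth$de_gene_mask[de$gene]
  expect_gte(mean(de$significant[planted]), 0.9)          # sensitivity
  expect_lte(mean(de$significant[!planted]), 0.05)        # FPR after BH

  # relabeling the groups flips the fold change, not the p-value
  de_rev <- wilcoxon_de(ln, pre, post)
  expect_equal(de_rev$log2fc, -de$log2fc)
  expect_equal(de_rev$p, de$p)

  # the significance rule is a strict conjunction of both thresholds
  fake <- de[1:2, ]
  expect_true(with(data.frame(log2fc = 0.6, padj = 0.04),
                   log2fc > 0.5 & padj < 0.05))
  expect_false(with(data.frame(log2fc = 0.6, padj = 0.06),
                    log2fc > 0.5 & padj < 0.05))
  expect_equal(de$significant, de$log2fc > 0.5 & de$padj < 0.05)
})

test_that("treatment signature = published genes significant pre vs post", {
  de <- data.frame(gene = paste0("g", 1:6),
                   log2fc = c(1, -1, 0.7, 0.2, 0.9, 0),
                   p = c(0.001, 0.001, 0.2, 0.01, 0.002, 0.9),
                   padj = c(0.01, 0.01, 0.4, 0.04, 0.02, 0.9))
  pub <- gene_signature("TLS", c("g2", "g3", "g4", "g9"))
  out <- derive_treatment_signature(pub, de)
  expect_equal(out$genes, c("g2", "g4"))   # order follows the published list
  expect_identical(out$source_tag, "neoCRT-TLS")
  # direction filter restricts to up-regulated genes when asked
  up <- derive_treatment_signature(pub, de, direction = "up")
  expect_equal(up$genes, "g4")
  # no significant overlap: empty result with a warning
  none <- data.frame(gene = "g1", log2fc = 1, p = 0.5, padj = 0.8)
  expect_warning(empty <- derive_treatment_signature(pub, none), "empty")
  expect_length(empty$genes, 0)
})

test_that("derived signature recovers the planted treatment genes", {
  cfg <- sim_config(n_genes = 400, n_cells = 800, treatment_genes = 31:70,
                    treatment_lfc = 1, marker_map = list(), seed = 23)
  sim <- simulate_cohort(cfg)
  ln <- lognormalize(sim$matrix)
  pre <- sim$cells$cell_id[sim$cells$timepoint == "pre"]
  post <- sim$cells$cell_id[sim$cells$timepoint == "post"]
  de <- wilcoxon_de(ln, post, pre)
  planted <- names(sim$truth$de_gene_mask)[sim$truth$de_gene_mask]
  # published list = planted genes plus a few decoys that do not shift
  pub <- gene_signature("TLS", c(planted, "g200", "g250", "g300"))
  out <- derive_treatment_signature(pub, de)
  jac <- length(intersect(out$genes, planted)) /
         length(union(out$genes, planted))
  expect_gte(jac, 0.9)
  expect_true(all(out$genes %in% pub$genes))  # always a subset of published
})

test_that("top_ratio_markers ranks by expression ratio and truncates at k", {
  # planted graded elevations: the top k must be the k largest elevations
  set.seed(12)
  n_genes <- 120; n_cells <- 300
  lfc <- rep(0, n_genes); lfc[31:60] <- seq(4, 1.1, length.out = 30)
  mu <- matrix(20, n_genes, n_cells)
  target_cols <- 1:150
  mu[, target_cols] <- mu[, target_cols] * 2^lfc
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = 5),
                   n_genes, dimnames = list(paste0("g", 1:n_genes),
                                            paste0("c", 1:n_cells)))
  ln <- lognormalize(expression_matrix(counts))
  target <- paste0("c", target_cols); other <- paste0("c", 151:300)
  mk <- top_ratio_markers(ln, target, other, k = 20)
  expect_length(mk$genes, 20)
  expect_setequal(mk$genes, paste0("g", 31:50))  # the 20 largest elevations
  # asking for more than exist returns all candidates with a warning
  expect_warning(all_mk <- top_ratio_markers(ln, target, other, k = 1000),
                 "candidates")
  expect_lte(length(all_mk$genes), 1000)
  expect_true(all(mk$genes %in% all_mk$genes))
})

test_that("score_ratio: identity, homogeneity, and shift handling", {
  s <- function(x) data.frame(entity_id = paste0("c", seq_along(x)),
                              score = x, method = "module")
  x <- c(1.5, 2, 3)
  expect_equal(score_ratio(s(x), s(x))$score, rep(1, 3))
  expect_equal(score_ratio(s(2 * x), s(x))$score, rep(2, 3))  # no shift
  expect_equal(attr(score_ratio(s(2 * x), s(x)), "shift"), 0)
  neg <- score_ratio(s(c(-1, 0, 1)), s(c(1, 1, 1)), eps = 1e-6)
  expect_true(all(is.finite(neg$score)) && all(neg$score > 0))
  expect_error(score_ratio(s(x), s(x)[1:2, ]), "entity set")
})

test_that("MSI classification uses a strict 3.5 cutoff with MSS boundary", {
  expect_identical(classify_msi(0.2), "MSS")
  expect_identical(classify_msi(3.5), "MSS")
  expect_identical(classify_msi(10.0), "MSI")
  expect_identical(classify_msi(c(3.49, 3.51)), c("MSS", "MSI"))
  expect_error(classify_msi(-1), "non-negative")
})
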
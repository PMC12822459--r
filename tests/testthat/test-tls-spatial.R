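score_df <- function(x) data.frame(entity_id = paste0("b", seq_along(x)),
                                   score = x, method = "summed")

test_that("threshold calibration passes exactly the top fraction", {
  set.seed(14)
  sc <- score_df(sample(1:1000))          # 1000 distinct scores
  spec <- calibrate_thresholds(sc, sc, p_t = 0.239, p_b = 0.054)
  expect_equal(sum(sc$score >= spec$cutoff_t), 239)
  expect_equal(sum(sc$score >= spec$cutoff_b), 54)

  # p = 0.5 on distinct symmetric scores: the upper median, half pass
  sym <- score_df(c(-(1:50), 1:50))
  spec2 <- calibrate_thresholds(sym, sym, p_t = 0.5, p_b = 0.5)
  expect_equal(spec2$cutoff_t, 1)
  expect_equal(mean(sym$score >= spec2$cutoff_t), 0.5)

  # constant scores: warning, everything passes
  expect_warning(spec3 <- calibrate_thresholds(score_df(rep(2, 10)),
                                               score_df(1:10)),
                 "constant")
  expect_equal(spec3$cutoff_t, 2)
  expect_error(calibrate_thresholds(sc, sc, p_t = 1.2), "\\(0, 1\\)")
})

test_that("TLS calls are the conjunction of both score thresholds", {
  set.seed(15)
  cfg <- sim_config(n_genes = 200, grid_shape = c(12, 12), n_mito = 0,
                    planted_regions = list(), marker_map = list(), seed = 2)
  tsig <- gene_signature("T", cfg$gene_ids[1:20])
  bsig <- gene_signature("B", cfg$gene_ids[21:40])
  sp <- simulate_spatial(cfg, tsig, bsig)
  samp <- spatial_sample(lognormalize(sp$sample$matrix), sp$sample$coords)
  calls <- call_tls_bins(samp, tsig, bsig, p_t = 0.3, p_b = 0.3)
  spec <- attr(calls, "spec")
  expect_equal(calls$is_tls,
               calls$t_score >= spec$cutoff_t & calls$b_score >= spec$cutoff_b)
  # conjunction bound
  expect_lte(sum(calls$is_tls),
             min(sum(calls$t_score >= spec$cutoff_t),
                 sum(calls$b_score >= spec$cutoff_b)))
  # a bin passing only one threshold is never called
  only_t <- calls$t_score >= spec$cutoff_t & calls$b_score < spec$cutoff_b
  expect_false(any(calls$is_tls[only_t]))
})

test_that("the TLS bin set shrinks monotonically in (p_t, p_b)", {
  set.seed(16)
  cfg <- sim_config(n_genes = 150, grid_shape = c(15, 15), n_mito = 0,
                    planted_regions = list(list(center = c(8, 8), radius = 3,
                                                t_lfc = 1, b_lfc = 1)),
                    marker_map = list(), seed = 4)
  tsig <- gene_signature("T", cfg$gene_ids[1:15])
  bsig <- gene_signature("B", cfg$gene_ids[16:30])
  sp <- simulate_spatial(cfg, tsig, bsig)
  samp <- spatial_sample(lognormalize(sp$sample$matrix), sp$sample$coords)
  ps <- c(0.05, 0.1, 0.2, 0.35, 0.5)
  sets <- list()
  for (pt in ps) for (pb in ps) {
    calls <- call_tls_bins(samp, tsig, bsig, p_t = pt, p_b = pb)
    sets[[paste(pt, pb)]] <- calls$bin_id[calls$is_tls]
  }
  for (i in seq_along(ps)[-1]) for (j in seq_along(ps)[-1]) {
    larger <- sets[[paste(ps[i], ps[j])]]
    expect_true(all(sets[[paste(ps[i - 1], ps[j])]] %in% larger))
    expect_true(all(sets[[paste(ps[i], ps[j - 1])]] %in% larger))
  }
})

test_that("region labeling honors adjacency semantics and min_size", {
  calls <- data.frame(bin_id = c("a", "b", "c"),
                      x = c(1, 2, 5), y = c(1, 2, 5),
                      is_tls = c(TRUE, TRUE, TRUE))
  lab8 <- label_regions(calls, connectivity = 8, min_size = 1)
  expect_equal(length(attr(lab8, "region_sizes")), 2)  # diagonal pair joins
  expect_equal(lab8$region_id[lab8$bin_id == "a"],
               lab8$region_id[lab8$bin_id == "b"])
  lab4 <- label_regions(calls, connectivity = 4, min_size = 1)
  expect_equal(length(attr(lab4, "region_sizes")), 3)  # diagonals split
  lab4m <- label_regions(calls, connectivity = 4, min_size = 2)
  expect_false(any(lab4m$is_tls))                      # all demoted
  # isolated single bin survives min_size = 1
  solo <- label_regions(data.frame(bin_id = "z", x = 3, y = 3, is_tls = TRUE),
                        min_size = 1)
  expect_equal(solo$region_id, 1L)
  expect_error(label_regions(calls, connectivity = 6), "4 or 8")
})

test_that("one planted disc comes back as exactly one region", {
  cfg <- sim_config(n_genes = 200, grid_shape = c(60, 60), n_mito = 0,
                    planted_regions = list(list(center = c(30, 30), radius = 3,
                                                t_lfc = 3, b_lfc = 3)),
                    marker_map = list(), seed = 6)
  tsig <- gene_signature("T", cfg$gene_ids[1:25])
  bsig <- gene_signature("B", cfg$gene_ids[26:50])
  sp <- simulate_spatial(cfg, tsig, bsig)
  # disc bin count equals the enumeration oracle
  expect_equal(sum(sp$truth$tls_bin_mask),
               brute_disc_count(c(30, 30), 3, 60, 60))
  samp <- spatial_sample(lognormalize(sp$sample$matrix), sp$sample$coords)
  planted_p <- sp$truth$planted_fraction
  calls <- call_tls_bins(samp, tsig, bsig, p_t = planted_p, p_b = planted_p)
  lab <- label_regions(calls)
  expect_equal(length(attr(lab, "region_sizes")), 1)
  expect_setequal(lab$bin_id[lab$is_tls],
                  names(sp$truth$tls_bin_mask)[sp$truth$tls_bin_mask])
})

test_that("tls_proportion counts TLS bins after the size filter", {
  calls <- data.frame(bin_id = letters[1:4], x = c(1, 2, 10, 20),
                      y = c(1, 1, 10, 20), is_tls = c(TRUE, TRUE, TRUE, FALSE))
  lab <- label_regions(calls, min_size = 2)
  expect_equal(tls_proportion(lab), 0.5)  # the isolated bin was demoted
  none <- label_regions(transform(calls, is_tls = FALSE))
  expect_equal(tls_proportion(none), 0)
  all_tls <- data.frame(bin_id = letters[1:4], x = 1:4, y = 1,
                        is_tls = TRUE)
  expect_equal(tls_proportion(label_regions(all_tls)), 1)
})

test_that("calls and regions are invariant to translating the grid", {
  cfg <- sim_config(n_genes = 100, grid_shape = c(20, 20), n_mito = 0,
                    planted_regions = list(list(center = c(10, 10), radius = 3,
                                                t_lfc = 2, b_lfc = 2)),
                    marker_map = list(), seed = 9)
  tsig <- gene_signature("T", cfg$gene_ids[1:10])
  bsig <- gene_signature("B", cfg$gene_ids[11:20])
  sp <- simulate_spatial(cfg, tsig, bsig)
  samp <- spatial_sample(lognormalize(sp$sample$matrix), sp$sample$coords)
  calls <- label_regions(call_tls_bins(samp, tsig, bsig))
  shifted_coords <- transform(sp$sample$coords, x = x + 100, y = y - 7)
  samp2 <- spatial_sample(lognormalize(sp$sample$matrix), shifted_coords)
  calls2 <- label_regions(call_tls_bins(samp2, tsig, bsig))
  expect_equal(calls$is_tls, calls2$is_tls)
  expect_equal(calls$region_id, calls2$region_id)
  expect_equal(tls_proportion(calls), tls_proportion(calls2))
})

test_that("validate_roc equals the all-pairs oracle and pROC", {
  set.seed(30)
  sc <- score_df(round(rnorm(30), 1))     # ties likely at 1 decimal
  lab <- rbinom(30, 1, 0.5) == 1
  lab[1:2] <- c(TRUE, FALSE)              # both classes guaranteed
  roc <- validate_roc(sc, lab)
  expect_equal(roc$auc, brute_auc(sc$score, lab))
  if (requireNamespace("pROC", quietly = TRUE)) {
    pr <- pROC::auc(pROC::roc(lab, sc$score, quiet = TRUE,
                              direction = "<"))
    expect_equal(roc$auc, as.numeric(pr))
  }
  # perfect separation
  sep <- validate_roc(score_df(c(1:10, 101:110)),
                      rep(c(FALSE, TRUE), each = 10))
  expect_equal(sep$auc, 1.0)
  # labels independent of scores: AUC near 1/2
  set.seed(31)
  big <- score_df(rnorm(2000))
  null_auc <- validate_roc(big, rbinom(2000, 1, 0.5) == 1)$auc
  expect_gt(null_auc, 0.45)
  expect_lt(null_auc, 0.55)
  expect_error(validate_roc(big, rep(TRUE, 2000)), "both classes")
})

test_that("planted TLS regions are recovered end-to-end with high fidelity", {
  cfg <- sim_config(seed = 42)            # the design defaults: 60x60, 3 discs
  tsig <- gene_signature("T", cfg$gene_ids[11:50])
  bsig <- gene_signature("B", cfg$gene_ids[51:90])
  sp <- simulate_spatial(cfg, tsig, bsig)
  samp <- spatial_sample(lognormalize(sp$sample$matrix), sp$sample$coords)
  calls <- label_regions(call_tls_bins(samp, tsig, bsig))
  truth <- sp$truth$tls_bin_mask[calls$bin_id]
  expect_gte(f1_score(calls$is_tls, truth), 0.9)
  expect_equal(length(attr(calls, "region_sizes")), 3)
  expect_lte(abs(tls_proportion(calls) - sp$truth$planted_fraction), 0.02)
  tls_sig <- gene_signature("TLS", c(tsig$genes, bsig$genes))
  roc <- validate_roc(summed_score(samp$matrix, tls_sig),
                      sp$truth$tls_bin_mask)
  expect_gte(roc$auc, 0.95)
})
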
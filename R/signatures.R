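#' Construct a gene signature
#'
#' A named, ordered, duplicate-free gene list with a provenance tag.
#'
#' @param name signature name.
#' @param genes character vector of gene identifiers.
#' @param source_tag free-text provenance, e.g. `"published"` or
#'   `"neoCRT-TLS"`.
#' @return a list of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, source_tag = "user") {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("empty gene signature '", name, "'")
  if (anyDuplicated(genes)) stop("duplicate genes in signature '", name, "'")
  structure(list(name = name, genes = genes, source_tag = source_tag),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes [%s]\n",
              x$name, length(x$genes), x$source_tag))
  invisible(x)
}

#' Read signatures from a two-column TSV (set_name, gene)
#'
#' @param path TSV file with columns `set_name` and `gene`.
#' @param source_tag provenance tag attached to every signature.
#' @return named list of [gene_signature()] objects.
#' @export
read_signatures <- function(path, source_tag = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("set_name", "gene") %in% names(df))) {
    stop("signature TSV needs columns 'set_name' and 'gene'")
  }
  sets <- split(df$gene, df$set_name)
  out <- lapply(names(sets), function(nm) {
    gene_signature(nm, unique(sets[[nm]]), source_tag)
  })
  names(out) <- names(sets)
  out
}

match_signature <- function(mat, sig) {
  present <- sig$genes[sig$genes %in% mat$gene_ids]
  if (length(present) == 0L) {
    stop("no gene of signature '", sig$name, "' is present in the matrix")
  }
  if (length(present) < length(sig$genes)) {
    warning(length(sig$genes) - length(present), " gene(s) of signature '",
            sig$name, "' absent from the matrix; dropped")
  }
  present
}

score_table <- function(entity_id, score, method_tag) {
  data.frame(entity_id = as.character(entity_id), score = as.numeric(score),
             method = method_tag, stringsAsFactors = FALSE)
}

#' Module score with expression-matched control genes
#'
#' The control-gene scoring scheme for log-normalized data: all genes are
#' ranked by mean expression across entities and cut into `n_bins`
#' equal-size bins; for each signature gene, `n_ctrl` control genes are drawn
#' from its bin (without replacement when the bin is large enough, with
#' replacement otherwise); the score of an entity is the mean over signature
#' genes minus the mean over the pooled control draws. On exchangeable data a
#' random signature therefore scores near zero, while coordinated elevation
#' of the signature genes shifts the score up.
#'
#' @param mat an [expression_matrix()], lognorm layer.
#' @param sig a [gene_signature()]; genes absent from the matrix are dropped
#'   with a warning.
#' @param n_bins number of mean-expression bins; default 25.
#' @param n_ctrl control genes sampled per signature gene; default 100.
#' @param seed integer seed making the control draw reproducible.
#' @return a score table: data frame with `entity_id`, `score`,
#'   `method = "module"`.
#' @export
module_score <- function(mat, sig, n_bins = 25, n_ctrl = 100, seed = 0L) {
  if (!inherits(mat, "expr_matrix")) stop("expected an 'expr_matrix'")
  genes <- match_signature(mat, sig)
  v <- as.matrix(mat$values)
  gene_means <- rowMeans(v)
  n_genes <- length(gene_means)
  n_bins <- min(n_bins, n_genes)
  # equal-size bins by mean-expression rank; ties broken by position
  rk <- rank(gene_means, ties.method = "first")
  bin_of <- ceiling(rk / (n_genes / n_bins))
  bin_of[bin_of > n_bins] <- n_bins

  ctrl_idx <- local_seed(seed, {
    unlist(lapply(genes, function(g) {
      b <- bin_of[[match(g, mat$gene_ids)]]
      pool <- which(bin_of == b)
      if (length(pool) >= n_ctrl) {
        sample(pool, n_ctrl, replace = FALSE)
      } else {
        sample(pool, n_ctrl, replace = TRUE)
      }
    }))
  })
  sig_mean <- colMeans(v[match(genes, mat$gene_ids), , drop = FALSE])
  ctrl_mean <- colMeans(v[ctrl_idx, , drop = FALSE])
  score_table(mat$entity_ids, sig_mean - ctrl_mean, "module")
}

#' Summed signature score
#'
#' Plain sum of the signature genes' values per entity (the scoring rule used
#' for spatial bins). Missing genes contribute 0 with a warning.
#'
#' @inheritParams module_score
#' @return a score table with `method = "summed"`.
#' @export
summed_score <- function(mat, sig) {
  if (!inherits(mat, "expr_matrix")) stop("expected an 'expr_matrix'")
  genes <- match_signature(mat, sig)
  rows <- match(genes, mat$gene_ids)
  s <- Matrix::colSums(mat$values[rows, , drop = FALSE])
  score_table(mat$entity_ids, as.numeric(s), "summed")
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test between two groups of entities
#' on log-normalized data (via [stats::wilcox.test()] with its default
#' normal approximation and continuity correction in the presence of ties),
#' BH adjustment across the tested genes, and fold changes computed on the
#' de-logged scale: `log2fc = log2(mean(expm1(A)) + eps) -
#' log2(mean(expm1(B)) + eps)`. A gene is flagged significant when
#' `log2fc > log2fc_min` and `padj < alpha`. Genes constant across both
#' groups get `p = 1`.
#'
#' @param mat an [expression_matrix()], lognorm layer.
#' @param group_a,group_b entity ids of the two groups (each of size >= 2).
#' @param log2fc_min significance threshold on log2 fold change; default 0.5.
#' @param alpha significance threshold on BH-adjusted p; default 0.05.
#' @param eps pseudocount inside the fold-change logs; default 1e-9.
#' @return data frame with `gene`, `log2fc`, `p`, `padj`, `significant`.
#' @export
wilcoxon_de <- function(mat, group_a, group_b, log2fc_min = 0.5,
                        alpha = 0.05, eps = 1e-9) {
  if (!inherits(mat, "expr_matrix")) stop("expected an 'expr_matrix'")
  ia <- match(group_a, mat$entity_ids)
  ib <- match(group_b, mat$entity_ids)
  if (anyNA(ia) || anyNA(ib)) stop("unknown entity ids in group definition")
  if (length(ia) < 2 || length(ib) < 2) stop("both groups need >= 2 entities")
  v <- as.matrix(mat$values)
  a <- v[, ia, drop = FALSE]
  b <- v[, ib, drop = FALSE]
  p <- vapply(seq_len(nrow(v)), function(i) {
    xa <- a[i, ]; xb <- b[i, ]
    if (max(xa, xb) == min(xa, xb)) return(1)
    stats::wilcox.test(xa, xb, exact = FALSE)$p.value
  }, numeric(1))
  log2fc <- log2(rowMeans(expm1(a)) + eps) - log2(rowMeans(expm1(b)) + eps)
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = mat$gene_ids, log2fc = log2fc, p = p, padj = padj,
             significant = log2fc > log2fc_min & padj < alpha,
             stringsAsFactors = FALSE)
}

#' Derive the treatment-associated TLS signature
#'
#' Intersects a published TLS gene list with the genes that are
#' significantly differentially expressed between pre- and post-treatment
#' cells. Only significance is filtered, not direction (a `direction`
#' argument restricts to up- or down-regulated genes when wanted); order
#' follows the published list.
#'
#' @param published a [gene_signature()] of literature TLS genes.
#' @param de pre-vs-post DE results from [wilcoxon_de()].
#' @param alpha adjusted-p cutoff; default 0.05.
#' @param direction `"any"` (default), `"up"` or `"down"` on the DE `log2fc`.
#' @return a [gene_signature()] tagged `"neoCRT-TLS"`.
#' @export
derive_treatment_signature <- function(published, de, alpha = 0.05,
                                       direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  sig_genes <- de$gene[de$padj < alpha]
  if (direction == "up") sig_genes <- intersect(sig_genes, de$gene[de$log2fc > 0])
  if (direction == "down") sig_genes <- intersect(sig_genes, de$gene[de$log2fc < 0])
  keep <- published$genes[published$genes %in% sig_genes]
  if (length(keep) == 0L) {
    warning("no published TLS gene is significantly DE pre vs post; ",
            "the derived signature is empty")
    return(structure(list(name = published$name, genes = character(0),
                          source_tag = "neoCRT-TLS"),
                     class = "gene_signature"))
  }
  gene_signature(published$name, keep, source_tag = "neoCRT-TLS")
}

#' Top-k markers by log expression ratio
#'
#' Marker selection for a target population (e.g. LAMP3+ dendritic cells vs
#' the other DC subsets): candidates are the significant DEGs of target vs
#' other (per [wilcoxon_de()] defaults, which already implies target > other),
#' ranked by `log2((mean expm1 target + eps) / (mean expm1 other + eps))`
#' descending; the top `k` are returned.
#'
#' @param mat an [expression_matrix()], lognorm layer.
#' @param target,other entity ids of the two populations.
#' @param k number of markers; default 20. If fewer candidates exist, all are
#'   returned with a warning.
#' @param name signature name for the result.
#' @return a [gene_signature()] tagged `"top-ratio-markers"`.
#' @export
top_ratio_markers <- function(mat, target, other, k = 20,
                              name = "target_markers") {
  de <- wilcoxon_de(mat, target, other)
  cand <- de[de$significant & de$log2fc > 0, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no significant marker candidates")
  cand <- cand[order(-cand$log2fc), , drop = FALSE]
  if (nrow(cand) < k) {
    warning("only ", nrow(cand), " candidates for k = ", k)
    k <- nrow(cand)
  }
  gene_signature(name, cand$gene[seq_len(k)], source_tag = "top-ratio-markers")
}

#' Ratio of two score tables
#'
#' Entity-wise ratio `(num + shift) / (den + shift)` of two score tables over
#' the same entities (e.g. progenitor- vs terminal-exhaustion signature
#' scores). Module scores can be negative, so when the joint minimum of both
#' tables is not positive, both are shifted by `-min + eps` to make the
#' ratio well defined; already-positive scores are left unshifted.
#'
#' @param num,den score tables (data frames with `entity_id`, `score`) over
#'   the same entity set.
#' @param eps positive offset used when shifting; default 1e-6.
#' @param shift override the automatic shift with a fixed value.
#' @return a score table with `method = "ratio"` and the applied shift in
#'   `attr(, "shift")`.
#' @export
score_ratio <- function(num, den, eps = 1e-6, shift = NULL) {
  if (!setequal(num$entity_id, den$entity_id) ||
      length(num$entity_id) != length(den$entity_id)) {
    stop("numerator and denominator score different entity sets")
  }
  den <- den[match(num$entity_id, den$entity_id), , drop = FALSE]
  if (is.null(shift)) {
    m <- min(c(num$score, den$score))
    shift <- if (m > 0) 0 else -m + eps
  }
  out <- score_table(num$entity_id,
                     (num$score + shift) / (den$score + shift), "ratio")
  attr(out, "shift") <- shift
  out
}

#' Classify microsatellite status from an MSI score
#'
#' Fixed-cutoff classification: scores above `cutoff` are MSI
#' (microsatellite instable), scores at or below it MSS (stable). The
#' boundary value itself is assigned to MSS.
#'
#' @param msi_score non-negative MSI score (fraction of unstable sites, in
#'   percent units).
#' @param cutoff default 3.5.
#' @return `"MSI"` or `"MSS"` (vectorized over `msi_score`).
#' @export
classify_msi <- function(msi_score, cutoff = 3.5) {
  if (any(msi_score < 0)) stop("MSI score must be non-negative")
  ifelse(msi_score > cutoff, "MSI", "MSS")
}
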
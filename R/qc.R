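#' QC filter configuration
#'
#' Thresholds for the MAD-based cell filters. A cell is removed when its
#' mitochondrial fraction exceeds the median by more than `mito_mad_mult`
#' MADs (one-sided, high side only), or its total UMI count or detected-gene
#' count deviates from the median by more than `umi_mad_mult` /
#' `gene_mad_mult` MADs (two-sided). MAD here is the raw median absolute
#' deviation from the median, with no consistency constant.
#'
#' @param mito_mad_mult MAD multiplier for the mitochondrial-percentage
#'   filter; default 5.
#' @param umi_mad_mult MAD multiplier for the UMI-count filter; default 3.
#' @param gene_mad_mult MAD multiplier for the detected-gene filter; default 3.
#' @param mito_gene_prefix regex anchored at the gene-id start that marks
#'   mitochondrial genes; default `"MT-"`.
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(mito_mad_mult = 5, umi_mad_mult = 3,
                      gene_mad_mult = 3, mito_gene_prefix = "MT-") {
  if (mito_mad_mult <= 0 || umi_mad_mult <= 0 || gene_mad_mult <= 0) {
    stop("MAD multipliers must be positive")
  }
  structure(list(mito_mad_mult = mito_mad_mult, umi_mad_mult = umi_mad_mult,
                 gene_mad_mult = gene_mad_mult,
                 mito_gene_prefix = mito_gene_prefix),
            class = "qc_config")
}

# raw MAD: median absolute deviation from the median, no 1.4826 constant
raw_mad <- function(x) stats::median(abs(x - stats::median(x)))

mad_filter_one <- function(umi, ngene, mito_pct, qc) {
  med_m <- stats::median(mito_pct); mad_m <- raw_mad(mito_pct)
  med_u <- stats::median(umi);      mad_u <- raw_mad(umi)
  med_g <- stats::median(ngene);    mad_g <- raw_mad(ngene)
  fail_mito <- mito_pct > med_m + qc$mito_mad_mult * mad_m
  fail_umi  <- abs(umi - med_u) > qc$umi_mad_mult * mad_u
  fail_gene <- abs(ngene - med_g) > qc$gene_mad_mult * mad_g
  data.frame(umi = umi, n_genes = ngene, mito_pct = mito_pct,
             fail_mito = fail_mito, fail_umi = fail_umi,
             fail_gene = fail_gene,
             keep = !(fail_mito | fail_umi | fail_gene))
}

#' MAD-based cell quality filter
#'
#' Computes per-cell QC metrics (total UMI count, detected genes,
#' mitochondrial percentage) from a counts matrix and removes outlier cells:
#' mitochondrial percentage more than `mito_mad_mult` MADs above the median
#' (high side only), or UMI / detected-gene counts more than
#' `umi_mad_mult` / `gene_mad_mult` MADs from the median in either direction.
#' MADs are raw medians of absolute deviations (no consistency constant), so
#' when a metric's MAD is zero only cells whose deviation is strictly
#' positive in the filtered direction can be removed.
#'
#' When `sample` is supplied, medians and MADs are computed within each
#' sample independently; otherwise globally.
#'
#' @param mat an [expression_matrix()] with a counts layer.
#' @param qc a [qc_config()].
#' @param sample optional character/factor of per-cell sample labels, same
#'   length and order as `mat$entity_ids`.
#' @return list with `kept` (character vector of kept entity ids) and
#'   `qc_table` (data frame keyed by `cell_id` with the three metrics, the
#'   three failure flags and the keep decision).
#' @export
mad_filter <- function(mat, qc = qc_config(), sample = NULL) {
  stopifnot_counts(mat)
  if (length(mat$entity_ids) == 0L) stop("empty matrix: no cells to filter")
  v <- mat$values
  umi <- as.numeric(Matrix::colSums(v))
  ngene <- as.numeric(Matrix::colSums(v > 0))
  mito_rows <- grepl(paste0("^", qc$mito_gene_prefix), mat$gene_ids)
  mito <- if (any(mito_rows)) {
    as.numeric(Matrix::colSums(v[mito_rows, , drop = FALSE]))
  } else {
    rep(0, length(umi))
  }
  mito_pct <- ifelse(umi > 0, 100 * mito / umi, 0)

  if (is.null(sample)) {
    tab <- mad_filter_one(umi, ngene, mito_pct, qc)
    tab$sample <- NA_character_
  } else {
    if (length(sample) != length(mat$entity_ids)) {
      stop("'sample' must have one label per cell")
    }
    sample <- as.character(sample)
    tab <- NULL
    for (s in unique(sample)) {
      idx <- which(sample == s)
      sub <- mad_filter_one(umi[idx], ngene[idx], mito_pct[idx], qc)
      sub$sample <- s
      sub$.idx <- idx
      tab <- rbind(tab, sub)
    }
    tab <- tab[order(tab$.idx), , drop = FALSE]
    tab$.idx <- NULL
  }
  tab <- cbind(cell_id = mat$entity_ids, tab)
  rownames(tab) <- NULL
  list(kept = mat$entity_ids[tab$keep], qc_table = tab)
}

#' Log-normalize a counts matrix
#'
#' Per cell: `value = ln(1 + count / cell_total * scale)`, the standard
#' library-size normalization followed by log1p. Cells with zero total counts
#' are left all-zero with a warning.
#'
#' @param mat an [expression_matrix()] with a counts layer.
#' @param scale target library size after normalization; default 10000.
#' @return an [expression_matrix()] with layer `"lognorm"`; for every
#'   non-empty cell, `sum(expm1(values))` equals `scale`.
#' @export
lognormalize <- function(mat, scale = 1e4) {
  stopifnot_counts(mat)
  totals <- as.numeric(Matrix::colSums(mat$values))
  if (any(totals == 0)) {
    warning(sum(totals == 0), " cell(s) with zero total counts left all-zero")
  }
  div <- ifelse(totals > 0, totals, 1)
  v <- as.matrix(mat$values)
  v <- log1p(sweep(v, 2, scale / div, `*`))
  expression_matrix(v, mat$gene_ids, mat$entity_ids, layer = "lognorm")
}
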
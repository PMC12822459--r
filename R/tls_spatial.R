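#' Construct a spatial sample
#'
#' A binned spatial transcriptomics sample: an expression matrix over bins
#' joined to integer grid coordinates and a sample label (e.g. `"CR"` for a
#' complete responder, `"NR"` for a non-responder).
#'
#' @param mat an [expression_matrix()] over bins.
#' @param coords data frame with columns `bin_id`, `x`, `y` (integer grid
#'   indices); every matrix entity must have exactly one coordinate row and
#'   coordinates must be unique.
#' @param sample_label sample name.
#' @return a list of class `spatial_sample`.
#' @export
spatial_sample <- function(mat, coords, sample_label = "sample") {
  if (!inherits(mat, "expr_matrix")) stop("expected an 'expr_matrix'")
  if (!all(c("bin_id", "x", "y") %in% names(coords))) {
    stop("coords needs columns bin_id, x, y")
  }
  coords$bin_id <- as.character(coords$bin_id)
  if (!setequal(coords$bin_id, mat$entity_ids) ||
      nrow(coords) != length(mat$entity_ids)) {
    stop("coordinates do not match the matrix bins one-to-one")
  }
  if (anyDuplicated(coords[, c("x", "y")])) stop("duplicate bin coordinates")
  coords <- coords[match(mat$entity_ids, coords$bin_id), , drop = FALSE]
  rownames(coords) <- NULL
  structure(list(matrix = mat, coords = coords, sample_label = sample_label),
            class = "spatial_sample")
}

#' @export
print.spatial_sample <- function(x, ...) {
  cat(sprintf("<spatial_sample> '%s': %d bins x %d genes\n", x$sample_label,
              length(x$matrix$entity_ids), length(x$matrix$gene_ids)))
  invisible(x)
}

#' Calibrate absolute score cutoffs from top-fraction thresholds
#'
#' Converts "top p" fractions into absolute score cutoffs: the cutoff is the
#' smallest observed score such that the fraction of entities with score >=
#' cutoff is at least `p` (equivalently the `ceiling(p * n)`-th largest
#' score), so with distinct scores exactly `ceiling(p * n)` entities pass.
#' The defaults are the single-cell calibration used for TLS calling: T-cell
#' scores in the top 23.9% and B-cell scores in the top 5.4%, the T/B cell
#' fractions observed in matched single-cell data; supplying those fractions
#' directly via `p_t`/`p_b` is the supported alternative.
#'
#' @param t_scores,b_scores score tables (data frames with `entity_id`,
#'   `score`) for the T- and B-signature.
#' @param p_t,p_b top-fractions in (0, 1); defaults 0.239 and 0.054.
#' @return a list of class `threshold_spec` with `p_t`, `p_b`, `cutoff_t`,
#'   `cutoff_b`.
#' @export
calibrate_thresholds <- function(t_scores, b_scores, p_t = 0.239,
                                 p_b = 0.054) {
  spec <- list(p_t = p_t, p_b = p_b,
               cutoff_t = top_fraction_cutoff(t_scores$score, p_t),
               cutoff_b = top_fraction_cutoff(b_scores$score, p_b))
  structure(spec, class = "threshold_spec")
}

top_fraction_cutoff <- function(scores, p) {
  if (p <= 0 || p >= 1) stop("top-fraction must lie in (0, 1)")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (max(scores) == min(scores)) {
    warning("constant scores: cutoff set to the constant, all entities pass")
    return(scores[[1]])
  }
  k <- ceiling(p * length(scores))
  sort(scores, decreasing = TRUE)[[k]]
}

#' Call TLS bins by joint T/B score thresholds
#'
#' A bin is a TLS candidate when its summed T-signature score and summed
#' B-signature score both reach their calibrated cutoffs
#' (see [calibrate_thresholds()]); scores are computed with [summed_score()].
#'
#' @param sample a [spatial_sample()] with log-normalized expression.
#' @param t_sig,b_sig [gene_signature()]s for T and B cells.
#' @param spec a `threshold_spec`; if `NULL`, calibrated on this sample's own
#'   score distributions with `p_t`/`p_b`.
#' @param p_t,p_b top-fractions used when `spec` is `NULL`.
#' @return data frame with `bin_id`, `x`, `y`, `t_score`, `b_score`,
#'   `is_tls`; the `threshold_spec` used is attached as `attr(, "spec")`.
#' @export
call_tls_bins <- function(sample, t_sig, b_sig, spec = NULL,
                          p_t = 0.239, p_b = 0.054) {
  ts <- summed_score(sample$matrix, t_sig)
  bs <- summed_score(sample$matrix, b_sig)
  if (is.null(spec)) spec <- calibrate_thresholds(ts, bs, p_t, p_b)
  calls <- data.frame(bin_id = sample$coords$bin_id,
                      x = sample$coords$x, y = sample$coords$y,
                      t_score = ts$score, b_score = bs$score,
                      is_tls = ts$score >= spec$cutoff_t &
                               bs$score >= spec$cutoff_b,
                      stringsAsFactors = FALSE)
  attr(calls, "spec") <- spec
  calls
}

#' Label connected TLS regions
#'
#' Groups called TLS bins into connected components on the integer grid
#' (4- or 8-neighbourhood) and demotes components smaller than `min_size`
#' back to non-TLS. Components are discovered in row-major order (increasing
#' `y`, then `x`), so labels are deterministic.
#'
#' @param calls data frame from [call_tls_bins()] (needs `bin_id`, `x`, `y`,
#'   `is_tls`).
#' @param connectivity 4 or 8 (default 8: diagonal bins touch).
#' @param min_size smallest component kept as a region; default 2.
#' @return `calls` with columns `region_id` (integer, `NA` for non-TLS bins)
#'   and `is_tls` updated after the size filter; region sizes in
#'   `attr(, "region_sizes")`.
#' @export
label_regions <- function(calls, connectivity = 8, min_size = 2) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  calls <- calls[order(calls$y, calls$x), , drop = FALSE]
  rownames(calls) <- NULL
  n <- nrow(calls)
  region <- rep(NA_integer_, n)
  tls_idx <- which(calls$is_tls)
  if (length(tls_idx)) {
    key <- paste(calls$x, calls$y)
    pos <- seq_len(n)
    names(pos) <- key
    offs <- if (connectivity == 4) {
      cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
    } else {
      cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
    }
    lab <- 0L
    for (start in tls_idx) {
      if (!is.na(region[[start]])) next
      lab <- lab + 1L
      queue <- start
      region[[start]] <- lab
      while (length(queue)) {
        i <- queue[[1]]; queue <- queue[-1]
        nb_keys <- paste(calls$x[[i]] + offs[, 1], calls$y[[i]] + offs[, 2])
        nb <- pos[nb_keys]
        nb <- nb[!is.na(nb)]
        nb <- nb[calls$is_tls[nb] & is.na(region[nb])]
        region[nb] <- lab
        queue <- c(queue, nb)
      }
    }
  }
  sizes <- table(region)
  small <- as.integer(names(sizes)[sizes < min_size])
  demote <- region %in% small
  calls$is_tls[demote] <- FALSE
  region[demote] <- NA_integer_
  # relabel surviving regions consecutively, preserving discovery order
  kept <- sort(unique(region[!is.na(region)]))
  region <- match(region, kept)
  calls$region_id <- region
  attr(calls, "region_sizes") <-
    as.integer(table(factor(region, levels = seq_along(kept))))
  calls
}

#' TLS proportion of a sample
#'
#' Fraction of bins called TLS (after the region min-size filter when
#' [label_regions()] has been applied) among all bins of the sample.
#'
#' @param calls data frame with an `is_tls` column over all bins.
#' @return a number in `[0, 1]`.
#' @export
tls_proportion <- function(calls) {
  if (nrow(calls) == 0L) stop("no bins")
  mean(calls$is_tls)
}

#' ROC validation of a signature score
#'
#' Area under the ROC curve of a score against binary labels, computed by
#' the rank statistic (Mann-Whitney): the probability that a randomly chosen
#' positive outscores a randomly chosen negative, with ties credited 0.5.
#' Also returns the ROC curve points at every distinct score threshold.
#'
#' @param scores score table (data frame with `entity_id`, `score`).
#' @param labels logical vector (or named logical over `entity_id`) marking
#'   positives; both classes must be present.
#' @return list with `auc` and `curve` (data frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
validate_roc <- function(scores, labels) {
  if (!is.null(names(labels))) labels <- labels[scores$entity_id]
  labels <- as.logical(labels)
  if (anyNA(labels) || length(labels) != nrow(scores)) {
    stop("labels must cover every scored entity")
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores$score)  # mean ranks on ties -> 0.5 credit per tied pair
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores$score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores$score[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores$score[!labels] >= t), numeric(1))
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                          tpr = c(0, tpr)))
}
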
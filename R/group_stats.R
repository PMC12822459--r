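#' Pearson correlation between two score tables
#'
#' Matches the two tables by entity id (intersection; missing entities are
#' dropped with a message), then computes the sample Pearson coefficient and
#' its two-sided p-value from the t transform via [stats::cor.test()].
#'
#' @param x,y score tables (data frames with `entity_id`, `score`).
#' @param x_name,y_name labels for the record.
#' @return data frame with `x_name`, `y_name`, `n`, `r`, `p`.
#' @export
pearson <- function(x, y, x_name = "x", y_name = "y") {
  shared <- intersect(x$entity_id, y$entity_id)
  dropped <- length(union(x$entity_id, y$entity_id)) - length(shared)
  if (dropped > 0) message(dropped, " entity(ies) without a match dropped")
  if (length(shared) < 3) stop("need >= 3 shared entities")
  xv <- x$score[match(shared, x$entity_id)]
  yv <- y$score[match(shared, y$entity_id)]
  if (stats::sd(xv) == 0) stop("zero variance in '", x_name, "'")
  if (stats::sd(yv) == 0) stop("zero variance in '", y_name, "'")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  data.frame(x_name = x_name, y_name = y_name, n = length(shared),
             r = unname(ct$estimate), p = ct$p.value,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, mapped back to the
#' input order (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Two-group comparison
#'
#' Two-sided Wilcoxon rank-sum (normal approximation with continuity
#' correction, as throughout the package) or Welch t test, with a direction
#' flag: the sign of (a - b) on medians for Wilcoxon, means for t.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return list with `statistic`, `p`, `direction`, `test`.
#' @export
two_group_test <- function(a, b, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (test == "wilcoxon") {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    dir <- sign(stats::median(a) - stats::median(b))
  } else {
    ht <- stats::t.test(a, b)
    dir <- sign(mean(a) - mean(b))
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, direction = dir,
       test = test)
}

#' Cell-type composition per group x timepoint, with pre-to-post changes
#'
#' Fraction of each cell type within every (group, timepoint) stratum, plus
#' a signed pre-to-post change column per group when both timepoints are
#' present. By default every cell is weighted equally (pooled bars); with
#' `per_sample_mean = TRUE` fractions are first computed per sample and then
#' averaged within the stratum.
#'
#' @param cells data frame with columns `group`, `timepoint` (levels
#'   `"pre"`/`"post"`), a cell-type column, and (for the per-sample mode) a
#'   `sample` column.
#' @param type_col name of the cell-type column; default `"subtype"`.
#' @param per_sample_mean average per-sample fractions instead of pooling
#'   cells; default `FALSE`.
#' @return list with `fractions` (data frame `group`, `timepoint`, cell
#'   type, `n`, `fraction`) and `changes` (data frame `group`, cell type,
#'   `pre`, `post`, `change = post - pre`; `NULL` when a group lacks a
#'   timepoint, with a warning).
#' @export
composition_summary <- function(cells, type_col = "subtype",
                                per_sample_mean = FALSE) {
  if (!per_sample_mean) {
    frac <- proportion_table(cells, subtype_col = type_col)
  } else {
    if (!"sample" %in% names(cells)) stop("per-sample mode needs a 'sample' column")
    per <- proportion_table(cbind(cells,
                                  .gt = paste(cells$group, cells$timepoint)),
                            subtype_col = type_col, group_col = "sample",
                            timepoint_col = ".gt")
    split_gt <- strsplit(per$timepoint, " ", fixed = TRUE)
    per$group <- vapply(split_gt, `[[`, character(1), 1)
    per$tp <- vapply(split_gt, `[[`, character(1), 2)
    agg <- stats::aggregate(fraction ~ group + tp + subtype, per, mean)
    n <- stats::aggregate(n ~ group + tp + subtype, per, sum)
    frac <- data.frame(group = agg$group, timepoint = agg$tp,
                       subtype = agg$subtype, n = n$n,
                       fraction = agg$fraction, stringsAsFactors = FALSE)
    names(frac)[names(frac) == "subtype"] <- type_col
  }
  names(frac)[names(frac) == "subtype"] <- type_col

  changes <- NULL
  wide <- frac
  groups <- unique(wide$group)
  ok <- TRUE
  for (g in groups) {
    tps <- unique(wide$timepoint[wide$group == g])
    if (!all(c("pre", "post") %in% tps)) {
      warning("group '", g, "' lacks a timepoint; change column omitted")
      ok <- FALSE
    }
  }
  if (ok && all(c("pre", "post") %in% unique(wide$timepoint))) {
    pre <- wide[wide$timepoint == "pre", c("group", type_col, "fraction")]
    post <- wide[wide$timepoint == "post", c("group", type_col, "fraction")]
    changes <- merge(pre, post, by = c("group", type_col),
                     suffixes = c("_pre", "_post"))
    names(changes)[names(changes) == "fraction_pre"] <- "pre"
    names(changes)[names(changes) == "fraction_post"] <- "post"
    changes$change <- changes$post - changes$pre
    changes <- changes[order(changes$group, changes[[type_col]]), ,
                       drop = FALSE]
    rownames(changes) <- NULL
  }
  list(fractions = frac, changes = changes)
}
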
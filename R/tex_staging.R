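#' Split a bimodal pseudotime distribution into early and terminal stages
#'
#' Exhausted T cells whose pseudotime distribution shows two peaks are split
#' into an early and a terminal stage at the antimode: a Gaussian kernel
#' density is estimated (Silverman's rule-of-thumb bandwidth by default, on a
#' 512-point grid spanning `[min - 3*bw, max + 3*bw]`), the two local maxima
#' of highest density are taken as the peaks (ties broken toward the more
#' separated pair), and the split point is the grid location of minimum
#' density strictly between them (midpoint of the tying grid locations if the
#' minimum is attained more than once). Cells at or below the split point are
#' labeled `"early"`, cells above it `"terminal"`.
#'
#' Kernel density estimates of finite samples carry small wiggles, so the
#' presence of two local maxima alone does not establish bimodality: the
#' antimode must also be a real dip. The split is accepted only when the
#' density at the antimode is below `min_dip` times the lower of the two
#' peak densities; otherwise the distribution is declared unimodal.
#'
#' @param pseudotime named numeric vector (names = cell ids) of finite,
#'   non-negative pseudotime values; at least 20 cells.
#' @param bandwidth `"silverman"` (default, [stats::bw.nrd0()]) or a positive
#'   numeric bandwidth.
#' @param min_dip largest antimode-to-lower-peak density ratio still accepted
#'   as bimodal; default 0.9.
#' @return a list of class `stage_assignment`: `stage` (named character,
#'   `"early"`/`"terminal"`), `split_point`, `peaks` (two pseudotime
#'   locations, increasing), `diagnostics` (densities at the peaks and the
#'   antimode, the bandwidth used, and the number of local maxima found).
#'   If the density has fewer than two local maxima a condition of class
#'   `tlscape_unimodal` is signalled, carrying the same diagnostics; callers
#'   may catch it and fall back to a quantile split.
#' @export
split_bimodal <- function(pseudotime, bandwidth = "silverman",
                          min_dip = 0.9) {
  x <- pseudotime
  if (is.null(names(x))) names(x) <- as.character(seq_along(x))
  if (length(x) < 20) stop("need >= 20 cells to estimate the density")
  if (any(!is.finite(x))) stop("pseudotime must be finite")
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(x)
        else as.numeric(bandwidth)
  if (!is.finite(bw) || bw <= 0) stop("invalid bandwidth")
  d <- stats::density(x, bw = bw, n = 512,
                      from = min(x) - 3 * bw, to = max(x) + 3 * bw)
  y <- d$y
  n <- length(y)
  # interior local maxima: strictly above the left neighbor, at least equal
  # to the right (so plateaus count once, at their left edge)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                     y[2:(n - 1)] >= y[3:n], FALSE)
  maxima <- which(is_max)
  unimodal_error <- function(reason, extra = list()) {
    cond <- structure(
      class = c("tlscape_unimodal", "error", "condition"),
      list(message = paste0("pseudotime density is not bimodal (", reason,
                            ")"),
           call = sys.call(-2),
           diagnostics = c(list(n_maxima = length(maxima), bandwidth = bw,
                                grid = d$x, density = y), extra)))
    stop(cond)
  }
  if (length(maxima) < 2) {
    unimodal_error(paste(length(maxima), "local maximum found"))
  }
  # the two highest-density maxima; ties toward the more separated pair
  ord <- order(-y[maxima], -abs(d$x[maxima] - stats::median(d$x[maxima])))
  top2 <- sort(maxima[ord[1:2]])
  between <- seq(top2[1] + 1, top2[2] - 1)
  ymin <- min(y[between])
  if (ymin > min_dip * min(y[top2])) {
    unimodal_error("the dip between the peaks is too shallow",
                   list(dip_ratio = ymin / min(y[top2])))
  }
  tie <- between[y[between] == ymin]
  split_point <- mean(d$x[tie])
  stage <- ifelse(x <= split_point, "early", "terminal")
  names(stage) <- names(x)
  peaks <- d$x[top2]
  structure(list(
    stage = stage, split_point = split_point, peaks = peaks,
    diagnostics = list(peak_density = y[top2], antimode_density = ymin,
                       bandwidth = bw, n_maxima = length(maxima))),
    class = "stage_assignment")
}

#' @export
print.stage_assignment <- function(x, ...) {
  cat(sprintf("<stage_assignment> %d cells: %d early / %d terminal, split at %.3f (peaks %.3f, %.3f)\n",
              length(x$stage), sum(x$stage == "early"),
              sum(x$stage == "terminal"), x$split_point,
              x$peaks[1], x$peaks[2]))
  invisible(x)
}

#' Compare signature scores between exhaustion stages
#'
#' Two-sided test of early vs terminal scores, Wilcoxon rank-sum or Welch t.
#' Direction is the sign of (early - terminal) on medians for the Wilcoxon
#' test and on means for the t test.
#'
#' @param scores score table (data frame with `entity_id`, `score`).
#' @param stages a `stage_assignment` from [split_bimodal()], covering the
#'   scored entities.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return list with `statistic`, `p`, `direction` (+1/0/-1), `n_early`,
#'   `n_terminal`, `test`.
#' @export
compare_stages <- function(scores, stages, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  st <- stages$stage[scores$entity_id]
  if (anyNA(st)) stop("stage assignment missing for some scored entities")
  a <- scores$score[st == "early"]
  b <- scores$score[st == "terminal"]
  if (length(a) < 2 || length(b) < 2) stop("each stage needs >= 2 cells")
  if (test == "wilcoxon") {
    ht <- stats::wilcox.test(a, b, exact = FALSE)
    dir <- sign(stats::median(a) - stats::median(b))
  } else {
    ht <- stats::t.test(a, b)
    dir <- sign(mean(a) - mean(b))
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, direction = dir,
       n_early = length(a), n_terminal = length(b), test = test)
}

#' Subtype proportions per group x timepoint stratum
#'
#' Fractions of each cell subtype within every (group, timepoint) stratum of
#' a cell table, with the underlying counts.
#'
#' @param cells data frame with columns `subtype`, `group`, `timepoint` (one
#'   row per cell). Alternative column names can be passed via `subtype_col`
#'   etc.
#' @param subtype_col,group_col,timepoint_col column names; defaults
#'   `"subtype"`, `"group"`, `"timepoint"`.
#' @return data frame with `group`, `timepoint`, `subtype`, `n`, `fraction`;
#'   fractions sum to 1 within each stratum.
#' @export
proportion_table <- function(cells, subtype_col = "subtype",
                             group_col = "group",
                             timepoint_col = "timepoint") {
  for (cn in c(subtype_col, group_col, timepoint_col)) {
    if (!cn %in% names(cells)) stop("missing column '", cn, "'")
  }
  if (anyNA(cells[[subtype_col]]) || anyNA(cells[[group_col]]) ||
      anyNA(cells[[timepoint_col]])) {
    stop("missing labels in the cell table")
  }
  tab <- as.data.frame(table(
    group = cells[[group_col]], timepoint = cells[[timepoint_col]],
    subtype = cells[[subtype_col]]), stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "n"
  stratum_n <- stats::ave(tab$n, tab$group, tab$timepoint, FUN = sum)
  tab <- tab[stratum_n > 0, , drop = FALSE]
  stratum_n <- stratum_n[stratum_n > 0]
  tab$fraction <- tab$n / stratum_n
  tab <- tab[order(tab$group, tab$timepoint, tab$subtype), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
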
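#' Simulation configuration
#'
#' Parameters of the synthetic cohort and spatial generators. The defaults
#' describe the study design the package targets: a neoadjuvant
#' chemoradiotherapy cohort with responder / non-responder groups sampled
#' pre- and post-treatment, negative-binomial counts with subtype-specific
#' marker elevation, a two-component pseudotime mixture for exhausted T
#' cells (Tex), and spatial grids carrying contiguous planted TLS regions
#' with jointly elevated T- and B-signature genes.
#'
#' @param n_genes,n_cells matrix dimensions. The first `n_mito` genes are
#'   named `MT-1`, `MT-2`, ... so mitochondrial QC is exercised; the rest are
#'   `g<k>`.
#' @param subtype_table data frame with columns `subtype`, `group`,
#'   `timepoint`, `fraction`; fractions must sum to 1 within each
#'   (group, timepoint) stratum. The default plants the composition shift the
#'   design centres on: B cells and Tex expand post-treatment in responders
#'   only.
#' @param marker_map named list (by subtype) of `list(genes = <gene ids or
#'   indices>, lfc = <log2-fold elevation>)`; marker genes of a subtype have
#'   their negative-binomial mean multiplied by `2^lfc` in cells of that
#'   subtype.
#' @param nb_dispersion shared negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); default 0.5.
#' @param depth_mean expected library size in counts; per-cell depth varies
#'   by a lognormal(0, 0.3) factor. Default 5000.
#' @param pseudotime_mix list of two components `c(weight, mean, sd)` for
#'   the early / terminal Tex pseudotime mixture; weights must sum to 1.
#'   Default `list(c(0.5, 5, 1), c(0.5, 20, 1))`.
#' @param early_weight_by_stratum optional data frame (`group`, `timepoint`,
#'   `weight`) overriding the early-component weight per stratum, to plant
#'   stage-composition shifts.
#' @param grid_shape `(rows, cols)` of the spatial grid; default `c(60, 60)`.
#' @param planted_regions list of
#'   `list(center = c(x, y), radius, t_lfc, b_lfc)` discs; a bin belongs to a
#'   disc when its Euclidean distance from the center is at most `radius`
#'   (integer bin coordinates). Default: three discs of radius 4-5 covering
#'   about 5.5% of the default grid — matched to the B-threshold calibration
#'   fraction, as the calibration premise implies — with +2 log2-fold T and
#'   B elevation.
#' @param treatment_genes gene ids or indices shifted in post-treatment
#'   cells by `treatment_lfc` (log2-fold); default none. These define the
#'   ground-truth DE mask.
#' @param treatment_lfc log2-fold pre-to-post shift; default 1.
#' @param tex_subtype subtype name carrying pseudotime; default `"Tex"`.
#' @param n_mito number of mitochondrial genes; default 10.
#' @param samples_per_stratum biological replicates per (group, timepoint);
#'   default 2.
#' @param seed integer seed; the generators derive a deterministic
#'   sub-stream per stage from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_cells = 4000,
                       subtype_table = NULL, marker_map = NULL,
                       nb_dispersion = 0.5, depth_mean = 5000,
                       pseudotime_mix = list(c(0.5, 5, 1), c(0.5, 20, 1)),
                       early_weight_by_stratum = NULL,
                       grid_shape = c(60, 60),
                       planted_regions = list(
                         list(center = c(15, 15), radius = 5, t_lfc = 2, b_lfc = 2),
                         list(center = c(45, 20), radius = 4, t_lfc = 2, b_lfc = 2),
                         list(center = c(30, 48), radius = 4.5, t_lfc = 2, b_lfc = 2)),
                       treatment_genes = integer(0), treatment_lfc = 1,
                       tex_subtype = "Tex", n_mito = 10,
                       samples_per_stratum = 2, seed = 1L) {
  if (n_genes <= 0 || n_cells <= 0) stop("non-positive dimensions")
  if (is.null(subtype_table)) {
    subtype_table <- expand.grid(
      subtype = c("Epithelial", "Tcell", "Bcell", "Myeloid", "Tex"),
      group = c("R", "NR"), timepoint = c("pre", "post"),
      stringsAsFactors = FALSE)
    base <- c(Epithelial = 0.40, Tcell = 0.25, Bcell = 0.10,
              Myeloid = 0.15, Tex = 0.10)
    post_r <- c(Epithelial = 0.29, Tcell = 0.25, Bcell = 0.18,
                Myeloid = 0.13, Tex = 0.15)
    subtype_table$fraction <- ifelse(
      subtype_table$group == "R" & subtype_table$timepoint == "post",
      post_r[subtype_table$subtype], base[subtype_table$subtype])
  }
  by_stratum <- tapply(subtype_table$fraction,
                       paste(subtype_table$group, subtype_table$timepoint),
                       sum)
  if (any(abs(by_stratum - 1) > 1e-8)) {
    stop("subtype fractions must sum to 1 within each group x timepoint")
  }
  gene_ids <- c(if (n_mito > 0) paste0("MT-", seq_len(n_mito)),
                paste0("g", seq_len(n_genes - n_mito)))
  if (is.null(marker_map)) {
    nm <- n_mito
    marker_map <- list(
      Tcell = list(genes = gene_ids[nm + 1:40], lfc = 2),
      Bcell = list(genes = gene_ids[nm + 41:80], lfc = 2),
      Tex   = list(genes = gene_ids[nm + 81:120], lfc = 2),
      Myeloid = list(genes = gene_ids[nm + 121:160], lfc = 2))
    marker_map <- marker_map[names(marker_map) %in% subtype_table$subtype]
  }
  marker_map <- lapply(marker_map, function(m) {
    g <- if (is.numeric(m$genes)) gene_ids[m$genes] else as.character(m$genes)
    if (anyNA(g) || !all(g %in% gene_ids)) stop("marker gene outside matrix")
    if (any(!is.finite(m$lfc))) stop("marker elevation must be finite")
    list(genes = g, lfc = m$lfc)
  })
  w <- vapply(pseudotime_mix, `[[`, numeric(1), 1)
  if (abs(sum(w) - 1) > 1e-8) stop("pseudotime mixture weights must sum to 1")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  for (r in planted_regions) {
    if (r$radius < 1) stop("region radius must be >= 1")
    if (any(!is.finite(c(r$t_lfc, r$b_lfc)))) stop("elevations must be finite")
    if (r$center[1] - r$radius < 1 || r$center[1] + r$radius > grid_shape[2] ||
        r$center[2] - r$radius < 1 || r$center[2] + r$radius > grid_shape[1]) {
      stop("planted region extends outside the grid")
    }
  }
  treatment_genes <- if (is.numeric(treatment_genes)) {
    gene_ids[treatment_genes]
  } else as.character(treatment_genes)
  if (anyNA(treatment_genes)) stop("treatment gene outside matrix")
  structure(list(
    n_genes = n_genes, n_cells = n_cells, gene_ids = gene_ids,
    subtype_table = subtype_table, marker_map = marker_map,
    nb_dispersion = nb_dispersion, depth_mean = depth_mean,
    pseudotime_mix = pseudotime_mix,
    early_weight_by_stratum = early_weight_by_stratum,
    grid_shape = grid_shape, planted_regions = planted_regions,
    treatment_genes = treatment_genes, treatment_lfc = treatment_lfc,
    tex_subtype = tex_subtype, n_mito = n_mito,
    samples_per_stratum = samples_per_stratum, seed = as.integer(seed)),
    class = "sim_config")
}

# gene baseline means on the count scale, summing to the expected depth
base_gene_means <- function(config) {
  mu <- local_seed(stage_seed(config$seed, "gene_means"),
                   stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1))
  mu / sum(mu) * config$depth_mean
}

nb_draw <- function(n, mu, dispersion) {
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a treatment cohort of single cells
#'
#' Draws a gene x cell count matrix plus a cell table from a [sim_config()]:
#' cells are split evenly over the group x timepoint strata and their
#' replicate samples; subtypes follow the configured per-stratum fractions;
#' counts are negative binomial with a shared dispersion, lognormal(0, 0.3)
#' per-cell depth factors, marker-gene mean elevation per subtype, and an
#' optional log2-fold shift of the treatment genes in post-treatment cells.
#' Tex cells carry pseudotime drawn from the configured two-component
#' mixture (truncated at 0); the generating component is recorded as the
#' ground-truth stage.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (counts [expression_matrix()]), `cells` (data
#'   frame: `cell_id`, `sample`, `group`, `timepoint`, `subtype`,
#'   `pseudotime` — `NA` outside Tex), and `truth` (list: `subtype`,
#'   `tex_stage` (named, Tex cells only), `de_gene_mask` (named logical over
#'   genes)).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("expected a 'sim_config'")
  strata <- unique(config$subtype_table[, c("group", "timepoint")])
  n_strata <- nrow(strata)
  stratum_of <- rep(seq_len(n_strata), length.out = config$n_cells)
  cells <- data.frame(
    cell_id = sprintf("cell%05d", seq_len(config$n_cells)),
    group = strata$group[stratum_of],
    timepoint = strata$timepoint[stratum_of],
    stringsAsFactors = FALSE)
  cells$sample <- paste0(cells$group, "_", cells$timepoint, "_s",
                         (seq_len(config$n_cells) %% config$samples_per_stratum) + 1L)

  cells$subtype <- local_seed(stage_seed(config$seed, "subtypes"), {
    out <- character(config$n_cells)
    for (i in seq_len(n_strata)) {
      idx <- which(stratum_of == i)
      st <- config$subtype_table[
        config$subtype_table$group == strata$group[i] &
        config$subtype_table$timepoint == strata$timepoint[i], ]
      out[idx] <- sample(st$subtype, length(idx), replace = TRUE,
                         prob = st$fraction)
    }
    out
  })

  # pseudotime for Tex cells, per-stratum early weight when configured
  tex_idx <- which(cells$subtype == config$tex_subtype)
  cells$pseudotime <- NA_real_
  tex_stage <- character(0)
  if (length(tex_idx)) {
    comps <- config$pseudotime_mix
    drawn <- local_seed(stage_seed(config$seed, "pseudotime"), {
      comp <- integer(length(tex_idx))
      for (i in seq_along(tex_idx)) {
        w <- vapply(comps, `[[`, numeric(1), 1)
        ov <- config$early_weight_by_stratum
        if (!is.null(ov)) {
          row <- ov[ov$group == cells$group[tex_idx[i]] &
                    ov$timepoint == cells$timepoint[tex_idx[i]], ]
          if (nrow(row) == 1) w <- c(row$weight, 1 - row$weight)
        }
        comp[i] <- sample.int(length(comps), 1, prob = w)
      }
      pt <- vapply(comp, function(k) {
        stats::rnorm(1, comps[[k]][2], comps[[k]][3])
      }, numeric(1))
      list(comp = comp, pt = pmax(pt, 0))
    })
    cells$pseudotime[tex_idx] <- drawn$pt
    tex_stage <- ifelse(drawn$comp == 1L, "early", "terminal")
    names(tex_stage) <- cells$cell_id[tex_idx]
  }

  base_mu <- base_gene_means(config)
  lfc_mat <- matrix(0, nrow = config$n_genes, ncol = config$n_cells)
  for (st in names(config$marker_map)) {
    m <- config$marker_map[[st]]
    rows <- match(m$genes, config$gene_ids)
    cols <- cells$subtype == st
    if (any(cols)) lfc_mat[rows, cols] <- lfc_mat[rows, cols] + m$lfc
  }
  if (length(config$treatment_genes)) {
    rows <- match(config$treatment_genes, config$gene_ids)
    cols <- cells$timepoint == "post"
    if (any(cols)) lfc_mat[rows, cols] <- lfc_mat[rows, cols] +
      config$treatment_lfc
  }

  counts <- local_seed(stage_seed(config$seed, "counts"), {
    depth <- stats::rlnorm(config$n_cells, 0, 0.3)
    mu <- (base_mu %o% depth) * 2^lfc_mat
    matrix(nb_draw(length(mu), as.vector(mu), config$nb_dispersion),
           nrow = config$n_genes)
  })
  mat <- expression_matrix(counts, config$gene_ids, cells$cell_id,
                           layer = "counts")
  truth <- list(
    subtype = stats::setNames(cells$subtype, cells$cell_id),
    tex_stage = tex_stage,
    de_gene_mask = stats::setNames(
      config$gene_ids %in% config$treatment_genes, config$gene_ids))
  cells <- cells[, c("cell_id", "sample", "group", "timepoint", "subtype",
                     "pseudotime")]
  list(matrix = mat, cells = cells, truth = truth)
}

# enumerate bins of a disc: Euclidean distance from center <= radius,
# integer coordinates
disc_bins <- function(center, radius, grid_shape) {
  xs <- seq_len(grid_shape[2]); ys <- seq_len(grid_shape[1])
  g <- expand.grid(x = xs, y = ys)
  g[(g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2, , drop = FALSE]
}

#' Simulate a binned spatial sample with planted TLS regions
#'
#' Generates a `rows x cols` grid of bins with negative-binomial background
#' counts; inside each planted disc the T-signature genes' means are
#' multiplied by `2^t_lfc` and the B-signature genes' by `2^b_lfc`. The
#' ground-truth mask marks exactly the planted bins.
#'
#' @param config a [sim_config()] (uses `grid_shape`, `planted_regions`,
#'   `n_genes`, `nb_dispersion`, `depth_mean`, `seed`).
#' @param t_sig,b_sig [gene_signature()]s drawn from the config's gene ids.
#' @param sample_label label for the sample; default `"CR"`.
#' @return list with `sample` (a [spatial_sample()], counts layer) and
#'   `truth` (list: `tls_bin_mask`, named logical over bins;
#'   `planted_fraction`).
#' @export
simulate_spatial <- function(config, t_sig, b_sig, sample_label = "CR") {
  if (!inherits(config, "sim_config")) stop("expected a 'sim_config'")
  if (any(config$grid_shape < 1)) stop("non-positive grid")
  stopifnot(inherits(t_sig, "gene_signature"), inherits(b_sig, "gene_signature"))
  if (!all(c(t_sig$genes, b_sig$genes) %in% config$gene_ids)) {
    stop("signature genes must be among the config's gene ids")
  }
  rows <- config$grid_shape[1]; cols <- config$grid_shape[2]
  coords <- expand.grid(x = seq_len(cols), y = seq_len(rows))
  coords <- coords[order(coords$y, coords$x), , drop = FALSE]
  coords$bin_id <- sprintf("bin_%d_%d", coords$x, coords$y)
  n_bins <- nrow(coords)

  mask <- rep(FALSE, n_bins)
  names(mask) <- coords$bin_id
  lfc_mat <- matrix(0, nrow = config$n_genes, ncol = n_bins)
  t_rows <- match(t_sig$genes, config$gene_ids)
  b_rows <- match(b_sig$genes, config$gene_ids)
  for (r in config$planted_regions) {
    db <- disc_bins(r$center, r$radius, config$grid_shape)
    ids <- sprintf("bin_%d_%d", db$x, db$y)
    j <- match(ids, coords$bin_id)
    mask[j] <- TRUE
    # last write wins where discs overlap; genes in both signatures take
    # the B elevation
    lfc_mat[t_rows, j] <- r$t_lfc
    lfc_mat[b_rows, j] <- r$b_lfc
  }

  base_mu <- base_gene_means(config)
  counts <- local_seed(stage_seed(config$seed, "spatial_counts"), {
    depth <- stats::rlnorm(n_bins, 0, 0.3)
    mu <- (base_mu %o% depth) * 2^lfc_mat
    matrix(nb_draw(length(mu), as.vector(mu), config$nb_dispersion),
           nrow = config$n_genes)
  })
  mat <- expression_matrix(counts, config$gene_ids, coords$bin_id,
                           layer = "counts")
  samp <- spatial_sample(mat, coords[, c("bin_id", "x", "y")], sample_label)
  list(sample = samp,
       truth = list(tls_bin_mask = mask, planted_fraction = mean(mask)))
}
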
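# shared small fixtures, built in code at test time

tiny_cohort <- function(n_genes = 300, n_cells = 600, seed = 11, ...) {
  simulate_cohort(sim_config(n_genes = n_genes, n_cells = n_cells,
                             seed = seed, ...))
}

# a null expression matrix: iid NB counts, no structure at all
null_matrix <- function(n_genes = 200, n_cells = 400, seed = 5,
                        layer = "lognorm") {
  set.seed(seed)
  counts <- matrix(rnbinom(n_genes * n_cells, mu = 5, size = 2),
                   nrow = n_genes,
                   dimnames = list(paste0("g", seq_len(n_genes)),
                                   paste0("c", seq_len(n_cells))))
  m <- expression_matrix(counts, layer = "counts")
  if (layer == "lognorm") lognormalize(m) else m
}
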
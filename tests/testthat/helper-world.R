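# A scaled-down world configuration for fast module tests: same planted
# structure as the defaults, an order of magnitude smaller.
small_config <- function(seed = 1, ...) {
  world_config(
    n_genes = 500,
    n_datasets = 3,
    n_samples_per_dataset = 20,
    n_pathways = 10,
    n_essential_pathways = 3,
    pathway_size = 8,
    ppi_block_sizes = rep(35, 6),
    n_chromosomes = 3,
    seed = seed,
    ...)
}
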
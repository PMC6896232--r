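# Shared fixtures built in code at test time.

# small two-condition generator config; biology kept weak so that
# normalization fixtures have a stable median gene
quiet_config <- function(n_genes = 400, n_motifs = 4, seed = 3,
                         noise_sd = 0.2, site_rate = 0.1,
                         timepoints = 4, replicates = 1) {
  generator_config(
    n_genes = n_genes, n_motifs = n_motifs,
    conditions = c("alpha", "beta"), timepoints_per_condition = timepoints,
    replicates = replicates, site_rate = site_rate, noise_sd = noise_sd,
    intercept_range = c(5, 5), depth_per_sample = 2e6, seed = seed
  )
}

# flat (zero-amplitude, zero-baseline) activity shapes for a config
flat_shapes <- function(config) {
  lapply(setNames(config$motif_ids, config$motif_ids), function(m) {
    lapply(setNames(config$conditions, config$conditions), function(cc) {
      activity_shape("constant", amplitude = 0)
    })
  })
}

# a tiny deterministic count matrix with parseable sample names
toy_counts <- function() {
  counts <- matrix(
    c(10L, 20L, 5L,
      40L, 10L, 0L),
    nrow = 3,
    dimnames = list(c("g1", "g2", "g3"), c("alpha_0_1", "alpha_1_1"))
  )
  count_matrix(counts, aligned_totals = c(1e6, 2e6))
}

one_hot_motif <- function(consensus, id = "M1", name = id) {
  bases <- strsplit(consensus, "")[[1]]
  pfm <- matrix(0, 4, length(bases))
  pfm[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <- 100
  motif_model(id, name, pfm)
}
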
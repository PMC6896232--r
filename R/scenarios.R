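# Documented synthetic scenarios used for recovery benchmarks.

scenario_shapes <- function() {
  lg <- function(a, onset, rate = 2) activity_shape("logistic", a, onset, rate)
  list(
    Tf1 = list(alpha = lg(+1.2, 2), beta = lg(-1.2, 2)),
    Tf2 = list(alpha = lg(+1.2, 4), beta = lg(+1.2, 4)),
    Tf3 = list(alpha = lg(-1.0, 5), beta = lg(+1.0, 5)),
    Tf4 = list(alpha = lg(+1.0, 1), beta = lg(+1.0, 5)),
    Tf5 = list(alpha = lg(-1.0, 3), beta = lg(+1.0, 1)),
    Tf6 = list(alpha = lg(+1.0, 5), beta = lg(-1.0, 1)),
    Tf7 = list(alpha = lg(-1.0, 1), beta = lg(-1.0, 3)),
    Tf8 = list(alpha = lg(+1.0, 3), beta = lg(+1.0, 1))
  )
}

#' The documented five-edge regulatory recovery scenario
#'
#' A fixed synthetic study for benchmarking edge recovery: eight
#' transcription factors with consensus (one-hot) motifs, two differentiation
#' conditions of eight days, 300 background genes whose promoters carry
#' Poisson-planted sites for every motif, and five planted regulatory
#' couplings onto the promoters of five target TFs — each target dominated
#' by a single regulator so that its expression tracks that regulator's
#' activity. The two regulators' trajectories are orthogonal by construction
#' (one antisymmetric, one symmetric across the condition pair), so neither
#' can proxy the other's targets, and TF promoters carry no sites beyond the
#' planted ones, so the binding-site condition blocks spurious edges.
#' Intercepts are held constant and noise low; the benchmark isolates the
#' edge rule, not normalization robustness.
#'
#' Planted edges: Tf1 -> Tf4 (+), Tf1 -> Tf5 (-), Tf1 -> Tf6 (+),
#' Tf2 -> Tf7 (+), Tf2 -> Tf8 (-); each target promoter carries two sites of
#' its regulator's motif and no other TF promoter carries any.
#'
#' @param seed Integer seed (default 42).
#' @param n_background Number of background genes (default 300).
#' @param coupling Absolute coupling strength in log2 units (default 2).
#' @param noise_sd Expression noise SD (default 0.15).
#' @return List with `config`, `motifs`, `promoters`, `sites` (true),
#'   `counts`, `log2_latent`, `activities`, `truth` (with `true_edges`), and
#'   `tf_map`.
#' @export
simulate_grn_scenario <- function(seed = 42, n_background = 300,
                                  coupling = 2, noise_sd = 0.15) {
  tf_ids <- paste0("Tf", 1:8)
  gene_ids <- c(sprintf("G%03d", seq_len(n_background)), tf_ids)
  config <- generator_config(
    n_genes = n_background + 8, n_motifs = 8,
    conditions = c("alpha", "beta"), timepoints_per_condition = 8,
    replicates = 1, site_rate = 0.3, activity_shapes = scenario_shapes(),
    intercept_range = c(5, 5), noise_sd = noise_sd, depth_per_sample = 2e6,
    gene_ids = gene_ids, motif_ids = tf_ids, seed = seed
  )
  motifs <- random_motifs(8, width = 10, dominance = 1, ids = tf_ids,
                          names = tf_ids, seed = seed)
  A <- generate_activities(config)
  planted <- tibble(
    regulator = c("Tf1", "Tf1", "Tf1", "Tf2", "Tf2"),
    target = c("Tf4", "Tf5", "Tf6", "Tf7", "Tf8"),
    coupling = coupling * c(1, -1, 1, 1, -1)
  )
  planted$sign <- ifelse(planted$coupling > 0, "inductive", "inhibitory")
  set.seed(seed + 10L)
  sites <- matrix(0L, config$n_genes, 8, dimnames = list(gene_ids, tf_ids))
  sites[seq_len(n_background), ] <-
    matrix(rpois(n_background * 8, config$site_rate), n_background, 8)
  effect <- matrix(0, config$n_genes, 8, dimnames = list(gene_ids, tf_ids))
  effect[seq_len(n_background), ] <- sites[seq_len(n_background), ]
  for (i in seq_len(nrow(planted))) {
    sites[planted$target[i], planted$regulator[i]] <- 2L
    effect[planted$target[i], planted$regulator[i]] <- planted$coupling[i]
  }
  prom <- generate_promoters(config, motifs, sites = sites)
  ex <- generate_expression(sites, A, config, effect = effect)
  truth <- synthetic_truth(sites, A, ex$truth$true_intercepts,
                           true_edges = planted[, c("regulator", "target", "sign")],
                           sample_depths = ex$truth$sample_depths)
  list(config = config, motifs = motifs, promoters = prom$promoters,
       sites = sites, counts = ex$counts, log2_latent = ex$log2_latent,
       activities = A, truth = truth,
       tf_map = setNames(as.list(tf_ids), tf_ids))
}

#' Run network inference on a synthetic scenario and score recovery
#'
#' Executes the full path — depth normalization, promoter scanning, motif
#' selection, edge inference — on a [simulate_grn_scenario()] dataset and
#' compares the inferred edges with the planted ones.
#'
#' @param scenario Result of [simulate_grn_scenario()].
#' @param rel_score Scan threshold (default 0.85).
#' @param corr_threshold Edge correlation threshold (default 0.8).
#' @param alpha Motif selection threshold (default 0.01).
#' @return List with the inferred `network`, the `model`, the site matrix
#'   `N`, and `recovery`: a one-row tibble with precision, recall, and the
#'   fraction of recovered edges with the correct sign.
#' @export
score_edge_recovery <- function(scenario, rel_score = 0.85,
                                corr_threshold = 0.8, alpha = 0.01) {
  expr <- normalize_counts(scenario$counts)
  N <- build_site_matrix(scenario$promoters, scenario$motifs,
                         rel_score = rel_score)
  model <- motif_significance(expr, N, alpha = alpha)
  net <- infer_edges(model, expr, N, threshold = corr_threshold,
                     motifs = scenario$motifs)
  truth <- scenario$truth$true_edges
  key <- function(df) paste(df$regulator, df$target)
  inferred <- net$edges
  tp_keys <- intersect(key(inferred), key(truth))
  precision <- if (nrow(inferred) == 0) NA_real_ else
    length(tp_keys) / nrow(inferred)
  recall <- length(tp_keys) / nrow(truth)
  sign_ok <- map_lgl(tp_keys, function(k) {
    inferred$sign[key(inferred) == k] == truth$sign[key(truth) == k]
  })
  recovery <- tibble(
    n_true = nrow(truth), n_inferred = nrow(inferred),
    n_recovered = length(tp_keys), precision = precision, recall = recall,
    sign_accuracy = if (length(sign_ok) > 0) mean(sign_ok) else NA_real_
  )
  list(network = net, model = model, N = N, recovery = recovery)
}
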
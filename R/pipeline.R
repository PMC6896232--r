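# Workflow drivers: configuration, the trajectory-mapping workflow and the
# network-inference workflow, each writing its artifacts with a manifest.

#' Pipeline configuration
#'
#' Collects file paths and every threshold used by the workflows, with the
#' pipeline defaults. Configurations can also be read from YAML with
#' [load_pipeline_config()].
#'
#' @param counts,promoters,motifs,gene_sets Input paths (TSV counts, FASTA
#'   promoters, JASPAR motifs, GMT gene sets).
#' @param out_dir Output directory.
#' @param min_max_rpm,min_fold Differential gene filter thresholds.
#' @param high_expr_min_rpm,median_window Fine normalization parameters.
#' @param pseudocount Pseudocount in rpm units.
#' @param tf_min_rpm TF eligibility threshold.
#' @param alpha Motif selection significance threshold.
#' @param corr_threshold Edge correlation threshold.
#' @param rel_score Promoter scan relative-score threshold.
#' @param resamples Enrichment resamplings.
#' @param seed Integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, promoters = NULL, motifs = NULL,
                            gene_sets = NULL, out_dir = ".",
                            min_max_rpm = 3, min_fold = 4,
                            high_expr_min_rpm = 32, median_window = 101,
                            pseudocount = 1, tf_min_rpm = 6, alpha = 0.01,
                            corr_threshold = 0.8, rel_score = 0.8,
                            resamples = 10000, seed = 1) {
  stopifnot(min_max_rpm >= 0, min_fold >= 1, alpha > 0, alpha <= 1,
            corr_threshold >= 0, corr_threshold <= 1,
            rel_score >= 0, rel_score <= 1, resamples >= 1000)
  structure(
    list(counts = counts, promoters = promoters, motifs = motifs,
         gene_sets = gene_sets, out_dir = out_dir,
         min_max_rpm = min_max_rpm, min_fold = min_fold,
         high_expr_min_rpm = high_expr_min_rpm,
         median_window = median_window, pseudocount = pseudocount,
         tf_min_rpm = tf_min_rpm, alpha = alpha,
         corr_threshold = corr_threshold, rel_score = rel_score,
         resamples = resamples, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @param overrides Named list of values taking precedence over the file.
#' @export
load_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

require_inputs <- function(config, fields) {
  for (f in fields) {
    p <- config[[f]]
    if (is.null(p)) abort(sprintf("config field '%s' is required", f))
    if (!file.exists(p)) abort(sprintf("input %s not found: %s", f, p))
  }
}

write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(path, config, stages) {
  jsonlite::write_json(
    list(package = "germnet",
         version = as.character(utils::packageVersion("germnet")),
         config = config[!map_lgl(config, is.null)],
         stages = stages),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the trajectory-mapping workflow
#'
#' Normalizes counts, computes the differential gene filter and per-condition
#' differential sets, clusters samples, fits the PCA trajectory map, and
#' writes every artifact (normalized matrix, factors, Newick tree, scores,
#' loadings, variance fractions, Venn regions) together with a JSON manifest
#' echoing every threshold and the seed. Deterministic given the seed.
#'
#' @param config A [pipeline_config()] with at least `counts` and `out_dir`.
#' @return Invisibly, a list with the in-memory results and written paths.
#' @export
run_trajectory_workflow <- function(config) {
  require_inputs(config, "counts")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cm <- load_counts(config$counts)
  expr <- normalize_counts(cm, config$high_expr_min_rpm,
                           config$median_window,
                           pseudocount = config$pseudocount)
  genes <- filter_genes(expr, config$min_max_rpm, config$min_fold)
  inform(sprintf("differential filter kept %d/%d genes",
                 length(genes), length(expr$gene_ids)))
  tree <- cluster_samples(expr, genes)
  pca <- fit_pca(expr, genes)
  diff <- differential_sets(expr, min_max_rpm = config$min_max_rpm,
                            min_fold = config$min_fold)
  out <- function(f) file.path(config$out_dir, f)
  paths <- c(
    normalized = write_tsv_matrix(expr$rpm, out("normalized_rpm.tsv"), "gene_id"),
    factors = {
      write.table(data.frame(sample = names(expr$normalization_factors),
                             factor = unname(expr$normalization_factors)),
                  out("fine_factors.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out("fine_factors.tsv")
    },
    tree = write_newick(tree, out("clustering.nwk")),
    scores = write_tsv_matrix(pca$scores, out("pca_scores.tsv"), "sample"),
    loadings = write_tsv_matrix(pca$loadings, out("pca_loadings.tsv"), "gene_id"),
    venn = {
      write.table(diff$venn, out("venn_regions.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      out("venn_regions.tsv")
    }
  )
  manifest <- write_manifest(out("manifest.json"), config, list(
    counts = dim(cm$counts), filtered_genes = length(genes),
    pca_components = ncol(pca$loadings),
    variance_fractions = pca$variance_fractions,
    differential_set_sizes = map_int(diff$sets, length),
    union_size = diff$union_size
  ))
  invisible(list(counts = cm, expr = expr, genes = genes, tree = tree,
                 pca = pca, differential = diff,
                 paths = c(paths, manifest = manifest)))
}

#' Run the network-inference workflow
#'
#' Normalizes counts, determines eligible TFs, scans promoters into the
#' site-count matrix, selects significant motifs, infers the signed network,
#' enumerates feed-forward loops and dense overlapping regulons, and writes
#' the site matrix, activities, p-values, edge table, SIF and GraphML
#' exports, and a JSON manifest. Deterministic given the seed.
#'
#' @param config A [pipeline_config()] with `counts`, `promoters`, `motifs`
#'   and `out_dir`.
#' @return Invisibly, a list with the in-memory results and written paths.
#' @export
run_network_workflow <- function(config) {
  require_inputs(config, c("counts", "promoters", "motifs"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cm <- load_counts(config$counts)
  motifs <- read_jaspar(config$motifs)
  promoters <- Biostrings::readDNAStringSet(config$promoters)
  expr <- normalize_counts(cm, config$high_expr_min_rpm,
                           config$median_window,
                           pseudocount = config$pseudocount)
  elig <- eligible_tfs(expr, motifs, config$tf_min_rpm)
  if (length(elig) == 0) abort("no eligible transcription factor motifs")
  N <- build_site_matrix(promoters, motifs[elig], rel_score = config$rel_score,
                         genes = expr$gene_ids)
  model <- motif_significance(expr, N, alpha = config$alpha)
  net <- infer_edges(model, expr, N, threshold = config$corr_threshold,
                     motifs = motifs)
  ffl <- count_ffl(net)
  dors <- find_dors(net)
  out <- function(f) file.path(config$out_dir, f)
  paths <- c(
    sites = write_tsv_matrix(N$N, out("site_counts.tsv"), "gene_id"),
    activities = write_tsv_matrix(model$A, out("activities.tsv"), "motif"),
    p_values = {
      write.table(attr(model, "selection"), out("motif_selection.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      out("motif_selection.tsv")
    },
    edges = export_network(net, out("network_edges.tsv"), "tsv"),
    sif = export_network(net, out("network.sif"), "sif"),
    graphml = export_network(net, out("network.graphml"), "graphml")
  )
  manifest <- write_manifest(out("manifest.json"), config, list(
    counts = dim(cm$counts), motifs_read = length(motifs),
    eligible_motifs = length(elig), selected_motifs = nrow(net$nodes),
    edges = nrow(net$edges), ffl = nrow(ffl), dors = nrow(dors)
  ))
  invisible(list(counts = cm, expr = expr, eligible = elig, N = N,
                 model = model, network = net, ffl = ffl, dors = dors,
                 paths = c(paths, manifest = manifest)))
}
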
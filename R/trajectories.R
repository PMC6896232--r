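# Sample clustering, PCA trajectory maps, and projection of external
# (cross-platform) expression profiles after harmonization.

log2_of <- function(expr) {
  if (inherits(expr, "expression_matrix")) expr$log2_expr else as.matrix(expr)
}

#' Average-linkage clustering of expression profiles
#'
#' Clusters samples by average linkage on either correlation distance
#' (1 - Pearson, the default) or Euclidean distance over the log2 expression
#' of the chosen genes.
#'
#' @param expr An [expression_matrix()] or log2 expression matrix.
#' @param genes Optional gene subset (e.g. from [filter_genes()]).
#' @param metric `"correlation"` or `"euclidean"`.
#' @return An [stats::hclust] tree over samples (method `"average"`).
#' @export
cluster_samples <- function(expr, genes = NULL,
                            metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  m <- log2_of(expr)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (ncol(m) < 2) abort("clustering needs at least 2 samples")
  d <- if (metric == "correlation") {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      abort(sprintf("constant sample profile under correlation distance: %s",
                    colnames(m)[which(sds == 0)[1]]))
    }
    as.dist(1 - cor(m))
  } else {
    dist(t(m))
  }
  hclust(d, method = "average")
}

#' Export a dendrogram in Newick format
#'
#' @param tree An [stats::hclust] tree.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), path)
  invisible(path)
}

#' Principal component trajectory map
#'
#' Gene-centred log2 expression is decomposed by singular value
#' decomposition with samples as observations; variance fractions come from
#' the squared singular values. The model stores the per-gene centring means
#' so external profiles can be projected into the same coordinate frame.
#'
#' @param expr An [expression_matrix()] or log2 expression matrix.
#' @param genes Optional gene subset used for the decomposition.
#' @param n_components Number of components to keep (default: all).
#' @return An object of class `pca_model` with `gene_ids`, `center`,
#'   `loadings` (genes x components, orthonormal), `variance_fractions`,
#'   and training `scores` (samples x components).
#' @export
fit_pca <- function(expr, genes = NULL, n_components = NULL) {
  m <- log2_of(expr)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (nrow(m) < 1) abort("gene filter left no genes")
  if (ncol(m) < 3) abort("PCA needs at least 3 samples")
  center <- rowMeans(m)
  xc <- m - center
  sv <- svd(t(xc)) # samples x genes: rows are observations
  k_max <- length(sv$d)
  k <- min(n_components %||% k_max, k_max)
  if (!is.null(n_components) && n_components > k_max) {
    abort(sprintf("requested %d components but at most %d available",
                  n_components, k_max))
  }
  varfrac <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d, k_max)[, seq_len(k), drop = FALSE]
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(scores) <- list(colnames(m), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(rownames(m), paste0("PC", seq_len(k)))
  structure(
    list(gene_ids = rownames(m), center = center, loadings = loadings,
         variance_fractions = varfrac[seq_len(k)], scores = scores),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  vf <- paste(sprintf("%.1f%%", 100 * head(x$variance_fractions, 3)),
              collapse = ", ")
  cat(sprintf("<pca_model> %d genes, %d samples, %d components (top: %s)\n",
              length(x$gene_ids), nrow(x$scores), ncol(x$loadings), vf))
  invisible(x)
}

#' Project external expression profiles onto a fitted PCA map
#'
#' Profiles are restricted to the genes shared with the model, centred with
#' the model's (training) means — never re-centred on the external data, so
#' the coordinate frame is preserved — and multiplied onto the loadings
#' restricted to the shared genes.
#'
#' @param model A [fit_pca()] model.
#' @param external Genes x samples matrix on the model's log2 scale (see
#'   [quantile_match()] / [center_genes()] for harmonization).
#' @param min_overlap Minimum fraction of model genes that must be present
#'   (default 0.5).
#' @return Samples x components score matrix.
#' @export
project_onto <- function(model, external, min_overlap = 0.5) {
  external <- as.matrix(external)
  shared <- intersect(model$gene_ids, rownames(external))
  frac <- length(shared) / length(model$gene_ids)
  if (frac < min_overlap) {
    abort(sprintf("only %.1f%% of model genes present in external data (< %g%%)",
                  100 * frac, 100 * min_overlap))
  }
  inform(sprintf("projecting with %d/%d model genes (%.1f%% missing)",
                 length(shared), length(model$gene_ids), 100 * (1 - frac)))
  xc <- external[shared, , drop = FALSE] - model$center[shared]
  scores <- t(xc) %*% model$loadings[shared, , drop = FALSE]
  rownames(scores) <- colnames(external)
  scores
}

#' Match a matrix to a reference distribution by quantiles
#'
#' Each value is replaced by the reference quantile of its within-sample
#' rank (ties get average ranks), so every output column is distributed like
#' the reference up to tie granularity. Used to adjust microarray probe
#' intensities to the distribution of sequencing read counts before
#' projection.
#'
#' @param external Numeric genes x samples matrix.
#' @param reference Numeric vector giving the target distribution.
#' @return Matrix of matched values, same shape and dimnames.
#' @export
quantile_match <- function(external, reference) {
  reference <- as.numeric(reference)
  if (length(reference) == 0) abort("reference distribution is empty")
  external <- as.matrix(external)
  ref_sorted <- sort(reference)
  n_ref <- length(ref_sorted)
  out <- apply(external, 2, function(x) {
    r <- rank(x, ties.method = "average")
    idx <- (r - 0.5) / length(x) * n_ref + 0.5
    approx(seq_len(n_ref), ref_sorted, xout = idx, rule = 2)$y
  })
  dimnames(out) <- dimnames(external)
  out
}

#' Centre genes across samples
#'
#' Subtracts each gene's mean across samples, correcting batch offsets
#' between platforms before projection.
#'
#' @param m Numeric genes x samples matrix.
#' @return Matrix with zero per-gene means.
#' @export
center_genes <- function(m) {
  m <- as.matrix(m)
  m - rowMeans(m)
}

#' Fold-variation gene filter over sample groups
#'
#' For each group of samples, a gene passes when its pseudocounted rpm fold
#' variation `(max + pc) / (min + pc)` is at least `fold` (inclusive).
#' Groups are combined as a disjunction (`"any"`, e.g. 16-fold during
#' endoderm, mesoderm *or* ectoderm differentiation) or conjunction
#' (`"all"`). Compose the two for filters that also require variation in an
#' external dataset (e.g. 8-fold across embryo sections).
#'
#' @param expr An [expression_matrix()] or rpm matrix.
#' @param groups Named list of sample vectors.
#' @param fold Scalar or per-group fold threshold.
#' @param combine `"any"` or `"all"`.
#' @param pseudocount Pseudocount in rpm units.
#' @return Character vector of gene ids (input order).
#' @export
variation_filter <- function(expr, groups, fold = 16, combine = c("any", "all"),
                             pseudocount = 1) {
  combine <- match.arg(combine)
  rpm <- rpm_of(expr)
  if (length(groups) == 0) abort("no sample groups given")
  fold <- rep_len(fold, length(groups))
  pass <- vapply(seq_along(groups), function(i) {
    samples <- groups[[i]]
    missing <- setdiff(samples, colnames(rpm))
    if (length(missing) > 0) {
      abort(sprintf("unknown sample(s) in group %s: %s",
                    names(groups)[i] %||% i, paste(missing, collapse = ", ")))
    }
    sub <- rpm[, samples, drop = FALSE]
    mx <- apply(sub, 1, max)
    mn <- apply(sub, 1, min)
    (mx + pseudocount) / (mn + pseudocount) >= fold[i]
  }, logical(nrow(rpm)))
  keep <- if (combine == "any") rowSums(pass) > 0 else rowSums(pass) == length(groups)
  rownames(rpm)[keep]
}

#' Named presets for the cross-platform projection gene filters
#'
#' `"episc"`: 16-fold variation during any of the three in vitro
#' differentiation courses. `"geoseq"`: additionally an 8-fold variation
#' across sections of the external spatial dataset (supply `section_rpm`).
#'
#' @param expr An [expression_matrix()] with sample metadata.
#' @param preset `"episc"` or `"geoseq"`.
#' @param section_rpm rpm-scale matrix of the external sections (geoseq
#'   preset only; genes shared with `expr`).
#' @param fold_course,fold_sections Fold thresholds (defaults 16 and 8).
#' @param pseudocount Pseudocount in rpm units.
#' @return Character vector of gene ids.
#' @export
variation_filter_preset <- function(expr, preset = c("episc", "geoseq"),
                                    section_rpm = NULL, fold_course = 16,
                                    fold_sections = 8, pseudocount = 1) {
  preset <- match.arg(preset)
  meta <- expr$sample_meta
  if (is.null(meta)) abort("preset filters need sample metadata")
  conds <- unique(meta$condition[meta$day > 0])
  groups <- lapply(setNames(conds, conds), function(cond) {
    union(meta$sample[meta$day == 0], meta$sample[meta$condition == cond])
  })
  genes <- variation_filter(expr, groups, fold_course, "any", pseudocount)
  if (preset == "geoseq") {
    if (is.null(section_rpm)) abort("geoseq preset needs section_rpm")
    sec <- variation_filter(section_rpm,
                            list(sections = colnames(section_rpm)),
                            fold_sections, "all", pseudocount)
    genes <- intersect(genes, sec)
  }
  genes
}
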
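# Count loading, depth normalization (gross + median-filter fine factors),
# expression filtering and per-condition differential gene sets.

#' Gene-level count matrix with sample metadata
#'
#' @param counts Genes x samples matrix of nonnegative integers with gene ids
#'   as rownames and sample names as colnames.
#' @param sample_meta Optional tibble with columns `sample`, `condition`,
#'   `day`, `replicate`; parsed from `condition_day_replicate` sample names
#'   when `NULL`.
#' @param aligned_totals Per-sample total aligned reads. Defaults to column
#'   sums, which undercounts when reads align outside the matrix; pass the
#'   true totals when available.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, sample_meta = NULL, aligned_totals = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) abort("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) abort("counts must have sample names as colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer or negative count at gene %s, sample %s",
                  rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  sample_meta <- sample_meta %||% parse_sample_names(colnames(counts))
  if (!all(colnames(counts) %in% sample_meta$sample)) {
    abort("sample_meta does not cover all samples")
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), ]
  aligned_totals <- aligned_totals %||% colSums(counts)
  aligned_totals <- rep_len(aligned_totals, ncol(counts))
  names(aligned_totals) <- colnames(counts)
  if (any(aligned_totals <= 0)) {
    abort(sprintf("aligned totals must be > 0 (offending sample: %s)",
                  colnames(counts)[which(aligned_totals <= 0)[1]]))
  }
  structure(
    list(counts = counts, gene_ids = rownames(counts),
         sample_meta = sample_meta, aligned_totals = aligned_totals),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$sample_meta$condition), collapse = ", ")))
  invisible(x)
}

#' Parse `condition_day_replicate` sample names
#'
#' @param samples Character vector like `"ectoderm_3_1"` (replicate optional,
#'   defaulting to 1).
#' @return Tibble with `sample`, `condition`, `day`, `replicate`.
#' @export
parse_sample_names <- function(samples) {
  m3 <- regmatches(samples, regexec("^(.+)_([0-9]+)_([0-9]+)$", samples))
  m2 <- regmatches(samples, regexec("^(.+)_([0-9]+)$", samples))
  rows <- map(seq_along(samples), function(i) {
    if (length(m3[[i]]) == 4) {
      list(condition = m3[[i]][2], day = as.integer(m3[[i]][3]),
           replicate = as.integer(m3[[i]][4]))
    } else if (length(m2[[i]]) == 3) {
      list(condition = m2[[i]][2], day = as.integer(m2[[i]][3]),
           replicate = 1L)
    } else {
      abort(sprintf(
        "cannot parse sample name '%s' (expected condition_day[_replicate])",
        samples[i]))
    }
  })
  tibble(sample = samples,
         condition = map_chr(rows, "condition"),
         day = map_int(rows, "day"),
         replicate = map_int(rows, "replicate"))
}

#' Read and write gene-level count matrices as TSV
#'
#' The TSV has a `gene_id` first column and one integer column per sample.
#' Aligned totals, when they differ from column sums, travel in a
#' `<path>.totals.tsv` sidecar; sample metadata can come from a sidecar TSV
#' with columns `sample`, `condition`, `day`, `replicate`.
#'
#' @param path TSV file path.
#' @param meta Optional path to a sample metadata sidecar TSV.
#' @param aligned_totals Optional per-sample totals (overrides any sidecar).
#' @return `load_counts()` returns a [count_matrix()].
#' @export
load_counts <- function(path, meta = NULL, aligned_totals = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_id") {
    abort("first column of a counts TSV must be 'gene_id'")
  }
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  if (!is.numeric(counts)) abort("non-numeric count column")
  sample_meta <- if (!is.null(meta)) {
    as_tibble(read.delim(meta, stringsAsFactors = FALSE))
  } else NULL
  totals_path <- paste0(path, ".totals.tsv")
  if (is.null(aligned_totals) && file.exists(totals_path)) {
    tt <- read.delim(totals_path, stringsAsFactors = FALSE)
    aligned_totals <- setNames(tt$aligned_total, tt$sample)[colnames(counts)]
  }
  cm <- count_matrix(counts, sample_meta, aligned_totals)
  inform(sprintf("loaded %d genes x %d samples from %s",
                 nrow(counts), ncol(counts), path))
  cm
}

#' @rdname load_counts
#' @param cm A [count_matrix()].
#' @param write_totals Write the aligned-totals sidecar (default: only when
#'   totals differ from column sums).
#' @export
write_counts <- function(cm, path, write_totals = NULL) {
  df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_totals <- write_totals %||%
    !isTRUE(all.equal(unname(cm$aligned_totals), unname(colSums(cm$counts))))
  if (write_totals) {
    write.table(
      data.frame(sample = names(cm$aligned_totals),
                 aligned_total = unname(cm$aligned_totals)),
      paste0(path, ".totals.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Gross depth normalization to reads per million
#'
#' `rpm[g, s] = counts[g, s] / aligned_totals[s] * 1e6` — no transcript-length
#' correction, since only relative changes across samples are of interest.
#'
#' @param cm A [count_matrix()].
#' @return Genes x samples rpm matrix.
#' @export
gross_normalize <- function(cm) {
  sweep(cm$counts, 2, cm$aligned_totals / 1e6, "/")
}

#' Normalized expression matrix
#'
#' Container produced by [fine_normalize()]: depth-corrected rpm, its
#' pseudocounted log2 view, and the per-sample fine normalization factors.
#'
#' @param rpm Genes x samples rpm matrix (post fine correction).
#' @param normalization_factors Per-sample fine factors applied.
#' @param pseudocount Pseudocount (rpm units) used for the log2 view.
#' @param sample_meta Optional sample metadata tibble.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(rpm, normalization_factors = NULL,
                              pseudocount = 1, sample_meta = NULL) {
  if (any(rpm < 0)) abort("rpm must be nonnegative")
  normalization_factors <- normalization_factors %||%
    setNames(rep(1, ncol(rpm)), colnames(rpm))
  if (any(normalization_factors <= 0)) abort("normalization factors must be > 0")
  structure(
    list(gene_ids = rownames(rpm), rpm = rpm,
         log2_expr = log2(rpm + pseudocount),
         normalization_factors = normalization_factors,
         pseudocount = pseudocount,
         sample_meta = sample_meta %||% parse_sample_names(colnames(rpm))),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, pseudocount %g rpm\n",
              nrow(x$rpm), ncol(x$rpm), x$pseudocount))
  invisible(x)
}

#' Fine normalization by median-filtered ratio matching
#'
#' After gross depth correction, residual per-sample scale distortions are
#' removed by matching each sample to a reference profile on genes highly
#' expressed in all samples: per-gene log2 ratios (sample minus reference)
#' are ordered by reference expression, smoothed with a running median, and
#' the sample's factor is `2^(-median)` of the smoothed ratios — i.e. the
#' shift that brings the median-filtered log expression onto the identity
#' line. Log2 factors are centred to mean zero so the overall scale is
#' preserved. The fitting genes are those whose geometric-mean rpm exceeds
#' `high_expr_min_rpm`: the geometric mean is invariant under the centred
#' factors, so the gene set is stable under re-normalization and the
#' procedure is exactly idempotent.
#'
#' @param rpm Genes x samples rpm matrix (from [gross_normalize()]).
#' @param high_expr_min_rpm Geometric-mean rpm a gene must exceed to enter
#'   the fit (default 32; genes with a zero count anywhere are excluded).
#' @param median_window Running median width in genes (odd; default 101).
#' @param reference Optional reference log2 profile over genes; default is
#'   the per-gene mean log2 rpm (log of the geometric mean profile).
#' @param pseudocount Pseudocount (rpm units) for the log2 view of the
#'   result.
#' @param sample_meta Optional sample metadata.
#' @return An [expression_matrix()] with corrected rpm and the factors.
#' @export
fine_normalize <- function(rpm, high_expr_min_rpm = 32, median_window = 101,
                           reference = NULL, pseudocount = 1,
                           sample_meta = NULL) {
  if (ncol(rpm) < 2) abort("fine normalization needs at least 2 samples")
  if (median_window %% 2 == 0) {
    median_window <- median_window + 1
    warn(sprintf("median_window must be odd; using %d", median_window))
  }
  gm <- exp(rowMeans(log(rpm))) # 0 if any sample has zero rpm
  high <- is.finite(gm) & gm > high_expr_min_rpm
  if (sum(high) < median_window) {
    abort(sprintf(paste0("only %d genes exceed %g rpm geometric mean ",
                         "(< window %d); lower high_expr_min_rpm"),
                  sum(high), high_expr_min_rpm, median_window))
  }
  lg <- log2(rpm[high, , drop = FALSE])
  ref <- reference %||% rowMeans(lg)
  if (length(ref) == nrow(rpm)) ref <- ref[high]
  if (length(ref) != nrow(lg)) abort("reference length does not match gene set")
  ord <- order(ref)
  shifts <- map_dbl(seq_len(ncol(lg)), function(s) {
    ratios <- (lg[, s] - ref)[ord]
    median(runmed(ratios, median_window))
  })
  shifts <- shifts - mean(shifts) # preserve overall scale; makes rerun a no-op
  factors <- setNames(2^(-shifts), colnames(rpm))
  out <- sweep(rpm, 2, factors, "*")
  expression_matrix(out, factors, pseudocount, sample_meta)
}

#' One-call normalization of a count matrix
#'
#' [gross_normalize()] followed by [fine_normalize()], carrying the sample
#' metadata through.
#'
#' @param cm A [count_matrix()].
#' @inheritParams fine_normalize
#' @return An [expression_matrix()].
#' @export
normalize_counts <- function(cm, high_expr_min_rpm = 32, median_window = 101,
                             reference = NULL, pseudocount = 1) {
  fine_normalize(gross_normalize(cm), high_expr_min_rpm, median_window,
                 reference, pseudocount, sample_meta = cm$sample_meta)
}

rpm_of <- function(expr) {
  if (inherits(expr, "expression_matrix")) expr$rpm else as.matrix(expr)
}

#' Expression and fold-change gene filter
#'
#' Keeps genes with maximal rpm above `min_max_rpm` over the chosen samples
#' and at least `min_fold` variation of pseudocounted rpm:
#' `(max + pc) / (min + pc) >= min_fold`. Input order is preserved.
#'
#' @param expr An [expression_matrix()] or rpm matrix.
#' @param min_max_rpm Expression threshold in rpm (default 3, strict `>`).
#' @param min_fold Fold-variation threshold (default 4, inclusive `>=`).
#' @param samples Sample subset (default all).
#' @param pseudocount Pseudocount in rpm units (default: the matrix's own,
#'   or 1).
#' @return Character vector of gene ids.
#' @export
filter_genes <- function(expr, min_max_rpm = 3, min_fold = 4, samples = NULL,
                         pseudocount = NULL) {
  rpm <- rpm_of(expr)
  pc <- pseudocount %||%
    (if (inherits(expr, "expression_matrix")) expr$pseudocount else 1)
  samples <- samples %||% colnames(rpm)
  if (length(samples) == 0) abort("sample subset is empty")
  missing <- setdiff(samples, colnames(rpm))
  if (length(missing) > 0) {
    abort(sprintf("unknown sample(s): %s", paste(missing, collapse = ", ")))
  }
  sub <- rpm[, samples, drop = FALSE]
  mx <- apply(sub, 1, max)
  mn <- apply(sub, 1, min)
  keep <- mx > min_max_rpm & (mx + pc) / (mn + pc) >= min_fold
  rownames(sub)[keep]
}

#' Per-condition differential gene sets and their Venn regions
#'
#' For each condition, applies [filter_genes()] over that condition's time
#' course together with the shared day-0 baseline samples. Returns the sets
#' and all Venn regions (for three conditions, the canonical 7 regions).
#'
#' @param expr An [expression_matrix()] (sample metadata required).
#' @param conditions Condition labels (default: all non-baseline-only
#'   conditions in the metadata).
#' @inheritParams filter_genes
#' @return List with `sets` (named list of gene id vectors), `venn` (tibble
#'   of exclusive region sizes), `union_size`.
#' @export
differential_sets <- function(expr, conditions = NULL, min_max_rpm = 3,
                              min_fold = 4) {
  meta <- expr$sample_meta
  if (is.null(meta)) abort("differential_sets needs sample metadata")
  conditions <- conditions %||% unique(meta$condition[meta$day > 0])
  unknown <- setdiff(conditions, meta$condition)
  if (length(unknown) > 0) {
    abort(sprintf("unknown condition(s): %s", paste(unknown, collapse = ", ")))
  }
  baseline <- meta$sample[meta$day == 0]
  sets <- lapply(setNames(conditions, conditions), function(cond) {
    samples <- union(baseline, meta$sample[meta$condition == cond])
    if (length(unique(meta$day[meta$sample %in% samples])) < 2) {
      abort(sprintf("condition %s needs timepoints beyond the day-0 baseline",
                    cond))
    }
    filter_genes(expr, min_max_rpm, min_fold, samples)
  })
  venn <- venn_regions(sets)
  list(sets = sets, venn = venn, union_size = length(unique(unlist(sets))))
}

#' Exclusive Venn region sizes of a list of sets
#'
#' @param sets Named list of character vectors.
#' @return Tibble with one row per nonempty membership pattern: `region`
#'   (e.g. `"A&B"`), one logical column per set, and `size`. Region sizes
#'   sum to the union size.
#' @export
venn_regions <- function(sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(sets)))
  colnames(patterns) <- names(sets)
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  rows <- map(seq_len(nrow(patterns)), function(i) {
    pat <- unlist(patterns[i, ])
    inside <- rowSums(membership[, pat, drop = FALSE]) == sum(pat) &
      rowSums(membership[, !pat, drop = FALSE]) == 0
    c(list(region = paste(names(sets)[pat], collapse = "&")),
      as.list(pat), list(size = sum(inside)))
  })
  out <- bind_rows(rows)
  arrange(out, desc(.data$size))
}
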
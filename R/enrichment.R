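# Resampling gene-set enrichment and multiple-testing correction.

#' Resampling-based gene-set enrichment test
#'
#' The observed statistic is the overlap between the gene set and the hit
#' set. The null distribution comes from drawing `resamples` random subsets
#' of size `|gene_set|` from the pool without replacement; the empirical
#' p-value uses the add-one correction
#' `p = (1 + #\{null >= observed\}) / (resamples + 1)`, so it is never zero
#' and converges to the hypergeometric upper tail.
#'
#' @param gene_set Character vector, a subset of `pool` (e.g. a pathway).
#' @param hit_set Character vector, a subset of `pool` (e.g. differential
#'   genes).
#' @param pool Character vector: the gene universe resampled from.
#' @param resamples Number of resamplings (default 10000, minimum 1000).
#' @param seed Optional seed.
#' @return One-row tibble with `observed`, `expected`, `resamples`,
#'   `p_value`.
#' @export
resampling_enrichment <- function(gene_set, hit_set, pool, resamples = 10000,
                                  seed = NULL) {
  if (resamples < 1000) abort("resamples must be >= 1000")
  out_set <- setdiff(gene_set, pool)
  out_hit <- setdiff(hit_set, pool)
  if (length(out_set) > 0 || length(out_hit) > 0) {
    abort(sprintf("genes outside the pool: %s",
                  paste(head(c(out_set, out_hit), 5), collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- unique(pool)
  k <- length(unique(gene_set))
  hits <- pool %in% hit_set
  observed <- sum(unique(gene_set) %in% hit_set)
  null_overlap <- vapply(seq_len(resamples), function(i) {
    sum(hits[sample.int(length(pool), k)])
  }, integer(1))
  tibble(
    observed = observed,
    expected = k * sum(hits) / length(pool),
    resamples = as.integer(resamples),
    p_value = (1 + sum(null_overlap >= observed)) / (resamples + 1)
  )
}

#' Enrichment of several gene sets with FDR correction
#'
#' Runs [resampling_enrichment()] per set and appends Benjamini-Hochberg
#' q-values.
#'
#' @param gene_sets Named list of character vectors.
#' @inheritParams resampling_enrichment
#' @return Tibble with one row per set: `set`, `set_size`, `observed`,
#'   `expected`, `p_value`, `q_value`.
#' @export
enrich_sets <- function(gene_sets, hit_set, pool, resamples = 10000,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- map(names(gene_sets), function(nm) {
    res <- resampling_enrichment(gene_sets[[nm]], hit_set, pool, resamples)
    mutate(res, set = nm, set_size = length(unique(gene_sets[[nm]])),
           .before = 1)
  })
  out <- bind_rows(rows)
  mutate(out, q_value = bh_adjust(out$p_value))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control; a thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, tab-separated genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
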
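# Motif activity response analysis: per-sample least squares of log2
# expression on promoter site counts, forward selection of significant
# motifs, and activity-expression correlation.

sites_of <- function(sites) {
  if (inherits(sites, "site_count_matrix")) sites$N else as.matrix(sites)
}

#' Transcription factors eligible for the network
#'
#' A motif is eligible when every constituent TF gene (dimer names split on
#' `::`) exceeds `min_max_rpm` reads per million in at least one of the
#' chosen samples. Motifs whose genes are absent from the expression matrix
#' are excluded with a warning.
#'
#' @param expr An [expression_matrix()] or rpm matrix.
#' @param motifs List of [motif_model()]s.
#' @param min_max_rpm Maximal-expression threshold (default 6, strict `>`).
#' @param samples Sample subset defining eligibility (default all).
#' @param tf_map Optional named list mapping motif id to gene id(s),
#'   overriding the name-derived mapping.
#' @return Character vector of eligible motif ids; the full eligibility
#'   record (motif, genes, max rpm, status) is attached as attribute
#'   `"record"`.
#' @export
eligible_tfs <- function(expr, motifs, min_max_rpm = 6, samples = NULL,
                         tf_map = NULL) {
  rpm <- rpm_of(expr)
  samples <- samples %||% colnames(rpm)
  sub <- rpm[, samples, drop = FALSE]
  rows <- map(motifs, function(m) {
    genes <- (tf_map %||% list())[[m$id]] %||% tf_genes(m)
    present <- genes %in% rownames(sub)
    if (!all(present)) {
      warn(sprintf("motif %s: gene(s) %s not in expression matrix; excluded",
                   m$id, paste(genes[!present], collapse = ", ")))
      return(tibble(motif = m$id, genes = paste(genes, collapse = ","),
                    min_of_max_rpm = NA_real_, eligible = FALSE))
    }
    maxes <- apply(sub[genes, , drop = FALSE], 1, max)
    tibble(motif = m$id, genes = paste(genes, collapse = ","),
           min_of_max_rpm = min(maxes), eligible = all(maxes > min_max_rpm))
  })
  record <- bind_rows(rows)
  structure(record$motif[record$eligible], record = record)
}

#' Fit per-sample motif activities by ordinary least squares
#'
#' The motif activity response model: for each sample `s`,
#' `log2_expr[g, s] = c[s] + sum_m N[g, m] * A[m, s] + noise`, fitted
#' independently per sample by least squares over genes. Activities are in
#' log2-expression units per predicted site.
#'
#' @param log2_expr Genes x samples log2 expression matrix (or an
#'   [expression_matrix()]).
#' @param sites Genes x motifs site-count matrix (or a
#'   `site_count_matrix`), restricted to candidate motifs; all-zero columns
#'   are dropped with a warning.
#' @return An object of class `activity_model` with `A` (motifs x samples),
#'   `intercepts`, `residual_variance`, `motif_ids`, and (after selection)
#'   `p_values`.
#' @export
fit_activities <- function(log2_expr, sites) {
  Y <- log2_of(log2_expr)
  N <- sites_of(sites)
  N <- N[rownames(Y), , drop = FALSE]
  zero <- colSums(N != 0) == 0
  if (any(zero)) {
    warn(sprintf("dropping all-zero site column(s): %s",
                 paste(colnames(N)[zero], collapse = ", ")))
    N <- N[, !zero, drop = FALSE]
  }
  if (nrow(Y) <= ncol(N)) abort("need more genes than candidate motifs")
  X <- cbind(`(Intercept)` = 1, N)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(sprintf("site matrix is rank deficient; collinear motif group(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  fit <- lm.fit(X, Y)
  coefs <- as.matrix(fit$coefficients)
  res <- as.matrix(fit$residuals)
  df <- nrow(Y) - ncol(X)
  structure(
    list(A = coefs[-1, , drop = FALSE],
         intercepts = setNames(coefs[1, ], colnames(Y)),
         residual_variance = setNames(colSums(res^2) / df, colnames(Y)),
         motif_ids = colnames(N), samples = colnames(Y), p_values = NULL),
    class = "activity_model"
  )
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity_model> %d motifs x %d samples%s\n",
              nrow(x$A), ncol(x$A),
              if (!is.null(x$p_values)) {
                sprintf(", %d selected", sum(!is.na(x$p_values) &
                                               x$p_values < attr(x, "alpha")))
              } else ""))
  invisible(x)
}

# one forward-selection pass for a single sample; returns admissions and the
# corrected p-values of each step's best candidate
forward_select_sample <- function(y, N, alpha) {
  candidates <- colnames(N)
  active <- character(0)
  evals <- setNames(rep(NA_real_, ncol(N)), candidates)
  n <- length(y)
  repeat {
    remaining <- setdiff(candidates, active)
    if (length(remaining) == 0) break
    X0 <- cbind(1, N[, active, drop = FALSE])
    rss <- vapply(remaining, function(m) {
      sum(lm.fit(cbind(X0, N[, m]), y)$residuals^2)
    }, numeric(1))
    best <- remaining[which.min(rss)]
    p1 <- ncol(X0) + 1L
    if (n - p1 <= 0) break
    rss0 <- sum(lm.fit(X0, y)$residuals^2)
    rss1 <- rss[[best]]
    f <- (rss0 - rss1) / (rss1 / (n - p1))
    p <- pf(f, 1, n - p1, lower.tail = FALSE)
    corrected <- p * length(remaining) # Bonferroni over remaining candidates
    evals[best] <- min(evals[best], corrected, na.rm = TRUE)
    if (alpha >= 1 || corrected < alpha) {
      active <- c(active, best)
    } else {
      break
    }
  }
  list(active = active, evals = evals)
}

#' Select significant motifs by per-sample forward selection
#'
#' Per sample, candidates are added to the regression greedily: at each step
#' the motif giving the greatest residual-variance reduction is scored by
#' the F-statistic of its coefficient and admitted if its p-value,
#' Bonferroni-corrected for the number of remaining candidates, is below
#' `alpha`; selection stops otherwise. A motif's overall p-value is its
#' smallest corrected p across samples; motifs admitted in at least one
#' sample are selected. Activities of the selected motifs are then refit
#' jointly (all selected motifs, every sample) so that every selected motif
#' carries a complete activity trajectory.
#'
#' @inheritParams fit_activities
#' @param alpha Per-step significance threshold (default 0.01). `alpha = 1`
#'   degenerates to selecting every candidate.
#' @return An `activity_model` over the selected motifs with `p_values`
#'   (named; `NA` for candidates never scored) and a `selection` tibble
#'   attribute; an empty selection is a valid result.
#' @export
motif_significance <- function(log2_expr, sites, alpha = 0.01) {
  Y <- log2_of(log2_expr)
  N <- sites_of(sites)
  N <- N[rownames(Y), , drop = FALSE]
  zero <- colSums(N != 0) == 0
  if (any(zero)) {
    warn(sprintf("dropping all-zero site column(s): %s",
                 paste(colnames(N)[zero], collapse = ", ")))
    N <- N[, !zero, drop = FALSE]
  }
  if (nrow(Y) <= ncol(N)) abort("need more genes than candidate motifs")
  per_sample <- lapply(seq_len(ncol(Y)), function(s) {
    forward_select_sample(Y[, s], N, alpha)
  })
  evals <- do.call(cbind, lapply(per_sample, `[[`, "evals"))
  p_best <- apply(evals, 1, function(v) {
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  })
  p_best <- pmin(p_best, 1)
  admitted <- unique(unlist(lapply(per_sample, `[[`, "active")))
  selected <- colnames(N)[colnames(N) %in% admitted]
  selection <- tibble(
    motif = colnames(N), p_value = unname(p_best[colnames(N)]),
    selected = colnames(N) %in% selected,
    n_samples_admitted = map_int(colnames(N), function(m) {
      sum(map_lgl(per_sample, function(ps) m %in% ps$active))
    })
  )
  if (length(selected) == 0) {
    inform("no motif reached significance; empty selection")
    model <- structure(
      list(A = matrix(0, 0, ncol(Y), dimnames = list(NULL, colnames(Y))),
           intercepts = colMeans(Y),
           residual_variance = apply(Y, 2, function(v) sum((v - mean(v))^2)) /
             (nrow(Y) - 1),
           motif_ids = character(0), samples = colnames(Y),
           p_values = p_best),
      class = "activity_model")
  } else {
    model <- fit_activities(Y, N[, selected, drop = FALSE])
    model$p_values <- p_best[model$motif_ids]
  }
  attr(model, "alpha") <- alpha
  attr(model, "selection") <- selection
  model
}

#' Correlation between a motif's activity and a gene's expression
#'
#' Pearson correlation of the motif's activity trajectory with the gene's
#' log2 expression over the chosen samples — e.g. to contrast a repressor's
#' rising motif activity with its falling transcript level.
#'
#' @param model An [fit_activities()] / [motif_significance()] model.
#' @param expr An [expression_matrix()] or log2 expression matrix.
#' @param motif Motif id in the model.
#' @param gene Gene id in the expression matrix.
#' @param samples Sample subset (default: the model's samples).
#' @return Pearson correlation coefficient.
#' @export
activity_expression_correlation <- function(model, expr, motif, gene,
                                            samples = NULL) {
  Y <- log2_of(expr)
  samples <- samples %||% model$samples
  if (length(samples) < 3) abort("need at least 3 samples")
  if (!motif %in% rownames(model$A)) {
    abort(sprintf("motif %s not in the activity model", motif))
  }
  if (!gene %in% rownames(Y)) abort(sprintf("gene %s not in expression", gene))
  a <- model$A[motif, samples]
  e <- Y[gene, samples]
  if (sd(a) == 0 || sd(e) == 0) {
    abort("constant activity or expression vector: correlation undefined")
  }
  cor(a, e)
}
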
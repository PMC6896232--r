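# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an activity model into long format
#'
#' @param x An `activity_model`.
#' @param ... Unused.
#' @return Tibble with `motif`, `sample`, `condition`, `day`, `activity`,
#'   and `p_value` when selection was run.
#' @export
tidy.activity_model <- function(x, ...) {
  if (nrow(x$A) == 0) {
    return(tibble(motif = character(), sample = character(),
                  activity = numeric()))
  }
  meta <- tryCatch(parse_sample_names(colnames(x$A)), error = function(e) NULL)
  out <- tibble(
    motif = rep(rownames(x$A), times = ncol(x$A)),
    sample = rep(colnames(x$A), each = nrow(x$A)),
    activity = as.vector(x$A)
  )
  if (!is.null(meta)) {
    out$condition <- meta$condition[match(out$sample, meta$sample)]
    out$day <- meta$day[match(out$sample, meta$sample)]
  }
  if (!is.null(x$p_values)) {
    out$p_value <- unname(x$p_values[out$motif])
  }
  out
}

#' @export
glance.activity_model <- function(x, ...) {
  tibble(
    n_motifs = nrow(x$A), n_samples = ncol(x$A),
    n_selected = if (!is.null(x$p_values)) nrow(x$A) else NA_integer_,
    mean_residual_variance = mean(x$residual_variance)
  )
}

#' Tidy a PCA model
#'
#' @param x A `pca_model`.
#' @param matrix `"scores"`, `"loadings"` or `"eigenvalues"`.
#' @param ... Unused.
#' @export
tidy.pca_model <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                           ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble(component = seq_along(x$variance_fractions),
                  variance_fraction = x$variance_fractions))
  }
  m <- if (matrix == "scores") x$scores else x$loadings
  id <- if (matrix == "scores") "sample" else "gene_id"
  out <- tibble(
    id = rep(rownames(m), times = ncol(m)),
    component = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  names(out)[1] <- id
  out
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble(n_genes = length(x$gene_ids), n_samples = nrow(x$scores),
         n_components = ncol(x$loadings),
         pc1_fraction = x$variance_fractions[1])
}

#' @export
tidy.grn_network <- function(x, ...) x$edges

#' @export
glance.grn_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_inductive = sum(x$edges$sign == "inductive"),
         n_inhibitory = sum(x$edges$sign == "inhibitory"))
}

#' Plot PCA trajectories
#'
#' Scatter of two score components, coloured by condition when sample names
#' parse as `condition_day_replicate`.
#'
#' @param object A `pca_model`.
#' @param components Two component indices (default 1:2).
#' @param ... Unused.
#' @export
autoplot.pca_model <- function(object, components = c(1, 2), ...) {
  sc <- object$scores[, components, drop = FALSE]
  df <- tibble(sample = rownames(sc), x = sc[, 1], y = sc[, 2])
  meta <- tryCatch(parse_sample_names(df$sample), error = function(e) NULL)
  lab <- function(i) sprintf("PC%d (%.1f%%)", components[i],
                             100 * object$variance_fractions[components[i]])
  p <- if (!is.null(meta)) {
    df$condition <- meta$condition
    df$day <- meta$day
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                     colour = .data$condition)) +
      ggplot2::geom_path(ggplot2::aes(group = .data$condition), alpha = 0.5) +
      ggplot2::geom_point(ggplot2::aes(size = .data$day))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = lab(1), y = lab(2)) + ggplot2::theme_minimal()
}

#' Plot motif activity trajectories
#'
#' @param object An `activity_model`.
#' @param motifs Motif subset (default: all).
#' @param ... Unused.
#' @export
autoplot.activity_model <- function(object, motifs = NULL, ...) {
  df <- tidy(object)
  if (!is.null(motifs)) df <- df[df$motif %in% motifs, ]
  if (!"day" %in% names(df)) {
    abort("sample names do not parse as condition_day_replicate")
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$activity,
                                   colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~motif, scales = "free_y") +
    ggplot2::labs(x = "day", y = "motif activity (log2 units / site)") +
    ggplot2::theme_minimal()
}
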
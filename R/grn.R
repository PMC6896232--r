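# Directed signed regulatory network: correlation-gated edges over predicted
# promoter sites, feed-forward loop and dense overlapping regulon census,
# network comparison, and SIF/GraphML export.

#' Construct a network object
#'
#' @param nodes Tibble with columns `motif`, `gene` (target-role gene id or
#'   `NA`), `p_value`.
#' @param edges Tibble with columns `regulator`, `target`, `sign`
#'   (`"inductive"`/`"inhibitory"`), `weight` (the correlation), `sites`.
#' @return An object of class `grn_network`.
#' @export
grn_network <- function(nodes, edges) {
  stopifnot(all(c("motif", "gene", "p_value") %in% names(nodes)),
            all(c("regulator", "target", "sign", "weight", "sites")
                %in% names(edges)))
  if (!all(edges$regulator %in% nodes$motif) ||
      !all(edges$target %in% nodes$motif)) {
    abort("edge endpoint not among nodes")
  }
  if (anyDuplicated(edges[, c("regulator", "target")])) {
    abort("duplicate edges")
  }
  if (nrow(edges) > 0 &&
      !all(edges$sign == ifelse(edges$weight > 0, "inductive", "inhibitory"))) {
    abort("edge sign inconsistent with weight")
  }
  edges <- arrange(edges, .data$regulator, .data$target)
  nodes <- arrange(nodes, .data$motif)
  structure(list(nodes = nodes, edges = edges), class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("<grn_network> %d nodes, %d edges (%d inductive, %d inhibitory)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "inductive"),
              sum(x$edges$sign == "inhibitory")))
  invisible(x)
}

# target-role gene of a motif: its single constituent gene; dimers have no
# unambiguous transcript and are excluded from the target role unless tf_map
# names one gene for them
target_gene_of <- function(motif_id, motifs, tf_map = NULL) {
  mapped <- (tf_map %||% list())[[motif_id]]
  if (!is.null(mapped)) {
    return(if (length(mapped) == 1) mapped else NA_character_)
  }
  m <- motifs[[motif_id]]
  genes <- if (!is.null(m)) tf_genes(m) else motif_id
  if (length(genes) == 1) genes else NA_character_
}

#' Infer the directed signed regulatory network
#'
#' For every ordered pair of nodes (selected motifs) an edge regulator ->
#' target is added when (i) the regulator has at least one predicted binding
#' site in the 1 kb promoter of the target's gene and (ii) the absolute
#' Pearson correlation between the regulator's motif activity and the target
#' gene's log2 expression exceeds `threshold` (strictly). Positive
#' correlation gives an inductive edge, negative an inhibitory one; the
#' correlation is stored as the edge weight.
#'
#' @param model An [motif_significance()] (or [fit_activities()]) model; its
#'   motifs are the nodes.
#' @param expr An [expression_matrix()] or log2 expression matrix.
#' @param sites A `site_count_matrix` (or genes x motifs matrix); presence
#'   (`>= 1`) gates edges regardless of any binarization.
#' @param threshold Correlation threshold (default 0.8, strict `>`).
#' @param motifs Optional list of [motif_model()]s for dimer-aware
#'   motif-to-gene mapping.
#' @param tf_map Optional named list motif id -> gene id overriding the
#'   mapping; a dimer with a single mapped gene becomes a valid target.
#' @param samples Samples over which the correlation is computed (default:
#'   the model's fitting samples).
#' @param allow_self Allow self-edges (default `FALSE`).
#' @return A [grn_network()].
#' @export
infer_edges <- function(model, expr, sites, threshold = 0.8, motifs = NULL,
                        tf_map = NULL, samples = NULL, allow_self = FALSE) {
  Y <- log2_of(expr)
  N <- sites_of(sites)
  samples <- samples %||% model$samples
  node_ids <- rownames(model$A)
  genes <- map_chr(node_ids, target_gene_of, motifs = motifs, tf_map = tf_map)
  targetable <- !is.na(genes) & genes %in% rownames(Y) & genes %in% rownames(N)
  if (any(!targetable)) {
    inform(sprintf("node(s) excluded from target role (no mappable gene): %s",
                   paste(node_ids[!targetable], collapse = ", ")))
  }
  nodes <- tibble(
    motif = node_ids, gene = ifelse(targetable, genes, NA_character_),
    p_value = if (!is.null(model$p_values)) {
      unname(model$p_values[node_ids])
    } else NA_real_
  )
  rows <- list()
  for (t in node_ids[targetable]) {
    gene_t <- genes[match(t, node_ids)]
    e <- Y[gene_t, samples]
    if (sd(e) == 0) next
    for (r in node_ids) {
      if (!allow_self && r == t) next
      n_sites <- N[gene_t, r]
      if (n_sites < 1) next
      a <- model$A[r, samples]
      if (sd(a) == 0) next
      w <- cor(a, e)
      if (abs(w) > threshold) {
        rows[[length(rows) + 1]] <- tibble(
          regulator = r, target = t,
          sign = if (w > 0) "inductive" else "inhibitory",
          weight = w, sites = as.integer(n_sites))
      }
    }
  }
  edges <- if (length(rows) > 0) bind_rows(rows) else
    tibble(regulator = character(), target = character(), sign = character(),
           weight = numeric(), sites = integer())
  grn_network(nodes, edges)
}

edge_list <- function(net) {
  split(net$edges$target, factor(net$edges$regulator,
                                 levels = net$nodes$motif))
}

#' Enumerate feed-forward loops
#'
#' All ordered node triples (a, b, c) with edges a -> b, b -> c and a -> c.
#' The three edge signs are reported; a loop is coherent when the sign of
#' the direct path equals the product of signs along the indirect path.
#'
#' @param net A [grn_network()].
#' @return Tibble with columns `a`, `b`, `c`, the three signs, and
#'   `coherent`.
#' @export
count_ffl <- function(net) {
  succ <- edge_list(net)
  sign_of <- setNames(ifelse(net$edges$sign == "inductive", 1L, -1L),
                      paste(net$edges$regulator, net$edges$target))
  rows <- list()
  for (a in names(succ)) {
    for (b in succ[[a]]) {
      if (b == a) next
      common <- intersect(succ[[b]], succ[[a]])
      for (ch in setdiff(common, c(a, b))) {
        s_ab <- sign_of[[paste(a, b)]]
        s_bc <- sign_of[[paste(b, ch)]]
        s_ac <- sign_of[[paste(a, ch)]]
        rows[[length(rows) + 1]] <- tibble(
          a = a, b = b, c = ch,
          sign_ab = s_ab, sign_bc = s_bc, sign_ac = s_ac,
          coherent = s_ab * s_bc == s_ac)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(a = character(), b = character(), c = character(),
                  sign_ab = integer(), sign_bc = integer(),
                  sign_ac = integer(), coherent = logical()))
  }
  arrange(bind_rows(rows), .data$a, .data$b, .data$c)
}

#' Find dense overlapping regulons
#'
#' A DOR is a maximal group of at least `min_regulators` regulators whose
#' target sets share at least `min_shared_targets` common targets (a
#' biclique with slack). Maximality means no further regulator can be added
#' without the shared-target set dropping below the minimum. Results are
#' ordered largest first.
#'
#' @param net A [grn_network()].
#' @param min_regulators Minimum regulator-set size (default 2).
#' @param min_shared_targets Minimum number of common targets (default 3).
#' @return Tibble with list-columns `regulators`, `shared_targets` and the
#'   corresponding sizes.
#' @export
find_dors <- function(net, min_regulators = 2, min_shared_targets = 3) {
  succ <- edge_list(net)
  succ <- succ[lengths(succ) >= min_shared_targets]
  regs <- names(succ)
  found <- list()
  recurse <- function(set, shared, start) {
    if (length(set) >= min_regulators) {
      found[[length(found) + 1]] <<- list(set = set, shared = sort(shared))
    }
    for (i in seq_along(regs)) {
      if (i < start) next
      r <- regs[i]
      new_shared <- intersect(shared, succ[[r]])
      if (length(new_shared) >= min_shared_targets) {
        recurse(c(set, r), new_shared, i + 1L)
      }
    }
  }
  for (i in seq_along(regs)) {
    recurse(regs[i], succ[[regs[i]]], i + 1L)
  }
  if (length(found) == 0) {
    return(tibble(regulators = list(), shared_targets = list(),
                  n_regulators = integer(), n_shared_targets = integer()))
  }
  # keep only maximal regulator sets: no single further regulator preserves
  # the minimum shared-target count (intersection is monotone, so this
  # implies no superset qualifies)
  maximal <- map_lgl(found, function(f) {
    extras <- setdiff(regs, f$set)
    !any(map_lgl(extras, function(r) {
      length(intersect(f$shared, succ[[r]])) >= min_shared_targets
    }))
  })
  found <- found[maximal]
  out <- tibble(
    regulators = map(found, "set"),
    shared_targets = map(found, "shared"),
    n_regulators = map_int(found, function(f) length(f$set)),
    n_shared_targets = map_int(found, function(f) length(f$shared))
  )
  out <- out[!duplicated(map_chr(out$regulators,
                                 function(s) paste(sort(s), collapse = "|"))), ]
  arrange(out, desc(.data$n_regulators), desc(.data$n_shared_targets))
}

#' Compare two networks
#'
#' Node identity is by motif id; edges match on (regulator, target). Each
#' node's role is reported per network: input (out-degree > 0), target
#' (in-degree > 0), or both.
#'
#' @param net_a,net_b [grn_network()] objects.
#' @return List with `shared_nodes`, `unique_a`, `unique_b`,
#'   `shared_edges` (tibble), and a `roles` tibble.
#' @export
compare_networks <- function(net_a, net_b) {
  nodes_a <- net_a$nodes$motif
  nodes_b <- net_b$nodes$motif
  key <- function(e) paste(e$regulator, e$target, sep = "->")
  shared_edge_keys <- intersect(key(net_a$edges), key(net_b$edges))
  role_in <- function(net, m) {
    out_deg <- sum(net$edges$regulator == m)
    in_deg <- sum(net$edges$target == m)
    if (out_deg > 0 && in_deg > 0) "input+target"
    else if (out_deg > 0) "input"
    else if (in_deg > 0) "target"
    else "isolated"
  }
  all_nodes <- sort(union(nodes_a, nodes_b))
  roles <- tibble(
    motif = all_nodes,
    in_a = all_nodes %in% nodes_a,
    in_b = all_nodes %in% nodes_b,
    role_a = map_chr(all_nodes,
                     function(m) if (m %in% nodes_a) role_in(net_a, m) else NA),
    role_b = map_chr(all_nodes,
                     function(m) if (m %in% nodes_b) role_in(net_b, m) else NA)
  )
  list(
    shared_nodes = sort(intersect(nodes_a, nodes_b)),
    unique_a = sort(setdiff(nodes_a, nodes_b)),
    unique_b = sort(setdiff(nodes_b, nodes_a)),
    shared_edges = filter(net_a$edges, key(net_a$edges) %in% shared_edge_keys),
    roles = roles
  )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a network for visualization
#'
#' `"sif"` writes `regulator <tab> sign <tab> target` lines; `"graphml"`
#' writes nodes with `gene`/`p_value` attributes and edges with
#' `sign`/`weight`/`sites` attributes. Ordering is deterministic: nodes
#' lexicographic, edges by (regulator, target). An empty network yields a
#' valid file.
#'
#' @param net A [grn_network()].
#' @param path Output file.
#' @param format `"sif"`, `"graphml"` or `"tsv"` (full edge table).
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort(sprintf("unknown format '%s'; supported: sif, graphml, tsv",
                  format[1]))
  })
  edges <- net$edges
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", edges$regulator, edges$sign, edges$target)
    writeLines(lines, path)
  } else if (format == "tsv") {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w('<?xml version="1.0" encoding="UTF-8"?>')
    w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
    w('  <key id="name" for="node" attr.name="name" attr.type="string"/>')
    w('  <key id="gene" for="node" attr.name="gene" attr.type="string"/>')
    w('  <key id="p_value" for="node" attr.name="p_value" attr.type="double"/>')
    w('  <key id="sign" for="edge" attr.name="sign" attr.type="string"/>')
    w('  <key id="weight" for="edge" attr.name="weight" attr.type="double"/>')
    w('  <key id="sites" for="edge" attr.name="sites" attr.type="long"/>')
    w('  <graph id="G" edgedefault="directed">')
    for (i in seq_len(nrow(net$nodes))) {
      nd <- net$nodes[i, ]
      w('    <node id="%s">', xml_escape(nd$motif))
      w('      <data key="name">%s</data>', xml_escape(nd$motif))
      if (!is.na(nd$gene)) w('      <data key="gene">%s</data>', xml_escape(nd$gene))
      if (!is.na(nd$p_value)) w('      <data key="p_value">%.10g</data>', nd$p_value)
      w('    </node>')
    }
    for (i in seq_len(nrow(edges))) {
      e <- edges[i, ]
      w('    <edge source="%s" target="%s">',
        xml_escape(e$regulator), xml_escape(e$target))
      w('      <data key="sign">%s</data>', e$sign)
      w('      <data key="weight">%.10g</data>', e$weight)
      w('      <data key="sites">%d</data>', e$sites)
      w('    </edge>')
    }
    w('  </graph>')
    w('</graphml>')
  }
  invisible(path)
}
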
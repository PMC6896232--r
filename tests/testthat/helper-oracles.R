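# Independent brute-force oracles. These deliberately re-derive results from
# first principles (character-level scanning, quadratic clustering, cubic
# triple enumeration, exhaustive subset search) and share no code with the
# implementation paths they check.

naive_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

naive_log_odds <- function(pfm, bg = rep(0.25, 4), pc = 0.8) {
  totals <- colSums(pfm)
  lo <- matrix(0, 4, ncol(pfm), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in 1:4) {
    for (j in seq_len(ncol(pfm))) {
      lo[b, j] <- log2((pfm[b, j] + pc * bg[b]) / (totals[j] + pc) / bg[b])
    }
  }
  lo
}

naive_scan <- function(seq, motif, rel = 0.8, bg = rep(0.25, 4), pc = 0.8) {
  lo <- naive_log_odds(motif$pfm, bg, pc)
  w <- ncol(lo)
  thr <- rel * sum(apply(lo, 2, max))
  count <- 0L
  for (s in c(seq, naive_revcomp(seq))) {
    chars <- strsplit(s, "")[[1]]
    if (length(chars) < w) next
    for (i in seq_len(length(chars) - w + 1)) {
      win <- chars[i:(i + w - 1)]
      if (any(win == "N")) next
      sc <- sum(lo[cbind(match(win, c("A", "C", "G", "T")), seq_len(w))])
      if (sc >= thr) count <- count + 1L
    }
  }
  count
}

# UPGMA by repeated search over the full distance matrix; returns the
# cophenetic matrix (merge height at which each pair first joins)
naive_avg_linkage_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- list(h = Inf, i = NA, j = NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best$h) best <- list(h = h, i = i, j = j)
      }
    }
    mi <- clusters[[best$i]]
    mj <- clusters[[best$j]]
    coph[mi, mj] <- best$h
    coph[mj, mi] <- best$h
    clusters[[best$i]] <- c(mi, mj)
    clusters[[best$j]] <- NULL
  }
  coph
}

cubic_ffl_count <- function(net) {
  nodes <- net$nodes$motif
  has <- function(a, b) any(net$edges$regulator == a & net$edges$target == b)
  count <- 0L
  for (a in nodes) for (b in nodes) for (ch in nodes) {
    if (a != b && b != ch && a != ch &&
        has(a, b) && has(b, ch) && has(a, ch)) {
      count <- count + 1L
    }
  }
  count
}

exhaustive_dors <- function(net, min_reg = 2, min_shared = 3) {
  succ <- split(net$edges$target,
                factor(net$edges$regulator, levels = net$nodes$motif))
  regs <- names(succ)[lengths(succ) >= min_shared]
  res <- list()
  if (length(regs) >= min_reg) {
    for (k in min_reg:length(regs)) {
      for (comb in utils::combn(regs, k, simplify = FALSE)) {
        shared <- Reduce(intersect, succ[comb])
        if (length(shared) >= min_shared) {
          res[[length(res) + 1]] <- list(set = sort(comb), shared = sort(shared))
        }
      }
    }
  }
  keep <- vapply(res, function(f) {
    extras <- setdiff(regs, f$set)
    !any(vapply(extras, function(r) {
      length(intersect(f$shared, succ[[r]])) >= min_shared
    }, logical(1)))
  }, logical(1))
  res[keep]
}

dor_keys <- function(regulators, shared_targets) {
  sort(mapply(function(r, t) {
    paste(paste(sort(unlist(r)), collapse = "|"),
          paste(sort(unlist(t)), collapse = "|"), sep = "=>")
  }, regulators, shared_targets))
}

random_network <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n))
  adj <- matrix(runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  w <- runif(nrow(idx), -1, 1)
  w[w == 0] <- 0.5
  edges <- tibble::tibble(
    regulator = ids[idx[, 1]], target = ids[idx[, 2]],
    sign = ifelse(w > 0, "inductive", "inhibitory"),
    weight = w, sites = 1L
  )
  nodes <- tibble::tibble(motif = ids, gene = ids, p_value = NA_real_)
  grn_network(nodes, edges)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
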
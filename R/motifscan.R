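# PWM parsing and promoter scanning: JASPAR PFMs -> log-odds -> site counts.

#' Create a motif model from a position frequency matrix
#'
#' A motif model couples a JASPAR-style position frequency matrix (PFM) with
#' the transcription factor name(s) it represents. Dimer motifs keep their
#' compound name verbatim (e.g. `"Fos::Jun"`); [tf_genes()] splits it into the
#' constituent gene symbols.
#'
#' @param id Motif identifier (e.g. a JASPAR accession).
#' @param name TF name; `::` separates constituents of a dimer.
#' @param pfm 4 x width numeric matrix of nonnegative base counts, rows in
#'   A, C, G, T order.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(id, name, pfm) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4) abort(sprintf("motif %s: PFM must have 4 rows (ACGT)", id))
  if (any(pfm < 0)) abort(sprintf("motif %s: negative PFM counts", id))
  if (any(colSums(pfm) <= 0)) abort(sprintf("motif %s: PFM column with zero total", id))
  rownames(pfm) <- DNA_BASES_ACGT
  structure(
    list(id = as.character(id), name = as.character(name), pfm = pfm),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s (%s), width %d, consensus %s\n",
              x$id, x$name, ncol(x$pfm), motif_consensus(x)))
  invisible(x)
}

#' @rdname motif_model
#' @param motif A `motif_model`.
#' @export
motif_width <- function(motif) ncol(motif$pfm)

#' @rdname motif_model
#' @export
motif_consensus <- function(motif) {
  paste(DNA_BASES_ACGT[apply(motif$pfm, 2, which.max)], collapse = "")
}

#' Constituent gene symbols of a motif
#'
#' Splits dimer names on `::`, so `"Fos::Jun"` maps to `c("Fos", "Jun")`.
#'
#' @param motif A `motif_model`.
#' @return Character vector of gene symbols.
#' @export
tf_genes <- function(motif) {
  strsplit(motif$name, "::", fixed = TRUE)[[1]]
}

#' Read and write motifs in JASPAR PFM format
#'
#' The JASPAR text format is a `>ID NAME` header followed by four rows of
#' counts, one per base, optionally wrapped as `A [ 1 2 3 ]`.
#'
#' @param path File path.
#' @return `read_jaspar()` returns a named list of [motif_model()] objects.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) abort("no JASPAR records found (no '>' headers)")
  ends <- c(starts[-1] - 1L, length(lines))
  motifs <- list()
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(trimws(header), "\\s+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else toks[1]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4) {
      abort(sprintf("motif %s: expected 4 base rows, found %d", id, length(body)))
    }
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (anyNA(vals)) abort(sprintf("motif %s: non-numeric PFM entries", id))
      vals
    })
    widths <- lengths(rows)
    if (length(unique(widths)) != 1) {
      abort(sprintf("motif %s: ragged PFM rows (widths %s)", id,
                    paste(widths, collapse = ",")))
    }
    pfm <- do.call(rbind, rows)
    motifs[[id]] <- motif_model(id, name, pfm)
  }
  motifs
}

#' @rdname read_jaspar
#' @param motifs List of `motif_model` objects.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$id, m$name), con)
    for (b in seq_len(4)) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES_ACGT[b],
                         paste(format(m$pfm[b, ], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Log-odds scoring matrix of a motif
#'
#' Converts a PFM to a position weight matrix of log2 odds against a
#' background base composition, with a pseudocount distributed according to
#' the background:
#' `score[b, j] = log2((count[b, j] + pc * bg[b]) / (total_j + pc) / bg[b])`.
#'
#' @param motif A [motif_model()].
#' @param background Background base probabilities (A, C, G, T); must sum
#'   to 1 and be strictly positive.
#' @param pseudocount Total pseudocount added per column (default 0.8).
#' @return 4 x width matrix of log2-odds scores.
#' @export
log_odds <- function(motif, background = rep(0.25, 4), pseudocount = 0.8) {
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    abort("background must be 4 positive probabilities summing to 1")
  }
  pfm <- motif$pfm
  totals <- colSums(pfm)
  prob <- sweep(pfm + pseudocount * background, 2, totals + pseudocount, "/")
  lo <- log2(prob / background)
  dimnames(lo) <- dimnames(pfm)
  lo
}

#' @rdname log_odds
#' @details `max_log_odds()` is the best achievable window score, i.e. the sum
#'   of per-column maxima; the scan threshold is expressed relative to it.
#' @export
max_log_odds <- function(motif, background = rep(0.25, 4), pseudocount = 0.8) {
  sum(apply(log_odds(motif, background, pseudocount), 2, max))
}

# encode ACGTN as 1..4 / NA
encode_dna <- function(seq) {
  x <- strsplit(toupper(seq), "")[[1]]
  code <- match(x, c(DNA_BASES_ACGT, "N"))
  if (anyNA(code)) abort("sequence contains characters outside ACGTN")
  code[code == 5L] <- NA_integer_
  code
}

#' Reverse complement of a DNA string (ACGTN)
#' @param seq Character scalar.
#' @export
reverse_complement <- function(seq) {
  x <- rev(strsplit(toupper(seq), "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(comp[x], collapse = "")
}

# window scores of one strand; NA where the window touches an N
strand_scores <- function(code, lo) {
  w <- ncol(lo)
  n <- length(code) - w + 1L
  if (n < 1L) return(numeric(0))
  idx <- outer(seq_len(n) - 1L, seq_len(w), "+")
  base <- code[idx]
  sc <- lo[cbind(as.vector(base), rep(seq_len(w), each = n))]
  rowSums(matrix(sc, n, w))
}

#' Count predicted binding sites in a sequence
#'
#' Slides the motif's log2-odds matrix over both strands of `seq` and counts
#' windows scoring at least `rel_score` times the maximum achievable score.
#' Windows containing `N` are skipped; overlapping hits each count.
#'
#' @param seq Promoter sequence (character scalar over ACGTN).
#' @param motif A [motif_model()].
#' @param rel_score Relative score threshold in \[0, 1\] (default 0.8).
#' @inheritParams log_odds
#' @param positions If `TRUE`, return hit positions/strands instead of the
#'   count.
#' @return Integer site count (or a tibble of hits when `positions = TRUE`).
#' @export
scan_sequence <- function(seq, motif, rel_score = 0.8,
                          background = rep(0.25, 4), pseudocount = 0.8,
                          positions = FALSE) {
  lo <- log_odds(motif, background, pseudocount)
  w <- ncol(lo)
  code <- encode_dna(seq)
  if (length(code) < w) {
    warn(sprintf("sequence shorter than motif %s (%d < %d): count 0",
                 motif$id, length(code), w))
    return(if (positions) tibble(position = integer(), strand = character())
           else 0L)
  }
  thr <- rel_score * sum(apply(lo, 2, max))
  fwd <- strand_scores(code, lo)
  rev <- strand_scores(rev(5L - code), lo) # reverse-complement strand
  if (positions) {
    n <- length(fwd)
    hit_f <- which(!is.na(fwd) & fwd >= thr)
    hit_r <- which(!is.na(rev) & rev >= thr)
    return(tibble(
      position = c(hit_f, n + 1L - hit_r),
      strand = rep(c("+", "-"), c(length(hit_f), length(hit_r)))
    ))
  }
  sum(fwd >= thr, na.rm = TRUE) + sum(rev >= thr, na.rm = TRUE)
}

#' Build the genes x motifs site-count matrix
#'
#' Scans each promoter with each motif and records predicted site counts in
#' the proximal promoter window. Promoters longer than `max_length` are
#' trimmed to their 3' (TSS-proximal) end with a warning.
#'
#' @param promoters Named character vector of promoter sequences (names are
#'   gene ids), or a `Biostrings::DNAStringSet`.
#' @param motifs List of [motif_model()] objects.
#' @inheritParams scan_sequence
#' @param max_length Promoter window size in bases (default 1000).
#' @param genes Optional gene universe; genes without a promoter get a zero
#'   row (or an error when `missing_promoter = "error"`).
#' @param missing_promoter `"zero"` (default) or `"error"`.
#' @return A `site_count_matrix`: list with integer matrix `N` (genes x
#'   motifs), `gene_ids`, `motif_ids`.
#' @export
build_site_matrix <- function(promoters, motifs, rel_score = 0.8,
                              background = rep(0.25, 4), pseudocount = 0.8,
                              max_length = 1000, genes = NULL,
                              missing_promoter = c("zero", "error")) {
  missing_promoter <- match.arg(missing_promoter)
  if (inherits(promoters, "DNAStringSet")) {
    promoters <- setNames(as.character(promoters), names(promoters))
  }
  if (length(promoters) > 0 && is.null(names(promoters))) {
    abort("promoters must be named by gene id")
  }
  too_long <- nchar(promoters) > max_length
  if (any(too_long)) {
    warn(sprintf("%d promoter(s) longer than %d bases; trimmed to proximal end",
                 sum(too_long), max_length))
    promoters[too_long] <- substring(
      promoters[too_long],
      nchar(promoters[too_long]) - max_length + 1L
    )
  }
  genes <- genes %||% names(promoters)
  missing <- setdiff(genes, names(promoters))
  if (length(missing) > 0) {
    if (missing_promoter == "error") {
      abort(sprintf("no promoter for gene(s): %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    inform(sprintf("%d gene(s) without promoter: zero site rows", length(missing)))
  }
  motif_ids <- unname(map_chr(motifs, "id"))
  N <- matrix(0L, length(genes), length(motifs),
              dimnames = list(genes, motif_ids))
  for (g in intersect(genes, names(promoters))) {
    for (j in seq_along(motifs)) {
      N[g, j] <- scan_sequence(promoters[[g]], motifs[[j]], rel_score,
                               background, pseudocount)
    }
  }
  structure(list(N = N, gene_ids = genes, motif_ids = motif_ids),
            class = "site_count_matrix")
}

#' @export
print.site_count_matrix <- function(x, ...) {
  cat(sprintf("<site_count_matrix> %d genes x %d motifs, %d predicted sites\n",
              length(x$gene_ids), length(x$motif_ids), sum(x$N)))
  invisible(x)
}
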
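# Synthetic data generator: promoters with planted PWM sites, smooth
# condition-specific motif-activity trajectories, expression from the additive
# site-count x activity model, Poisson (optionally overdispersed) count
# sampling, and a microarray-like intensity transform. Ground truth is
# recorded for recovery tests.

#' Configuration of the synthetic data generator
#'
#' Collects the knobs of the generative model: promoters of
#' `promoter_length` i.i.d. uniform ACGT bases receive, per motif,
#' Poisson(`site_rate`) planted sites; per-motif activities follow smooth
#' per-condition trajectories sharing a common value at day 0; log2
#' expression is `intercept + sites %*% activities + Gaussian noise`; counts
#' are sampled at `depth_per_sample` aligned reads.
#'
#' @param n_genes,n_motifs Numbers of genes and motifs (`n_genes >= n_motifs`).
#' @param promoter_length Promoter window in bases (default 1000).
#' @param conditions Condition labels (default the three germ-layer
#'   differentiation regimes).
#' @param timepoints_per_condition Days per condition, starting at day 0.
#' @param replicates Biological replicates per condition/day (default 2).
#' @param site_rate Expected planted sites per promoter per motif.
#' @param activity_shapes Optional nested list `[[motif]][[condition]]` of
#'   [activity_shape()] specs; randomly drawn when `NULL`.
#' @param amplitude_sd SD of random trajectory amplitudes (log2 units/site).
#' @param intercept_range Range of per-sample intercepts (log2 units).
#' @param noise_sd Gaussian noise SD on log2 expression.
#' @param depth_per_sample Expected aligned reads per sample.
#' @param overdispersion Negative-binomial overdispersion (0 = Poisson).
#' @param log2_cap Guard against overflow of `2^L` (error above this).
#' @param gene_ids,motif_ids Optional identifier vectors.
#' @param seed Integer seed; all generator operations are deterministic
#'   functions of the config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_genes, n_motifs, promoter_length = 1000,
                             conditions = c("ectoderm", "mesoderm", "endoderm"),
                             timepoints_per_condition = 8, replicates = 2,
                             site_rate = 0.5, activity_shapes = NULL,
                             amplitude_sd = 1, intercept_range = c(4, 6),
                             noise_sd = 0.5, depth_per_sample = 5e6,
                             overdispersion = 0, log2_cap = 30,
                             gene_ids = NULL, motif_ids = NULL, seed = 1) {
  if (n_genes < n_motifs) abort("n_genes must be >= n_motifs")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (any(depth_per_sample <= 0)) abort("depth_per_sample must be > 0")
  if (site_rate < 0) abort("site_rate must be >= 0")
  if (timepoints_per_condition < 1) abort("need at least one timepoint")
  cfg <- structure(
    list(n_genes = n_genes, n_motifs = n_motifs,
         promoter_length = promoter_length, conditions = conditions,
         timepoints_per_condition = timepoints_per_condition,
         replicates = replicates, site_rate = site_rate,
         activity_shapes = activity_shapes, amplitude_sd = amplitude_sd,
         intercept_range = intercept_range, noise_sd = noise_sd,
         depth_per_sample = depth_per_sample, overdispersion = overdispersion,
         log2_cap = log2_cap,
         gene_ids = gene_ids %||% sprintf("G%04d", seq_len(n_genes)),
         motif_ids = motif_ids %||% sprintf("M%02d", seq_len(n_motifs)),
         seed = as.integer(seed)),
    class = "generator_config"
  )
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config> %d genes, %d motifs, %d conditions x ",
                     "%d days x %d reps, site_rate %.2f, noise_sd %.2f, seed %d\n"),
              x$n_genes, x$n_motifs, length(x$conditions),
              x$timepoints_per_condition, x$replicates, x$site_rate,
              x$noise_sd, x$seed))
  invisible(x)
}

#' Sample grid implied by a generator config
#'
#' Samples are named `condition_day_replicate`; every condition starts at the
#' shared undifferentiated day 0.
#'
#' @param config A [generator_config()].
#' @return Tibble with columns `sample`, `condition`, `day`, `replicate`.
#' @export
sample_grid <- function(config) {
  grid <- expand.grid(
    replicate = seq_len(config$replicates),
    day = seq_len(config$timepoints_per_condition) - 1L,
    condition = config$conditions,
    stringsAsFactors = FALSE
  )
  tibble(
    sample = sprintf("%s_%d_%d", grid$condition, grid$day, grid$replicate),
    condition = grid$condition, day = grid$day, replicate = grid$replicate
  )
}

#' Trajectory shape of a motif activity in one condition
#'
#' All shapes except `constant` are exactly 0 at day 0, so conditions share
#' the undifferentiated origin by construction. `logistic` is a sigmoid
#' rescaled to start at 0 and approach `amplitude`; `linear` ramps from
#' `onset` to the last day.
#'
#' @param type `"constant"`, `"linear"` or `"logistic"`.
#' @param amplitude Plateau activity change (log2-expression units per site).
#' @param onset Day at which the trajectory turns on.
#' @param rate Logistic steepness (per day).
#' @param baseline Day-0 activity; must agree across the conditions of a
#'   motif (the shared origin).
#' @export
activity_shape <- function(type = c("logistic", "linear", "constant"),
                           amplitude = 1, onset = 2, rate = 1.5,
                           baseline = 0) {
  type <- match.arg(type)
  structure(list(type = type, amplitude = amplitude, onset = onset,
                 rate = rate, baseline = baseline), class = "activity_shape")
}

eval_shape <- function(shape, t, t_max) {
  shape$baseline + with(shape, switch(type,
    constant = rep(amplitude, length(t)),
    linear = {
      span <- max(t_max - onset, 1e-9)
      amplitude * pmax(0, t - onset) / span
    },
    logistic = {
      base <- plogis(rate * (0 - onset))
      amplitude * (plogis(rate * (t - onset)) - base) / (1 - base)
    }
  ))
}

random_shapes <- function(config) {
  t_max <- config$timepoints_per_condition - 1L
  shapes <- vector("list", config$n_motifs)
  names(shapes) <- config$motif_ids
  for (m in config$motif_ids) {
    base_m <- rnorm(1, 0, config$amplitude_sd) # shared day-0 origin
    shapes[[m]] <- lapply(setNames(config$conditions, config$conditions),
      function(cond) {
        activity_shape("logistic",
                       amplitude = rnorm(1, 0, config$amplitude_sd),
                       onset = runif(1, 0.2, 0.6) * max(t_max, 1),
                       rate = runif(1, 1, 3), baseline = base_m)
      })
  }
  shapes
}

#' Generate the true motif-activity matrix
#'
#' Evaluates each motif's per-condition trajectory shape on the sample grid.
#' Activities vary smoothly within each condition and all conditions share
#' the same value at day 0 (the common undifferentiated origin); replicates
#' of a condition/day share the activity.
#'
#' @param config A [generator_config()].
#' @return Motifs x samples numeric matrix.
#' @export
generate_activities <- function(config) {
  shapes <- config$activity_shapes
  if (is.null(shapes)) {
    set.seed(config$seed + 1L)
    shapes <- random_shapes(config)
  }
  grid <- sample_grid(config)
  t_max <- config$timepoints_per_condition - 1L
  A <- matrix(0, config$n_motifs, nrow(grid),
              dimnames = list(config$motif_ids, grid$sample))
  for (m in config$motif_ids) {
    cond_shapes <- shapes[[m]]
    if (is.null(cond_shapes)) abort(sprintf("no activity shape for motif %s", m))
    day0 <- map_dbl(config$conditions,
                    function(cond) eval_shape(cond_shapes[[cond]], 0, t_max))
    if (diff(range(day0)) > 1e-9) {
      abort(sprintf("motif %s: conditions disagree at day 0 (shared origin)", m))
    }
    for (cond in config$conditions) {
      sel <- grid$condition == cond
      A[m, sel] <- eval_shape(cond_shapes[[cond]], grid$day[sel], t_max)
    }
  }
  A
}

#' Generate promoters with planted motif sites
#'
#' Each promoter is an i.i.d. uniform ACGT string; per motif, a
#' Poisson(`site_rate`) number of occurrences is sampled base-by-base from
#' the PFM's column probabilities and planted at non-overlapping positions on
#' a uniformly chosen strand. The planted counts are the ground-truth site
#' matrix.
#'
#' @param config A [generator_config()].
#' @param motifs List of [motif_model()]s (length `n_motifs`).
#' @param sites Optional genes x motifs integer matrix of counts to plant
#'   instead of Poisson draws.
#' @param max_tries Placement retries per site before giving up.
#' @return List with `promoters` (named character vector) and `true_sites`
#'   (genes x motifs integer matrix).
#' @export
generate_promoters <- function(config, motifs, sites = NULL, max_tries = 200) {
  widths <- map_int(motifs, motif_width)
  if (any(widths > config$promoter_length)) {
    abort("motif wider than promoter_length")
  }
  if (length(motifs) != config$n_motifs) {
    abort("length(motifs) must equal config$n_motifs")
  }
  set.seed(config$seed + 2L)
  n_genes <- config$n_genes
  len <- config$promoter_length
  true_sites <- matrix(0L, n_genes, config$n_motifs,
                       dimnames = list(config$gene_ids, config$motif_ids))
  if (!is.null(sites)) {
    sites <- as.matrix(sites)
    stopifnot(nrow(sites) == n_genes, ncol(sites) == config$n_motifs)
  }
  promoters <- character(n_genes)
  names(promoters) <- config$gene_ids
  for (g in seq_len(n_genes)) {
    chars <- sample(DNA_BASES_ACGT, len, replace = TRUE)
    occupied <- logical(len)
    for (j in seq_len(config$n_motifs)) {
      k <- if (is.null(sites)) rpois(1, config$site_rate) else sites[g, j]
      if (k == 0) next
      pfm <- motifs[[j]]$pfm
      w <- ncol(pfm)
      prob <- sweep(pfm, 2, colSums(pfm), "/")
      for (s in seq_len(k)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          pos <- sample.int(len - w + 1L, 1)
          if (!any(occupied[pos:(pos + w - 1L)])) {
            site <- map_chr(seq_len(w),
                            function(col) sample(DNA_BASES_ACGT, 1,
                                                 prob = prob[, col]))
            site <- paste(site, collapse = "")
            if (runif(1) < 0.5) site <- reverse_complement(site)
            chars[pos:(pos + w - 1L)] <- strsplit(site, "")[[1]]
            occupied[pos:(pos + w - 1L)] <- TRUE
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          abort(sprintf(
            "promoter %s too crowded: failed to place site of %s after %d tries",
            config$gene_ids[g], motifs[[j]]$id, max_tries))
        }
        true_sites[g, j] <- true_sites[g, j] + 1L
      }
    }
    promoters[g] <- paste(chars, collapse = "")
  }
  list(promoters = promoters, true_sites = true_sites)
}

#' Ground truth of a synthetic dataset
#'
#' @param true_sites Genes x motifs planted site counts.
#' @param true_activities Motifs x samples activity matrix.
#' @param true_intercepts Per-sample intercepts (log2 units).
#' @param true_edges Tibble of planted regulatory couplings
#'   (`regulator`, `target`, `sign`); every regulator must have at least one
#'   site in its target's promoter.
#' @param sample_depths Per-sample expected aligned reads.
#' @export
synthetic_truth <- function(true_sites, true_activities, true_intercepts,
                            true_edges = NULL, sample_depths = NULL) {
  true_edges <- true_edges %||%
    tibble(regulator = character(), target = character(), sign = character())
  if (nrow(true_edges) > 0) {
    ok <- map_lgl(seq_len(nrow(true_edges)), function(i) {
      true_sites[true_edges$target[i], true_edges$regulator[i]] >= 1
    })
    if (!all(ok)) abort("true edge without a site in the target promoter")
  }
  structure(
    list(true_sites = true_sites, true_activities = true_activities,
         true_intercepts = true_intercepts, true_edges = true_edges,
         sample_depths = sample_depths),
    class = "synthetic_truth"
  )
}

#' Generate expression and read counts from planted sites and activities
#'
#' Log2 expression is `L[g,s] = intercept[s] + sum_m effect[g,m] * A[m,s] +
#' noise`; counts are Poisson (negative binomial when `overdispersion > 0`)
#' with per-gene means proportional to `2^L`, scaled so each sample's
#' expected total equals its depth.
#'
#' @param true_sites Genes x motifs planted site counts.
#' @param true_activities Motifs x samples activities.
#' @param config A [generator_config()].
#' @param intercepts Optional per-sample intercepts (drawn uniformly from
#'   `intercept_range` when `NULL`).
#' @param effect Optional genes x motifs effect matrix replacing
#'   `true_sites` in the expression model (signed couplings for regulatory
#'   scenarios); sites still gate edge ground truth.
#' @return List with `counts` (a [count_matrix()]), `log2_latent` (the
#'   noise-bearing log2 expression before count sampling) and `truth`
#'   (a [synthetic_truth()]).
#' @export
generate_expression <- function(true_sites, true_activities, config,
                                intercepts = NULL, effect = NULL) {
  effect <- effect %||% true_sites
  stopifnot(nrow(effect) == nrow(true_sites),
            ncol(effect) == nrow(true_activities))
  set.seed(config$seed + 3L)
  n_samples <- ncol(true_activities)
  samples <- colnames(true_activities)
  intercepts <- intercepts %||%
    runif(n_samples, config$intercept_range[1], config$intercept_range[2])
  names(intercepts) <- samples
  L <- matrix(intercepts, nrow(effect), n_samples, byrow = TRUE) +
    effect %*% true_activities
  if (config$noise_sd > 0) {
    L <- L + matrix(rnorm(length(L), 0, config$noise_sd), nrow(L))
  }
  dimnames(L) <- list(rownames(true_sites), samples)
  if (any(L > config$log2_cap)) {
    bad <- which(L > config$log2_cap, arr.ind = TRUE)[1, ]
    abort(sprintf("log2 expression exceeds cap %g at gene %s, sample %s",
                  config$log2_cap, rownames(L)[bad[1]], colnames(L)[bad[2]]))
  }
  depth <- rep_len(config$depth_per_sample, n_samples)
  names(depth) <- samples
  expL <- 2^L
  lambda <- sweep(expL, 2, depth / colSums(expL), "*")
  counts <- if (config$overdispersion > 0) {
    matrix(rnbinom(length(lambda), mu = lambda,
                   size = 1 / config$overdispersion), nrow(lambda))
  } else {
    matrix(rpois(length(lambda), lambda), nrow(lambda))
  }
  dimnames(counts) <- dimnames(L)
  cm <- count_matrix(counts, sample_meta = parse_sample_names(samples),
                     aligned_totals = depth)
  list(
    counts = cm, log2_latent = L,
    truth = synthetic_truth(true_sites, true_activities, intercepts,
                            sample_depths = depth)
  )
}

#' Microarray-like intensity transform
#'
#' Applies a monotone nonlinear distortion plus additive Gaussian noise to an
#' expression matrix so that the intensity distribution differs from the
#' input distribution while rank order is (stochastically) preserved. Used as
#' a stand-in for cross-platform probe intensities when exercising quantile
#' matching.
#'
#' @param m Numeric matrix (nonnegative log2 expression).
#' @param coefs Coefficients `c(a, b, c)` of the distortion
#'   `a + b * x + c * x^2` (monotone for `x >= 0` when `b, c >= 0`).
#' @param noise_sd Additive noise SD (intensity units).
#' @param seed Optional seed.
#' @return Matrix of distorted intensities, same shape and dimnames.
#' @export
microarray_like <- function(m, coefs = c(2, 1.5, 0.08), noise_sd = 0.25,
                            seed = NULL) {
  if (!all(is.finite(m))) abort("expression matrix must be finite")
  if (!is.null(seed)) set.seed(seed)
  out <- coefs[1] + coefs[2] * m + coefs[3] * m^2
  if (noise_sd > 0) out <- out + matrix(rnorm(length(m), 0, noise_sd), nrow(m))
  dimnames(out) <- dimnames(m)
  out
}

#' Random information-rich motifs
#'
#' Near one-hot PFMs (one dominant base per column) useful as planted
#' regulator motifs: at the default dominance a planted occurrence scores
#' close to the maximum achievable log-odds.
#'
#' @param n Number of motifs.
#' @param width Motif width in bases.
#' @param total Column count total.
#' @param dominance Fraction of the column total on the dominant base.
#' @param ids,names Optional identifiers (defaults `M01`, ...).
#' @param seed Optional seed.
#' @return Named list of [motif_model()]s.
#' @export
random_motifs <- function(n, width = 10, total = 100, dominance = 0.85,
                          ids = NULL, names = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- ids %||% sprintf("M%02d", seq_len(n))
  names <- names %||% ids
  motifs <- vector("list", n)
  for (i in seq_len(n)) {
    pfm <- matrix(total * (1 - dominance) / 3, 4, width)
    dom <- sample.int(4, width, replace = TRUE)
    pfm[cbind(dom, seq_len(width))] <- total * dominance
    motifs[[i]] <- motif_model(ids[i], names[i], pfm)
  }
  setNames(motifs, ids)
}

#' Generate a complete synthetic dataset
#'
#' Runs the whole generative model: motifs (unless supplied), promoters with
#' planted sites, activity trajectories, latent log2 expression and sampled
#' counts.
#'
#' @param config A [generator_config()].
#' @param motifs Optional list of motifs; random information-rich motifs are
#'   drawn otherwise.
#' @return List with `config`, `motifs`, `promoters`, `activities`,
#'   `counts`, `log2_latent`, `truth`.
#' @export
simulate_dataset <- function(config, motifs = NULL) {
  if (is.null(motifs)) {
    set.seed(config$seed)
    motifs <- random_motifs(config$n_motifs, ids = config$motif_ids,
                            names = config$motif_ids)
  }
  A <- generate_activities(config)
  prom <- generate_promoters(config, motifs)
  ex <- generate_expression(prom$true_sites, A, config)
  list(config = config, motifs = motifs, promoters = prom$promoters,
       activities = A, counts = ex$counts, log2_latent = ex$log2_latent,
       truth = ex$truth)
}

#' Write synthetic artifacts to disk
#'
#' Counts go to TSV (via [write_counts()]), promoters to FASTA (record id =
#' gene id), and the ground truth to a JSON sidecar.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    promoters = file.path(dir, "promoters.fa"),
    truth = file.path(dir, "truth.json")
  )
  write_counts(sim$counts, paths[["counts"]])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$promoters),
                              paths[["promoters"]])
  truth <- sim$truth
  jsonlite::write_json(
    list(true_sites = truth$true_sites,
         true_activities = truth$true_activities,
         true_intercepts = truth$true_intercepts,
         true_edges = truth$true_edges,
         sample_depths = truth$sample_depths),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(paths)
}
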
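test_that("average-linkage clustering matches brute-force UPGMA", {
  # two identical samples merge at height 0
  m <- cbind(alpha_0_1 = c(1, 5, 3, 8), alpha_1_1 = c(1, 5, 3, 8),
             alpha_2_1 = c(9, 2, 7, 1))
  rownames(m) <- sprintf("g%d", 1:4)
  tree <- cluster_samples(m)
  expect_equal(min(tree$height), 0, tolerance = 1e-12)

  # hand execution on 3 samples: first merge at min distance, second at the
  # mean of the two cross distances
  d <- as.matrix(1 - cor(m))
  expect_equal(tree$height[1], min(d[upper.tri(d)]), tolerance = 1e-12)
  expect_equal(tree$height[2], mean(d[3, 1:2]), tolerance = 1e-12)

  # oracle equivalence on a larger fixture via cophenetic distances
  set.seed(41)
  fx <- matrix(rnorm(60 * 8), 60, 8,
               dimnames = list(sprintf("g%02d", 1:60),
                               sprintf("alpha_%d_1", 0:7)))
  tr <- cluster_samples(fx)
  coph <- as.matrix(stats::cophenetic(tr))
  want <- naive_avg_linkage_cophenetic(1 - cor(fx))
  dimnames(want) <- dimnames(coph)
  expect_equal(coph, want, tolerance = 1e-10)

  # constant profile under correlation distance errors
  bad <- cbind(m, alpha_3_1 = rep(2, 4))
  expect_error(cluster_samples(bad), "constant sample")
  # euclidean metric tolerates it
  expect_s3_class(cluster_samples(bad, metric = "euclidean"), "hclust")

  # newick export
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, colnames(fx))
})

test_that("PCA decomposes variance and projection is self-consistent", {
  # rank-1 data: single activity pattern, no noise
  u <- rnorm(50)
  v <- seq(-2, 2, length.out = 6)
  m1 <- outer(u, v) + 5
  dimnames(m1) <- list(sprintf("g%02d", 1:50), sprintf("alpha_%d_1", 0:5))
  p1 <- fit_pca(m1)
  expect_equal(p1$variance_fractions[1], 1, tolerance = 1e-10)

  set.seed(7)
  m <- matrix(rnorm(80 * 7, mean = 4), 80, 7,
              dimnames = list(sprintf("g%02d", 1:80),
                              sprintf("alpha_%d_1", 0:6)))
  p <- fit_pca(m)
  expect_equal(sum(p$variance_fractions), 1, tolerance = 1e-10)
  expect_true(all(diff(p$variance_fractions) <= 1e-12))
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)

  # projecting the training data reproduces the stored scores
  sc <- suppressMessages(project_onto(p, m))
  expect_equal(sc, p$scores, tolerance = 1e-8)

  # an external sample identical to a training sample gets identical scores
  ext <- m[, 3, drop = FALSE]
  colnames(ext) <- "external"
  expect_equal(unname(suppressMessages(project_onto(p, ext))[1, ]),
               unname(p$scores[3, ]), tolerance = 1e-8)

  # brute-force dot products with shuffled, subset genes
  keep <- sample(rownames(m), 60)
  ext2 <- m[keep, 1:2] + 0.3
  got <- suppressMessages(project_onto(p, ext2))
  want <- t(vapply(1:2, function(s) {
    x <- ext2[, s] - p$center[keep]
    vapply(seq_len(ncol(p$loadings)), function(k) {
      sum(x * p$loadings[keep, k])
    }, numeric(1))
  }, numeric(ncol(p$loadings))))
  expect_equal(unname(got), unname(want), tolerance = 1e-10)

  # overlap guard
  expect_error(project_onto(p, m[1:10, ]), "model genes")
  expect_error(fit_pca(m[, 1:2]), "3 samples")
})

test_that("quantile matching reproduces the reference distribution", {
  set.seed(13)
  ref <- rexp(500, 0.1)
  ext <- matrix(rnorm(500 * 3, 50, 10), 500, 3)

  got <- quantile_match(ext, ref)
  # per-sample sorted output equals the sorted reference (equal lengths)
  for (s in 1:3) {
    expect_equal(sort(got[, s]), sort(ref), tolerance = 1e-10)
  }
  # sup-distance between output ECDF and reference ECDF <= 1/n
  F_ref <- stats::ecdf(ref)
  F_out <- stats::ecdf(got[, 1])
  grid <- sort(c(ref, got[, 1]))
  expect_lte(max(abs(F_ref(grid) - F_out(grid))), 1 / length(ref) + 1e-12)

  # a monotone distortion of the reference is restored exactly
  distorted <- matrix(ref^1.7 + 3, ncol = 1)
  expect_equal(sort(quantile_match(distorted, ref)[, 1]), sort(ref),
               tolerance = 1e-10)
  expect_equal(order(quantile_match(distorted, ref)[, 1]), order(ref))

  expect_error(quantile_match(ext, numeric(0)), "empty")
})

test_that("gene centring removes per-gene means", {
  m <- matrix(rnorm(20), 4, 5)
  rownames(m) <- sprintf("g%d", 1:4)
  cg <- center_genes(m)
  expect_true(all(abs(rowMeans(cg)) < 1e-12))
  expect_equal(center_genes(cg), cg) # idempotent
  expect_true(all(center_genes(matrix(7, 2, 3)) == 0))
})

test_that("variation filter applies inclusive group fold thresholds", {
  rpm <- rbind(
    g16 = c(1, 15, 1, 1),   # exactly 16-fold with pseudocount 0
    g2 = c(8, 9, 8, 8),
    gbig = c(1, 99, 1, 1)
  )
  colnames(rpm) <- sprintf("alpha_%d_1", 0:3)
  grp <- list(course = colnames(rpm))
  # pseudocount 0: (15+0)/(1+0)... use values making the boundary exact
  rpm["g16", ] <- c(1, 16, 1, 1)
  expect_true("g16" %in% variation_filter(rpm, grp, fold = 16, pseudocount = 0))
  expect_false("g2" %in% variation_filter(rpm, grp, fold = 16, pseudocount = 0))
  # threshold 1 keeps everything
  expect_equal(variation_filter(rpm, grp, fold = 1), rownames(rpm))
  expect_error(variation_filter(rpm, list(x = "nope"), 2), "unknown sample")

  # brute force on a random fixture with two groups, any/all
  set.seed(55)
  fx <- matrix(rexp(80 * 6, 0.05), 80, 6,
               dimnames = list(sprintf("g%02d", 1:80),
                               c(sprintf("alpha_%d_1", 0:2),
                                 sprintf("beta_%d_1", 0:2))))
  groups <- list(a = colnames(fx)[1:3], b = colnames(fx)[4:6])
  fold_of <- function(v) (max(v) + 1) / (min(v) + 1)
  want_any <- rownames(fx)[vapply(seq_len(nrow(fx)), function(i) {
    fold_of(fx[i, 1:3]) >= 4 || fold_of(fx[i, 4:6]) >= 4
  }, logical(1))]
  want_all <- rownames(fx)[vapply(seq_len(nrow(fx)), function(i) {
    fold_of(fx[i, 1:3]) >= 4 && fold_of(fx[i, 4:6]) >= 4
  }, logical(1))]
  expect_identical(variation_filter(fx, groups, 4, "any"), want_any)
  expect_identical(variation_filter(fx, groups, 4, "all"), want_all)
})

test_that("preset filters compose course and section criteria", {
  cfg <- quiet_config(n_genes = 300, n_motifs = 4, seed = 23,
                      site_rate = 0.4, noise_sd = 0.3)
  sim <- simulate_dataset(cfg)
  expr <- normalize_counts(sim$counts, median_window = 51)
  g_episc <- variation_filter_preset(expr, "episc", fold_course = 4)
  expect_gt(length(g_episc), 0)
  # the geoseq preset can only shrink the episc set
  sec <- expr$rpm[, 1:3] * matrix(2^rnorm(nrow(expr$rpm) * 3, 0, 1),
                                  ncol = 3)
  colnames(sec) <- sprintf("sec_%d_1", 1:3)
  g_geo <- variation_filter_preset(expr, "geoseq", section_rpm = sec,
                                   fold_course = 4, fold_sections = 2)
  expect_true(all(g_geo %in% g_episc))
  expect_error(variation_filter_preset(expr, "geoseq"), "section_rpm")
})
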
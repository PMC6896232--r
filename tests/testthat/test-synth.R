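test_that("promoter generation plants the requested sites", {
  cfg <- quiet_config(n_genes = 30, n_motifs = 2, seed = 9)
  motifs <- random_motifs(2, width = 8, ids = cfg$motif_ids,
                          names = cfg$motif_ids, seed = 9)

  # degenerate rate: pure background, no sites recorded
  cfg0 <- quiet_config(n_genes = 30, n_motifs = 2, seed = 9)
  cfg0$site_rate <- 0
  p0 <- generate_promoters(cfg0, motifs)
  expect_true(all(p0$true_sites == 0))
  expect_true(all(nchar(p0$promoters) == cfg0$promoter_length))

  # one-hot PFM: every planted occurrence is the consensus or its reverse
  # complement
  cons <- one_hot_motif("ACGTACGTAC")
  cfg1 <- generator_config(n_genes = 40, n_motifs = 1, site_rate = 1,
                           conditions = "alpha", timepoints_per_condition = 2,
                           replicates = 1, seed = 5, motif_ids = "M1")
  p1 <- generate_promoters(cfg1, list(cons))
  found <- vapply(names(p1$promoters), function(g) {
    hits <- scan_sequence(p1$promoters[[g]], cons, rel_score = 0.999)
    hits >= p1$true_sites[g, 1]
  }, logical(1))
  expect_true(all(found))
})

test_that("planted site counts follow the Poisson rate", {
  cfg <- generator_config(n_genes = 200, n_motifs = 5, site_rate = 0.5,
                          conditions = "alpha", timepoints_per_condition = 2,
                          replicates = 1, seed = 1)
  motifs <- random_motifs(5, ids = cfg$motif_ids, names = cfg$motif_ids,
                          seed = 1)
  p <- generate_promoters(cfg, motifs)
  n <- length(p$true_sites)
  se <- sqrt(0.5 / n)
  expect_lt(abs(mean(p$true_sites) - 0.5), 3 * se)
})

test_that("activity trajectories respect shapes and the shared origin", {
  cfg <- quiet_config(n_genes = 20, n_motifs = 2, timepoints = 8)

  # constant shape, amplitude 0 -> all-zero matrix
  cfg$activity_shapes <- flat_shapes(cfg)
  expect_true(all(generate_activities(cfg) == 0))

  # logistic asymptotes: ~0 at day 0, ~amplitude at the last day
  lg <- activity_shape("logistic", amplitude = 2, onset = 4, rate = 3)
  cfg$activity_shapes <- lapply(flat_shapes(cfg), function(s) {
    lapply(s, function(x) lg)
  })
  A <- generate_activities(cfg)
  grid <- sample_grid(cfg)
  expect_equal(unname(A[, grid$day == 0]), matrix(0, 2, 2), tolerance = 1e-6)
  expect_true(all(abs(A[, grid$day == 7] - 2) < 0.01))

  # opposite-sign amplitudes -> anticorrelated condition profiles
  opp <- list(
    alpha = activity_shape("logistic", amplitude = 1.5, onset = 3),
    beta = activity_shape("logistic", amplitude = -1.5, onset = 3)
  )
  cfg$activity_shapes <- lapply(flat_shapes(cfg), function(s) opp)
  A2 <- generate_activities(cfg)
  a <- A2[1, grid$condition == "alpha"]
  b <- A2[1, grid$condition == "beta"]
  expect_lt(cor(a[-1], b[-1]), 0)

  # conditions disagreeing at day 0 are rejected
  bad <- list(alpha = activity_shape("constant", amplitude = 1),
              beta = activity_shape("constant", amplitude = 2))
  cfg$activity_shapes <- lapply(flat_shapes(cfg), function(s) bad)
  expect_error(generate_activities(cfg), "day 0")
})

test_that("expression follows the additive site-activity model", {
  # plug-in check: N = [1, 0, 2], A = 0.5, c = 1 -> L = [1.5, 1.0, 2.0]
  cfg <- generator_config(n_genes = 3, n_motifs = 1, noise_sd = 0,
                          conditions = "alpha", timepoints_per_condition = 1,
                          replicates = 1, gene_ids = c("g1", "g2", "g3"),
                          motif_ids = "M1", seed = 1)
  N <- matrix(c(1L, 0L, 2L), 3, 1, dimnames = list(cfg$gene_ids, "M1"))
  A <- matrix(0.5, 1, 1, dimnames = list("M1", "alpha_0_1"))
  ex <- generate_expression(N, A, cfg, intercepts = 1)
  expect_equal(unname(ex$log2_latent[, 1]), c(1.5, 1.0, 2.0))

  # all-zero activities -> identical expected expression within a sample
  A0 <- matrix(0, 1, 1, dimnames = dimnames(A))
  ex0 <- generate_expression(N, A0, cfg, intercepts = 1)
  expect_true(all(ex0$log2_latent == 1))

  # overflow guard names the offender
  A_big <- matrix(20, 1, 1, dimnames = dimnames(A))
  expect_error(generate_expression(N, A_big, cfg, intercepts = 1),
               "g3.*alpha_0_1")
})

test_that("noise-free least squares recovers activities and intercepts", {
  cfg <- quiet_config(n_genes = 100, n_motifs = 3, seed = 21, noise_sd = 0,
                      site_rate = 0.6)
  sim <- simulate_dataset(cfg)
  fit <- fit_activities(sim$log2_latent, sim$truth$true_sites)
  expect_equal(fit$A[rownames(sim$activities), ], sim$activities,
               tolerance = 1e-8)
  expect_equal(fit$intercepts, sim$truth$true_intercepts, tolerance = 1e-8)
})

test_that("microarray transform distorts distribution but preserves ranks", {
  cfg <- quiet_config(n_genes = 300, seed = 8)
  sim <- simulate_dataset(cfg)
  m <- log2(gross_normalize(sim$counts) + 1)

  # identity coefficients, zero noise -> unchanged
  expect_equal(microarray_like(m, coefs = c(0, 1, 0), noise_sd = 0), m)

  # monotone distortion, zero noise -> per-sample Spearman correlation 1
  y <- microarray_like(m, noise_sd = 0)
  rho <- vapply(seq_len(ncol(m)), function(s) {
    cor(m[, s], y[, s], method = "spearman")
  }, numeric(1))
  expect_equal(rho, rep(1, ncol(m)))

  # default transform shifts the distribution away from the input
  y2 <- microarray_like(m, seed = 1)
  ks <- suppressWarnings(stats::ks.test(as.vector(m), as.vector(y2)))
  expect_gt(unname(ks$statistic), 0)
})

test_that("generation is deterministic given the seed", {
  cfg <- quiet_config(n_genes = 50, seed = 17)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(quiet_config(n_genes = 50, seed = 17))
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  s3 <- simulate_dataset(quiet_config(n_genes = 50, seed = 18))
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("synthetic truth validates edge-site consistency", {
  sites <- matrix(0L, 2, 2, dimnames = list(c("g1", "g2"), c("M1", "M2")))
  A <- matrix(0, 2, 2, dimnames = list(c("M1", "M2"), c("s1", "s2")))
  edges <- tibble::tibble(regulator = "M1", target = "g1", sign = "inductive")
  expect_error(synthetic_truth(sites, A, c(0, 0), true_edges = edges),
               "without a site")
  sites["g1", "M1"] <- 1L
  expect_s3_class(synthetic_truth(sites, A, c(0, 0), true_edges = edges),
                  "synthetic_truth")
})

test_that("synthetic artifacts round-trip through disk formats", {
  cfg <- quiet_config(n_genes = 20, seed = 30)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_synthetic(sim, dir)
  expect_true(all(file.exists(paths)))
  cm <- suppressMessages(load_counts(paths[["counts"]]))
  expect_equal(cm$counts, sim$counts$counts)
  expect_equal(cm$aligned_totals, sim$counts$aligned_totals)
  prom <- Biostrings::readDNAStringSet(paths[["promoters"]])
  expect_equal(as.character(prom), sim$promoters)
})
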
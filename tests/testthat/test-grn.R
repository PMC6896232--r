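make_model <- function(A, p = NULL) {
  structure(list(A = A, intercepts = setNames(rep(0, ncol(A)), colnames(A)),
                 residual_variance = setNames(rep(1, ncol(A)), colnames(A)),
                 motif_ids = rownames(A), samples = colnames(A),
                 p_values = p),
            class = "activity_model")
}

test_that("edges require a binding site and a strong correlation", {
  samples <- sprintf("alpha_%d_1", 0:7)
  a <- seq(-1, 1, length.out = 8)
  A <- rbind(R1 = a, R2 = rev(a) * 0.5 + rnorm(8, 0, 0.01))
  colnames(A) <- samples
  set.seed(50)
  Y <- rbind(R1 = rnorm(8, 5, 1), R2 = rnorm(8, 5, 1),
             T1 = 5 + 2 * a, T2 = 5 - 2 * a)
  colnames(Y) <- samples
  N <- matrix(0L, 4, 2, dimnames = list(rownames(Y), rownames(A)))
  N["T1", "R1"] <- 2L
  N["T2", "R2"] <- 0L # perfect anticorrelation but no site
  model <- make_model(A[, samples])
  # target nodes must be motifs; use a 4-node model
  A4 <- rbind(A, T1 = rnorm(8, 0, 0.1), T2 = rnorm(8, 0, 0.1))
  colnames(A4) <- samples
  N4 <- matrix(0L, 4, 4, dimnames = list(rownames(Y), rownames(A4)))
  N4["T1", "R1"] <- 2L
  net <- infer_edges(make_model(A4), Y, N4, threshold = 0.8)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$regulator, "R1")
  expect_equal(net$edges$target, "T1")
  expect_equal(net$edges$sign, "inductive")
  expect_equal(net$edges$sites, 2L)

  # no site -> no edge even at |r| ~ 1
  N4b <- N4
  N4b["T2", "R1"] <- 0L
  expect_equal(nrow(infer_edges(make_model(A4), Y, N4b, 0.8)$edges), 1L)

  # boundary: r exactly at the threshold is excluded (strict >)
  Yb <- Y
  Yb["T1", ] <- A4["R1", ] # r = 1 against R1
  netb <- infer_edges(make_model(A4), Yb, N4, threshold = 1)
  expect_equal(nrow(netb$edges), 0L)

  # raising the threshold never adds edges
  n_low <- nrow(infer_edges(make_model(A4), Y, N4, 0.5)$edges)
  n_high <- nrow(infer_edges(make_model(A4), Y, N4, 0.9)$edges)
  expect_lte(n_high, n_low)

  # dimers without a single mappable gene are excluded from the target role
  dimer <- list(one_hot_motif("ACGT", id = "R1", name = "Fos::Jun"))
  expect_message(net_d <- infer_edges(make_model(A4), Y, N4, 0.8,
                                      motifs = setNames(dimer, "R1")),
                 "target role")
  expect_true(is.na(net_d$nodes$gene[net_d$nodes$motif == "R1"]))
})

test_that("network objects enforce their invariants", {
  nodes <- tibble::tibble(motif = c("a", "b"), gene = c("a", "b"),
                          p_value = c(NA_real_, NA_real_))
  good <- tibble::tibble(regulator = "a", target = "b", sign = "inductive",
                         weight = 0.9, sites = 1L)
  expect_s3_class(grn_network(nodes, good), "grn_network")
  # sign must match the weight
  bad_sign <- good
  bad_sign$weight <- -0.9
  expect_error(grn_network(nodes, bad_sign), "sign")
  # duplicate edges are refused
  expect_error(grn_network(nodes, rbind(good, good)), "duplicate")
  # dangling endpoints are refused
  dangling <- good
  dangling$target <- "zzz"
  expect_error(grn_network(nodes, dangling), "endpoint")
})

test_that("FFL census matches cubic enumeration", {
  # canonical 3-node FFL
  nodes <- tibble::tibble(motif = c("a", "b", "c"), gene = c("a", "b", "c"),
                          p_value = NA_real_)
  edges <- tibble::tibble(
    regulator = c("a", "b", "a"), target = c("b", "c", "c"),
    sign = c("inductive", "inductive", "inhibitory"),
    weight = c(0.9, 0.85, -0.9), sites = 1L
  )
  net <- grn_network(nodes, edges)
  ffl <- count_ffl(net)
  expect_equal(nrow(ffl), 1L)
  expect_equal(ffl$a, "a")
  expect_equal(ffl$b, "b")
  expect_equal(ffl$c, "c")
  # (+ . +) indirect vs (-) direct: incoherent
  expect_false(ffl$coherent)

  # two-node graph has no FFLs
  net2 <- grn_network(nodes[1:2, ], edges[1, ])
  expect_equal(nrow(count_ffl(net2)), 0L)

  # oracle equivalence on 20 random graphs
  for (s in 1:20) {
    rn <- random_network(sample(4:8, 1), p = 0.35, seed = 100 + s)
    expect_equal(nrow(count_ffl(rn)), cubic_ffl_count(rn),
                 info = sprintf("graph %d", s))
  }
})

test_that("DOR detection matches exhaustive subset search", {
  # two regulators sharing three targets form exactly one DOR
  ids <- c("r1", "r2", "t1", "t2", "t3")
  nodes <- tibble::tibble(motif = ids, gene = ids, p_value = NA_real_)
  edges <- tibble::tibble(
    regulator = rep(c("r1", "r2"), each = 3),
    target = rep(c("t1", "t2", "t3"), 2),
    sign = "inductive", weight = 0.9, sites = 1L
  )
  net <- grn_network(nodes, edges)
  dors <- find_dors(net)
  expect_equal(nrow(dors), 1L)
  expect_setequal(unlist(dors$regulators[[1]]), c("r1", "r2"))
  expect_setequal(unlist(dors$shared_targets[[1]]), c("t1", "t2", "t3"))

  # a single-regulator star is no DOR
  star <- grn_network(nodes, edges[1:3, ])
  expect_equal(nrow(find_dors(star)), 0L)

  # exhaustive-search equivalence on random 10-node graphs
  for (s in 1:6) {
    rn <- random_network(10, p = 0.4, seed = 200 + s)
    got <- find_dors(rn, min_regulators = 2, min_shared_targets = 3)
    want <- exhaustive_dors(rn, 2, 3)
    expect_equal(dor_keys(got$regulators, got$shared_targets),
                 dor_keys(lapply(want, `[[`, "set"),
                          lapply(want, `[[`, "shared")),
                 info = sprintf("graph %d", s))
  }
})

test_that("network comparison reports shared and unique structure", {
  net_a <- random_network(8, p = 0.35, seed = 301)
  expect_equal(compare_networks(net_a, net_a)$shared_nodes,
               sort(net_a$nodes$motif))
  expect_length(compare_networks(net_a, net_a)$unique_a, 0)

  net_b <- random_network(8, p = 0.35, seed = 302)
  nb <- net_b
  nb$nodes$motif <- sub("^N", "Q", nb$nodes$motif)
  nb$nodes$gene <- nb$nodes$motif
  nb$edges$regulator <- sub("^N", "Q", nb$edges$regulator)
  nb$edges$target <- sub("^N", "Q", nb$edges$target)
  cmp <- compare_networks(net_a, nb)
  expect_length(cmp$shared_nodes, 0)
  expect_equal(nrow(cmp$shared_edges), 0L)

  # roles: out-degree > 0 -> input; in-degree > 0 -> target
  roles <- compare_networks(net_a, net_a)$roles
  m <- roles$motif[1]
  out_deg <- sum(net_a$edges$regulator == m)
  in_deg <- sum(net_a$edges$target == m)
  expected <- if (out_deg > 0 && in_deg > 0) "input+target"
  else if (out_deg > 0) "input" else if (in_deg > 0) "target" else "isolated"
  expect_equal(roles$role_a[1], expected)
})

test_that("network export formats are valid and deterministic", {
  net <- random_network(6, p = 0.4, seed = 400)
  dir <- withr::local_tempdir()

  sif <- file.path(dir, "net.sif")
  export_network(net, sif, "sif")
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_match(lines[1], "^\\S+\t(inductive|inhibitory)\t\\S+$")

  # empty network -> valid (empty) SIF and parsable GraphML
  empty <- grn_network(net$nodes[0, ], net$edges[0, ])
  export_network(empty, file.path(dir, "empty.sif"), "sif")
  expect_length(readLines(file.path(dir, "empty.sif")), 0)

  gml <- file.path(dir, "net.graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  # attributes survive the round trip
  el <- igraph::as_data_frame(g, "edges")
  key_got <- paste(el$from, el$to)
  key_want <- paste(net$edges$regulator, net$edges$target)
  expect_setequal(key_got, key_want)
  expect_equal(el$weight[match(key_want, key_got)], net$edges$weight,
               tolerance = 1e-9)
  expect_equal(el$sign[match(key_want, key_got)], net$edges$sign)

  # byte-identical re-export
  gml2 <- file.path(dir, "net2.graphml")
  export_network(net, gml2, "graphml")
  expect_identical(readLines(gml), readLines(gml2))
  expect_error(export_network(net, file.path(dir, "x"), "dot"),
               "supported")
})

test_that("the documented synthetic scenario is fully recovered", {
  sc <- simulate_grn_scenario(seed = 42)
  res <- suppressMessages(suppressWarnings(score_edge_recovery(sc)))
  expect_gte(res$recovery$precision, 0.9)
  expect_gte(res$recovery$recall, 0.9)
  expect_equal(res$recovery$sign_accuracy, 1)
  # every FFL's edges exist in the network
  ffl <- count_ffl(res$network)
  if (nrow(ffl) > 0) {
    key <- paste(res$network$edges$regulator, res$network$edges$target)
    expect_true(all(paste(ffl$a, ffl$b) %in% key &
                      paste(ffl$b, ffl$c) %in% key &
                      paste(ffl$a, ffl$c) %in% key))
  }
  # sign consistency across all inferred edges
  e <- res$network$edges
  expect_true(all(e$sign == ifelse(e$weight > 0, "inductive", "inhibitory")))
  # edge monotonicity in the correlation threshold on the same fit
  net9 <- infer_edges(res$model, normalize_counts(sc$counts), res$N,
                      threshold = 0.9, motifs = sc$motifs)
  key8 <- paste(e$regulator, e$target)
  key9 <- paste(net9$edges$regulator, net9$edges$target)
  expect_true(all(key9 %in% key8))
})
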
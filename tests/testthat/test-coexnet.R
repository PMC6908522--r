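test_that("similarity matches the textbook Pearson formula", {
  set.seed(1)
  v <- matrix(rnorm(15), 3, 5)
  rownames(v) <- c("a", "b", "c")
  st <- make_study(v, c("control", "control", "case", "case", "case"))
  sim <- similarity_matrix(st)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(sim[i, j], abs(pearson(v[i, ], v[j, ])), tolerance = 1e-12)
  expect_equal(unname(diag(sim)), rep(1, 3))
  ## |r| of x and -x is 1
  st2 <- make_study(rbind(a = 1:5, b = -(1:5)),
                    c("control", "control", "case", "case", "case"))
  expect_equal(unname(similarity_matrix(st2)["a", "b"]), 1)
  ## requested genes missing from the study are reported
  expect_warning(sim3 <- similarity_matrix(st, gene_subset = c("a", "b", "zz")),
                 "absent")
  expect_identical(attr(sim3, "missing_genes"), "zz")
  expect_identical(rownames(sim3), c("a", "b"))
})

test_that("zero-variance genes are dropped with a warning", {
  v <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  st <- make_study(v, c("control", "control", "case", "case"))
  expect_warning(sim <- similarity_matrix(st), "zero-variance")
  expect_identical(rownames(sim), c("a", "c"))
})

test_that("clustering coefficient matches hand-enumerated graphs", {
  tri <- gene_network(c("A", "B", "C"),
                      rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  expect_equal(clustering_coefficient(tri), 1)
  cyc4 <- gene_network(LETTERS[1:4],
                       rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A")))
  expect_equal(clustering_coefficient(cyc4), 0)
  ## triangle plus pendant D-A: locals 2/3? no - (1/3, 1, 1) at A, B, C
  pend <- gene_network(LETTERS[1:4],
                       rbind(c("A", "B"), c("B", "C"), c("A", "C"), c("D", "A")))
  expect_equal(clustering_coefficient(pend), 7 / 9, tolerance = 1e-12)
})

test_that("expected random clustering coefficient is the edge density", {
  expect_equal(expected_random_cc(10, 9), 0.2)
  expect_equal(expected_random_cc(5, 0), 0)
  expect_equal(expected_random_cc(6, 15), 1)
  expect_error(expected_random_cc(4, 7), class = "coexmeta_network_error")
  expect_error(expected_random_cc(1, 0), class = "coexmeta_network_error")
})

test_that("thresholding is a monotone filtration with closed edge rule", {
  set.seed(4)
  v <- matrix(rnorm(20 * 12), 20, 12)
  st <- make_study(v, rep(c("control", "case"), each = 6))
  sim <- similarity_matrix(st)
  taus <- seq(0, 1, by = 0.1)
  nets <- lapply(taus, function(t) build_network(sim, t))
  keys <- lapply(nets, function(n)
    if (nrow(n$edges)) edge_keys(n$edges[, 1], n$edges[, 2]) else character(0))
  for (i in seq_along(taus)[-1])
    expect_true(all(keys[[i]] %in% keys[[i - 1]]))
  ## tau = 0 gives the complete graph on non-constant genes
  expect_identical(nrow(nets[[1]]$edges), 190L)
  ## every kept edge satisfies |r| >= tau
  n7 <- nets[[7]]
  if (nrow(n7$edges)) expect_true(all(n7$weights >= taus[7]))
})

test_that("threshold scan records sizes and selection follows the D curve", {
  ## block-diagonal similarity: 1 within blocks, 0 between
  labs <- sprintf("g%02d", 1:9)
  sim <- matrix(0, 9, 9, dimnames = list(labs, labs))
  for (b in 0:2) sim[b * 3 + 1:3, b * 3 + 1:3] <- 1
  class(sim) <- c("SimilarityMatrix", "matrix", "array")
  scan <- threshold_scan(sim, grid = seq(0.5, 0.9, by = 0.1))
  expect_true(all(scan$n_edges == 9))
  expect_true(all(abs(scan$D - scan$D[1]) < 1e-12))   # constant D
  ## tie-break: smallest grid value
  expect_equal(select_threshold(scan, min_edges = 5), 0.5)
  ## all-zero off-diagonal: every network empty, selection errors
  sim0 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(sim0) <- 1
  class(sim0) <- c("SimilarityMatrix", "matrix", "array")
  scan0 <- threshold_scan(sim0, grid = seq(0.5, 0.9, by = 0.1))
  expect_true(all(scan0$n_edges == 0))
  expect_true(all(scan0$C == 0 & scan0$C_o == 0))
  expect_error(select_threshold(scan0), class = "coexmeta_network_error")
})

test_that("planted blocks are recovered at the selected threshold", {
  cfg <- sim_config(n_genes = 100, n_blocks = 5, block_size = 20,
                    within_block_r = 0.8, between_block_r = 0.1,
                    shared_block_fraction = 1.0,
                    samples_per_group = c(30, 30), seed = 7)
  pair <- gen_coexpression_pair(cfg)
  sim <- similarity_matrix(pair$study_a)
  scan <- threshold_scan(sim)
  ## D peaks strictly between the between- and within-block correlations
  tau_peak <- scan$tau[which.max(scan$D)]
  expect_gt(tau_peak, 0.1)
  expect_lt(tau_peak, 0.8)
  tau <- select_threshold(scan)
  net <- build_network(sim, tau)
  got <- edge_keys(net$edges[, 1], net$edges[, 2])
  want <- pair$truth$shared_edges
  jac <- length(intersect(got, want)) / length(union(got, want))
  expect_gte(jac, 0.8)
})

test_that("CCP intersection equals brute-force edge-set intersection", {
  ea <- rbind(c("a", "b"), c("b", "c"), c("c", "d"))
  eb <- rbind(c("b", "c"), c("c", "d"), c("d", "e"))
  na <- gene_network(letters[1:4], ea)
  nb <- gene_network(letters[2:5], eb)
  ccp <- ccp_intersection(na, nb)
  expect_setequal(ccp$nodes, c("b", "c", "d"))
  expect_setequal(edge_keys(ccp$edges[, 1], ccp$edges[, 2]), c("b|c", "c|d"))
  ## idempotence and empty intersection
  self <- ccp_intersection(na, na)
  expect_setequal(edge_keys(self$edges[, 1], self$edges[, 2]),
                  edge_keys(ea[, 1], ea[, 2]))
  dis <- ccp_intersection(na, gene_network(c("x", "y"), rbind(c("x", "y"))))
  expect_identical(nrow(dis$edges), 0L)
  expect_length(dis$nodes, 0)
})

test_that("CCP is commutative and bounded on random graph pairs", {
  set.seed(9)
  for (r in 1:25) {
    a <- random_network(sample(5:30, 1), runif(1, 0.05, 0.4))
    b <- random_network(sample(5:30, 1), runif(1, 0.05, 0.4))
    ab <- ccp_intersection(a, b)
    ba <- ccp_intersection(b, a)
    kab <- edge_keys(ab$edges[, 1], ab$edges[, 2])
    expect_setequal(kab, edge_keys(ba$edges[, 1], ba$edges[, 2]))
    expect_lte(nrow(ab$edges), min(nrow(a$edges), nrow(b$edges)))
    ## oracle: raw string-set intersection
    ref <- intersect(edge_keys(a$edges[, 1], a$edges[, 2]),
                     edge_keys(b$edges[, 1], b$edges[, 2]))
    expect_setequal(kab, ref)
  }
})

test_that("hub ranking orders by degree with lexicographic ties", {
  star <- gene_network(c("hub", letters[1:4]),
                       cbind("hub", letters[1:4]))
  expect_identical(hub_rank(star, 1)$gene, "hub")
  tri <- gene_network(c("b", "a", "c"),
                      rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_identical(hub_rank(tri, 3)$gene, c("a", "b", "c"))
  expect_error(hub_rank(tri, 0), class = "coexmeta_config_error")
  ## planted hub in a generated similarity structure
  set.seed(21)
  n <- 30
  hubsig <- rnorm(40)
  v <- rbind(HUB = hubsig,
             t(sapply(1:10, function(i) hubsig * 2 + rnorm(40, sd = 0.3))),
             matrix(rnorm(19 * 40), 19, 40))
  rownames(v) <- c("HUB", sprintf("nb%02d", 1:10), sprintf("bg%02d", 1:19))
  st <- make_study(v, rep(c("control", "case"), each = 20))
  net <- build_network(similarity_matrix(st), 0.8)
  expect_identical(hub_rank(net, 1)$gene, "HUB")
})
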
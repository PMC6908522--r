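test_that("pooled standard error matches hand evaluations", {
  ## zero within-group variance
  v <- rbind(c(1, 1, 1, 3, 3, 3))
  expect_equal(unname(pooled_se(v, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))), 0)
  ## case = [2, 4], ctrl = [1, 3]: s = sqrt(2), t = 1/sqrt(2)
  v2 <- rbind(c(1, 3, 2, 4))
  s <- pooled_se(v2, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(unname(s), sqrt(2), tolerance = 1e-12)
  st <- make_study(rbind(f1 = c(1, 3, 2, 4)),
                   c("control", "control", "case", "case"))
  stat <- sam_statistics(st, s0 = 0)
  expect_equal(unname(stat$d), 0.70711, tolerance = 1e-5)
  ## symmetry: equal within-group variance => identical s across features
  v3 <- rbind(c(0, 2, 5, 7), c(10, 12, 1, 3), c(-1, 1, 0, 2))
  expect_equal(sd(pooled_se(v3, c(FALSE, FALSE, TRUE, TRUE))), 0)
  expect_error(pooled_se(rbind(c(1, 2, 3)), c(TRUE, FALSE, FALSE)),
               class = "coexmeta_stats_error")
})

test_that("with s0 = 0 the d-statistic is the pooled two-sample t", {
  set.seed(11)
  v <- matrix(rnorm(200 * 12), 200, 12)
  grp <- rep(c("control", "case"), each = 6)
  st <- make_study(v, grp)
  d <- sam_statistics(st, s0 = 0)$d
  case <- grp == "case"
  t_ref <- apply(v, 1, function(x) oracle_t_stat(x[case], x[!case]))
  expect_equal(unname(d), unname(t_ref), tolerance = 1e-12)
})

test_that("d-statistic honors s0, direction and antisymmetry", {
  st <- make_study(rbind(f1 = c(1, 1, 1, 3, 3, 3)),
                   rep(c("control", "case"), each = 3))
  stat <- sam_statistics(st, s0 = 0.5)
  expect_equal(unname(stat$d), 4)          # (3 - 1) / (0 + 0.5)
  expect_identical(unname(stat$direction), 1)
  flip <- make_study(rbind(f1 = c(1, 1, 1, 3, 3, 3)),
                     rep(c("case", "control"), each = 3))
  expect_equal(unname(sam_statistics(flip, s0 = 0.5)$d), -4)
  same <- make_study(rbind(f1 = c(1, 2, 1, 2)),
                     c("control", "control", "case", "case"))
  s2 <- sam_statistics(same, s0 = 0.5)
  expect_equal(unname(s2$d), 0)
  expect_identical(unname(s2$direction), 0)
})

test_that("s0 estimate matches an exhaustive grid oracle", {
  set.seed(3)
  m <- 2000
  ## Tusher-style: gene-specific variances spanning orders of magnitude
  sds <- exp(rnorm(m, 0, 1))
  v <- matrix(rnorm(m * 8, 0, sds), m, 8)
  grp <- rep(c("control", "case"), each = 4)
  case <- grp == "case"
  delta <- rowMeans(v[, case]) - rowMeans(v[, !case])
  s <- pooled_se(v, case)
  got <- estimate_s0(delta, s)
  ## independent naive grid search over the same objective
  alphas <- seq(0, 1, by = 0.05)
  cvs <- sapply(alphas, function(a) {
    s0 <- quantile(s, a, names = FALSE)
    d <- delta / (s + s0)
    bins <- cut(rank(s, ties.method = "first"), 100)
    mads <- tapply(d, bins, mad)
    sd(mads) / mean(mads)
  })
  expect_equal(as.numeric(got), quantile(s, alphas[which.min(cvs)],
                                         names = FALSE))
  ## degenerate: all s equal
  expect_warning(s0c <- estimate_s0(rnorm(200), rep(2, 200)), "identical")
  expect_equal(as.numeric(s0c), 0)
})

test_that("permutation p-values match a brute-force enumeration", {
  set.seed(5)
  v <- matrix(rnorm(4 * 6), 4, 6)
  grp <- rep(c("control", "case"), each = 3)
  st <- make_study(v, grp)
  s0 <- 0.1
  res <- suppressWarnings(permutation_pvalues(st, s0 = s0, B = 50, seed = 5))
  ## choose(6,3) - 1 = 19 distinct non-identity relabelings
  expect_identical(res$B, 19L)
  ## brute force over ALL non-identity case-assignments of size 3
  case0 <- grp == "case"
  sets <- combn(6, 3)
  dmat <- c()
  for (j in seq_len(ncol(sets))) {
    g <- seq_len(6) %in% sets[, j]
    if (identical(g, case0)) next
    dj <- apply(v, 1, function(x) {
      sp <- sqrt(((sum((x[g] - mean(x[g]))^2) + sum((x[!g] - mean(x[!g]))^2)) / 4) *
                   (2 / 3))
      (mean(x[g]) - mean(x[!g])) / (sp + s0)
    })
    dmat <- cbind(dmat, abs(dj))
  }
  d_obs <- abs(sam_statistics(st, s0 = s0)$d)
  m <- 4; B <- ncol(dmat)
  p_ref <- vapply(d_obs, function(di) (1 + sum(dmat >= di - 1e-9)) / (1 + m * B),
                  numeric(1))
  expect_equal(unname(res$p), unname(p_ref), tolerance = 1e-12)
})

test_that("constant features get p = 1 and p is order-invariant", {
  v <- matrix(5, 3, 8)
  rownames(v) <- c("a", "b", "c")
  st <- make_study(v, rep(c("control", "case"), each = 4))
  res <- suppressWarnings(permutation_pvalues(st, s0 = 0.5, B = 50, seed = 1))
  expect_true(all(res$p == 1))
  ## feature order invariance
  set.seed(6)
  v2 <- matrix(rnorm(80), 10, 8)
  rownames(v2) <- sprintf("f%02d", 1:10)
  st2 <- make_study(v2, rep(c("control", "case"), each = 4))
  p1 <- suppressWarnings(permutation_pvalues(st2, 0.1, B = 60, seed = 2))$p
  st3 <- make_study(v2[10:1, ], rep(c("control", "case"), each = 4))
  p2 <- suppressWarnings(permutation_pvalues(st3, 0.1, B = 60, seed = 2))$p
  expect_equal(p1[names(p2)], p2)
})

test_that("permutation null p-values are approximately uniform", {
  cfg <- sim_config(n_genes = 1000, samples_per_group = c(10, 10),
                    effect_size = 0, seed = 9)
  g <- gen_expression_study(cfg, "LC", 9, "NUL")
  st <- suppressMessages(normalize_study(g$study))
  res <- permutation_pvalues(st, s0 = sam_statistics(st)$s0, B = 200, seed = 9)
  ks <- suppressWarnings(ks.test(res$p, "punif"))$statistic
  expect_lte(unname(ks), 0.05)
  expect_true(mean(res$p <= 0.05) >= 0.03 && mean(res$p <= 0.05) <= 0.07)
})

test_that("Storey q-values follow the closed form and reduce to BH", {
  q1 <- storey_q(0.8)
  expect_equal(q1$pi0, 1)
  expect_equal(q1$q, 0.8)
  q2 <- storey_q(c(0.01, 0.02, 0.03), pi0 = 1)
  expect_equal(q2$q, c(0.03, 0.03, 0.03))
  q3 <- storey_q(rep(1, 5))
  expect_equal(q3$pi0, 1)
  expect_true(all(q3$q == 1))
  expect_error(storey_q(c(0.5, 1.2)), class = "coexmeta_stats_error")
  ## monotone in p after step-up
  set.seed(7)
  p <- runif(100)
  q <- storey_q(p)$q
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("DEG calls respect the q threshold and report study FDR", {
  cfg <- sim_config(n_genes = 600, samples_per_group = c(10, 10),
                    n_winner_up = 30, n_winner_down = 30,
                    effect_size = 2, baseline_meanlog = log(500),
                    baseline_sdlog = 0.6, seed = 13)
  g <- gen_expression_study(cfg, "LC", 13, "S")
  st <- suppressMessages(normalize_study(g$study))
  sam <- suppressWarnings(sam_analysis(st, B = 100, seed = 13))
  tab <- sam$table
  expect_true(all(tab$q[tab$called] < 0.01))
  expect_identical(tab$direction, as.integer(sign(tab$delta_mean)))
  expect_true(sam$fdr_at_call >= 0)
  degs <- call_degs(sam)
  expect_true(all(degs$up %in% tab$feature[tab$direction > 0]))
  ## empty call set: fdr 0, no flag
  cfg0 <- sim_config(n_genes = 300, samples_per_group = c(5, 5),
                     effect_size = 0, seed = 14)
  g0 <- gen_expression_study(cfg0, "LC", 14, "S0")
  sam0 <- suppressWarnings(sam_analysis(suppressMessages(normalize_study(g0$study)),
                                        B = 60, seed = 14))
  if (!any(sam0$table$called)) {
    expect_equal(sam0$fdr_at_call, 0)
    expect_true(sam0$fdr_conforms)
  }
})
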
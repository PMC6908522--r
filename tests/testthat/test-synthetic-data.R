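test_that("config validation names the offending field", {
  expect_error(sim_config(n_genes = -5), "n_genes",
               class = "coexmeta_config_error")
  expect_error(sim_config(winner_penetrance = 1.5), "winner_penetrance",
               class = "coexmeta_config_error")
  expect_error(sim_config(within_block_r = 0.3, between_block_r = 0.5),
               "between_block_r", class = "coexmeta_config_error")
  expect_error(sim_config(n_genes = 50, n_blocks = 10, block_size = 10),
               "n_blocks", class = "coexmeta_config_error")
})

test_that("generation is deterministic and seed-split is stable", {
  cfg <- sim_config(n_genes = 100, samples_per_group = c(5, 8), n_blocks = 2,
                    block_size = 5, n_winner_up = 10, n_winner_down = 10, seed = 3)
  a <- gen_expression_study(cfg, "LC", 11, "S1")
  b <- gen_expression_study(cfg, "LC", 11, "S1")
  expect_identical(a$study$values, b$study$values)
  ## adding studies never changes earlier ones: study i depends only on
  ## child_seed(root, i)
  expect_identical(child_seed(3, 1), child_seed(3, 1))
  expect_false(child_seed(3, 1) == child_seed(3, 2))
  small <- function(n_lc) sim_config(n_genes = 50, n_lc_studies = n_lc,
                                     n_ld_studies = 1, n_blocks = 2,
                                     block_size = 5, n_winner_up = 5,
                                     n_winner_down = 5,
                                     samples_per_group = c(5, 5), seed = 3)
  col <- gen_study_collection(small(2))
  col2 <- gen_study_collection(small(3))
  expect_identical(col[[1]]$study$values, col2[[1]]$study$values)
})

test_that("planted up-genes are shifted up in the case group", {
  cfg <- sim_config(n_genes = 1000, samples_per_group = c(10, 10),
                    effect_size = 1.5, winner_penetrance = 1.0, seed = 1)
  g <- gen_expression_study(cfg, "LC", 1, "S1")
  lg <- log2(pmax(g$study$values, 1))
  case <- unname(g$study$group) == "case"
  delta <- rowMeans(lg[, case]) - rowMeans(lg[, !case])
  up <- g$truth$planted_up
  ## sign test: essentially all planted-up genes shifted positive
  n_pos <- sum(delta[up] > 0)
  expect_true(binom.test(n_pos, length(up), 0.5,
                         alternative = "greater")$p.value < 1e-6)
  expect_gt(mean(delta[up]), 1)
})

test_that("null simulation carries no group signal", {
  cfg <- sim_config(n_genes = 500, samples_per_group = c(10, 10),
                    effect_size = 0, n_winner_up = 20, n_winner_down = 20,
                    seed = 4)
  g <- gen_expression_study(cfg, "LC", 4, "S0")
  lg <- log2(pmax(g$study$values, 1))
  case <- unname(g$study$group) == "case"
  t_stats <- apply(lg, 1, function(x) oracle_t_stat(x[case], x[!case]))
  expect_lt(mean(abs(t_stats) > 2.1), 0.1)  # ~5% nominal at df=18
})

test_that("collection plants winners with globally fixed directions", {
  cfg <- sim_config(n_genes = 200, n_lc_studies = 6, n_ld_studies = 4,
                    samples_per_group = c(5, 5), winner_penetrance = 1.0,
                    n_winner_up = 30, n_winner_down = 20, n_blocks = 2,
                    block_size = 10, seed = 5)
  col <- gen_study_collection(cfg)
  expect_length(col, 10)
  classes <- vapply(col, function(x) x$study$disease_class, character(1))
  expect_identical(sum(classes == "LC"), 6L)
  ups <- lapply(col, function(x) x$truth$planted_up)
  expect_true(all(vapply(ups, identical, logical(1), ups[[1]])))
})

test_that("penetrance thins planted genes per study binomially", {
  cfg <- sim_config(n_genes = 500, n_winner_up = 200, n_winner_down = 0,
                    samples_per_group = c(5, 5), winner_penetrance = 0.5,
                    seed = 6)
  col <- gen_study_collection(cfg)
  fracs <- vapply(col, function(x) length(x$truth$planted_up) / 200, numeric(1))
  ## each study fires each winner w.p. 0.5: 3 MC sd of binomial(200, .5)
  expect_true(all(abs(fracs - 0.5) < 3 * sqrt(0.25 / 200)))
})

test_that("coexpression pair hits the target within-block correlation", {
  cfg <- sim_config(n_genes = 120, n_blocks = 5, block_size = 20,
                    within_block_r = 0.8, between_block_r = 0.1,
                    shared_block_fraction = 1.0, n_winner_up = 10,
                    n_winner_down = 10,
                    samples_per_group = c(30, 30), seed = 7)
  pair <- gen_coexpression_pair(cfg)
  sim <- similarity_matrix(pair$study_a)
  memb <- pair$truth$block_membership_a
  b1 <- names(memb)[!is.na(memb) & memb == "B01"]
  rbar <- mean(sim[b1, b1][upper.tri(diag(length(b1)))])
  expect_lt(abs(rbar - 0.8), 0.1)
  ## no shared structure when shared fraction is 0 and between r is 0
  cfg0 <- sim_config(n_genes = 60, n_blocks = 3, block_size = 10,
                     within_block_r = 0.7, between_block_r = 0,
                     shared_block_fraction = 0, n_winner_up = 5,
                     n_winner_down = 5,
                     samples_per_group = c(20, 20), seed = 8)
  expect_length(gen_coexpression_pair(cfg0)$truth$shared_edges, 0)
})

test_that("within-block correlation is monotone in the target r", {
  rs <- c(0.3, 0.6, 0.9)
  got <- vapply(rs, function(r) {
    cfg <- sim_config(n_genes = 40, n_blocks = 2, block_size = 20,
                      within_block_r = r, between_block_r = 0,
                      shared_block_fraction = 1, n_winner_up = 5,
                      n_winner_down = 5,
                      samples_per_group = c(40, 40), seed = 9)
    pair <- gen_coexpression_pair(cfg)
    sim <- similarity_matrix(pair$study_a)
    memb <- pair$truth$block_membership_a
    b1 <- names(memb)[!is.na(memb) & memb == "B01"]
    mean(sim[b1, b1][upper.tri(diag(length(b1)))])
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("survival cohort honors censoring and hazard settings", {
  co <- gen_survival_cohort(500, true_hr = 2, censor_rate = 0, seed = 2)
  expect_true(all(co$event == 1))
  co2 <- gen_survival_cohort(5000, true_hr = 2, censor_rate = 0.3, seed = 2)
  expect_lt(abs(mean(co2$event == 0) - 0.3), 0.03)
  expect_error(gen_survival_cohort(1, 2, 0.2, 1), class = "coexmeta_config_error")
  expect_error(gen_survival_cohort(10, -1, 0.2, 1), class = "coexmeta_config_error")
  expect_error(gen_survival_cohort(10, 2, 1, 1), class = "coexmeta_config_error")
})
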
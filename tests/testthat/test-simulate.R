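test_that("identical config and seed give bit-identical cohorts", {
  cfg <- sim_config(n_samples_per_group = 10, n_features = 40,
                    n_pos_effect = 5, n_neg_effect = 3, seed = 7)
  a <- simulate_reference_cohort(cfg)
  b <- simulate_reference_cohort(cfg)
  expect_identical(ft_matrix(a$table), ft_matrix(b$table))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)

  ta <- simulate_target_cohort(cfg, a$truth)
  tb <- simulate_target_cohort(cfg, b$truth)
  expect_identical(ft_matrix(ta$table), ft_matrix(tb$table))

  expect_identical(simulate_contaminant_scores(a$truth, seed = 3),
                   simulate_contaminant_scores(a$truth, seed = 3))
  ca <- simulate_coupled_omics(12, 6, 5, 0.5, seed = 7)
  cb <- simulate_coupled_omics(12, 6, 5, 0.5, seed = 7)
  expect_identical(ca$x, cb$x)
})

test_that("generated counts are non-negative integers over the shared universe", {
  cfg <- sim_config(n_samples_per_group = 8, n_features = 30,
                    n_pos_effect = 4, n_neg_effect = 2, seed = 2)
  ref <- simulate_reference_cohort(cfg)
  m <- ft_matrix(ref$table)
  expect_true(all(m >= 0) && all(m == round(m)))
  expect_true(all(nchar(ft_feature_ids(ref$table)) == 150))
  expect_true(all(grepl("^[ACGT]+$", ft_feature_ids(ref$table))))
  tgt <- simulate_target_cohort(cfg, ref$truth,
                                c(rural = 1, urban = 0.5, CD = 0))
  expect_identical(ft_feature_ids(tgt$table), ft_feature_ids(ref$table))
  expect_setequal(unique(tgt$metadata$group), c("rural", "urban", "CD"))
  # planted sets are disjoint subsets of the universe
  expect_length(intersect(ref$truth$planted_positive,
                          ref$truth$planted_negative), 0)
  expect_true(all(c(ref$truth$planted_positive, ref$truth$planted_negative,
                    ref$truth$planted_contaminants) %in% ft_feature_ids(ref$table)))
})

test_that("planted positive features have higher group-A relative abundance", {
  sim <- simulate_reference_cohort(sim_config(seed = 21))  # 30/20, lfc 2, 50/group
  m <- ft_matrix(sim$table)
  rel <- m / rowSums(m)
  in_a <- sim$metadata$group == "rural"
  mean_diff <- function(ids) {
    colMeans(rel[in_a, ids, drop = FALSE]) - colMeans(rel[!in_a, ids, drop = FALSE])
  }
  # 50 planted features in all; at least 45 shifted in the planted direction
  n_directional <- sum(mean_diff(sim$truth$planted_positive) > 0) +
    sum(mean_diff(sim$truth$planted_negative) < 0)
  expect_gte(n_directional, 45)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_pos_effect = 60, n_neg_effect = 50,
                          n_features = 100), "n_pos_effect")
  expect_error(sim_config(effect_log2fc = -1), "effect_log2fc")
  expect_error(sim_config(depth_mean = 0), "depth_mean")
  expect_error(sim_config(contaminant_fraction = 1), "contaminant_fraction")
  expect_error(simulate_coupled_omics(10, 0, 5, 0.5, seed = 1), "p_features_x")
  expect_error(simulate_coupled_omics(10, 5, 5, 1.2, seed = 1),
               "shared_variance_fraction")
})

test_that("contaminant scores separate planted contaminants by construction", {
  cfg <- sim_config(n_samples_per_group = 5, n_features = 60,
                    n_pos_effect = 0, n_neg_effect = 0,
                    contaminant_fraction = 0.2, seed = 5)
  ref <- simulate_reference_cohort(cfg)
  sc <- simulate_contaminant_scores(ref$truth, seed = 9)
  env <- rowMeans(sc[c("f_water", "f_soil", "f_mouse")])
  is_cont <- sc$feature_id %in% ref$truth$planted_contaminants
  expect_true(all(env[is_cont] > sc$f_human[is_cont]))
  expect_true(all(env[!is_cont] <= sc$f_human[!is_cont]))
  expect_true(all(sc$f_water >= 0 & sc$f_human <= 1))
  filtered <- filter_contaminants(ref$table, sc)
  expect_setequal(filter_report(filtered)$feature_id,
                  ref$truth$planted_contaminants)

  # zero planted contaminants -> filter removes nothing
  cfg0 <- sim_config(n_samples_per_group = 5, n_features = 30,
                     n_pos_effect = 0, n_neg_effect = 0,
                     contaminant_fraction = 0, seed = 6)
  ref0 <- simulate_reference_cohort(cfg0)
  sc0 <- simulate_contaminant_scores(ref0$truth, seed = 1)
  expect_identical(ft_feature_ids(filter_contaminants(ref0$table, sc0)),
                   ft_feature_ids(ref0$table))
})

test_that("coupled blocks are exactly rank-one at full shared variance", {
  sim <- simulate_coupled_omics(15, 8, 6, shared_variance_fraction = 1,
                                seed = 13)
  expect_equal(qr(sim$x)$rank, 1)
  fc <- first_components(sim$x, sim$y)
  expect_equal(abs(stats::cor(fc$scores_x, fc$scores_y,
                              method = "spearman")), 1)
  expect_equal(abs(stats::cor(fc$scores_x, sim$truth$latent_scores)), 1,
               tolerance = 1e-8)
})
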
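two_group_labels <- function(n_a, n_b) rep(c("A", "B"), c(n_a, n_b))

test_that("rank-mean effects match hand-computed rank tables", {
  # values (10, 9, 2, 1): ranks (4, 3, 2, 1) -> effect 3.5 - 1.5 = 2
  tb <- toy_table(matrix(c(10, 9, 2, 1), 1), kind = "abundance")
  eff <- rank_mean_statistic(tb, two_group_labels(2, 2))
  expect_equal(eff$effect, 2)

  # ties: (5, 5, 5, 1) -> ranks (3, 3, 3, 1) -> effect 3 - 2 = 1
  tb2 <- toy_table(matrix(c(5, 5, 5, 1), 1), kind = "abundance")
  expect_equal(rank_mean_statistic(tb2, two_group_labels(2, 2))$effect, 1)

  # constant feature: all ranks tied -> effect 0 and p = 1
  tb3 <- toy_table(matrix(c(7, 7, 7, 7, 7, 7), 1), kind = "abundance")
  pn <- permutation_null(tb3, two_group_labels(3, 3))
  expect_equal(pn$observed$effect, 0)
  expect_equal(pn$observed$p_raw, 1)

  expect_error(rank_mean_statistic(tb, c("A", "A", "A", "B")), ">= 2 samples")
  expect_error(rank_mean_statistic(tb, rep("A", 4)), "two groups")
})

test_that("3-vs-3 exhaustive mode enumerates all 20 label splits", {
  tb <- toy_table(matrix(c(9, 8, 7, 3, 2, 1), 1), kind = "abundance")
  pn <- permutation_null(tb, two_group_labels(3, 3),
                         da_config(n_permutations = 1000))
  expect_true(pn$exhaustive)
  expect_equal(pn$n_permutations, 20)
  # perfectly separating feature: only the true split and its complement
  # reach the maximal |effect| -> two-sided p = 2/20
  expect_equal(pn$observed$p_raw, 0.1)
})

test_that("sampled p-values converge to the exhaustive values", {
  tb <- toy_table(withr::with_seed(8, matrix(rpois(5 * 6, 12), 5)),
                  kind = "counts")
  labels <- two_group_labels(3, 3)
  exact <- permutation_null(tb, labels, da_config(n_permutations = 1000))
  expect_true(exact$exhaustive)
  sampled <- permutation_null(
    tb, labels, da_config(n_permutations = 4000, seed = 99,
                          allow_exhaustive = FALSE))
  expect_false(sampled$exhaustive)
  se <- sqrt(exact$observed$p_raw * (1 - exact$observed$p_raw) / 4000)
  expect_true(all(abs(sampled$observed$p_raw - exact$observed$p_raw) <=
                    3 * se + 2 / 4000))
})

test_that("statistic and p-values are invariant to monotone transforms", {
  tb <- random_count_table(30, 16, seed = 3)
  rel <- normalize_metabolites(tb)
  labels <- two_group_labels(8, 8)
  base <- permutation_null(rel, labels, da_config(n_permutations = 200, seed = 1))
  transformed <- as_feature_table(
    dplyr::mutate(tibble::as_tibble(rel),
                  dplyr::across(-feature_id, ~ (.x + 0.01)^3)),
    kind = "abundance")
  tr <- permutation_null(transformed, labels,
                         da_config(n_permutations = 200, seed = 1))
  expect_equal(tr$observed$effect, base$observed$effect)
  expect_equal(tr$observed$p_raw, base$observed$p_raw)
})

test_that("swapping group labels negates effects, keeps p and selection", {
  tb <- random_count_table(40, 20, seed = 14)
  g1 <- factor(two_group_labels(10, 10), levels = c("A", "B"))
  g2 <- factor(g1, levels = c("B", "A"))  # same assignment, roles swapped
  a <- differential_features(tb, g1, da_config(n_permutations = 300, seed = 5))
  b <- differential_features(tb, g2, da_config(n_permutations = 300, seed = 5))
  expect_equal(b$results$effect, -a$results$effect)
  expect_equal(b$results$p_raw, a$results$p_raw)
  expect_equal(b$results$significant, a$results$significant)
})

test_that("dsFDR selection equals an independent brute-force threshold scan", {
  for (s in 1:5) {
    tb <- toy_table(withr::with_seed(s, {
      m <- matrix(rpois(6 * 6, 10), 6)
      m[1:2, 1:3] <- m[1:2, 1:3] + 25   # two planted features
      m
    }), kind = "counts")
    pn <- permutation_null(tb, two_group_labels(3, 3),
                           da_config(n_permutations = 1000))
    expect_true(pn$exhaustive)
    sel <- dsfdr_select(pn$observed, pn$null_statistics, alpha = 0.25)
    bf <- brute_force_dsfdr(pn$observed$effect, pn$null_statistics, 0.25)
    expect_identical(unname(sel$significant), unname(bf))
  }
})

test_that("vanishing alpha empties the selection", {
  tb <- random_count_table(15, 12, seed = 4)
  pn <- permutation_null(tb, two_group_labels(6, 6),
                         da_config(n_permutations = 200, seed = 2))
  sel <- dsfdr_select(pn$observed, pn$null_statistics, alpha = 1e-6)
  expect_false(any(sel$significant))
  expect_error(dsfdr_select(pn$observed, pn$null_statistics, alpha = 0), "alpha")
})

test_that("sampled permutation runs are seed-deterministic", {
  tb <- random_count_table(20, 14, seed = 6)
  cfg <- da_config(n_permutations = 150, seed = 77)
  a <- permutation_null(tb, two_group_labels(7, 7), cfg)
  b <- permutation_null(tb, two_group_labels(7, 7), cfg)
  expect_identical(a$observed, b$observed)
  expect_identical(a$null_statistics, b$null_statistics)
})

test_that("planted features are recovered with the correct direction", {
  hits <- vapply(1:3, function(s) {
    sim <- simulate_reference_cohort(sim_config(seed = s))
    da <- differential_features(sim$table, sim$metadata,
                                da_config(n_permutations = 500, seed = s + 50))
    r <- da$results
    ok <- sum(r$significant & r$effect > 0 &
                r$feature_id %in% sim$truth$planted_positive) +
      sum(r$significant & r$effect < 0 &
            r$feature_id %in% sim$truth$planted_negative)
    ok / 50
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})
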
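make_da_toy <- function() {
  # planted separation so both directions are significant
  m <- withr::with_seed(31, {
    m <- matrix(rpois(8 * 12, 20), 8)
    m[1:3, 1:6] <- m[1:3, 1:6] + 60   # higher in A
    m[4:5, 7:12] <- m[4:5, 7:12] + 90 # higher in B; planted mass balanced
                                      # across groups so the null features
                                      # stay undiluted
    m
  })
  tb <- toy_table(m, kind = "counts")
  differential_features(tb, rep(c("A", "B"), each = 6),
                        da_config(n_permutations = 500, seed = 1, alpha = 0.25))
}

test_that("index definitions are built from signed significant sets", {
  da <- make_da_toy()
  idx <- build_index_definition(da, name = "toy")
  expect_s3_class(idx, "index_definition")
  expect_setequal(idx$positive_features, c("feat01", "feat02", "feat03"))
  expect_setequal(idx$negative_features, c("feat04", "feat05"))
  expect_match(idx$provenance, "alpha")

  # no significant features -> informative error
  null_tb <- random_count_table(10, 8, seed = 2)
  null_da <- differential_features(null_tb, rep(c("A", "B"), each = 4),
                                   da_config(n_permutations = 200, seed = 3))
  expect_error(build_index_definition(null_da), "alpha")
  expect_error(index_definition("a", character()), "nonempty")
  expect_error(index_definition(c("a", "b"), c("b", "c")), "disjoint")
})

test_that("sequence matching handles identical, extended and disjoint universes", {
  seqs <- withr::with_seed(17, vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
    character(1)))
  idx <- index_definition(seqs[1:3], seqs[4:5])
  tb <- toy_table(matrix(1:12, 6), features = seqs, kind = "counts")
  m1 <- match_features(idx, tb)
  expect_setequal(m1$positive_features, seqs[1:3])
  cov <- attr(m1, "coverage")
  expect_equal(cov$fraction, c(1, 1))

  # table sequences extended by 10 nt still match via common-prefix truncation
  ext <- paste0(seqs, "ACGTACGTAC")
  tb_ext <- toy_table(matrix(1:12, 6), features = ext, kind = "counts")
  m2 <- match_features(idx, tb_ext)
  expect_setequal(m2$positive_features, ext[1:3])

  # disjoint universes -> error
  other <- withr::with_seed(99, vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
    character(1)))
  tb_other <- toy_table(matrix(1:8, 4), features = other, kind = "counts")
  expect_error(match_features(idx, tb_other), "does not match")

  # below the minimum overlap nothing matches
  expect_error(match_features(idx, toy_table(matrix(1:2, 1),
                                             features = substr(seqs[1], 1, 50),
                                             kind = "counts")), "does not match")
})

test_that("index scores equal a hand-computed rank table's log-ratios", {
  # 3 samples x 4 features; positive = p1, p2; negative = n1, n2
  m <- matrix(c(5, 1, 3,    # p1 across s1..s3
                6, 2, 3,    # p2
                1, 4, 2,    # n1
                1, 6, 3), nrow = 4, byrow = TRUE)
  tb <- toy_table(m, features = c("p1", "p2", "n1", "n2"), kind = "abundance")
  idx <- index_definition(c("p1", "p2"), c("n1", "n2"))
  got <- score_index(tb, idx)
  # independent hand oracle: rank each feature across samples
  r <- apply(t(m), 2, rank)  # samples x features
  expected <- log(rowMeans(r[, 1:2]) / rowMeans(r[, 3:4]))
  expect_equal(got$score, unname(expected))
  expect_identical(got$sample_id, c("s01", "s02", "s03"))
})

test_that("identical rank profiles in both sets score zero everywhere", {
  m <- matrix(c(5, 1, 3,
                10, 2, 6), nrow = 2, byrow = TRUE)  # same ranks per feature
  tb <- toy_table(m, features = c("p", "n"), kind = "abundance")
  sc <- score_index(tb, index_definition("p", "n"))
  expect_equal(sc$score, rep(0, 3))
})

test_that("swapping positive and negative sets negates every score exactly", {
  tb <- random_count_table(20, 15, seed = 8)
  ids <- ft_feature_ids(tb)
  idx <- index_definition(ids[1:6], ids[7:12])
  swapped <- index_definition(ids[7:12], ids[1:6])
  expect_equal(score_index(tb, idx)$score, -score_index(tb, swapped)$score)
})

test_that("scores are invariant to strictly monotone per-feature transforms", {
  tb <- random_count_table(12, 10, seed = 9)
  rel <- normalize_metabolites(tb)
  ids <- ft_feature_ids(rel)
  idx <- index_definition(ids[1:4], ids[5:8])
  base <- score_index(rel, idx)
  tr <- as_feature_table(
    dplyr::mutate(tibble::as_tibble(rel),
                  dplyr::across(-feature_id, ~ exp(5 * .x))),
    kind = "abundance")
  expect_equal(score_index(tr, idx)$score, base$score)
})

test_that("adding a sample changes scores only through rank re-computation", {
  tb <- random_count_table(10, 8, seed = 12)
  rel <- normalize_metabolites(tb)
  ids <- ft_feature_ids(rel)
  idx <- index_definition(ids[1:3], ids[4:6])
  extended <- as_feature_table(
    dplyr::mutate(tibble::as_tibble(rel),
                  extra = withr::with_seed(5, runif(10))),
    kind = "abundance")
  got <- score_index(extended, idx)
  # brute-force re-rank oracle over the extended sample set
  m <- ft_matrix(extended)
  r <- apply(m, 2, rank)
  oracle <- log(rowMeans(r[, ids[1:3]]) / rowMeans(r[, ids[4:6]]))
  expect_equal(got$score, unname(oracle))
})

test_that("group comparison reproduces the exact rank-sum tail at separation", {
  scores <- tibble::tibble(sample_id = sprintf("s%02d", 1:20),
                           score = c(11:20, 1:10))
  md <- tibble::tibble(sample_id = scores$sample_id,
                       group = rep(c("hi", "lo"), each = 10))
  cmp <- compare_index_groups(scores, md, "hi", "lo")
  expect_equal(cmp$p_value, 2 / choose(20, 10))
  expect_identical(cmp$direction, "a_higher")
  expect_error(compare_index_groups(scores, md, "hi", "absent"), "absent")

  same <- tibble::tibble(sample_id = md$sample_id,
                         score = rep(c(1, 2, 3, 4, 5), 4))
  expect_gt(compare_index_groups(same, md, "hi", "lo")$p_value, 0.9)
})

test_that("the end-to-end pipeline recovers the planted group gradient", {
  cfg <- sim_config(n_samples_per_group = 25, n_features = 120,
                    n_pos_effect = 15, n_neg_effect = 10, seed = 77)
  ref <- simulate_reference_cohort(cfg)
  tgt <- simulate_target_cohort(cfg, ref$truth)
  rep1 <- run_index_pipeline(ref$table, ref$metadata, tgt$table, tgt$metadata,
                             da = da_config(n_permutations = 400),
                             seed = 123)
  meds <- rep1$scores |>
    dplyr::group_by(group) |>
    dplyr::summarise(med = stats::median(score), .groups = "drop")
  med <- stats::setNames(meds$med, meds$group)
  expect_true(med[["rural"]] > med[["rural-urban"]])
  expect_true(med[["rural-urban"]] > med[["CD"]])
  expect_true(med[["urban"]] > med[["CD"]])

  # byte-identical rerun with the same seed
  rep2 <- run_index_pipeline(ref$table, ref$metadata, tgt$table, tgt$metadata,
                             da = da_config(n_permutations = 400),
                             seed = 123)
  expect_identical(rep1$scores, rep2$scores)
  expect_identical(rep1$comparisons, rep2$comparisons)

  # zero-effect simulation -> no index can be built
  null_cfg <- sim_config(n_samples_per_group = 12, n_features = 60,
                         n_pos_effect = 0, n_neg_effect = 0,
                         effect_log2fc = 0, seed = 5)
  null_ref <- simulate_reference_cohort(null_cfg)
  null_tgt <- simulate_target_cohort(null_cfg, null_ref$truth)
  expect_error(
    run_index_pipeline(null_ref$table, null_ref$metadata,
                       null_tgt$table, null_tgt$metadata,
                       da = da_config(n_permutations = 300), seed = 9),
    "alpha")
})

test_that("index definitions round-trip through JSON", {
  idx <- index_definition(c("AAA", "CCC"), c("GGG"), name = "demo",
                          provenance = "unit test")
  path <- withr::local_tempfile(fileext = ".json")
  write_index_definition(idx, path)
  back <- read_index_definition(path)
  expect_identical(back$positive_features, idx$positive_features)
  expect_identical(back$name, "demo")
})
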
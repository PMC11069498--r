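#' Differential abundance configuration
#'
#' @param n_permutations Number of label permutations (default 1000). When
#'   the number of distinct two-group label assignments is at most this,
#'   all assignments are enumerated exhaustively instead of sampled.
#' @param alpha Discrete-FDR level (default 0.1).
#' @param seed Integer RNG seed (optional; only used when sampling).
#' @param two_sided Two-sided test on `|effect|` (default `TRUE`).
#' @param allow_exhaustive Switch off to force sampled permutations even
#'   when exhaustive enumeration would be feasible (mainly for
#'   convergence checks).
#' @return A `da_config` list.
#' @export
da_config <- function(n_permutations = 1000, alpha = 0.1, seed = NULL,
                      two_sided = TRUE, allow_exhaustive = TRUE) {
  assert_scalar_number(n_permutations, "n_permutations", min = 1)
  assert_scalar_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  if (alpha >= 1) abort("`alpha` must be in (0, 1)")
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 seed = seed, two_sided = isTRUE(two_sided),
                 allow_exhaustive = isTRUE(allow_exhaustive)),
            class = "da_config")
}

resolve_groups <- function(table, groups) {
  sids <- ft_sample_ids(table)
  if (is.data.frame(groups)) {
    groups <- stats::setNames(groups$group, groups$sample_id)[sids]
  }
  if (!is.null(names(groups))) groups <- groups[sids]
  lev_order <- if (is.factor(groups)) intersect(levels(groups), unique(as.character(groups)))
  groups <- as.character(groups)
  if (length(groups) != length(sids) || anyNA(groups)) {
    abort("`groups` must give a label for every sample in the table")
  }
  lev <- lev_order %||% unique(groups)
  if (length(lev) != 2L) abort(sprintf("exactly two groups required, got %d", length(lev)))
  if (any(table(groups) < 2)) abort("each group needs >= 2 samples")
  factor(groups, levels = lev)
}

# per-feature across-sample average ranks, samples x features; counts are
# converted to relative abundances first so depth differences cannot drive
# rank shifts
rank_matrix <- function(table) {
  m <- ft_matrix(table)
  if (ft_kind(table) == "counts") m <- m / rowSums(m)
  apply(m, 2, rank)
}

#' Rank-mean two-group statistic
#'
#' For each feature, its abundances are ranked across all samples (ties get
#' average ranks) and the effect is the mean rank in group A minus the mean
#' rank in group B (first and second group label respectively). Being
#' rank-based, the statistic is invariant to any strictly monotone
#' per-feature transform of the abundances.
#'
#' @param table A `feature_tbl` (counts or relative).
#' @param groups Two-group assignment: a vector aligned with (or named by)
#'   the table's samples, or a metadata tibble with `sample_id` and
#'   `group`.
#' @return A tibble with `feature_id` and `effect` (rank units).
#' @export
#' @examples
#' tb <- as_feature_table(tibble::tibble(
#'   feature_id = "f1", s1 = 10, s2 = 9, s3 = 2, s4 = 1))
#' rank_mean_statistic(tb, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
rank_mean_statistic <- function(table, groups) {
  table <- as_feature_table(table, kind = ft_kind(table))
  g <- resolve_groups(table, groups)
  R <- rank_matrix(table)
  a <- levels(g)[1]
  eff <- colMeans(R[g == a, , drop = FALSE]) - colMeans(R[g != a, , drop = FALSE])
  tibble(feature_id = colnames(R), effect = unname(eff))
}

# all (or sampled) group-A index sets as a 0/1 samples x n_perm matrix
permutation_assignments <- function(n, n_a, n_permutations, seed,
                                    allow_exhaustive = TRUE) {
  n_exact <- choose(n, n_a)
  if (allow_exhaustive && n_exact <= n_permutations) {
    sets <- utils::combn(n, n_a)
    P <- matrix(0, n, ncol(sets))
    P[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n_a))] <- 1
    list(P = P, exhaustive = TRUE)
  } else {
    P <- with_seed_opt(seed, vapply(seq_len(n_permutations), function(i) {
      z <- numeric(n); z[sample.int(n, n_a)] <- 1; z
    }, numeric(n)))
    list(P = P, exhaustive = FALSE)
  }
}

#' Permutation null for the rank-mean statistic
#'
#' Permutes the two-group labels (exhaustively when the number of distinct
#' assignments is at most `n_permutations`, sampled otherwise) and
#' recomputes the rank-mean effect for every feature under every
#' assignment. Two-sided p-values are the fraction of permuted `|effect|`
#' at or above the observed `|effect|`; in sampled mode the observed
#' labelling is included in numerator and denominator (add-one rule) so p
#' is never zero, while exhaustive mode reports the exact fraction.
#'
#' @inheritParams rank_mean_statistic
#' @param config A [da_config()].
#' @return A list: `observed` (tibble `feature_id`, `effect`, `p_raw`),
#'   `null_statistics` (features x permutations matrix, retained for the
#'   discrete-FDR scan), `exhaustive` flag.
#' @export
permutation_null <- function(table, groups, config = da_config()) {
  table <- as_feature_table(table, kind = ft_kind(table))
  g <- resolve_groups(table, groups)
  R <- rank_matrix(table)
  n <- nrow(R)
  n_a <- sum(g == levels(g)[1])
  n_b <- n - n_a
  obs <- colMeans(R[g == levels(g)[1], , drop = FALSE]) -
    colMeans(R[g != levels(g)[1], , drop = FALSE])

  asg <- permutation_assignments(n, n_a, config$n_permutations, config$seed,
                                 config$allow_exhaustive %||% TRUE)
  tot <- colSums(R)
  sum_a <- crossprod(R, asg$P)                     # features x n_perm
  null <- sum_a / n_a - (tot - sum_a) / n_b        # rank-mean difference per perm

  stat_obs <- if (config$two_sided) abs(obs) else obs
  stat_null <- if (config$two_sided) abs(null) else null
  ge <- stat_null >= rep(stat_obs, ncol(stat_null)) - 1e-12
  hits <- rowSums(ge)
  p <- if (asg$exhaustive) hits / ncol(null) else (hits + 1) / (ncol(null) + 1)

  list(observed = tibble(feature_id = colnames(R), effect = unname(obs),
                         p_raw = unname(p)),
       null_statistics = null, exhaustive = asg$exhaustive,
       n_permutations = ncol(null))
}

#' Discrete-FDR feature selection
#'
#' The permutation plug-in FDR threshold scan for sparse discrete data: for
#' every candidate threshold `t` over the observed `|effect|` values, the
#' estimated FDR is the mean over permutations of the number of null
#' `|statistics| >= t`, divided by the number of observed `|effect| >= t`
#' (floored at 1). The smallest `t` whose estimated FDR is at most `alpha`
#' is chosen and all features with `|effect| >= t` are called significant;
#' if no threshold qualifies the selection is empty.
#'
#' @param effects Numeric vector of observed effects (named by feature id,
#'   or a tibble with `feature_id` and `effect`).
#' @param null_statistics Features x permutations matrix of null effects.
#' @param alpha FDR level in (0, 1).
#' @return A list: `significant` (logical per feature), `threshold`,
#'   `fdr_curve` (tibble of candidate thresholds and estimated FDR).
#' @export
dsfdr_select <- function(effects, null_statistics, alpha = 0.1) {
  assert_scalar_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE)
  if (alpha >= 1) abort("`alpha` must be in (0, 1)")
  if (is.data.frame(effects)) {
    effects <- stats::setNames(effects$effect, effects$feature_id)
  }
  stopifnot(length(effects) == nrow(null_statistics))
  aobs <- abs(effects)
  anull <- abs(null_statistics)
  cand <- sort(unique(aobs[aobs > 0]))
  if (!length(cand)) {
    return(list(significant = stats::setNames(rep(FALSE, length(effects)), names(effects)),
                threshold = Inf,
                fdr_curve = tibble(threshold = numeric(), fdr = numeric())))
  }
  eps <- 1e-12
  n_obs_ge <- vapply(cand, function(t) sum(aobs >= t - eps), numeric(1))
  mean_null_ge <- vapply(cand, function(t) mean(colSums(anull >= t - eps)), numeric(1))
  fdr <- mean_null_ge / pmax(1, n_obs_ge)
  ok <- which(fdr <= alpha)
  thr <- if (length(ok)) cand[min(ok)] else Inf
  list(significant = stats::setNames(aobs >= thr - eps, names(effects)),
       threshold = thr,
       fdr_curve = tibble(threshold = cand, n_observed = n_obs_ge,
                          mean_null = mean_null_ge, fdr = fdr))
}

#' Two-group differential abundance with discrete-FDR control
#'
#' Composes the rank-mean statistic, its permutation null and the
#' discrete-FDR threshold scan, and splits the significant features by
#' effect sign into higher-in-A / higher-in-B sets.
#'
#' @inheritParams permutation_null
#' @return A `ruralindex_da` object; `tidy()` gives the per-feature table
#'   (`feature_id`, `effect`, `p_raw`, `significant`, `direction`),
#'   `glance()` the selection summary.
#' @export
#' @examples
#' sim <- simulate_reference_cohort(sim_config(
#'   n_samples_per_group = 15, n_features = 60, n_pos_effect = 8,
#'   n_neg_effect = 4, seed = 1))
#' da <- differential_features(sim$table, sim$metadata,
#'                             config = da_config(n_permutations = 200, seed = 1))
#' glance(da)
differential_features <- function(table, groups, config = da_config()) {
  table <- as_feature_table(table, kind = ft_kind(table))
  g <- resolve_groups(table, groups)
  pn <- permutation_null(table, groups, config)
  sel <- dsfdr_select(pn$observed, pn$null_statistics, config$alpha)
  res <- pn$observed |>
    mutate(significant = unname(sel$significant),
           direction = dplyr::if_else(.data$effect >= 0, "higher_in_A", "higher_in_B"))
  structure(list(
    results = res,
    groups = levels(g),
    threshold = sel$threshold,
    fdr_curve = sel$fdr_curve,
    exhaustive = pn$exhaustive,
    n_permutations = pn$n_permutations,
    config = config), class = "ruralindex_da")
}

#' @export
print.ruralindex_da <- function(x, ...) {
  cat(sprintf("Rank-mean differential abundance: %s vs %s\n",
              x$groups[1], x$groups[2]))
  cat(sprintf("  %d features, %d permutations (%s), dsFDR alpha = %g\n",
              nrow(x$results), x$n_permutations,
              if (x$exhaustive) "exhaustive" else "sampled", x$config$alpha))
  cat(sprintf("  significant: %d higher in %s, %d higher in %s (|effect| >= %s)\n",
              sum(x$results$significant & x$results$effect > 0), x$groups[1],
              sum(x$results$significant & x$results$effect < 0), x$groups[2],
              format(x$threshold, digits = 4)))
  invisible(x)
}

#' @export
tidy.ruralindex_da <- function(x, ...) x$results

#' @export
glance.ruralindex_da <- function(x, ...) {
  tibble(group_a = x$groups[1], group_b = x$groups[2],
         n_features = nrow(x$results),
         n_significant = sum(x$results$significant),
         n_higher_in_a = sum(x$results$significant & x$results$effect > 0),
         n_higher_in_b = sum(x$results$significant & x$results$effect < 0),
         threshold = x$threshold,
         alpha = x$config$alpha,
         n_permutations = x$n_permutations,
         exhaustive = x$exhaustive)
}
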
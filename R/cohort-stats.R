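#' Age-bin matching between two groups
#'
#' Bins ages into fixed-width bins anchored at zero (`[0, w), [w, 2w), ...`)
#' and equalizes the per-bin sample counts of the two groups by randomly
#' dropping samples from the larger group, so age is balanced before group
#' comparisons.
#'
#' @param metadata Sample metadata with `sample_id`, `group` and `age`.
#' @param group_a,group_b The two groups to match.
#' @param bin_width Bin width in years (default 10).
#' @param seed Integer RNG seed for the random drops.
#' @return A tibble of retained `sample_id`s (with group and bin); the
#'   per-bin audit is attached as the `audit` attribute. Samples outside
#'   the two groups are untouched (not returned, not dropped).
#' @export
#' @examples
#' md <- tibble::tibble(sample_id = as.character(1:6),
#'                      group = rep(c("a", "b"), each = 3),
#'                      age = c(21, 25, 47, 23, 44, 49))
#' age_match(md, "a", "b", seed = 1)
age_match <- function(metadata, group_a, group_b, bin_width = 10, seed = NULL) {
  metadata <- validate_sample_metadata(metadata)
  assert_scalar_number(bin_width, "bin_width", min = 0, strict_min = TRUE)
  df <- filter(metadata, .data$group %in% c(group_a, group_b))
  if (!"age" %in% names(df) || anyNA(df$age)) {
    missing <- if ("age" %in% names(df)) df$sample_id[is.na(df$age)] else df$sample_id
    abort(sprintf("missing ages for sample(s): %s", paste(missing, collapse = ", ")))
  }
  df$bin <- floor(df$age / bin_width) * bin_width
  retained <- with_seed_opt(seed, {
    df |>
      group_by(.data$bin) |>
      dplyr::group_modify(function(d, key) {
        keep_n <- min(sum(d$group == group_a), sum(d$group == group_b))
        dplyr::bind_rows(lapply(c(group_a, group_b), function(g) {
          dg <- d[d$group == g, , drop = FALSE]
          dg[sort(sample.int(nrow(dg), keep_n)), , drop = FALSE]
        }))
      }) |>
      ungroup()
  })
  audit <- df |>
    group_by(.data$bin) |>
    summarise(n_a = sum(.data$group == group_a),
              n_b = sum(.data$group == group_b), .groups = "drop") |>
    mutate(retained_per_group = pmin(.data$n_a, .data$n_b))
  out <- retained[c("sample_id", "group", "bin")]
  attr(out, "audit") <- audit
  out
}

#' Concordance between two contrasts' per-feature coefficients
#'
#' Compares per-feature effect coefficients from two independent two-group
#' contrasts (e.g. rural-urban vs rural, and CD vs urban controls):
#' per-feature direction-agreement flags (sign agreement; zero coefficients
#' count as disagreement) plus Spearman's rho and its two-sided p over the
#' coefficient pairs.
#'
#' @param coefs_a,coefs_b Coefficient tibbles with `feature_id` and
#'   `coefficient` (optionally `p`, `q`).
#' @param features Optional feature subset to compare on.
#' @return A `ruralindex_concordance` list: `pairs` (per-feature tibble
#'   with `agree`), `agreement` fraction, `rho`, `p_value`, `n`.
#' @export
concordance <- function(coefs_a, coefs_b, features = NULL) {
  need <- function(df, nm) {
    df <- as_tibble(df)
    if (!all(c("feature_id", "coefficient") %in% names(df))) {
      abort(sprintf("`%s` needs `feature_id` and `coefficient` columns", nm))
    }
    df
  }
  a <- need(coefs_a, "coefs_a")
  b <- need(coefs_b, "coefs_b")
  pairs <- inner_join(a[c("feature_id", "coefficient")],
                      b[c("feature_id", "coefficient")],
                      by = "feature_id", suffix = c("_a", "_b"))
  if (!is.null(features)) pairs <- filter(pairs, .data$feature_id %in% features)
  if (nrow(pairs) < 3) abort("need >= 3 shared features for a rank correlation")
  pairs <- mutate(pairs,
                  agree = sign(.data$coefficient_a) == sign(.data$coefficient_b) &
                    sign(.data$coefficient_a) != 0)
  ct <- suppressWarnings(stats::cor.test(pairs$coefficient_a, pairs$coefficient_b,
                                         method = "spearman", exact = FALSE))
  structure(list(pairs = pairs,
                 agreement = mean(pairs$agree),
                 rho = unname(ct$estimate),
                 p_value = ct$p.value,
                 n = nrow(pairs)), class = "ruralindex_concordance")
}

#' @export
print.ruralindex_concordance <- function(x, ...) {
  cat(sprintf("Coefficient concordance over %d features: rho = %.3f (p = %.3g), %.0f%% same direction\n",
              x$n, x$rho, x$p_value, 100 * x$agreement))
  invisible(x)
}

#' @export
tidy.ruralindex_concordance <- function(x, ...) x$pairs

#' @export
glance.ruralindex_concordance <- function(x, ...) {
  tibble(n = x$n, rho = x$rho, p_value = x$p_value, agreement = x$agreement)
}

#' Success probability for the consistency binomial test
#'
#' With a fraction `p_all` of positive correlations in the full sample set
#' and `p_cd` in the subset, the chance that an independent pair of
#' correlation signs agrees is `p_all * p_cd + (1 - p_all) * (1 - p_cd)`.
#' This accounts for the unbalanced positive-to-negative correlation ratio:
#' when most correlations are positive, sign agreement is likely even with
#' no real consistency.
#'
#' @param p_all Fraction of positive correlations in the full set.
#' @param p_cd Fraction of positive correlations in the subset.
#' @return The null success probability.
#' @export
#' @examples
#' consistency_success_probability(0.9, 0.8)  # 0.74
consistency_success_probability <- function(p_all, p_cd) {
  assert_scalar_number(p_all, "p_all", min = 0, max = 1)
  assert_scalar_number(p_cd, "p_cd", min = 0, max = 1)
  p_all * p_cd + (1 - p_all) * (1 - p_cd)
}

#' Exact binomial test for direction consistency
#'
#' Tests whether `n_consistent` of `n_total` correlation pairs sharing the
#' same direction is more than expected under the null success probability
#' of [consistency_success_probability()]. One-sided upper tail by default
#' (the hypothesis is excess consistency); a two-sided variant (via
#' [stats::binom.test()]) is available.
#'
#' @param n_total Number of correlation pairs.
#' @param n_consistent Number sharing direction.
#' @param p_all,p_cd Fractions of positive correlations (see
#'   [consistency_success_probability()]); alternatively supply
#'   `success_prob` directly.
#' @param success_prob Optional explicit null success probability.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A one-row tibble with the success probability and the exact
#'   p-value.
#' @export
consistency_binomial_test <- function(n_total, n_consistent, p_all = NULL,
                                      p_cd = NULL, success_prob = NULL,
                                      alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  assert_scalar_number(n_total, "n_total", min = 1)
  assert_scalar_number(n_consistent, "n_consistent", min = 0, max = n_total)
  if (is.null(success_prob)) {
    if (is.null(p_all) || is.null(p_cd)) {
      abort("supply either `p_all` and `p_cd`, or `success_prob`")
    }
    success_prob <- consistency_success_probability(p_all, p_cd)
  }
  assert_scalar_number(success_prob, "success_prob", min = 0, max = 1)
  p <- if (alternative == "greater") {
    stats::pbinom(n_consistent - 1, n_total, success_prob, lower.tail = FALSE)
  } else {
    stats::binom.test(n_consistent, n_total, success_prob,
                      alternative = "two.sided")$p.value
  }
  tibble(n_total = as.integer(n_total), n_consistent = as.integer(n_consistent),
         success_prob = success_prob, alternative = alternative, p_value = p)
}
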
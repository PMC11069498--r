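#' Prevalence filter
#'
#' Removes features observed (nonzero) in fewer than `min_fraction` of the
#' samples. The boundary is strict: a feature present in exactly
#' `min_fraction` of the samples is kept. Samples are never touched.
#'
#' @param table A `feature_tbl` of kind counts, relative or abundance.
#' @param min_fraction Minimum fraction of samples a feature must be
#'   observed in (default 0.01, i.e. 1%).
#' @return The filtered table; the removed feature ids are attached as the
#'   `removed_features` attribute, retrievable with [filter_report()].
#' @export
#' @examples
#' tb <- as_feature_table(tibble::tibble(
#'   feature_id = c("a", "b"), s1 = c(5, 0), s2 = c(3, 0)))
#' filter_prevalence(tb, 0.5)
filter_prevalence <- function(table, min_fraction = 0.01) {
  table <- as_feature_table(table, kind = ft_kind(table))
  assert_scalar_number(min_fraction, "min_fraction", min = 0, max = 1)
  if (ft_kind(table) == "log") abort("prevalence filtering needs counts/relative abundances")
  m <- ft_matrix(table)
  if (nrow(m) == 0L || ncol(m) == 0L) abort("empty feature table")
  prev <- colMeans(m > 0)
  drop <- prev < min_fraction
  out <- as_feature_table(as_tibble(table)[!drop, , drop = FALSE], kind = ft_kind(table))
  attr(out, "removed_features") <- tibble(
    feature_id = colnames(m)[drop], prevalence = unname(prev[drop]),
    reason = "prevalence")
  out
}

#' Contaminant filter
#'
#' Removes features whose mean environment f-score over water, soil and
#' mouse exceeds (strictly) the human f-score; ties are kept. Features with
#' no score row are kept and reported as unscored.
#'
#' @param table A `feature_tbl`.
#' @param scores A contaminant-score tibble
#'   (`feature_id, f_water, f_soil, f_mouse, f_human`).
#' @return The filtered table with a `removed_features` attribute; unscored
#'   feature ids are attached as `unscored_features`.
#' @export
filter_contaminants <- function(table, scores) {
  table <- as_feature_table(table, kind = ft_kind(table))
  scores <- validate_contaminant_scores(scores)
  ids <- ft_feature_ids(table)
  sc <- scores[match(ids, scores$feature_id), ]
  unscored <- ids[is.na(sc$feature_id)]
  env_mean <- rowMeans(cbind(sc$f_water, sc$f_soil, sc$f_mouse))
  drop <- !is.na(sc$feature_id) & env_mean > sc$f_human
  out <- as_feature_table(as_tibble(table)[!drop, , drop = FALSE], kind = ft_kind(table))
  attr(out, "removed_features") <- tibble(
    feature_id = ids[drop], env_mean = env_mean[drop],
    f_human = sc$f_human[drop], reason = "contaminant")
  attr(out, "unscored_features") <- unscored
  out
}

#' Report of features/samples removed by a filter
#'
#' @param table A table returned by one of the filters or [rarefy()].
#' @return A tibble of removed features, or for [rarefy()] the dropped
#'   sample ids.
#' @export
filter_report <- function(table) {
  attr(table, "removed_features") %||% attr(table, "dropped_samples") %||%
    tibble(feature_id = character())
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (via [vegan::rrarefy()]); samples with fewer than `depth` total
#' reads are dropped and reported. Seed-deterministic.
#'
#' @param table A `feature_tbl` of kind counts.
#' @param depth Target reads per sample (e.g. 33000 or 4000).
#' @param seed Integer RNG seed (optional).
#' @return A counts `feature_tbl` whose sample sums all equal `depth`;
#'   dropped sample ids are attached as the `dropped_samples` attribute.
#' @export
rarefy <- function(table, depth, seed = NULL) {
  table <- as_feature_table(table, kind = ft_kind(table))
  if (ft_kind(table) != "counts") abort("rarefy needs a counts table")
  assert_scalar_number(depth, "depth", min = 0, strict_min = TRUE)
  m <- ft_matrix(table)
  keep <- rowSums(m) >= depth
  dropped <- rownames(m)[!keep]
  if (!any(keep)) abort(sprintf("no sample has >= %d reads", as.integer(depth)))
  # rrarefy warns when a table has no singleton counts (as dense toy tables
  # legitimately may); that heuristic is irrelevant here
  sub <- with_seed_opt(seed, withCallingHandlers(
    vegan::rrarefy(m[keep, , drop = FALSE], depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) invokeRestart("muffleWarning")
    }))
  out <- ft_from_matrix(sub, kind = "counts")
  attr(out, "dropped_samples") <- tibble(sample_id = dropped,
                                         total_reads = rowSums(m)[!keep])
  out
}

#' Sum-normalize a metabolite (or count) table
#'
#' Divides each metabolite value by the per-sample total so every sample
#' sums to 1. Idempotent.
#'
#' @param table A non-negative `feature_tbl`.
#' @return A `feature_tbl` of kind relative.
#' @export
normalize_metabolites <- function(table) {
  table <- as_feature_table(table, kind = ft_kind(table))
  m <- ft_matrix(table)
  tot <- rowSums(m)
  if (any(tot == 0)) abort(sprintf("all-zero sample(s): %s",
                                   paste(rownames(m)[tot == 0], collapse = ", ")))
  ft_from_matrix(m / tot, kind = "relative")
}

#' Clean metabolites for correlation analysis
#'
#' Per metabolite: zeros are replaced by a fifth of the lowest strictly
#' positive value, values are log-transformed, and log values further than
#' four standard deviations from the metabolite's mean are clipped to that
#' bound (so single extreme samples cannot drive downstream correlations).
#'
#' @param table A non-negative `feature_tbl`; every metabolite needs at
#'   least one nonzero value.
#' @param sd_trim Trim bound in standard deviations (default 4).
#' @return A `feature_tbl` of kind log.
#' @export
prep_metabolites_for_correlation <- function(table, sd_trim = 4) {
  table <- as_feature_table(table, kind = ft_kind(table))
  assert_scalar_number(sd_trim, "sd_trim", min = 0, strict_min = TRUE)
  m <- ft_matrix(table)
  if (any(m < 0)) abort("metabolite table must be non-negative")
  allzero <- colSums(m > 0) == 0
  if (any(allzero)) abort(sprintf("metabolite(s) with all zeros: %s",
                                  paste(colnames(m)[allzero], collapse = ", ")))
  cleaned <- apply(m, 2, function(v) {
    v[v == 0] <- min(v[v > 0]) / 5
    lv <- log(v)
    mu <- mean(lv)
    s <- stats::sd(lv)
    if (is.na(s) || s == 0) return(lv)
    pmin(pmax(lv, mu - sd_trim * s), mu + sd_trim * s)
  })
  cleaned <- matrix(cleaned, nrow = nrow(m), dimnames = dimnames(m))
  ft_from_matrix(cleaned, kind = "log")
}
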
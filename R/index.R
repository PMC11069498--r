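#' Signed-ASV index definitions
#'
#' An index definition is a pair of disjoint, nonempty ASV sequence sets: a
#' numerator ("positive", e.g. rural- or health-associated) set and a
#' denominator ("negative") set, plus free-text provenance.
#'
#' @param positive,negative Character vectors of ASV sequences.
#' @param name Index name.
#' @param provenance Free-text provenance (source cohort, alpha, seed).
#' @return An `index_definition`.
#' @export
index_definition <- function(positive, negative, name = "index",
                             provenance = "") {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  if (!length(positive) || !length(negative)) {
    abort("both the positive and negative feature sets must be nonempty")
  }
  if (length(intersect(positive, negative))) {
    abort("positive and negative feature sets must be disjoint")
  }
  structure(list(name = name, positive_features = positive,
                 negative_features = negative, provenance = provenance),
            class = "index_definition")
}

#' @export
print.index_definition <- function(x, ...) {
  cat(sprintf("Index \"%s\": %d positive / %d negative features\n",
              x$name, length(x$positive_features), length(x$negative_features)))
  if (nzchar(x$provenance)) cat(" ", x$provenance, "\n")
  invisible(x)
}

#' @export
tidy.index_definition <- function(x, ...) {
  tibble(feature_id = c(x$positive_features, x$negative_features),
         set = rep(c("positive", "negative"),
                   c(length(x$positive_features), length(x$negative_features))))
}

#' Build an index definition from differential-abundance results
#'
#' Significant features higher in the first (reference) group become the
#' positive set, significant features lower become the negative set.
#'
#' @param da A `ruralindex_da` object from [differential_features()].
#' @param name Index name.
#' @return An `index_definition`.
#' @export
build_index_definition <- function(da, name = "rural_index") {
  stopifnot(inherits(da, "ruralindex_da"))
  res <- da$results
  pos <- res$feature_id[res$significant & res$effect > 0]
  neg <- res$feature_id[res$significant & res$effect < 0]
  if (!length(pos) || !length(neg)) {
    abort(paste0("need significant features in both directions to build an ",
                 "index (", length(pos), " higher / ", length(neg),
                 " lower found); consider relaxing alpha"))
  }
  index_definition(pos, neg, name = name,
                   provenance = sprintf(
                     "derived from %s vs %s, dsFDR alpha = %g, %d permutations",
                     da$groups[1], da$groups[2], da$config$alpha,
                     da$n_permutations))
}

#' Match an index definition against a feature table by sequence
#'
#' ASVs are sequence-identified, so cross-cohort matching is exact string
#' matching after truncating each pair to the shorter of the two sequence
#' lengths (common-prefix matching; sequences trimmed at different lengths
#' by different pipelines still match). Pairs whose common length is below
#' `min_overlap` nucleotides are not matched.
#'
#' @param index An `index_definition`.
#' @param table A `feature_tbl` whose feature ids are nucleotide sequences.
#' @param min_overlap Minimum common sequence length for a match
#'   (default 150 nt, the conventional post-trim ASV length).
#' @return The matched `index_definition` (feature ids rewritten to the
#'   table's ids) with a `coverage` attribute giving the matched fraction
#'   per set.
#' @export
match_features <- function(index, table, min_overlap = 150) {
  stopifnot(inherits(index, "index_definition"))
  tab_ids <- ft_feature_ids(table)
  match_set <- function(seqs) {
    hits <- map(seqs, function(s) {
      L <- pmin(nchar(s), nchar(tab_ids))
      ok <- L >= min_overlap & strtrim(tab_ids, L) == strtrim(s, L)
      tab_ids[ok]
    })
    unique(unlist(hits))
  }
  pos <- match_set(index$positive_features)
  neg <- match_set(index$negative_features)
  coverage <- tibble(
    set = c("positive", "negative"),
    n_index = c(length(index$positive_features), length(index$negative_features)),
    n_matched = c(length(pos), length(neg)))
  coverage$fraction <- coverage$n_matched / coverage$n_index
  if (!length(pos) || !length(neg)) {
    abort(sprintf("index \"%s\" does not match the table (%d/%d positive, %d/%d negative matched)",
                  index$name, length(pos), coverage$n_index[1],
                  length(neg), coverage$n_index[2]))
  }
  out <- index_definition(pos, neg, name = index$name,
                          provenance = paste(index$provenance, "| matched by sequence"))
  attr(out, "coverage") <- coverage
  out
}

#' Per-sample log-rank-ratio index scores
#'
#' Each feature's relative abundance is rank-transformed across samples
#' (ties get average ranks); a sample's score is the natural log of the
#' ratio of its mean rank over the positive set to its mean rank over the
#' negative set. Average ranks are always >= 1, so scores are finite.
#' Features of the index absent from a sample still contribute their (low)
#' across-sample rank -- zeros are informative.
#'
#' @param table A `feature_tbl` (counts are converted to relative
#'   abundances first).
#' @param index A (matched) `index_definition`.
#' @param rank_across Rank each feature across samples (default, matching
#'   the published health-index construction); set to `FALSE` to rank
#'   features within each sample instead.
#' @return A tibble with `sample_id` and `score`.
#' @export
#' @examples
#' tb <- as_feature_table(tibble::tibble(
#'   feature_id = c("p1", "p2", "n1", "n2"),
#'   s1 = c(5, 6, 1, 1), s2 = c(1, 2, 4, 6), s3 = c(3, 3, 2, 3)))
#' idx <- index_definition(c("p1", "p2"), c("n1", "n2"))
#' score_index(tb, idx)
score_index <- function(table, index, rank_across = TRUE) {
  stopifnot(inherits(index, "index_definition"))
  table <- as_feature_table(table, kind = ft_kind(table))
  missing <- setdiff(c(index$positive_features, index$negative_features),
                     ft_feature_ids(table))
  if (length(missing)) {
    abort(sprintf("index features absent from the table (run match_features first): %d missing",
                  length(missing)))
  }
  m <- ft_matrix(table)
  if (ft_kind(table) == "counts") m <- m / rowSums(m)
  R <- if (rank_across) apply(m, 2, rank) else t(apply(m, 1, rank))
  if (is.null(dim(R))) R <- matrix(R, nrow = nrow(m), dimnames = dimnames(m))
  pos_mean <- rowMeans(R[, index$positive_features, drop = FALSE])
  neg_mean <- rowMeans(R[, index$negative_features, drop = FALSE])
  tibble(sample_id = rownames(m), score = unname(log(pos_mean / neg_mean)))
}

#' Compare index scores between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) comparison of per-sample
#' index scores between two metadata groups.
#'
#' @param scores A tibble from [score_index()].
#' @param metadata Sample metadata with `sample_id` and `group`.
#' @param group_a,group_b Group labels to compare.
#' @return A one-row tibble: group medians, direction, W statistic and
#'   two-sided p-value.
#' @export
compare_index_groups <- function(scores, metadata, group_a, group_b) {
  metadata <- validate_sample_metadata(metadata)
  df <- inner_join(scores[c("sample_id", "score")],
                   metadata[c("sample_id", "group")], by = "sample_id") |>
    filter(.data$group %in% c(group_a, group_b))
  if (sum(df$group == group_a) < 2 || sum(df$group == group_b) < 2) {
    abort(sprintf("need >= 2 scored samples in each of \"%s\" and \"%s\"",
                  group_a, group_b))
  }
  xa <- df$score[df$group == group_a]
  xb <- df$score[df$group == group_b]
  wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = NULL))
  tibble(group_a = group_a, group_b = group_b,
         n_a = length(xa), n_b = length(xb),
         median_a = stats::median(xa), median_b = stats::median(xb),
         direction = dplyr::if_else(stats::median(xa) >= stats::median(xb),
                                    "a_higher", "b_higher"),
         statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' End-to-end index pipeline
#'
#' Runs the full index workflow: prevalence (and optional contaminant)
#' filtering and optional rarefaction of the reference cohort, rank-mean
#' differential abundance with discrete-FDR control, index construction,
#' sequence matching to the target cohort, per-sample scoring, and all
#' pairwise group comparisons in the target metadata.
#'
#' @param ref_table,ref_metadata Reference cohort (two groups).
#' @param target_table,target_metadata Target cohort (any groups).
#' @param contaminant_scores Optional f-score tibble applied to both
#'   cohorts.
#' @param min_prevalence Prevalence filter fraction (default 0.01).
#' @param rarefaction_depth Optional even depth; `NULL` skips rarefaction.
#' @param da DA configuration, a [da_config()].
#' @param index_name Name of the built index.
#' @param min_overlap Sequence-match overlap, see [match_features()].
#' @param seed Global seed fanned out to per-stage seeds with
#'   [derive_seed()].
#' @return A `ruralindex_report` list: the differential-abundance object,
#'   the (matched) index, target scores joined with metadata, group
#'   comparisons and a stage log.
#' @export
run_index_pipeline <- function(ref_table, ref_metadata,
                               target_table, target_metadata,
                               contaminant_scores = NULL,
                               min_prevalence = 0.01,
                               rarefaction_depth = NULL,
                               da = da_config(),
                               index_name = "rural_index",
                               min_overlap = 150,
                               seed = 0) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  prep <- function(tab, label) {
    tab <- filter_prevalence(tab, min_prevalence)
    note("%s: prevalence filter removed %d features", label, nrow(filter_report(tab)))
    if (!is.null(contaminant_scores)) {
      tab <- filter_contaminants(tab, contaminant_scores)
      note("%s: contaminant filter removed %d features", label, nrow(filter_report(tab)))
    }
    tab
  }
  ref <- prep(ref_table, "reference")
  tgt <- prep(target_table, "target")
  if (!is.null(rarefaction_depth)) {
    ref <- rarefy(ref, rarefaction_depth, seed = derive_seed(seed, "rarefy_ref"))
    tgt <- rarefy(tgt, rarefaction_depth, seed = derive_seed(seed, "rarefy_target"))
    note("rarefied both cohorts to %d reads", as.integer(rarefaction_depth))
  }

  if (is.null(da$seed)) da$seed <- derive_seed(seed, "diffabund")
  dares <- differential_features(ref, ref_metadata, config = da)
  note("differential abundance: %d significant of %d features",
       sum(dares$results$significant), nrow(dares$results))

  idx <- build_index_definition(dares, name = index_name)
  matched <- match_features(idx, tgt, min_overlap = min_overlap)
  cov <- attr(matched, "coverage")
  note("index matched to target: %d/%d positive, %d/%d negative",
       cov$n_matched[1], cov$n_index[1], cov$n_matched[2], cov$n_index[2])

  scores <- score_index(tgt, matched) |>
    left_join(validate_sample_metadata(target_metadata), by = "sample_id")
  grp <- unique(scores$group)
  comparisons <- purrr::map_dfr(
    utils::combn(grp, 2, simplify = FALSE),
    function(pr) compare_index_groups(scores, target_metadata, pr[1], pr[2]))

  structure(list(differential_abundance = dares, index = matched,
                 coverage = cov, scores = scores,
                 comparisons = comparisons, log = log, seed = seed),
            class = "ruralindex_report")
}

#' @export
print.ruralindex_report <- function(x, ...) {
  cat("Index pipeline report\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  meds <- x$scores |> group_by(.data$group) |>
    summarise(median_score = stats::median(.data$score), .groups = "drop")
  print(meds)
  invisible(x)
}

#' Read/write index definitions as JSON
#'
#' @param index An `index_definition`.
#' @param path File path.
#' @return The index / `path` invisibly.
#' @export
write_index_definition <- function(index, path) {
  jsonlite::write_json(unclass(index), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_index_definition
#' @export
read_index_definition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  index_definition(x$positive_features, x$negative_features,
                   name = x$name %||% "index", provenance = x$provenance %||% "")
}
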
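#' Simulation configuration
#'
#' Parameters of the Dirichlet-multinomial cohort generator. Counts for each
#' sample are drawn as `Multinomial(depth, p)` with
#' `p ~ Dirichlet(alpha_group)`; the baseline concentration vector is
#' log-normal (`alpha_i = base_concentration * w_i`,
#' `w_i ~ LogNormal(0, 1)`), which gives the strong overdispersion and
#' skewed abundance distribution typical of 16S ASV tables. Planted effects
#' multiply the concentrations of selected features by
#' `2^(+/- effect_log2fc)` in the first group, preserving compositionality.
#' Sequencing depths are negative-binomial with mean `depth_mean` and size
#' `depth_dispersion`. Feature ids are synthetic 150-nt sequences, so
#' cross-cohort matching by sequence is exercised.
#'
#' @param n_samples_per_group Samples per group label.
#' @param n_features Total number of ASV features.
#' @param n_pos_effect,n_neg_effect Number of planted group-elevated /
#'   group-depleted features (elevated/depleted in the first group).
#' @param effect_log2fc Planted log2 fold-change magnitude (>= 0).
#' @param depth_mean,depth_dispersion Sequencing-depth negative-binomial
#'   mean (reads) and size parameter.
#' @param base_concentration Scale of the Dirichlet concentration vector.
#' @param contaminant_fraction Fraction of features planted as contaminants.
#' @param age_range_per_group Named list of `c(min, max)` age intervals in
#'   years, one per group (recycled if a single interval is given).
#' @param groups Group labels (two for a reference cohort).
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_samples_per_group = 20, n_features = 100,
#'                   n_pos_effect = 10, n_neg_effect = 5, seed = 1)
sim_config <- function(n_samples_per_group = 50,
                       n_features = 200,
                       n_pos_effect = 30,
                       n_neg_effect = 20,
                       effect_log2fc = 2,
                       depth_mean = 10000,
                       depth_dispersion = 20,
                       base_concentration = 0.5,
                       contaminant_fraction = 0.05,
                       age_range_per_group = list(c(20, 60)),
                       groups = c("rural", "urban"),
                       seed = NULL) {
  assert_scalar_number(n_samples_per_group, "n_samples_per_group", min = 2)
  assert_scalar_number(n_features, "n_features", min = 1)
  assert_scalar_number(n_pos_effect, "n_pos_effect", min = 0)
  assert_scalar_number(n_neg_effect, "n_neg_effect", min = 0)
  if (n_pos_effect + n_neg_effect > n_features) {
    abort("`n_pos_effect` + `n_neg_effect` exceeds `n_features`")
  }
  assert_scalar_number(effect_log2fc, "effect_log2fc", min = 0)
  assert_scalar_number(depth_mean, "depth_mean", min = 0, strict_min = TRUE)
  assert_scalar_number(depth_dispersion, "depth_dispersion", min = 0, strict_min = TRUE)
  assert_scalar_number(base_concentration, "base_concentration", min = 0, strict_min = TRUE)
  assert_scalar_number(contaminant_fraction, "contaminant_fraction", min = 0, max = 1 - 1e-12)
  if (!is.character(groups) || length(groups) < 2L || anyDuplicated(groups)) {
    abort("`groups` must be >= 2 distinct labels")
  }
  if (!is.list(age_range_per_group)) age_range_per_group <- list(age_range_per_group)
  if (is.null(names(age_range_per_group)) && length(age_range_per_group) == 1L) {
    age_range_per_group <- stats::setNames(rep(age_range_per_group, length(groups)), groups)
  }
  bad_age <- vapply(age_range_per_group,
                    function(r) length(r) != 2 || any(r < 0) || r[1] > r[2], logical(1))
  if (any(bad_age)) abort("`age_range_per_group` entries must be valid c(min, max) in years")
  structure(list(
    n_samples_per_group = as.integer(n_samples_per_group),
    n_features = as.integer(n_features),
    n_pos_effect = as.integer(n_pos_effect),
    n_neg_effect = as.integer(n_neg_effect),
    effect_log2fc = effect_log2fc,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    base_concentration = base_concentration,
    contaminant_fraction = contaminant_fraction,
    age_range_per_group = age_range_per_group,
    groups = groups, seed = seed), class = "sim_config")
}

random_asv_sequences <- function(n, length = 150) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
}

rdirichlet_one <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))   # degenerate guard for tiny alpha
  g / sum(g)
}

draw_cohort <- function(config, base_alpha, group_log2_effect, feature_ids,
                        prefix = "S") {
  groups <- names(group_log2_effect$pos_shift)
  n <- config$n_samples_per_group
  samples <- list()
  meta <- list()
  for (g in groups) {
    alpha_g <- base_alpha
    alpha_g[group_log2_effect$pos_idx] <-
      alpha_g[group_log2_effect$pos_idx] * 2^group_log2_effect$pos_shift[[g]]
    alpha_g[group_log2_effect$neg_idx] <-
      alpha_g[group_log2_effect$neg_idx] * 2^(-group_log2_effect$neg_shift[[g]])
    depth <- pmax(stats::rnbinom(n, mu = config$depth_mean,
                                 size = config$depth_dispersion), 50L)
    counts <- vapply(seq_len(n), function(i) {
      p <- rdirichlet_one(alpha_g)
      as.numeric(stats::rmultinom(1, size = depth[i], prob = p))
    }, numeric(config$n_features))
    samples[[g]] <- t(counts)  # n x features
    rng <- config$age_range_per_group[[g]] %||% config$age_range_per_group[[1]]
    meta[[g]] <- tibble(
      sample_id = sprintf("%s_%s_%03d", prefix, g, seq_len(n)),
      group = g,
      age = round(stats::runif(n, rng[1], rng[2])),
      gender = sample(c("female", "male"), n, replace = TRUE),
      site = prefix)
  }
  m <- do.call(rbind, samples)
  metadata <- dplyr::bind_rows(meta)
  rownames(m) <- metadata$sample_id
  colnames(m) <- feature_ids
  list(table = ft_from_matrix(m, kind = "counts"), metadata = metadata)
}

#' Simulate a two-group reference cohort
#'
#' Generates a counts feature table, sample metadata and the planted ground
#' truth for a two-group (e.g. rural vs urban) cohort with planted
#' differentially abundant ASVs. See [sim_config()] for the generative
#' model. Identical config + seed gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with `table` (`feature_tbl`, counts), `metadata`
#'   (tibble) and `truth` (planted feature sets, contaminants, baseline
#'   concentrations).
#' @export
simulate_reference_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$groups) != 2L) abort("a reference cohort has exactly two groups")
  with_seed_opt(config$seed %||% stop_no_seed(), {
    feature_ids <- random_asv_sequences(config$n_features)
    w <- exp(stats::rnorm(config$n_features, 0, 1))
    base_alpha <- config$base_concentration * w
    planted <- sample.int(config$n_features, config$n_pos_effect + config$n_neg_effect)
    pos_idx <- planted[seq_len(config$n_pos_effect)]
    neg_idx <- setdiff(planted, pos_idx)
    n_cont <- floor(config$contaminant_fraction * config$n_features)
    cont_pool <- setdiff(seq_len(config$n_features), planted)
    cont_idx <- if (n_cont > 0 && length(cont_pool))
      sample(cont_pool, min(n_cont, length(cont_pool))) else integer()
    shifts <- list(
      pos_idx = pos_idx, neg_idx = neg_idx,
      pos_shift = stats::setNames(list(config$effect_log2fc, 0), config$groups),
      neg_shift = stats::setNames(list(config$effect_log2fc, 0), config$groups))
    cohort <- draw_cohort(config, base_alpha, shifts, feature_ids, prefix = "REF")
    truth <- list(
      feature_ids = feature_ids,
      planted_positive = feature_ids[pos_idx],
      planted_negative = feature_ids[neg_idx],
      planted_contaminants = feature_ids[cont_idx],
      base_alpha = base_alpha,
      latent_scores = NULL)
    c(cohort, list(truth = truth))
  })
}

stop_no_seed <- function() abort("`seed` must be set in the simulation config")

#' Simulate a multi-group target cohort sharing the reference features
#'
#' Re-uses the reference cohort's feature universe (identical ASV
#' sequences) and planted feature sets, scaling the planted log2 effect per
#' group. A monotone scale map (e.g. rural = 1, rural-urban = 0.5,
#' urban = 0.4, CD = 0) plants a monotone index gradient across groups.
#'
#' @param config A [sim_config()]; its `groups` field is ignored in favour
#'   of `names(group_effect_scale)`.
#' @param truth The `truth` element returned by
#'   [simulate_reference_cohort()].
#' @param group_effect_scale Named numeric map group -> effect multiplier
#'   (>= 0).
#' @return A list with `table` and `metadata`.
#' @export
simulate_target_cohort <- function(config, truth,
                                   group_effect_scale = c(rural = 1, `rural-urban` = 0.5,
                                                          urban = 0.4, CD = 0)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(group_effect_scale)) || any(!nzchar(names(group_effect_scale)))) {
    abort("`group_effect_scale` must be a named group -> multiplier map")
  }
  if (any(group_effect_scale < 0)) abort("effect multipliers must be >= 0")
  groups <- names(group_effect_scale)
  cfg <- config
  cfg$groups <- groups
  if (is.null(cfg$age_range_per_group[[groups[1]]] %||% NULL)) {
    cfg$age_range_per_group <- stats::setNames(
      rep(list(cfg$age_range_per_group[[1]]), length(groups)), groups)
  }
  pos_idx <- match(truth$planted_positive, truth$feature_ids)
  neg_idx <- match(truth$planted_negative, truth$feature_ids)
  shifts <- list(
    pos_idx = pos_idx, neg_idx = neg_idx,
    pos_shift = as.list(config$effect_log2fc * group_effect_scale),
    neg_shift = as.list(config$effect_log2fc * group_effect_scale))
  with_seed_opt(derive_seed(config$seed %||% stop_no_seed(), "target_cohort"),
                draw_cohort(cfg, truth$base_alpha, shifts, truth$feature_ids,
                            prefix = "TGT"))
}

#' Simulate contaminant f-scores
#'
#' Planted contaminants get environment scores (water, soil, mouse) whose
#' mean exceeds their human score; all other features get the reverse. All
#' scores lie in \[0, 1\], so [filter_contaminants()] removes exactly the
#' planted set.
#'
#' @param truth Ground truth from [simulate_reference_cohort()].
#' @param feature_ids Feature ids to score (default: all generated).
#' @param seed Integer RNG seed.
#' @return A contaminant-score tibble.
#' @export
simulate_contaminant_scores <- function(truth, feature_ids = truth$feature_ids,
                                        seed = NULL) {
  if (!length(feature_ids)) abort("`feature_ids` must be nonempty")
  is_cont <- feature_ids %in% truth$planted_contaminants
  with_seed_opt(seed, {
    n <- length(feature_ids)
    env <- matrix(stats::runif(3 * n, 0, 0.45), ncol = 3)
    human <- stats::runif(n, 0.55, 1)
    env[is_cont, ] <- stats::runif(3 * sum(is_cont), 0.55, 1)
    human[is_cont] <- stats::runif(sum(is_cont), 0, 0.45)
    tibble(feature_id = feature_ids,
           f_water = env[, 1], f_soil = env[, 2], f_mouse = env[, 3],
           f_human = human)
  })
}

#' Simulate a pair of omics blocks sharing a latent component
#'
#' Both blocks are `sqrt(f) * latent %o% loading + sqrt(1 - f) * noise`
#' with a common per-sample latent score, where `f` is the shared variance
#' fraction; at `f = 1` each block is exactly rank one and the blocks'
#' first components correlate perfectly.
#'
#' @param n_samples Number of samples (rows).
#' @param p_features_x,p_features_y Features per block.
#' @param shared_variance_fraction Fraction of each feature's variance
#'   carried by the shared latent component, in \[0, 1\].
#' @param seed Integer RNG seed.
#' @return A list with matrices `x`, `y` and `truth$latent_scores`.
#' @export
simulate_coupled_omics <- function(n_samples, p_features_x, p_features_y,
                                   shared_variance_fraction = 0.5, seed = NULL) {
  assert_scalar_number(n_samples, "n_samples", min = 3)
  assert_scalar_number(p_features_x, "p_features_x", min = 1)
  assert_scalar_number(p_features_y, "p_features_y", min = 1)
  assert_scalar_number(shared_variance_fraction, "shared_variance_fraction",
                       min = 0, max = 1)
  with_seed_opt(seed, {
    z <- stats::rnorm(n_samples)
    f <- shared_variance_fraction
    make_block <- function(p, tag) {
      load <- stats::rnorm(p)
      load <- load / sqrt(mean(load^2))
      noise <- matrix(stats::rnorm(n_samples * p), n_samples, p)
      m <- sqrt(f) * (z %o% load) + sqrt(1 - f) * noise
      dimnames(m) <- list(sprintf("S%03d", seq_len(n_samples)),
                          sprintf("%s%04d", tag, seq_len(p)))
      m
    }
    x <- make_block(p_features_x, "X")
    y <- make_block(p_features_y, "Y")
    list(x = x, y = y, truth = list(latent_scores = z))
  })
}

#' Write a simulated cohort to disk
#'
#' Writes the feature table TSV, an ASV FASTA, the metadata TSV and a
#' ground-truth JSON sidecar.
#'
#' @param cohort A list from [simulate_reference_cohort()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return The output paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    table = file.path(dir, paste0(prefix, "_table.tsv")),
    fasta = file.path(dir, paste0(prefix, "_asvs.fasta")),
    metadata = file.path(dir, paste0(prefix, "_metadata.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_feature_table(cohort$table, paths$table)
  write_asv_fasta(ft_feature_ids(cohort$table), paths$fasta)
  write_sample_metadata(cohort$metadata, paths$metadata)
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth[c("planted_positive", "planted_negative",
                                        "planted_contaminants")],
                         paths$truth, auto_unbox = FALSE)
  }
  invisible(paths)
}
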
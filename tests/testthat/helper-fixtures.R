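# small deterministic fixtures built in code

toy_table <- function(m, kind = NULL, features = NULL, samples = NULL) {
  # m: features x samples matrix or vector-per-feature list
  m <- as.matrix(m)
  features <- features %||% sprintf("feat%02d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  df <- tibble::as_tibble(stats::setNames(as.data.frame(m), samples))
  as_feature_table(dplyr::bind_cols(tibble::tibble(feature_id = features), df),
                   kind = kind)
}

random_count_table <- function(n_features, n_samples, seed, max_count = 50,
                               zero_prob = 0.4) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_features * n_samples, max_count / 4), n_features)
    m[runif(length(m)) < zero_prob] <- 0
    toy_table(m, kind = "counts")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force dsFDR threshold scan (plain loops, no shared code
# with the implementation)
brute_force_dsfdr <- function(obs, null_mat, alpha) {
  aobs <- abs(obs)
  cand <- sort(unique(aobs[aobs > 0]))
  chosen <- Inf
  for (t in cand) {
    d <- 0
    for (o in aobs) if (o >= t - 1e-12) d <- d + 1
    tot <- 0
    for (j in seq_len(ncol(null_mat))) {
      for (v in abs(null_mat[, j])) if (v >= t - 1e-12) tot <- tot + 1
    }
    r <- tot / ncol(null_mat)
    if (r / max(1, d) <= alpha) { chosen <- t; break }
  }
  aobs >= chosen - 1e-12
}
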
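#' First latent components of a pair of omics blocks
#'
#' Extracts the first two-block partial-least-squares component of two
#' samples-by-features blocks by iterative power steps on the
#' cross-covariance (NIPALS), which converge to the dominant singular pair
#' of `t(X) %*% Y`. Optional sparsity soft-thresholds each loading vector
#' so only the top `keep_fraction` of features (by absolute loading) stay
#' nonzero, as in sparse PLS; at `keep_fraction = 1` the method is plain
#' two-block PLS. The component orientation is canonicalized: the
#' largest-magnitude x loading is positive and the y component is aligned
#' to non-negative covariance with the x scores, so results are
#' reproducible and the cross-block correlation has a well-defined sign.
#'
#' @param x,y Numeric samples x features matrices (or data frames) over
#'   the same samples, >= 3 samples.
#' @param center,scale. Column-center (always recommended) and
#'   unit-variance scale the blocks (defaults `TRUE`).
#' @param keep_fraction_x,keep_fraction_y Fraction of features kept
#'   nonzero per loading vector (default 1 = no sparsity).
#' @param tol Convergence tolerance on the score vectors.
#' @param max_iter Iteration cap.
#' @return A list with per-block score vectors (`scores_x`, `scores_y`),
#'   loadings, and the iteration count. Deterministic given data/config.
#' @export
first_components <- function(x, y, center = TRUE, scale. = TRUE,
                             keep_fraction_x = 1, keep_fraction_y = 1,
                             tol = 1e-10, max_iter = 500) {
  prep_block <- function(m, nm) {
    m <- as.matrix(m)
    if (!is.numeric(m)) abort(sprintf("block `%s` must be numeric", nm))
    sds <- apply(m, 2, stats::sd)
    if (all(sds == 0)) abort(sprintf("block `%s` has no variation (all columns constant)", nm))
    m <- scale(m, center = center, scale = FALSE)
    if (scale.) {
      keep_sd <- ifelse(sds > 0, sds, 1)
      m <- sweep(m, 2, keep_sd, "/")
    }
    m
  }
  assert_scalar_number(keep_fraction_x, "keep_fraction_x", min = 0, max = 1, strict_min = TRUE)
  assert_scalar_number(keep_fraction_y, "keep_fraction_y", min = 0, max = 1, strict_min = TRUE)
  x <- prep_block(x, "x")
  y <- prep_block(y, "y")
  if (nrow(x) != nrow(y)) abort("blocks must share the same samples")
  if (nrow(x) < 3) abort("need >= 3 samples")

  soft_keep <- function(w, keep) {
    if (keep >= 1) return(w)
    n_keep <- max(1L, ceiling(keep * length(w)))
    if (n_keep >= length(w)) return(w)
    lambda <- sort(abs(w), decreasing = TRUE)[n_keep + 1L]
    sign(w) * pmax(abs(w) - lambda, 0)
  }
  normalize <- function(w) {
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) abort("loading vector collapsed to zero (keep fraction too small?)")
    w / nrm
  }

  u <- y[, which.max(apply(y, 2, stats::var))]
  if (all(u == 0)) u <- y[, 1]
  t_old <- rep(Inf, nrow(x))
  it <- 0L
  repeat {
    it <- it + 1L
    w <- normalize(soft_keep(drop(crossprod(x, u)), keep_fraction_x))
    t_s <- drop(x %*% w)
    cv <- normalize(soft_keep(drop(crossprod(y, t_s)), keep_fraction_y))
    u <- drop(y %*% cv)
    if (max(abs(t_s - t_old)) < tol * (1 + max(abs(t_s))) || it >= max_iter) break
    t_old <- t_s
  }
  # canonical orientation: the dominant x loading is positive, and the y
  # component keeps its (non-negative, by construction of the power step)
  # covariance with the x scores -- so the observed correlation's sign is
  # reproducible and comparable across permutations
  if (w[which.max(abs(w))] < 0) { w <- -w; t_s <- -t_s }
  if (sum(t_s * u) < 0) { cv <- -cv; u <- -u }
  list(scores_x = t_s, scores_y = u, loadings_x = w, loadings_y = cv,
       iterations = it)
}

#' Permutation significance of paired-omics shared variation
#'
#' Measures shared variation between two omics blocks as the Spearman
#' correlation of their first latent components, and assesses significance
#' by permuting the sample order of one block `n_permutations` times,
#' refitting the components per permutation, and counting the permutations
#' with a strictly higher correlation than the observed one
#' (`p = count / n_permutations`; an add-one variant that can never return
#' exactly zero is available behind `add_one`).
#'
#' @inheritParams first_components
#' @param n_permutations Number of permutations (default 100).
#' @param seed Integer RNG seed.
#' @param permute Which block's samples to shuffle (default `"y"`).
#' @param add_one Use `(count + 1) / (n + 1)` instead of the literal
#'   `count / n` rule.
#' @param ... Passed to [first_components()].
#' @return A `coupling_result`: `rho_observed`, `null_rhos`, `p`,
#'   `n_permutations`.
#' @export
#' @examples
#' sim <- simulate_coupled_omics(30, 12, 8, shared_variance_fraction = 0.9,
#'                               seed = 1)
#' coupling_significance(sim$x, sim$y, n_permutations = 50, seed = 1)
coupling_significance <- function(x, y, n_permutations = 100, seed = NULL,
                                  permute = c("y", "x"), add_one = FALSE, ...) {
  permute <- match.arg(permute)
  assert_scalar_number(n_permutations, "n_permutations", min = 1)
  x <- as.matrix(x)
  y <- as.matrix(y)
  fit <- first_components(x, y, ...)
  rho_obs <- stats::cor(fit$scores_x, fit$scores_y, method = "spearman")
  null_rhos <- with_seed_opt(seed, vapply(seq_len(n_permutations), function(b) {
    idx <- sample.int(nrow(x))
    f <- if (permute == "y") first_components(x, y[idx, , drop = FALSE], ...)
         else first_components(x[idx, , drop = FALSE], y, ...)
    stats::cor(f$scores_x, f$scores_y, method = "spearman")
  }, numeric(1)))
  hits <- sum(null_rhos > rho_obs)
  p <- if (add_one) (hits + 1) / (n_permutations + 1) else hits / n_permutations
  structure(list(rho_observed = rho_obs, null_rhos = null_rhos, p = p,
                 n_permutations = as.integer(n_permutations),
                 permuted_block = permute, add_one = add_one),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("Paired-omics coupling: rho = %.3f, p = %g (%d permutations of block %s)\n",
              x$rho_observed, x$p, x$n_permutations, x$permuted_block))
  invisible(x)
}

#' @export
tidy.coupling_result <- function(x, ...) {
  tibble(permutation = seq_along(x$null_rhos), null_rho = x$null_rhos)
}

#' @export
glance.coupling_result <- function(x, ...) {
  tibble(rho_observed = x$rho_observed, p_value = x$p,
         n_permutations = x$n_permutations,
         null_mean = mean(x$null_rhos), null_sd = stats::sd(x$null_rhos))
}
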
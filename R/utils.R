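#' @importFrom rlang abort warn inform `%||%` .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange left_join inner_join group_by
#'   summarise ungroup bind_rows pull across n rename
#' @importFrom purrr map map_dbl map_int map_chr map2 imap pmap walk
NULL

#' Derive a stage-specific seed from a global seed
#'
#' Fans a single pipeline seed out into per-stage seeds by stable hashing of
#' the stage name, so adding a stage never perturbs the random stream of
#' earlier stages. The result is always a valid 32-bit integer seed.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(42, "rarefy")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) * 7919 + h * 13003 + 17) %% 2147483629)
}

# run expr under a local RNG state when seed is given; leave the global
# stream untouched either way when seed is NULL it uses (and advances) the
# current stream.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number", name))
  }
  low_ok <- if (strict_min) x > min else x >= min
  if (!low_ok || x > max) {
    abort(sprintf("`%s` = %s is outside its valid range", name, format(x)))
  }
  invisible(x)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(abs(x - round(x)) < tol, na.rm = TRUE)
}
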
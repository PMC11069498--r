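#' Feature tables
#'
#' A feature table holds a samples-by-features abundance matrix in the
#' long-established "features in rows" TSV layout used by QIIME2/BIOM
#' exports: a tibble whose first column is `feature_id` (an ASV nucleotide
#' sequence or a metabolite name) and whose remaining columns are numeric
#' per-sample abundances. A `kind` attribute records the measurement scale:
#'
#' * `"counts"` -- non-negative integers (sequencing reads),
#' * `"relative"` -- per-sample proportions summing to 1,
#' * `"abundance"` -- arbitrary non-negative intensities (e.g. raw
#'   metabolite peak areas),
#' * `"log"` -- log-transformed values (may be negative).
#'
#' @param x A data frame with a `feature_id` character column and numeric
#'   sample columns.
#' @param kind Measurement scale; inferred when `NULL` (integer values =>
#'   counts, per-sample sums of 1 => relative, otherwise abundance).
#' @return A `feature_tbl`: a tibble with the `kind` attribute set.
#' @export
#' @examples
#' as_feature_table(tibble::tibble(
#'   feature_id = c("f1", "f2"), s1 = c(3, 7), s2 = c(0, 10)
#' ))
as_feature_table <- function(x, kind = NULL) {
  x <- as_tibble(x)
  if (ncol(x) < 2L) abort("a feature table needs `feature_id` plus >= 1 sample column")
  if (names(x)[1] != "feature_id") names(x)[1] <- "feature_id"
  x$feature_id <- as.character(x$feature_id)
  if (anyDuplicated(x$feature_id)) {
    abort(sprintf("duplicate feature ids: %s",
                  paste(unique(x$feature_id[duplicated(x$feature_id)]), collapse = ", ")))
  }
  if (anyDuplicated(names(x))) abort("duplicate sample ids in header")
  vals <- x[-1]
  bad_col <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad_col)) abort(sprintf("non-numeric sample column(s): %s",
                                     paste(bad_col, collapse = ", ")))
  m <- as.matrix(vals)
  if (anyNA(m)) {
    abort(sprintf("missing values in feature row(s): %s",
                  paste(x$feature_id[rowSums(is.na(m)) > 0], collapse = ", ")))
  }
  kind <- kind %||% infer_kind(m)
  if (kind != "log" && any(m < 0)) {
    abort(sprintf("negative values in feature row(s): %s",
                  paste(unique(x$feature_id[rowSums(m < 0) > 0]), collapse = ", ")))
  }
  if (kind == "counts" && !is_wholenumber(m)) {
    abort("kind = \"counts\" requires integer-valued abundances")
  }
  if (kind == "relative") {
    sums <- colSums(m)
    if (any(abs(sums - 1) > 1e-9)) {
      abort(sprintf("kind = \"relative\" requires per-sample sums of 1 (off: %s)",
                    paste(names(vals)[abs(sums - 1) > 1e-9], collapse = ", ")))
    }
  }
  structure(x, kind = match.arg(kind, c("counts", "relative", "abundance", "log")),
            class = c("feature_tbl", class(as_tibble(x))))
}

infer_kind <- function(m) {
  if (is_wholenumber(m) && all(m >= 0)) return("counts")
  if (all(abs(colSums(m) - 1) <= 1e-9)) return("relative")
  if (any(m < 0)) return("log")
  "abundance"
}

#' @rdname as_feature_table
#' @export
ft_kind <- function(x) attr(x, "kind") %||% infer_kind(ft_matrix(x))

#' @rdname as_feature_table
#' @export
ft_sample_ids <- function(x) setdiff(names(x), "feature_id")

#' @rdname as_feature_table
#' @export
ft_feature_ids <- function(x) x$feature_id

#' Convert a feature table to/from a samples-by-features matrix
#'
#' `ft_matrix()` returns the numeric matrix with samples in rows and features
#' in columns (the orientation most statistics want); `ft_from_matrix()` is
#' its inverse.
#'
#' @param x A feature table.
#' @param m A samples x features matrix with dimnames.
#' @param kind Measurement scale for the rebuilt table.
#' @return A matrix, or a `feature_tbl`.
#' @export
ft_matrix <- function(x) {
  m <- t(as.matrix(as_tibble(x)[setdiff(names(x), "feature_id")]))
  dimnames(m) <- list(setdiff(names(x), "feature_id"), x$feature_id)
  m
}

#' @rdname ft_matrix
#' @export
ft_from_matrix <- function(m, kind = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- as_tibble(t(m), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(feature_id = colnames(m)), df)
  as_feature_table(df, kind = kind)
}

#' Read and write feature tables
#'
#' Reads a features-in-rows TSV (plain or QIIME2-exported: a leading
#' `"# Constructed from biom file"` comment line is skipped and a `#OTU ID`
#' header is accepted). Validation errors name the offending row.
#'
#' @param path File path.
#' @param kind Optional explicit measurement scale (otherwise inferred).
#' @param x A feature table.
#' @return `read_feature_table()` returns a `feature_tbl`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path, kind = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#\\s", lines)]           # comment lines ("# ...")
  if (!length(lines)) abort(sprintf("%s: empty table", path))
  lines[1] <- sub("^#OTU ID", "feature_id", lines[1])
  ntab <- lengths(regmatches(lines, gregexpr("\t", lines)))
  if (length(unique(ntab)) != 1L) {
    abort(sprintf("%s: ragged row(s) at line %s", path,
                  paste(which(ntab != ntab[1]), collapse = ", ")))
  }
  first_name <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][1]
  ct <- do.call(readr::cols, c(
    stats::setNames(list(readr::col_character()), first_name),
    list(.default = readr::col_double())))
  df <- readr::read_tsv(I(paste0(lines, collapse = "\n")), col_types = ct)
  names(df)[1] <- "feature_id"
  as_feature_table(df, kind = kind)
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' Read and write sample metadata
#'
#' Sample metadata is a tibble with mandatory `sample_id` and `group`
#' columns and optional `age` (years), `gender`, `site`.
#'
#' @param path File path.
#' @param x A metadata tibble.
#' @return A tibble / `path` invisibly.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols())
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(x, path) {
  readr::write_tsv(validate_sample_metadata(x), path)
  invisible(path)
}

validate_sample_metadata <- function(df) {
  df <- as_tibble(df)
  missing <- setdiff(c("sample_id", "group"), names(df))
  if (length(missing)) abort(sprintf("metadata lacks column(s): %s",
                                     paste(missing, collapse = ", ")))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) abort("duplicate sample ids in metadata")
  if (any(is.na(df$group) | !nzchar(df$group))) abort("empty group labels in metadata")
  if ("age" %in% names(df) && any(df$age < 0, na.rm = TRUE)) abort("negative ages in metadata")
  df
}

#' Read and write contaminant f-score tables
#'
#' One row per ASV with environment-association scores in \[0, 1\]:
#' `f_water`, `f_soil`, `f_mouse` (mus musculus) and `f_human`
#' (homo sapiens), as produced by dbBact-style term association.
#'
#' @param path File path.
#' @param x A contaminant-score tibble.
#' @return A tibble / `path` invisibly.
#' @export
read_contaminant_scores <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), .default = readr::col_double()))
  validate_contaminant_scores(df)
}

#' @rdname read_contaminant_scores
#' @export
write_contaminant_scores <- function(x, path) {
  readr::write_tsv(validate_contaminant_scores(x), path)
  invisible(path)
}

validate_contaminant_scores <- function(df) {
  df <- as_tibble(df)
  need <- c("feature_id", "f_water", "f_soil", "f_mouse", "f_human")
  missing <- setdiff(need, names(df))
  if (length(missing)) abort(sprintf("score table lacks column(s): %s",
                                     paste(missing, collapse = ", ")))
  sc <- as.matrix(df[c("f_water", "f_soil", "f_mouse", "f_human")])
  if (anyNA(sc) || any(sc < 0) || any(sc > 1)) {
    abort(sprintf("malformed f-score row(s): %s",
                  paste(df$feature_id[rowSums(is.na(sc) | sc < 0 | sc > 1) > 0],
                        collapse = ", ")))
  }
  df
}

#' Write ASV sequences to FASTA
#'
#' Sequence-identified features (the feature ids themselves are the ASV
#' nucleotide strings) written as a FASTA file with running ASV labels.
#'
#' @param sequences Character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asv_fasta <- function(sequences, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::DNAStringSet(sequences)
    names(set) <- sprintf("ASV%05d", seq_along(sequences))
    Biostrings::writeXStringSet(set, path)
  } else {
    writeLines(paste0(">ASV", sprintf("%05d", seq_along(sequences)), "\n", sequences), path)
  }
  invisible(path)
}
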
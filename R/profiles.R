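#' Single-cell profile tables
#'
#' A `profile_table` holds one row per segmented cell: per-cell annotations
#' (treatment, well, plate, phenotype label, gene, ...) in a metadata block
#' whose column names carry the `Metadata_` prefix -- the dominant
#' convention in image-based profiling -- and a numeric matrix of
#' morphology features (one named column per feature). The two blocks
#' always have the same number of rows; row order carries no meaning and
#' every downstream operation is invariant to row permutation.
#'
#' @param metadata a data frame of per-cell annotations; column names must
#'   start with `Metadata_` (the prefix is added when absent).
#' @param features a numeric matrix or data frame of morphology features
#'   with unique, non-`Metadata_` column names.
#' @return an object of class `profile_table` with elements `metadata`
#'   (tibble) and `features` (numeric matrix).
#' @examples
#' pt <- profile_table(
#'   metadata = data.frame(Metadata_treatment = c("DMSO", "DMSO", "drugA")),
#'   features = matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("f1", "f2")))
#' )
#' n_cells(pt)
#' @export
profile_table <- function(metadata, features) {
  metadata <- tibble::as_tibble(as.data.frame(metadata))
  nm <- names(metadata)
  missing_prefix <- !startsWith(nm, "Metadata_")
  names(metadata)[missing_prefix] <- paste0("Metadata_", nm[missing_prefix])

  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || !is.numeric(features))
    stop("`features` must be a numeric matrix or all-numeric data frame")
  if (is.null(colnames(features)) || anyDuplicated(colnames(features)))
    stop("feature columns must have unique names")
  if (any(startsWith(colnames(features), "Metadata_")))
    stop("feature names must not carry the `Metadata_` prefix")
  if (nrow(metadata) != nrow(features))
    stop("metadata and features must have identical row counts (",
         nrow(metadata), " vs ", nrow(features), ")")

  structure(list(metadata = metadata, features = features),
            class = "profile_table")
}

#' @export
print.profile_table <- function(x, ...) {
  cat("<profile_table> ", n_cells(x), " cells x ",
      ncol(x$features), " features; metadata: ",
      paste(names(x$metadata), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of cells in a profile table
#' @param x a `profile_table`.
#' @return integer row count.
#' @export
n_cells <- function(x) nrow(x$features)

#' Feature names of a profile table
#' @param x a `profile_table`.
#' @return character vector of feature column names.
#' @export
feature_names <- function(x) colnames(x$features)

#' Load single-cell profiles from Parquet or CSV
#'
#' Reads a flat table whose `Metadata_`-prefixed columns become the
#' metadata block and whose remaining columns become numeric features.
#' Missing feature values are rejected by default: the downstream
#' distributional tests and transport distances assume complete feature
#' vectors, and silent imputation would change their results. With
#' `allow_missing = TRUE`, rows containing any missing feature are dropped
#' and the count is reported.
#'
#' @param path path to the file.
#' @param format `"auto"` (by extension), `"parquet"`, or `"csv"`.
#' @param allow_missing drop rows with missing feature values instead of
#'   erroring.
#' @return a [profile_table()].
#' @export
load_profiles <- function(path, format = c("auto", "parquet", "csv"),
                          allow_missing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, parquet = "parquet", csv = "csv",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass `format` explicitly"))
  }
  df <- switch(format,
    parquet = as.data.frame(arrow::read_parquet(path)),
    csv = utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  )
  as_profile_table(df, allow_missing = allow_missing, source = path)
}

#' Coerce a flat data frame into a profile table
#'
#' @param df data frame with `Metadata_`-prefixed annotation columns plus
#'   numeric feature columns.
#' @inheritParams load_profiles
#' @param source label used in error messages.
#' @return a [profile_table()].
#' @export
as_profile_table <- function(df, allow_missing = FALSE, source = "input") {
  meta_idx <- startsWith(names(df), "Metadata_")
  if (!any(meta_idx))
    stop(source, ": no `Metadata_`-prefixed columns found")
  if (all(meta_idx))
    stop(source, ": no feature columns found")

  feat <- df[!meta_idx]
  for (nm in names(feat)) {
    col <- feat[[nm]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      stop(source, ": feature column '", nm, "' is non-numeric",
           if (length(bad)) paste0(" (first offending row: ", bad[1], ")"))
    }
  }
  feat <- as.matrix(feat)

  if (anyNA(feat)) {
    if (!allow_missing) {
      bad <- which(is.na(feat), arr.ind = TRUE)[1, ]
      stop(source, ": missing value in feature column '",
           colnames(feat)[bad["col"]], "' at row ", bad["row"],
           "; use `allow_missing = TRUE` to drop incomplete rows")
    }
    keep <- stats::complete.cases(feat)
    ms_log("dropped ", sum(!keep), " of ", nrow(feat),
           " rows with missing feature values")
    feat <- feat[keep, , drop = FALSE]
    df <- df[keep, , drop = FALSE]
  }
  profile_table(df[meta_idx], feat)
}

#' Write a profile table to Parquet or CSV
#'
#' Inverse of [load_profiles()]: metadata and feature columns are written
#' side by side in one flat table.
#'
#' @param x a `profile_table`.
#' @param path output path.
#' @param format `"auto"`, `"parquet"`, or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(x, path, format = c("auto", "parquet", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, parquet = "parquet", csv = "csv",
                     stop("cannot infer format from extension '.", ext, "'"))
  }
  df <- cbind(as.data.frame(x$metadata), as.data.frame(x$features))
  switch(format,
    parquet = arrow::write_parquet(df, path),
    csv = utils::write.csv(df, path, row.names = FALSE)
  )
  invisible(path)
}

# resolve a selector name against metadata columns, accepting the name
# with or without the Metadata_ prefix
resolve_meta_col <- function(x, name) {
  cols <- names(x$metadata)
  if (name %in% cols) return(name)
  pref <- paste0("Metadata_", name)
  if (pref %in% cols) return(pref)
  stop("unknown metadata column '", name, "' (available: ",
       paste(cols, collapse = ", "), ")")
}

#' Select a cell population by metadata predicates
#'
#' A selector is a named list mapping metadata column names (with or
#' without the `Metadata_` prefix) to accepted values; clauses are
#' combined conjunctively. An empty selector returns the full table. This
#' is how the two control populations -- e.g. DMSO-treated diseased cells
#' as the reference state and DMSO-treated healthy cells as the target
#' state -- are carved out of a screen.
#'
#' @param x a `profile_table`.
#' @param selector named list of accepted value(s) per metadata column.
#' @return a `profile_table` with the matching rows (possibly empty).
#' @examples
#' pt <- profile_table(
#'   metadata = data.frame(Metadata_treatment = c("DMSO", "drugA", "DMSO")),
#'   features = matrix(0, 3, 1, dimnames = list(NULL, "f1"))
#' )
#' n_cells(select_population(pt, list(treatment = "DMSO")))
#' @export
select_population <- function(x, selector = list()) {
  subset_cells(x, selector_mask(x, selector))
}

# logical row mask for a conjunctive selector
selector_mask <- function(x, selector = list()) {
  stopifnot(inherits(x, "profile_table"))
  keep <- rep(TRUE, n_cells(x))
  if (length(selector) == 0) return(keep)
  if (is.null(names(selector)) || any(names(selector) == ""))
    stop("selector must be a fully named list")
  for (nm in names(selector)) {
    col <- resolve_meta_col(x, nm)
    keep <- keep & (x$metadata[[col]] %in% selector[[nm]])
  }
  keep
}

# row-subset a profile table (logical or integer index)
subset_cells <- function(x, idx) {
  profile_table(x$metadata[idx, , drop = FALSE],
                x$features[idx, , drop = FALSE])
}

# stack two profile tables with identical schemas
bind_profiles <- function(...) {
  parts <- list(...)
  meta <- do.call(rbind, lapply(parts, function(p) as.data.frame(p$metadata)))
  feat <- do.call(rbind, lapply(parts, function(p) p$features))
  profile_table(meta, feat)
}
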
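#' Derive on- and off-morphology signatures
#'
#' Compares the reference and target cell populations feature by feature
#' with two-sample Kolmogorov-Smirnov tests, corrects the p-values across
#' the full feature space in a single Benjamini-Hochberg family, and
#' partitions the features: those with adjusted p strictly below `alpha`
#' form the on-morphology signature (the axis along which a perturbation
#' should move cells from the reference towards the target state), the
#' remainder form the off-morphology signature (features expected to stay
#' unchanged, whose alteration flags off-target activity).
#'
#' Features constant in both populations are degenerate for the KS test;
#' they receive statistic 0 and p-value 1 (hence land in the
#' off-signature) with a warning.
#'
#' @param reference,target `profile_table`s with identical feature
#'   schemas, at least `min_cells` cells each.
#' @param alpha FDR threshold, default 0.05.
#' @param min_cells hard floor on population size (default 2).
#' @param test per-feature two-sample test; the Kolmogorov-Smirnov test
#'   is the only shipped implementation, the argument marks the
#'   extension point for other non-parametric tests.
#' @return a `signature_result`: list with `per_feature` (tibble of
#'   feature, ks_statistic, p_value, p_adjusted), `on_features`,
#'   `off_features`, `alpha`, `reference_n`, `target_n`.
#' @export
derive_signatures <- function(reference, target, alpha = 0.05,
                              min_cells = 2, test = c("ks")) {
  test <- match.arg(test)
  stopifnot(inherits(reference, "profile_table"),
            inherits(target, "profile_table"))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  fr <- feature_names(reference); ft <- feature_names(target)
  if (!identical(sort(fr), sort(ft))) {
    diff <- union(setdiff(fr, ft), setdiff(ft, fr))
    stop("feature schemas differ between populations: ",
         paste(diff, collapse = ", "))
  }
  if (n_cells(reference) < min_cells || n_cells(target) < min_cells)
    stop("each population needs at least ", min_cells, " cells (got ",
         n_cells(reference), " and ", n_cells(target), ")")

  feats <- fr
  tgt <- target$features[, feats, drop = FALSE]
  ref <- reference$features
  stat <- p <- numeric(length(feats))
  constant <- character(0)
  for (k in seq_along(feats)) {
    xr <- ref[, feats[k]]; xt <- tgt[, k]
    if (length(unique(c(xr, xt))) == 1L) {
      constant <- c(constant, feats[k])
      stat[k] <- 0; p[k] <- 1
      next
    }
    res <- ks_two_sample(xr, xt)
    stat[k] <- res$statistic; p[k] <- res$p_value
  }
  if (length(constant))
    warning("constant feature(s) assigned to the off-signature: ",
            paste(constant, collapse = ", "))

  bh <- bh_adjust(p, alpha)
  per_feature <- tibble::tibble(
    feature = feats, ks_statistic = stat,
    p_value = p, p_adjusted = bh$adjusted
  )
  structure(list(
    per_feature = per_feature,
    on_features = feats[bh$rejected],
    off_features = feats[!bh$rejected],
    alpha = alpha,
    reference_n = n_cells(reference),
    target_n = n_cells(target)
  ), class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("<signature_result> alpha = ", x$alpha, "; on-signature: ",
      length(x$on_features), " features; off-signature: ",
      length(x$off_features), " features (n = ", x$reference_n,
      " reference / ", x$target_n, " target cells)\n", sep = "")
  invisible(x)
}

#' Randomly reassign features between the on- and off-signatures
#'
#' Negative-control transformation: draws a uniformly random membership
#' that preserves the sizes of both signatures, leaving the per-feature
#' statistics untouched. Used by the feature-shuffled evaluation mode to
#' show that scores under destroyed covariance no longer track biology.
#'
#' @param signature a `signature_result`.
#' @param seed integer seed; the same seed reproduces the same assignment.
#' @return a `signature_result` with permuted membership.
#' @export
shuffle_feature_assignment <- function(signature, seed) {
  stopifnot(inherits(signature, "signature_result"))
  feats <- signature$per_feature$feature
  n_on <- length(signature$on_features)
  if (n_on == 0 || n_on == length(feats)) return(signature)
  on_new <- with_seed(seed, sample(feats, n_on))
  out <- signature
  out$on_features <- feats[feats %in% on_new]
  out$off_features <- setdiff(feats, out$on_features)
  out
}

#' Permute feature values column-wise across cells
#'
#' Independently permutes every feature column across all rows, leaving
#' metadata untouched. Per-column value multisets (hence all marginal
#' statistics) are preserved while the covariance structure between
#' features is destroyed -- the second negative control used in the
#' evaluation procedures.
#'
#' @param table a `profile_table`.
#' @param seed integer seed.
#' @return a `profile_table` of the same shape.
#' @export
shuffle_feature_values <- function(table, seed) {
  stopifnot(inherits(table, "profile_table"))
  n <- n_cells(table)
  if (n == 0) stop("table is empty")
  feat <- table$features
  feat <- with_seed(seed, {
    for (j in seq_len(ncol(feat))) feat[, j] <- feat[sample.int(n), j]
    feat
  })
  profile_table(table$metadata, feat)
}

#' Serialise a signature result
#'
#' Writes the per-feature test table as CSV and a JSON sidecar recording
#' alpha, the population sizes, and the on/off partition.
#'
#' @param signature a `signature_result`.
#' @param csv_path path for the per-feature CSV.
#' @param json_path path for the JSON sidecar (default: same stem).
#' @return `csv_path`, invisibly.
#' @export
write_signatures <- function(signature, csv_path,
                             json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(signature, "signature_result"))
  utils::write.csv(as.data.frame(signature$per_feature), csv_path,
                   row.names = FALSE)
  jsonlite::write_json(
    list(alpha = signature$alpha,
         reference_n = signature$reference_n,
         target_n = signature$target_n,
         on_features = signature$on_features,
         off_features = signature$off_features),
    json_path, auto_unbox = TRUE, digits = NA
  )
  invisible(csv_path)
}
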
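#' Reference distance between the two control states
#'
#' Earth Mover's Distance between the reference and target populations
#' restricted to the on-signature features. This is the normalising
#' constant for all efficacy scores: a perturbation at distance equal to
#' it scores 1 (morphologically still at the reference state), one at the
#' target scores towards 0.
#'
#' @param reference,target `profile_table`s.
#' @param signature a `signature_result` with a non-empty on-signature.
#' @param ... passed to [emd()].
#' @return a positive scalar.
#' @export
reference_distance <- function(reference, target, signature, ...) {
  check_on_signature(signature)
  d <- emd(on_matrix(reference, signature), on_matrix(target, signature),
           ...)
  if (d <= 0)
    stop("reference distance is zero: the reference and target states are ",
         "indistinguishable over the on-signature, so efficacy scores are ",
         "undefined at alpha = ", signature$alpha)
  d
}

#' Efficacy (on-) score of a perturbation
#'
#' EMD between the perturbed population and the target population over the
#' on-signature features, divided by the reference distance. 1.0 means the
#' perturbation is morphologically equivalent to the reference state, 0.0
#' a complete return to the target state; values above 1.0 indicate cells
#' pushed farther from the target than the reference itself. In practice
#' a fresh draw from the target distribution scores slightly above 0
#' because two finite samples never coincide exactly.
#'
#' @param perturbed a `profile_table` of the perturbation's cells.
#' @param target the target-state `profile_table`.
#' @param signature a `signature_result`.
#' @param ref_dist positive normalising constant from
#'   [reference_distance()].
#' @param ... passed to [emd()].
#' @return nonnegative scalar score.
#' @export
on_score <- function(perturbed, target, signature, ref_dist, ...) {
  check_on_signature(signature)
  if (!is.numeric(ref_dist) || ref_dist <= 0)
    stop("`ref_dist` must be a positive number")
  if (n_cells(perturbed) == 0) stop("perturbed population is empty")
  emd(on_matrix(perturbed, signature), on_matrix(target, signature), ...) /
    ref_dist
}

#' Specificity (off-) score of a perturbation
#'
#' Per off-signature feature, a two-sample KS test between the perturbed
#' population and the comparison population, Benjamini-Hochberg corrected
#' within the off-feature family of this perturbation; the score is the
#' fraction of off-features rejected. A low score means the perturbation
#' leaves the features that should not move untouched (high specificity).
#'
#' @param perturbed a `profile_table`.
#' @param comparison the population the perturbation is compared against
#'   (the target state by default at the screen level; see
#'   [score_screen()]'s `off_comparison`).
#' @param signature a `signature_result` with a non-empty off-signature.
#' @param alpha FDR threshold (defaults to the signature's alpha).
#' @return a list with `score` in `[0, 1]`, logical `flags` named by
#'   off-feature, and a `per_feature` tibble.
#' @export
off_score <- function(perturbed, comparison, signature,
                      alpha = signature$alpha) {
  stopifnot(inherits(signature, "signature_result"))
  if (length(signature$off_features) == 0)
    stop("off-signature is empty: the off-score is undefined")
  if (n_cells(perturbed) < 2 || n_cells(comparison) < 2)
    stop("both populations need at least 2 cells")
  offs <- signature$off_features
  stat <- p <- numeric(length(offs))
  for (k in seq_along(offs)) {
    xr <- perturbed$features[, offs[k]]
    xc <- comparison$features[, offs[k]]
    if (length(unique(c(xr, xc))) == 1L) {
      stat[k] <- 0; p[k] <- 1
    } else {
      res <- ks_two_sample(xr, xc)
      stat[k] <- res$statistic; p[k] <- res$p_value
    }
  }
  bh <- bh_adjust(p, alpha)
  flags <- stats::setNames(bh$rejected, offs)
  list(
    score = mean(flags),
    flags = flags,
    per_feature = tibble::tibble(feature = offs, ks_statistic = stat,
                                 p_value = p, p_adjusted = bh$adjusted)
  )
}

#' Score every perturbation group in a screen
#'
#' Resolves the reference and target control populations, derives the
#' shared reference distance, and scores each perturbation group --
#' treatments pooled across wells by default, or each treatment x well
#' independently with `pool_wells = FALSE`. All groups share one
#' reference distance. The controls themselves may be scored (the
#' reference group anchors at on-score 1.0 and the target group at 0.0
#' when scored as the exact same point sets).
#'
#' Populations larger than `max_cells` are uniformly subsampled (seeded)
#' before the transport problem, since EMD cost scales quadratically with
#' the number of cells; the off-score KS tests always use all cells.
#'
#' @param profiles a `profile_table` for the whole screen.
#' @param signature a `signature_result` (typically from
#'   [derive_signatures()] on the two control populations).
#' @param reference_sel,target_sel selectors (named lists) resolving the
#'   reference- and target-state populations.
#' @param group_by character vector of metadata columns defining
#'   perturbation groups (e.g. `"Metadata_treatment"`).
#' @param pool_wells pool cells across wells within a group (default
#'   TRUE); otherwise `well_col` is appended to the grouping.
#' @param well_col metadata column naming wells.
#' @param off_comparison population the off-score compares against:
#'   `"target"` (default) or `"reference"`.
#' @param max_cells subsampling cap per population for EMD (default
#'   5000); `Inf` disables.
#' @param seed integer seed for the subsampling draws.
#' @param emd_method passed to [emd()].
#' @return a tibble with one row per scored group: group keys, `n_cells`,
#'   `raw_emd`, `reference_distance`, `on_score`, `off_score`,
#'   `n_off_significant`, `n_off_total`.
#' @export
score_screen <- function(profiles, signature, reference_sel, target_sel,
                         group_by = "Metadata_treatment",
                         pool_wells = TRUE, well_col = "Metadata_well",
                         off_comparison = c("target", "reference"),
                         max_cells = 5000, seed = 1,
                         emd_method = c("joint", "per_feature")) {
  off_comparison <- match.arg(off_comparison)
  emd_method <- match.arg(emd_method)
  stopifnot(inherits(profiles, "profile_table"))
  check_on_signature(signature)
  if (length(signature$off_features) == 0)
    stop("off-signature is empty: off-scores are undefined")

  reference <- select_population(profiles, reference_sel)
  target <- select_population(profiles, target_sel)
  if (n_cells(reference) == 0) stop("reference population is empty")
  if (n_cells(target) == 0) stop("target population is empty")

  ref_emd <- cap_cells(reference, max_cells, derive_seed(seed, 1))
  tgt_emd <- cap_cells(target, max_cells, derive_seed(seed, 2))
  ref_dist <- reference_distance(ref_emd, tgt_emd, signature,
                                 method = emd_method)
  comparison <- if (off_comparison == "target") target else reference

  cols <- vapply(group_by, function(g) resolve_meta_col(profiles, g),
                 character(1))
  if (!pool_wells) cols <- c(cols, resolve_meta_col(profiles, well_col))
  keydf <- as.data.frame(profiles$metadata[, cols, drop = FALSE])
  key <- interaction(keydf, drop = TRUE, sep = "\r")
  groups <- split(seq_len(n_cells(profiles)), key)

  rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (length(idx) == 0) next
    grp <- subset_cells(profiles, idx)
    if (n_cells(grp) < 2) {
      warning("skipping group '", gsub("\r", " / ", names(groups)[g]),
              "' with fewer than 2 cells")
      next
    }
    grp_emd <- cap_cells(grp, max_cells, derive_seed(seed, 100 + g))
    raw <- emd(on_matrix(grp_emd, signature),
               on_matrix(tgt_emd, signature), method = emd_method)
    off <- off_score(grp, comparison, signature)
    keys <- keydf[idx[1], , drop = FALSE]
    rownames(keys) <- NULL
    rows[[g]] <- cbind(keys, data.frame(
      n_cells = length(idx),
      raw_emd = raw,
      reference_distance = ref_dist,
      on_score = raw / ref_dist,
      off_score = off$score,
      n_off_significant = sum(off$flags),
      n_off_total = length(off$flags)
    ))
  }
  tibble::as_tibble(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
}

check_on_signature <- function(signature) {
  stopifnot(inherits(signature, "signature_result"))
  if (length(signature$on_features) == 0)
    stop("on-signature is empty: no feature separates the reference and ",
         "target states at alpha = ", signature$alpha,
         "; the two states are statistically indistinguishable and ",
         "efficacy scoring is undefined")
  invisible(signature)
}

on_matrix <- function(x, signature) {
  x$features[, signature$on_features, drop = FALSE]
}

cap_cells <- function(x, max_cells, seed) {
  if (!is.finite(max_cells) || n_cells(x) <= max_cells) return(x)
  idx <- with_seed(seed, sample.int(n_cells(x), max_cells))
  subset_cells(x, idx)
}
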
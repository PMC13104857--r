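#' Cross-plate replicate analysis
#'
#' Assesses whether scores for the same treatment reproduce across
#' plates. Each plate serves once as the reference plate. Per treatment
#' on that plate and per iteration: the treatment's cells on the
#' reference plate act as the reference state and a fresh random
#' subsample of that plate's control cells as the target state;
#' signatures and the normalising reference distance are derived from
#' that pair. The same treatment is then scored on every other plate
#' (`paired`), alongside a randomly drawn different treatment on that
#' plate (`non_paired`) whose identity is re-drawn per iteration --
#' the null in which treatment identity carries no information across
#' plates. A paired score near 1.0 therefore means the treatment looks
#' the same on the query plate as on the reference plate.
#'
#' Control subsampling uses `control_subsample_fraction` with a floor of
#' `min_control_cells`; a warning is emitted when the floor binds, since
#' the fraction is then not the one actually applied.
#'
#' @param profiles a multi-plate `profile_table`.
#' @param plate_col,treatment_col metadata column names.
#' @param control_selector selector for the control (target-state) cells,
#'   which must be present on every plate.
#' @param n_iterations signature-derivation iterations per (reference
#'   plate, treatment) with fresh control subsamples (default 10).
#' @param control_subsample_fraction fraction of control cells drawn per
#'   iteration (default 0.0002).
#' @param min_control_cells floor on the control subsample (default 50).
#' @param alpha FDR threshold for signature derivation.
#' @param seed integer root seed.
#' @param max_cells EMD subsampling cap.
#' @param off_comparison off-score comparison population.
#' @return a `replicate_result`: list with `scores` (one row per
#'   reference plate x query plate x treatment x condition x iteration)
#'   and `summary` (per score type: per-condition means and SDs,
#'   Mann-Whitney p, BH-adjusted p).
#' @export
replicate_analysis <- function(profiles, plate_col = "Metadata_plate",
                               treatment_col = "Metadata_treatment",
                               control_selector, n_iterations = 10,
                               control_subsample_fraction = 2e-04,
                               min_control_cells = 50, alpha = 0.05,
                               seed = 1, max_cells = 5000,
                               off_comparison = c("target", "reference")) {
  off_comparison <- match.arg(off_comparison)
  stopifnot(inherits(profiles, "profile_table"))
  plate_col <- resolve_meta_col(profiles, plate_col)
  treatment_col <- resolve_meta_col(profiles, treatment_col)

  plate <- as.character(profiles$metadata[[plate_col]])
  trt <- as.character(profiles$metadata[[treatment_col]])
  plates <- sort(unique(plate))
  if (length(plates) < 2) stop("need at least 2 plates")
  is_control <- selector_mask(profiles, control_selector)
  if (!any(is_control)) stop("control population is empty")
  for (p in plates)
    if (!any(is_control & plate == p))
      stop("controls missing on plate ", p)

  floor_warned <- FALSE
  rows <- list()
  comb <- 0L
  for (ref_plate in plates) {
    treatments <- sort(unique(trt[plate == ref_plate & !is_control]))
    query_plates <- setdiff(plates, ref_plate)
    for (tr in treatments) {
      ref_cells_idx <- which(plate == ref_plate & trt == tr & !is_control)
      if (length(ref_cells_idx) < 2) next
      present <- vapply(query_plates, function(q)
        any(plate == q & trt == tr & !is_control), logical(1))
      if (!any(present)) {
        ms_log("treatment '", tr, "' absent from all non-reference ",
               "plates; skipped")
        next
      }
      ctrl_idx <- which(is_control & plate == ref_plate)
      n_sub <- max(min_control_cells,
                   ceiling(control_subsample_fraction * length(ctrl_idx)))
      n_sub <- min(n_sub, length(ctrl_idx))
      if (n_sub == min_control_cells && !floor_warned &&
          control_subsample_fraction * length(ctrl_idx) < min_control_cells) {
        warning("control subsample floor of ", min_control_cells,
                " cells binds (fraction ", control_subsample_fraction,
                " of ", length(ctrl_idx), " controls); the effective ",
                "fraction is larger than requested", call. = FALSE)
        floor_warned <- TRUE
      }
      comb <- comb + 1L
      ref_state <- subset_cells(profiles, ref_cells_idx)
      for (it in seq_len(n_iterations)) {
        it_seed <- derive_seed(seed, comb * 1000 + it)
        ctrl_sub_idx <- with_seed(it_seed, sample(ctrl_idx, n_sub))
        tgt_state <- subset_cells(profiles, ctrl_sub_idx)
        sig <- suppressWarnings(
          derive_signatures(ref_state, tgt_state, alpha = alpha)
        )
        if (length(sig$on_features) == 0 ||
            length(sig$off_features) == 0) {
          ms_log("empty signature for treatment '", tr, "' on plate ",
                 ref_plate, " (iteration ", it, "); skipped")
          next
        }
        ref_emd <- cap_cells(ref_state, max_cells, derive_seed(it_seed, 1))
        tgt_emd <- cap_cells(tgt_state, max_cells, derive_seed(it_seed, 2))
        rd <- reference_distance(ref_emd, tgt_emd, sig)
        comparison <- if (off_comparison == "target") tgt_state
                      else ref_state
        for (q in query_plates[present]) {
          q_trts <- setdiff(unique(trt[plate == q & !is_control]), tr)
          pick <- if (length(q_trts))
            with_seed(derive_seed(it_seed, 50 + match(q, plates)),
                      sample(q_trts, 1))
          else NA_character_
          for (cond in c("paired", "non_paired")) {
            q_tr <- if (cond == "paired") tr else pick
            if (is.na(q_tr)) next
            q_idx <- which(plate == q & trt == q_tr & !is_control)
            if (length(q_idx) < 2) next
            qpop <- subset_cells(profiles, q_idx)
            q_emd <- cap_cells(qpop, max_cells, derive_seed(it_seed, 3))
            rows[[length(rows) + 1]] <- tibble::tibble(
              reference_plate = ref_plate, query_plate = q,
              treatment = tr, condition = cond, iteration = it,
              scored_treatment = q_tr,
              on_score = on_score(q_emd, tgt_emd, sig, rd),
              off_score = off_score(qpop, comparison, sig)$score
            )
          }
        }
      }
    }
  }
  scores <- do.call(rbind, rows)
  if (is.null(scores) || !nrow(scores)) {
    warning("no scorable comparisons: every signature derivation was ",
            "empty or every treatment lacked cross-plate replicates",
            call. = FALSE)
    return(structure(list(scores = tibble::tibble(), summary = NULL),
                     class = "replicate_result"))
  }

  summarise_one <- function(col) {
    x <- scores[[col]][scores$condition == "paired"]
    y <- scores[[col]][scores$condition == "non_paired"]
    p <- if (length(x) && length(y)) {
      pv <- mann_whitney_u(x, y)$p_value
      if (is.finite(pv)) pv else NA_real_  # e.g. all scores tied
    } else NA_real_
    tibble::tibble(
      score_type = sub("_score", "", col),
      mean_paired = mean(x), sd_paired = stats::sd(x),
      mean_non_paired = mean(y), sd_non_paired = stats::sd(y),
      p_value = p
    )
  }
  summary <- rbind(summarise_one("on_score"), summarise_one("off_score"))
  ok <- !is.na(summary$p_value)
  summary$p_adjusted <- NA_real_
  if (any(ok))
    summary$p_adjusted[ok] <- bh_adjust(summary$p_value[ok], alpha)$adjusted

  structure(list(scores = scores, summary = summary),
            class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  cat("<replicate_result> ", nrow(x$scores), " scored comparisons (",
      sum(x$scores$condition == "paired"), " paired / ",
      sum(x$scores$condition == "non_paired"), " non-paired)\n", sep = "")
  print(as.data.frame(x$summary))
  invisible(x)
}
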
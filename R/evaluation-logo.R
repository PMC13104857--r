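#' Leave-one-gene-out (LOGO) scoring of a labelled screen
#'
#' For each phenotype independently and each gene with at least
#' `min_cells` cells labelled with that phenotype: the target population
#' is all cells of that phenotype excluding the held-out gene's cells,
#' the reference population is the one named by `reference_selector`
#' (e.g. interphase negative-control cells); signatures are derived on
#' that pair and the held-out gene's full cell set -- across all its
#' labels, treating the gene as one perturbation group -- is scored for
#' efficacy and specificity. Holding the gene's cells out of the target
#' prevents the leakage that would otherwise let a gene trivially
#' retrieve itself.
#'
#' Genes below `min_cells` are excluded with reason `"below min_cells"`;
#' genes whose signature derivation leaves an empty on- or off-signature
#' are excluded with reason `"empty signature"`. In
#' `mode = "feature_shuffled"` the negative control is run instead:
#' signatures are derived on the original populations (so each keeps its
#' original on/off sizes), their membership is then randomly reassigned,
#' and the scoring itself runs on column-wise permuted feature values --
#' destroying the covariance structure the scores rely on while
#' preserving signature sizes and all labels.
#'
#' @param profiles a `profile_table` with phenotype and gene annotations.
#' @param phenotype_col,gene_col metadata column names.
#' @param reference_selector selector for the reference-state population.
#' @param alpha FDR threshold for signature derivation.
#' @param min_cells minimum labelled cells per (phenotype, gene) pair
#'   (default 5).
#' @param mode `"real"` or `"feature_shuffled"`.
#' @param seed integer seed (drives the shuffled mode and subsampling).
#' @param phenotypes phenotype labels to evaluate; defaults to all labels
#'   outside the reference population (and not `"unlabelled"`).
#' @param query_scope `"gene"` (default: score all cells of the held-out
#'   gene) or `"phenotype"` (restrict the query to the gene's cells with
#'   the phenotype label).
#' @param off_comparison passed through to the off-score comparison
#'   population choice (target or reference).
#' @param max_cells EMD subsampling cap.
#' @return a `logo_result`: tibble with one row per (phenotype, gene) --
#'   scores, held-out cell count, labelled-cell proportion, within-
#'   phenotype ranks (midranks, rank 1 = lowest score), and exclusion
#'   flag + reason.
#' @export
logo_analysis <- function(profiles, phenotype_col = "Metadata_phenotype",
                          gene_col = "Metadata_gene",
                          reference_selector, alpha = 0.05, min_cells = 5,
                          mode = c("real", "feature_shuffled"), seed = 1,
                          phenotypes = NULL,
                          query_scope = c("gene", "phenotype"),
                          off_comparison = c("target", "reference"),
                          max_cells = 5000) {
  mode <- match.arg(mode)
  query_scope <- match.arg(query_scope)
  off_comparison <- match.arg(off_comparison)
  stopifnot(inherits(profiles, "profile_table"))
  phenotype_col <- resolve_meta_col(profiles, phenotype_col)
  gene_col <- resolve_meta_col(profiles, gene_col)

  # in shuffled mode signatures come from the original populations (sizes
  # preserved) while all scoring uses the permuted values
  scoring_profiles <- if (mode == "feature_shuffled") {
    shuffle_feature_values(profiles, derive_seed(seed, 1))
  } else profiles

  in_reference <- selector_mask(profiles, reference_selector)
  if (!any(in_reference)) stop("reference population is empty")
  reference <- subset_cells(profiles, in_reference)
  scoring_reference <- subset_cells(scoring_profiles, in_reference)

  phen <- as.character(profiles$metadata[[phenotype_col]])
  gene <- as.character(profiles$metadata[[gene_col]])
  if (is.null(phenotypes)) {
    phenotypes <- setdiff(unique(phen[!in_reference]), "unlabelled")
  }

  rows <- list()
  sig_counter <- 0L
  for (ph in phenotypes) {
    ph_idx <- which(phen == ph & !in_reference)
    genes <- sort(unique(gene[ph_idx]))
    for (g in genes) {
      held_ph <- ph_idx[gene[ph_idx] == g]
      row <- tibble::tibble(
        phenotype = ph, gene = g, on_score = NA_real_,
        off_score = NA_real_, n_heldout_cells = NA_integer_,
        labeled_cell_proportion = NA_real_, on_rank = NA_real_,
        off_rank = NA_real_, excluded = TRUE, reason = NA_character_
      )
      if (length(held_ph) < min_cells) {
        row$reason <- "below min_cells"
        rows[[length(rows) + 1]] <- row
        next
      }
      target_idx <- setdiff(ph_idx, ph_idx[gene[ph_idx] == g])
      query_idx <- if (query_scope == "gene") {
        which(gene == g & !in_reference)
      } else held_ph
      # leakage guard by construction: the held-out gene's rows never
      # enter the target population
      stopifnot(length(intersect(query_idx, target_idx)) == 0)
      if (length(target_idx) < 2) {
        row$reason <- "target too small"
        rows[[length(rows) + 1]] <- row
        next
      }
      target <- subset_cells(profiles, target_idx)
      sig_counter <- sig_counter + 1L
      sig <- suppressWarnings(
        derive_signatures(reference, target, alpha = alpha)
      )
      if (mode == "feature_shuffled")
        sig <- shuffle_feature_assignment(sig,
                                          derive_seed(seed, 1000 + sig_counter))
      if (length(sig$on_features) == 0 || length(sig$off_features) == 0) {
        row$reason <- "empty signature"
        rows[[length(rows) + 1]] <- row
        next
      }
      sc_target <- subset_cells(scoring_profiles, target_idx)
      sc_reference <- scoring_reference
      query <- subset_cells(scoring_profiles, query_idx)
      sseed <- derive_seed(seed, 2000 + sig_counter)
      ref_emd <- cap_cells(sc_reference, max_cells, derive_seed(sseed, 1))
      tgt_emd <- cap_cells(sc_target, max_cells, derive_seed(sseed, 2))
      qry_emd <- cap_cells(query, max_cells, derive_seed(sseed, 3))
      rd <- reference_distance(ref_emd, tgt_emd, sig)
      comparison <- if (off_comparison == "target") sc_target
                    else sc_reference
      row$on_score <- on_score(qry_emd, tgt_emd, sig, rd)
      row$off_score <- off_score(query, comparison, sig)$score
      row$n_heldout_cells <- length(held_ph)
      row$labeled_cell_proportion <-
        length(held_ph) / sum(gene == g & !in_reference)
      row$excluded <- FALSE
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  # within-phenotype midranks over scored genes (rank 1 = lowest score)
  for (ph in unique(out$phenotype)) {
    ok <- which(out$phenotype == ph & !out$excluded)
    out$on_rank[ok] <- rank(out$on_score[ok])
    out$off_rank[ok] <- rank(out$off_score[ok])
  }
  structure(out, class = c("logo_result", class(out)))
}

#' Rank concordance across phenotypes with a label-permutation null
#'
#' Builds the phenotype x gene rank matrix over genes scored in every
#' phenotype ("complete rankings", midranks for ties), computes Kendall's
#' W, and compares it against a null distribution obtained by permuting
#' gene labels within each phenotype independently, `n_permutations`
#' times. The empirical p-value is the proportion of permuted W values
#' at least as large as the observed one. Also returns the pairwise
#' Spearman correlation matrix between per-phenotype rank vectors.
#'
#' @param logo a `logo_result`.
#' @param score `"on"` or `"off"`: which score's ranks to use.
#' @param n_permutations number of label permutations (default 5000).
#' @param seed integer seed for the permutation stream.
#' @return a `concordance_result`: list with `observed_w`, `null_w`,
#'   `empirical_p`, `pairwise_spearman` (symmetric, unit diagonal), and
#'   `genes` (the complete-ranking gene set).
#' @export
rank_concordance <- function(logo, score = c("on", "off"),
                             n_permutations = 5000, seed = 1) {
  score <- match.arg(score)
  scored <- logo[!logo$excluded, , drop = FALSE]
  phens <- unique(scored$phenotype)
  if (length(phens) < 2) stop("need at least 2 phenotypes with scores")
  counts <- table(scored$gene)
  complete <- names(counts)[counts == length(phens)]
  if (length(complete) < 2)
    stop("fewer than 2 genes scored in every phenotype")

  col <- if (score == "on") "on_score" else "off_score"
  mat <- matrix(NA_real_, length(phens), length(complete),
                dimnames = list(phens, complete))
  for (ph in phens) {
    sub <- scored[scored$phenotype == ph, , drop = FALSE]
    mat[ph, ] <- sub[[col]][match(complete, sub$gene)]
  }
  ranks <- t(apply(mat, 1, rank))
  observed <- kendalls_w(ranks)

  null_w <- with_seed(derive_seed(seed, 1), {
    vapply(seq_len(n_permutations), function(i) {
      perm <- t(apply(ranks, 1, sample))
      kendalls_w(perm)
    }, numeric(1))
  })
  p <- empirical_pvalue(observed, null_w, direction = "ge")

  m <- length(phens)
  rho <- diag(1, m)
  dimnames(rho) <- list(phens, phens)
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      rho[i, j] <- rho[j, i] <-
        spearman_rho(ranks[i, ], ranks[j, ])$statistic
    }
  }
  structure(list(observed_w = observed, null_w = null_w, empirical_p = p,
                 pairwise_spearman = rho, genes = complete),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result> W = ", signif(x$observed_w, 4),
      "; null mean = ", signif(mean(x$null_w), 4),
      "; empirical p = ", signif(x$empirical_p, 4),
      " (", length(x$null_w), " permutations, ",
      length(x$genes), " genes)\n", sep = "")
  invisible(x)
}

#' Relate efficacy rank to labelled-cell proportion
#'
#' Pools all scored (phenotype, gene) rows and correlates the
#' within-phenotype efficacy rank with the gene's labelled-cell
#' proportion (Spearman); a negative correlation means genes producing
#' more cells of a phenotype rank better for it. Also reports the
#' per-phenotype sign tally of the correlation and the R-squared of a
#' least-squares fit of rank on proportion.
#'
#' @param logo a `logo_result`.
#' @return a list with `rho`, `p_value`, `r_squared`, and `sign_tally`
#'   (per-phenotype counts of negative / nonnegative correlations).
#' @export
rank_vs_proportion <- function(logo) {
  scored <- logo[!logo$excluded, , drop = FALSE]
  if (nrow(scored) < 3) stop("need at least 3 scored (gene, phenotype) rows")
  res <- spearman_rho(scored$on_rank, scored$labeled_cell_proportion)
  fit <- stats::lm(on_rank ~ labeled_cell_proportion, data = scored)
  r2 <- summary(fit)$r.squared
  signs <- vapply(split(scored, scored$phenotype), function(sub) {
    if (nrow(sub) < 3 ||
        stats::sd(sub$labeled_cell_proportion) == 0 ||
        stats::sd(sub$on_rank) == 0) return(NA_real_)
    spearman_rho(sub$on_rank, sub$labeled_cell_proportion)$statistic
  }, numeric(1))
  list(rho = res$statistic, p_value = res$p_value, r_squared = r2,
       sign_tally = c(negative = sum(signs < 0, na.rm = TRUE),
                      nonnegative = sum(signs >= 0, na.rm = TRUE),
                      undefined = sum(is.na(signs))))
}
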
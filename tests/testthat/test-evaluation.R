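# compact labelled screen used across the LOGO tests
logo_fixture <- function(seed = 61, n_genes = 6, n_phenotypes = 2) {
  generate_logo_screen(
    n_phenotypes = n_phenotypes, n_genes = n_genes,
    n_cells_per_gene = 120, n_reference_cells = 250,
    n_features = 16, n_on_features = 3, effect_size = 3, seed = seed
  )
}

test_that("LOGO scores genes without leaking held-out cells", {
  res <- logo_fixture()
  logo <- suppressMessages(logo_analysis(
    res$profiles, reference_selector = list(phenotype = "reference"),
    seed = 62
  ))
  expect_s3_class(logo, "logo_result")
  scored <- logo[!logo$excluded, ]
  expect_gt(nrow(scored), 0)
  # ranks within each phenotype are a permutation of 1..n_scored
  for (ph in unique(scored$phenotype)) {
    rk <- sort(scored$on_rank[scored$phenotype == ph])
    expect_equal(rk, seq_along(rk))
  }
  # excluded genes carry no scores
  expect_true(all(is.na(logo$on_score[logo$excluded])))
})

test_that("genes below the minimum cell filter are excluded with a reason", {
  res <- logo_fixture()
  pt <- res$profiles
  # forge a gene with only 4 cells of pheno_1
  idx <- which(pt$metadata$Metadata_phenotype == "pheno_1")[1:4]
  meta <- pt$metadata
  meta$Metadata_gene[idx] <- "gene_rare"
  pt2 <- profile_table(meta, pt$features)
  logo <- suppressMessages(logo_analysis(
    pt2, reference_selector = list(phenotype = "reference"), seed = 63
  ))
  rare <- logo[logo$gene == "gene_rare" & logo$phenotype == "pheno_1", ]
  expect_true(rare$excluded)
  expect_equal(rare$reason, "below min_cells")
})

test_that("planted target-proximal genes out-rank reference-like genes", {
  # gene 1 is almost all phenotype-labelled (near the target state),
  # gene 4 mostly reference-like: gene 1 must rank better in every seed
  for (seed in 64:66) {
    res <- generate_logo_screen(
      n_phenotypes = 1, n_genes = 4, n_cells_per_gene = 120,
      n_reference_cells = 250, n_features = 16, n_on_features = 3,
      prop = matrix(c(0.9, 0.6, 0.3, 0.1), 4, 1), seed = seed
    )
    logo <- suppressMessages(logo_analysis(
      res$profiles, reference_selector = list(phenotype = "reference"),
      seed = seed
    ))
    scored <- logo[!logo$excluded, ]
    expect_lt(scored$on_score[scored$gene == "gene_01"],
              scored$on_score[scored$gene == "gene_04"])
  }
})

test_that("efficacy rank tracks labelled-cell proportion in real mode only", {
  res <- logo_fixture(seed = 67, n_genes = 8)
  real <- suppressMessages(logo_analysis(
    res$profiles, reference_selector = list(phenotype = "reference"),
    seed = 68
  ))
  rel <- rank_vs_proportion(real)
  expect_lt(rel$rho, 0)
  expect_gte(rel$r_squared, 0)

  shuf <- suppressMessages(logo_analysis(
    res$profiles, reference_selector = list(phenotype = "reference"),
    mode = "feature_shuffled", seed = 68
  ))
  rel_shuf <- rank_vs_proportion(shuf)
  # decoupled: clearly weaker than the planted association
  expect_gt(rel_shuf$rho, rel$rho)
})

test_that("rank concordance recovers identities and a calibrated null", {
  # perfect concordance
  logo <- structure(tibble::tibble(
    phenotype = rep(c("a", "b", "c"), each = 4),
    gene = rep(paste0("g", 1:4), 3),
    on_score = rep(c(0.1, 0.2, 0.3, 0.4), 3),
    off_score = rep(c(0.1, 0.2, 0.3, 0.4), 3),
    n_heldout_cells = 10L, labeled_cell_proportion = 0.5,
    on_rank = rep(1:4, 3), off_rank = rep(1:4, 3),
    excluded = FALSE, reason = NA_character_
  ), class = c("logo_result", "tbl_df", "tbl", "data.frame"))
  conc <- rank_concordance(logo, n_permutations = 200, seed = 69)
  expect_equal(conc$observed_w, 1)
  expect_lte(conc$empirical_p, 0.05)
  expect_equal(diag(conc$pairwise_spearman), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(conc$pairwise_spearman))
  expect_length(conc$null_w, 200)

  # two exactly reversed phenotypes: W = 0
  rev_logo <- logo[logo$phenotype %in% c("a", "b"), ]
  rev_logo$on_score[rev_logo$phenotype == "b"] <-
    rev(rev_logo$on_score[rev_logo$phenotype == "b"])
  rev_logo$on_rank[rev_logo$phenotype == "b"] <- 4:1
  conc0 <- rank_concordance(rev_logo, n_permutations = 50, seed = 70)
  expect_equal(conc0$observed_w, 0)

  # null W mean for independent rankings is about 1/m
  m <- 3
  expect_lt(abs(mean(conc$null_w) - 1 / m), 0.08)
})

test_that("random rankings sit inside their own permutation null", {
  set.seed(71)
  logo <- structure(tibble::tibble(
    phenotype = rep(c("a", "b", "c"), each = 8),
    gene = rep(paste0("g", 1:8), 3),
    on_score = runif(24), off_score = runif(24),
    n_heldout_cells = 10L, labeled_cell_proportion = 0.5,
    on_rank = as.vector(replicate(3, sample(8))),
    off_rank = as.vector(replicate(3, sample(8))),
    excluded = FALSE, reason = NA_character_
  ), class = c("logo_result", "tbl_df", "tbl", "data.frame"))
  logo$on_score <- logo$on_rank / 10
  conc <- rank_concordance(logo, n_permutations = 400, seed = 72)
  expect_gt(conc$empirical_p, 0.01)
})

test_that("replicate analysis separates paired from permuted treatments", {
  cfg <- screen_config(n_features = 12, n_cells_per_group = 60,
                       n_treatments = 4, n_plates = 3, effect_size = 3,
                       seed = 73)
  res <- make_multiplate(cfg, plate_effect_sd = 0.2, n_control_cells = 150)
  rep_res <- suppressWarnings(suppressMessages(replicate_analysis(
    res$profiles, control_selector = list(treatment = "control"),
    n_iterations = 3, seed = 74
  )))
  sc <- rep_res$scores
  # bookkeeping: every ordered plate pair appears
  pairs <- unique(sc[, c("reference_plate", "query_plate")])
  expect_equal(nrow(pairs), 3 * 2)
  paired <- sc[sc$condition == "paired", ]
  expect_equal(nrow(paired), 3 * 2 * 4 * 3)  # plates x queries x trts x iters
  # paired scores concentrate near 1, permuted ones spread
  sm <- rep_res$summary
  on <- sm[sm$score_type == "on", ]
  expect_lt(abs(on$mean_paired - 1), 0.35)
  expect_lt(on$sd_paired, on$sd_non_paired)
  expect_lt(on$p_value, 0.05)
  expect_true(all(sm$p_adjusted >= sm$p_value - 1e-12))
})

test_that("replicate analysis is invariant to plate ordering", {
  cfg <- screen_config(n_features = 10, n_cells_per_group = 50,
                       n_treatments = 2, n_plates = 2, effect_size = 3,
                       seed = 75)
  res <- make_multiplate(cfg, plate_effect_sd = 0.1, n_control_cells = 120)
  pt <- res$profiles
  set.seed(1)
  perm <- sample(n_cells(pt))
  pt_perm <- profile_table(pt$metadata[perm, , drop = FALSE],
                           pt$features[perm, , drop = FALSE])
  a <- suppressWarnings(suppressMessages(replicate_analysis(
    pt, control_selector = list(treatment = "control"),
    n_iterations = 2, seed = 76
  )))
  b <- suppressWarnings(suppressMessages(replicate_analysis(
    pt_perm, control_selector = list(treatment = "control"),
    n_iterations = 2, seed = 76
  )))
  expect_equal(a$summary$mean_paired, b$summary$mean_paired,
               tolerance = 0.15)
  expect_equal(sort(unique(a$scores$treatment)),
               sort(unique(b$scores$treatment)))
})

test_that("a no-signal screen produces no spurious separation", {
  cfg <- screen_config(n_features = 12, n_cells_per_group = 60,
                       n_treatments = 3, n_plates = 3, effect_size = 0,
                       seed = 77)
  res <- make_multiplate(cfg, plate_effect_sd = 0, n_control_cells = 150)
  rep_res <- suppressWarnings(suppressMessages(replicate_analysis(
    res$profiles, control_selector = list(treatment = "control"),
    n_iterations = 3, seed = 78
  )))
  if (!is.null(rep_res$summary)) {
    pa <- rep_res$summary$p_adjusted
    expect_true(all(is.na(pa) | pa >= 0.05))
  } else {
    # every signature was empty: nothing to separate, which is the point
    expect_equal(nrow(rep_res$scores), 0)
  }
})
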
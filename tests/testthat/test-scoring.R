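# shared medium-size screen: 10 features, 3 planted at 3 SD, 200 cells
scoring_screen <- function(seed = 41) {
  two_state_table(n = 200, n_features = 10, n_on = 3, effect = 3,
                  seed = seed)
}

test_that("scores anchor at 1 for the reference and 0 for the target", {
  screen <- scoring_screen()
  r <- ref_pop(screen); t <- tgt_pop(screen)
  sig <- derive_signatures(r, t)
  rd <- reference_distance(r, t, sig)
  expect_gt(rd, 0)
  expect_identical(on_score(r, t, sig, rd), 1)
  expect_identical(on_score(t, t, sig, rd), 0)
})

test_that("a population pushed past the reference scores above 1", {
  screen <- scoring_screen()
  r <- ref_pop(screen); t <- tgt_pop(screen)
  sig <- derive_signatures(r, t)
  rd <- reference_distance(r, t, sig)
  away <- r
  shift <- colMeans(t$features) - colMeans(r$features)
  away$features <- sweep(r$features, 2, 2 * shift, `-`)
  expect_gt(on_score(away, t, sig, rd), 1)
})

test_that("a fresh draw from the target distribution scores above 0", {
  s1 <- scoring_screen(seed = 42)
  s2 <- scoring_screen(seed = 43)  # independent draw, same distribution
  r <- ref_pop(s1); t <- tgt_pop(s1)
  sig <- derive_signatures(r, t)
  rd <- reference_distance(r, t, sig)
  fresh <- tgt_pop(s2)
  sc <- on_score(fresh, t, sig, rd)
  expect_gt(sc, 0)
  expect_lt(sc, 0.5)  # but far closer to the target than the reference
})

test_that("degenerate states are caught", {
  screen <- scoring_screen()
  r <- ref_pop(screen); t <- tgt_pop(screen)
  sig <- derive_signatures(r, t)
  # identical reference and target: zero distance must be a hard error
  expect_error(reference_distance(t, t, sig), "indistinguishable")
  expect_error(on_score(r, t, sig, ref_dist = 0), "positive")
  # empty on-signature
  sig_empty <- sig
  sig_empty$on_features <- character(0)
  expect_error(reference_distance(r, t, sig_empty), "on-signature is empty")
  sig_nooff <- sig
  sig_nooff$off_features <- character(0)
  expect_error(off_score(r, t, sig_nooff), "off-signature is empty")
})

test_that("reference distance ignores off-signature features", {
  screen <- scoring_screen()
  r <- ref_pop(screen); t <- tgt_pop(screen)
  sig <- derive_signatures(r, t)
  rd <- reference_distance(r, t, sig)
  add_noise_col <- function(pt, seed) {
    set.seed(seed)
    f <- cbind(pt$features, noise = rnorm(n_cells(pt), sd = 10))
    profile_table(pt$metadata, f)
  }
  r2 <- add_noise_col(r, 1); t2 <- add_noise_col(t, 2)
  expect_equal(reference_distance(r2, t2, sig), rd)
})

test_that("off-score counts exactly the planted off-target features", {
  # off-signature of 10 features, exactly 3 shifted by 3 SD at n = 500
  set.seed(244)
  feats <- sprintf("f%02d", 1:12)
  mu_ref <- rep(0, 12)
  mu_tgt <- c(3, 3, rep(0, 10))          # on-signature: f01, f02
  draw <- function(mu) {
    x <- sweep(matrix(rnorm(500 * 12), 500, 12), 2, mu, `+`)
    colnames(x) <- feats
    profile_table(data.frame(Metadata_t = rep("x", 500)), x)
  }
  r <- draw(mu_ref); t <- draw(mu_tgt)
  sig <- derive_signatures(r, t)
  expect_setequal(sig$on_features, c("f01", "f02"))
  mu_pert <- mu_tgt
  mu_pert[3:5] <- 3                       # 3 of the 10 off-features shift
  pert <- draw(mu_pert)
  off <- off_score(pert, t, sig)
  expect_equal(off$score, 0.3)
  expect_setequal(names(off$flags)[off$flags], c("f03", "f04", "f05"))
  # identical comparison population: nothing significant
  expect_equal(off_score(t, t, sig)$score, 0)
  # all off-features shifted: everything significant
  mu_all <- mu_tgt + c(0, 0, rep(3, 10))
  expect_equal(off_score(draw(mu_all), t, sig)$score, 1)
})

test_that("off-score is invariant to changes confined to the on-signature", {
  screen <- scoring_screen()
  r <- ref_pop(screen); t <- tgt_pop(screen)
  sig <- derive_signatures(r, t)
  pert <- r
  base <- off_score(pert, t, sig)$score
  pert2 <- pert
  pert2$features[, sig$on_features] <-
    pert$features[, sig$on_features] + 100
  expect_equal(off_score(pert2, t, sig)$score, base)
})

test_that("screen scoring returns one row per group with shared normalisation", {
  res <- generate_screen(screen_config(
    n_features = 10, n_on_features = 3, effect_size = 3,
    n_cells_per_group = 120, efficacy_grid = c(0.3, 0.9),
    n_wells = 6, seed = 45
  ))
  pt <- res$profiles
  sig <- derive_signatures(
    select_population(pt, list(role = "reference")),
    select_population(pt, list(role = "target"))
  )
  pooled <- score_screen(pt, sig,
                         reference_sel = list(role = "reference"),
                         target_sel = list(role = "target"),
                         group_by = "Metadata_treatment", seed = 2)
  expect_equal(nrow(pooled), 4)  # reference, target, two treatments
  expect_equal(length(unique(pooled$reference_distance)), 1)
  ref_row <- pooled[pooled$Metadata_treatment == "reference", ]
  tgt_row <- pooled[pooled$Metadata_treatment == "target", ]
  expect_identical(ref_row$on_score, 1)
  expect_identical(tgt_row$on_score, 0)
  expect_true(all(pooled$off_score >= 0 & pooled$off_score <= 1))
  expect_equal(pooled$on_score, pooled$raw_emd / pooled$reference_distance)

  unpooled <- score_screen(pt, sig,
                           reference_sel = list(role = "reference"),
                           target_sel = list(role = "target"),
                           group_by = "Metadata_treatment",
                           pool_wells = FALSE, seed = 2)
  expect_equal(nrow(unpooled), 4 * 6)
})

test_that("per-well efficacy scores degrade with cell sparsity", {
  # heavy random subsampling of wells: sparser wells sit farther from the
  # target, so on-score correlates negatively with cell count
  set.seed(46)
  res <- generate_screen(screen_config(
    n_features = 10, n_on_features = 3, effect_size = 3,
    n_cells_per_group = 600, efficacy_grid = 1, n_treatments = 1,
    n_wells = 8, seed = 47
  ))
  pt <- res$profiles
  keep <- rep(TRUE, n_cells(pt))
  trt <- pt$metadata$Metadata_treatment == "trt_01"
  wells <- unique(pt$metadata$Metadata_well[trt])
  target_sizes <- round(seq(5, 70, length.out = length(wells)))
  for (k in seq_along(wells)) {
    idx <- which(trt & pt$metadata$Metadata_well == wells[k])
    drop <- sample(idx, max(0, length(idx) - target_sizes[k]))
    keep[drop] <- FALSE
  }
  pt_sub <- select_population(pt, list())     # copy
  pt_sub <- profile_table(pt$metadata[keep, , drop = FALSE],
                          pt$features[keep, , drop = FALSE])
  sig <- derive_signatures(
    select_population(pt_sub, list(role = "reference")),
    select_population(pt_sub, list(role = "target"))
  )
  per_well <- score_screen(pt_sub, sig,
                           reference_sel = list(role = "reference"),
                           target_sel = list(role = "target"),
                           group_by = "Metadata_treatment",
                           pool_wells = FALSE, seed = 3)
  per_well <- per_well[per_well$Metadata_treatment == "trt_01", ]
  rho <- spearman_rho(per_well$on_score, per_well$n_cells)$statistic
  expect_lt(rho, 0)
})

test_that("empty groups are skipped with a warning, not a crash", {
  screen <- scoring_screen()
  pt <- screen$profiles
  # add a singleton group
  one <- profile_table(
    data.frame(Metadata_treatment = "lonely", Metadata_well = "W01",
               Metadata_plate = "P1", Metadata_gene = "lonely",
               Metadata_role = "perturbed"),
    pt$features[1, , drop = FALSE]
  )
  pt2 <- morphoscore:::bind_profiles(pt, one)
  sig <- derive_signatures(ref_pop(screen), tgt_pop(screen))
  expect_warning(
    res <- score_screen(pt2, sig,
                        reference_sel = list(role = "reference"),
                        target_sel = list(role = "target"),
                        group_by = "Metadata_treatment", seed = 2),
    "fewer than 2"
  )
  expect_false("lonely" %in% res$Metadata_treatment)
})
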
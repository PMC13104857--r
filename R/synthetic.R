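#' Configuration for a synthetic single-cell screen
#'
#' Defines the generative conditions for a screen with planted ground
#' truth: a Gaussian reference population, a target population shifted on
#' a known on-subset of features, and perturbation groups whose means
#' interpolate (or extrapolate) between the two states at graded
#' efficacies. Defaults emulate a well-powered two-state contrast: 20
#' features of which 5 separate the states at 3 SD, 500 cells per group
#' -- an effect size and depth at which per-feature tests recover the
#' planted subset essentially perfectly.
#'
#' @param n_features total number of morphology features.
#' @param n_on_features number of planted state-separating features.
#' @param effect_size reference-to-target mean shift on the planted
#'   subset, in within-population SD units.
#' @param n_cells_per_group cells per population / perturbation group.
#' @param correlation shared-factor equicorrelation between features, in
#'   `[0, 1)`; 0 gives independent features.
#' @param efficacy_grid efficacies `lambda` of the perturbation groups:
#'   group means sit at `(1 - lambda) * reference + lambda * target`
#'   (values outside `[0, 1]` extrapolate).
#' @param off_shift_features number of off-subset features receiving a
#'   planted off-target shift in perturbation groups.
#' @param off_shift_size magnitude (SD units) of that off-target shift.
#' @param n_plates,n_wells,n_treatments layout: plates, wells per group,
#'   and treatment count (defaults to the grid length; the grid is
#'   recycled across treatments).
#' @param seed root seed; all draws are derived from it.
#' @return a `screen_config` list.
#' @export
screen_config <- function(n_features = 20, n_on_features = 5,
                          effect_size = 3, n_cells_per_group = 500,
                          correlation = 0,
                          efficacy_grid = c(0, 0.25, 0.5, 0.75, 1),
                          off_shift_features = 0, off_shift_size = 0,
                          n_plates = 1, n_wells = 1,
                          n_treatments = length(efficacy_grid),
                          seed = 1) {
  cfg <- list(n_features = n_features, n_on_features = n_on_features,
              effect_size = effect_size,
              n_cells_per_group = n_cells_per_group,
              correlation = correlation, efficacy_grid = efficacy_grid,
              off_shift_features = off_shift_features,
              off_shift_size = off_shift_size,
              n_plates = n_plates, n_wells = n_wells,
              n_treatments = n_treatments, seed = seed)
  validate_screen_config(cfg)
  structure(cfg, class = "screen_config")
}

validate_screen_config <- function(cfg) {
  with(cfg, {
    if (n_features < 1 || n_on_features < 0 || n_on_features > n_features)
      stop("need 0 <= n_on_features <= n_features, n_features >= 1")
    if (n_cells_per_group < 2) stop("n_cells_per_group must be >= 2")
    if (correlation < 0 || correlation >= 1)
      stop("correlation must lie in [0, 1)")
    if (off_shift_features > n_features - n_on_features)
      stop("off_shift_features exceeds the off-subset size")
    if (n_plates < 1 || n_wells < 1 || n_treatments < 1)
      stop("layout counts must be positive")
  })
  invisible(cfg)
}

# constant-valued metadata block of n rows
scalar_meta <- function(n, treatment, well, plate, gene, role = NULL,
                        phenotype = NULL) {
  cols <- list(Metadata_treatment = treatment, Metadata_well = well,
               Metadata_plate = plate, Metadata_gene = gene)
  if (!is.null(role)) cols$Metadata_role <- role
  if (!is.null(phenotype)) cols$Metadata_phenotype <- phenotype
  as.data.frame(lapply(cols, rep, n), stringsAsFactors = FALSE)
}

# Gaussian draw with optional shared-factor equicorrelation rho:
# X = sqrt(1 - rho) Z + sqrt(rho) F, F one factor per cell.
draw_population <- function(n, mu, rho) {
  d <- length(mu)
  z <- matrix(stats::rnorm(n * d), n, d)
  if (rho > 0) {
    f <- stats::rnorm(n)
    z <- sqrt(1 - rho) * z + sqrt(rho) * f
  }
  sweep(z, 2, mu, `+`)
}

#' Generate a synthetic screen with planted ground truth
#'
#' Emits a profile table with a reference population (multivariate normal,
#' mean 0), a target population shifted by `effect_size` SD on the planted
#' on-subset, and one group per treatment whose mean interpolates between
#' the two states at its efficacy `lambda` (recycled from
#' `efficacy_grid`), optionally with planted off-target shifts. Cells are
#' spread evenly over `n_wells` wells; metadata columns record treatment,
#' well, plate, gene (the treatment id) and the population role. Output
#' is byte-identical for a fixed config.
#'
#' @param config a [screen_config()].
#' @return a list with `profiles` (a `profile_table`) and `ground_truth`
#'   (planted on-features, per-treatment `lambda` and off-target subsets).
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  with_seed(config$seed, {
    feats <- sprintf("f%02d", seq_len(config$n_features))
    on_idx <- seq_len(config$n_on_features)
    mu_ref <- rep(0, config$n_features)
    mu_tgt <- mu_ref
    mu_tgt[on_idx] <- config$effect_size

    lambdas <- rep(config$efficacy_grid,
                   length.out = config$n_treatments)
    trt_ids <- sprintf("trt_%02d", seq_len(config$n_treatments))

    off_pool <- setdiff(seq_len(config$n_features), on_idx)
    blocks <- list()
    truth_off <- stats::setNames(vector("list", length(trt_ids)), trt_ids)

    add_block <- function(role, id, mu) {
      x <- draw_population(config$n_cells_per_group, mu, config$correlation)
      colnames(x) <- feats
      wells <- sprintf("W%02d",
                       rep_len(seq_len(config$n_wells), nrow(x)))
      meta <- data.frame(
        Metadata_treatment = id,
        Metadata_well = paste0(id, "_", wells),
        Metadata_plate = "P1",
        Metadata_gene = id,
        Metadata_role = role,
        stringsAsFactors = FALSE
      )
      blocks[[length(blocks) + 1]] <<- profile_table(meta, x)
    }

    add_block("reference", "reference", mu_ref)
    add_block("target", "target", mu_tgt)
    for (k in seq_along(trt_ids)) {
      mu <- (1 - lambdas[k]) * mu_ref + lambdas[k] * mu_tgt
      off_sub <- integer(0)
      if (config$off_shift_features > 0) {
        off_sub <- sample(off_pool, config$off_shift_features)
        mu[off_sub] <- mu[off_sub] + config$off_shift_size
      }
      truth_off[[k]] <- feats[sort(off_sub)]
      add_block("perturbed", trt_ids[k], mu)
    }
    list(
      profiles = do.call(bind_profiles, blocks),
      ground_truth = list(on_features = feats[on_idx],
                          lambda = stats::setNames(lambdas, trt_ids),
                          off_shifted = truth_off,
                          config = unclass(config))
    )
  })
}

#' Generate a multi-plate screen with shared treatment effects
#'
#' Emulates a cross-plate replicate layout: every treatment has one
#' effect vector (a random direction of length `effect_size`), shared
#' across all plates, plus an additive plate-level offset of scale
#' `plate_effect_sd` applied to all cells on a plate. Control cells
#' (mean at the plate offset only) are present on every plate under
#' treatment id `"control"`. With `plate_effect_sd = 0`, per-treatment
#' means are identical across plates up to sampling error.
#'
#' @param config a [screen_config()]; `n_plates` must be at least 2.
#' @param plate_effect_sd SD of the additive plate offset.
#' @param n_control_cells control cells per plate (default twice
#'   `n_cells_per_group`).
#' @return a list with `profiles` and `ground_truth` (per-treatment
#'   effect vectors and per-plate offsets).
#' @export
make_multiplate <- function(config, plate_effect_sd = 0,
                            n_control_cells = 2 * config$n_cells_per_group) {
  stopifnot(inherits(config, "screen_config"))
  if (config$n_plates < 2) stop("n_plates must be >= 2")
  with_seed(config$seed, {
    feats <- sprintf("f%02d", seq_len(config$n_features))
    trt_ids <- sprintf("trt_%02d", seq_len(config$n_treatments))
    # one fixed random effect vector per treatment, shared across plates;
    # magnitudes vary around effect_size (0.5x-1.5x) as in real screens
    deltas <- lapply(trt_ids, function(id) {
      v <- stats::rnorm(config$n_features)
      v / sqrt(sum(v^2)) * config$effect_size * stats::runif(1, 0.5, 1.5)
    })
    names(deltas) <- trt_ids
    plate_ids <- sprintf("P%d", seq_len(config$n_plates))
    offsets <- lapply(plate_ids, function(p)
      stats::rnorm(config$n_features, sd = plate_effect_sd))
    names(offsets) <- plate_ids

    blocks <- list()
    for (p in plate_ids) {
      xc <- draw_population(n_control_cells, offsets[[p]],
                            config$correlation)
      colnames(xc) <- feats
      blocks[[length(blocks) + 1]] <- profile_table(
        scalar_meta(n_control_cells, treatment = "control", well = "W00",
                    plate = p, gene = "control", role = "control"),
        xc
      )
      for (id in trt_ids) {
        for (w in seq_len(config$n_wells)) {
          x <- draw_population(config$n_cells_per_group,
                               offsets[[p]] + deltas[[id]],
                               config$correlation)
          colnames(x) <- feats
          blocks[[length(blocks) + 1]] <- profile_table(
            scalar_meta(nrow(x), treatment = id,
                        well = sprintf("W%02d", w), plate = p,
                        gene = id, role = "perturbed"),
            x
          )
        }
      }
    }
    list(profiles = do.call(bind_profiles, blocks),
         ground_truth = list(deltas = deltas, plate_offsets = offsets,
                             config = unclass(config)))
  })
}

#' Generate a labelled screen for leave-one-gene-out evaluation
#'
#' Emulates a phenotype-annotated knockdown screen: a reference
#' population (negative-control cells, phenotype `"reference"`), and for
#' each phenotype a target distribution shifted on its own planted
#' feature subset. Each gene's cells are a mixture: for phenotype `k`, a
#' fraction `prop[g, k]` of the gene's cells is drawn from phenotype
#' `k`'s target distribution and carries that phenotype label; the
#' remaining cells are drawn from the reference distribution and labelled
#' `"unlabelled"`. Genes whose labelled fraction for a phenotype is
#' higher therefore sit distributionally closer to that phenotype's
#' target -- the planted monotone structure that leave-one-gene-out
#' scoring should recover.
#'
#' @param n_phenotypes number of phenotypes.
#' @param n_genes number of perturbed genes.
#' @param n_cells_per_gene cells per gene.
#' @param n_reference_cells reference (negative-control) cells.
#' @param n_features total features; each phenotype gets its own disjoint
#'   planted subset of `n_on_features`.
#' @param n_on_features planted subset size per phenotype.
#' @param effect_size shift (SD units) of each phenotype's target.
#' @param prop optional `n_genes x n_phenotypes` matrix of labelled-cell
#'   fractions (rows summing to at most 1); by default an evenly spaced
#'   gradient so gene ranks are planted.
#' @param seed root seed.
#' @return a list with `profiles` and `ground_truth` (the proportion
#'   matrix and per-phenotype planted subsets).
#' @export
generate_logo_screen <- function(n_phenotypes = 2, n_genes = 6,
                                 n_cells_per_gene = 120,
                                 n_reference_cells = 300,
                                 n_features = 20, n_on_features = 4,
                                 effect_size = 3, prop = NULL, seed = 1) {
  if (n_on_features * n_phenotypes > n_features)
    stop("phenotype subsets exceed the feature space")
  phen_ids <- sprintf("pheno_%d", seq_len(n_phenotypes))
  gene_ids <- sprintf("gene_%02d", seq_len(n_genes))
  if (is.null(prop)) {
    # planted gradient: labelled fraction decreases smoothly with gene
    # index, identically for every phenotype
    base <- seq(0.8, 0.15, length.out = n_genes) / n_phenotypes
    prop <- matrix(base, n_genes, n_phenotypes)
  }
  prop <- as.matrix(prop)
  if (any(rowSums(prop) > 1) || any(prop < 0))
    stop("`prop` rows must be nonnegative and sum to at most 1")
  dimnames(prop) <- list(gene_ids, phen_ids)

  with_seed(seed, {
    feats <- sprintf("f%02d", seq_len(n_features))
    subsets <- split(seq_len(n_on_features * n_phenotypes),
                     rep(seq_len(n_phenotypes), each = n_on_features))
    mus <- lapply(subsets, function(ix) {
      mu <- rep(0, n_features); mu[ix] <- effect_size; mu
    })

    blocks <- list()
    add <- function(n, mu, gene, phen) {
      if (n == 0) return(invisible())
      x <- draw_population(n, mu, 0)
      colnames(x) <- feats
      blocks[[length(blocks) + 1]] <<- profile_table(
        scalar_meta(n, treatment = gene, well = "W01", plate = "P1",
                    gene = gene, phenotype = phen),
        x
      )
    }
    add(n_reference_cells, rep(0, n_features), "none", "reference")
    for (g in seq_len(n_genes)) {
      n_lab <- round(prop[g, ] * n_cells_per_gene)
      n_rest <- n_cells_per_gene - sum(n_lab)
      for (k in seq_len(n_phenotypes))
        add(n_lab[k], mus[[k]], gene_ids[g], phen_ids[k])
      add(n_rest, rep(0, n_features), gene_ids[g], "unlabelled")
    }
    list(profiles = do.call(bind_profiles, blocks),
         ground_truth = list(
           prop = prop,
           phenotype_features = lapply(subsets, function(ix) feats[ix])))
  })
}

#' Serialise synthetic ground truth to JSON
#' @param ground_truth the `ground_truth` element of a generator result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
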
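# small in-code fixtures shared across test files

# a hand-sized profile table with a known metadata layout
tiny_profiles <- function() {
  profile_table(
    metadata = data.frame(
      Metadata_treatment = c("DMSO", "DMSO", "drugA", "drugA", "DMSO"),
      Metadata_plate = c("P1", "P2", "P1", "P2", "P1"),
      stringsAsFactors = FALSE
    ),
    features = matrix(as.numeric(1:10), 5, 2,
                      dimnames = list(NULL, c("f1", "f2")))
  )
}

# two-population table with a planted shift on the first n_on features
two_state_table <- function(n = 200, n_features = 10, n_on = 3,
                            effect = 3, seed = 1) {
  res <- generate_screen(screen_config(
    n_features = n_features, n_on_features = n_on, effect_size = effect,
    n_cells_per_group = n, efficacy_grid = 0.5, n_treatments = 1,
    seed = seed
  ))
  res
}

ref_pop <- function(screen) {
  select_population(screen$profiles, list(Metadata_role = "reference"))
}
tgt_pop <- function(screen) {
  select_population(screen$profiles, list(Metadata_role = "target"))
}
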
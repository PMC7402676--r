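options(littermix.quiet = TRUE)

ZERO_EFFECTS <- c(boreal = 0, temperate = 0, mediterranean = 0,
                  subtropical = 0, tropical = 0)

# memoise expensive generated objects across test files in one process
.littermix_cache <- new.env(parent = emptyenv())
cached <- function(key, fn) {
  if (is.null(.littermix_cache[[key]])) .littermix_cache[[key]] <- fn()
  .littermix_cache[[key]]
}

small_dataset <- function() cached("fixture", function() fixture_small(42))

default_dataset <- function() {
  cached("default65", function() generate_dataset(generator_config(seed = 7)))
}

effects_table <- function(lnrr, variance, ...) {
  tibble::tibble(lnrr = lnrr, variance = variance, ...)
}

# hand-rolled four-table dataset: two studies, one 2-species mixture each
tiny_manual_dataset <- function() {
  studies <- tibble::tibble(
    study_id = c("A", "B"),
    latitude = c(45.2, -12.1), longitude = c(8.1, 130.4),
    biome = c("temperate", "tropical"),
    mat = c(8.5, 26.1), map = c(900, 2100),
    forest_type = c("natural", "planted"),
    mesh_size = c(1.5, 0.5), selected = c(TRUE, TRUE))
  species <- tibble::tibble(
    species_id = c("A_s1", "A_s2", "B_s1", "B_s2"),
    study_id = c("A", "A", "B", "B"),
    life_form = c("tree", "tree", "tree", "shrub"),
    leaf_habit = c("deciduous", "evergreen", "deciduous", "deciduous"),
    N = c(14, 8, 12, 16), P = c(1.2, 0.8, 1.5, NA),
    K = c(5, 4, 6, 5), Ca = c(9, 7, 8, 10), Mg = c(2, 1.5, 2.2, 1.9),
    cellulose = c(240, 260, 250, 230), lignin = c(150, 290, 170, 140),
    C_N = c(34, 60, 40, 30), N_P = c(11.7, 10, 8, NA),
    lignin_N = c(10.7, 36.2, 14.2, 8.75))
  observations <- tibble::tibble(
    study_id = rep(c("A", "B"), each = 3),
    treatment_id = c("A_s1", "A_s2", "A_mix", "B_s1", "B_s2", "B_mix"),
    is_mixture = rep(c(FALSE, FALSE, TRUE), 2),
    harvest_index = 1L,
    harvest_time = rep(c(365, 300), each = 3),
    is_final_harvest = TRUE,
    mass_loss = c(40, 60, 55, 30, 50, 38),
    mass_loss_sd = c(5, 5, 4, 3, 6, 4),
    n_reps = 4L,
    conc_N = c(12, 9, 11, NA, NA, NA),
    conc_N_sd = c(1, 0.8, 1, NA, NA, NA),
    conc_P = NA_real_, conc_P_sd = NA_real_)
  compositions <- tibble::tibble(
    study_id = c("A", "A", "B", "B"),
    treatment_id = c("A_mix", "A_mix", "B_mix", "B_mix"),
    species_id = c("A_s1", "A_s2", "B_s1", "B_s2"),
    proportion = c(0.5, 0.5, 0.75, 0.25))
  validate_litter_dataset(list(studies = studies, species = species,
                               observations = observations,
                               compositions = compositions))
}
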
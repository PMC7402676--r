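#' Dataset schema and I/O for litter-mixture decomposition compilations
#'
#' A littermix dataset is a list of four tibbles mirroring the curated CSV
#' tables of a litterbag meta-analysis:
#'
#' * `studies` — one row per field study: `study_id`, `latitude`, `longitude`
#'   (decimal degrees), `biome` (boreal / temperate / mediterranean /
#'   subtropical / tropical), `mat` (mean annual temperature, degrees C),
#'   `map` (mean annual precipitation, mm), `forest_type` (natural / planted),
#'   `mesh_size` (litterbag mesh aperture, mm), and `selected` — the boolean
#'   flag marking the single experimental condition retained per species
#'   combination. Rows with `selected = FALSE` are kept but never analysed.
#' * `species` — one row per component litter species: `species_id`,
#'   `study_id`, `life_form` (tree / shrub / herb), `leaf_habit`
#'   (deciduous / evergreen), and initial chemical traits `N`, `P`, `K`,
#'   `Ca`, `Mg`, `cellulose`, `lignin` (mg g^-1) plus ratios `C_N`, `N_P`,
#'   `lignin_N` (unitless). Missing traits are empty cells.
#' * `observations` — one row per treatment x harvest: `study_id`,
#'   `treatment_id`, `is_mixture`, `harvest_index` (ordinal sampling
#'   occasion), `harvest_time` (days), `is_final_harvest`, `mass_loss`
#'   (% of initial dry mass), `mass_loss_sd`, `n_reps`, and optional
#'   nutrient concentrations at harvest `conc_N`, `conc_N_sd`, `conc_P`,
#'   `conc_P_sd` (mg g^-1).
#' * `compositions` — one row per mixture component: `study_id`,
#'   `treatment_id`, `species_id`, `proportion` (initial dry-mass fraction;
#'   fractions of one treatment sum to 1).
#'
#' @name litter_dataset
NULL

BIOMES <- c("boreal", "temperate", "mediterranean", "subtropical", "tropical")
FOREST_TYPES <- c("natural", "planted")
LIFE_FORMS <- c("tree", "shrub", "herb")
LEAF_HABITS <- c("deciduous", "evergreen")
TRAIT_NAMES <- c("N", "P", "K", "Ca", "Mg", "cellulose", "lignin",
                 "C_N", "N_P", "lignin_N")

dataset_col_types <- function() {
  list(
    studies = c(study_id = "character", latitude = "numeric",
                longitude = "numeric", biome = "character",
                mat = "numeric", map = "numeric",
                forest_type = "character", mesh_size = "numeric",
                selected = "logical"),
    species = c(species_id = "character", study_id = "character",
                life_form = "character", leaf_habit = "character",
                setNames(rep("numeric", length(TRAIT_NAMES)), TRAIT_NAMES)),
    observations = c(study_id = "character", treatment_id = "character",
                     is_mixture = "logical", harvest_index = "integer",
                     harvest_time = "numeric",
                     is_final_harvest = "logical", mass_loss = "numeric",
                     mass_loss_sd = "numeric", n_reps = "integer",
                     conc_N = "numeric", conc_N_sd = "numeric",
                     conc_P = "numeric", conc_P_sd = "numeric"),
    compositions = c(study_id = "character", treatment_id = "character",
                     species_id = "character", proportion = "numeric")
  )
}

required_columns <- function() {
  list(
    studies = c("study_id", "latitude", "longitude", "biome", "mat", "map",
                "forest_type", "mesh_size", "selected"),
    species = c("species_id", "study_id", "life_form", "leaf_habit",
                TRAIT_NAMES),
    observations = c("study_id", "treatment_id", "is_mixture",
                     "harvest_index", "harvest_time", "is_final_harvest",
                     "mass_loss", "mass_loss_sd", "n_reps"),
    compositions = c("study_id", "treatment_id", "species_id", "proportion")
  )
}

new_litter_dataset <- function(studies, species, observations, compositions,
                               truth = NULL) {
  structure(
    list(studies = tibble::as_tibble(studies),
         species = tibble::as_tibble(species),
         observations = tibble::as_tibble(observations),
         compositions = tibble::as_tibble(compositions),
         truth = truth),
    class = "litter_dataset"
  )
}

#' @export
print.litter_dataset <- function(x, ...) {
  cat("<litter_dataset>\n")
  cat(sprintf("  studies:      %d (%d selected)\n",
              nrow(x$studies), sum(x$studies$selected)))
  cat(sprintf("  species:      %d\n", nrow(x$species)))
  cat(sprintf("  observations: %d (%d mixture rows)\n",
              nrow(x$observations), sum(x$observations$is_mixture)))
  cat(sprintf("  compositions: %d rows / %d mixtures\n",
              nrow(x$compositions),
              dplyr::n_distinct(x$compositions$treatment_id)))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Read a curated litter-decomposition dataset from CSV tables
#'
#' Reads the four-table schema (see [litter_dataset]) and validates every
#' invariant before returning. Validation failures raise a schema error
#' naming the file, row and field concerned; nothing is silently dropped.
#'
#' @param path Directory containing `studies.csv`, `species.csv`,
#'   `observations.csv` and `compositions.csv`; alternatively pass the four
#'   file paths individually.
#' @param studies,species,observations,compositions Individual file paths,
#'   overriding `path`.
#' @param dispersion Either `"sd"` (default; `mass_loss_sd` and `conc_*_sd`
#'   columns hold standard deviations) or `"se"` (they hold standard errors,
#'   converted on read via `sd = se * sqrt(n_reps)`).
#' @return A validated `litter_dataset`.
#' @export
read_litter_dataset <- function(path = NULL, studies = NULL, species = NULL,
                                observations = NULL, compositions = NULL,
                                dispersion = c("sd", "se")) {
  dispersion <- match.arg(dispersion)
  files <- list(
    studies = studies %||% file.path(path, "studies.csv"),
    species = species %||% file.path(path, "species.csv"),
    observations = observations %||% file.path(path, "observations.csv"),
    compositions = compositions %||% file.path(path, "compositions.csv")
  )
  for (nm in names(files)) {
    if (!file.exists(files[[nm]])) {
      schema_abort(sprintf("Input table not found: %s", files[[nm]]),
                   file = files[[nm]])
    }
  }
  types <- dataset_col_types()
  req <- required_columns()
  tabs <- purrr::imap(files, function(f, nm) {
    # base read.csv: its double parser is correctly rounded, so numeric
    # values survive the CSV cycle bit-exactly
    hdr <- names(utils::read.csv(f, nrows = 1, check.names = FALSE))
    tab <- tibble::as_tibble(utils::read.csv(
      f, colClasses = types[[nm]][intersect(names(types[[nm]]), hdr)],
      na.strings = "", check.names = FALSE, stringsAsFactors = FALSE))
    miss_cols <- setdiff(req[[nm]], names(tab))
    if (length(miss_cols) > 0) {
      schema_abort(sprintf("Missing column(s) in %s: %s", basename(f),
                           paste(miss_cols, collapse = ", ")),
                   file = f, field = miss_cols[1])
    }
    tab
  })
  obs <- tabs$observations
  for (col in c("conc_N", "conc_N_sd", "conc_P", "conc_P_sd")) {
    if (!col %in% names(obs)) obs[[col]] <- NA_real_
  }
  if (dispersion == "se") {
    obs$mass_loss_sd <- obs$mass_loss_sd * sqrt(obs$n_reps)
    obs$conc_N_sd <- obs$conc_N_sd * sqrt(obs$n_reps)
    obs$conc_P_sd <- obs$conc_P_sd * sqrt(obs$n_reps)
  }
  ds <- new_litter_dataset(tabs$studies, tabs$species, obs, tabs$compositions)
  validate_litter_dataset(ds, files = purrr::map_chr(files, basename))
}

#' Validate a litter dataset against the schema invariants
#'
#' Checks enum membership, range invariants (mesh size positive, mass loss in
#' \[0, 100\], positive traits, proportions summing to one per mixture with at
#' least two components) and referential integrity across the four tables.
#'
#' @param dataset A `litter_dataset` (or plain list of the four tables).
#' @param files Optional named character vector of file names used in error
#'   messages.
#' @return The dataset, invisibly classed as `litter_dataset`.
#' @export
validate_litter_dataset <- function(dataset, files = NULL) {
  files <- files %||% c(studies = "studies", species = "species",
                        observations = "observations",
                        compositions = "compositions")
  st <- dataset$studies; sp <- dataset$species
  ob <- dataset$observations; cp <- dataset$compositions

  bad <- which(!st$biome %in% BIOMES)
  if (length(bad)) {
    schema_abort(sprintf("Unknown biome '%s' (must be one of %s).",
                         st$biome[bad[1]], paste(BIOMES, collapse = ", ")),
                 file = files[["studies"]], row = bad, field = "biome")
  }
  bad <- which(!st$forest_type %in% FOREST_TYPES)
  if (length(bad)) {
    schema_abort("forest_type must be 'natural' or 'planted'.",
                 file = files[["studies"]], row = bad, field = "forest_type")
  }
  bad <- which(!(st$mesh_size > 0))
  if (length(bad)) {
    schema_abort("mesh_size must be > 0 mm.",
                 file = files[["studies"]], row = bad, field = "mesh_size")
  }
  bad <- which(st$map < 0)
  if (length(bad)) {
    schema_abort("map (mean annual precipitation) must be >= 0 mm.",
                 file = files[["studies"]], row = bad, field = "map")
  }
  if (anyDuplicated(st$study_id)) {
    schema_abort("Duplicated study_id.", file = files[["studies"]],
                 row = which(duplicated(st$study_id)), field = "study_id")
  }

  bad <- which(!sp$life_form %in% LIFE_FORMS & !is.na(sp$life_form))
  if (length(bad)) {
    schema_abort("life_form must be tree, shrub or herb.",
                 file = files[["species"]], row = bad, field = "life_form")
  }
  bad <- which(!sp$leaf_habit %in% LEAF_HABITS & !is.na(sp$leaf_habit))
  if (length(bad)) {
    schema_abort("leaf_habit must be deciduous or evergreen.",
                 file = files[["species"]], row = bad, field = "leaf_habit")
  }
  for (tr in TRAIT_NAMES) {
    bad <- which(!is.na(sp[[tr]]) & sp[[tr]] <= 0)
    if (length(bad)) {
      schema_abort(sprintf("Trait %s must be > 0 when present.", tr),
                   file = files[["species"]], row = bad, field = tr)
    }
  }
  dangling <- setdiff(sp$study_id, st$study_id)
  if (length(dangling)) {
    schema_abort(sprintf("species table references unknown study_id '%s'.",
                         dangling[1]),
                 file = files[["species"]], field = "study_id")
  }

  bad <- which(ob$mass_loss < 0 | ob$mass_loss > 100)
  if (length(bad)) {
    schema_abort("mass_loss must lie in [0, 100] %.",
                 file = files[["observations"]], row = bad, field = "mass_loss")
  }
  bad <- which(ob$mass_loss_sd < 0)
  if (length(bad)) {
    schema_abort("mass_loss_sd must be >= 0.",
                 file = files[["observations"]], row = bad,
                 field = "mass_loss_sd")
  }
  bad <- which(ob$n_reps < 1)
  if (length(bad)) {
    schema_abort("n_reps must be >= 1 replicate litterbags.",
                 file = files[["observations"]], row = bad, field = "n_reps")
  }
  bad <- which(!(ob$harvest_time > 0))
  if (length(bad)) {
    schema_abort("harvest_time must be > 0 days.",
                 file = files[["observations"]], row = bad,
                 field = "harvest_time")
  }
  dangling <- setdiff(ob$study_id, st$study_id)
  if (length(dangling)) {
    schema_abort(sprintf("observations reference unknown study_id '%s'.",
                         dangling[1]),
                 file = files[["observations"]], field = "study_id")
  }

  if (nrow(cp) > 0) {
    bad <- which(cp$proportion <= 0 | cp$proportion > 1)
    if (length(bad)) {
      schema_abort("Each proportion must lie in (0, 1].",
                   file = files[["compositions"]], row = bad,
                   field = "proportion")
    }
    sums <- cp |>
      dplyr::summarise(total = sum(.data$proportion),
                       n = dplyr::n(), .by = "treatment_id")
    bad_sum <- sums$treatment_id[abs(sums$total - 1) > 1e-9]
    if (length(bad_sum)) {
      schema_abort(sprintf(
        "proportions sum != 1 for treatment '%s' (sum = %.6f).",
        bad_sum[1], sums$total[sums$treatment_id == bad_sum[1]][1]),
        file = files[["compositions"]], field = "proportion")
    }
    bad_n <- sums$treatment_id[sums$n < 2]
    if (length(bad_n)) {
      schema_abort(sprintf("mixture '%s' has fewer than 2 components.",
                           bad_n[1]),
                   file = files[["compositions"]], field = "species_id")
    }
    dangling <- setdiff(cp$species_id, sp$species_id)
    if (length(dangling)) {
      schema_abort(sprintf("compositions reference unknown species_id '%s'.",
                           dangling[1]),
                   file = files[["compositions"]], field = "species_id")
    }
    # every mixture observation must have a composition
    mix_tr <- unique(ob$treatment_id[ob$is_mixture])
    dangling <- setdiff(mix_tr, cp$treatment_id)
    if (length(dangling)) {
      schema_abort(sprintf(
        "mixture observation '%s' has no composition record.", dangling[1]),
        file = files[["observations"]], field = "treatment_id")
    }
  }
  if (!inherits(dataset, "litter_dataset")) {
    dataset <- new_litter_dataset(st, sp, ob, cp, truth = dataset$truth)
  }
  invisible(dataset)
}

#' Write a litter dataset to the four-table CSV schema
#'
#' Inverse of [read_litter_dataset()]; `read(write(x))` is field-for-field
#' identical to `x`. Ground truth attached by the generator is written to
#' `truth.json` alongside the tables.
#'
#' @param dataset A `litter_dataset`.
#' @param path Output directory, created if needed.
#' @return `path`, invisibly.
#' @export
write_litter_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  # render doubles at 17 significant digits so the CSV cycle is bit-exact
  fmt <- function(tab) {
    dplyr::mutate(tab, dplyr::across(
      dplyr::where(is.double),
      function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))))
  }
  readr::write_csv(fmt(dataset$studies), file.path(path, "studies.csv"),
                   progress = FALSE)
  readr::write_csv(fmt(dataset$species), file.path(path, "species.csv"),
                   progress = FALSE)
  readr::write_csv(fmt(dataset$observations),
                   file.path(path, "observations.csv"), progress = FALSE)
  readr::write_csv(fmt(dataset$compositions),
                   file.path(path, "compositions.csv"), progress = FALSE)
  if (!is.null(dataset$truth)) {
    jsonlite::write_json(
      purrr::map(dataset$truth, function(x) {
        if (inherits(x, "litter_config")) unclass(x) else x
      }),
      file.path(path, "truth.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(path)
}

# ---- categorical classifiers --------------------------------------------

#' Classify litterbag mesh aperture into decomposer-access classes
#'
#' Mesh size controls which decomposers reach the litter: fine mesh
#' (< 1 mm) excludes most mesofauna, coarse mesh (> 2 mm) admits
#' macrofauna. Boundaries at exactly 1 and 2 mm fall in the middle class,
#' so the three classes partition the positive line.
#'
#' @param mesh_size Mesh aperture in mm (> 0); vectorised.
#' @return Factor with levels `lt1`, `1to2`, `gt2`.
#' @export
#' @examples
#' classify_mesh(c(0.5, 1, 2, 5))
classify_mesh <- function(mesh_size) {
  check_number(mesh_size, "mesh_size", lower = 0, strict_lower = TRUE)
  out <- ifelse(mesh_size < 1, "lt1", ifelse(mesh_size <= 2, "1to2", "gt2"))
  factor(out, levels = c("lt1", "1to2", "gt2"))
}

#' Classify a mixture as equal- or non-equal-ratio
#'
#' @param proportions Numeric vector of initial mass fractions of one
#'   mixture (must sum to 1).
#' @return `"equal"` if all fractions are identical within 1e-9 after
#'   normalisation, else `"non_equal"`.
#' @export
classify_evenness <- function(proportions) {
  if (length(proportions) < 2) abort("A mixture needs >= 2 components.")
  p <- proportions / sum(proportions)
  if (max(p) - min(p) < 1e-9) "equal" else "non_equal"
}

#' Classify the leaf-habit composition of a mixture
#'
#' @param habits Character vector of component leaf habits
#'   (`"deciduous"` / `"evergreen"`).
#' @return `"decid_decid"`, `"ever_ever"`, `"decid_ever"`, or `NA` (with a
#'   logged note) when any habit is unknown.
#' @export
classify_functional_composition <- function(habits) {
  if (length(habits) < 2) abort("A mixture needs >= 2 components.")
  if (anyNA(habits) || !all(habits %in% LEAF_HABITS)) {
    log_note("labels", "unknown leaf habit; mixture excluded from the functional-composition grouping")
    return(NA_character_)
  }
  if (all(habits == "deciduous")) return("decid_decid")
  if (all(habits == "evergreen")) return("ever_ever")
  "decid_ever"
}

#' Classify forest stand structure from component life forms
#'
#' Distinguishes mixtures built only from canopy trees from those that also
#' include understory shrubs or herbs.
#'
#' @param life_forms Character vector of component life forms
#'   (`"tree"` / `"shrub"` / `"herb"`).
#' @return `"canopy_only"`, `"plus_understory"`, or `NA` when any life form
#'   is unknown (logged).
#' @export
classify_stand_structure <- function(life_forms) {
  if (length(life_forms) < 2) abort("A mixture needs >= 2 components.")
  if (anyNA(life_forms) || !all(life_forms %in% LIFE_FORMS)) {
    log_note("labels", "unknown life form; mixture excluded from the stand-structure grouping")
    return(NA_character_)
  }
  if (all(life_forms == "tree")) "canopy_only" else "plus_understory"
}

#' Build the full grouping-label table for every mixture treatment
#'
#' Joins study metadata, composition and species tables into one row of
#' categorical labels per mixture: biome, species richness, evenness,
#' functional composition, forest type, stand structure and mesh class.
#' Mixtures whose labels cannot be derived (unknown habit or life form)
#' carry `NA` in that column and are excluded from that grouping only.
#'
#' @param dataset A validated `litter_dataset`.
#' @return A tibble with one row per mixture treatment.
#' @export
label_mixtures <- function(dataset) {
  if (nrow(dataset$compositions) == 0) {
    return(tibble::tibble(
      treatment_id = character(), study_id = character(),
      biome = character(), richness = integer(), evenness = character(),
      functional_composition = character(), forest_type = character(),
      stand_structure = character(), mesh_class = character()
    ))
  }
  comp <- dataset$compositions |>
    dplyr::left_join(
      dplyr::select(dataset$species, "species_id", "leaf_habit", "life_form"),
      by = "species_id"
    )
  labs <- comp |>
    dplyr::summarise(
      study_id = .data$study_id[1],
      richness = dplyr::n(),
      evenness = classify_evenness(.data$proportion),
      functional_composition =
        classify_functional_composition(.data$leaf_habit),
      stand_structure = classify_stand_structure(.data$life_form),
      .by = "treatment_id"
    )
  labs |>
    dplyr::left_join(
      dplyr::select(dataset$studies, "study_id", "biome", "forest_type",
                    "mesh_size"),
      by = "study_id"
    ) |>
    dplyr::mutate(mesh_class = as.character(classify_mesh(.data$mesh_size))) |>
    dplyr::select("treatment_id", "study_id", "biome", "richness",
                  "evenness", "functional_composition", "forest_type",
                  "stand_structure", "mesh_class")
}
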
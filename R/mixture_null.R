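#' Additive-null expectation for a mixture response
#'
#' The expected ("control") value of a mixture response under purely
#' additive decomposition is the weighted mean of the component
#' single-species values, weighted by their initial mass proportions.
#'
#' @param component_means Numeric vector of single-species response values.
#' @param proportions Matching vector of mass fractions (sum to 1).
#' @return The proportion-weighted mean; always within the range of
#'   `component_means`.
#' @export
#' @examples
#' expected_value(c(40, 60), c(0.75, 0.25))
expected_value <- function(component_means, proportions) {
  if (length(component_means) != length(proportions)) {
    abort("`component_means` and `proportions` must have equal length.")
  }
  if (length(component_means) < 2) abort("Need >= 2 components.")
  if (abs(sum(proportions) - 1) > 1e-9) {
    abort("`proportions` must sum to 1.")
  }
  sum(proportions * component_means)
}

#' Dispersion of the additive-null expectation
#'
#' The single-species observations entering the null are independent
#' experimental units, so the standard deviation of the weighted mean
#' propagates as `sqrt(sum(p_i^2 * sd_i^2))`. The effective replicate count
#' is taken conservatively as the minimum across components.
#'
#' @param component_sds Standard deviations of component observations (>= 0).
#' @param component_ns Replicate counts (>= 1).
#' @param proportions Mass fractions (same length).
#' @return A list with `sd` and `n`.
#' @export
expected_dispersion <- function(component_sds, component_ns, proportions) {
  n <- length(proportions)
  if (length(component_sds) != n || length(component_ns) != n) {
    abort("All inputs must have equal length.")
  }
  check_number(component_sds, "component_sds", lower = 0)
  check_number(component_ns, "component_ns", lower = 1)
  list(sd = sqrt(sum(proportions^2 * component_sds^2)),
       n = min(component_ns))
}

# delta-method sd of relative release (%) given concentration sd
release_sd <- function(conc_sd, conc_0, mass_remaining_frac, mode) {
  if (mode == "amount_based") 100 * mass_remaining_frac * conc_sd / conc_0
  else 100 * conc_sd / conc_0
}

#' Build paired observed/expected records for every mixture observation
#'
#' Pairs each mixture x harvest observation with its additive-null
#' expectation computed from the component single-species observations at
#' the same sampling occasion (`harvest_index`). One pair is produced per
#' available response: `mass_loss` always, `N_release` / `P_release` when
#' concentrations are reported for the mixture, all its components, and the
#' components' initial concentrations (species traits). Single-species
#' observations are located by the convention `treatment_id == species_id`.
#'
#' The additive-null *mass loss* is attached to every pair (including
#' nutrient pairs) as `expected_mass_loss`, the decomposition-stage axis
#' used by [staged_meta()].
#'
#' For nutrient responses the null weights component releases by initial
#' nutrient mass fraction `p_i * conc0_i / sum(p_j * conc0_j)` by default
#' (a nutrient budget); `nutrient_weights = "dry_mass"` falls back to dry
#' mass proportions.
#'
#' Mixtures lacking a component observation at a harvest are skipped with a
#' logged reason, never silently; the skip table is attached as
#' `attr(, "skipped")`.
#'
#' @param dataset A validated `litter_dataset`.
#' @param nutrient_mode Passed to [nutrient_release()].
#' @param nutrient_weights `"nutrient_mass"` (default) or `"dry_mass"`.
#' @return A tibble of class `litter_pairs`: one row per mixture x harvest x
#'   response with observed/expected mean, sd, n, `expected_mass_loss`, and
#'   the grouping labels from [label_mixtures()].
#' @export
build_pairs <- function(dataset,
                        nutrient_mode = c("amount_based",
                                          "concentration_based"),
                        nutrient_weights = c("nutrient_mass", "dry_mass")) {
  nutrient_mode <- match.arg(nutrient_mode)
  nutrient_weights <- match.arg(nutrient_weights)

  empty <- tibble::tibble(
    study_id = character(), treatment_id = character(),
    response = character(), harvest_index = integer(),
    harvest_time = double(), is_final_harvest = logical(),
    observed_mean = double(), observed_sd = double(), observed_n = integer(),
    expected_mean = double(), expected_sd = double(), expected_n = integer(),
    expected_mass_loss = double(),
    biome = character(), richness = integer(), evenness = character(),
    functional_composition = character(), forest_type = character(),
    stand_structure = character(), mesh_class = character()
  )
  skipped <- tibble::tibble(treatment_id = character(),
                            harvest_index = integer(),
                            response = character(), reason = character())

  sel_studies <- dataset$studies$study_id[dataset$studies$selected]
  obs <- dplyr::filter(dataset$observations, .data$study_id %in% sel_studies)
  mix <- dplyr::filter(obs, .data$is_mixture)
  if (nrow(mix) == 0) {
    return(structure(empty, skipped = skipped,
                     class = c("litter_pairs", class(empty))))
  }

  singles <- obs |>
    dplyr::filter(!.data$is_mixture) |>
    dplyr::select("study_id", species_id = "treatment_id", "harvest_index",
                  s_ml = "mass_loss", s_ml_sd = "mass_loss_sd",
                  s_n = "n_reps",
                  s_conc_N = "conc_N", s_conc_N_sd = "conc_N_sd",
                  s_conc_P = "conc_P", s_conc_P_sd = "conc_P_sd")

  comp <- dataset$compositions |>
    dplyr::semi_join(mix, by = "treatment_id") |>
    dplyr::left_join(
      dplyr::select(dataset$species, "species_id",
                    trait_N = "N", trait_P = "P"),
      by = "species_id"
    )

  # one row per mixture-harvest x component, matched to the component's
  # single-species observation at the same sampling occasion
  comp_h <- mix |>
    dplyr::select("study_id", "treatment_id", "harvest_index") |>
    dplyr::inner_join(comp, by = c("study_id", "treatment_id"),
                      relationship = "many-to-many") |>
    dplyr::left_join(singles,
                     by = c("study_id", "species_id", "harvest_index"))

  miss <- comp_h |>
    dplyr::filter(is.na(.data$s_ml)) |>
    dplyr::distinct(.data$treatment_id, .data$harvest_index) |>
    dplyr::mutate(response = "all",
                  reason = "missing component single-species observation")
  if (nrow(miss) > 0) {
    skipped <- dplyr::bind_rows(skipped, miss)
    log_note("pairs", sprintf(
      "%d mixture-harvest combination(s) skipped: missing component observation",
      nrow(miss)))
    comp_h <- dplyr::anti_join(comp_h, miss,
                               by = c("treatment_id", "harvest_index"))
    mix <- dplyr::anti_join(mix, miss,
                            by = c("treatment_id", "harvest_index"))
  }
  if (nrow(mix) == 0) {
    return(structure(empty, skipped = skipped,
                     class = c("litter_pairs", class(empty))))
  }

  null_ml <- comp_h |>
    dplyr::summarise(
      expected_mean = sum(.data$proportion * .data$s_ml),
      expected_sd = sqrt(sum(.data$proportion^2 * .data$s_ml_sd^2)),
      expected_n = as.integer(min(.data$s_n)),
      .by = c("treatment_id", "harvest_index")
    )

  labels <- label_mixtures(dataset)

  ml_pairs <- mix |>
    dplyr::select("study_id", "treatment_id", "harvest_index",
                  "harvest_time", "is_final_harvest",
                  observed_mean = "mass_loss", observed_sd = "mass_loss_sd",
                  observed_n = "n_reps") |>
    dplyr::inner_join(null_ml, by = c("treatment_id", "harvest_index")) |>
    dplyr::mutate(response = "mass_loss",
                  expected_mass_loss = .data$expected_mean)

  # ---- nutrient responses ------------------------------------------------
  nut_pairs <- purrr::map(c(N = "N", P = "P"), function(nu) {
    conc_col <- paste0("conc_", nu)
    sd_col <- paste0("conc_", nu, "_sd")
    s_conc <- paste0("s_conc_", nu)
    s_sd <- paste0("s_conc_", nu, "_sd")
    trait <- paste0("trait_", nu)

    mix_nu <- dplyr::filter(mix, !is.na(.data[[conc_col]]))
    if (nrow(mix_nu) == 0) return(NULL)

    ch <- comp_h |>
      dplyr::semi_join(mix_nu, by = c("treatment_id", "harvest_index"))
    bad <- ch |>
      dplyr::filter(is.na(.data[[s_conc]]) | is.na(.data[[trait]])) |>
      dplyr::distinct(.data$treatment_id, .data$harvest_index) |>
      dplyr::mutate(response = paste0(nu, "_release"),
                    reason = "missing component concentration or initial trait")
    ch <- dplyr::anti_join(ch, bad, by = c("treatment_id", "harvest_index"))
    mix_nu <- dplyr::anti_join(mix_nu, bad,
                               by = c("treatment_id", "harvest_index"))

    if (nrow(ch) == 0) {
      return(list(pairs = NULL, skipped = bad))
    }
    ch <- ch |>
      dplyr::mutate(
        s_mrf = 1 - .data$s_ml / 100,
        s_rel = nutrient_release(.data[[trait]], .data[[s_conc]],
                                 pmax(.data$s_mrf, 1e-9),
                                 mode = nutrient_mode)$relative_release,
        s_rel_sd = release_sd(dplyr::coalesce(.data[[s_sd]], 0),
                              .data[[trait]], pmax(.data$s_mrf, 1e-9),
                              nutrient_mode),
        w_raw = if (nutrient_weights == "nutrient_mass") {
          .data$proportion * .data[[trait]]
        } else {
          .data$proportion
        }
      )
    exp_nu <- ch |>
      dplyr::summarise(
        conc0_mix = sum(.data$proportion * .data[[trait]]),
        expected_mean = sum(.data$w_raw * .data$s_rel) / sum(.data$w_raw),
        expected_sd = sqrt(sum((.data$w_raw / sum(.data$w_raw))^2 *
                                 .data$s_rel_sd^2)),
        expected_n = as.integer(min(.data$s_n)),
        .by = c("treatment_id", "harvest_index")
      )
    pr <- mix_nu |>
      dplyr::inner_join(exp_nu, by = c("treatment_id", "harvest_index")) |>
      dplyr::mutate(
        mrf = pmax(1 - .data$mass_loss / 100, 1e-9),
        observed_mean = nutrient_release(
          .data$conc0_mix, .data[[conc_col]], .data$mrf,
          mode = nutrient_mode)$relative_release,
        observed_sd = release_sd(dplyr::coalesce(.data[[sd_col]], 0),
                                 .data$conc0_mix, .data$mrf, nutrient_mode),
        observed_n = .data$n_reps,
        response = paste0(nu, "_release")
      ) |>
      dplyr::select("study_id", "treatment_id", "harvest_index",
                    "harvest_time", "is_final_harvest",
                    "observed_mean", "observed_sd", "observed_n",
                    "expected_mean", "expected_sd", "expected_n", "response")
    list(pairs = pr, skipped = bad)
  })
  for (res in nut_pairs) {
    if (!is.null(res) && nrow(res$skipped) > 0) {
      skipped <- dplyr::bind_rows(skipped, res$skipped)
      log_note("pairs", sprintf(
        "%d nutrient pair(s) skipped: missing concentrations or traits",
        nrow(res$skipped)))
    }
  }
  nut_tab <- dplyr::bind_rows(purrr::map(nut_pairs, "pairs"))
  if (nrow(nut_tab) > 0) {
    nut_tab <- nut_tab |>
      dplyr::left_join(
        dplyr::select(null_ml, "treatment_id", "harvest_index",
                      expected_mass_loss = "expected_mean"),
        by = c("treatment_id", "harvest_index")
      )
  }

  pairs <- dplyr::bind_rows(ml_pairs, nut_tab) |>
    dplyr::left_join(dplyr::select(labels, -"study_id"),
                     by = "treatment_id") |>
    dplyr::arrange(.data$study_id, .data$treatment_id, .data$harvest_index,
                   match(.data$response,
                         c("mass_loss", "N_release", "P_release"))) |>
    dplyr::select(dplyr::all_of(names(empty)))

  structure(pairs, skipped = skipped,
            class = c("litter_pairs", setdiff(class(pairs), "litter_pairs")))
}
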
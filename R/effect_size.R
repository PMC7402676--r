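#' Log response ratio of observed vs expected decomposition
#'
#' The effect-size metric of the meta-analysis: `ln(observed) -
#' ln(expected)`. Positive values mean the mixture decomposed (or released
#' nutrients) faster than the additive null predicts (synergy), negative
#' values slower (antagonism), zero exactly additive.
#'
#' @param observed_mean Mixture (treatment) mean (> 0); vectorised.
#' @param expected_mean Additive-null (control) mean (> 0).
#' @return lnRR, unitless.
#' @export
#' @examples
#' ln_response_ratio(60, 50) # log(1.2)
ln_response_ratio <- function(observed_mean, expected_mean) {
  check_number(observed_mean, "observed_mean", lower = 0, strict_lower = TRUE)
  check_number(expected_mean, "expected_mean", lower = 0, strict_lower = TRUE)
  log(observed_mean) - log(expected_mean)
}

#' Sampling variance of the log response ratio
#'
#' The standard large-sample variance of lnRR:
#' `v = s_e^2 / (N_e * xbar_e^2) + s_c^2 / (N_c * xbar_c^2)`,
#' where the `e` terms describe the observed mixture and the `c` terms the
#' additive-null control.
#'
#' @param sd_e,n_e,mean_e Treatment (mixture) sd, replicate count, mean.
#' @param sd_c,n_c,mean_c Control (additive null) sd, count, mean.
#' @return The sampling variance, strictly positive.
#' @export
lnrr_variance <- function(sd_e, n_e, mean_e, sd_c, n_c, mean_c) {
  check_number(sd_e, "sd_e", lower = 0)
  check_number(sd_c, "sd_c", lower = 0)
  check_number(n_e, "n_e", lower = 1)
  check_number(n_c, "n_c", lower = 1)
  check_number(mean_e, "mean_e", lower = 0, strict_lower = TRUE)
  check_number(mean_c, "mean_c", lower = 0, strict_lower = TRUE)
  v <- sd_e^2 / (n_e * mean_e^2) + sd_c^2 / (n_c * mean_c^2)
  if (any(v == 0)) {
    abort("degenerate pair: both standard deviations are zero.")
  }
  v
}

#' Back-transform lnRR to a percent change
#'
#' @param lnrr Log response ratio(s).
#' @return `(exp(lnrr) - 1) * 100`: the percent by which the mixture exceeds
#'   (positive) or falls short of (negative) the additive expectation.
#' @export
percent_effect <- function(lnrr) {
  check_number(lnrr, "lnrr")
  (exp(lnrr) - 1) * 100
}

#' Compute effect sizes for a table of paired observations
#'
#' Applies [ln_response_ratio()] and [lnrr_variance()] to every pair.
#' Pairs with a non-positive observed or expected mean (possible for
#' nutrient release under net immobilization) cannot enter a log ratio and
#' are excluded with a recorded reason, as are degenerate pairs with zero
#' total variance; exclusions are attached as `attr(, "exclusions")` and
#' logged, never silent.
#'
#' @param pairs A `litter_pairs` tibble from [build_pairs()].
#' @return A tibble of class `litter_effects`: one row per retained pair
#'   with `lnrr`, `variance`, response, `expected_mass_loss` and grouping
#'   labels.
#' @export
compute_effect_sizes <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  x <- tibble::as_tibble(pairs)
  reason <- rep(NA_character_, nrow(x))
  nonpos <- x$observed_mean <= 0 | x$expected_mean <= 0
  reason[nonpos] <- "non-positive mean (immobilization or zero release)"
  zerovar <- !nonpos &
    (x$observed_sd^2 / (x$observed_n) + x$expected_sd^2 / x$expected_n) == 0
  reason[zerovar] <- "degenerate pair: zero variance on both sides"
  excl <- x |>
    dplyr::mutate(reason = reason) |>
    dplyr::filter(!is.na(reason)) |>
    dplyr::select("study_id", "treatment_id", "harvest_index", "response",
                  "reason")
  if (nrow(excl) > 0) {
    log_note("effects", sprintf("%d pair(s) excluded from effect sizes (%s)",
                                nrow(excl),
                                paste(unique(excl$reason), collapse = "; ")))
  }
  keep <- x[is.na(reason), , drop = FALSE]
  out <- keep |>
    dplyr::mutate(
      lnrr = ln_response_ratio(.data$observed_mean, .data$expected_mean),
      variance = lnrr_variance(.data$observed_sd, .data$observed_n,
                               .data$observed_mean, .data$expected_sd,
                               .data$expected_n, .data$expected_mean)
    ) |>
    dplyr::select("study_id", "treatment_id", "response", "harvest_index",
                  "harvest_time", "is_final_harvest", "lnrr", "variance",
                  "expected_mass_loss", "biome", "richness", "evenness",
                  "functional_composition", "forest_type", "stand_structure",
                  "mesh_class")
  structure(out, exclusions = excl,
            class = c("litter_effects", setdiff(class(out), "litter_effects")))
}
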
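#' Mean character difference between two species
#'
#' Trait distance used inside Rao's quadratic entropy: the mean absolute
#' difference across the traits considered, `d_ij = (1/n) * sum_k |X_ik -
#' X_jk|`. With a single trait (the usual case here, since litter studies
#' rarely report the same full trait set) this is simply the absolute
#' difference.
#'
#' @param traits_i,traits_j Equal-length numeric vectors of trait values
#'   for species i and j.
#' @return The mean character difference (>= 0, trait units).
#' @export
#' @examples
#' mean_character_difference(c(4, 6), c(2, 10))
mean_character_difference <- function(traits_i, traits_j) {
  if (length(traits_i) != length(traits_j)) {
    abort("`traits_i` and `traits_j` must have equal length.")
  }
  if (length(traits_i) == 0) abort("Need at least one trait.")
  mean(abs(traits_i - traits_j))
}

#' Rao's quadratic entropy of a trait within a mixture
#'
#' Abundance-weighted expected trait difference between two randomly drawn
#' components: the upper-triangle sum `sum_{i<j} d_ij * p_i * p_j` over
#' species pairs (no factor 2), with `d_ij` the mean character difference
#' and `p` the initial mass fractions. Zero when all components share the
#' trait value; scales linearly with the trait's units.
#'
#' @param trait_values Trait value of each component (no missing values; a
#'   mixture with a missing trait has undefined divergence for that trait).
#' @param proportions Initial mass fractions (sum to 1).
#' @return Rao's Q, in trait units.
#' @export
#' @examples
#' rao_q(c(10, 2), c(0.5, 0.5)) # 8 * 0.25
rao_q <- function(trait_values, proportions) {
  s <- length(trait_values)
  if (s < 2) abort("Need >= 2 components.")
  if (length(proportions) != s) abort("Lengths differ.")
  if (abs(sum(proportions) - 1) > 1e-9) abort("`proportions` must sum to 1.")
  if (anyNA(trait_values)) abort("missing trait value: divergence undefined.")
  total <- 0
  for (i in seq_len(s - 1)) {
    for (j in seq(i + 1, s)) {
      total <- total +
        abs(trait_values[i] - trait_values[j]) * proportions[i] * proportions[j]
    }
  }
  total
}

#' Trait divergence of every mixture, one trait at a time
#'
#' Computes [rao_q()] per mixture and trait over the standard litter-trait
#' set. Mixtures with a missing trait value get `NA` for that trait (logged
#' once) and are excluded from that trait's regression only.
#'
#' @param dataset A validated `litter_dataset`.
#' @param traits Trait columns to use (default: all ten).
#' @return A tibble `treatment_id` x `trait` x `rao` (long format), with
#'   `n_traits = 1` recorded for transparency.
#' @export
trait_divergence <- function(dataset, traits = TRAIT_NAMES) {
  comp <- dataset$compositions |>
    dplyr::left_join(
      dplyr::select(dataset$species, "species_id",
                    dplyr::all_of(traits)),
      by = "species_id"
    )
  if (nrow(comp) == 0) {
    return(tibble::tibble(treatment_id = character(), trait = character(),
                          rao = double(), n_traits = integer()))
  }
  long <- comp |>
    tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait",
                        values_to = "value")
  out <- long |>
    dplyr::summarise(
      rao = if (anyNA(.data$value)) NA_real_ else
        rao_q(.data$value, .data$proportion),
      .by = c("treatment_id", "trait")
    ) |>
    dplyr::mutate(n_traits = 1L)
  n_miss <- sum(is.na(out$rao))
  if (n_miss > 0) {
    log_note("divergence", sprintf(
      "%d mixture-trait combination(s) with missing traits excluded from divergence",
      n_miss))
  }
  out
}

#' One mixture-effect value per study within a mass-loss window
#'
#' For the trait-divergence regressions, each study contributes a single
#' data point: the arithmetic mean of its mass-loss effect sizes whose
#' additive-null mass loss falls inside the window (default 10-40%, the
#' stage where non-additive effects are strongest). Studies with no
#' in-window effect are excluded.
#'
#' @param effects A `litter_effects` tibble (all harvests).
#' @param window Closed interval of expected mass loss, %.
#' @return Tibble `study_id`, `treatment_id`, `lnrr` (window mean per
#'   mixture treatment, averaged over in-window harvests), plus per-study
#'   means in `attr(, "per_study")`.
#' @export
window_effect_per_study <- function(effects, window = c(10, 40)) {
  x <- tibble::as_tibble(effects) |>
    dplyr::filter(.data$response == "mass_loss",
                  .data$expected_mass_loss >= window[1],
                  .data$expected_mass_loss <= window[2])
  per_treatment <- x |>
    dplyr::summarise(lnrr = mean(.data$lnrr),
                     .by = c("study_id", "treatment_id"))
  per_study <- x |>
    dplyr::summarise(lnrr = mean(.data$lnrr), .by = "study_id")
  structure(per_treatment, per_study = per_study)
}

#' Ordinary least-squares regression of mixture effects on a moderator
#'
#' Unweighted OLS of effect sizes on a continuous moderator (trait
#' divergence, MAT or MAP), reporting the slope, intercept, r-squared,
#' two-sided slope p-value and n.
#'
#' @param x Moderator values (finite; must vary).
#' @param y Effect sizes (same length, n >= 3).
#' @return A one-row tibble of class `litter_regression` with columns
#'   `slope`, `intercept`, `r_squared`, `p_value`, `n_points`; the `lm` fit
#'   is attached as `attr(, "fit")`.
#' @export
moderator_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need >= 3 points for a regression.")
  if (max(x) - min(x) < 1e-12) abort("degenerate regressor: x has zero variance.")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  # constant response: flat line fits perfectly but explains nothing
  r2 <- if (stats::var(y) == 0) 0 else sm$r.squared
  p <- if (stats::var(y) == 0) 1 else sm$coefficients[2, 4]
  out <- tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    p_value = p,
    n_points = length(x)
  )
  structure(out, fit = fit,
            class = c("litter_regression", setdiff(class(out),
                                                   "litter_regression")))
}

#' Regressions of window-mean mixture effects on trait divergence
#'
#' Runs one OLS regression per trait: study-level mean mixture effect
#' (from [window_effect_per_study()]) against the study-mean Rao divergence
#' of that trait across the study's mixtures. A leverage-sensitivity rerun
#' excluding the highest-divergence points is available via
#' `exclude_top_frac`.
#'
#' @param dataset A `litter_dataset`.
#' @param effects All-harvest `litter_effects` for the same dataset.
#' @param traits Traits to regress on.
#' @param window Mass-loss window passed to [window_effect_per_study()].
#' @param exclude_top_frac Fraction of the largest-divergence points to drop
#'   before refitting (0 = use all points).
#' @param min_points Minimum points to attempt a fit.
#' @return Tibble: one row per trait with slope, r2, p, n (traits with too
#'   few points are reported with NA estimates).
#' @export
divergence_regressions <- function(dataset, effects, traits = TRAIT_NAMES,
                                   window = c(10, 40),
                                   exclude_top_frac = 0, min_points = 3) {
  eff <- window_effect_per_study(effects, window = window)
  div <- trait_divergence(dataset, traits = traits)
  joined <- dplyr::inner_join(eff, div, by = "treatment_id",
                              relationship = "many-to-many")
  purrr::map(traits, function(tr) {
    d <- joined |>
      dplyr::filter(.data$trait == tr, !is.na(.data$rao)) |>
      dplyr::summarise(rao = mean(.data$rao), lnrr = mean(.data$lnrr),
                       .by = "study_id")
    if (exclude_top_frac > 0 && nrow(d) > 0) {
      cut <- stats::quantile(d$rao, 1 - exclude_top_frac)
      d <- dplyr::filter(d, .data$rao <= cut)
    }
    if (nrow(d) < min_points || length(unique(d$rao)) < 2) {
      return(tibble::tibble(trait = tr, slope = NA_real_,
                            intercept = NA_real_, r_squared = NA_real_,
                            p_value = NA_real_, n_points = nrow(d)))
    }
    reg <- moderator_regression(d$rao, d$lnrr)
    dplyr::bind_cols(tibble::tibble(trait = tr), tibble::as_tibble(reg))
  }) |>
    dplyr::bind_rows()
}
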
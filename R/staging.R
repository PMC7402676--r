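#' Decomposition-stage intervals of additive-null mass loss
#'
#' Stages are 10% increments of mass loss up to 70%, with a single final
#' interval from 70 to 100% (late-stage observations are scarce). The
#' intervals partition \[0, 100\].
#'
#' @return A tibble with `label`, `lower`, `upper`.
#' @export
mass_loss_intervals <- function() {
  lower <- c(seq(0, 60, by = 10), 70)
  upper <- c(seq(10, 70, by = 10), 100)
  tibble::tibble(
    label = paste0(lower, "-", upper),
    lower = lower,
    upper = upper
  )
}

#' Assign an observation to its decomposition-stage interval
#'
#' Binning is by the *expected* (additive-null) mass loss, the stage the
#' mixture would have reached were mixing purely additive. Bins are
#' half-open `[lower, upper)`; the final bin 70-100 is closed at 100.
#'
#' @param expected_mass_loss Additive-null mass loss, % in \[0, 100\];
#'   vectorised.
#' @return Factor of interval labels, ordered by stage.
#' @export
#' @examples
#' assign_interval(c(5, 35, 40, 100))
assign_interval <- function(expected_mass_loss) {
  check_number(expected_mass_loss, "expected_mass_loss",
               lower = 0, upper = 100)
  iv <- mass_loss_intervals()
  idx <- findInterval(expected_mass_loss, iv$lower)
  factor(iv$label[idx], levels = iv$label)
}

#' Per-stage meta-analysis across the decomposition trajectory
#'
#' Bins all-harvest effect sizes into the mass-loss intervals of
#' [mass_loss_intervals()] and pools each interval separately with a
#' bootstrap CI, tracing how the mixture effect develops as decomposition
#' proceeds. A study may contribute to several intervals through different
#' harvests; each pair lands in exactly one interval.
#'
#' @param effects A `litter_effects` tibble carrying `expected_mass_loss`
#'   (use all harvests, not only the final one).
#' @param response Which response to stage (default `"mass_loss"`).
#' @param collapse_study If `TRUE`, multiple harvests of one study falling
#'   in the same interval are first averaged so each study contributes at
#'   most one effect per interval (default `FALSE`: harvests kept as
#'   separate observations).
#' @param reps,seed,method,level As in [bootstrap_ci()].
#' @return An object of class `litter_staging`: a tibble with one row per
#'   interval (`k`, pooled lnRR, percent effect, CI, significance flags;
#'   intervals with k < 2 carry no CI, empty intervals k = 0).
#' @export
staged_meta <- function(effects, response = "mass_loss",
                        collapse_study = FALSE, reps = 4999, seed = 1,
                        method = c("bias_corrected", "percentile"),
                        level = 0.95) {
  method <- match.arg(method)
  x <- tibble::as_tibble(effects) |>
    dplyr::filter(.data$response == !!response)
  if (anyNA(x$expected_mass_loss)) {
    abort("effects must carry expected_mass_loss for staging.")
  }
  x$interval <- assign_interval(x$expected_mass_loss)
  if (collapse_study) {
    x <- x |>
      dplyr::summarise(
        lnrr = mean(.data$lnrr),
        variance = mean(.data$variance) / dplyr::n(),
        .by = c("study_id", "treatment_id", "interval")
      )
  }
  iv <- mass_loss_intervals()
  rows <- purrr::map(iv$label, function(lab) {
    d <- x[x$interval == lab, , drop = FALSE]
    k <- nrow(d)
    if (k == 0) {
      return(tibble::tibble(
        interval = lab, k = 0L, pooled_lnrr = NA_real_,
        percent_effect = NA_real_, tau_squared = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_,
        significant = FALSE, direction = NA_character_, low_n = TRUE))
    }
    m <- meta_analyze(d, reps = reps, seed = derive_seed(seed, match(lab, iv$label)),
                      method = method, level = level)
    tibble::tibble(
      interval = lab, k = as.integer(k), pooled_lnrr = m$pooled_lnrr,
      percent_effect = m$percent_effect, tau_squared = m$tau_squared,
      ci_low = m$ci_low, ci_high = m$ci_high,
      significant = m$significant, direction = m$direction, low_n = m$low_n)
  })
  out <- dplyr::bind_rows(rows)
  out$interval <- factor(out$interval, levels = iv$label)
  structure(out, response = response, reps = reps, seed = seed,
            class = c("litter_staging", setdiff(class(out), "litter_staging")))
}
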
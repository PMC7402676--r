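#' Tidy a pooled meta-analysis result
#'
#' @param x A `litter_meta` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate` (pooled lnRR), `percent_effect`,
#'   `conf.low`, `conf.high`, `significant`, `direction`.
#' @export
tidy.litter_meta <- function(x, ...) {
  tibble::tibble(
    estimate = x$pooled_lnrr,
    percent_effect = x$percent_effect,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    significant = x$significant,
    direction = x$direction
  )
}

#' Model-level summary of a pooled meta-analysis
#'
#' @param x A `litter_meta` object.
#' @param ... Unused.
#' @return One-row tibble: `k`, `tau.squared`, `q.total`, bootstrap
#'   settings.
#' @export
glance.litter_meta <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    tau.squared = x$tau_squared,
    q.total = x$q_total,
    reps = x$reps,
    method = x$method,
    level = x$level
  )
}

#' Tidy a subgroup analysis: one row per group
#'
#' @param x A `litter_subgroup` object.
#' @param ... Unused.
#' @return Tibble with `group`, `k`, `estimate`, `percent_effect`,
#'   `conf.low`, `conf.high`, `significant`, `direction`, `low_n`.
#' @export
tidy.litter_subgroup <- function(x, ...) {
  x$groups |>
    dplyr::select(
      "group", "k", estimate = "pooled_lnrr", "percent_effect",
      conf.low = "ci_low", conf.high = "ci_high", "significant",
      "direction", "low_n")
}

#' Heterogeneity partition of a subgroup analysis
#'
#' @param x A `litter_subgroup` object.
#' @param ... Unused.
#' @return One-row tibble with the Q partition (`q.total = q.between +
#'   q.within` under fixed-effect weights), degrees of freedom, the
#'   chi-squared `p.between`, and the pooled within-group tau-squared.
#' @export
glance.litter_subgroup <- function(x, ...) {
  tibble::tibble(
    by = x$by,
    groups = nrow(x$groups),
    k = sum(x$groups$k),
    q.total = x$q_total,
    q.between = x$q_between,
    q.within = x$q_within,
    df.between = x$df_between,
    df.within = x$df_within,
    p.between = x$p_between,
    tau.squared.pooled = x$tau_squared_pooled
  )
}

#' Tidy a moderator regression
#'
#' @param x A `litter_regression` one-row tibble.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, plus `r.squared`, `p.value`,
#'   `n`.
#' @export
tidy.litter_regression <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    r.squared = x$r_squared,
    p.value = x$p_value,
    n = x$n_points
  )
}
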
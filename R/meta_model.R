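#' DerSimonian-Laird estimate of between-study variance
#'
#' Method-of-moments estimator: with fixed-effect weights `w = 1/v`,
#' `Q = sum(w * (y - ybar_FE)^2)` and
#' `tau^2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))`.
#'
#' @param lnrr Effect sizes.
#' @param variance Their sampling variances (> 0).
#' @return The tau-squared estimate, with the Q statistic attached as
#'   `attr(, "Q")`. With fewer than two effects tau-squared is defined as 0
#'   and a warning is logged.
#' @export
#' @examples
#' dl_tau_squared(c(0.2, 0), c(0.01, 0.01)) # Q = 2, tau2 = 0.01
dl_tau_squared <- function(lnrr, variance) {
  stopifnot(length(lnrr) == length(variance))
  check_number(variance, "variance", lower = 0, strict_lower = TRUE)
  k <- length(lnrr)
  if (k < 2) {
    log_note("meta", "tau-squared undefined for k < 2; defined as 0")
    return(structure(0, Q = 0))
  }
  w <- 1 / variance
  theta_fe <- sum(w * lnrr) / sum(w)
  q <- sum(w * (lnrr - theta_fe)^2)
  c_denom <- sum(w) - sum(w^2) / sum(w)
  structure(max(0, (q - (k - 1)) / c_denom), Q = q)
}

#' Random-effects pooled estimate
#'
#' Inverse-variance weighted mean with random-effects weights
#' `w* = 1 / (v + tau^2)`.
#'
#' @param lnrr Effect sizes.
#' @param variance Sampling variances.
#' @param tau_squared Between-study variance (e.g. from
#'   [dl_tau_squared()]).
#' @return The pooled lnRR.
#' @export
pooled_effect <- function(lnrr, variance, tau_squared = 0) {
  stopifnot(length(lnrr) >= 1, length(lnrr) == length(variance))
  check_number(tau_squared, "tau_squared", lower = 0)
  w <- 1 / (variance + tau_squared)
  sum(w * lnrr) / sum(w)
}

# bootstrap pooled-effect distribution: resample effects with replacement,
# re-estimate DL tau2 and the RE pooled mean per replicate (vectorised)
boot_pooled <- function(lnrr, variance, reps) {
  k <- length(lnrr)
  idx <- matrix(sample.int(k, reps * k, replace = TRUE), reps, k)
  yy <- matrix(lnrr[idx], reps, k)
  vv <- matrix(variance[idx], reps, k)
  w <- 1 / vv
  sw <- rowSums(w)
  ybar <- rowSums(w * yy) / sw
  q <- rowSums(w * (yy - ybar)^2)
  c_denom <- sw - rowSums(w * w) / sw
  tau2 <- pmax(0, (q - (k - 1)) / c_denom)
  ws <- 1 / (vv + tau2)
  rowSums(ws * yy) / rowSums(ws)
}

# interval from a bootstrap distribution around a point estimate
boot_interval <- function(boot, est, method, level = 0.95) {
  alpha <- (1 - level) / 2
  if (max(boot) - min(boot) < 1e-15) {
    return(c(boot[1], boot[1]))
  }
  if (method == "percentile") {
    return(unname(stats::quantile(boot, c(alpha, 1 - alpha))))
  }
  # bias-corrected percentile (BC; MetaWin-style, no acceleration)
  p0 <- mean(boot < est)
  p0 <- min(max(p0, 1 / (length(boot) + 1)), length(boot) / (length(boot) + 1))
  z0 <- qnorm(p0)
  lo <- pnorm(2 * z0 + qnorm(alpha))
  hi <- pnorm(2 * z0 + qnorm(1 - alpha))
  unname(stats::quantile(boot, c(lo, hi)))
}

#' Bootstrap confidence interval for the pooled effect
#'
#' Resamples effect sizes with replacement at the observation level,
#' re-estimating the DerSimonian-Laird tau-squared and the random-effects
#' pooled mean in every replicate, and returns the 95% interval either as
#' raw percentiles or bias-corrected percentiles (default; the convention
#' of classic meta-analysis software).
#'
#' @param lnrr,variance Effect sizes and sampling variances (k >= 2).
#' @param reps Bootstrap replicates (>= 999; default 4999).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @param method `"bias_corrected"` (default) or `"percentile"`.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(lnrr, variance, reps = 4999, seed = 1,
                         method = c("bias_corrected", "percentile"),
                         level = 0.95) {
  method <- match.arg(method)
  if (length(lnrr) < 2) abort("cannot bootstrap a single observation.")
  if (reps < 999) abort("`reps` must be >= 999 for stable 2.5% tails.")
  tau2 <- dl_tau_squared(lnrr, variance)
  est <- pooled_effect(lnrr, variance, tau2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  boot <- boot_pooled(lnrr, variance, reps)
  ci <- boot_interval(boot, est, method, level)
  c(ci_low = ci[1], ci_high = ci[2])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

direction_of <- function(pooled, significant) {
  dplyr::case_when(
    significant & pooled > 0 ~ "synergistic",
    significant & pooled < 0 ~ "antagonistic",
    .default = "additive"
  )
}

#' Random-effects meta-analysis of a set of effect sizes
#'
#' Pools lnRR effect sizes under the DerSimonian-Laird random-effects model
#' and attaches a bootstrap confidence interval. The effect is judged
#' significant at alpha = 0.05 when the 95% CI excludes zero; direction is
#' `synergistic` (> 0), `antagonistic` (< 0) or `additive` (CI overlaps 0).
#'
#' @param effects A `litter_effects` tibble (or any data frame with `lnrr`
#'   and `variance` columns).
#' @param reps,seed,method,level Passed to [bootstrap_ci()].
#' @param min_k_ci Minimum number of effects required to report a CI;
#'   smaller sets are reported as point estimates flagged `low_n` (the
#'   convention "sample size too low to run statistics").
#' @return An object of class `litter_meta` with fields `k`, `pooled_lnrr`,
#'   `percent_effect`, `tau_squared`, `q_total`, `ci_low`, `ci_high`,
#'   `significant`, `direction`, `low_n`. Supports [tidy()], [glance()]
#'   and `print()`.
#' @export
meta_analyze <- function(effects, reps = 4999, seed = 1,
                         method = c("bias_corrected", "percentile"),
                         level = 0.95, min_k_ci = 2) {
  method <- match.arg(method)
  y <- effects$lnrr
  v <- effects$variance
  k <- length(y)
  if (k == 0) abort("no effect sizes to pool.")
  tau2 <- dl_tau_squared(y, v)
  est <- pooled_effect(y, v, tau2)
  if (k >= max(2, min_k_ci)) {
    ci <- bootstrap_ci(y, v, reps = reps, seed = seed, method = method,
                       level = level)
    low_n <- FALSE
  } else {
    ci <- c(ci_low = NA_real_, ci_high = NA_real_)
    low_n <- TRUE
  }
  signif <- !low_n && (ci[["ci_low"]] > 0 || ci[["ci_high"]] < 0)
  structure(
    list(k = k, pooled_lnrr = est, percent_effect = percent_effect(est),
         tau_squared = as.numeric(tau2), q_total = attr(tau2, "Q"),
         ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
         significant = signif,
         direction = direction_of(est, signif),
         low_n = low_n, reps = reps, seed = seed, method = method,
         level = level),
    class = "litter_meta"
  )
}

#' @export
print.litter_meta <- function(x, ...) {
  cat(sprintf(
    "<litter_meta> k = %d | lnRR = %.4f (%.1f%%) | tau^2 = %.4f\n",
    x$k, x$pooled_lnrr, x$percent_effect, x$tau_squared))
  if (x$low_n) {
    cat("  sample size too low to bootstrap a CI\n")
  } else {
    cat(sprintf("  95%% bootstrap CI [%.4f, %.4f] -> %s\n",
                x$ci_low, x$ci_high, x$direction))
  }
  invisible(x)
}

#' Subgroup meta-analysis with heterogeneity partitioning
#'
#' Splits effect sizes by a categorical moderator and partitions total
#' heterogeneity, computed with fixed-effect weights `1/v` so the identity
#' `Q_total = Q_between + Q_within` is exact, in the manner of a one-way
#' weighted ANOVA. `p_between` tests homogeneity of group means against a
#' chi-squared distribution with `groups - 1` df.
#'
#' Per-group pooled effects use random-effects weights with a single
#' tau-squared pooled across groups (estimated from `Q_within`; the classic
#' mixed-model convention), and per-group CIs come from a joint stratified
#' bootstrap that re-estimates the pooled tau-squared in every replicate.
#' Effects with a missing group label are dropped with a log note.
#'
#' @param effects A `litter_effects` tibble.
#' @param by Name of the grouping column (string).
#' @param reps,seed,method,level As in [bootstrap_ci()].
#' @param min_k_ci Groups with fewer effects are reported without a CI and
#'   flagged.
#' @return An object of class `litter_subgroup`: a per-group results tibble
#'   (`$groups`) plus `q_total`, `q_between`, `q_within`, `df_between`,
#'   `df_within`, `p_between`, `tau_squared_pooled`.
#' @export
subgroup_analysis <- function(effects, by, reps = 4999, seed = 1,
                              method = c("bias_corrected", "percentile"),
                              level = 0.95, min_k_ci = 2) {
  method <- match.arg(method)
  stopifnot(is.character(by), length(by) == 1, by %in% names(effects))
  x <- tibble::as_tibble(effects)
  drop <- is.na(x[[by]])
  if (any(drop)) {
    log_note("subgroup", sprintf(
      "%d effect(s) without a '%s' label dropped from this grouping",
      sum(drop), by))
    x <- x[!drop, , drop = FALSE]
  }
  if (nrow(x) == 0) abort("no labelled effects to analyse.")
  x$.group <- as.character(x[[by]])
  splits <- split(x, x$.group)
  k <- nrow(x)
  g <- length(splits)

  w_all <- 1 / x$variance
  grand <- sum(w_all * x$lnrr) / sum(w_all)
  q_total <- sum(w_all * (x$lnrr - grand)^2)
  per <- purrr::map(splits, function(d) {
    w <- 1 / d$variance
    m <- sum(w * d$lnrr) / sum(w)
    list(k = nrow(d), q = sum(w * (d$lnrr - m)^2),
         c_denom = sum(w) - sum(w^2) / sum(w), fe_mean = m)
  })
  q_within <- sum(purrr::map_dbl(per, "q"))
  q_between <- q_total - q_within
  df_between <- g - 1
  df_within <- k - g
  p_between <- if (df_between > 0) {
    stats::pchisq(q_between, df_between, lower.tail = FALSE)
  } else NA_real_
  c_sum <- sum(purrr::map_dbl(per, "c_denom"))
  tau2_pooled <- if (c_sum > 0) max(0, (q_within - df_within) / c_sum) else 0

  ests <- purrr::map_dbl(splits, function(d) {
    pooled_effect(d$lnrr, d$variance, tau2_pooled)
  })

  # joint stratified bootstrap, re-estimating the pooled tau2 per replicate
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mats <- purrr::map(splits, function(d) {
    kg <- nrow(d)
    idx <- matrix(sample.int(kg, reps * kg, replace = TRUE), reps, kg)
    list(y = matrix(d$lnrr[idx], reps, kg),
         v = matrix(d$variance[idx], reps, kg))
  })
  qs <- matrix(0, reps, g)
  cs <- matrix(0, reps, g)
  for (i in seq_len(g)) {
    w <- 1 / mats[[i]]$v
    sw <- rowSums(w)
    m <- rowSums(w * mats[[i]]$y) / sw
    qs[, i] <- rowSums(w * (mats[[i]]$y - m)^2)
    cs[, i] <- sw - rowSums(w * w) / sw
  }
  c_rep <- rowSums(cs)
  tau2_rep <- ifelse(c_rep > 0,
                     pmax(0, (rowSums(qs) - df_within) / c_rep), 0)
  cis <- purrr::imap(splits, function(d, nm) {
    i <- match(nm, names(splits))
    if (nrow(d) < max(2, min_k_ci)) {
      return(c(NA_real_, NA_real_))
    }
    ws <- 1 / (mats[[i]]$v + tau2_rep)
    boot <- rowSums(ws * mats[[i]]$y) / rowSums(ws)
    boot_interval(boot, ests[[nm]], method, level)
  })

  groups <- tibble::tibble(
    group = names(splits),
    k = purrr::map_dbl(per, "k"),
    pooled_lnrr = unname(ests),
    percent_effect = percent_effect(unname(ests)),
    ci_low = purrr::map_dbl(cis, 1),
    ci_high = purrr::map_dbl(cis, 2),
    q_group = purrr::map_dbl(per, "q")
  ) |>
    dplyr::mutate(
      low_n = is.na(.data$ci_low),
      significant = !.data$low_n &
        (.data$ci_low > 0 | .data$ci_high < 0),
      direction = direction_of(.data$pooled_lnrr, .data$significant)
    )

  structure(
    list(by = by, groups = groups, q_total = q_total,
         q_between = q_between, q_within = q_within,
         df_between = df_between, df_within = df_within,
         p_between = p_between, tau_squared_pooled = tau2_pooled,
         reps = reps, seed = seed, method = method),
    class = "litter_subgroup"
  )
}

#' @export
print.litter_subgroup <- function(x, ...) {
  cat(sprintf("<litter_subgroup> by %s: Q_between = %.3f (df = %d, p = %.4g)\n",
              x$by, x$q_between, x$df_between, x$p_between))
  print(x$groups)
  invisible(x)
}
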
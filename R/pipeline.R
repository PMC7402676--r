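#' Analysis configuration for the full pipeline
#'
#' @param reps Bootstrap replicates for every pooled CI (default 4999).
#' @param seed Master seed; every stochastic sub-analysis derives its own
#'   stream from it, so the whole report is a pure function of
#'   `(dataset, config)`.
#' @param method Bootstrap CI flavour, see [bootstrap_ci()].
#' @param nutrient_mode,nutrient_weights Passed to [build_pairs()].
#' @param divergence_window Mass-loss window for the trait-divergence
#'   regressions (closed, %).
#' @param min_k_subgroup Subgroups smaller than this are reported without a
#'   CI and flagged (the "sample size too low to run statistics"
#'   convention).
#' @return A `litter_run_config` list.
#' @export
pipeline_config <- function(reps = 4999, seed = 1L,
                            method = c("bias_corrected", "percentile"),
                            nutrient_mode = c("amount_based",
                                              "concentration_based"),
                            nutrient_weights = c("nutrient_mass",
                                                 "dry_mass"),
                            divergence_window = c(10, 40),
                            min_k_subgroup = 3) {
  structure(
    list(reps = reps, seed = as.integer(seed), method = match.arg(method),
         nutrient_mode = match.arg(nutrient_mode),
         nutrient_weights = match.arg(nutrient_weights),
         divergence_window = divergence_window,
         min_k_subgroup = min_k_subgroup),
    class = "litter_run_config")
}

meta_to_row <- function(m) {
  tibble::tibble(
    k = m$k, pooled_lnrr = m$pooled_lnrr, percent_effect = m$percent_effect,
    tau_squared = m$tau_squared, ci_low = m$ci_low, ci_high = m$ci_high,
    significant = m$significant, direction = m$direction, low_n = m$low_n)
}

#' Mixture vs single-species nutrient release summary
#'
#' Compares mean relative (% of the initial amount) and absolute
#' (mg per g initial litter) N and P release between mixture and
#' single-species observations at the final harvest, with a Welch
#' two-sample test on the observation-level means.
#'
#' @param dataset A validated `litter_dataset`.
#' @param nutrient_mode Accounting mode, see [nutrient_release()].
#' @param final_only Restrict to final-harvest observations (default).
#' @return A tibble with one row per nutrient x group plus Welch p-values
#'   for the relative and absolute contrasts (`NA` when a group is empty).
#' @export
nutrient_summary <- function(dataset,
                             nutrient_mode = c("amount_based",
                                               "concentration_based"),
                             final_only = TRUE) {
  nutrient_mode <- match.arg(nutrient_mode)
  sel <- dataset$studies$study_id[dataset$studies$selected]
  obs <- dataset$observations |>
    dplyr::filter(.data$study_id %in% sel)
  if (final_only) obs <- dplyr::filter(obs, .data$is_final_harvest)

  conc0_mix <- dataset$compositions |>
    dplyr::left_join(dplyr::select(dataset$species, "species_id", "N", "P"),
                     by = "species_id") |>
    dplyr::summarise(conc0_N = sum(.data$proportion * .data$N),
                     conc0_P = sum(.data$proportion * .data$P),
                     .by = "treatment_id")
  conc0_single <- dplyr::select(dataset$species,
                                treatment_id = "species_id",
                                conc0_N = "N", conc0_P = "P")
  conc0 <- dplyr::bind_rows(conc0_mix, conc0_single)
  obs <- dplyr::left_join(obs, conc0, by = "treatment_id")

  rows <- purrr::map(c(N = "N", P = "P"), function(nu) {
    conc_col <- paste0("conc_", nu)
    c0_col <- paste0("conc0_", nu)
    d <- obs |>
      dplyr::filter(!is.na(.data[[conc_col]]), !is.na(.data[[c0_col]]),
                    .data[[c0_col]] > 0, .data$mass_loss < 100)
    if (nrow(d) == 0) return(NULL)
    rel <- nutrient_release(d[[c0_col]], d[[conc_col]],
                            1 - d$mass_loss / 100, mode = nutrient_mode)
    d$relative <- rel$relative_release
    d$absolute <- rel$absolute_release
    mix <- d[d$is_mixture, ]
    sng <- d[!d$is_mixture, ]
    welch <- function(a, b) {
      if (length(a) < 2 || length(b) < 2) return(NA_real_)
      stats::t.test(a, b)$p.value
    }
    tibble::tibble(
      nutrient = nu,
      group = c("mixture", "single"),
      n = c(nrow(mix), nrow(sng)),
      mean_relative_release = c(mean(mix$relative), mean(sng$relative)),
      mean_absolute_release = c(mean(mix$absolute), mean(sng$absolute)),
      p_relative = welch(mix$relative, sng$relative),
      p_absolute = welch(mix$absolute, sng$absolute))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(nutrient = character(), group = character(),
                          n = integer(), mean_relative_release = double(),
                          mean_absolute_release = double(),
                          p_relative = double(), p_absolute = double())
  }
  out
}

subgroup_to_rows <- function(sg, factor_name, response) {
  dplyr::bind_cols(
    tibble::tibble(factor = factor_name, response = response),
    sg$groups)
}

subgroup_to_het <- function(sg, factor_name, response) {
  tibble::tibble(
    factor = factor_name, response = response,
    q_total = sg$q_total, q_between = sg$q_between, q_within = sg$q_within,
    df_between = sg$df_between, df_within = sg$df_within,
    p_between = sg$p_between, tau_squared_pooled = sg$tau_squared_pooled)
}

#' Run the full litter-mixture meta-analysis pipeline
#'
#' Orchestrates the whole analysis: paired observed/expected records,
#' effect sizes, overall and per-biome random-effects pooling per response
#' at the final harvest, categorical subgroup analyses for mass loss
#' (richness, evenness, functional composition, forest type x stand
#' structure, mesh class), decomposition-stage meta-analysis across all
#' harvests, trait-divergence and climate regressions, and the
#' mixture-vs-single nutrient release summary. Deterministic given the
#' config seed. Every input observation is either analysed or excluded with
#' a recorded reason.
#'
#' @param dataset A validated `litter_dataset`.
#' @param config A [pipeline_config()].
#' @return An object of class `litter_report` (a list of result tibbles
#'   plus a `counts` section and the config echo). See [write_report()].
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  reps <- config$reps
  method <- config$method
  seed <- config$seed

  pairs <- build_pairs(dataset, nutrient_mode = config$nutrient_mode,
                       nutrient_weights = config$nutrient_weights)
  skipped <- attr(pairs, "skipped")
  effects <- compute_effect_sizes(pairs)
  exclusions <- attr(effects, "exclusions")
  eff_final <- dplyr::filter(effects, .data$is_final_harvest)

  responses <- c("mass_loss", "N_release", "P_release")

  overall <- purrr::imap(setNames(responses, responses), function(rs, nm) {
    d <- dplyr::filter(eff_final, .data$response == rs)
    if (nrow(d) == 0) return(NULL)
    m <- meta_analyze(d, reps = reps,
                      seed = derive_seed(seed, match(rs, responses)),
                      method = method)
    dplyr::bind_cols(tibble::tibble(response = rs), meta_to_row(m))
  }) |>
    dplyr::bind_rows()

  biome_rows <- list(); het_rows <- list()
  for (rs in responses) {
    d <- dplyr::filter(eff_final, .data$response == rs)
    if (nrow(d) < 2 || dplyr::n_distinct(d$biome) < 2) next
    sg <- subgroup_analysis(d, "biome", reps = reps,
                            seed = derive_seed(seed, 10 + match(rs, responses)),
                            method = method,
                            min_k_ci = config$min_k_subgroup)
    biome_rows[[rs]] <- subgroup_to_rows(sg, "biome", rs)
    het_rows[[rs]] <- subgroup_to_het(sg, "biome", rs)
  }

  eff_ml <- dplyr::filter(eff_final, .data$response == "mass_loss")
  cat_factors <- c("richness", "evenness", "functional_composition",
                   "mesh_class")
  sub_rows <- list(); i <- 0
  for (fc in cat_factors) {
    i <- i + 1
    d <- eff_ml
    d[[fc]] <- as.character(d[[fc]])
    if (nrow(d) < 2 || dplyr::n_distinct(d[[fc]], na.rm = TRUE) < 2) next
    sg <- subgroup_analysis(d, fc, reps = reps,
                            seed = derive_seed(seed, 20 + i),
                            method = method,
                            min_k_ci = config$min_k_subgroup)
    sub_rows[[fc]] <- subgroup_to_rows(sg, fc, "mass_loss")
    het_rows[[fc]] <- subgroup_to_het(sg, fc, "mass_loss")
  }
  # forest type x stand structure: natural/planted crossed with
  # canopy-only vs + understory
  d <- eff_ml |>
    dplyr::mutate(forest_stand = ifelse(
      is.na(.data$stand_structure), NA_character_,
      paste(.data$forest_type, .data$stand_structure, sep = ":")))
  if (nrow(d) >= 2 && dplyr::n_distinct(d$forest_stand, na.rm = TRUE) >= 2) {
    sg <- subgroup_analysis(d, "forest_stand", reps = reps,
                            seed = derive_seed(seed, 30), method = method,
                            min_k_ci = config$min_k_subgroup)
    sub_rows[["forest_stand"]] <- subgroup_to_rows(sg, "forest_stand",
                                                   "mass_loss")
    het_rows[["forest_stand"]] <- subgroup_to_het(sg, "forest_stand",
                                                  "mass_loss")
  }

  staging <- purrr::imap(setNames(responses, responses), function(rs, nm) {
    d <- dplyr::filter(effects, .data$response == rs)
    if (nrow(d) == 0) return(NULL)
    st <- staged_meta(effects, response = rs, reps = reps,
                      seed = derive_seed(seed, 40 + match(rs, responses)),
                      method = method)
    dplyr::bind_cols(tibble::tibble(response = rs), tibble::as_tibble(st))
  }) |>
    dplyr::bind_rows()

  div_tab <- suppressMessages(trait_divergence(dataset))
  div_reg <- divergence_regressions(dataset, effects,
                                    window = config$divergence_window)

  clim <- eff_ml |>
    dplyr::left_join(dplyr::select(dataset$studies, "study_id", "mat",
                                   "map"),
                     by = "study_id")
  clim_reg <- purrr::map(c(mat = "mat", map = "map"), function(v) {
    x <- clim[[v]]
    if (sum(is.finite(x) & is.finite(clim$lnrr)) < 3 ||
        length(unique(x[is.finite(x)])) < 2) {
      return(NULL)
    }
    dplyr::bind_cols(tibble::tibble(moderator = toupper(v)),
                     tibble::as_tibble(moderator_regression(x, clim$lnrr)))
  }) |>
    dplyr::bind_rows()

  nutrients <- nutrient_summary(dataset,
                                nutrient_mode = config$nutrient_mode)

  counts <- list(
    n_studies = sum(dataset$studies$selected),
    n_observations = nrow(dataset$observations),
    n_mixture_observations = sum(dataset$observations$is_mixture),
    pairs_built = pairs |>
      dplyr::count(.data$response, name = "n"),
    pairs_built_final = pairs |>
      dplyr::filter(.data$is_final_harvest) |>
      dplyr::count(.data$response, name = "n"),
    pairs_skipped = skipped |>
      dplyr::count(.data$response, .data$reason, name = "n"),
    effects_excluded = exclusions |>
      dplyr::count(.data$response, .data$reason, name = "n"),
    effects_analyzed = effects |>
      dplyr::count(.data$response, name = "n")
  )

  structure(
    list(counts = counts,
         overall = overall,
         subgroups = dplyr::bind_rows(c(biome_rows, sub_rows)),
         heterogeneity = dplyr::bind_rows(het_rows),
         staging = staging,
         regressions = list(divergence = div_reg, climate = clim_reg),
         divergence = div_tab,
         nutrients = nutrients,
         pairs = tibble::as_tibble(pairs),
         effects = tibble::as_tibble(effects),
         config = unclass(config)),
    class = "litter_report")
}

#' @export
print.litter_report <- function(x, ...) {
  cat("<litter_report>\n")
  cat(sprintf("  %d studies | %d pairs | %d effect sizes\n",
              x$counts$n_studies, sum(x$counts$pairs_built$n),
              sum(x$counts$effects_analyzed$n)))
  cat("  overall (final harvest):\n")
  print(x$overall)
  invisible(x)
}

#' Serialize a pipeline report to a canonical JSON string
#'
#' The serialization is stable: running the pipeline twice on the same
#' dataset and config yields byte-identical JSON.
#'
#' @param report A `litter_report`.
#' @return A JSON string (class `json`).
#' @export
report_json <- function(report) {
  payload <- list(
    counts = report$counts,
    overall = report$overall,
    subgroups = report$subgroups,
    heterogeneity = report$heterogeneity,
    staging = report$staging,
    regressions = report$regressions,
    nutrients = report$nutrients,
    config = report$config
  )
  jsonlite::toJSON(payload, dataframe = "columns", auto_unbox = TRUE,
                   digits = NA, null = "null", na = "null")
}

#' Write a pipeline report and its audit tables to disk
#'
#' Emits `report.json` (the full serialized report) plus the audit tables
#' `pairs.csv`, `effects.csv`, `staging_results.csv`, `regressions.csv`,
#' `divergence.csv` (per-mixture, per-trait Rao values) and
#' `meta_results.json` (overall + subgroup pooled results).
#'
#' @param report A `litter_report`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_json(report), file.path(path, "report.json"))
  readr::write_csv(report$pairs, file.path(path, "pairs.csv"),
                   progress = FALSE)
  readr::write_csv(report$effects, file.path(path, "effects.csv"),
                   progress = FALSE)
  readr::write_csv(report$staging, file.path(path, "staging_results.csv"),
                   progress = FALSE)
  readr::write_csv(report$divergence, file.path(path, "divergence.csv"),
                   progress = FALSE)
  readr::write_csv(
    dplyr::bind_rows(
      dplyr::mutate(report$regressions$divergence,
                    moderator = paste0("divergence_", .data$trait),
                    .keep = "unused"),
      report$regressions$climate),
    file.path(path, "regressions.csv"), progress = FALSE)
  jsonlite::write_json(
    list(overall = report$overall, subgroups = report$subgroups,
         heterogeneity = report$heterogeneity),
    file.path(path, "meta_results.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
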
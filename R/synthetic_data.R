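#' Configuration for the synthetic litterbag-compilation generator
#'
#' Defaults are sized to the shape of a global litter-mixture compilation:
#' 65 studies across five forest biomes yielding roughly 284 final-harvest
#' mixture observations, with the richness mix heavily weighted to
#' two-species mixtures and about four fifths of mixtures at equal mass
#' ratios. See the methods vignette for the rationale behind every default.
#'
#' @param n_studies Number of field studies.
#' @param biome_mix Named proportions over the five biomes (sum to 1).
#' @param true_effects Named biome -> true mass-loss lnRR applied inside the
#'   interaction window.
#' @param tau Between-study sd of the study-level effect (lnRR units).
#' @param interaction_window `(lower, upper)` % of additive-null mass loss
#'   inside which the non-additive interaction acts.
#' @param divergence_slope Named numeric: added lnRR per unit Rao divergence,
#'   per trait (empty = no trait-linked interaction).
#' @param n_reps Replicate litterbags per treatment x harvest.
#' @param measurement_cv Within-study coefficient of variation of replicate
#'   litterbags (lognormal, multiplicative).
#' @param harvest_schedule Candidate study durations, days: each study draws
#'   its total exposure time from this vector (litterbag studies vary widely
#'   in duration, which is what spreads final harvests across decomposition
#'   stages).
#' @param harvests_mix Sampling probabilities over `harvest_schedule`.
#' @param harvests_per_study `(min, max)` number of harvests per study,
#'   drawn uniformly; harvests are evenly spaced over the study duration.
#' @param richness_mix Named proportions over mixture richness levels.
#' @param evenness_fraction Fraction of mixtures at exactly equal ratios.
#' @param mixtures_per_study `(min, max)` mixtures drawn uniformly per study.
#' @param nutrient_fraction Named fractions of studies reporting N and P
#'   concentrations (P is measured only where N is).
#' @param imm_phase,imm_amp Immobilization phase length (as mass-loss
#'   fraction) and amplitude per nutrient: the remaining-amount fraction
#'   rises to `1 + amp` while mass loss < phase, then declines to 0.
#' @param nutrient_shift Named percentage points added to mixture relative
#'   nutrient release over the additive null (the nutrient-cycling analogue
#'   of the mass-loss interaction).
#' @param nutrient_shift_sd Between-study sd of the nutrient shift
#'   (percentage points); nutrient interactions vary strongly among
#'   studies, which is what leaves a small mean P shift non-significant.
#' @param k_scale Decay-rate scale: species decay constant
#'   `k = k_scale / lignin:N * lognormal noise` per year, so low-quality
#'   (high lignin:N) litter decomposes slower.
#' @param prob_missing_trait Per species x trait probability that a
#'   non-nitrogen trait goes unreported.
#' @param seed Default integer seed for [generate_dataset()].
#' @return A `litter_config` list.
#' @export
generator_config <- function(
    n_studies = 65,
    biome_mix = c(boreal = 0.08, temperate = 0.38, mediterranean = 0.05,
                  subtropical = 0.34, tropical = 0.15),
    true_effects = c(boreal = 0, temperate = 0.08, mediterranean = 0,
                     subtropical = 0.06, tropical = 0),
    tau = 0.05,
    interaction_window = c(10, 40),
    divergence_slope = numeric(),
    n_reps = 4L,
    measurement_cv = 0.1,
    harvest_schedule = c(91, 182, 365, 730),
    harvests_mix = c(0.10, 0.20, 0.35, 0.35),
    harvests_per_study = c(1, 4),
    richness_mix = c(`2` = 196, `3` = 41, `4` = 34, `6` = 13) / 284,
    evenness_fraction = 225 / 284,
    mixtures_per_study = c(2, 7),
    nutrient_fraction = c(N = 26 / 65, P = 13 / 65),
    imm_phase = c(N = 0.2, P = 0),
    imm_amp = c(N = 0.15, P = 0),
    nutrient_shift = c(N = 15, P = 2),
    nutrient_shift_sd = c(N = 10, P = 8),
    k_scale = 8,
    prob_missing_trait = 0.05,
    seed = 1L) {
  cfg <- list(
    n_studies = n_studies, biome_mix = biome_mix,
    true_effects = true_effects, tau = tau,
    interaction_window = interaction_window,
    divergence_slope = divergence_slope, n_reps = as.integer(n_reps),
    measurement_cv = measurement_cv, harvest_schedule = harvest_schedule,
    harvests_mix = harvests_mix, harvests_per_study = harvests_per_study,
    richness_mix = richness_mix,
    evenness_fraction = evenness_fraction,
    mixtures_per_study = mixtures_per_study,
    nutrient_fraction = nutrient_fraction,
    imm_phase = imm_phase, imm_amp = imm_amp,
    nutrient_shift = nutrient_shift,
    nutrient_shift_sd = nutrient_shift_sd, k_scale = k_scale,
    prob_missing_trait = prob_missing_trait, seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "litter_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_studies < 0) abort("n_studies must be >= 0.")
  if (abs(sum(cfg$biome_mix) - 1) > 1e-9) abort("biome_mix must sum to 1.")
  if (!setequal(names(cfg$biome_mix), BIOMES)) {
    abort("biome_mix must name the five biomes.")
  }
  if (abs(sum(cfg$richness_mix) - 1) > 1e-9) {
    abort("richness_mix must sum to 1.")
  }
  if (cfg$tau < 0) abort("tau must be >= 0.")
  if (cfg$measurement_cv <= 0) abort("measurement_cv must be > 0.")
  w <- cfg$interaction_window
  if (length(w) != 2 || w[1] < 0 || w[2] > 100 || w[1] >= w[2]) {
    abort("infeasible config: interaction_window must lie within [0, 100].")
  }
  if (length(cfg$harvests_mix) != length(cfg$harvest_schedule)) {
    abort("harvests_mix must match harvest_schedule in length.")
  }
  if (cfg$harvests_per_study[1] < 1 ||
      cfg$harvests_per_study[2] < cfg$harvests_per_study[1]) {
    abort("harvests_per_study must be an increasing pair of counts >= 1.")
  }
  invisible(cfg)
}

# remaining-amount fraction of a nutrient as a function of mass-loss
# fraction m: immobilization builds to (1 + amp) while m < phase, then the
# amount declines linearly to zero at complete mass loss
nutrient_amount_fraction <- function(m, amp, phase) {
  ifelse(phase > 0 & m < phase,
         1 + amp * m / phase,
         (1 + amp) * pmax(1 - m, 0) / (1 - phase))
}

biome_climate_table <- function() {
  tibble::tibble(
    biome = BIOMES,
    mat_mu = c(-1, 8, 16, 18, 26), mat_sd = c(3, 4, 3, 3, 2),
    map_mu = c(600, 900, 500, 1500, 2200), map_sd = c(150, 250, 120, 350, 450),
    lat_mu = c(58, 45, 38, 28, 8), lat_sd = c(4, 6, 3, 4, 6)
  )
}

empty_dataset <- function(truth = NULL) {
  new_litter_dataset(
    studies = tibble::tibble(
      study_id = character(), latitude = double(), longitude = double(),
      biome = character(), mat = double(), map = double(),
      forest_type = character(), mesh_size = double(), selected = logical()),
    species = tibble::tibble(
      species_id = character(), study_id = character(),
      life_form = character(), leaf_habit = character(),
      N = double(), P = double(), K = double(), Ca = double(), Mg = double(),
      cellulose = double(), lignin = double(), C_N = double(),
      N_P = double(), lignin_N = double()),
    observations = tibble::tibble(
      study_id = character(), treatment_id = character(),
      is_mixture = logical(), harvest_index = integer(),
      harvest_time = double(), is_final_harvest = logical(),
      mass_loss = double(), mass_loss_sd = double(), n_reps = integer(),
      conc_N = double(), conc_N_sd = double(), conc_P = double(),
      conc_P_sd = double()),
    compositions = tibble::tibble(
      study_id = character(), treatment_id = character(),
      species_id = character(), proportion = double()),
    truth = truth
  )
}

row_sds <- function(m) {
  if (ncol(m) < 2) return(rep(0, nrow(m)))
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
}

#' Generate a complete synthetic litterbag compilation with ground truth
#'
#' Draws a dataset in the four-table schema of [litter_dataset] that
#' emulates the statistical structure the meta-analysis assumes:
#'
#' * study-level true mixture effects `theta ~ N(biome effect, tau^2)`,
#'   active only while the additive-null mass loss lies inside the
#'   interaction window, plus an optional trait-divergence term
#'   `sum(beta_t * Rao_t)`;
#' * species decay constants decreasing in lignin:N, single-species
#'   trajectories `1 - exp(-k t)` observed through multiplicative lognormal
#'   replicate error (so positivity is preserved for the log ratio);
#' * mixture observations equal to the additive null times
#'   `exp(true lnRR)`, measured with the same error model;
#' * nutrient concentrations following an immobilization-then-release
#'   trajectory, with a configurable mixture shift in relative release;
#' * evergreen species drawn with higher lignin, lignin:N and C:N than
#'   deciduous species.
#'
#' The realized additive null (built from the *noisy* single-species means,
#' exactly what [build_pairs()] reconstructs) is recorded in the attached
#' ground truth, together with study effects, per-treatment true lnRR and
#' interval-level mean true effects, so parameter-recovery tests can score
#' the pipeline without external data.
#'
#' @param config A `litter_config` from [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`); the dataset is a
#'   pure function of `(config, seed)`.
#' @return A `litter_dataset` with `$truth` attached.
#' @export
generate_dataset <- function(config = generator_config(),
                             seed = config$seed) {
  validate_generator_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  n <- config$n_studies
  if (n == 0) {
    truth <- list(
      study_effects = tibble::tibble(study_id = character(),
                                     biome = character(), theta = double()),
      treatment_truth = tibble::tibble(
        study_id = character(), treatment_id = character(),
        harvest_index = integer(), harvest_time = double(),
        null_true = double(), realized_null = double(),
        in_window = logical(), true_lnrr = double(),
        true_observed = double()),
      divergence = tibble::tibble(treatment_id = character(),
                                  trait = character(), rao = double()),
      config = config, seed = as.integer(seed))
    return(empty_dataset(truth))
  }

  clim <- biome_climate_table()
  studies <- tibble::tibble(
    study_id = sprintf("S%03d", seq_len(n)),
    biome = sample(names(config$biome_mix), n, TRUE, prob = config$biome_mix)
  ) |>
    dplyr::left_join(clim, by = "biome") |>
    dplyr::mutate(
      latitude = round(rnorm(n, .data$lat_mu, .data$lat_sd) *
                         sample(c(-1, 1), n, TRUE, prob = c(0.25, 0.75)), 3),
      longitude = round(runif(n, -180, 180), 3),
      mat = round(rnorm(n, .data$mat_mu, .data$mat_sd), 1),
      map = round(pmax(rnorm(n, .data$map_mu, .data$map_sd), 100)),
      forest_type = sample(FOREST_TYPES, n, TRUE, prob = c(0.6, 0.4)),
      mesh_size = sample(c(0.5, 1, 1.5, 2, 4), n, TRUE,
                         prob = c(0.22, 0.15, 0.15, 0.15, 0.33)),
      selected = TRUE
    ) |>
    dplyr::select("study_id", "latitude", "longitude", "biome", "mat",
                  "map", "forest_type", "mesh_size", "selected")

  measure_N <- runif(n) < config$nutrient_fraction[["N"]]
  p_cond <- min(1, config$nutrient_fraction[["P"]] /
                  max(config$nutrient_fraction[["N"]], 1e-12))
  measure_P <- measure_N & (runif(n) < p_cond)
  duration <- resample(config$harvest_schedule, n, TRUE,
                       prob = config$harvests_mix)
  hrange <- config$harvests_per_study
  n_harv <- resample(seq(hrange[1], hrange[2]), n, TRUE)
  n_mix <- resample(seq(config$mixtures_per_study[1],
                        config$mixtures_per_study[2]), n, TRUE)

  # ---- mixtures and species pools ---------------------------------------
  rich_levels <- as.integer(names(config$richness_mix))
  mixtures <- tibble::tibble(
    study_id = rep(studies$study_id, n_mix),
    mix_no = unlist(purrr::map(n_mix, seq_len), use.names = FALSE)
  ) |>
    dplyr::mutate(
      treatment_id = sprintf("%s_mix%02d", .data$study_id, .data$mix_no),
      richness = rich_levels[sample.int(length(rich_levels), dplyr::n(),
                                        TRUE, prob = config$richness_mix)],
      equal_ratio = runif(dplyr::n()) < config$evenness_fraction
    )
  pool_size <- mixtures |>
    dplyr::summarise(n_sp = max(.data$richness) + 1L, .by = "study_id")

  n_sp_tot <- sum(pool_size$n_sp)
  species <- tibble::tibble(
    study_id = rep(pool_size$study_id, pool_size$n_sp),
    sp_no = unlist(purrr::map(pool_size$n_sp, seq_len), use.names = FALSE)
  ) |>
    dplyr::mutate(
      species_id = sprintf("%s_sp%02d", .data$study_id, .data$sp_no),
      leaf_habit = sample(LEAF_HABITS, n_sp_tot, TRUE, prob = c(0.55, 0.45)),
      life_form = sample(LIFE_FORMS, n_sp_tot, TRUE,
                         prob = c(0.75, 0.15, 0.10)),
      ever = .data$leaf_habit == "evergreen",
      N = rlnorm(n_sp_tot, ifelse(.data$ever, log(9), log(13)), 0.22),
      P = rlnorm(n_sp_tot, ifelse(.data$ever, log(0.9), log(1.3)), 0.3),
      K = rlnorm(n_sp_tot, log(5), 0.3),
      Ca = rlnorm(n_sp_tot, log(8), 0.3),
      Mg = rlnorm(n_sp_tot, log(2), 0.3),
      cellulose = rlnorm(n_sp_tot, log(250), 0.15),
      lignin = rlnorm(n_sp_tot, ifelse(.data$ever, log(280), log(160)), 0.18),
      C_tot = rnorm(n_sp_tot, 480, 30),
      C_N = .data$C_tot / .data$N,
      N_P = .data$N / .data$P,
      lignin_N = .data$lignin / .data$N,
      k_true = config$k_scale / .data$lignin_N * exp(rnorm(n_sp_tot, 0, 0.15))
    )

  # components: sample richness species from the study pool per mixture
  comp_list <- purrr::pmap(
    list(mixtures$study_id, mixtures$treatment_id, mixtures$richness,
         mixtures$equal_ratio,
         pool_size$n_sp[match(mixtures$study_id, pool_size$study_id)]),
    function(sid, tid, r, eq, np) {
      picks <- sample.int(np, r)
      p <- if (eq) rep(1 / r, r) else {
        g <- stats::rgamma(r, 2)
        g / sum(g)
      }
      tibble::tibble(study_id = sid, treatment_id = tid,
                     species_id = sprintf("%s_sp%02d", sid, picks),
                     proportion = p)
    })
  compositions <- dplyr::bind_rows(comp_list)

  # ---- true trajectories -------------------------------------------------
  # harvests evenly spaced over each study's own duration
  harvests <- tibble::tibble(
    study_id = rep(studies$study_id, n_harv),
    harvest_index = unlist(purrr::map(n_harv, seq_len), use.names = FALSE)
  ) |>
    dplyr::mutate(
      harvest_time = unlist(purrr::map2(n_harv, duration, function(h, d) {
        d * seq_len(h) / h
      }), use.names = FALSE),
      is_final_harvest = unlist(purrr::map(n_harv, function(h) {
        seq_len(h) == h
      }), use.names = FALSE)
    )

  used_species <- dplyr::distinct(compositions, .data$study_id,
                                  .data$species_id)
  singles_grid <- used_species |>
    dplyr::inner_join(harvests, by = "study_id",
                      relationship = "many-to-many") |>
    dplyr::left_join(dplyr::select(species, "species_id", "k_true", "N",
                                   "P"),
                     by = "species_id") |>
    dplyr::mutate(true_ml = (1 - exp(-.data$k_true *
                                       .data$harvest_time / 365)) * 100)

  theta <- rnorm(n, config$true_effects[studies$biome], config$tau)
  study_effects <- tibble::tibble(study_id = studies$study_id,
                                  biome = studies$biome, theta = theta)

  # Rao divergence (true traits) for the traits with a configured slope
  slope_traits <- names(config$divergence_slope)
  div_term <- rep(0, nrow(mixtures))
  div_truth <- tibble::tibble(treatment_id = character(),
                              trait = character(), rao = double())
  if (length(slope_traits) > 0) {
    comp_tr <- compositions |>
      dplyr::left_join(
        dplyr::select(species, "species_id",
                      dplyr::all_of(slope_traits)),
        by = "species_id")
    div_truth <- comp_tr |>
      tidyr::pivot_longer(dplyr::all_of(slope_traits), names_to = "trait",
                          values_to = "value") |>
      dplyr::summarise(rao = rao_q(.data$value, .data$proportion),
                       .by = c("treatment_id", "trait"))
    dterm <- div_truth |>
      dplyr::mutate(add = .data$rao *
                      config$divergence_slope[.data$trait]) |>
      dplyr::summarise(add = sum(.data$add), .by = "treatment_id")
    div_term <- dterm$add[match(mixtures$treatment_id, dterm$treatment_id)]
    div_term[is.na(div_term)] <- 0
  }

  mix_grid <- compositions |>
    dplyr::inner_join(
      dplyr::select(singles_grid, "study_id", "species_id",
                    "harvest_index", "harvest_time", "is_final_harvest",
                    "true_ml"),
      by = c("study_id", "species_id"),
      relationship = "many-to-many") |>
    dplyr::summarise(
      null_true = sum(.data$proportion * .data$true_ml),
      .by = c("study_id", "treatment_id", "harvest_index",
              "harvest_time", "is_final_harvest"))
  w <- config$interaction_window
  mix_grid <- mix_grid |>
    dplyr::mutate(
      in_window = .data$null_true >= w[1] & .data$null_true <= w[2],
      true_lnrr = ifelse(
        .data$in_window,
        theta[match(.data$study_id, studies$study_id)] +
          div_term[match(.data$treatment_id, mixtures$treatment_id)],
        0),
      true_obs = pmin(.data$null_true * exp(.data$true_lnrr), 100))

  # ---- measured mass loss ------------------------------------------------
  cv <- config$measurement_cv
  nr <- config$n_reps
  measure <- function(true_vals) {
    eps <- matrix(rnorm(length(true_vals) * nr, -cv^2 / 2, cv),
                  nrow = length(true_vals))
    reps <- pmin(true_vals * exp(eps), 100)
    list(mean = rowMeans(reps), sd = row_sds(reps))
  }
  ms <- measure(singles_grid$true_ml)
  singles_grid$ml_mean <- ms$mean
  singles_grid$ml_sd <- ms$sd
  mm <- measure(mix_grid$true_obs)
  mix_grid$ml_mean <- mm$mean
  mix_grid$ml_sd <- mm$sd

  # realized additive null from the noisy single-species means
  realized <- compositions |>
    dplyr::inner_join(
      dplyr::select(singles_grid, "study_id", "species_id",
                    "harvest_index", "ml_mean"),
      by = c("study_id", "species_id"),
      relationship = "many-to-many") |>
    dplyr::summarise(realized_null = sum(.data$proportion * .data$ml_mean),
                     .by = c("treatment_id", "harvest_index"))
  mix_grid <- dplyr::left_join(mix_grid, realized,
                               by = c("treatment_id", "harvest_index"))

  # ---- nutrient concentrations ------------------------------------------
  conc0_mix <- compositions |>
    dplyr::left_join(dplyr::select(species, "species_id", "N", "P"),
                     by = "species_id") |>
    dplyr::summarise(conc0_N = sum(.data$proportion * .data$N),
                     conc0_P = sum(.data$proportion * .data$P),
                     .by = "treatment_id")

  nutrient_cols <- function(grid, conc0, null_frac, obs_ml, measured) {
    out <- list()
    for (nu in c("N", "P")) {
      amp <- config$imm_amp[[nu]]
      phase <- config$imm_phase[[nu]]
      f <- null_frac[[nu]]
      mrf <- pmax(1 - obs_ml / 100, 0.01)
      conc_true <- conc0[[nu]] * f / mrf
      noise <- exp(rnorm(nrow(grid), 0, cv / sqrt(nr)))
      cm <- conc_true * noise
      csd <- conc_true * cv
      keep <- measured[[nu]]
      out[[paste0("conc_", nu)]] <- ifelse(keep, cm, NA_real_)
      out[[paste0("conc_", nu, "_sd")]] <- ifelse(keep, csd, NA_real_)
    }
    out
  }

  st_N <- setNames(measure_N, studies$study_id)
  st_P <- setNames(measure_P, studies$study_id)

  # single species: remaining-amount fractions from own trajectory
  sg_frac <- list(
    N = nutrient_amount_fraction(singles_grid$true_ml / 100,
                                 config$imm_amp[["N"]],
                                 config$imm_phase[["N"]]),
    P = nutrient_amount_fraction(singles_grid$true_ml / 100,
                                 config$imm_amp[["P"]],
                                 config$imm_phase[["P"]]))
  sg_nut <- nutrient_cols(
    singles_grid,
    conc0 = list(N = singles_grid$N, P = singles_grid$P),
    null_frac = sg_frac, obs_ml = singles_grid$true_ml,
    measured = list(N = st_N[singles_grid$study_id],
                    P = st_P[singles_grid$study_id]))

  # mixtures: nutrient-mass-weighted null fraction, minus the mixture shift
  comp_nut <- compositions |>
    dplyr::left_join(dplyr::select(species, "species_id", "N", "P",
                                   "k_true"),
                     by = "species_id") |>
    dplyr::inner_join(
      dplyr::select(singles_grid, "study_id", "species_id",
                    "harvest_index", "true_ml"),
      by = c("study_id", "species_id"),
      relationship = "many-to-many")
  mix_frac_tab <- comp_nut |>
    dplyr::mutate(
      fN = nutrient_amount_fraction(.data$true_ml / 100,
                                    config$imm_amp[["N"]],
                                    config$imm_phase[["N"]]),
      fP = nutrient_amount_fraction(.data$true_ml / 100,
                                    config$imm_amp[["P"]],
                                    config$imm_phase[["P"]])) |>
    dplyr::summarise(
      fN = sum(.data$proportion * .data$N * .data$fN) /
        sum(.data$proportion * .data$N),
      fP = sum(.data$proportion * .data$P * .data$fP) /
        sum(.data$proportion * .data$P),
      .by = c("treatment_id", "harvest_index"))
  mg <- mix_grid |>
    dplyr::left_join(mix_frac_tab, by = c("treatment_id", "harvest_index")) |>
    dplyr::left_join(conc0_mix, by = "treatment_id")
  shift_N <- setNames(rnorm(n, config$nutrient_shift[["N"]],
                            config$nutrient_shift_sd[["N"]]),
                      studies$study_id)
  shift_P <- setNames(rnorm(n, config$nutrient_shift[["P"]],
                            config$nutrient_shift_sd[["P"]]),
                      studies$study_id)
  mg_frac <- list(
    N = pmax(mg$fN - shift_N[mg$study_id] / 100, 0.02),
    P = pmax(mg$fP - shift_P[mg$study_id] / 100, 0.02))
  mg_nut <- nutrient_cols(
    mg, conc0 = list(N = mg$conc0_N, P = mg$conc0_P),
    null_frac = mg_frac, obs_ml = mg$true_obs,
    measured = list(N = st_N[mg$study_id], P = st_P[mg$study_id]))

  # ---- assemble observation table ---------------------------------------
  obs_single <- tibble::tibble(
    study_id = singles_grid$study_id,
    treatment_id = singles_grid$species_id,
    is_mixture = FALSE,
    harvest_index = as.integer(singles_grid$harvest_index),
    harvest_time = singles_grid$harvest_time,
    is_final_harvest = singles_grid$is_final_harvest,
    mass_loss = singles_grid$ml_mean,
    mass_loss_sd = singles_grid$ml_sd,
    n_reps = nr,
    conc_N = sg_nut$conc_N, conc_N_sd = sg_nut$conc_N_sd,
    conc_P = sg_nut$conc_P, conc_P_sd = sg_nut$conc_P_sd)
  obs_mix <- tibble::tibble(
    study_id = mg$study_id,
    treatment_id = mg$treatment_id,
    is_mixture = TRUE,
    harvest_index = as.integer(mg$harvest_index),
    harvest_time = mg$harvest_time,
    is_final_harvest = mg$is_final_harvest,
    mass_loss = mg$ml_mean,
    mass_loss_sd = mg$ml_sd,
    n_reps = nr,
    conc_N = mg_nut$conc_N, conc_N_sd = mg_nut$conc_N_sd,
    conc_P = mg_nut$conc_P, conc_P_sd = mg_nut$conc_P_sd)
  observations <- dplyr::bind_rows(obs_single, obs_mix) |>
    dplyr::arrange(.data$study_id, .data$is_mixture, .data$treatment_id,
                   .data$harvest_index)

  # mask unreported traits (k and nutrient dynamics were built from the
  # complete trait set; reporting gaps affect only the written table)
  species_out <- species |>
    dplyr::select("species_id", "study_id", "life_form", "leaf_habit",
                  "N", "P", "K", "Ca", "Mg", "cellulose", "lignin",
                  "C_N", "N_P", "lignin_N")
  if (config$prob_missing_trait > 0) {
    for (tr in c("P", "K", "Ca", "Mg", "cellulose", "lignin")) {
      gone <- runif(nrow(species_out)) < config$prob_missing_trait
      species_out[[tr]][gone] <- NA_real_
      if (tr == "lignin") species_out$lignin_N[gone] <- NA_real_
      if (tr == "P") {
        species_out$N_P[gone] <- NA_real_
      }
    }
  }

  truth <- list(
    study_effects = study_effects,
    treatment_truth = mix_grid |>
      dplyr::select("study_id", "treatment_id", "harvest_index",
                    "harvest_time", "null_true", "realized_null",
                    "in_window", "true_lnrr", true_observed = "true_obs"),
    divergence = div_truth,
    config = config, seed = as.integer(seed))

  validate_litter_dataset(new_litter_dataset(
    studies, species_out, observations,
    dplyr::select(compositions, "study_id", "treatment_id", "species_id",
                  "proportion"),
    truth = truth))
}

#' Miniature deterministic dataset for examples and fast tests
#'
#' Three studies of two-species mixtures over two harvests, nitrogen
#' measured everywhere with a pronounced early immobilization phase (so at
#' least one pair is excluded from the N-release meta-analysis as
#' immobilized), and one species with a deliberately unreported Ca value
#' (so one mixture drops out of the Ca divergence regression). Byte-stable
#' given the seed.
#'
#' @param seed Integer seed (default 42).
#' @return A small `litter_dataset` with ground truth.
#' @export
fixture_small <- function(seed = 42) {
  cfg <- generator_config(
    n_studies = 3,
    harvest_schedule = 365,
    harvests_mix = 1,
    harvests_per_study = c(2, 2),
    richness_mix = c(`2` = 1),
    mixtures_per_study = c(2, 2),
    nutrient_fraction = c(N = 1, P = 0.5),
    imm_phase = c(N = 0.35, P = 0),
    imm_amp = c(N = 0.35, P = 0),
    n_reps = 3L,
    measurement_cv = 0.08,
    tau = 0.03,
    prob_missing_trait = 0,
    seed = as.integer(seed)
  )
  ds <- generate_dataset(cfg)
  ds$species$Ca[1] <- NA_real_
  ds
}
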
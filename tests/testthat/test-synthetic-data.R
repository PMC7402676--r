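test_that("generation is a pure function of config and seed", {
  cfg <- generator_config(n_studies = 6, seed = 19)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  for (tab in c("studies", "species", "observations", "compositions")) {
    expect_identical(a[[tab]], b[[tab]])
  }
  expect_identical(a$truth$treatment_truth, b$truth$treatment_truth)
  c2 <- generate_dataset(cfg, seed = 20)
  expect_false(identical(a$observations, c2$observations))
  # written files are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_litter_dataset(a, d1)
  write_litter_dataset(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("an empty configuration yields schema-valid empty tables", {
  e <- generate_dataset(generator_config(n_studies = 0))
  expect_equal(nrow(e$studies), 0)
  expect_equal(nrow(e$observations), 0)
  expect_no_error(validate_litter_dataset(e))
  expect_equal(nrow(build_pairs(e)), 0)
})

test_that("generated datasets satisfy every schema invariant", {
  ds <- default_dataset()
  expect_no_error(validate_litter_dataset(ds))
  obs <- ds$observations
  expect_true(all(obs$mass_loss >= 0 & obs$mass_loss <= 100))
  expect_true(all(obs$mass_loss_sd >= 0))
  sums <- tapply(ds$compositions$proportion,
                 ds$compositions$treatment_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("default compilation matches the intended shape", {
  ds <- default_dataset()
  expect_equal(nrow(ds$studies), 65)
  n_final_mix <- sum(ds$observations$is_mixture &
                       ds$observations$is_final_harvest)
  expect_gt(n_final_mix, 200)
  expect_lt(n_final_mix, 380)
  rich <- dplyr::count(ds$compositions, treatment_id)
  expect_true(all(rich$n %in% c(2, 3, 4, 6)))
  # two-species mixtures dominate
  expect_gt(mean(rich$n == 2), 0.5)
})

test_that("noise-free trajectories are monotone and evergreens carry higher lignin:N", {
  ds <- default_dataset()
  tt <- ds$truth$treatment_truth |>
    dplyr::arrange(treatment_id, harvest_index)
  mono <- tapply(tt$null_true, tt$treatment_id,
                 function(x) all(diff(x) >= 0))
  expect_true(all(mono))
  sp <- ds$species[!is.na(ds$species$lignin_N), ]
  ev <- sp$lignin_N[sp$leaf_habit == "evergreen"]
  de <- sp$lignin_N[sp$leaf_habit == "deciduous"]
  expect_gt(median(ev), median(de))
  # stochastic dominance, checked at a few quantiles
  qs <- c(0.25, 0.5, 0.75)
  expect_true(all(quantile(ev, qs) > quantile(de, qs)))
  expect_gt(median(sp$C_N[sp$leaf_habit == "evergreen"]),
            median(sp$C_N[sp$leaf_habit == "deciduous"]))
})

test_that("the miniature fixture has its documented features", {
  fx <- small_dataset()
  expect_equal(nrow(fx$studies), 3)
  expect_true(all(dplyr::count(fx$compositions, treatment_id)$n == 2))
  expect_equal(max(fx$observations$harvest_index), 2)
  pairs <- build_pairs(fx)
  expect_gt(sum(pairs$response != "mass_loss"), 0)
  eff <- suppressMessages(compute_effect_sizes(pairs))
  excl <- attr(eff, "exclusions")
  expect_gt(nrow(excl), 0) # immobilization exclusion present
  expect_true(anyNA(fx$species$Ca)) # deliberately unreported trait
  fx2 <- fixture_small(42)
  expect_identical(fx$observations, fx2$observations)
})

test_that("infeasible generator configurations are rejected", {
  expect_error(generator_config(interaction_window = c(-5, 40)),
               "interaction_window")
  expect_error(generator_config(interaction_window = c(60, 40)),
               "interaction_window")
  expect_error(generator_config(tau = -1), "tau")
  expect_error(generator_config(measurement_cv = 0), "measurement_cv")
  expect_error(
    generator_config(biome_mix = c(boreal = 0.5, temperate = 0.5)),
    "biome_mix")
})

test_that("with vanishing noise the pipeline recovers configured effects almost exactly", {
  cfg <- generator_config(
    n_studies = 12, tau = 0, measurement_cv = 1e-6,
    true_effects = c(boreal = 0.05, temperate = 0.05, mediterranean = 0.05,
                     subtropical = 0.05, tropical = 0.05),
    interaction_window = c(0, 100), seed = 3)
  ds <- generate_dataset(cfg)
  ef <- compute_effect_sizes(build_pairs(ds))
  ml <- ef[ef$response == "mass_loss" & ef$is_final_harvest, ]
  expect_lt(max(abs(ml$lnrr - 0.05)), 1e-3)
})
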
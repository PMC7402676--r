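test_that("mean character difference matches hand evaluation", {
  expect_equal(mean_character_difference(10, 10), 0)
  expect_equal(mean_character_difference(10, 2), 8)
  expect_equal(mean_character_difference(c(4, 6), c(2, 10)), 3)
  expect_error(mean_character_difference(c(1, 2), 1), "length")
})

test_that("Rao's Q matches the printed upper-triangle sum", {
  expect_equal(rao_q(c(10, 2), c(0.5, 0.5)), 8 * 0.25)
  expect_equal(rao_q(c(7, 7, 7), c(0.2, 0.3, 0.5)), 0)
  expect_equal(rao_q(c(10, 2), c(0.75, 0.25)), 8 * 0.1875)
  expect_error(rao_q(c(10, NA), c(0.5, 0.5)), "missing")
  expect_error(rao_q(10, 1), "components")
})

test_that("Rao's Q equals brute-force enumeration, is permutation-invariant and homogeneous", {
  brute <- function(x, p) {
    # full ordered double sum over all pairs, halved
    s <- length(x)
    tot <- 0
    for (i in seq_len(s)) for (j in seq_len(s)) {
      tot <- tot + abs(x[i] - x[j]) * p[i] * p[j]
    }
    tot / 2
  }
  set.seed(23)
  for (r in 1:20) {
    s <- sample(2:6, 1)
    x <- runif(s, 0, 300)
    g <- rgamma(s, 1); p <- g / sum(g)
    expect_equal(rao_q(x, p), brute(x, p), tolerance = 1e-12)
    o <- sample(s)
    expect_equal(rao_q(x[o], p[o]), rao_q(x, p), tolerance = 1e-12)
    expect_equal(rao_q(10 * x, p), 10 * rao_q(x, p), tolerance = 1e-9)
  }
})

test_that("per-trait divergence handles missing traits by exclusion", {
  ds <- tiny_manual_dataset()
  dv <- suppressMessages(trait_divergence(ds))
  a_n <- dv$rao[dv$treatment_id == "A_mix" & dv$trait == "N"]
  expect_equal(a_n, abs(14 - 8) * 0.25)
  b_n <- dv$rao[dv$treatment_id == "B_mix" & dv$trait == "N"]
  expect_equal(b_n, abs(12 - 16) * 0.75 * 0.25)
  # B_s2 has no P value: P divergence undefined for B_mix
  expect_true(is.na(dv$rao[dv$treatment_id == "B_mix" & dv$trait == "P"]))
  expect_equal(unique(dv$n_traits), 1L)
})

test_that("window averaging takes one point per study inside 10-40%", {
  eff <- tibble::tibble(
    study_id = c("A", "A", "B", "C"),
    treatment_id = c("Am", "Am", "Bm", "Cm"),
    response = "mass_loss",
    lnrr = c(0.06, 0.10, 0.08, 0.5),
    variance = 0.01,
    expected_mass_loss = c(15, 35, 25, 9))
  w <- window_effect_per_study(eff)
  per_study <- attr(w, "per_study")
  expect_equal(per_study$lnrr[per_study$study_id == "A"], 0.08)
  expect_equal(per_study$lnrr[per_study$study_id == "B"], 0.08)
  # 9% and 41% fall outside the closed window
  expect_false("C" %in% per_study$study_id)
  eff$expected_mass_loss[4] <- 41
  w2 <- window_effect_per_study(eff)
  expect_false("C" %in% attr(w2, "per_study")$study_id)
})

test_that("moderator regression reproduces exact and degenerate fits", {
  r <- suppressWarnings(moderator_regression(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)
  r2 <- suppressWarnings(moderator_regression(c(0, 1, 2, 3), c(2, 2, 2, 2)))
  expect_equal(r2$slope, 0)
  expect_equal(r2$r_squared, 0)
  expect_error(moderator_regression(rep(1, 5), rnorm(5)), "degenerate")
  expect_error(moderator_regression(1:2, 1:2), "3 points")
  # agreement with lm on noisy data
  set.seed(5)
  x <- runif(30); y <- 0.5 * x + rnorm(30, 0, 0.1)
  r3 <- moderator_regression(x, y)
  fit <- lm(y ~ x)
  expect_equal(r3$slope, unname(coef(fit)[2]))
  expect_equal(r3$p_value, summary(fit)$coefficients[2, 4])
})

test_that("a configured divergence-effect slope is recovered by regression", {
  # precise-measurement regime: the slope standard error must sit well
  # below the 0.01 recovery band (power analysis in the methods vignette)
  cfg <- generator_config(
    n_studies = 60, divergence_slope = c(N = 0.02),
    true_effects = ZERO_EFFECTS, tau = 0,
    measurement_cv = 0.05, n_reps = 8L, seed = 77)
  ds <- cached("divslope", function() generate_dataset(cfg))
  ef <- compute_effect_sizes(build_pairs(ds))
  rg <- divergence_regressions(ds, ef, traits = "N")
  expect_lt(abs(rg$slope - 0.02), 0.01)
  expect_lt(rg$p_value, 0.05)
  expect_gt(rg$slope, 0)
})

test_that("leverage-sensitivity refit drops the top-divergence points", {
  set.seed(6)
  ds <- small_dataset()
  ef <- suppressMessages(compute_effect_sizes(build_pairs(ds)))
  full <- divergence_regressions(ds, ef, traits = "N", window = c(0, 100))
  trimmed <- divergence_regressions(ds, ef, traits = "N",
                                    window = c(0, 100),
                                    exclude_top_frac = 0.34)
  expect_lte(trimmed$n_points, full$n_points)
})
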
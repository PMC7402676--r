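test_that("stage intervals partition [0, 100] with a wide final bin", {
  iv <- mass_loss_intervals()
  expect_equal(nrow(iv), 8)
  expect_equal(iv$lower[1], 0)
  expect_equal(iv$upper[8], 100)
  expect_equal(iv$lower[-1], iv$upper[-8])
  expect_equal(iv$label[8], "70-100")
})

test_that("interval assignment is half-open with a closed top", {
  expect_equal(as.character(assign_interval(35)), "30-40")
  expect_equal(as.character(assign_interval(40)), "40-50")
  expect_equal(as.character(assign_interval(0)), "0-10")
  expect_equal(as.character(assign_interval(70)), "70-100")
  expect_equal(as.character(assign_interval(100)), "70-100")
  expect_error(assign_interval(101), "expected_mass_loss")
  expect_error(assign_interval(-2), "expected_mass_loss")
  # exhaustive and exclusive over the range
  x <- seq(0, 100, by = 0.5)
  got <- assign_interval(x)
  expect_false(anyNA(got))
  expect_equal(length(got), length(x))
})

test_that("staged meta-analysis pools per interval and flags small bins", {
  # two populated intervals, one singleton, rest empty; the second group
  # straddles zero symmetrically so its pooled effect is exactly null
  eff <- tibble::tibble(
    study_id = sprintf("S%02d", 1:13),
    treatment_id = sprintf("T%02d", 1:13),
    response = "mass_loss",
    lnrr = c(0.18, 0.19, 0.2, 0.21, 0.22, 0.2,
             -0.03, -0.02, -0.01, 0.01, 0.02, 0.03, 0.4),
    variance = 0.004,
    expected_mass_loss = c(seq(10.5, 19.5, length.out = 6),
                           seq(50.5, 59.5, length.out = 6), 95))
  st <- staged_meta(eff, reps = 999, seed = 2)
  expect_equal(nrow(st), 8)
  expect_equal(st$k[st$interval == "10-20"], 6L)
  expect_equal(st$k[st$interval == "50-60"], 6L)
  expect_equal(st$k[st$interval == "0-10"], 0L)
  expect_true(st$significant[st$interval == "10-20"])
  expect_false(st$significant[st$interval == "50-60"])
  one <- st[st$interval == "70-100", ]
  expect_true(one$low_n)
  expect_equal(one$pooled_lnrr, 0.4)
  # every pair lands in exactly one interval
  expect_equal(sum(st$k), nrow(eff))
})

test_that("collapsing a study's harvests leaves one effect per interval", {
  eff <- tibble::tibble(
    study_id = c("A", "A", "A", "B", "B", "B", "C", "C"),
    treatment_id = c("Am", "Am", "Am", "Bm", "Bm", "Bm", "Cm", "Cm"),
    response = "mass_loss",
    lnrr = c(0.1, 0.2, 0.4, 0, 0.1, 0.5, 0.2, 0.3),
    variance = 0.01,
    expected_mass_loss = c(12, 18, 55, 15, 19, 57, 13, 17))
  st <- staged_meta(eff, collapse_study = TRUE, reps = 999, seed = 1)
  expect_equal(st$k[st$interval == "10-20"], 3L)
  # study A contributes mean(0.1, 0.2) to the 10-20 bin
  st2 <- staged_meta(eff, collapse_study = FALSE, reps = 999, seed = 1)
  expect_equal(st2$k[st2$interval == "10-20"], 6L)
})

test_that("the interaction window localizes significance to its bins", {
  eff8 <- c(boreal = 0.08, temperate = 0.08, mediterranean = 0.08,
            subtropical = 0.08, tropical = 0.08)
  cfg <- generator_config(true_effects = eff8,
                          interaction_window = c(10, 40), seed = 6)
  ds <- cached("staging6", function() generate_dataset(cfg))
  ef <- compute_effect_sizes(build_pairs(ds))
  st <- staged_meta(ef, reps = 999, seed = 66)
  sig <- as.character(st$interval[st$significant & !st$low_n])
  expect_setequal(sig, c("10-20", "20-30", "30-40"))
})
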
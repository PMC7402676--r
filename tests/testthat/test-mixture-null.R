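test_that("additive expectation is the proportion-weighted mean", {
  expect_equal(expected_value(c(40, 60), c(0.5, 0.5)), 50)
  expect_equal(expected_value(c(40, 60), c(0.75, 0.25)),
               0.75 * 40 + 0.25 * 60)
  expect_equal(expected_value(c(55, 55), c(0.3, 0.7)), 55)
  expect_error(expected_value(c(40, 60), c(0.5, 0.4, 0.1)), "length")
  expect_error(expected_value(c(40, 60), c(0.5, 0.4)), "sum")
})

test_that("expectation is convex and permutation-invariant", {
  set.seed(11)
  for (i in 1:25) {
    r <- sample(2:5, 1)
    m <- runif(r, 0, 100)
    g <- rgamma(r, 1)
    p <- g / sum(g)
    e <- expected_value(m, p)
    expect_gte(e, min(m))
    expect_lte(e, max(m))
    o <- sample(r)
    expect_equal(expected_value(m[o], p[o]), e)
  }
})

test_that("null dispersion propagates independent components", {
  d <- expected_dispersion(c(5, 5), c(4, 4), c(0.5, 0.5))
  expect_equal(d$sd, sqrt(0.25 * 25 + 0.25 * 25))
  expect_equal(d$n, 4)
  expect_equal(expected_dispersion(c(0, 0), c(3, 3), c(0.5, 0.5))$sd, 0)
  d <- expected_dispersion(c(6, 0), c(3, 5), c(0.5, 0.5))
  expect_equal(d$sd, 3)
  expect_equal(d$n, 3)
  expect_error(expected_dispersion(c(1, 2), c(3, 3, 3), c(0.5, 0.5)),
               "length")
})

test_that("build_pairs pairs each mixture harvest with its additive null", {
  ds <- tiny_manual_dataset()
  pairs <- build_pairs(ds)
  # study A: mass loss + N pair; study B (no concentrations): mass loss only
  expect_equal(nrow(pairs), 3)
  expect_setequal(unique(pairs$response), c("mass_loss", "N_release"))
  a_ml <- dplyr::filter(pairs, study_id == "A", response == "mass_loss")
  expect_equal(a_ml$expected_mean, 0.5 * 40 + 0.5 * 60)
  expect_equal(a_ml$expected_sd, sqrt(0.25 * 25 + 0.25 * 25))
  expect_equal(a_ml$observed_mean, 55)
  b_ml <- dplyr::filter(pairs, study_id == "B", response == "mass_loss")
  expect_equal(b_ml$expected_mean, 0.75 * 30 + 0.25 * 50)
  # expected_mass_loss carried on the nutrient pair too
  a_n <- dplyr::filter(pairs, study_id == "A", response == "N_release")
  expect_equal(a_n$expected_mass_loss, 50)
  # labels joined
  expect_equal(a_ml$biome, "temperate")
  expect_equal(b_ml$evenness, "non_equal")
})

test_that("nutrient null uses the nutrient-mass budget by default", {
  ds <- tiny_manual_dataset()
  pairs <- build_pairs(ds)
  a_n <- dplyr::filter(pairs, study_id == "A", response == "N_release")
  # component releases, amount-based
  rel1 <- (1 - 12 * 0.6 / 14) * 100
  rel2 <- (1 - 9 * 0.4 / 8) * 100
  w <- c(0.5 * 14, 0.5 * 8)
  expect_equal(a_n$expected_mean, sum(w * c(rel1, rel2)) / sum(w))
  # dry-mass fallback
  pairs2 <- build_pairs(ds, nutrient_weights = "dry_mass")
  a_n2 <- dplyr::filter(pairs2, study_id == "A", response == "N_release")
  expect_equal(a_n2$expected_mean, mean(c(rel1, rel2)))
})

test_that("missing component observations skip the pair with a reason", {
  ds <- tiny_manual_dataset()
  ds$observations <- dplyr::filter(ds$observations, treatment_id != "B_s2")
  pairs <- suppressMessages(build_pairs(ds))
  expect_equal(sum(pairs$study_id == "B"), 0)
  sk <- attr(pairs, "skipped")
  expect_equal(nrow(sk), 1)
  expect_match(sk$reason, "missing component")
})

test_that("generated pairs reproduce the generator's realized null exactly", {
  ds <- small_dataset()
  pairs <- build_pairs(ds)
  truth <- ds$truth$treatment_truth
  j <- dplyr::inner_join(
    dplyr::filter(pairs, response == "mass_loss"),
    truth, by = c("treatment_id", "harvest_index"))
  expect_equal(nrow(j), sum(pairs$response == "mass_loss"))
  expect_lt(max(abs(j$expected_mean - j$realized_null)), 1e-12)
})
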
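test_that("negative-exponential conversion matches direct evaluation", {
  expect_equal(mass_loss_from_k(0, 3), 0)
  expect_equal(mass_loss_from_k(0.6931, 1), (1 - exp(-0.6931)) * 100,
               tolerance = 1e-12)
  expect_equal(mass_loss_from_k(0.6931, 1), 50, tolerance = 1e-2)
  expect_equal(mass_loss_from_k(0.5, 2), (1 - exp(-1)) * 100,
               tolerance = 1e-12)
  expect_error(mass_loss_from_k(-0.1, 1), "k")
  expect_error(mass_loss_from_k(0.1, -1), "t")
})

test_that("mass loss is monotone in k and t and bounded by 100", {
  k <- seq(0, 3, length.out = 30)
  ml <- mass_loss_from_k(k, 1.5)
  expect_true(all(diff(ml) > 0))
  t <- seq(0, 50, length.out = 30)
  ml_t <- mass_loss_from_k(0.4, t)
  expect_true(all(diff(ml_t) > 0))
  expect_lt(max(ml_t), 100)
  expect_equal(mass_loss_from_k(0.5, 1e6), 100, tolerance = 1e-9)
})

test_that("mass_loss_from_remaining is an involution on [0, 100]", {
  expect_equal(mass_loss_from_remaining(100), 0)
  expect_equal(mass_loss_from_remaining(0), 100)
  expect_equal(mass_loss_from_remaining(55), 45)
  x <- runif(50, 0, 100)
  expect_equal(mass_loss_from_remaining(mass_loss_from_remaining(x)), x)
  expect_error(mass_loss_from_remaining(120), "remaining")
})

test_that("nutrient release accounts for amounts and flags immobilization", {
  r <- nutrient_release(10, 10, 1)
  expect_equal(r$remaining_fraction, 1)
  expect_equal(r$relative_release, 0)
  expect_false(r$immobilized)

  r <- nutrient_release(10, 12, 0.5, mode = "amount_based")
  expect_equal(r$remaining_fraction, 0.6)
  expect_equal(r$relative_release, 40)
  expect_equal(r$absolute_release, 4.0)
  expect_false(r$immobilized)

  r <- nutrient_release(10, 12, 1.0, mode = "amount_based")
  expect_equal(r$remaining_fraction, 1.2)
  expect_equal(r$relative_release, -20)
  expect_true(r$immobilized)

  r <- nutrient_release(10, 12, 0.5, mode = "concentration_based")
  expect_equal(r$remaining_fraction, 1.2)
  expect_true(r$immobilized)

  expect_error(nutrient_release(0, 5, 0.5), "conc_0")
})

test_that("relative release is scale-free, absolute release scales with conc_0", {
  base <- nutrient_release(10, 6, 0.8)
  scaled <- nutrient_release(30, 18, 0.8)
  expect_equal(scaled$relative_release, base$relative_release)
  expect_equal(scaled$absolute_release, 3 * base$absolute_release)
})
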
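test_that("DerSimonian-Laird worked example is exact", {
  tau2 <- dl_tau_squared(c(0.2, 0), c(0.01, 0.01))
  expect_equal(attr(tau2, "Q"), 2.0)
  expect_equal(as.numeric(tau2), 0.01)
  expect_equal(pooled_effect(c(0.2, 0), c(0.01, 0.01), 0.01), 0.1)
})

test_that("tau-squared is zero for homogeneous effects and floors at zero", {
  expect_equal(as.numeric(dl_tau_squared(rep(0.1, 5), rep(0.01, 5))), 0)
  # Q below its df truncates at zero
  set.seed(21)
  y <- rnorm(10, 0, 0.001)
  expect_gte(as.numeric(dl_tau_squared(y, rep(0.04, 10))), 0)
  expect_equal(as.numeric(suppressMessages(dl_tau_squared(0.2, 0.01))), 0)
})

test_that("DL estimate and RE pooling agree with metafor on random instances", {
  skip_if_not_installed("metafor")
  set.seed(91)
  for (i in 1:10) {
    k <- sample(5:40, 1)
    v <- runif(k, 0.002, 0.05)
    y <- rnorm(k, 0.05, sqrt(0.02 + v))
    fit <- metafor::rma(yi = y, vi = v, method = "DL")
    tau2 <- dl_tau_squared(y, v)
    expect_equal(as.numeric(tau2), as.numeric(fit$tau2), tolerance = 1e-10)
    expect_equal(pooled_effect(y, v, tau2), as.numeric(fit$beta),
                 tolerance = 1e-10)
  }
})

test_that("tau-squared recovery at simulation scale", {
  set.seed(55)
  y <- rnorm(50, 0.1, sqrt(0.04 + 0.01))
  t2 <- as.numeric(dl_tau_squared(y, rep(0.01, 50)))
  expect_gt(t2, 0.02)
  expect_lt(t2, 0.06)
})

test_that("unequal-variance pooling matches hand computation", {
  expect_equal(pooled_effect(c(0.3, 0), c(0.01, 0.04), 0),
               (100 * 0.3) / 125)
  expect_equal(pooled_effect(0.17, 0.01, 0), 0.17)
  # order invariance and duplication invariance
  set.seed(8)
  y <- rnorm(12); v <- runif(12, 0.005, 0.05)
  t2 <- as.numeric(dl_tau_squared(y, v))
  o <- sample(12)
  expect_equal(pooled_effect(y[o], v[o], t2), pooled_effect(y, v, t2))
  expect_equal(pooled_effect(c(y, y), c(v, v), t2),
               pooled_effect(y, v, t2))
})

test_that("bootstrap CI is deterministic, degenerate-safe, and needs k >= 2", {
  y <- rnorm(20, 0.1, 0.1); v <- runif(20, 0.005, 0.02)
  ci1 <- bootstrap_ci(y, v, reps = 999, seed = 42)
  ci2 <- bootstrap_ci(y, v, reps = 999, seed = 42)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_ci(y, v, reps = 999, seed = 43)
  expect_false(identical(ci1, ci3))

  flat <- bootstrap_ci(rep(0.1, 6), rep(0.01, 6), reps = 999, seed = 1)
  expect_equal(unname(flat), c(0.1, 0.1))

  expect_error(bootstrap_ci(0.1, 0.01, reps = 999, seed = 1),
               "single observation")
  expect_error(bootstrap_ci(y, v, reps = 500, seed = 1), "reps")
})

test_that("meta_analyze classifies direction from the bootstrap CI", {
  set.seed(2)
  pos <- effects_table(rnorm(40, 0.15, 0.03), runif(40, 0.002, 0.01))
  m <- meta_analyze(pos, reps = 999, seed = 5)
  expect_true(m$significant)
  expect_equal(m$direction, "synergistic")
  expect_true(m$ci_low <= m$pooled_lnrr && m$pooled_lnrr <= m$ci_high)

  neg <- effects_table(rnorm(40, -0.15, 0.03), runif(40, 0.002, 0.01))
  m2 <- meta_analyze(neg, reps = 999, seed = 5)
  expect_equal(m2$direction, "antagonistic")

  nul <- effects_table(rnorm(40, 0, 0.1), runif(40, 0.002, 0.01))
  m3 <- meta_analyze(nul, reps = 999, seed = 5)
  expect_equal(m3$direction, ifelse(m3$significant, m3$direction,
                                    "additive"))
  single <- effects_table(0.2, 0.01)
  m4 <- suppressMessages(meta_analyze(single, reps = 999, seed = 1))
  expect_true(m4$low_n)
  expect_equal(m4$pooled_lnrr, 0.2)
  expect_equal(m4$direction, "additive")
})

test_that("tidy and glance expose the meta result as tibbles", {
  set.seed(4)
  m <- meta_analyze(effects_table(rnorm(20, 0.1, 0.05),
                                  runif(20, 0.002, 0.01)),
                    reps = 999, seed = 9)
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "percent_effect", "conf.low", "conf.high",
                     "significant", "direction"))
  gl <- glance(m)
  expect_equal(gl$k, 20)
  expect_gte(gl$tau.squared, 0)
})

test_that("Q partitions exactly into between and within components", {
  brute_q <- function(y, v, g) {
    w <- 1 / v
    grand <- sum(w * y) / sum(w)
    qt <- sum(w * (y - grand)^2)
    qw <- sum(tapply(seq_along(y), g, function(i) {
      m <- sum(w[i] * y[i]) / sum(w[i])
      sum(w[i] * (y[i] - m)^2)
    }))
    c(qt = qt, qw = qw, qb = qt - qw)
  }
  set.seed(17)
  for (i in 1:50) {
    ng <- sample(2:4, 1)
    kg <- sample(2:8, ng, replace = TRUE)
    g <- rep(letters[seq_len(ng)], kg)
    y <- rnorm(sum(kg), rep(rnorm(ng, 0, 0.1), kg), 0.1)
    v <- runif(sum(kg), 0.002, 0.05)
    sg <- subgroup_analysis(effects_table(y, v, grp = g), "grp",
                            reps = 999, seed = i)
    expect_lt(abs(sg$q_total - (sg$q_between + sg$q_within)), 1e-8)
    bq <- brute_q(y, v, g)
    expect_equal(sg$q_total, unname(bq["qt"]), tolerance = 1e-10)
    expect_equal(sg$q_within, unname(bq["qw"]), tolerance = 1e-10)
    expect_equal(sg$df_between + sg$df_within, sum(kg) - 1)
  }
})

test_that("identical groups produce zero between-group heterogeneity", {
  y <- c(0.2, 0.1, 0.05); v <- c(0.01, 0.02, 0.01)
  eff <- effects_table(c(y, y), c(v, v), grp = rep(c("a", "b"), each = 3))
  sg <- subgroup_analysis(eff, "grp", reps = 999, seed = 3)
  expect_equal(sg$q_between, 0, tolerance = 1e-12)
  expect_equal(sg$groups$pooled_lnrr[1], sg$groups$pooled_lnrr[2])
})

test_that("separated groups are detected by the between-group test", {
  set.seed(31)
  hits <- 0
  for (s in 1:10) {
    y <- c(rnorm(40, 0.10, sqrt(0.005)), rnorm(40, 0, sqrt(0.005)))
    eff <- effects_table(y, rep(0.005, 80),
                         grp = rep(c("hi", "lo"), each = 40))
    sg <- subgroup_analysis(eff, "grp", reps = 999, seed = s)
    hits <- hits + (sg$p_between < 0.05)
  }
  expect_gte(hits, 9)
})

test_that("subgroups with one effect are flagged without a CI", {
  eff <- effects_table(c(0.1, 0.12, 0.3), c(0.01, 0.01, 0.02),
                       grp = c("a", "a", "b"))
  sg <- subgroup_analysis(eff, "grp", reps = 999, seed = 1)
  b <- sg$groups[sg$groups$group == "b", ]
  expect_true(b$low_n)
  expect_true(is.na(b$ci_low))
  expect_equal(b$pooled_lnrr, 0.3)
  expect_false(b$significant)
})
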
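test_that("mesh classes partition the positive line with inclusive 1-2 mm", {
  got <- classify_mesh(c(0.1, 0.5, 0.99, 1, 1.5, 2, 2.01, 4, 5))
  expect_equal(as.character(got),
               c("lt1", "lt1", "lt1", "1to2", "1to2", "1to2",
                 "gt2", "gt2", "gt2"))
  expect_error(classify_mesh(0), "mesh_size")
  expect_error(classify_mesh(-1), "mesh_size")
  # partition: every positive aperture lands in exactly one class
  x <- runif(200, 0.01, 10)
  expect_false(anyNA(classify_mesh(x)))
})

test_that("evenness, functional composition and stand structure classify per definition", {
  expect_equal(classify_evenness(c(0.5, 0.5)), "equal")
  expect_equal(classify_evenness(c(0.75, 0.25)), "non_equal")
  expect_equal(classify_evenness(c(1, 1, 1) / 3), "equal")

  expect_equal(classify_functional_composition(c("deciduous", "deciduous")),
               "decid_decid")
  expect_equal(
    classify_functional_composition(rep("evergreen", 3)), "ever_ever")
  expect_equal(classify_functional_composition(c("deciduous", "evergreen")),
               "decid_ever")
  expect_true(is.na(suppressMessages(
    classify_functional_composition(c("deciduous", NA)))))

  expect_equal(classify_stand_structure(c("tree", "tree")), "canopy_only")
  expect_equal(classify_stand_structure(c("tree", "shrub")),
               "plus_understory")
  expect_equal(classify_stand_structure(c("shrub", "herb")),
               "plus_understory")
})

test_that("write-then-read round-trips a generated dataset field-for-field", {
  ds <- default_dataset()
  dir <- withr::local_tempdir()
  write_litter_dataset(ds, dir)
  back <- read_litter_dataset(dir)
  for (tab in c("studies", "species", "observations", "compositions")) {
    expect_equal(as.data.frame(back[[tab]]), as.data.frame(ds[[tab]]),
                 tolerance = NULL, info = tab)
  }
  expect_true(file.exists(file.path(dir, "truth.json")))
})

test_that("schema violations raise errors naming the offending field", {
  ds <- tiny_manual_dataset()
  bad <- ds
  bad$compositions$proportion[1] <- 0.4 # now sums to 0.9
  expect_error(validate_litter_dataset(bad), "sum != 1")

  bad <- ds
  bad$studies$biome[1] <- "alpine"
  expect_error(validate_litter_dataset(bad), "biome")

  bad <- ds
  bad$observations$mass_loss[1] <- 140
  expect_error(validate_litter_dataset(bad), "mass_loss")

  bad <- ds
  bad$compositions$species_id[1] <- "ghost"
  expect_error(validate_litter_dataset(bad), "ghost")

  dir <- withr::local_tempdir()
  write_litter_dataset(ds, dir)
  st <- readr::read_csv(file.path(dir, "studies.csv"),
                        show_col_types = FALSE)
  readr::write_csv(st[, setdiff(names(st), "mesh_size")],
                   file.path(dir, "studies.csv"))
  expect_error(read_litter_dataset(dir), "mesh_size")
})

test_that("standard errors are converted to sds on read when flagged", {
  ds <- tiny_manual_dataset()
  dir <- withr::local_tempdir()
  write_litter_dataset(ds, dir)
  back <- read_litter_dataset(dir, dispersion = "se")
  expect_equal(back$observations$mass_loss_sd,
               ds$observations$mass_loss_sd * sqrt(ds$observations$n_reps))
})

test_that("every mixture carries a complete label row or an explicit NA", {
  ds <- default_dataset()
  labs <- label_mixtures(ds)
  expect_setequal(labs$treatment_id,
                  unique(ds$compositions$treatment_id))
  expect_false(anyNA(labs$biome))
  expect_false(anyNA(labs$mesh_class))
  expect_true(all(labs$evenness %in% c("equal", "non_equal")))
  # richness equals the component count of the linked composition
  comp_n <- dplyr::count(ds$compositions, treatment_id)
  expect_equal(labs$richness[match(comp_n$treatment_id, labs$treatment_id)],
               comp_n$n)
})
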
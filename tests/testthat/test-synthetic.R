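test_that("single-component recipes produce pure nodules", {
  comps <- default_components("low")
  comps$dense$target_fraction <- 1
  comps$air_like$target_fraction <- 0
  comps$intermediate$target_fraction <- 0
  rec <- nodule_recipe("low", diameter_mm = 12, components = comps, seed = 2)
  nod <- generate_nodule(rec)
  expect_equal(unname(nod$truth), c(1, 0, 0))
  expect_true(all(nod$component_map[nod$mask$voxels] == 1L))
})

test_that("identical seeds reproduce bit-identical nodules", {
  rec <- nodule_recipe("low", diameter_mm = 15, seed = 7)
  a <- generate_nodule(rec)
  b <- generate_nodule(rec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_identical(a$truth, b$truth)
})

test_that("component HU sampling matches the stated distribution", {
  comps <- default_components("low")
  comps$dense$sd_hu <- 10
  # large dense fraction for >= 5000 dense voxels at 25 mm
  comps$dense$target_fraction <- 0.8
  comps$air_like$target_fraction <- 0.05
  comps$intermediate$target_fraction <- 0.15
  nod <- generate_nodule(nodule_recipe("low", diameter_mm = 25,
                                       components = comps, seed = 5))
  dense_vox <- nod$volume$voxels[nod$component_map == 1L]
  expect_gte(length(dense_vox), 5000)
  expect_lt(abs(mean(dense_vox) - (-72.6)), 3)
})

test_that("nodule masks are single connected components of realistic size", {
  for (s in 1:4) {
    nod <- generate_nodule(nodule_recipe(sample(c("low", "high"), 1),
                                         diameter_mm = runif(1, 10, 22), seed = s))
    cc <- habitatMSI:::.cc6(as.logical(nod$mask$voxels), dim(nod$mask$voxels))
    expect_identical(attr(cc, "n_components"), 1L)
    expect_gte(sum(nod$mask$voxels), 30)
  }
  expect_error(generate_nodule(nodule_recipe("low", diameter_mm = 2)),
               class = "habitat_degenerate_geometry_error")
})

test_that("realized component fractions track recipe targets within 0.05", {
  for (s in 1:3) {
    rec <- nodule_recipe("high", diameter_mm = 16, seed = 20 + s)
    nod <- generate_nodule(rec)
    targets <- vapply(rec$components, function(c) c$target_fraction, 0)
    expect_lt(max(abs(nod$truth - targets)), 0.05)
  }
})

test_that("grade separates the dense-component fraction by construction", {
  lows <- vapply(1:40, function(s)
    generate_nodule(nodule_recipe("low", diameter_mm = 11, seed = s))$truth[["dense"]], 0)
  highs <- vapply(1:40, function(s)
    generate_nodule(nodule_recipe("high", diameter_mm = 11, seed = 100 + s))$truth[["dense"]], 0)
  expect_gt(mean(highs) - mean(lows), 0.1)
})

test_that("cohort bookkeeping: sizes, prevalence, determinism", {
  rec <- cohort_recipe(seed = 31)
  co <- generate_cohort(rec, images = FALSE)
  tab <- co$table
  expect_identical(nrow(tab), 355L)
  expect_identical(as.integer(table(tab$cohort)[c("training", "validation", "test")]),
                   c(161L, 66L, 128L))
  per <- tapply(tab$grade == "high", tab$cohort, sum)
  expect_identical(as.integer(per[c("training", "validation", "test")]),
                   as.integer(round(0.186 * c(161, 66, 128))))
  expect_identical(sum(tab$grade == "high"), 66L)
  # two runs, same seed: identical tables
  co2 <- generate_cohort(rec, images = FALSE)
  expect_identical(co$table, co2$table)
  # prevalence 0 still succeeds
  z <- generate_cohort(cohort_recipe(n_train = 5, n_val = 3, n_test = 3,
                                     prevalence_high = 0, seed = 1), images = FALSE)
  expect_true(all(z$table$grade == "low"))
})

test_that("cohort covariates carry the baseline-table structure", {
  tab <- generate_cohort(cohort_recipe(seed = 8), images = FALSE)$table
  needed <- c("gender", "age", "smoking", "alcohol", "stage", "lobe",
              "diameter_mm", "shape", "attenuation", "lobulation",
              "air_bronchogram", "spiculation", "pleural_tag", "cavity")
  expect_true(all(needed %in% names(tab)))
  # solid attenuation enriched in high grade, as in the study population
  solid <- tapply(tab$attenuation == "solid", tab$grade, mean)
  expect_gt(solid[["high"]], solid[["low"]])
  expect_gt(median(tab$diameter_mm[tab$grade == "high"]),
            median(tab$diameter_mm[tab$grade == "low"]) - 1)
})

test_that("cohort writing produces NIfTI pairs and refuses collisions", {
  dir <- tempfile("cohort_")
  rec <- cohort_recipe(n_train = 2, n_val = 1, n_test = 1, seed = 3)
  co <- generate_cohort(rec, out_dir = dir)
  files <- list.files(dir)
  expect_identical(sum(grepl("_image.nii.gz$", files)), 4L)
  expect_identical(sum(grepl("_mask.nii.gz$", files)), 4L)
  expect_true("cohort.tsv" %in% files)
  img <- read_nifti_volume(file.path(dir, "case_001_image.nii.gz"))
  msk <- read_nifti_mask(file.path(dir, "case_001_mask.nii.gz"))
  expect_identical(dim(img$voxels), dim(msk$voxels))
  expect_error(generate_cohort(rec, out_dir = dir),
               class = "habitat_output_collision_error")
  unlink(dir, recursive = TRUE)
})
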
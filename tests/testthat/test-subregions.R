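test_that("elbow selection matches worked second-difference examples", {
  expect_identical(select_k_elbow(c(100, 20, 18, 17)), 2L)
  # linear decline has no elbow: smallest interior candidate by tie-break
  expect_identical(select_k_elbow(c(100, 75, 50, 25)), 2L)
  # flat-at-zero curve returns the smallest candidate
  expect_identical(select_k_elbow(c(0, 0, 0, 0)), 1L)
  expect_error(select_k_elbow(c(10, 20, 30)), class = "habitat_invalid_curve_error")
  expect_error(select_k_elbow(c(10, 5)), class = "habitat_parameter_error")
})

test_that("three well-separated phenotype clusters are recovered (k and means)", {
  set.seed(11)
  x <- c(rnorm(200, 0.1, 0.02), rnorm(200, 0.5, 0.02), rnorm(200, 0.9, 0.02))
  m <- fit_subregion_model(x, 1:6, seed = 3)
  expect_identical(m$k, 3L)
  expect_lt(max(abs(sort(m$means) - c(0.1, 0.5, 0.9))), 0.05)
  expect_identical(select_k_elbow(m$sse_curve, m$k_candidates), 3L)
  # same inputs + same seed: identical parameters
  m2 <- fit_subregion_model(x, 1:6, seed = 3)
  expect_identical(m$means, m2$means)
  expect_identical(m$sse_curve, m2$sse_curve)
})

test_that("degenerate and limiting mixture fits behave as documented", {
  # identical phenotypes: flat zero SSE, smallest candidate
  m <- fit_subregion_model(rep(0.5, 50), 1:4, seed = 1)
  expect_identical(m$k, 1L)
  expect_true(all(m$sse_curve == 0))
  # k = 1 closed form: pooled mean / variance
  set.seed(2)
  x <- runif(300)
  m1 <- fit_subregion_model(x, 1:3, seed = 1)
  i1 <- which(m1$k_candidates == 1)
  expect_lt(abs(m1$sse_curve[i1] - sum((x - mean(x))^2)), 1e-6)
  expect_error(fit_subregion_model(runif(3), 1:6, seed = 1),
               class = "habitat_degenerate_fit_error")
})

test_that("canonical labels order components by attenuation", {
  # means 0.9 / 0.1 / 0.5 -> canonical labels 1 / 2 / 3
  expect_identical(habitatMSI:::canonical_label_order(c(0.9, 0.1, 0.5)),
                   c(1L, 2L, 3L))
  expect_identical(habitatMSI:::canonical_label_order(c(0.1, 0.9, 0.5)),
                   c(2L, 1L, 3L))
  # general k: 1 = highest, 2 = lowest, remaining descending
  expect_identical(habitatMSI:::canonical_label_order(c(0.2, 0.8, 0.5, 0.6, 0.05)),
                   c(5L, 1L, 4L, 3L, 2L))
})

test_that("canonical relabeling is invariant to component permutation", {
  v <- unit_voi(small_nodule(diameter = 13, seed = 12))
  sv <- compute_supervoxels(v$unit, v$mask)
  model <- list(weights = c(0.3, 0.3, 0.4), means = c(0.85, 0.35, 0.62),
                variances = c(0.002, 0.004, 0.003))
  perm <- c(3, 1, 2)
  mperm <- list(weights = model$weights[perm], means = model$means[perm],
                variances = model$variances[perm])
  mk <- function(m) structure(c(m, list(k = 3L,
    label_order = habitatMSI:::canonical_label_order(m$means),
    sse_curve = c(3, 2, 1), k_candidates = 1:3, fit_seed = 1L)),
    class = "subregion_model")
  a <- assign_subregions(sv, mk(model))
  b <- assign_subregions(sv, mk(mperm))
  expect_identical(a$labels, b$labels)
  # inference is deterministic
  expect_identical(assign_subregions(sv, mk(model))$labels, a$labels)
})

test_that("posterior assignment picks the dominating component", {
  model <- structure(list(k = 3L, weights = rep(1 / 3, 3),
                          means = c(0.9, 0.1, 0.5),
                          variances = rep(1e-4, 3),
                          label_order = habitatMSI:::canonical_label_order(c(0.9, 0.1, 0.5)),
                          sse_curve = c(3, 2, 1), k_candidates = 1:3,
                          fit_seed = 1L), class = "subregion_model")
  comp <- habitatMSI:::apply_posterior(c(0.9, 0.1, 0.5), model)
  expect_identical(comp, c(1L, 2L, 3L))
  expect_error(assign_subregions(structure(list(), class = "supervoxel_map"),
                                 structure(list(), class = "list")),
               class = "habitat_state_error")
})

test_that("subregion statistics count labels and attenuation exactly", {
  lab <- array(0L, dim = c(10, 10, 1))
  lab[1:3, 1:10, 1] <- 1L            # 30 voxels of label 1
  lab[4:10, 1:10, 1] <- 3L           # 70 voxels of label 3
  lm <- structure(list(labels = lab, k = 3L, spacing = c(1, 1, 1)),
                  class = "subregion_labelmap")
  hu <- array(0, dim = dim(lab))
  hu[lab == 1L] <- -70; hu[lab == 3L] <- -420
  vol <- ct_volume(hu)
  st <- subregion_stats(lm, vol)
  expect_equal(st$proportion, c(0.3, 0, 0.7))
  expect_equal(st$mean_hu[1], -70)
  expect_equal(st$mean_hu[3], -420)
  expect_true(is.na(st$mean_hu[2]) && st$degenerate[2])
  expect_equal(sum(st$proportion), 1, tolerance = 1e-9)
})

test_that("subregion model JSON serialization round-trips", {
  set.seed(4)
  x <- c(rnorm(150, 0.2, 0.03), rnorm(150, 0.7, 0.03))
  m <- fit_subregion_model(x, 1:4, seed = 9)
  tf <- tempfile(fileext = ".json")
  write_subregion_model(m, tf)
  m2 <- read_subregion_model(tf)
  expect_equal(m2$means, m$means, tolerance = 1e-12)
  expect_identical(m2$k, m$k)
  expect_identical(m2$label_order, m$label_order)
  unlink(tf)
})
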
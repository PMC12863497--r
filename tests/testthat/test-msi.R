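test_that("MSI matrix dimension and elementary counting examples", {
  lab <- array(0L, dim = c(3, 3, 3)); lab[2, 2, 2] <- 1L
  m <- build_msi_matrix(lab, k = 3)
  expect_identical(dim(unclass(m)), c(4L, 4L))
  expect_equal(m["0", "1"], 6)
  expect_equal(sum(unclass(m)) - m["0", "1"] - m["1", "0"], 0)

  lab2 <- array(0L, dim = c(4, 3, 3)); lab2[2, 2, 2] <- 1L; lab2[3, 2, 2] <- 2L
  m2 <- build_msi_matrix(lab2, k = 3)
  expect_equal(m2["1", "2"], 1)
  expect_equal(m2["0", "1"], 5)
  expect_equal(m2["0", "2"], 5)
  expect_equal(m2["0", "0"], 0)
  expect_error(build_msi_matrix(array(5L, c(2, 2, 2)), k = 3),
               class = "habitat_label_domain_error")
  expect_error(build_msi_matrix(array(0L, c(2, 2, 2)), k = 3),
               class = "habitat_empty_mask_error")
})

test_that("MSI counts equal the brute-force all-pairs oracle on random maps", {
  set.seed(99)
  for (r in 1:100) {
    k <- sample(1:3, 1)
    lab <- random_labelmap(k = k, max_dim = if (r <= 90) 8 else 12)
    conn <- if (r %% 3 == 0) 26 else 6
    m <- build_msi_matrix(lab, connectivity = conn, k = k)
    expect_identical(array(as.numeric(m), dim(m)),
                     array(as.numeric(brute_msi(lab, k, conn)), dim(m)))
  }
})

test_that("pair conservation: counts account for every ordered neighbor pair", {
  set.seed(7)
  for (r in 1:10) {
    lab <- random_labelmap(k = 3, max_dim = 9)
    m <- unclass(build_msi_matrix(lab, k = 3))
    # independent count of ordered neighbor pairs touching the mask
    d <- dim(lab)
    tot <- 0
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
        xx <- x + o[1]; yy <- y + o[2]; zz <- z + o[3]
        if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3]) next
        if (lab[x, y, z] > 0 || lab[xx, yy, zz] > 0) tot <- tot + 1
      }
    }
    expect_equal(2 * sum(m[upper.tri(m)]) + 2 * sum(diag(m)), tot)
  }
})

test_that("first-order features: canonical enumeration and counting oracle", {
  lab2 <- array(0L, dim = c(4, 3, 3)); lab2[2, 2, 2] <- 1L; lab2[3, 2, 2] <- 2L
  m <- build_msi_matrix(lab2, k = 3)
  f <- first_order_features(m)
  expect_length(f, 33L)
  expect_false(any(duplicated(names(f))))
  expect_equal(unname(f["MSI_border_proportion_1_2"]), 1 / 11)
  expect_equal(unname(f[c("volume_proportion_1", "volume_proportion_2",
                          "volume_proportion_3")]), c(0.5, 0.5, 0))
  expect_equal(unname(f["min_volume_proportion"]), 0)
  # the six border proportions sum to one whenever B > 0
  expect_equal(sum(f[sprintf("MSI_border_proportion_%d_%d", c(0,0,0,1,1,2),
                             c(1,2,3,2,3,3))]), 1, tolerance = 1e-12)
  expect_error(first_order_features(build_msi_matrix(lab2, k = 2)),
               class = "habitat_parameter_error")
})

test_that("B = 0 lesions fall back to the flagged 0/0 convention", {
  lab <- array(1L, dim = c(3, 3, 3))  # label 1 fills the grid, no background
  m <- build_msi_matrix(lab, k = 3)
  f <- first_order_features(m)
  expect_true(all(is.finite(f)))
  expect_equal(unname(f["MSI_border_proportion_1_2"]), 0)
  expect_true(attr(f, "degenerate")[["MSI_border_proportion_1_2"]])
  expect_equal(unname(f["interior_ratio_1"]), 1)
})

test_that("second-order features match closed-form evaluations", {
  P <- matrix(0, 2, 2); P[1, 2] <- P[2, 1] <- 0.5
  f <- second_order_features(P)
  expect_length(f, 5L)
  expect_equal(unname(f), c(1, -1, 0.5, 0.5, 1), ignore_attr = TRUE)
  # point mass on a diagonal cell
  Q <- matrix(0, 4, 4); Q[2, 2] <- 7
  g <- second_order_features(Q)
  expect_equal(unname(g[c("MSI_contrast", "MSI_energy", "MSI_entropy")]),
               c(0, 1, 0), ignore_attr = TRUE)
  expect_equal(unname(g["MSI_correlation"]), 0, ignore_attr = TRUE)  # degenerate marginal
  expect_true(attr(g, "degenerate")[["MSI_correlation"]])
})

test_that("the composed feature vector is stable, 38 long, and symmetric", {
  set.seed(21)
  lab <- random_labelmap(k = 3, max_dim = 9)
  v <- msi_feature_vector(lab, k = 3)
  expect_length(v, 38L)
  expect_identical(names(v)[34:38],
                   c("MSI_contrast", "MSI_correlation", "MSI_energy",
                     "MSI_homogeneity", "MSI_entropy"))
  # mirror reflections leave adjacency counts unchanged
  for (ax in 1:3) {
    idx <- rep(list(quote(expr = )), 3)
    mir <- switch(ax,
                  lab[dim(lab)[1]:1, , , drop = FALSE],
                  lab[, dim(lab)[2]:1, , drop = FALSE],
                  lab[, , dim(lab)[3]:1, drop = FALSE])
    expect_equal(msi_feature_vector(mir, k = 3), v, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # 26-connectivity variant also runs and stays finite
  v26 <- msi_feature_vector(lab, connectivity = 26, k = 3)
  expect_length(v26, 38L)
  expect_true(all(is.finite(v26)))
})

test_that("feature tables bind per-lesion vectors with stable columns", {
  set.seed(3)
  maps <- list(a = random_labelmap(3, 7), b = random_labelmap(3, 7))
  tab <- msi_feature_table(maps, k = 3)
  expect_identical(nrow(tab), 2L)
  expect_identical(ncol(tab), 39L)
  expect_identical(tab$case_id, c("a", "b"))
})
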
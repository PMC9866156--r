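test_that("PCA-env axes come from the pooled background", {
  # isotropic 2-variable background: PC1 explains about half the variance
  withr::with_seed(21, {
    bg1 <- tibble::tibble(a = rnorm(2000), b = rnorm(2000))
    bg2 <- tibble::tibble(a = rnorm(2000), b = rnorm(2000))
    occ <- tibble::tibble(a = rnorm(50), b = rnorm(50))
  })
  sp <- pca_env(bg1, bg2, occ, occ)
  expect_equal(sp$explained[1], 0.5, tolerance = 0.05)
  # identical occurrence tables project to identical score clouds
  expect_identical(sp$scores$native_occ, sp$scores$invasive_occ)

  # duplicating every background point leaves the axes unchanged
  sp2 <- pca_env(dplyr::bind_rows(bg1, bg1), dplyr::bind_rows(bg2, bg2),
                 occ, occ)
  expect_equal(sp2$pca$rotation, sp$pca$rotation)

  bg1$c <- 1; bg2$c <- 1; occ$c <- 1
  expect_warning(sp3 <- pca_env(bg1, bg2, occ, occ), "constant")
  expect_false("c" %in% sp3$variables)
  expect_error(pca_env(bg1[1:2, ], bg2, occ, occ), "at least 3")
})

test_that("the occupancy grid corrects for availability", {
  space <- grid_space()
  bg <- score_cloud(5000, sd = 1, seed = 31)

  # occurrences distributed like the background: z close to uniform over
  # the supported cells (total-variation distance)
  occ_like_bg <- score_cloud(5000, sd = 1, seed = 32)
  z <- occupancy(occ_like_bg, bg, space)
  u <- z$support / sum(z$support)
  tv <- 0.5 * sum(abs(z$z - u))
  expect_lt(tv, 0.15)

  # a single tight cluster peaks at the cluster's cell
  tight <- score_cloud(200, center = c(1, -1), sd = 0.05, seed = 33)
  zt <- occupancy(tight, bg, space)
  peak <- which(zt$z == max(zt$z), arr.ind = TRUE)[1, ]
  expect_equal(space$grid_x[peak[1]], 1, tolerance = 0.2)
  expect_equal(space$grid_y[peak[2]], -1, tolerance = 0.2)

  # duplicating every point (same weights, fixed bandwidth) leaves z alone
  zd <- occupancy(rbind(tight, tight), bg, space, bandwidth = c(0.5, 0.5))
  z1 <- occupancy(tight, bg, space, bandwidth = c(0.5, 0.5))
  expect_equal(zd$z, z1$z, tolerance = 1e-12)

  expect_error(occupancy(tight[1:3, ], bg, space), "at least 5")
  far <- score_cloud(10, center = c(50, 50), sd = 0.01, seed = 34)
  expect_error(occupancy(far, bg, space), "outside background support")
})

test_that("Schoener's D identities hold exactly", {
  z1 <- manual_occupancy(matrix(c(0.5, 0.5, 0), 1))
  z2 <- manual_occupancy(matrix(c(0, 0.5, 0.5), 1))
  expect_equal(schoener_d(z1, z1), 1.0)
  expect_equal(schoener_d(z1, z2), 0.5)
  disjoint <- manual_occupancy(matrix(c(0, 0, 1), 1))
  expect_equal(schoener_d(z1, disjoint), 0)
  expect_equal(schoener_d(manual_occupancy(matrix(c(1, 0, 0), 1)), disjoint), 0)

  # symmetry on random occupancies
  for (seed in 1:5) {
    withr::with_seed(seed, {
      a <- manual_occupancy(matrix(runif(25), 5))
      b <- manual_occupancy(matrix(runif(25), 5))
    })
    expect_equal(schoener_d(a, b), schoener_d(b, a))
    expect_gte(schoener_d(a, b), 0)
    expect_lte(schoener_d(a, b), 1)
  }
  expect_error(schoener_d(z1, manual_occupancy(matrix(1))), "dimension")
})

test_that("COUE indices decompose occupancy on the analog mask", {
  zn <- manual_occupancy(matrix(c(0.5, 0.5, 0), 1))
  zi <- manual_occupancy(matrix(c(0, 0.5, 0.5), 1))
  res <- coue(zn, zi)
  expect_equal(res$expansion, 0.5)
  expect_equal(res$stability, 0.5)
  expect_equal(res$unfilling, 0.5)

  same <- coue(zn, zn)
  expect_equal(same$expansion, 0)
  expect_equal(same$stability, 1)
  expect_equal(same$unfilling, 0)

  # invasive support inside native support: no expansion
  sub <- coue(manual_occupancy(matrix(c(0.4, 0.3, 0.3), 1)),
              manual_occupancy(matrix(c(0.5, 0.5, 0), 1)))
  expect_equal(sub$expansion, 0)

  # E + S = 1 exactly, all indices in [0,1], on random grids
  for (seed in 1:5) {
    withr::with_seed(seed, {
      a <- manual_occupancy(matrix(runif(16) * rbinom(16, 1, 0.6), 4))
      b <- manual_occupancy(matrix(runif(16) * rbinom(16, 1, 0.6), 4))
    })
    r <- coue(a, b)
    expect_equal(r$expansion + r$stability, 1, tolerance = 1e-15)
    expect_true(all(unlist(r) >= 0 & unlist(r) <= 1))
  }

  no_mask <- manual_occupancy(matrix(c(1, 0), 1),
                              support = matrix(c(FALSE, FALSE), 1))
  expect_error(coue(no_mask, no_mask), "analog")
})

test_that("equivalency test is exact on identical samples and never returns p = 0", {
  space <- grid_space()
  bg <- score_cloud(2000, sd = 1, seed = 41)
  occ <- score_cloud(100, sd = 0.3, seed = 42)
  et <- equivalency_test(occ, occ, bg, bg, space, reps = 19, seed = 1)
  expect_equal(et$observed, 1.0)
  expect_equal(et$p, 1.0)          # lower tail: every null D <= 1
  expect_gte(et$p_upper, 1 / 20)
  expect_length(et$null, 19)
  expect_true(all(et$null > 0 & et$null <= 1))

  # determinism
  et2 <- equivalency_test(occ, occ, bg, bg, space, reps = 19, seed = 1)
  expect_identical(et$null, et2$null)
})

test_that("similarity test p-values obey the permutation formula", {
  space <- grid_space()
  bg <- score_cloud(2000, sd = 1, seed = 51)
  occ <- score_cloud(150, sd = 0.3, seed = 52)
  z1 <- occupancy(occ, bg, space)
  z2 <- occupancy(score_cloud(150, sd = 0.3, seed = 53), bg, space)

  one <- similarity_test(z1, z2, reps = 1, seed = 2)
  expect_true(one$p %in% c(0.5, 1.0))

  st <- similarity_test(z1, z2, reps = 49, seed = 3)
  expect_equal(st$p, (sum(st$null >= st$observed) + 1) / 50)
  expect_gt(st$p, 0)
  # identical tight niches on a broad background: overlap beyond chance
  expect_lte(st$p, 0.1)
})

test_that("PNO profiles are normalized suitability-weighted histograms", {
  # uniform suitability over a uniform variable: flat profile
  prof <- pno_profile(seq(0, 1, length.out = 1000), rep(1, 1000), n_bins = 10)
  expect_equal(sum(prof$mass), 1)
  expect_true(all(abs(prof$mass - 0.1) < 0.01))

  withr::with_seed(61, {
    v <- rnorm(500); w <- runif(500)
  })
  expect_equal(sum(pno_profile(v, w, n_bins = 17)$mass), 1)
  expect_error(pno_profile(v, w, n_bins = 1), "n_bins")
  expect_error(pno_profile(v, w[1:3]), "length")

  # weighting by a Gaussian-response suitability peaks near the optimum
  w2 <- exp(-(v - 0.5)^2 / 0.02)
  prof2 <- pno_profile(v, w2, n_bins = 30, limits = c(-3, 3))
  expect_equal(prof2$bin_mid[which.max(prof2$mass)], 0.5, tolerance = 0.15)

  st <- generate_landscape(2, 10, 10, 0, seed = 6)
  m <- structure(list(p = matrix(500L, 10, 10), xmin = st$xmin, ymax = st$ymax,
                      cellsize = st$cellsize, scenario = "t"),
                 class = "nk_map")
  expect_error(pno_from_map(m, st, "zz"), "unknown variable")
  expect_equal(sum(pno_from_map(m, st, "env1", n_bins = 8)$mass), 1)
})

test_that("the full niche comparison returns coherent tidy output", {
  p <- make_range_pair(n_native = 120, n_invasive = 120, nrow = 40, ncol = 40,
                       seed = 3)
  vars <- names(p$native_stack$layers)
  nb <- tibble::as_tibble(as.data.frame(nichekit:::stack_matrix(p$native_stack)))
  ib <- tibble::as_tibble(as.data.frame(nichekit:::stack_matrix(p$invasive_stack)))
  nc <- niche_compare(extract_env(p$native_stack, p$native_occ)[vars],
                      extract_env(p$invasive_stack, p$invasive_occ)[vars],
                      nb, ib, R = 60, reps = 9, seed = 1)
  g <- glance(nc)
  expect_equal(g$expansion + g$stability, 1)
  expect_true(g$D > 0 && g$D <= 1)
  expect_true(all(c(g$equivalency_p, g$similarity_p_nat_to_inv,
                    g$similarity_p_inv_to_nat) > 0))
  td <- tidy(nc)
  expect_equal(nrow(td), 7)
  expect_s3_class(autoplot(nc$equivalency), "ggplot")
  expect_s3_class(autoplot(nc$z_native), "ggplot")
})
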
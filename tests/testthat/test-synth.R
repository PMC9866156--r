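test_that("landscape generation is deterministic and validates its grid", {
  a <- generate_landscape(2, 50, 50, autocorr_range = 5, seed = 1)
  b <- generate_landscape(2, 50, 50, autocorr_range = 5, seed = 1)
  expect_identical(a$layers, b$layers)
  expect_false(identical(
    a$layers,
    generate_landscape(2, 50, 50, autocorr_range = 5, seed = 2)$layers
  ))
  expect_error(generate_landscape(2, 5, 50), "degenerate")
  expect_error(generate_landscape(1, 50, 50), "n_layers")
})

test_that("layers are standardized to the requested moments", {
  st <- generate_landscape(3, 40, 40, autocorr_range = 4, seed = 3,
                           means = c(0, 10, 100), sds = c(1, 2, 5))
  for (i in 1:3) {
    expect_equal(mean(st$layers[[i]]), c(0, 10, 100)[i], tolerance = 1e-10)
    expect_equal(sd(st$layers[[i]]), c(1, 2, 5)[i], tolerance = 1e-10)
  }
})

test_that("autocorrelation range controls spatial structure (Moran's I oracle)", {
  # no smoothing: independent cells, lag-1 correlation near zero
  st0 <- generate_landscape(2, 50, 50, autocorr_range = 0, seed = 4)
  m <- st0$layers[[1]]
  lag1 <- cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)]))
  expect_lt(abs(lag1), 0.08)

  # wider kernel means strictly larger Moran's I at the same seed
  i_wide <- morans_i_queen(generate_landscape(2, 50, 50, 10, seed = 5)$layers[[1]])
  i_narrow <- morans_i_queen(generate_landscape(2, 50, 50, 2, seed = 5)$layers[[1]])
  expect_gt(i_wide, i_narrow)
  expect_lt(abs(morans_i_queen(m)), 0.08)
})

test_that("suitability surface follows the Gaussian response closed forms", {
  st <- env_stack(list(env1 = matrix(c(0, 0.5, 3, 0), 2, 2),
                       env2 = matrix(0, 2, 2)),
                  cellsize = 0.1)
  sp <- virtual_species(c(env1 = 0, env2 = 0), c(env1 = 0.5, env2 = 0.5))
  s <- suitability_surface(sp, st)$layers$suitability
  expect_equal(s[1, 1], 1.0)            # at the optimum
  expect_equal(s[2, 1], exp(-0.5))      # one variable at opt + breadth
  expect_equal(s[1, 2], exp(-18))       # far from optimum

  flat <- virtual_species(c(env1 = 0, env2 = 0), c(env1 = Inf, env2 = Inf))
  expect_true(all(suitability_surface(flat, st)$layers$suitability == 1))

  expect_error(
    suitability_surface(virtual_species(c(zz = 0), c(zz = 1)), st), "zz")
})

test_that("product aggregation stays in [0,1] and under each member response", {
  for (seed in 1:5) {
    st <- generate_landscape(3, 20, 20, 2, seed = seed)
    sp <- virtual_species(
      c(env1 = 0.2, env2 = -0.3, env3 = 0),
      c(env1 = 0.5, env2 = 0.8, env3 = Inf)
    )
    s <- suitability_surface(sp, st)$layers$suitability
    expect_true(all(s >= 0 & s <= 1))
    r1 <- exp(-(st$layers$env1 - 0.2)^2 / (2 * 0.25))
    expect_true(all(s <= r1 + 1e-12))
  }
})

test_that("occurrence sampling honours the surface and the seed", {
  z <- matrix(0, 10, 10); z[4, 7] <- 0.8
  surf <- env_stack(list(suitability = z), cellsize = 1, ymax = 10)
  occ <- sample_occurrences(surf, 5, seed = 1)
  expect_equal(nrow(occ), 5)
  expect_true(all(occ$lon == 6.5) && all(occ$lat == 6.5))  # that cell's center

  surf_u <- env_stack(list(suitability = matrix(1, 10, 10)), cellsize = 1,
                      ymax = 10)
  a <- sample_occurrences(surf_u, 100, seed = 9)
  expect_identical(a, sample_occurrences(surf_u, 100, seed = 9))

  # uniform surface: per-cell counts consistent with a uniform multinomial
  big <- sample_occurrences(surf_u, 1e4, seed = 2)
  counts <- table(factor(paste(big$lon, big$lat),
                         levels = paste(cell_centers(surf_u)$lon,
                                        cell_centers(surf_u)$lat)))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.001)

  expect_error(sample_occurrences(surf, 2, mode = "threshold", seed = 1),
               "threshold")
  expect_error(
    sample_occurrences(env_stack(list(suitability = matrix(0, 8, 8))), 1),
    "identically zero")
})

test_that("range pairs keep regions disjoint and validate counts", {
  p <- make_range_pair(n_native = 30, n_invasive = 30, nrow = 20, ncol = 20,
                       seed = 1)
  expect_equal(nrow(p$native_occ), 30)
  expect_equal(unique(p$invasive_occ$range_label), "invasive")
  ext_n <- c(p$native_stack$xmin,
             p$native_stack$xmin + 20 * p$native_stack$cellsize)
  expect_lte(ext_n[2], p$invasive_stack$xmin)

  expect_error(make_range_pair(n_native = 0), "at least one")
  expect_error(make_range_pair(nrow = 20, ncol = 20, gap = -10, seed = 1),
               "overlap")
})

test_that("niche offsets shift the invasive species' driving optimum", {
  p <- make_range_pair(niche_offset = 1.5, n_native = 20, n_invasive = 20,
                       nrow = 20, ncol = 20, seed = 2)
  resp <- p$species_invasive$response
  expect_equal(resp$optimum[resp$variable == "env1"], 1.5)
  expect_equal(resp$optimum[resp$variable == "env2"], 0)
  expect_error(make_range_pair(niche_offset = c(bad = 1)), "response variables")
})

test_that("future perturbations shift only the named layers", {
  st <- generate_landscape(2, 10, 10, 0, seed = 1)
  fut <- perturb_stack(st, add = c(env1 = 2), scenario = "2050s")
  expect_equal(fut$layers$env1, st$layers$env1 + 2)
  expect_equal(fut$layers$env2, st$layers$env2)
  expect_equal(fut$scenario, "2050s")
  set <- make_scenario_set(st, list(f1 = list(add = c(env1 = 1))))
  expect_named(set, c("near-current", "f1"))
  expect_error(perturb_stack(st, add = c(zz = 1)), "zz")
})
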
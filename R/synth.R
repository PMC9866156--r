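#' Generate a synthetic multi-layer environmental landscape
#'
#' Each layer is spatially autocorrelated Gaussian noise: seeded white noise
#' smoothed with a separable Gaussian kernel (sd = `autocorr_range` cells,
#' edge-renormalized), then standardized to the requested mean and sd. With
#' `autocorr_range = 0` cells are independent. Deterministic given `seed`.
#'
#' @param n_layers number of layers (>= 2).
#' @param nrow,ncol grid dimensions (each >= 8).
#' @param autocorr_range smoothing kernel sd, in cells (0 = none).
#' @param seed integer seed.
#' @param layer_names optional character vector of layer names; defaults to
#'   `env1..envK`.
#' @param means,sds target per-layer mean and sd after standardization
#'   (recycled; defaults 0 and 1).
#' @param xmin,ymax,cellsize grid registration (degrees).
#' @param scenario scenario tag.
#' @return an [env_stack()].
#' @export
generate_landscape <- function(n_layers, nrow = 50, ncol = 50,
                               autocorr_range = 5, seed = 1,
                               layer_names = NULL, means = 0, sds = 1,
                               xmin = 0, ymax = nrow * cellsize,
                               cellsize = 0.1, scenario = "near-current") {
  if (n_layers < 2) abort("`n_layers` must be >= 2")
  if (nrow < 8 || ncol < 8) abort("degenerate grid: need at least 8 rows and 8 columns")
  layer_names <- layer_names %||% paste0("env", seq_len(n_layers))
  means <- rep_len(means, n_layers)
  sds <- rep_len(sds, n_layers)
  layers <- withr::with_seed(seed, {
    lapply(seq_len(n_layers), function(i) {
      m <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
      if (autocorr_range > 0) m <- smooth_gaussian(m, autocorr_range)
      (m - mean(m)) / stats::sd(m) * sds[i] + means[i]
    })
  })
  names(layers) <- layer_names
  env_stack(layers, xmin = xmin, ymax = ymax, cellsize = cellsize,
            scenario = scenario)
}

# Separable Gaussian smoothing with edge renormalization: convolve values and
# a ones-mask with the same kernel and take the ratio, so edge cells are not
# damped toward zero.
smooth_gaussian <- function(m, sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  conv1 <- function(x) {
    n <- length(x)
    xp <- c(rep(0, h), x, rep(0, h))
    out <- stats::filter(xp, k, sides = 2)
    out[(h + 1):(h + n)]
  }
  ones <- matrix(1, base::nrow(m), base::ncol(m))
  pass <- function(mm) {
    mm <- apply(mm, 2, conv1)
    t(apply(t(mm), 2, conv1))
  }
  pass(m) / pass(ones)
}

#' Define a virtual species by parametric response curves
#'
#' A virtual species has a Gaussian response to each named predictor
#' (`exp(-(x - optimum)^2 / (2 breadth^2))`); an infinite breadth means a flat
#' (nuisance) response. Per-variable responses are combined into a suitability
#' in \[0, 1\] by the aggregation rule (default: product).
#'
#' @param optima named numeric vector of response optima, in predictor units.
#' @param breadths named numeric vector of response breadths (sd of the
#'   Gaussian response); `Inf` = flat response. Names must match `optima`.
#' @param aggregation `"product"` (default) or `"geometric"` mean.
#' @return an object of class `virtual_species`.
#' @export
virtual_species <- function(optima, breadths,
                            aggregation = c("product", "geometric")) {
  aggregation <- match.arg(aggregation)
  if (is.null(names(optima)) || !identical(sort(names(optima)), sort(names(breadths)))) {
    abort("`optima` and `breadths` must be named and share the same names")
  }
  if (any(breadths <= 0)) abort("breadths must be positive")
  structure(
    list(response = tibble(variable = names(optima),
                           optimum = unname(optima),
                           breadth = unname(breadths[names(optima)])),
         aggregation = aggregation),
    class = "virtual_species"
  )
}

#' Default two-driver virtual species
#'
#' Two driving variables with a shared narrow breadth plus any number of flat nuisance
#' variables — the standard ground-truth species for recovery experiments
#' (variable importance, response-curve and niche-shift checks).
#'
#' @param driving names of the two driving variables.
#' @param nuisance names of flat-response variables.
#' @param optimum,breadth shared optimum and breadth of the drivers.
#' @return a [virtual_species()].
#' @export
default_species <- function(driving = c("env1", "env2"), nuisance = "env3",
                            optimum = 0, breadth = 0.35) {
  vars <- c(driving, nuisance)
  virtual_species(
    optima = stats::setNames(rep(optimum, length(vars)), vars),
    breadths = stats::setNames(c(rep(breadth, length(driving)),
                                 rep(Inf, length(nuisance))), vars)
  )
}

#' Suitability surface of a virtual species over a landscape
#'
#' @param species a [virtual_species()].
#' @param stack an [env_stack()] providing every response variable.
#' @return an [env_stack()] with the single layer `suitability` in \[0, 1\].
#' @export
suitability_surface <- function(species, stack) {
  missing <- setdiff(species$response$variable, names(stack$layers))
  if (length(missing) > 0) {
    abort(sprintf("stack is missing response variable(s): %s",
                  paste(missing, collapse = ", ")))
  }
  d <- stack_dim(stack)
  finite <- species$response[is.finite(species$response$breadth), ]
  parts <- lapply(seq_len(base::nrow(finite)), function(i) {
    x <- stack$layers[[finite$variable[i]]]
    exp(-(x - finite$optimum[i])^2 / (2 * finite$breadth[i]^2))
  })
  if (length(parts) == 0) {
    suit <- matrix(1, d[1], d[2])
  } else if (species$aggregation == "product") {
    suit <- Reduce(`*`, parts)
  } else {
    suit <- Reduce(`*`, parts)^(1 / length(parts))
  }
  na <- Reduce(`|`, lapply(stack$layers[species$response$variable], is.na))
  suit[na] <- NA
  env_stack(list(suitability = suit), xmin = stack$xmin, ymax = stack$ymax,
            cellsize = stack$cellsize, scenario = stack$scenario)
}

#' Realized prevalence of a species on a landscape
#'
#' Fraction of valid cells with suitability >= `level`.
#'
#' @param species a [virtual_species()].
#' @param stack an [env_stack()].
#' @param level suitability threshold (default 0.5).
#' @return a single numeric fraction.
#' @export
species_prevalence <- function(species, stack, level = 0.5) {
  s <- suitability_surface(species, stack)$layers$suitability
  mean(s >= level, na.rm = TRUE)
}

#' Sample occurrence points from a suitability surface
#'
#' Probabilistic mode draws cells (with replacement) with probability
#' proportional to suitability; threshold mode draws distinct cells uniformly
#' among cells with suitability >= `threshold`. Points are placed at cell
#' centers unless `jitter` is set.
#'
#' @param surface an [env_stack()] with a `suitability` layer, as returned by
#'   [suitability_surface()].
#' @param n number of points.
#' @param mode `"probabilistic"` (default) or `"threshold"`.
#' @param seed integer seed.
#' @param range_label label for the sampled records (`"native"`/`"invasive"`).
#' @param threshold suitability cutoff for threshold mode.
#' @param jitter if `TRUE`, add uniform within-cell jitter to coordinates.
#' @return an occurrence tibble (`lon`, `lat`, `range_label`, `source`).
#' @export
sample_occurrences <- function(surface, n, mode = c("probabilistic", "threshold"),
                               seed = 1, range_label = "native",
                               threshold = 0.5, jitter = FALSE) {
  mode <- match.arg(mode)
  stopifnot_scalar_count(n, "n")
  s <- surface$layers$suitability
  if (is.null(s)) abort("`surface` must have a 'suitability' layer")
  w <- as.vector(t(s))  # row-major, matches cell_centers() order
  w[is.na(w)] <- 0
  if (all(w == 0)) abort("surface is identically zero: nothing to sample")
  cc <- cell_centers(surface)
  withr::with_seed(seed, {
    if (mode == "probabilistic") {
      idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    } else {
      ok <- which(w >= threshold)
      if (length(ok) < n) {
        abort(sprintf("threshold mode: %d cells at suitability >= %g but n = %d",
                      length(ok), threshold, n))
      }
      idx <- ok[sample.int(length(ok), n)]
    }
    lon <- cc$lon[idx]
    lat <- cc$lat[idx]
    if (jitter) {
      half <- surface$cellsize / 2
      lon <- lon + stats::runif(n, -half, half)
      lat <- lat + stats::runif(n, -half, half)
    }
    tibble(lon = lon, lat = lat, range_label = range_label, source = "synthetic")
  })
}

#' Generate a native/invasive range pair with a known niche offset
#'
#' Builds two disjoint landscapes (the "native" and "invaded" regions), a
#' virtual species, and a shifted copy of that species whose driving optima
#' are displaced by `niche_offset`; occurrences are sampled from each range's
#' own suitability surface. `niche_offset = 0` gives two samples of the
#' identical niche — the null case for equivalency testing.
#'
#' By default the invaded region reuses the native region's climate field
#' (translated geographically), so environmental availability is identical in
#' the two ranges and any niche difference is attributable to the species
#' alone — the controlled setting a virtual-species experiment needs for its
#' null case to be exchangeable. Set `shared_landscape = FALSE` for an
#' independent field realization in the invaded region (availability then
#' differs between ranges, as it does between real continents).
#'
#' @param species a [virtual_species()]; default [default_species()].
#' @param niche_offset named numeric vector of optimum shifts (predictor
#'   units) applied to the invasive-range species; names must be response
#'   variables. A single unnamed value shifts the first driving variable.
#' @param n_native,n_invasive occurrence counts per range (>= 1).
#' @param seed integer seed.
#' @param nrow,ncol,autocorr_range landscape parameters per region.
#' @param cellsize cell size in degrees.
#' @param gap longitudinal gap between the two regions (degrees).
#' @param shared_landscape if `TRUE` (default) the invaded region is a
#'   geographic translation of the native field; if `FALSE`, an independent
#'   realization.
#' @return list with `native_occ`, `invasive_occ`, `native_stack`,
#'   `invasive_stack`, `species`, `species_invasive`.
#' @export
make_range_pair <- function(species = default_species(), niche_offset = 0,
                            n_native = 500, n_invasive = 500, seed = 1,
                            nrow = 80, ncol = 80, autocorr_range = 5,
                            cellsize = 0.1, gap = 5, shared_landscape = TRUE) {
  if (n_native < 1 || n_invasive < 1) abort("need at least one occurrence per range")
  vars <- species$response$variable
  if (is.null(names(niche_offset))) {
    if (length(niche_offset) == 1) {
      driver <- vars[is.finite(species$response$breadth)][1]
      niche_offset <- stats::setNames(niche_offset, driver)
    } else if (length(niche_offset) == length(vars)) {
      niche_offset <- stats::setNames(niche_offset, vars)
    } else {
      abort("`niche_offset` length must match the number of response variables")
    }
  }
  if (!all(names(niche_offset) %in% vars)) {
    abort("`niche_offset` names must be response variables")
  }

  width <- ncol * cellsize
  native_stack <- generate_landscape(
    length(vars), nrow, ncol, autocorr_range, seed = derive_seed(seed, "land-nat"),
    layer_names = vars, cellsize = cellsize, xmin = 0, scenario = "native"
  )
  if (shared_landscape) {
    invasive_stack <- native_stack
    invasive_stack$xmin <- width + gap
    invasive_stack$scenario <- "invasive"
  } else {
    invasive_stack <- generate_landscape(
      length(vars), nrow, ncol, autocorr_range, seed = derive_seed(seed, "land-inv"),
      layer_names = vars, cellsize = cellsize, xmin = width + gap,
      scenario = "invasive"
    )
  }
  if (stack_extent(native_stack)["xmax"] > stack_extent(invasive_stack)["xmin"]) {
    abort("native and invaded regions overlap")
  }

  sp_inv <- species
  for (v in names(niche_offset)) {
    i <- match(v, sp_inv$response$variable)
    sp_inv$response$optimum[i] <- sp_inv$response$optimum[i] + niche_offset[[v]]
  }

  native_occ <- sample_occurrences(
    suitability_surface(species, native_stack), n_native,
    seed = derive_seed(seed, "occ-nat"), range_label = "native"
  )
  invasive_occ <- sample_occurrences(
    suitability_surface(sp_inv, invasive_stack), n_invasive,
    seed = derive_seed(seed, "occ-inv"), range_label = "invasive"
  )

  list(native_occ = native_occ, invasive_occ = invasive_occ,
       native_stack = native_stack, invasive_stack = invasive_stack,
       species = species, species_invasive = sp_inv)
}
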
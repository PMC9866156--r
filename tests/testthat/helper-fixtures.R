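# Shared fixtures, all generated in code. Sizes are kept small; the
# acceptance suite exercises the full study conditions.

# A small deterministic landscape + specialist species + labelled samples.
small_bundle <- function(seed = 1, nrow = 30, ncol = 30, n_pres = 150,
                         n_abs = 300) {
  stack <- generate_landscape(3, nrow, ncol, autocorr_range = 3, seed = seed,
                              cellsize = 0.1)
  species <- default_species()
  surface <- suitability_surface(species, stack)
  pres <- sample_occurrences(surface, n_pres, seed = seed + 1)
  pabs <- sample_pseudo_absence(stack, pres, n_abs, seed = seed + 2)
  list(stack = stack, species = species, surface = surface,
       presences = pres, absences = pabs,
       samples = make_sample_matrix(stack, pres, pabs))
}

# Linearly separable two-class data: classes split cleanly on x1.
separable_blobs <- function(n = 60, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    label = rep(c(1L, 0L), each = n),
    x1 = c(rnorm(n, 3, 0.3), rnorm(n, -3, 0.3)),
    x2 = rnorm(2 * n)
  ))
}

# Hand-built occupancy object on a tiny grid (masses given row-major).
manual_occupancy <- function(z, support = NULL) {
  z <- as.matrix(z)
  structure(list(z = z / sum(z), o = z / sum(z),
                 e = matrix(1 / length(z), nrow(z), ncol(z)),
                 support = support %||% matrix(TRUE, nrow(z), ncol(z)),
                 grid_x = seq_len(nrow(z)), grid_y = seq_len(ncol(z))),
            class = "nk_occupancy")
}

# GLM fitted so that it predicts a constant probability everywhere
# (constant predictors give a rank-deficient fit = the label mean).
constant_model <- function(p_const, variables = c("env1", "env2", "env3")) {
  stopifnot(p_const > 0, p_const < 1)
  n <- 100
  k <- round(p_const * n)
  stopifnot(k / n == p_const)  # keep the constant exact
  train <- tibble::tibble(label = rep(c(1L, 0L), c(k, n - k)))
  for (v in variables) train[[v]] <- 1
  suppressWarnings(sdm_fit(sdm_spec("GLM"), train))
}

# Minimal ensemble wrapper around explicit member models.
manual_ensemble <- function(models, tss = rep(0.5, length(models)),
                            weighted = FALSE, cutoff = 500) {
  structure(
    list(families = unique(vapply(models, function(m) m$spec$family, "")),
         members = tibble::tibble(model = models, tss = tss,
                                  rep = seq_along(models), status = "ok"),
         weighted = weighted, cutoff = cutoff, boundaries = c(400, 600)),
    class = "nk_ensemble"
  )
}

# Niche-score fixture: occurrence/background score matrices around given
# centers, plus a matching niche-space grid.
score_cloud <- function(n, center = c(0, 0), sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- cbind(rnorm(n, center[1], sd), rnorm(n, center[2], sd))
    colnames(m) <- c("pc1", "pc2")
    m
  })
}

grid_space <- function(lim = 4, R = 60) {
  list(grid_x = seq(-lim, lim, length.out = R),
       grid_y = seq(-lim, lim, length.out = R), R = R)
}

# Direct-sum Moran's I with queen contiguity, the independent oracle for
# landscape autocorrelation (computed via neighbour shifts; exact).
morans_i_queen <- function(m) {
  x <- m - mean(m)
  num <- 0
  w_sum <- 0
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nrow(shifts))) {
    dr <- shifts$dr[i]; dc <- shifts$dc[i]
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    a <- x[r1, c1]
    b <- x[r1 - dr, c1 - dc]
    num <- num + sum(a * b)
    w_sum <- w_sum + length(a)
  }
  (length(x) / w_sum) * num / sum(x^2)
}
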
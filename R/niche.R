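#' PCA-env: a two-axis environmental niche space
#'
#' Fits a PCA on the pooled background environments of both ranges (centered
#' and scaled) and projects the occurrence environments of each range onto
#' the same two leading axes. A rectangular R x R grid spanning the pooled
#' background scores (with a small margin) carries the occupancy densities.
#'
#' @param native_bg,invasive_bg data frames of background environments (one
#'   row per background point, shared variables).
#' @param native_occ,invasive_occ data frames of occurrence environments.
#' @param R grid resolution per axis (default 100).
#' @param margin fractional extension of the score range on each side
#'   (default 0.05), so kernel mass near the edge stays on the grid.
#' @return an object of class `nk_niche_space`: PCA rotation, explained
#'   variance, grid axes, and scores for all four point sets.
#' @export
pca_env <- function(native_bg, invasive_bg, native_occ, invasive_occ,
                    R = 100, margin = 0.05) {
  sets <- lapply(list(native_bg = native_bg, invasive_bg = invasive_bg,
                      native_occ = native_occ, invasive_occ = invasive_occ),
                 as_tibble)
  vars <- Reduce(intersect, lapply(sets, names))
  vars <- setdiff(vars, c("lon", "lat", "range_label", "label", "source"))
  if (length(vars) < 2) abort("need at least 2 shared environmental variables")
  if (base::nrow(sets$native_bg) < 3 || base::nrow(sets$invasive_bg) < 3) {
    abort("need at least 3 background points per range")
  }
  pooled_bg <- dplyr::bind_rows(sets$native_bg[vars], sets$invasive_bg[vars])
  constant <- vapply(pooled_bg, function(v) stats::sd(v) == 0, TRUE)
  if (any(constant)) {
    warn(sprintf("dropping constant variable(s): %s",
                 paste(vars[constant], collapse = ", ")))
    vars <- vars[!constant]
    pooled_bg <- pooled_bg[vars]
  }
  pca <- stats::prcomp(pooled_bg, center = TRUE, scale. = TRUE)
  expl <- pca$sdev^2 / sum(pca$sdev^2)
  scores <- lapply(sets, function(s) {
    sc <- stats::predict(pca, s[vars])[, 1:2, drop = FALSE]
    colnames(sc) <- c("pc1", "pc2")
    sc
  })
  bg_scores <- rbind(scores$native_bg, scores$invasive_bg)
  lims <- apply(bg_scores, 2, function(v) {
    r <- range(v); r + c(-1, 1) * margin * diff(r)
  })
  structure(
    list(pca = pca, variables = vars, explained = expl[1:2],
         grid_x = seq(lims[1, 1], lims[2, 1], length.out = R),
         grid_y = seq(lims[1, 2], lims[2, 2], length.out = R),
         R = R, scores = scores),
    class = "nk_niche_space"
  )
}

#' @export
print.nk_niche_space <- function(x, ...) {
  cat(sprintf("<nk_niche_space> %d variables, %d x %d grid, PC1/PC2 explain %.1f%% / %.1f%%\n",
              length(x$variables), x$R, x$R,
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

# Silverman rule-of-thumb bandwidth (0.9 * min(sd, IQR/1.34) * n^(-1/5),
# times 4 for kde2d's internal h/4 convention) with a fallback for
# degenerate spreads.
nrd_safe <- function(v, fallback) {
  h <- 4 * stats::bw.nrd0(v)
  if (!is.finite(h) || h <= 0) fallback else h
}

#' Background availability density on a niche-space grid
#'
#' Kernel density of the background scores, normalized to sum 1, together
#' with the background-support mask: cells whose density reaches the
#' `support_quantile`-th percentile of the density observed at the background
#' points themselves. (A quantile over raw grid values would be useless — a
#' Gaussian KDE is positive everywhere and spans dozens of orders of
#' magnitude, so near-zero tail cells would pass and their `o/e` ratios would
#' swallow the occupancy mass.) Precompute this once when building many
#' occupancies against the same background, e.g. in permutation tests.
#'
#' @param scores_bg two-column matrix of background scores.
#' @param space an `nk_niche_space`.
#' @param bandwidth optional numeric length-2 bandwidth override.
#' @param support_quantile availability-support quantile (default 0.05).
#' @return an `nk_bg_density` list with `e`, `support`, `threshold`.
#' @export
bg_density <- function(scores_bg, space, bandwidth = NULL,
                       support_quantile = 0.05) {
  cell <- c(diff(space$grid_x[1:2]), diff(space$grid_y[1:2]))
  lims <- c(range(space$grid_x), range(space$grid_y))
  h_bg <- bandwidth %||% c(nrd_safe(scores_bg[, 1], cell[1]),
                           nrd_safe(scores_bg[, 2], cell[2]))
  e <- MASS::kde2d(scores_bg[, 1], scores_bg[, 2], h = h_bg,
                   n = space$R, lims = lims)$z
  e <- e / sum(e)
  bg_cells <- cbind(
    pmin(pmax(findInterval(scores_bg[, 1], space$grid_x), 1), space$R),
    pmin(pmax(findInterval(scores_bg[, 2], space$grid_y), 1), space$R)
  )
  thr <- stats::quantile(e[bg_cells], support_quantile, names = FALSE)
  structure(list(e = e, support = e >= thr, threshold = thr),
            class = "nk_bg_density")
}

#' Availability-corrected occupancy grid
#'
#' Gaussian kernel densities of the occurrences (`o`) and the background
#' (`e`) on the niche-space grid (bandwidth: Silverman's rule per axis, or a
#' supplied value). Occupancy is `z = o / e` restricted to background
#' support — cells whose availability density reaches the 5th percentile of
#' the density observed at the background points — and normalized to sum 1,
#' so occupancy never extends beyond environments that actually exist.
#'
#' @param scores_occ two-column matrix of occurrence scores (`pc1`, `pc2`).
#' @param scores_bg two-column matrix of background scores, or a precomputed
#'   [bg_density()] object.
#' @param space an `nk_niche_space`.
#' @param bandwidth optional numeric length-2 bandwidth override.
#' @param support_quantile quantile of the background density at the
#'   background points below which availability is treated as absent
#'   (default 0.05).
#' @return an object of class `nk_occupancy`: matrices `z`, `o`, `e`, logical
#'   `support`, and the grid axes.
#' @export
occupancy <- function(scores_occ, scores_bg, space, bandwidth = NULL,
                      support_quantile = 0.05) {
  if (base::nrow(scores_occ) < 5) abort("need at least 5 occurrence points")
  cell <- c(diff(space$grid_x[1:2]), diff(space$grid_y[1:2]))
  lims <- c(range(space$grid_x), range(space$grid_y))
  h_occ <- bandwidth %||% c(nrd_safe(scores_occ[, 1], cell[1]),
                            nrd_safe(scores_occ[, 2], cell[2]))
  o <- MASS::kde2d(scores_occ[, 1], scores_occ[, 2], h = h_occ,
                   n = space$R, lims = lims)$z
  if (sum(o) == 0) abort("all occurrences fall outside background support")
  o <- o / sum(o)
  bg <- if (inherits(scores_bg, "nk_bg_density")) scores_bg else {
    bg_density(scores_bg, space, bandwidth = bandwidth,
               support_quantile = support_quantile)
  }
  e <- bg$e
  support <- bg$support
  z <- matrix(0, space$R, space$R)
  z[support] <- o[support] / e[support]
  if (sum(z) == 0) abort("all occurrences fall outside background support")
  z <- z / sum(z)
  structure(list(z = z, o = o, e = e, support = support,
                 grid_x = space$grid_x, grid_y = space$grid_y),
            class = "nk_occupancy")
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.nk_occupancy <- function(object, ...) {
  df <- expand.grid(pc1 = object$grid_x, pc2 = object$grid_y)
  df$z <- as.vector(object$z)  # kde2d z: rows = x, cols = y
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc1, y = .data$pc2, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = "Occupancy in environmental space") +
    ggplot2::theme_minimal()
}

occupancy_grid_of <- function(x) {
  if (inherits(x, "nk_occupancy")) x$z else x
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum |z1 - z2|`, from 0 (no overlap) to 1 (identical
#' occupancies). Symmetric in its arguments.
#'
#' @param z1,z2 `nk_occupancy` objects (or plain occupancy matrices) on the
#'   same grid.
#' @return D in \[0, 1\].
#' @export
schoener_d <- function(z1, z2) {
  m1 <- occupancy_grid_of(z1)
  m2 <- occupancy_grid_of(z2)
  if (!all(dim(m1) == dim(m2))) abort("occupancy grids differ in dimension")
  1 - 0.5 * sum(abs(m1 - m2))
}

#' Niche expansion, stability and unfilling (COUE)
#'
#' Restricted to the analog environment (cells with background support in
#' both ranges) and with each occupancy renormalized there: expansion `E` is
#' the invasive occupancy in cells empty of native occupancy, stability
#' `S = 1 - E`, and unfilling `U` is the native occupancy in cells empty of
#' invasive occupancy.
#'
#' @param z_native,z_invasive `nk_occupancy` objects on a shared grid.
#' @return tibble with `expansion`, `stability`, `unfilling`.
#' @export
coue <- function(z_native, z_invasive) {
  if (!inherits(z_native, "nk_occupancy") || !inherits(z_invasive, "nk_occupancy")) {
    abort("`z_native` and `z_invasive` must be nk_occupancy objects")
  }
  mask <- z_native$support & z_invasive$support
  if (!any(mask)) abort("empty analog-environment mask")
  zn <- z_native$z * mask
  zi <- z_invasive$z * mask
  if (sum(zn) == 0 || sum(zi) == 0) abort("no occupancy mass inside the analog mask")
  zn <- zn / sum(zn)
  zi <- zi / sum(zi)
  E <- sum(zi[zn == 0])
  U <- sum(zn[zi == 0])
  tibble(expansion = E, stability = 1 - E, unfilling = U)
}

#' Niche equivalency permutation test
#'
#' Pools the two ranges' occurrence scores and re-splits them at random into
#' the original sample sizes `reps` times; each replicate's occupancies are
#' rebuilt against the fixed range backgrounds and Schoener's D recomputed.
#' The primary p-value is lower-tailed
#' (`p = (#\{null D <= observed D\} + 1) / (reps + 1)`): equivalency is
#' rejected when the observed overlap is lower than the permutation null.
#' The upper-tail p is also returned.
#'
#' @param scores_occ1,scores_occ2 occurrence score matrices (from
#'   [pca_env()]).
#' @param scores_bg1,scores_bg2 background score matrices.
#' @param space an `nk_niche_space`.
#' @param reps permutation count (default 100).
#' @param seed integer seed.
#' @return an `nk_perm_test` list: `observed`, `null` (length `reps`), `p`
#'   (lower tail), `p_upper`, `reps`.
#' @export
equivalency_test <- function(scores_occ1, scores_occ2, scores_bg1, scores_bg2,
                             space, reps = 100, seed = 1) {
  stopifnot_scalar_count(reps, "reps")
  bg1 <- bg_density(scores_bg1, space)
  bg2 <- bg_density(scores_bg2, space)
  z1 <- occupancy(scores_occ1, bg1, space)
  z2 <- occupancy(scores_occ2, bg2, space)
  observed <- schoener_d(z1, z2)
  pooled <- rbind(scores_occ1, scores_occ2)
  n1 <- base::nrow(scores_occ1)
  null <- withr::with_seed(derive_seed(seed, "equivalency"), {
    vapply(seq_len(reps), function(i) {
      take <- sample.int(base::nrow(pooled), n1)
      schoener_d(
        occupancy(pooled[take, , drop = FALSE], bg1, space),
        occupancy(pooled[-take, , drop = FALSE], bg2, space)
      )
    }, 0)
  })
  structure(list(observed = observed, null = null,
                 p = (sum(null <= observed) + 1) / (reps + 1),
                 p_upper = (sum(null >= observed) + 1) / (reps + 1),
                 reps = reps, test = "equivalency"),
            class = "nk_perm_test")
}

# Rigid integer-cell shift of an occupancy matrix; truncated mass is dropped
# and the remainder renormalized. Returns NULL when no mass survives.
shift_grid <- function(z, dr, dc) {
  n <- base::nrow(z); m <- base::ncol(z)
  out <- matrix(0, n, m)
  src_r <- seq_len(n) - dr
  src_c <- seq_len(m) - dc
  ok_r <- src_r >= 1 & src_r <= n
  ok_c <- src_c >= 1 & src_c <= m
  if (!any(ok_r) || !any(ok_c)) return(NULL)
  out[which(ok_r), which(ok_c)] <- z[src_r[ok_r], src_c[ok_c], drop = FALSE]
  s <- sum(out)
  if (s == 0) return(NULL)
  out / s
}

# Mass-centroid cell (row, col) of an occupancy matrix.
centroid_cell <- function(z) {
  rows <- rowSums(z); cols <- colSums(z)
  c(round(sum(seq_along(rows) * rows) / sum(rows)),
    round(sum(seq_along(cols) * cols) / sum(cols)))
}

#' Niche similarity permutation test (one direction)
#'
#' The test range's occupancy density is relocated rigidly and uniformly at
#' random within its own background support `reps` times; D against the fixed
#' other range is recomputed each time. Upper-tailed:
#' `p = (#\{null D >= observed D\} + 1) / (reps + 1)` — small p means the two
#' niches overlap more than expected from background availability alone.
#'
#' @param z_test occupancy of the range being relocated (`nk_occupancy`).
#' @param z_ref fixed occupancy of the other range.
#' @param reps permutation count (default 100).
#' @param seed integer seed.
#' @return an `nk_perm_test` list.
#' @export
similarity_test <- function(z_test, z_ref, reps = 100, seed = 1) {
  stopifnot_scalar_count(reps, "reps")
  observed <- schoener_d(z_test, z_ref)
  support_cells <- which(z_test$support, arr.ind = TRUE)
  if (base::nrow(support_cells) < 2) abort("background support too small to shift")
  from <- centroid_cell(z_test$z)
  null <- withr::with_seed(derive_seed(seed, "similarity"), {
    vapply(seq_len(reps), function(i) {
      for (try in 1:50) {
        to <- support_cells[sample.int(base::nrow(support_cells), 1), ]
        shifted <- shift_grid(z_test$z, to[1] - from[1], to[2] - from[2])
        if (!is.null(shifted)) return(schoener_d(shifted, z_ref$z))
      }
      schoener_d(z_test$z, z_ref$z)
    }, 0)
  })
  structure(list(observed = observed, null = null,
                 p = (sum(null >= observed) + 1) / (reps + 1),
                 p_upper = (sum(null >= observed) + 1) / (reps + 1),
                 reps = reps, test = "similarity"),
            class = "nk_perm_test")
}

#' @export
print.nk_perm_test <- function(x, ...) {
  cat(sprintf("<nk_perm_test> %s: observed D = %.3f, p = %.4g (%d reps)\n",
              x$test, x$observed, x$p, x$reps))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.nk_perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(D = object$null), ggplot2::aes(x = .data$D)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(title = sprintf("%s test: observed D vs null (p = %.4g)",
                                  object$test, object$p)) +
    ggplot2::theme_minimal()
}

#' Full niche comparison between a native and an invasive range
#'
#' Convenience driver: PCA-env on the pooled backgrounds, occupancy grids,
#' Schoener's D, COUE indices, the equivalency test and both directions of
#' the similarity test.
#'
#' @param native_occ_env,invasive_occ_env data frames of occurrence
#'   environments.
#' @param native_bg_env,invasive_bg_env data frames of background
#'   environments.
#' @param R niche-grid resolution (default 100).
#' @param reps permutation count for both tests (default 100).
#' @param seed integer seed.
#' @return an object of class `nk_coue` with fields `space`, `z_native`,
#'   `z_invasive`, `D`, `indices` (E/S/U), `equivalency`,
#'   `similarity_nat_to_inv`, `similarity_inv_to_nat`.
#' @export
niche_compare <- function(native_occ_env, invasive_occ_env,
                          native_bg_env, invasive_bg_env,
                          R = 100, reps = 100, seed = 1) {
  space <- pca_env(native_bg_env, invasive_bg_env,
                   native_occ_env, invasive_occ_env, R = R)
  z_nat <- occupancy(space$scores$native_occ, space$scores$native_bg, space)
  z_inv <- occupancy(space$scores$invasive_occ, space$scores$invasive_bg, space)
  structure(
    list(space = space, z_native = z_nat, z_invasive = z_inv,
         D = schoener_d(z_nat, z_inv),
         indices = coue(z_nat, z_inv),
         equivalency = equivalency_test(space$scores$native_occ,
                                        space$scores$invasive_occ,
                                        space$scores$native_bg,
                                        space$scores$invasive_bg,
                                        space, reps = reps,
                                        seed = derive_seed(seed, "eqv")),
         similarity_nat_to_inv = similarity_test(z_nat, z_inv, reps = reps,
                                                 seed = derive_seed(seed, "sim12")),
         similarity_inv_to_nat = similarity_test(z_inv, z_nat, reps = reps,
                                                 seed = derive_seed(seed, "sim21"))),
    class = "nk_coue"
  )
}

#' @export
print.nk_coue <- function(x, ...) {
  cat(sprintf("<nk_coue> D = %.3f | E = %.3f S = %.3f U = %.3f | equivalency p = %.4g\n",
              x$D, x$indices$expansion, x$indices$stability,
              x$indices$unfilling, x$equivalency$p))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.nk_coue <- function(x, ...) {
  tibble(
    statistic = c("D", "expansion", "stability", "unfilling",
                  "equivalency_p", "similarity_p_nat_to_inv",
                  "similarity_p_inv_to_nat"),
    value = c(x$D, x$indices$expansion, x$indices$stability,
              x$indices$unfilling, x$equivalency$p,
              x$similarity_nat_to_inv$p, x$similarity_inv_to_nat$p)
  )
}

#' @exportS3Method generics::glance
#' @export
glance.nk_coue <- function(x, ...) {
  tibble(D = x$D, expansion = x$indices$expansion,
         stability = x$indices$stability, unfilling = x$indices$unfilling,
         equivalency_p = x$equivalency$p,
         similarity_p_nat_to_inv = x$similarity_nat_to_inv$p,
         similarity_p_inv_to_nat = x$similarity_inv_to_nat$p,
         pc1_var = x$space$explained[1], pc2_var = x$space$explained[2])
}

#' Predicted niche occupancy (PNO) profile
#'
#' Histogram of an environmental variable weighted by a suitability or
#' occupancy mass, normalized to sum 1 — the marginal environmental
#' requirement implied by the model.
#'
#' @param values numeric vector of the variable.
#' @param weights non-negative weights (suitability `p`, occupancy mass, ...).
#' @param n_bins number of bins (>= 2).
#' @param limits optional `c(min, max)` range for the bins.
#' @return tibble with `bin_mid` and `mass` (sums to 1).
#' @export
pno_profile <- function(values, weights, n_bins = 20, limits = range(values)) {
  if (n_bins < 2) abort("`n_bins` must be >= 2")
  if (length(values) != length(weights)) abort("values/weights length mismatch")
  keep <- is.finite(values) & is.finite(weights)
  values <- values[keep]; weights <- weights[keep]
  if (sum(weights) <= 0) abort("total weight must be positive")
  edges <- seq(limits[1], limits[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1), n_bins)
  mass <- vapply(seq_len(n_bins), function(b) sum(weights[bin == b]), 0)
  tibble(bin_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
         mass = mass / sum(mass))
}

#' PNO profile of one stack variable under a projected suitability map
#'
#' @param map an `nk_map` from [project_suitability()].
#' @param stack the [env_stack()] the map was projected on.
#' @param variable layer name.
#' @param n_bins number of bins.
#' @return tibble from [pno_profile()].
#' @export
pno_from_map <- function(map, stack, variable, n_bins = 20) {
  if (!variable %in% names(stack$layers)) {
    abort(sprintf("unknown variable '%s'", variable))
  }
  vals <- as.vector(t(stack$layers[[variable]]))
  w <- as.vector(t(map$p))
  keep <- !is.na(vals) & !is.na(w)
  pno_profile(vals[keep], w[keep], n_bins = n_bins)
}
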
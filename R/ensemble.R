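#' Select the top-k model families by mean AUC and TSS
#'
#' Ranks families by `(mean AUC + mean TSS) / 2` descending; ties are broken
#' by TSS, then family name.
#'
#' @param summary tibble with `family`, `auc`, `tss` (see [summarize_evals()]).
#' @param k number of families to keep (default 3).
#' @return character vector of `k` family names, best first.
#' @export
select_top_k <- function(summary, k = 3) {
  if (k > base::nrow(summary)) abort("`k` exceeds the number of summarized families")
  summary |>
    dplyr::mutate(score = (.data$auc + .data$tss) / 2) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$tss), .data$family) |>
    dplyr::slice_head(n = k) |>
    dplyr::pull("family")
}

#' Build an ensemble from replicated fits
#'
#' Keeps every successful replicate of the top-k families as a committee
#' member. The ensemble binarization cutoff (0-1000 scale) is recomputed per
#' run: each replicate's holdout is scored by that replicate's member models,
#' labels and averaged scores are pooled across replicates, and the
#' TSS-maximizing threshold of the pooled set becomes the cutoff — the one
#' cutoff reused for all scenario projections.
#'
#' @param replicates an `nk_replicates` tibble from [run_replicates()].
#' @param data the sample matrix the replicates were fitted on (for pooled
#'   holdout scoring).
#' @param k number of member families (default 3).
#' @param weighted if `TRUE`, members are TSS-weighted in [ensemble_predict()].
#' @param boundaries upper class boundaries of the four-class scheme
#'   (default `c(400, 600)`).
#' @return an object of class `nk_ensemble`.
#' @export
build_ensemble <- function(replicates, data, k = 3, weighted = FALSE,
                           boundaries = c(400, 600)) {
  summary <- summarize_evals(replicates)
  families <- select_top_k(summary, k)
  members <- replicates |>
    dplyr::filter(.data$family %in% families, .data$status == "ok")
  if (base::nrow(members) == 0) abort("no successful member replicates")

  # pooled holdout predictions of the per-replicate committees
  pooled <- purrr::map_dfr(unique(members$rep), function(r) {
    rows <- members[members$rep == r, ]
    test_idx <- rows$test_idx[[1]]
    test <- data[test_idx, ]
    scores <- rowMeans(vapply(rows$model, function(m) predict(m, test),
                              numeric(base::nrow(test))))
    tibble(label = test$label, score = scores)
  })
  ev <- max_tss(pooled$label, pooled$score)
  cutoff <- max(1, min(999, round(ev$cutoff * 1000)))

  structure(
    list(families = families, members = members, weighted = weighted,
         cutoff = cutoff, boundaries = boundaries,
         pooled_auc = roc_auc(pooled$label, pooled$score),
         pooled_tss = ev$tss_max, summary = summary),
    class = "nk_ensemble"
  )
}

#' @export
print.nk_ensemble <- function(x, ...) {
  cat(sprintf("<nk_ensemble> %d member replicate(s) from {%s}; cutoff %d/1000\n",
              base::nrow(x$members), paste(x$families, collapse = ", "), x$cutoff))
  invisible(x)
}

#' @exportS3Method generics::glance
#' @export
glance.nk_ensemble <- function(x, ...) {
  tibble(n_members = base::nrow(x$members),
         families = paste(x$families, collapse = ","),
         auc = x$pooled_auc, tss = x$pooled_tss, cutoff = x$cutoff)
}

#' Ensemble suitability prediction on the 0-1000 scale
#'
#' Unweighted committee mean over all member replicate scores (TSS-weighted
#' mean when the ensemble was built with `weighted = TRUE`), scaled by 1000
#' and rounded to integer once, at ensemble output.
#'
#' @param em an `nk_ensemble`.
#' @param newdata data frame over the model variables.
#' @return integer vector of `p` values in \[0, 1000\].
#' @export
ensemble_predict <- function(em, newdata) {
  if (base::nrow(em$members) == 0) abort("ensemble has no members")
  scores <- vapply(em$members$model, function(m) predict(m, newdata),
                   numeric(base::nrow(newdata)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (em$weighted) {
    w <- em$members$tss
    p <- as.vector(scores %*% (w / sum(w)))
  } else {
    p <- rowMeans(scores)
  }
  as.integer(round(p * 1000))
}

#' Binarize a 0-1000 suitability map
#'
#' @param p integer matrix/vector of suitability values (0-1000), `NA` = nodata.
#' @param cutoff suitable iff `p >= cutoff`; must lie in (0, 1000).
#' @return 0/1 values with `NA` preserved.
#' @export
binarize <- function(p, cutoff) {
  if (cutoff <= 0 || cutoff >= 1000) abort("`cutoff` must be in (0, 1000)")
  out <- ifelse(p >= cutoff, 1L, 0L)
  if (is.matrix(p)) out <- matrix(out, base::nrow(p), base::ncol(p))
  out
}

#' Four-class suitability map
#'
#' Partitions \[0, 1000\] into unsuitable `[0, c)`, low `[c, 400)`, moderate
#' `[400, 600)` and high `[600, 1000]`, where `c` is the data-derived
#' TSS-maximizing cutoff. `c` must be below the first fixed boundary.
#'
#' @param p suitability values (0-1000).
#' @param cutoff data-derived cutoff `c`.
#' @param boundaries fixed upper boundaries (default `c(400, 600)`).
#' @return integer classes 0-3 (`NA` preserved) with a
#'   `levels` attribute `c("unsuitable", "low", "moderate", "high")`.
#' @export
classify4 <- function(p, cutoff, boundaries = c(400, 600)) {
  if (cutoff >= boundaries[1]) {
    abort(sprintf("cutoff (%g) must be below the first class boundary (%g)",
                  cutoff, boundaries[1]))
  }
  out <- ifelse(p >= boundaries[2], 3L,
         ifelse(p >= boundaries[1], 2L,
         ifelse(p >= cutoff, 1L, 0L)))
  if (is.matrix(p)) out <- matrix(out, base::nrow(p), base::ncol(p))
  attr(out, "levels") <- c("unsuitable", "low", "moderate", "high")
  out
}

#' Permutation variable importance of an ensemble
#'
#' For each variable: `1 - r`, where `r` is the Pearson correlation between
#' ensemble predictions on the original data and on data with that variable's
#' column permuted, averaged over `n_perm` seeded permutations. Negative
#' correlations are clamped to importance 1. A constant-prediction ensemble
#' yields importance 0 for every variable, with a warning.
#'
#' @param em an `nk_ensemble`.
#' @param data sample matrix (predictors; `label` ignored).
#' @param n_perm number of permutations per variable (default 3).
#' @param seed integer seed.
#' @param variables variables to score (default: the model variables). A
#'   variable no member model uses scores 0 — permuting it cannot change the
#'   predictions.
#' @return tibble with `variable`, `importance` in \[0, 1\], sorted descending.
#' @export
variable_importance <- function(em, data, n_perm = 3, seed = 1,
                                variables = NULL) {
  stopifnot_scalar_count(n_perm, "n_perm")
  variables <- variables %||% em$members$model[[1]]$variables
  data <- as_tibble(data)
  base_p <- ensemble_predict(em, data)
  if (stats::sd(base_p) == 0) {
    warn("constant-prediction ensemble: all importances are 0")
    return(tibble(variable = variables, importance = 0))
  }
  imp <- vapply(variables, function(v) {
    vals <- vapply(seq_len(n_perm), function(i) {
      perm <- data
      perm[[v]] <- withr::with_seed(derive_seed(seed, paste0("perm-", v), i),
                                    sample(perm[[v]]))
      p <- ensemble_predict(em, perm)
      if (stats::sd(p) == 0) return(1)
      1 - stats::cor(base_p, p)
    }, 0)
    mean(pmin(vals, 1))
  }, 0)
  tibble(variable = variables, importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Ensemble response curve for one variable
#'
#' Evaluation-strip curve: the target variable is varied over `grid` while
#' every other variable is held at its background mean.
#'
#' @param em an `nk_ensemble`.
#' @param variable variable name.
#' @param grid ascending numeric grid of values for `variable`.
#' @param background sample matrix supplying the means of the other variables.
#' @return tibble of class `nk_response`: `value`, `p` (0-1000).
#' @export
response_curve <- function(em, variable, grid, background) {
  variables <- em$members$model[[1]]$variables
  if (!variable %in% variables) abort(sprintf("unknown variable '%s'", variable))
  if (is.unsorted(grid)) abort("`grid` must be sorted ascending")
  background <- as_tibble(background)
  newdata <- as_tibble(lapply(
    stats::setNames(variables, variables),
    function(v) rep(mean(background[[v]]), length(grid))
  ))
  newdata[[variable]] <- grid
  out <- tibble(value = grid, p = ensemble_predict(em, newdata))
  class(out) <- c("nk_response", class(out))
  attr(out, "variable") <- variable
  out
}

#' Suitable range of a response curve
#'
#' Maximal intervals of the variable where the response (on the 0-1 scale,
#' i.e. `p / 1000`) is at least `level`. The default level 0.6 is the
#' highly-suitable threshold.
#'
#' @param curve an `nk_response` tibble from [response_curve()].
#' @param level suitability level on the 0-1 scale (default 0.6).
#' @return tibble with `start`, `end` per maximal interval (possibly empty).
#' @export
suitable_range <- function(curve, level = 0.6) {
  ok <- curve$p / 1000 >= level
  if (!any(ok)) return(tibble(start = numeric(0), end = numeric(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble(start = curve$value[starts[keep]], end = curve$value[ends[keep]])
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.nk_response <- function(object, level = 0.6, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$p / 1000)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = level, linetype = "dashed") +
    ggplot2::labs(x = attr(object, "variable"), y = "ensemble suitability",
                  title = sprintf("Response curve (%s)", attr(object, "variable"))) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
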
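#' Area under the ROC curve
#'
#' Mann-Whitney formulation via midranks: the probability that a random
#' presence outscores a random absence, with ties contributing 1/2.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) abort("labels and scores differ in length")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Maximize the true skill statistic over thresholds
#'
#' Evaluates `TSS(t) = sensitivity(t) + specificity(t) - 1` at every distinct
#' observed score plus `+Inf`, with a prediction positive iff `score >= t`.
#' Ties are broken toward the smallest threshold, i.e. the most inclusive
#' predicted-suitable area — the conservative choice for invasion early
#' warning.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @return list with `tss_max`, `cutoff`, `sensitivity`, `specificity`.
#' @export
max_tss <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  thresholds <- c(sort(unique(scores)), Inf)
  stat <- vapply(thresholds, function(t) {
    pos <- scores >= t
    sens <- sum(pos & labels == 1) / n1
    spec <- sum(!pos & labels == 0) / n0
    c(sens + spec - 1, sens, spec)
  }, numeric(3))
  best <- which(stat[1, ] == max(stat[1, ]))[1]  # smallest t among ties
  list(tss_max = stat[1, best], cutoff = thresholds[best],
       sensitivity = stat[2, best], specificity = stat[3, best])
}

#' Per-family means over replicates
#'
#' @param replicates an `nk_replicates` tibble from [run_replicates()] (or any
#'   tibble with `family`, `status`, `auc`, `tss`).
#' @return tibble with one row per family: mean `auc`, mean `tss`, number of
#'   successful replicates `n`. Failed replicates are excluded, with a message
#'   giving the count.
#' @export
summarize_evals <- function(replicates) {
  n_failed <- sum(replicates$status != "ok")
  if (n_failed > 0) inform(sprintf("excluding %d failed replicate(s)", n_failed))
  replicates |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(auc = mean(.data$auc), tss = mean(.data$tss),
                     n = dplyr::n(), .groups = "drop")
}

#' @exportS3Method generics::tidy
#' @export
tidy.nk_replicates <- function(x, ...) {
  tibble::as_tibble(x)[c("family", "rep", "status", "auc", "tss", "cutoff",
                         "sensitivity", "specificity")]
}

#' @exportS3Method generics::glance
#' @export
glance.nk_replicates <- function(x, ...) {
  tibble(n_models = base::nrow(x),
         n_families = length(unique(x$family)),
         n_failed = sum(x$status != "ok"),
         mean_auc = mean(x$auc, na.rm = TRUE),
         mean_tss = mean(x$tss, na.rm = TRUE))
}

#' Plot per-family evaluation metrics
#'
#' @param object an `nk_replicates` tibble.
#' @param ... unused.
#' @return a ggplot: AUC and TSS per family across replicates.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.nk_replicates <- function(object, ...) {
  df <- tidy.nk_replicates(object) |>
    dplyr::filter(.data$status == "ok") |>
    tidyr::pivot_longer(c("auc", "tss"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Holdout performance by model family") +
    ggplot2::theme_minimal()
}
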
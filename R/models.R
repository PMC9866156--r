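#' The eight supported single-SDM families
#' @export
SDM_FAMILIES <- c("ANN", "CTA", "FDA", "GBM", "GLM", "MAXENT", "RF", "SRE")

#' Specify a single species-distribution model
#'
#' @param family one of [SDM_FAMILIES].
#' @param hyperparams named list overriding the family's documented defaults.
#' @param seed integer seed controlling every stochastic element of the fit.
#' @return an object of class `sdm_spec`.
#' @export
sdm_spec <- function(family, hyperparams = list(), seed = 1L) {
  family <- toupper(family)
  if (!family %in% SDM_FAMILIES) {
    abort(sprintf("unknown family '%s'; must be one of %s", family,
                  paste(SDM_FAMILIES, collapse = ", ")))
  }
  hp <- utils::modifyList(default_hyperparams(family), hyperparams)
  structure(list(family = family, hyperparams = hp, seed = as.integer(seed)),
            class = "sdm_spec")
}

# Fixed, documented defaults per family. The contract is the interface and
# the performance invariants, not bit-compatibility with any other toolkit.
default_hyperparams <- function(family) {
  switch(family,
    ANN    = list(size = 5, decay_grid = c(0.001, 0.01, 0.1), cv_folds = 3,
                  maxit = 300),
    CTA    = list(),
    FDA    = list(knot_probs = c(0.25, 0.5, 0.75)),
    GBM    = list(max_rounds = 2500, eta = 0.01, max_depth = 3,
                  early_stopping = 25, holdout_frac = 0.2),
    GLM    = list(),
    # background weight 10: large enough for the IWLR presence-background
    # approximation, small enough for a stable glmnet path
    MAXENT = list(knot_probs = c(0.25, 0.5, 0.75), background_weight = 10,
                  alpha = 1, cv_folds = 5),
    RF     = list(ntree = 500),
    SRE    = list(quantiles = c(0.025, 0.975))
  )
}

hinge_basis <- function(x, knots) {
  out <- vapply(knots, function(k) pmax(x - k, 0), numeric(length(x)))
  colnames(out) <- paste0("h", seq_along(knots))
  out
}

# Linear + quadratic + per-variable hinge expansion used by FDA and MAXENT.
expand_features <- function(x, variables, knots, quadratic = TRUE) {
  blocks <- lapply(variables, function(v) {
    b <- cbind(lin = x[[v]], hinge_basis(x[[v]], knots[[v]]))
    if (quadratic) b <- cbind(b, quad = x[[v]]^2)
    colnames(b) <- paste0(v, "_", colnames(b))
    b
  })
  do.call(cbind, blocks)
}

#' Fit a single SDM
#'
#' One fit contract for all eight families. `train` is a sample matrix: a
#' `label` column (1 = presence, 0 = pseudo-absence) plus predictors.
#' Family recipes: GLM = binomial regression with linear + quadratic terms;
#' CTA = single classification tree; RF = bagged tree ensemble; GBM =
#' stagewise boosted trees with internal-holdout early stopping; ANN =
#' one-hidden-layer network, weight decay chosen by internal CV; FDA =
#' linear discriminant on a hinge/quadratic basis expansion; MAXENT =
#' penalized presence-background logistic (IWLR form) on
#' linear + quadratic + hinge features; SRE = per-variable percentile
#' envelope on presences only.
#'
#' @param spec an [sdm_spec()].
#' @param train sample-matrix tibble (see [make_sample_matrix()]).
#' @return an object of class `nk_sdm` with a [predict][predict.nk_sdm] method.
#' @export
sdm_fit <- function(spec, train) {
  if (!inherits(spec, "sdm_spec")) abort("`spec` must be an sdm_spec")
  train <- as_tibble(train)
  if (!"label" %in% names(train)) abort("`train` needs a `label` column")
  variables <- setdiff(names(train), "label")
  y <- as.integer(train$label)
  x <- train[variables]
  n_pres <- sum(y == 1)
  if (spec$family == "SRE") {
    if (n_pres < 5) abort("SRE needs at least 5 presences")
  } else if (n_pres == 0 || sum(y == 0) == 0) {
    abort(sprintf("%s needs both presence and background records", spec$family))
  }
  hp <- spec$hyperparams
  fit <- withr::with_seed(spec$seed, switch(spec$family,
    GLM = fit_glm(x, y, variables),
    CTA = fit_cta(x, y),
    RF = fit_rf(x, y, hp),
    GBM = fit_gbm(x, y, hp),
    ANN = fit_ann(x, y, hp),
    FDA = fit_fda(x, y, variables, hp),
    MAXENT = fit_maxent(x, y, variables, hp),
    SRE = fit_sre(x, y, variables, hp)
  ))
  structure(list(spec = spec, variables = variables, fit = fit),
            class = "nk_sdm")
}

quad_formula <- function(variables) {
  stats::as.formula(paste(
    "label ~", paste(sprintf("%s + I(%s^2)", variables, variables), collapse = " + ")
  ))
}

fit_glm <- function(x, y, variables) {
  df <- dplyr::mutate(x, label = y)
  suppressWarnings(stats::glm(quad_formula(variables), data = df, family = stats::binomial()))
}

fit_cta <- function(x, y) {
  df <- dplyr::mutate(x, label = factor(y, levels = c(0, 1)))
  rpart::rpart(label ~ ., data = df, method = "class")
}

fit_rf <- function(x, y, hp) {
  randomForest::randomForest(x = as.data.frame(x),
                             y = factor(y, levels = c(0, 1)),
                             ntree = hp$ntree)
}

fit_gbm <- function(x, y, hp) {
  xm <- as.matrix(x)
  # stratified internal holdout for early stopping
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  hold <- c(sample(idx1, max(1, round(hp$holdout_frac * length(idx1)))),
            sample(idx0, max(1, round(hp$holdout_frac * length(idx0)))))
  dtrain <- xgboost::xgb.DMatrix(xm[-hold, , drop = FALSE], label = y[-hold],
                                 nthread = 1)
  dval <- xgboost::xgb.DMatrix(xm[hold, , drop = FALSE], label = y[hold],
                               nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = hp$eta,
                  max_depth = hp$max_depth, nthread = 1,
                  eval_metric = "logloss"),
    data = dtrain, nrounds = hp$max_rounds, evals = list(val = dval),
    early_stopping_rounds = hp$early_stopping, verbose = 0
  )
  best <- xgboost::xgb.attr(booster, "best_iteration")
  list(booster = booster,
       best_iter = if (is.null(best)) hp$max_rounds else as.integer(best))
}

fit_ann <- function(x, y, hp) {
  xm <- as.matrix(x)
  folds <- rep_len(seq_len(hp$cv_folds), length(y))[sample.int(length(y))]
  cv_auc <- vapply(hp$decay_grid, function(dec) {
    aucs <- vapply(seq_len(hp$cv_folds), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) return(NA_real_)
      net <- nnet::nnet(xm[tr, , drop = FALSE], y[tr], size = hp$size,
                        decay = dec, maxit = hp$maxit, entropy = TRUE,
                        trace = FALSE)
      roc_auc(y[!tr], as.vector(stats::predict(net, xm[!tr, , drop = FALSE])))
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  decay <- hp$decay_grid[which.max(cv_auc)]
  net <- nnet::nnet(xm, y, size = hp$size, decay = decay, maxit = hp$maxit,
                    entropy = TRUE, trace = FALSE)
  list(net = net, decay = decay)
}

fit_fda <- function(x, y, variables, hp) {
  knots <- lapply(x, function(v) stats::quantile(v, hp$knot_probs, names = FALSE))
  fm <- expand_features(x, variables, knots, quadratic = TRUE)
  keep <- apply(fm, 2, function(cc) stats::sd(cc) > 0)
  fm <- fm[, keep, drop = FALSE]
  lda <- suppressWarnings(
    MASS::lda(fm, grouping = factor(y, levels = c(0, 1)))
  )
  list(lda = lda, knots = knots, keep = keep)
}

fit_maxent <- function(x, y, variables, hp) {
  knots <- lapply(x, function(v) stats::quantile(v, hp$knot_probs, names = FALSE))
  fm <- expand_features(x, variables, knots, quadratic = TRUE)
  w <- ifelse(y == 1, 1, hp$background_weight)
  w <- w / mean(w)
  foldid <- rep_len(seq_len(hp$cv_folds), length(y))[sample.int(length(y))]
  cv <- glmnet::cv.glmnet(fm, y, family = "binomial", weights = w,
                          alpha = hp$alpha, foldid = foldid)
  list(cv = cv, knots = knots)
}

fit_sre <- function(x, y, variables, hp) {
  pres <- x[y == 1, , drop = FALSE]
  env <- lapply(pres, function(v) stats::quantile(v, hp$quantiles, names = FALSE))
  list(envelope = env)
}

#' Predict suitability scores from a fitted SDM
#'
#' @param object an `nk_sdm` from [sdm_fit()].
#' @param newdata data frame providing every model variable.
#' @param ... unused.
#' @return numeric scores in \[0, 1\]; SRE returns 0/1 envelope membership.
#' @export
predict.nk_sdm <- function(object, newdata, ...) {
  missing <- setdiff(object$variables, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("newdata is missing variable(s): %s",
                  paste(missing, collapse = ", ")))
  }
  x <- as_tibble(newdata)[object$variables]
  f <- object$fit
  p <- switch(object$spec$family,
    GLM = suppressWarnings(
      as.vector(stats::predict(f, newdata = x, type = "response"))),
    CTA = stats::predict(f, newdata = x, type = "prob")[, "1"],
    RF = stats::predict(f, newdata = as.data.frame(x), type = "prob")[, "1"],
    GBM = stats::predict(f$booster,
                         xgboost::xgb.DMatrix(as.matrix(x), nthread = 1),
                         iterationrange = c(1, f$best_iter)),
    ANN = as.vector(stats::predict(f$net, as.matrix(x))),
    FDA = {
      fm <- expand_features(x, object$variables, f$knots,
                            quadratic = TRUE)[, f$keep, drop = FALSE]
      stats::predict(f$lda, fm)$posterior[, "1"]
    },
    MAXENT = {
      fm <- expand_features(x, object$variables, f$knots, quadratic = TRUE)
      as.vector(stats::predict(f$cv, fm, s = "lambda.min", type = "response"))
    },
    SRE = {
      inside <- rep(TRUE, base::nrow(x))
      for (v in object$variables) {
        e <- f$envelope[[v]]
        inside <- inside & x[[v]] >= e[1] & x[[v]] <= e[2]
      }
      as.numeric(inside)
    }
  )
  unname(clip01(as.numeric(p)))
}

#' @export
print.nk_sdm <- function(x, ...) {
  cat(sprintf("<nk_sdm> family %s, %d variable(s), seed %d\n",
              x$spec$family, length(x$variables), x$spec$seed))
  invisible(x)
}

#' Fit replicated SDMs over stratified train/test splits
#'
#' Draws `reps` independent stratified random 75/25 splits (presences and
#' pseudo-absences split together, stratified by label), fits every requested
#' family on each training fold, and evaluates AUC and max-TSS on the fold's
#' holdout. A family that fails on a fold is recorded as failed, never
#' silently dropped.
#'
#' @param data sample-matrix tibble (`label` + predictors).
#' @param families character vector of families (default all eight).
#' @param split training fraction (default 0.75).
#' @param reps number of repetitions (default 10).
#' @param seed master seed; per-split and per-fit sub-seeds are derived with
#'   [derive_seed()].
#' @return an `nk_replicates` tibble: one row per family x replicate with the
#'   fitted model, holdout indices, evaluation metrics and status.
#' @export
run_replicates <- function(data, families = SDM_FAMILIES, split = 0.75,
                           reps = 10, seed = 1) {
  data <- as_tibble(data)
  families <- toupper(families)
  bad <- setdiff(families, SDM_FAMILIES)
  if (length(bad) > 0) abort(sprintf("unknown family: %s", paste(bad, collapse = ", ")))
  idx1 <- which(data$label == 1)
  idx0 <- which(data$label == 0)
  if (length(idx1) < 4 || length(idx0) < 4) {
    abort("need at least 4 records of each class to split")
  }
  rows <- purrr::map_dfr(seq_len(reps), function(r) {
    test_idx <- withr::with_seed(derive_seed(seed, "split", r), {
      c(sample(idx1, max(1, round((1 - split) * length(idx1)))),
        sample(idx0, max(1, round((1 - split) * length(idx0)))))
    })
    train <- data[-test_idx, ]
    test <- data[test_idx, ]
    purrr::map_dfr(families, function(fam) {
      spec <- sdm_spec(fam, seed = derive_seed(seed, fam, r))
      res <- tryCatch({
        m <- sdm_fit(spec, train)
        scores <- predict(m, test)
        ev <- max_tss(test$label, scores)
        tibble(family = fam, rep = r, status = "ok", error = NA_character_,
               auc = roc_auc(test$label, scores), tss = ev$tss_max,
               cutoff = ev$cutoff, sensitivity = ev$sensitivity,
               specificity = ev$specificity,
               model = list(m), test_idx = list(test_idx))
      }, error = function(e) {
        tibble(family = fam, rep = r, status = "failed",
               error = conditionMessage(e),
               auc = NA_real_, tss = NA_real_, cutoff = NA_real_,
               sensitivity = NA_real_, specificity = NA_real_,
               model = list(NULL), test_idx = list(test_idx))
      })
      res
    })
  })
  structure(rows, class = c("nk_replicates", class(rows)))
}
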
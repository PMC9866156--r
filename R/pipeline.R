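#' Default run configuration
#'
#' All stage parameters of the end-to-end pipeline with their standard
#' defaults: 75/25 stratified split, 10 repetitions, 1000 pseudo-absences,
#' |r| > 0.8 collinearity filter, top-3 ensemble, four-class boundaries at
#' 400 and 600, 100 niche permutations on a 100 x 100 grid.
#'
#' @param ... named overrides of any top-level field.
#' @return a `RunConfig` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    families = SDM_FAMILIES,
    split = 0.75,
    reps = 10,
    n_pseudo_absence = 1000,
    collinearity_threshold = 0.8,
    priority = NULL,          # default: input column order
    thinning_cell_size = NULL, # default: the analysis grid's cell size
    k = 3,
    boundaries = c(400, 600),
    niche_reps = 100,
    niche_R = 100,
    synth = list(nrow = 80, ncol = 80, n_layers = 3, autocorr_range = 5,
                 cellsize = 0.1, n_native = 500, n_invasive = 500,
                 niche_offset = 0),
    # three futures of increasing severity: additive warming-style shifts on
    # the first (temperature-role) driver; the nuisance layer is untouched,
    # mirroring non-climatic layers held constant across scenarios
    scenarios = list(
      `2050s-SSP1-2.6` = list(add = c(env1 = 0.25)),
      `2050s-SSP2-4.5` = list(add = c(env1 = 0.50)),
      `2050s-SSP5-8.5` = list(add = c(env1 = 0.75, env2 = 0.25))
    )
  )
  utils::modifyList(cfg, list(...))
}

#' Read a YAML run configuration
#'
#' @param path YAML file; any field of [default_config()] may be set.
#' @return a `RunConfig` list (defaults filled in).
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  cfg
}

validate_config <- function(cfg) {
  bad <- setdiff(toupper(cfg$families), SDM_FAMILIES)
  if (length(bad) > 0) {
    abort(sprintf("config error: unknown model family: %s", paste(bad, collapse = ", ")))
  }
  if (cfg$split <= 0 || cfg$split >= 1) abort("config error: split must be in (0, 1)")
  if (length(cfg$boundaries) != 2 || diff(cfg$boundaries) <= 0) {
    abort("config error: boundaries must be two increasing values")
  }
  if (cfg$k > length(cfg$families)) abort("config error: k exceeds number of families")
  invisible(cfg)
}

# Tiny FNV-1a content hash for the run manifest.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", derive_seed(0L, s))
}

#' Run the full pipeline on a synthetic bundle
#'
#' Executes the stages in workflow order: simulate a native/invaded range
#' pair, clean + thin occurrences, draw pseudo-absences, extract and filter
#' predictors, fit replicated SDMs, evaluate and select the top-k ensemble,
#' project near-current and perturbed future scenarios (class areas, change
#' maps, centroid shifts), and quantify niche dynamics between ranges.
#' Deterministic given `seed`; every stage derives its own sub-seed.
#'
#' @param config a `RunConfig` (see [default_config()], [read_config()]).
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, tables are written as CSV,
#'   niche results and a run manifest as JSON.
#' @return an `nk_run` list with all stage outputs.
#' @export
run_pipeline <- function(config = default_config(), seed = 1, out_dir = NULL) {
  validate_config(config)
  sy <- config$synth

  # --- simulate
  pair <- make_range_pair(
    niche_offset = sy$niche_offset, n_native = sy$n_native,
    n_invasive = sy$n_invasive, seed = derive_seed(seed, "synth"),
    nrow = sy$nrow, ncol = sy$ncol, autocorr_range = sy$autocorr_range,
    cellsize = sy$cellsize
  )
  stack <- pair$native_stack

  # --- prep
  thin_cs <- config$thinning_cell_size %||% stack$cellsize
  occ <- clean_occurrences(pair$native_occ)
  occ <- thin_to_grid(occ, thin_cs, origin = c(stack$xmin,
                                               stack_extent(stack)["ymin"]))
  pabs <- sample_pseudo_absence(stack, occ, n = config$n_pseudo_absence,
                                seed = derive_seed(seed, "pabs"))
  samples <- make_sample_matrix(stack, occ, pabs)
  retained <- filter_collinear(samples, threshold = config$collinearity_threshold,
                               priority = config$priority)
  samples <- samples[c("label", retained)]

  # --- models + evaluation
  replicates <- run_replicates(samples, families = config$families,
                               split = config$split, reps = config$reps,
                               seed = derive_seed(seed, "fit"))
  summary <- summarize_evals(replicates)

  # --- ensemble
  em <- build_ensemble(replicates, samples, k = config$k,
                       boundaries = config$boundaries)
  importance <- variable_importance(em, samples, n_perm = 3,
                                    seed = derive_seed(seed, "imp"))
  curves <- purrr::map(stats::setNames(retained, retained), function(v) {
    response_curve(em, v, grid = seq(min(samples[[v]]), max(samples[[v]]),
                                     length.out = 100),
                   background = samples)
  })
  ranges <- purrr::map_dfr(curves, function(cu) {
    r <- suitable_range(cu)
    if (base::nrow(r) > 0) r$variable <- attr(cu, "variable")
    r
  })

  # --- projection
  scenario_stacks <- make_scenario_set(stack, config$scenarios)
  maps <- purrr::map(scenario_stacks, function(s) project_suitability(em, s))
  class_maps <- purrr::map(maps, function(m)
    classify4(m$p, em$cutoff, config$boundaries))
  areas <- purrr::imap_dfr(class_maps, function(cm, tag)
    dplyr::mutate(area_by_class(cm, maps[[tag]]), scenario = tag))
  bins <- purrr::map(maps, function(m) binarize(m$p, em$cutoff))
  base_tag <- names(maps)[1]
  changes <- purrr::imap(bins[-1], function(b, tag)
    change_map(bins[[base_tag]], b, maps[[tag]]))
  centroids <- purrr::imap_dfr(bins, function(b, tag)
    centroid_suitable(b, maps[[tag]]))
  shifts <- purrr::map_dfr(names(maps)[-1], function(tag) {
    dplyr::mutate(centroid_shift(centroids[centroids$scenario == base_tag, ],
                                 centroids[centroids$scenario == tag, ]),
                  scenario = tag)
  })

  # --- niche dynamics between ranges
  nat_bg <- as_tibble(as.data.frame(stack_matrix(pair$native_stack)))
  inv_bg <- as_tibble(as.data.frame(stack_matrix(pair$invasive_stack)))
  nat_bg <- nat_bg[stats::complete.cases(nat_bg), ]
  inv_bg <- inv_bg[stats::complete.cases(inv_bg), ]
  vars <- names(pair$native_stack$layers)
  niche <- niche_compare(
    extract_env(pair$native_stack, pair$native_occ)[vars],
    extract_env(pair$invasive_stack, pair$invasive_occ)[vars],
    nat_bg, inv_bg, R = config$niche_R, reps = config$niche_reps,
    seed = derive_seed(seed, "niche")
  )

  run <- structure(
    list(config = config, seed = seed, pair = pair, occurrences = occ,
         pseudo_absences = pabs, samples = samples, retained = retained,
         replicates = replicates, summary = summary, ensemble = em,
         importance = importance, curves = curves, suitable_ranges = ranges,
         maps = maps, class_maps = class_maps, areas = areas,
         changes = changes, centroids = centroids, shifts = shifts,
         niche = niche),
    class = "nk_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.nk_run <- function(x, ...) {
  cat(sprintf("<nk_run> seed %d | %d models | ensemble {%s} AUC %.3f TSS %.3f | D = %.3f\n",
              x$seed, base::nrow(x$replicates),
              paste(x$ensemble$families, collapse = ","),
              x$ensemble$pooled_auc, x$ensemble$pooled_tss, x$niche$D))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  w(run$occurrences, "occurrences.csv")
  w(run$pseudo_absences, "pseudo_absences.csv")
  w(tidy(run$replicates), "evaluations.csv")
  w(run$summary, "summary.csv")
  w(run$importance, "importance.csv")
  w(run$areas, "areas.csv")
  w(run$centroids, "centroids.csv")
  if (base::nrow(run$shifts) > 0) w(run$shifts, "centroid_shifts.csv")
  jsonlite::write_json(
    list(D = run$niche$D,
         indices = as.list(run$niche$indices),
         equivalency = list(observed = run$niche$equivalency$observed,
                            null = run$niche$equivalency$null,
                            p = run$niche$equivalency$p),
         similarity = list(
           nat_to_inv = list(p = run$niche$similarity_nat_to_inv$p),
           inv_to_nat = list(p = run$niche$similarity_inv_to_nat$p))),
    file.path(out_dir, "niche.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(seed = run$seed, config_hash = config_hash(run$config),
         retained_variables = run$retained,
         families = run$ensemble$families, cutoff = run$ensemble$cutoff,
         n_models = base::nrow(run$replicates),
         auc = run$ensemble$pooled_auc, tss = run$ensemble$pooled_tss),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}
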
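#' Clean an occurrence table
#'
#' Validates coordinates, removes exact duplicate `(lon, lat, range_label)`
#' records, and drops records matching a user-supplied exclusion list (e.g.
#' administrative-centroid coordinates that stand in for unknown true
#' locations). Record order is otherwise preserved.
#'
#' @param occ occurrence tibble with `lon`, `lat` and optionally
#'   `range_label`, `source`.
#' @param exclude optional data frame with `lon`, `lat` of coordinates to
#'   drop (exact match).
#' @return the cleaned occurrence tibble.
#' @export
clean_occurrences <- function(occ, exclude = NULL) {
  occ <- as_tibble(occ)
  if (base::nrow(occ) == 0) return(occ)
  if (!all(c("lon", "lat") %in% names(occ))) abort("`occ` needs lon and lat columns")
  bad <- which(!is.finite(occ$lon) | !is.finite(occ$lat) |
                 occ$lon < -180 | occ$lon >= 180 | abs(occ$lat) > 90)
  if (length(bad) > 0) {
    abort(sprintf("malformed coordinates at row(s): %s",
                  paste(utils::head(bad, 10), collapse = ", ")))
  }
  if (!"range_label" %in% names(occ)) occ$range_label <- NA_character_
  keep <- !duplicated(occ[, c("lon", "lat", "range_label")])
  occ <- occ[keep, ]
  if (!is.null(exclude) && base::nrow(exclude) > 0) {
    drop <- paste(occ$lon, occ$lat) %in% paste(exclude$lon, exclude$lat)
    occ <- occ[!drop, ]
  }
  occ
}

#' Thin occurrences to one record per grid cell
#'
#' Assigns each record to the cell `floor((coord - origin) / cell_size)` and
#' keeps the first record encountered per cell, so thinning is idempotent and
#' order-stable.
#'
#' @param occ occurrence tibble.
#' @param cell_size thinning cell size in degrees (> 0).
#' @param origin grid origin `c(lon, lat)`; default `c(-180, -90)`.
#' @return the thinned occurrence tibble.
#' @export
thin_to_grid <- function(occ, cell_size, origin = c(-180, -90)) {
  if (cell_size <= 0) abort("`cell_size` must be positive")
  if (base::nrow(occ) == 0) return(occ)
  key <- paste(floor((occ$lon - origin[1]) / cell_size),
               floor((occ$lat - origin[2]) / cell_size))
  occ[!duplicated(key), ]
}

#' Sample pseudo-absence (background) points
#'
#' Draws `n` distinct cells uniformly at random from the valid (no-nodata)
#' cells of the stack, excluding cells occupied by a presence. Points are
#' placed at cell centers. Deterministic given `seed`.
#'
#' @param stack an [env_stack()].
#' @param presences occurrence tibble of presence points.
#' @param n number of pseudo-absences (default 1000).
#' @param seed integer seed.
#' @param range_label label for the background records.
#' @return an occurrence tibble of `n` background points.
#' @export
sample_pseudo_absence <- function(stack, presences, n = 1000, seed = 1,
                                  range_label = "background") {
  stopifnot_scalar_count(n, "n")
  valid <- !Reduce(`|`, lapply(stack$layers, is.na))
  pres <- cell_of(stack, presences$lon, presences$lat)
  d <- stack_dim(stack)
  occupied <- matrix(FALSE, d[1], d[2])
  inb <- !is.na(pres$row)
  occupied[cbind(pres$row[inb], pres$col[inb])] <- TRUE
  pool <- which(t(valid & !occupied))  # row-major cell index
  if (length(pool) < n) {
    abort(sprintf("only %d valid background cells available, %d requested (short by %d)",
                  length(pool), n, n - length(pool)))
  }
  cc <- cell_centers(stack)
  idx <- withr::with_seed(seed, pool[sample.int(length(pool), n)])
  tibble(lon = cc$lon[idx], lat = cc$lat[idx],
         range_label = range_label, source = "pseudo-absence")
}

#' Extract environmental values at points
#'
#' Nearest-cell (containing-cell) lookup per layer. Rows hitting nodata in any
#' layer are dropped with a warning giving the count; points outside the
#' raster extent are an error naming the first offending point index.
#'
#' @param stack an [env_stack()].
#' @param points occurrence tibble.
#' @param variables layers to extract (default all).
#' @return tibble of predictor values, one row per retained point, with the
#'   point columns (`lon`, `lat`, `range_label`) preserved.
#' @export
extract_env <- function(stack, points, variables = names(stack$layers)) {
  rc <- cell_of(stack, points$lon, points$lat)
  out_of_extent <- which(is.na(rc$row))
  if (length(out_of_extent) > 0) {
    abort(sprintf("point(s) outside raster extent, first at index %d",
                  out_of_extent[1]))
  }
  vals <- purrr::map_dfc(variables, function(v) {
    m <- stack$layers[[v]]
    if (is.null(m)) abort(sprintf("stack is missing layer '%s'", v))
    tibble("{v}" := m[cbind(rc$row, rc$col)])
  })
  keep_cols <- intersect(c("lon", "lat", "range_label"), names(points))
  out <- dplyr::bind_cols(as_tibble(points)[keep_cols], vals)
  bad <- !stats::complete.cases(out[variables])
  if (any(bad)) {
    warn(sprintf("dropped %d point(s) falling on nodata cells", sum(bad)))
    out <- out[!bad, ]
  }
  out
}

#' Build a labelled presence/background sample matrix
#'
#' @param stack an [env_stack()].
#' @param presences,absences occurrence tibbles.
#' @param variables predictors to extract.
#' @return tibble with `label` (1 = presence, 0 = pseudo-absence) and one
#'   column per predictor.
#' @export
make_sample_matrix <- function(stack, presences, absences,
                               variables = names(stack$layers)) {
  p <- extract_env(stack, presences, variables)
  a <- extract_env(stack, absences, variables)
  dplyr::bind_rows(
    dplyr::mutate(p[variables], label = 1L, .before = 1),
    dplyr::mutate(a[variables], label = 0L, .before = 1)
  )
}

#' Greedy collinearity filter
#'
#' Scans variables in priority order and accepts a variable iff its absolute
#' Pearson correlation with every already-accepted variable is at most
#' `threshold`. Zero-variance columns are excluded with a warning
#' (correlation undefined). The retained set is a greedy certificate: every
#' dropped variable correlates above the threshold with some retained one.
#'
#' @param data data frame of candidate predictors (a `label` column, if
#'   present, is ignored).
#' @param threshold maximum tolerated `|r|` (default 0.8).
#' @param priority character vector ordering the variables (default: column
#'   order); earlier = more important.
#' @return character vector of retained variable names, in priority order.
#' @export
filter_collinear <- function(data, threshold = 0.8, priority = NULL) {
  data <- as_tibble(data)
  data$label <- NULL
  vars <- priority %||% names(data)
  if (!all(vars %in% names(data))) abort("`priority` names unknown variables")
  if (length(vars) < 2) abort("need at least 2 variables")
  if (base::nrow(data) < 3) abort("need at least 3 rows")
  sds <- vapply(data[vars], stats::sd, 0)
  if (any(sds == 0)) {
    warn(sprintf("excluding zero-variance variable(s): %s",
                 paste(vars[sds == 0], collapse = ", ")))
    vars <- vars[sds > 0]
  }
  retained <- character(0)
  for (v in vars) {
    r <- vapply(retained, function(u) abs(stats::cor(data[[v]], data[[u]])), 0)
    if (all(r <= threshold)) retained <- c(retained, v)
  }
  retained
}

#' Read / write occurrence CSV
#'
#' Header: `lon, lat` with optional `range_label`, `source`.
#'
#' @param path CSV file path.
#' @return `read_occurrences()` returns an occurrence tibble.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lon", "lat") %in% names(df))) abort("occurrence CSV needs lon, lat")
  as_tibble(df)
}

#' @rdname read_occurrences
#' @param occ occurrence tibble.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}
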
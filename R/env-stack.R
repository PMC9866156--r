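#' Environmental raster stack
#'
#' A set of named, co-registered environmental layers on one geographic grid
#' (WGS84 lon/lat, square cells in degrees), plus a scenario tag. Row 1 is the
#' northern edge; coordinates are cell-center registered. Missing cells are
#' `NA` in any layer.
#'
#' @param layers named list of numeric matrices, all the same dimension.
#' @param xmin western edge of the grid (degrees).
#' @param ymax northern edge of the grid (degrees).
#' @param cellsize cell size in degrees (square cells).
#' @param scenario scenario tag, e.g. `"near-current"` or `"2050s-SSP5-8.5"`.
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers, xmin = 0, ymax = 0, cellsize = 1,
                      scenario = "near-current") {
  if (!is.list(layers) || length(layers) == 0 || is.null(names(layers)) ||
      any(!nzchar(names(layers)))) {
    abort("`layers` must be a non-empty named list of matrices")
  }
  if (anyDuplicated(names(layers))) abort("layer names must be unique")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all layers must share the same dimensions")
  }
  if (cellsize <= 0) abort("`cellsize` must be positive")
  structure(
    list(layers = layers, xmin = xmin, ymax = ymax, cellsize = cellsize,
         crs = "WGS84", scenario = scenario),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat(sprintf("<env_stack> %d layer(s), %d x %d cells, %.4g deg, scenario '%s'\n",
              length(x$layers), d[1], d[2], x$cellsize, x$scenario))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

stack_dim <- function(stack) dim(stack$layers[[1]])

stack_extent <- function(stack) {
  d <- stack_dim(stack)
  c(xmin = stack$xmin, xmax = stack$xmin + d[2] * stack$cellsize,
    ymin = stack$ymax - d[1] * stack$cellsize, ymax = stack$ymax)
}

#' Cell centers of a stack's grid
#'
#' @param stack an [env_stack()].
#' @return tibble with `row`, `col`, `lon`, `lat` for every cell, row-major
#'   from the northwest corner.
#' @export
cell_centers <- function(stack) {
  d <- stack_dim(stack)
  # row-major order (northwest corner first, column varying fastest), matching
  # the cell indexing used throughout the package
  g <- expand.grid(col = seq_len(d[2]), row = seq_len(d[1]))
  tibble(
    row = g$row, col = g$col,
    lon = stack$xmin + (g$col - 0.5) * stack$cellsize,
    lat = stack$ymax - (g$row - 0.5) * stack$cellsize
  )
}

# Row/col of the cell containing each point; NA where outside the extent.
cell_of <- function(stack, lon, lat) {
  d <- stack_dim(stack)
  col <- floor((lon - stack$xmin) / stack$cellsize) + 1
  row <- floor((stack$ymax - lat) / stack$cellsize) + 1
  # points exactly on the east/south edge belong to the last cell
  col[lon == stack$xmin + d[2] * stack$cellsize] <- d[2]
  row[lat == stack$ymax - d[1] * stack$cellsize] <- d[1]
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble(row = as.integer(row), col = as.integer(col))
}

# Matrix (cells x layers) of all layer values, row-major cell order.
stack_matrix <- function(stack, variables = names(stack$layers)) {
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing) > 0) {
    abort(sprintf("stack is missing layer(s): %s", paste(missing, collapse = ", ")))
  }
  vapply(variables, function(v) as.vector(t(stack$layers[[v]])),
         numeric(prod(stack_dim(stack))))
}

#' Convert a stack to a long tibble
#'
#' @param x an [env_stack()].
#' @param ... unused.
#' @return tibble with `lon`, `lat`, `layer`, `value`.
#' @exportS3Method tibble::as_tibble
#' @export
as_tibble.env_stack <- function(x, ...) {
  cc <- cell_centers(x)
  purrr::map_dfr(names(x$layers), function(nm) {
    m <- x$layers[[nm]]
    dplyr::mutate(cc, layer = nm, value = m[cbind(cc$row, cc$col)])
  })
}

#' Apply additive/multiplicative perturbations to selected layers
#'
#' Builds a "future scenario" stack by shifting layers parametrically:
#' `value * mul + add` per named layer. Unnamed layers pass through unchanged,
#' which matches holding non-climatic layers (altitude, human-influence)
#' constant across scenarios.
#'
#' @param stack an [env_stack()].
#' @param add named numeric vector of additive shifts (per layer).
#' @param mul named numeric vector of multiplicative factors (per layer).
#' @param scenario tag for the perturbed stack.
#' @return a new [env_stack()].
#' @export
perturb_stack <- function(stack, add = NULL, mul = NULL, scenario = "future") {
  for (v in names(add)) {
    if (!v %in% names(stack$layers)) abort(sprintf("unknown layer '%s'", v))
    stack$layers[[v]] <- stack$layers[[v]] + add[[v]]
  }
  for (v in names(mul)) {
    if (!v %in% names(stack$layers)) abort(sprintf("unknown layer '%s'", v))
    stack$layers[[v]] <- stack$layers[[v]] * mul[[v]]
  }
  stack$scenario <- scenario
  stack
}

#' Build a scenario set from a baseline stack
#'
#' @param baseline the near-current [env_stack()].
#' @param perturbations named list (tag -> list(add=, mul=)) defining each
#'   future scenario as a parametric shift of the baseline.
#' @return named list of stacks; the first element is always the baseline
#'   under its own scenario tag.
#' @export
make_scenario_set <- function(baseline, perturbations = list()) {
  out <- list(baseline)
  names(out) <- baseline$scenario
  for (tag in names(perturbations)) {
    p <- perturbations[[tag]]
    out[[tag]] <- perturb_stack(baseline, add = p$add, mul = p$mul, scenario = tag)
  }
  out
}

#' Write / read an environmental stack as ESRI ASCII grids
#'
#' One plain-text `.asc` file per layer plus a `stack.json` sidecar carrying
#' layer order, cell registration and the scenario tag.
#'
#' @param stack an [env_stack()].
#' @param dir directory to write into (created if needed).
#' @return `write_env_stack()` returns `dir` invisibly; `read_env_stack()`
#'   returns an [env_stack()].
#' @export
write_env_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- stack_dim(stack)
  for (nm in names(stack$layers)) {
    m <- stack$layers[[nm]]
    con <- file.path(dir, paste0(nm, ".asc"))
    hdr <- c(
      sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
      sprintf("xllcorner %.10g", stack$xmin),
      sprintf("yllcorner %.10g", stack$ymax - d[1] * stack$cellsize),
      sprintf("cellsize %.10g", stack$cellsize),
      "NODATA_value -9999"
    )
    m[is.na(m)] <- -9999
    body <- apply(m, 1, function(r) paste(format(r, digits = 10), collapse = " "))
    writeLines(c(hdr, body), con)
  }
  jsonlite::write_json(
    list(layers = names(stack$layers), scenario = stack$scenario),
    file.path(dir, "stack.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_env_stack
#' @param dir directory previously written by `write_env_stack()`.
#' @export
read_env_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  layers <- list()
  hdr <- NULL
  for (nm in meta$layers) {
    lines <- readLines(file.path(dir, paste0(nm, ".asc")))
    kv <- strsplit(lines[1:6], "\\s+")
    hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                           tolower(vapply(kv, `[`, "", 1)))
    vals <- scan(text = lines[-(1:6)], quiet = TRUE)
    m <- matrix(vals, nrow = hdr[["nrows"]], byrow = TRUE)
    m[m == hdr[["nodata_value"]]] <- NA
    layers[[nm]] <- m
  }
  env_stack(layers,
            xmin = hdr[["xllcorner"]],
            ymax = hdr[["yllcorner"]] + hdr[["nrows"]] * hdr[["cellsize"]],
            cellsize = hdr[["cellsize"]], scenario = meta$scenario)
}
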
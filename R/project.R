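#' Project an ensemble onto an environmental stack
#'
#' Cellwise [ensemble_predict()]; any cell with nodata in a model layer is
#' nodata in the output.
#'
#' @param em an `nk_ensemble`.
#' @param stack an [env_stack()] providing every model variable.
#' @return an `nk_map`: grid geometry plus an integer `p` matrix (0-1000,
#'   `NA` = nodata) and the stack's scenario tag.
#' @export
project_suitability <- function(em, stack) {
  variables <- em$members$model[[1]]$variables
  xm <- stack_matrix(stack, variables)  # errors if a layer is missing
  valid <- stats::complete.cases(xm)
  p <- rep(NA_integer_, base::nrow(xm))
  if (any(valid)) {
    p[valid] <- ensemble_predict(em, as_tibble(as.data.frame(xm[valid, , drop = FALSE])))
  }
  d <- stack_dim(stack)
  structure(
    list(p = matrix(p, d[1], d[2], byrow = TRUE),
         xmin = stack$xmin, ymax = stack$ymax, cellsize = stack$cellsize,
         scenario = stack$scenario),
    class = "nk_map"
  )
}

#' @export
print.nk_map <- function(x, ...) {
  cat(sprintf("<nk_map> %d x %d cells, scenario '%s', p in [%s, %s]\n",
              base::nrow(x$p), base::ncol(x$p), x$scenario,
              min(x$p, na.rm = TRUE), max(x$p, na.rm = TRUE)))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.nk_map <- function(object, ...) {
  stack <- env_stack(list(p = object$p), object$xmin, object$ymax,
                     object$cellsize, object$scenario)
  ggplot2::ggplot(as_tibble(stack),
                  ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "p", na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Ensemble suitability (%s)", object$scenario)) +
    ggplot2::theme_minimal()
}

# Spherical area (km^2) of every cell in one grid row band:
# R^2 * dlambda * (sin(top) - sin(bottom)), R = 6371 km.
EARTH_RADIUS_KM <- 6371.0

row_cell_area_km2 <- function(ymax, cellsize, nrow) {
  top <- ymax - (seq_len(nrow) - 1) * cellsize
  bottom <- top - cellsize
  EARTH_RADIUS_KM^2 * (cellsize * pi / 180) *
    (sin(top * pi / 180) - sin(bottom * pi / 180))
}

# Matrix of per-cell spherical areas matching a map/stack geometry.
cell_area_matrix <- function(geom) {
  d <- if (inherits(geom, "nk_map")) dim(geom$p) else stack_dim(geom)
  matrix(rep(row_cell_area_km2(geom$ymax, geom$cellsize, d[1]), d[2]),
         d[1], d[2])
}

#' Area per suitability class
#'
#' Sums the spherical area of each class of a classified map. Cell areas use
#' the exact spherical-band formula with Earth radius 6371 km.
#'
#' @param classes integer matrix of classes (e.g. from [classify4()] or
#'   [binarize()]), `NA` = nodata.
#' @param geom an `nk_map` or [env_stack()] supplying grid geometry.
#' @return tibble with `class`, `label` (when the matrix carries class
#'   levels), and `area_km2`; classes absent from the map get area 0.
#' @export
area_by_class <- function(classes, geom) {
  areas <- cell_area_matrix(geom)
  levels_attr <- attr(classes, "levels")
  cls <- sort(unique(as.vector(classes[!is.na(classes)])))
  if (!is.null(levels_attr)) cls <- union(seq_along(levels_attr) - 1L, cls)
  out <- tibble(
    class = as.integer(cls),
    area_km2 = vapply(cls, function(k) sum(areas[!is.na(classes) & classes == k]), 0)
  )
  if (!is.null(levels_attr)) {
    out$label <- levels_attr[out$class + 1L]
    out <- out[c("class", "label", "area_km2")]
  }
  out
}

#' Change map between two binary suitability maps
#'
#' @param bin_now,bin_future binary matrices (same geometry; 1 = suitable).
#' @param geom grid geometry (an `nk_map` or [env_stack()]).
#' @return list with `states` (integer matrix: 0 stable-unsuitable, 1 gain,
#'   2 loss, 3 stable-suitable) and `areas`, a tibble of km^2 per state.
#' @export
change_map <- function(bin_now, bin_future, geom) {
  if (!all(dim(bin_now) == dim(bin_future))) abort("geometry mismatch")
  states <- matrix(NA_integer_, base::nrow(bin_now), base::ncol(bin_now))
  ok <- !is.na(bin_now) & !is.na(bin_future)
  states[ok] <- 0L
  states[ok & bin_now == 0 & bin_future == 1] <- 1L
  states[ok & bin_now == 1 & bin_future == 0] <- 2L
  states[ok & bin_now == 1 & bin_future == 1] <- 3L
  attr(states, "levels") <- c("stable-unsuitable", "gain", "loss", "stable-suitable")
  list(states = states, areas = area_by_class(states, geom))
}

#' Centroid of the suitable area
#'
#' Area-weighted mean of suitable cell centers (weights = spherical cell
#' areas); `weight = "none"` gives the unweighted mean, `weight = "p"`
#' weights by the continuous suitability surface. Longitudes are averaged
#' arithmetically, so a suitable region straddling the antimeridian is an
#' error.
#'
#' @param bin binary suitability matrix (or, for `weight = "p"`, an integer p
#'   matrix where positive cells count as suitable).
#' @param geom grid geometry.
#' @param weight `"area"` (default), `"none"`, or `"p"`.
#' @param p continuous p matrix, required for `weight = "p"`.
#' @return tibble with `lon`, `lat`, `scenario`.
#' @export
centroid_suitable <- function(bin, geom, weight = c("area", "none", "p"), p = NULL) {
  weight <- match.arg(weight)
  d <- dim(bin)
  idx <- which(!is.na(bin) & bin == 1, arr.ind = TRUE)
  if (base::nrow(idx) == 0) abort("no suitable cells")
  lon <- geom$xmin + (idx[, 2] - 0.5) * geom$cellsize
  lat <- geom$ymax - (idx[, 1] - 0.5) * geom$cellsize
  if (max(lon) - min(lon) > 180) {
    abort("suitable region straddles the antimeridian; centroid undefined")
  }
  w <- switch(weight,
    none = rep(1, base::nrow(idx)),
    area = cell_area_matrix(geom)[idx],
    p = {
      if (is.null(p)) abort("`p` matrix required for weight = 'p'")
      cell_area_matrix(geom)[idx] * p[idx]
    })
  tibble(lon = sum(lon * w) / sum(w), lat = sum(lat * w) / sum(w),
         scenario = geom$scenario %||% NA_character_)
}

#' Great-circle shift between two centroids
#'
#' Haversine distance (R = 6371 km) and initial bearing from `from` to `to`.
#'
#' @param from,to tibbles/lists with `lon`, `lat` in degrees.
#' @return tibble with `distance_km` and `bearing_deg` (0 = north, clockwise).
#' @export
centroid_shift <- function(from, to) {
  rad <- pi / 180
  phi1 <- from$lat * rad; phi2 <- to$lat * rad
  dphi <- (to$lat - from$lat) * rad
  dlam <- (to$lon - from$lon) * rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  dist <- 2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
  theta <- atan2(sin(dlam) * cos(phi2),
                 cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam))
  tibble(distance_km = dist, bearing_deg = (theta / rad) %% 360)
}
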
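#' Kernel 95% home range
#'
#' Fixed bivariate Gaussian kernel density estimate of the utilization
#' distribution on a regular grid, with the home range taken as the
#' smallest-density-threshold contour containing `level` of the total mass.
#' Bandwidth is the bivariate normal reference rule per axis,
#' `h_j = sd_j * n^(-1/6)`, times `bw_mult`.
#'
#' @param lat,lon fix coordinates in decimal degrees (>= 30 fixes).
#' @param level utilization level (default 0.95).
#' @param bw_mult scalar bandwidth multiplier (default 1).
#' @param grid_n grid points per axis (default 200).
#' @param origin projection origin `c(lat0, lon0)`; defaults to the fix
#'   centroid. Pass the shared study origin when intersecting with a cell
#'   grid.
#' @param individual_id,season optional labels carried on the result.
#' @return a `cpf_homerange`: list with `region` (mask `cpf_region`),
#'   `area_km2`, `mass` (the contour's actual enclosed mass fraction),
#'   `bandwidth`, `level` and the labels.
#' @export
kde_home_range <- function(lat, lon, level = 0.95, bw_mult = 1,
                           grid_n = 200, origin = NULL,
                           individual_id = NA_character_,
                           season = NA_character_) {
  n <- length(lat)
  stopifnot(length(lon) == n)
  if (n < 30) stop("kde_home_range() needs >= 30 fixes")
  if (is.null(origin)) origin <- c(mean(lat), mean(lon))
  pr <- project_tmerc(lat, lon, origin[1], origin[2])
  x <- pr$x; y <- pr$y
  if (stats::sd(x) < 1e-6 || stats::sd(y) < 1e-6) {
    stop("fixes are (near-)coincident; kernel home range undefined")
  }
  hx <- stats::sd(x) * n^(-1 / 6) * bw_mult
  hy <- stats::sd(y) * n^(-1 / 6) * bw_mult
  gx <- seq(min(x) - 3.5 * hx, max(x) + 3.5 * hx, length.out = grid_n)
  gy <- seq(min(y) - 3.5 * hy, max(y) + 3.5 * hy, length.out = grid_n)
  # dens[i, j] = (1/n) sum_k dnorm(gx_i; x_k, hx) dnorm(gy_j; y_k, hy)
  Dx <- outer(gx, x, function(g, xx) stats::dnorm(g, xx, hx))
  Dy <- outer(gy, y, function(g, yy) stats::dnorm(g, yy, hy))
  dens <- (Dx %*% t(Dy)) / n
  cellarea <- diff(gx[1:2]) * diff(gy[1:2])
  dv <- sort(as.numeric(dens), decreasing = TRUE)
  cum <- cumsum(dv) * cellarea
  thr <- dv[which(cum >= level)[1]]
  if (is.na(thr)) thr <- dv[length(dv)]
  mask <- dens >= thr
  structure(list(
    individual_id = individual_id, season = season,
    region = new_region_mask(gx, gy, mask, origin),
    area_km2 = sum(mask) * cellarea / 1e6,
    mass = sum(dens[mask]) * cellarea,
    bandwidth = c(hx = hx, hy = hy),
    level = level, n_fixes = n
  ), class = "cpf_homerange")
}

#' @export
print.cpf_homerange <- function(x, ...) {
  cat(sprintf("<cpf_homerange %s: %.1f km^2 at %.0f%% (mass %.3f, n = %d)>\n",
              x$individual_id, x$area_km2, 100 * x$level, x$mass, x$n_fixes))
  invisible(x)
}

#' Export home ranges as GeoJSON
#'
#' @param homeranges list of `cpf_homerange` objects (or a single one).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_homerange_geojson <- function(homeranges, path) {
  if (inherits(homeranges, "cpf_homerange")) homeranges <- list(homeranges)
  features <- lapply(homeranges, function(hr) {
    rings <- region_polygons(hr$region)
    coords <- lapply(rings, function(r) {
      m <- rbind(as.matrix(r[c("lon", "lat")]), as.matrix(r[1, c("lon", "lat")]))
      lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
    })
    list(type = "Feature",
         properties = list(individual_id = hr$individual_id,
                           season = hr$season,
                           area_km2 = hr$area_km2, level = hr$level),
         geometry = list(type = "MultiPolygon",
                         coordinates = lapply(coords, list)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
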
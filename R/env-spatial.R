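# Planar regions and the gridded-weather cell geometry.
#
# All planar geometry lives in one local transverse-Mercator projection whose
# origin is carried on each object; mixing origins is an error. Regions come
# in two flavours: an analytic disc, and a raster mask (the KDE contour).

new_region_disc <- function(cx, cy, r, origin) {
  structure(list(type = "disc", cx = cx, cy = cy, r = r, origin = origin),
            class = "cpf_region")
}

new_region_mask <- function(gx, gy, mask, origin) {
  structure(list(type = "mask", gx = gx, gy = gy, mask = mask,
                 cellarea = diff(gx[1:2]) * diff(gy[1:2]), origin = origin),
            class = "cpf_region")
}

check_same_origin <- function(a_origin, b_origin) {
  if (max(abs(a_origin - b_origin)) > 1e-9) {
    stop("objects use different projection origins; build them from one origin")
  }
}

#' Area of a region in km^2
#' @param region a `cpf_region`.
#' @return area in km^2.
#' @export
region_area_km2 <- function(region) {
  switch(region$type,
         disc = pi * region$r^2 / 1e6,
         mask = sum(region$mask) * region$cellarea / 1e6)
}

#' Disc of given area around a nest centroid
#'
#' Circular region of exactly `area_km2` centred on the nest centroid, used
#' as the weather-extraction footprint for territories without a tracked
#' bird. The default 70 km^2 is the population's average breeding-season
#' home range.
#'
#' @param lat,lon nest centroid in decimal degrees.
#' @param area_km2 disc area (default 70).
#' @param origin projection origin `c(lat0, lon0)`; defaults to the centroid
#'   itself.
#' @return a `cpf_region` of type disc.
#' @export
nest_disc <- function(lat, lon, area_km2 = 70, origin = c(lat, lon)) {
  if (!is.finite(area_km2) || area_km2 <= 0) stop("disc area must be > 0")
  pr <- project_tmerc(lat, lon, origin[1], origin[2])
  new_region_disc(pr$x, pr$y, sqrt(area_km2 * 1e6 / pi), origin)
}

#' Polygonize a region
#'
#' Returns the region outline(s) as lon/lat rings: a disc becomes a regular
#' polygon with `n_vertices` vertices; a mask region is traced with
#' [grDevices::contourLines()].
#'
#' @param region a `cpf_region`.
#' @param n_vertices vertices for disc polygonization (default 128).
#' @return list of data.frames with columns lon, lat (one per ring).
#' @export
region_polygons <- function(region, n_vertices = 128) {
  if (region$type == "disc") {
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    x <- region$cx + region$r * cos(th)
    y <- region$cy + region$r * sin(th)
    ll <- unproject_tmerc(x, y, region$origin[1], region$origin[2])
    return(list(data.frame(lon = ll$lon, lat = ll$lat)))
  }
  dens <- region$mask * 1
  cl <- grDevices::contourLines(region$gx, region$gy, dens, levels = 0.5)
  lapply(cl, function(ring) {
    ll <- unproject_tmerc(ring$x, ring$y, region$origin[1], region$origin[2])
    data.frame(lon = ll$lon, lat = ll$lat)
  })
}

#' Build the weather cell grid
#'
#' Lays a square grid of `cell_km` x `cell_km` cells (8 x 8 km by default,
#' emulating a gridded meteorological reanalysis) over the bounding box of
#' the supplied points plus a margin, in the shared local projection.
#'
#' @param lat,lon points the grid must cover (e.g. nest coordinates).
#' @param cell_km cell edge length in km (default 8).
#' @param margin_km margin around the bounding box (default 12).
#' @param origin projection origin; defaults to the points' centroid.
#' @return data.frame (cell_id, cx, cy, lat, lon) with attributes `origin`
#'   and `size_m`; cx/cy are cell-centre planar metres.
#' @export
make_weather_cells <- function(lat, lon, cell_km = 8, margin_km = 12,
                               origin = c(mean(lat), mean(lon))) {
  pr <- project_tmerc(lat, lon, origin[1], origin[2])
  s <- cell_km * 1000
  m <- margin_km * 1000
  xr <- range(pr$x) + c(-m, m)
  yr <- range(pr$y) + c(-m, m)
  cx <- seq(floor(xr[1] / s) * s + s / 2, xr[2] + s / 2, by = s)
  cy <- seq(floor(yr[1] / s) * s + s / 2, yr[2] + s / 2, by = s)
  grid <- expand.grid(cx = cx, cy = cy)
  ll <- unproject_tmerc(grid$cx, grid$cy, origin[1], origin[2])
  cells <- data.frame(cell_id = sprintf("c%04d", seq_len(nrow(grid))),
                      cx = grid$cx, cy = grid$cy,
                      lat = ll$lat, lon = ll$lon,
                      stringsAsFactors = FALSE)
  attr(cells, "origin") <- origin
  attr(cells, "size_m") <- s
  cells
}

#' Cell containing a point
#' @param cells a cell grid from [make_weather_cells()].
#' @param lat,lon point coordinates in degrees.
#' @return cell_id (vectorised).
#' @export
cell_for_point <- function(cells, lat, lon) {
  origin <- attr(cells, "origin")
  pr <- project_tmerc(lat, lon, origin[1], origin[2])
  vapply(seq_along(pr$x), function(i) {
    d2 <- (cells$cx - pr$x[i])^2 + (cells$cy - pr$y[i])^2
    cells$cell_id[which.min(d2)]
  }, character(1))
}

# Cells whose square geometry intersects the region. For a disc: clamp the
# centre to the square and compare to the radius. For a mask: any TRUE grid
# point inside the square. With `weights`, returns the fraction of the
# region's sampled points per cell instead of a 0/1 membership.
region_cells <- function(region, cells, weights = FALSE) {
  origin <- attr(cells, "origin")
  check_same_origin(region$origin, origin)
  h <- attr(cells, "size_m") / 2
  if (region$type == "disc") {
    if (!weights) {
      dx <- pmax(abs(region$cx - cells$cx) - h, 0)
      dy <- pmax(abs(region$cy - cells$cy) - h, 0)
      return(cells$cell_id[dx^2 + dy^2 <= region$r^2])
    }
    # rasterize the disc for area weights
    step <- region$r / 40
    g <- seq(-region$r, region$r, by = step)
    pts <- expand.grid(x = g, y = g)
    pts <- pts[pts$x^2 + pts$y^2 <= region$r^2, ]
    px <- region$cx + pts$x; py <- region$cy + pts$y
  } else {
    idx <- which(region$mask, arr.ind = TRUE)
    px <- region$gx[idx[, 1]]; py <- region$gy[idx[, 2]]
    if (!weights) {
      ids <- unique(vapply(seq_along(px), function(i) {
        j <- which(abs(cells$cx - px[i]) <= h & abs(cells$cy - py[i]) <= h)[1]
        if (is.na(j)) NA_character_ else cells$cell_id[j]
      }, character(1)))
      return(ids[!is.na(ids)])
    }
  }
  cid <- vapply(seq_along(px), function(i) {
    j <- which(abs(cells$cx - px[i]) <= h & abs(cells$cy - py[i]) <= h)[1]
    if (is.na(j)) NA_character_ else cells$cell_id[j]
  }, character(1))
  tab <- table(cid[!is.na(cid)])
  w <- as.numeric(tab) / sum(tab)
  names(w) <- names(tab)
  w
}
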
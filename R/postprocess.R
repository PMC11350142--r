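# modal filter of one categorical layer (integer codes, NA = nodata);
# ties keep the center value, nodata cells are excluded from the vote and
# stay nodata themselves
modal_filter_layer <- function(m, window = 3) {
  h <- nrow(m); w <- ncol(m)
  r <- (window - 1) / 2
  codes <- sort(unique(m[!is.na(m)]))
  if (!length(codes)) return(m)
  counts <- array(0L, c(h, w, length(codes)))
  for (dr in -r:r) {
    rs <- pmin(pmax(seq_len(h) + dr, 1), h)
    rs_valid <- (seq_len(h) + dr >= 1) & (seq_len(h) + dr <= h)
    for (dc in -r:r) {
      cs <- pmin(pmax(seq_len(w) + dc, 1), w)
      cs_valid <- (seq_len(w) + dc >= 1) & (seq_len(w) + dc <= w)
      shifted <- m[rs, cs, drop = FALSE]
      shifted[!rs_valid, ] <- NA
      shifted[, !cs_valid] <- NA
      for (ci in seq_along(codes)) {
        hit <- !is.na(shifted) & shifted == codes[ci]
        counts[, , ci] <- counts[, , ci] + hit
      }
    }
  }
  out <- m
  for (row in seq_len(h)) {
    for (col in seq_len(w)) {
      if (is.na(m[row, col])) next
      cnt <- counts[row, col, ]
      top <- which(cnt == max(cnt))
      if (length(top) == 1) out[row, col] <- codes[top]
      # tie: retain center value
    }
  }
  out
}

#' Focal (modal) smoothing of a season raster
#'
#' Replaces each cell of every month layer by the majority season code in
#' its square neighborhood; ties retain the center value and nodata cells
#' are excluded from the vote. Because spatial smoothing acts per month it
#' can break a pixel's temporal contiguity, so a per-pixel repair pass
#' projects every affected non-tropical pixel back onto its nearest
#' (minimum-Hamming) contiguous calendar.
#'
#' @param sr a `season_raster`.
#' @param window odd window size >= 3 (default 3).
#' @param repair run the contiguity re-repair pass (default `TRUE`).
#' @return a smoothed `season_raster`.
#' @export
focal_smooth <- function(sr, window = 3, repair = TRUE) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  seasons <- sr$seasons
  for (b in seq_len(12))
    seasons[, , b] <- modal_filter_layer(sr$seasons[, , b], window)
  if (repair) {
    for (row in seq_len(nrow(sr$zones))) {
      for (col in seq_len(ncol(sr$zones))) {
        z <- sr$zones[row, col]
        if (is.na(z) || z == ZONES[["tropical"]]) next
        lab <- seasons[row, col, ]
        if (!is_circularly_contiguous(lab)) {
          # Hamming-only projection: constant features make all contiguous
          # partitions equal in SSE, so only disagreement counts
          seasons[row, col, ] <- enforce_contiguity(lab, matrix(0, 12, 1))
        }
      }
    }
  }
  structure(list(seasons = seasons, zones = sr$zones, grid = sr$grid),
            class = "season_raster")
}

# Equal Earth projection (spherical form), authalic sphere radius in m
EE_RADIUS <- 6371007.181
EE_COEF <- c(A1 = 1.340264, A2 = -0.081106, A3 = 0.000893, A4 = 0.003796)
EE_M <- sqrt(3) / 2

ee_poly <- function(theta) {
  EE_COEF[["A1"]] * theta + EE_COEF[["A2"]] * theta^3 +
    EE_COEF[["A3"]] * theta^7 + EE_COEF[["A4"]] * theta^9
}
ee_dpoly <- function(theta) {
  EE_COEF[["A1"]] + 3 * EE_COEF[["A2"]] * theta^2 +
    7 * EE_COEF[["A3"]] * theta^6 + 9 * EE_COEF[["A4"]] * theta^8
}

#' Equal Earth forward and inverse projection
#'
#' Spherical Equal Earth: an equal-area pseudocylindrical projection. The
#' forward map takes longitude/latitude in degrees to meters; the inverse
#' solves the parametric latitude by Newton iteration.
#'
#' @param lon,lat coordinates in degrees.
#' @return `equal_earth_forward`: list with `x`, `y` in meters;
#'   `equal_earth_inverse`: list with `lon`, `lat` in degrees.
#' @export
equal_earth_forward <- function(lon, lat) {
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  theta <- asin(EE_M * sin(phi))
  list(x = EE_RADIUS * 2 * sqrt(3) * lam * cos(theta) / (3 * ee_dpoly(theta)),
       y = EE_RADIUS * ee_poly(theta))
}

#' @rdname equal_earth_forward
#' @param x,y projected coordinates in meters.
#' @export
equal_earth_inverse <- function(x, y) {
  yr <- y / EE_RADIUS
  theta <- yr
  for (i in 1:12) {
    delta <- (ee_poly(theta) - yr) / ee_dpoly(theta)
    theta <- theta - delta
    if (max(abs(delta)) < 1e-12) break
  }
  phi <- asin(pmin(pmax(sin(theta) / EE_M, -1), 1))
  lam <- 3 * x * ee_dpoly(theta) / (EE_RADIUS * 2 * sqrt(3) * cos(theta))
  list(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Reproject a categorical raster to Equal Earth
#'
#' Builds a regular target grid in Equal Earth meters covering the source
#' extent and fills it by nearest-neighbor lookup through the inverse
#' projection (categorical data must not be interpolated). Cells mapping
#' outside the source extent become nodata.
#'
#' @param x a `season_raster` or a list with `values` (matrix or 3-D
#'   array) and `grid` in `"EPSG:4326"`.
#' @param res target cell size in meters; default preserves the source
#'   cell count along x.
#' @return object of the same shape on an `"EqualEarth"` grid.
#' @export
reproject_equal_earth <- function(x, res = NULL) {
  is_sr <- inherits(x, "season_raster")
  g <- x$grid
  if (g$crs != "EPSG:4326")
    stop("source CRS must be EPSG:4326, got ", g$crs)
  vals <- if (is_sr) x$seasons else x$values
  if (length(dim(vals)) == 2) vals <- array(vals, c(dim(vals), 1))
  # project the source corner/edge lattice to bound the target extent
  lon <- grid_x(g, seq_len(g$width))
  lat <- grid_y(g, seq_len(g$height))
  edge <- rbind(expand.grid(lon = range(lon) + c(-0.5, 0.5) * g$xres,
                            lat = lat),
                expand.grid(lon = lon,
                            lat = range(lat) + c(-0.5, 0.5) * g$yres))
  pr <- equal_earth_forward(edge$lon, edge$lat)
  if (is.null(res))
    res <- (max(pr$x) - min(pr$x)) / g$width
  wt <- max(2L, ceiling((max(pr$x) - min(pr$x)) / res))
  ht <- max(2L, ceiling((max(pr$y) - min(pr$y)) / res))
  gt <- ws_grid(wt, ht, xmin = min(pr$x), ymax = max(pr$y),
                xres = res, yres = res, crs = "EqualEarth")
  inv <- equal_earth_inverse(
    rep(grid_x(gt, seq_len(wt)), each = ht),
    rep(grid_y(gt, seq_len(ht)), times = wt))
  cc <- round(grid_col(g, inv$lon))
  rr <- round(grid_row(g, inv$lat))
  inside <- cc >= 1 & cc <= g$width & rr >= 1 & rr <= g$height
  nb <- dim(vals)[3]
  out <- array(NA_real_, c(ht, wt, nb))
  idx_r <- rep(seq_len(ht), times = wt)
  idx_c <- rep(seq_len(wt), each = ht)
  for (b in seq_len(nb)) {
    src <- vals[, , b]
    v <- rep(NA_real_, length(cc))
    v[inside] <- src[cbind(rr[inside], cc[inside])]
    layer <- matrix(NA_real_, ht, wt)
    layer[cbind(idx_r, idx_c)] <- v
    out[, , b] <- layer
  }
  if (is_sr) {
    zl <- matrix(NA_integer_, ht, wt)
    v <- rep(NA_integer_, length(cc))
    v[inside] <- x$zones[cbind(rr[inside], cc[inside])]
    zl[cbind(idx_r, idx_c)] <- v
    structure(list(seasons = array(as.integer(out), dim(out)), zones = zl,
                   grid = gt),
              class = "season_raster")
  } else {
    list(values = out, grid = gt)
  }
}
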
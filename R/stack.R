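#' Regular grid definition
#'
#' Minimal georeferencing for the in-memory rasters: a north-up regular
#' grid, cell (row 1, col 1) at the top-left corner.
#'
#' @param width,height grid dimensions in cells.
#' @param xmin,ymax coordinates of the top-left corner of the grid (not of
#'   the first cell center).
#' @param xres,yres cell size (positive) in CRS units.
#' @param crs character CRS tag; `"EPSG:4326"` (longitude/latitude degrees)
#'   or `"EqualEarth"` (meters).
#' @return an object of class `ws_grid`.
#' @export
ws_grid <- function(width, height, xmin = -180, ymax = 90,
                    xres = 360 / width, yres = xres, crs = "EPSG:4326") {
  stopifnot(width >= 1, height >= 1, xres > 0, yres > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 xmin = xmin, ymax = ymax, xres = xres, yres = yres,
                 crs = crs),
            class = "ws_grid")
}

# cell-center coordinates
grid_x <- function(g, col) g$xmin + (col - 0.5) * g$xres
grid_y <- function(g, row) g$ymax - (row - 0.5) * g$yres
# inverse: fractional column/row of a coordinate
grid_col <- function(g, x) (x - g$xmin) / g$xres + 0.5
grid_row <- function(g, y) (g$ymax - y) / g$yres + 0.5

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("width", "height", "xmin", "ymax",
                                "xres", "yres")],
                   unclass(b)[c("width", "height", "xmin", "ymax",
                                "xres", "yres")])) && a$crs == b$crs
}

# variables a stack may carry; first four are required
STACK_VARS <- c("tmin", "tmax", "precip", "srad", "ndvi", "pet", "aridity")

#' Multi-variable monthly climate stack
#'
#' Container for co-registered 12-month climate layers on one grid. Each
#' variable is a height x width x 12 array in calendar band order
#' January..December.
#'
#' @param grid a [ws_grid()].
#' @param vars named list of height x width x 12 arrays; must include
#'   `tmin`, `tmax`, `precip`, `srad`; `ndvi` and `pet` (or `aridity`) are
#'   optional.
#' @param mask logical height x width matrix, `TRUE` where valid; default:
#'   cells where all required variables are finite in all months.
#' @return an object of class `climate_stack`.
#' @export
climate_stack <- function(grid, vars, mask = NULL) {
  req <- c("tmin", "tmax", "precip", "srad")
  missing_req <- setdiff(req, names(vars))
  if (length(missing_req))
    stop("missing required variable(s): ", paste(missing_req, collapse = ", "))
  if (!any(c("pet", "aridity") %in% names(vars)))
    stop("missing required variable(s): pet (or aridity)")
  for (nm in names(vars)) {
    d <- dim(vars[[nm]])
    if (length(d) != 3 || d[1] != grid$height || d[2] != grid$width || d[3] != 12)
      stop("variable ", nm, " must be a ", grid$height, " x ", grid$width,
           " x 12 array")
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, grid$height, grid$width)
    for (nm in req)
      mask <- mask & apply(is.finite(vars[[nm]]), c(1, 2), all)
  }
  structure(list(grid = grid, vars = vars, mask = mask),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  g <- x$grid
  cat("<climate_stack>", g$width, "x", g$height, "cells,",
      sum(x$mask), "valid; vars:", paste(names(x$vars), collapse = ", "),
      "; crs:", g$crs, "\n")
  invisible(x)
}

#' Extract one cell as a pixel_climate
#'
#' @param stack a [climate_stack()].
#' @param col,row 1-based cell indices (column, row).
#' @return a [pixel_climate()] with all derived fields.
#' @export
extract_pixel <- function(stack, col, row) {
  g <- stack$grid
  if (col < 1 || col > g$width || row < 1 || row > g$height)
    stop("cell (", col, ",", row, ") outside grid")
  if (!stack$mask[row, col])
    stop("no data: cell (", col, ",", row, ") is masked")
  v <- function(nm) if (nm %in% names(stack$vars)) stack$vars[[nm]][row, col, ] else NULL
  pixel_climate(tmin = v("tmin"), tmax = v("tmax"), precip = v("precip"),
                srad = v("srad"), ndvi = v("ndvi"), pet = v("pet"),
                aridity = v("aridity"))
}

# bilinear resampling of one layer (matrix) from grid gs to grid gt;
# output values are convex combinations of the 4 surrounding input cells
resample_bilinear_layer <- function(m, gs, gt) {
  out <- matrix(NA_real_, gt$height, gt$width)
  xs <- grid_x(gt, seq_len(gt$width))
  ys <- grid_y(gt, seq_len(gt$height))
  fc <- grid_col(gs, xs)
  fr <- grid_row(gs, ys)
  c0 <- pmin(pmax(floor(fc), 1), gs$width)   # left cell-center index
  r0v <- pmin(pmax(floor(fr), 1), gs$height)
  c1 <- pmin(c0 + 1, gs$width)
  wx <- pmin(pmax(fc - c0, 0), 1)
  for (r in seq_len(gt$height)) {
    r0 <- r0v[r]
    r1 <- min(r0 + 1, gs$height)
    wy <- min(max(fr[r] - r0, 0), 1)
    top <- m[r0, c0] * (1 - wx) + m[r0, c1] * wx
    bot <- m[r1, c0] * (1 - wx) + m[r1, c1] * wx
    out[r, ] <- top * (1 - wy) + bot * wy
  }
  out
}

# nearest-neighbour resampling (categorical layers)
resample_nearest_layer <- function(m, gs, gt) {
  cc <- pmin(pmax(round(grid_col(gs, grid_x(gt, seq_len(gt$width)))), 1), gs$width)
  rr <- pmin(pmax(round(grid_row(gs, grid_y(gt, seq_len(gt$height)))), 1), gs$height)
  m[rr, cc, drop = FALSE]
}

resample_array <- function(a, gs, gt, method = "bilinear") {
  nb <- dim(a)[3]
  out <- array(NA_real_, c(gt$height, gt$width, nb))
  for (b in seq_len(nb)) {
    out[, , b] <- if (method == "bilinear")
      resample_bilinear_layer(a[, , b], gs, gt)
    else resample_nearest_layer(a[, , b], gs, gt)
  }
  out
}

#' Read a set of monthly rasters into a climate stack
#'
#' Reads one 12-band raster per variable, aligns everything onto a target
#' grid (continuous fields by bilinear interpolation), and masks to the
#' common footprint of the required variables.
#'
#' @param config named character vector or list mapping variable names
#'   (`tmin`, `tmax`, `precip`, `srad`, optionally `ndvi`, `pet`,
#'   `aridity`) to raster paths, or the path of a YAML file holding such a
#'   mapping.
#' @param target optional [ws_grid()] to resample onto; default is the
#'   `tmin` grid.
#' @param resample allow resampling of variables whose grid differs from
#'   the target (default `TRUE`; if `FALSE`, a grid mismatch is an error).
#' @return a [climate_stack()].
#' @export
read_monthly_stack <- function(config, target = NULL, resample = TRUE) {
  if (is.character(config) && length(config) == 1 && file.exists(config) &&
      grepl("\\.ya?ml$", config))
    config <- yaml::read_yaml(config)
  config <- unlist(config)
  req <- c("tmin", "tmax", "precip", "srad")
  missing_req <- setdiff(req, names(config))
  if (length(missing_req))
    stop("config missing variable(s): ", paste(missing_req, collapse = ", "))
  rasters <- lapply(config, read_raster_tif)
  for (nm in names(rasters))
    if (dim(rasters[[nm]]$values)[3] != 12)
      stop("variable ", nm, " has ", dim(rasters[[nm]]$values)[3],
           " bands; expected 12")
  if (is.null(target)) target <- rasters[["tmin"]]$grid
  vars <- list()
  for (nm in names(rasters)) {
    r <- rasters[[nm]]
    if (grids_equal(r$grid, target)) {
      vars[[nm]] <- r$values
    } else {
      if (!resample)
        stop("grid of ", nm, " differs from target and resample = FALSE")
      if (r$grid$crs != target$crs)
        stop("CRS mismatch for ", nm, ": ", r$grid$crs, " vs ", target$crs)
      vars[[nm]] <- resample_array(r$values, r$grid, target, "bilinear")
    }
  }
  climate_stack(target, vars)
}
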
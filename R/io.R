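# On-disk raster format: multi-page TIFF written with the tiff package,
# georeferencing in a standard 6-line ESRI world file (<path>.tfw-style,
# named <path sans ext>.wld here since pages share one transform), and a
# JSON sidecar carrying CRS, storage type and per-band offset/scale.
# Continuous bands are stored as 16-bit scaled integers (quantization error
# = band range / 65535); categorical bands as 8-bit codes with 0 = nodata.

sidecar_paths <- function(path) {
  base <- sub("\\.tiff?$", "", path)
  list(wld = paste0(base, ".wld"), json = paste0(base, ".json"))
}

write_world_file <- function(grid, path) {
  ul_x <- grid$xmin + grid$xres / 2
  ul_y <- grid$ymax - grid$yres / 2
  writeLines(format(c(grid$xres, 0, 0, -grid$yres, ul_x, ul_y), digits = 15),
             path)
}

read_world_file <- function(path, width, height, crs) {
  v <- as.numeric(readLines(path))
  ws_grid(width = width, height = height,
          xmin = v[5] - v[1] / 2, ymax = v[6] + v[1] / 2,
          xres = v[1], yres = -v[4], crs = crs)
}

#' Write a raster to a multi-page TIFF with sidecar georeferencing
#'
#' @param values numeric/integer matrix or height x width x bands array.
#' @param grid a [ws_grid()].
#' @param path output `.tif` path; a `.wld` world file and a `.json`
#'   metadata sidecar are written alongside.
#' @param type `"float"` (16-bit scaled continuous storage) or `"byte"`
#'   (8-bit categorical codes, 0 = nodata).
#' @return `path`, invisibly.
#' @export
write_raster_tif <- function(values, grid, path, type = c("float", "byte")) {
  type <- match.arg(type)
  if (length(dim(values)) == 2) values <- array(values, c(dim(values), 1))
  nb <- dim(values)[3]
  sp <- sidecar_paths(path)
  pages <- vector("list", nb)
  meta <- list(crs = grid$crs, type = type, bands = nb)
  if (type == "byte") {
    for (b in seq_len(nb)) {
      m <- values[, , b]
      m[is.na(m)] <- 0
      if (any(m < 0 | m > 255)) stop("byte raster codes must be in 0..255")
      pages[[b]] <- m / 255
    }
  } else {
    offs <- numeric(nb); scls <- numeric(nb)
    for (b in seq_len(nb)) {
      m <- values[, , b]
      fin <- is.finite(m)
      lo <- if (any(fin)) min(m[fin]) else 0
      hi <- if (any(fin)) max(m[fin]) else 1
      scl <- if (hi > lo) (hi - lo) / (65535 - 1) else 1
      offs[b] <- lo; scls[b] <- scl
      enc <- (m - lo) / scl + 1       # 0 reserved for nodata
      enc[!fin] <- 0
      pages[[b]] <- pmin(pmax(enc / 65535, 0), 1)
    }
    meta$offset <- offs; meta$scale <- scls
  }
  tiff::writeTIFF(pages, path,
                  bits.per.sample = if (type == "byte") 8L else 16L)
  write_world_file(grid, sp$wld)
  jsonlite::write_json(meta, sp$json, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster_tif()]
#'
#' @param path `.tif` path with `.wld`/`.json` sidecars.
#' @return list with `values` (height x width x bands array; byte rasters
#'   come back as integer codes with `NA` at nodata) and `grid`.
#' @export
read_raster_tif <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  sp <- sidecar_paths(path)
  for (p in c(sp$wld, sp$json))
    if (!file.exists(p)) stop("missing sidecar for ", path, ": ", p)
  meta <- jsonlite::read_json(sp$json, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nb <- length(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  grid <- read_world_file(sp$wld, w, h, meta$crs)
  out <- array(NA_real_, c(h, w, nb))
  for (b in seq_len(nb)) {
    if (meta$type == "byte") {
      m <- round(pages[[b]] * 255)
      m[m == 0] <- NA
      out[, , b] <- m
    } else {
      enc <- round(pages[[b]] * 65535)
      m <- (enc - 1) * meta$scale[b] + meta$offset[b]
      m[enc == 0] <- NA
      out[, , b] <- m
    }
  }
  list(values = out, grid = grid)
}

#' Long-format month-season table of a season raster
#'
#' @param sr a `season_raster`.
#' @return data.frame with columns `x`, `y` (cell-center coordinates),
#'   `month` (1..12) and `season` (lowercase name), one row per valid cell
#'   and month.
#' @export
season_table <- function(sr) {
  g <- sr$grid
  valid <- which(!is.na(sr$zones), arr.ind = TRUE)
  if (!nrow(valid))
    return(data.frame(x = numeric(0), y = numeric(0),
                      month = integer(0), season = character(0)))
  rows <- do.call(rbind, lapply(seq_len(nrow(valid)), function(i) {
    r <- unname(valid[i, 1]); c <- unname(valid[i, 2])
    data.frame(x = rep(grid_x(g, c), 12), y = rep(grid_y(g, r), 12),
               month = 1:12, season = unname(season_name(sr$seasons[r, c, ])))
  }))
  rownames(rows) <- NULL
  rows
}

#' Write the published output formats
#'
#' Writes the 12-band season raster (`seasons.tif`, uint8 season codes,
#' 0 = nodata), the single-band climate-zone raster (`zones.tif`, uint8
#' zone codes), and the long-format text table `seasons.txt` with columns
#' x, y, month, season.
#'
#' @param sr a `season_raster`.
#' @param zones optional integer zone matrix (defaults to `sr$zones`).
#' @param outdir output directory, created if needed.
#' @return named character vector of the files written.
#' @export
write_outputs <- function(sr, zones = NULL, outdir) {
  if (is.null(zones)) zones <- sr$zones
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f_season <- file.path(outdir, "seasons.tif")
  f_zone <- file.path(outdir, "zones.tif")
  f_txt <- file.path(outdir, "seasons.txt")
  write_raster_tif(sr$seasons, sr$grid, f_season, type = "byte")
  write_raster_tif(zones, sr$grid, f_zone, type = "byte")
  tab <- season_table(sr)
  write.csv(tab, f_txt, row.names = FALSE, quote = FALSE)
  c(seasons = f_season, zones = f_zone, table = f_txt)
}

#' Read back a season raster written by [write_outputs()]
#'
#' @param outdir directory holding `seasons.tif` and `zones.tif`.
#' @return a `season_raster`.
#' @export
read_season_raster <- function(outdir) {
  s <- read_raster_tif(file.path(outdir, "seasons.tif"))
  z <- read_raster_tif(file.path(outdir, "zones.tif"))
  structure(list(seasons = array(as.integer(s$values), dim(s$values)),
                 zones = matrix(as.integer(z$values[, , 1]),
                                z$grid$height, z$grid$width),
                 grid = s$grid),
            class = "season_raster")
}
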
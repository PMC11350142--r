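test_that("modal smoothing replaces isolated dissent and respects ties and nodata", {
  # constant layer is a fixed point
  sr_const <- structure(list(
    seasons = array(SEASONS[["summer"]], c(5, 5, 12)),
    zones = matrix(ZONES[["arctic_montane"]], 5, 5),
    grid = ws_grid(5, 5)), class = "season_raster")
  sm <- focal_smooth(sr_const, repair = FALSE)
  expect_identical(sm$seasons, sr_const$seasons)

  # single dissenting pixel in a uniform neighborhood is outvoted
  m <- matrix(1L, 5, 5); m[3, 3] <- 3L
  sm1 <- worldseasons:::modal_filter_layer(m)
  expect_equal(sm1[3, 3], 1L)

  # exact tie (4 ones vs 4 twos) retains the center value
  m2 <- rbind(c(1L, 1L, 2L), c(1L, 3L, 2L), c(2L, 2L, 1L))
  expect_equal(worldseasons:::modal_filter_layer(m2)[2, 2], 3L)

  # nodata is excluded from the vote and stays nodata
  m3 <- matrix(1L, 3, 3); m3[1, ] <- NA
  sm3 <- worldseasons:::modal_filter_layer(m3)
  expect_true(all(is.na(sm3[1, ])))
  expect_true(all(sm3[2:3, ] == 1L))

  expect_error(focal_smooth(sr_const, window = 4), "odd")
})

test_that("smoothing never invents labels absent from the input neighborhood", {
  set.seed(13)
  for (i in 1:5) {
    m <- matrix(sample(c(1:4, NA), 49, replace = TRUE), 7, 7)
    sm <- worldseasons:::modal_filter_layer(m)
    for (r in 1:7) for (c in 1:7) {
      if (is.na(m[r, c])) next
      nb <- m[max(1, r - 1):min(7, r + 1), max(1, c - 1):min(7, c + 1)]
      expect_true(sm[r, c] %in% nb[!is.na(nb)])
    }
  }
})

test_that("the repair pass restores circular contiguity after smoothing", {
  af <- matrix("temperate", 6, 6)
  af[, 4:6] <- "arctic"
  mr <- make_raster(6, 6, af, seed = 31, noise_sd = 1)
  sr <- classify_raster(mr$stack)
  sm <- focal_smooth(sr, window = 3, repair = TRUE)
  for (r in 1:6) for (c in 1:6) {
    z <- sm$zones[r, c]
    if (is.na(z) || z == ZONES[["tropical"]]) next
    expect_true(worldseasons:::is_circularly_contiguous(sm$seasons[r, c, ]))
  }
})

test_that("Equal Earth projection is equal-area and inverts to machine precision", {
  set.seed(2)
  lon <- runif(100, -179, 179); lat <- runif(100, -85, 85)
  f <- equal_earth_forward(lon, lat)
  inv <- equal_earth_inverse(f$x, f$y)
  expect_equal(inv$lon, lon, tolerance = 1e-9)
  expect_equal(inv$lat, lat, tolerance = 1e-9)

  # area scale factor: |Jacobian| must equal R^2 cos(lat) everywhere
  R <- 6371007.181; h <- 1e-5
  for (phi in c(0, 30, 60, 80)) {
    a <- equal_earth_forward(10, phi)
    dxdl <- (equal_earth_forward(10 + h, phi)$x - a$x) / (h * pi / 180)
    dxdp <- (equal_earth_forward(10, phi + h)$x - a$x) / (h * pi / 180)
    dydp <- (equal_earth_forward(10, phi + h)$y - a$y) / (h * pi / 180)
    dydl <- (equal_earth_forward(10 + h, phi)$y - a$y) / (h * pi / 180)
    expect_equal((dxdl * dydp - dxdp * dydl) / (R^2 * cos(phi * pi / 180)),
                 1, tolerance = 1e-4)
  }
  # published outline proportions of the projection
  expect_equal(equal_earth_forward(180, 0)$x / equal_earth_forward(0, 90)$y,
               2.05458, tolerance = 1e-4)
})

test_that("categorical reprojection uses nearest neighbor and keeps nodata", {
  af <- matrix("temperate", 8, 8); af[1, ] <- NA
  mr <- make_raster(8, 8, af, seed = 3, noise_sd = 0)
  sr <- classify_raster(mr$stack)
  ee <- reproject_equal_earth(sr)
  expect_equal(ee$grid$crs, "EqualEarth")
  # only labels present in the source can appear
  expect_true(all(ee$seasons[!is.na(ee$seasons)] %in%
                    sr$seasons[!is.na(sr$seasons)]))
  # the masked northern strip maps to nodata rows
  expect_true(anyNA(ee$seasons))
  expect_error(reproject_equal_earth(
    structure(list(seasons = sr$seasons, zones = sr$zones,
                   grid = ws_grid(8, 8, crs = "EqualEarth")),
              class = "season_raster")), "EPSG:4326")
})

test_that("raster outputs round-trip bit-identically with a consistent text table", {
  af <- matrix(c("temperate", "tropical_bimodal", "desert_cold", "arctic"),
               4, 4)
  mr <- make_raster(4, 4, af, seed = 9, noise_sd = 1)
  sr <- classify_raster(mr$stack)
  outdir <- withr::local_tempdir()
  files <- write_outputs(sr, outdir = outdir)
  expect_true(all(file.exists(files)))
  rt <- read_season_raster(outdir)
  expect_identical(rt$seasons, sr$seasons)
  expect_identical(rt$zones, sr$zones)
  expect_equal(rt$grid$xres, sr$grid$xres)

  tab <- read.csv(files[["table"]])
  expect_equal(nrow(tab), 12 * sum(!is.na(sr$zones)))
  expect_true(all(tab$month %in% 1:12))
  # cross-format consistency: table rows equal the raster's codes
  for (i in sample(nrow(tab), 25)) {
    r <- round(worldseasons:::grid_row(sr$grid, tab$y[i]))
    c <- round(worldseasons:::grid_col(sr$grid, tab$x[i]))
    expect_equal(tab$season[i],
                 season_name(sr$seasons[r, c, tab$month[i]]))
  }
})

test_that("continuous rasters survive the 16-bit scaled storage round trip", {
  g <- ws_grid(5, 4, xmin = 10, ymax = 50, xres = 0.5)
  vals <- array(rnorm(5 * 4 * 12, 15, 10), c(4, 5, 12))
  vals[2, 2, ] <- NA
  f <- file.path(withr::local_tempdir(), "t.tif")
  write_raster_tif(vals, g, f, type = "float")
  rd <- read_raster_tif(f)
  rng <- diff(range(vals, na.rm = TRUE))
  expect_lt(max(abs(rd$values - vals), na.rm = TRUE), rng / 65000)
  expect_true(all(is.na(rd$values[2, 2, ])))
  expect_equal(rd$grid$xmin, 10)
  expect_equal(rd$grid$yres, 0.5)
})

test_that("monthly stacks read back through config with bilinear alignment", {
  mr <- make_raster(6, 5, "temperate", seed = 21, noise_sd = 1)
  st <- mr$stack
  d <- withr::local_tempdir()
  cfg <- list()
  for (nm in names(st$vars)) {
    p <- file.path(d, paste0(nm, ".tif"))
    write_raster_tif(st$vars[[nm]], st$grid, p)
    cfg[[nm]] <- p
  }
  st2 <- read_monthly_stack(cfg)
  expect_equal(st2$vars$tmin, st$vars$tmin, tolerance = 1e-2)
  expect_equal(st2$grid$xres, st$grid$xres)

  # a coarser NDVI layer is bilinearly resampled within local bounds
  coarse_g <- ws_grid(3, 3, xmin = st$grid$xmin, ymax = st$grid$ymax,
                      xres = st$grid$xres * 2, yres = st$grid$yres * 2)
  coarse <- array(runif(3 * 3 * 12, 0, 1), c(3, 3, 12))
  p <- file.path(d, "ndvi_coarse.tif")
  write_raster_tif(coarse, coarse_g, p)
  cfg$ndvi <- p
  st3 <- read_monthly_stack(cfg)
  expect_true(all(st3$vars$ndvi >= min(coarse) - 1e-3 &
                    st3$vars$ndvi <= max(coarse) + 1e-3))

  cfg$tmin <- NULL
  expect_error(read_monthly_stack(cfg), "tmin")
})
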
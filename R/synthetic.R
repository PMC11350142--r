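# seasonal harmonic: value 1 at month `peak`, -1 half a year away;
# `period` 12 for annual, 6 for twice-yearly (bimodal tropical rainfall)
season_wave <- function(peak, period = 12) cos(2 * pi * ((1:12) - peak) / period)

ARCHETYPES <- c("temperate", "tropical_unimodal", "tropical_bimodal",
                "desert_hot", "desert_cold", "arctic")

# per-variable Gaussian noise scales at noise_sd = 1 (units of the variable)
NOISE_BASE <- c(temp = 0.5, precip = 4, srad = 0.5, ndvi = 0.02, pet = 4)

#' Synthetic archetype specification
#'
#' Parameter set for one synthetic location emulating the climate structure
#' of a zone: temperate cells get a sinusoidal annual temperature cycle
#' (mean 10 deg C, half-amplitude 12, coldest month January in the northern
#' hemisphere) with mild rainfall seasonality and NDVI tracking temperature
#' with a one-month delay; tropical cells near-constant heat (26 +/- 1
#' deg C) with monsoonal rainfall (one or two peaks, range > 150 mm) and
#' NDVI tracking rainfall; deserts annual aridity < 0.1 with a 15 deg C
#' (hot) or 25 deg C (cold) peak-to-peak temperature cycle; arctic cells
#' monthly-mean minima never above 10 deg C with solar radiation peaking at
#' the summer solstice. Gaussian noise is added per variable with scale
#' `noise_sd` times a fixed per-variable base; archetype parameters leave a
#' margin of at least twice the noise scale on every zone gate, which the
#' constructor verifies.
#'
#' @param archetype one of `"temperate"`, `"tropical_unimodal"`,
#'   `"tropical_bimodal"`, `"desert_hot"`, `"desert_cold"`, `"arctic"`.
#' @param hemisphere `"N"` or `"S"` (southern-hemisphere cycles are shifted
#'   by six months).
#' @param noise_sd nonnegative noise multiplier (0 = noise-free).
#' @param seed integer seed for the noise draws.
#' @param tmid_shift additive offset on the temperature cycle (deg C), used
#'   by [make_raster()] for smooth spatial parameter fields.
#' @param precip_shift additive offset on rainfall (mm).
#' @return an object of class `archetype_spec`.
#' @export
archetype_spec <- function(archetype, hemisphere = "N", noise_sd = 1,
                           seed = 1L, tmid_shift = 0, precip_shift = 0) {
  archetype <- match.arg(archetype, ARCHETYPES)
  stopifnot(hemisphere %in% c("N", "S"), noise_sd >= 0)
  spec <- structure(list(archetype = archetype, hemisphere = hemisphere,
                         noise_sd = noise_sd, seed = as.integer(seed),
                         tmid_shift = tmid_shift, precip_shift = precip_shift),
                    class = "archetype_spec")
  check_gate_margins(spec)
  spec
}

# noise-free variable curves of a spec; ph = hemisphere phase shift
archetype_curves <- function(spec) {
  ph <- if (spec$hemisphere == "N") 0 else 6
  a <- spec$archetype
  w <- function(peak, period = 12) season_wave(peak + ph, period)
  cv <- switch(a,
    temperate = list(
      tmid = 10 + 12 * w(7), tspan = 5,
      precip = 65 + 20 * w(7), pet = 60 + 45 * w(7),
      srad = 15 + 8 * w(6.5), ndvi = 0.45 + 0.25 * w(8)),
    tropical_unimodal = list(
      tmid = 26 + 1 * w(7), tspan = 4,
      precip = 120 + 100 * w(7.5), pet = rep(120, 12),
      srad = 20 + 2 * w(5), ndvi = 0.6 + 0.15 * w(8.5)),
    tropical_bimodal = list(
      tmid = 26 + 1 * w(7), tspan = 4,
      precip = 120 + 90 * w(4, 6), pet = rep(120, 12),
      srad = 20 + 2 * w(5), ndvi = 0.6 + 0.12 * w(5, 6)),
    desert_hot = list(
      tmid = 28 + 7.5 * w(7.5), tspan = 8,
      precip = pmax(4 + 2 * w(8), 0), pet = 200 + 50 * w(7.5),
      srad = 22 + 6 * w(6.5), ndvi = rep(0.08, 12)),
    desert_cold = list(
      tmid = 2 + 12.5 * w(7.5), tspan = 7,
      precip = pmax(6 + 3 * w(7.5), 0), pet = 80 + 40 * w(7.5),
      srad = 18 + 8 * w(6.5), ndvi = rep(0.1, 12)),
    arctic = list(
      tmid = -8 + 9 * w(7.5), tspan = 4,
      precip = 30 + 5 * w(7.5), pet = 15 + 10 * w(7.5),
      srad = 12 + 11 * w(6.5), ndvi = 0.2 + 0.1 * w(8)))
  cv$tmid <- cv$tmid + spec$tmid_shift
  cv$precip <- pmax(cv$precip + spec$precip_shift, 0)
  cv
}

intended_zone <- function(archetype) {
  switch(archetype,
         temperate = ZONES[["temperate"]],
         tropical_unimodal = , tropical_bimodal = ZONES[["tropical"]],
         desert_hot = , desert_cold = ZONES[["desert"]],
         arctic = ZONES[["arctic_montane"]])
}

# verify the noise-free curves satisfy the intended zone's gate with a
# margin of at least 2x the relevant noise scale (default thresholds)
check_gate_margins <- function(spec) {
  cv <- archetype_curves(spec)
  th <- zone_thresholds()
  zone <- intended_zone(spec$archetype)
  ai <- sum(cv$precip) / sum(cv$pet)
  tnoise <- 2 * spec$noise_sd * NOISE_BASE[["temp"]]
  pnoise <- 2 * spec$noise_sd * NOISE_BASE[["precip"]]
  ok <- switch(zone_name(zone),
    desert = ai < th$desert_ai_thresh / 2,
    arctic_montane = ai >= 2 * th$desert_ai_thresh &&
      max(cv$tmid - cv$tspan) + tnoise <= th$arctic_tmin_ceiling,
    tropical = diff(range(cv$precip)) - pnoise > th$precip_diff_thresh &&
      diff(range(cv$tmid)) + tnoise < th$temp_diff_thresh &&
      min(cv$tmid) - tnoise >= th$tropical_min_temp &&
      ai >= 2 * th$desert_ai_thresh,
    temperate = ai >= 2 * th$desert_ai_thresh &&
      max(cv$tmid - cv$tspan) - tnoise > th$arctic_tmin_ceiling &&
      diff(range(cv$tmid)) - tnoise > th$temp_diff_thresh)
  if (!isTRUE(ok))
    stop("archetype '", spec$archetype,
         "' violates its zone gate margin at noise_sd = ", spec$noise_sd)
  invisible(TRUE)
}

# analytic ground-truth calendar from the generating phases
archetype_truth <- function(spec) {
  ph <- if (spec$hemisphere == "N") 0 else 6
  rot <- function(m) ((m - 1 + ph) %% 12) + 1
  a <- spec$archetype
  labels <- integer(12)
  if (a == "temperate") {
    labels[rot(c(12, 1, 2))] <- SEASONS[["winter"]]
    labels[rot(3:5)] <- SEASONS[["spring"]]
    labels[rot(6:8)] <- SEASONS[["summer"]]
    labels[rot(9:11)] <- SEASONS[["autumn"]]
  } else {
    cv <- archetype_curves(spec)
    key <- switch(a, tropical_unimodal = , tropical_bimodal = cv$precip,
                  cv$tmid)
    hi_code <- switch(a, tropical_unimodal = , tropical_bimodal =
                        SEASONS[["wet"]],
                      desert_hot = , desert_cold = SEASONS[["hotter"]],
                      arctic = SEASONS[["summer"]])
    lo_code <- switch(a, tropical_unimodal = , tropical_bimodal =
                        SEASONS[["dry"]],
                      desert_hot = , desert_cold = SEASONS[["cooler"]],
                      arctic = SEASONS[["winter"]])
    labels <- ifelse(key > mean(key), hi_code, lo_code)
  }
  structure(list(zone = as.integer(intended_zone(a)),
                 labels = as.integer(labels),
                 names = season_name(labels)),
            class = "season_calendar")
}

#' Generate one synthetic pixel with known ground truth
#'
#' @param spec an [archetype_spec()].
#' @return list with `pixel` (a [pixel_climate()]), `zone` (intended zone
#'   code) and `truth` (the analytic `season_calendar` derived from the
#'   generating phases, independent of the classifier).
#' @export
make_pixel <- function(spec) {
  cv <- archetype_curves(spec)
  noise <- function(scale) {
    if (spec$noise_sd == 0) rep(0, 12)
    else rnorm(12, 0, spec$noise_sd * scale)
  }
  px <- withr_seed(spec$seed, {
    tmid <- cv$tmid + noise(NOISE_BASE[["temp"]])
    pixel_climate(
      tmin = tmid - cv$tspan, tmax = tmid + cv$tspan,
      precip = pmax(cv$precip + noise(NOISE_BASE[["precip"]]), 0),
      srad = pmax(cv$srad + noise(NOISE_BASE[["srad"]]), 0),
      ndvi = pmin(pmax(cv$ndvi + noise(NOISE_BASE[["ndvi"]]), -1), 1),
      pet = pmax(cv$pet + noise(NOISE_BASE[["pet"]]), 0))
  })
  list(pixel = px, zone = intended_zone(spec$archetype),
       truth = archetype_truth(spec))
}

#' Generate a synthetic climate raster with truth layers
#'
#' Builds a climate stack whose cells follow per-cell archetypes with
#' spatially smooth low-frequency parameter variation inside archetype
#' blocks, plus seeded per-cell noise.
#'
#' @param width,height grid size in cells.
#' @param archetype_field character matrix (height x width) of archetype
#'   names, or one name recycled to all cells; `NA` cells are masked.
#' @param seed integer seed.
#' @param noise_sd per-cell noise multiplier (see [archetype_spec()]).
#' @param hemisphere `"N"` or `"S"`.
#' @param grid optional [ws_grid()]; default spans 20 deg at 0.5 deg cells.
#' @return list with `stack` (a [climate_stack()]), `zone_truth` (integer
#'   matrix) and `season_truth` (height x width x 12 integer array).
#' @export
make_raster <- function(width, height, archetype_field = "temperate",
                        seed = 1L, noise_sd = 0, hemisphere = "N",
                        grid = NULL) {
  if (!is.matrix(archetype_field))
    archetype_field <- matrix(archetype_field, height, width)
  stopifnot(nrow(archetype_field) == height, ncol(archetype_field) == width)
  if (is.null(grid))
    grid <- ws_grid(width, height, xmin = -10, ymax = 55, xres = 0.5,
                    yres = 0.5, crs = "EPSG:4326")
  vars <- lapply(setNames(STACK_VARS[1:6], STACK_VARS[1:6]),
                 function(nm) array(NA_real_, c(height, width, 12)))
  zone_truth <- matrix(NA_integer_, height, width)
  season_truth <- array(NA_integer_, c(height, width, 12))
  for (row in seq_len(height)) {
    for (col in seq_len(width)) {
      a <- archetype_field[row, col]
      if (is.na(a)) next
      # smooth sub-degree parameter drift within blocks
      tshift <- 0.4 * sin(2 * pi * col / width) + 0.3 * cos(2 * pi * row / height)
      pshift <- 3 * sin(2 * pi * row / height)
      spec <- archetype_spec(a, hemisphere = hemisphere, noise_sd = noise_sd,
                             seed = seed + row * 1009L + col * 9176L,
                             tmid_shift = tshift, precip_shift = pshift)
      mp <- make_pixel(spec)
      for (nm in names(vars)) vars[[nm]][row, col, ] <- mp$pixel[[nm]]
      zone_truth[row, col] <- mp$zone
      season_truth[row, col, ] <- mp$truth$labels
    }
  }
  mask <- !is.na(zone_truth)
  list(stack = climate_stack(grid, vars, mask = mask),
       zone_truth = zone_truth, season_truth = season_truth)
}

#' Generate synthetic reference records with paired pixels
#'
#' Draws archetype pixels, labels each one with [classify_pixel()] under
#' the supplied parameters, optionally flips each month's label to a
#' same-zone alternative with probability `label_flip_p` (emulating
#' offset-style disagreement in real reference calendars), and returns
#' canonical-vocabulary records plus the pixel lookup the evaluator needs.
#' The default archetypes exclude deserts, whose cooler/hotter vocabulary
#' does not occur in reference calendars.
#'
#' @param params a [ws_params()] used to label the pixels.
#' @param n_per_archetype cities drawn per archetype.
#' @param noise_sd climate-noise multiplier for the drawn pixels.
#' @param label_flip_p per-month label-flip probability in [0, 1).
#' @param seed integer seed.
#' @param archetypes archetype names to draw from.
#' @param hemisphere `"N"` or `"S"`.
#' @return list with `records` (data.frame: city, country, lon, lat,
#'   jan..dec) and `pixel_lookup` (named list of [pixel_climate()]).
#' @export
make_reference_set <- function(params = default_params(),
                               n_per_archetype = 10, noise_sd = 0,
                               label_flip_p = 0, seed = 1L,
                               archetypes = c("temperate",
                                              "tropical_unimodal",
                                              "tropical_bimodal", "arctic"),
                               hemisphere = "N") {
  stopifnot(n_per_archetype >= 1, label_flip_p >= 0, label_flip_p < 1)
  recs <- list()
  lookup <- list()
  i <- 0
  for (a in archetypes) {
    for (j in seq_len(n_per_archetype)) {
      i <- i + 1
      city <- paste0(a, "_", j)
      spec <- archetype_spec(a, hemisphere = hemisphere, noise_sd = noise_sd,
                             seed = seed + 7919L * i)
      mp <- make_pixel(spec)
      cal <- classify_pixel(mp$pixel, params)
      labels <- cal$names
      if (label_flip_p > 0) {
        allowed <- season_name(zone_season_set(cal$zone))
        labels <- withr_seed(seed + 104729L * i, {
          flip <- runif(12) < label_flip_p
          vapply(seq_len(12), function(m) {
            if (!flip[m]) labels[m]
            else sample(setdiff(allowed, labels[m]), 1)
          }, "")
        })
      }
      lonlat <- withr_seed(seed + 15485863L * i,
                           c(runif(1, -180, 180), runif(1, -60, 70)))
      rec <- data.frame(city = city, country = a,
                        lon = lonlat[1], lat = lonlat[2],
                        stringsAsFactors = FALSE)
      rec[MONTH_KEYS] <- as.list(labels)
      recs[[i]] <- rec
      lookup[[city]] <- mp$pixel
    }
  }
  list(records = do.call(rbind, recs), pixel_lookup = lookup)
}
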
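#' Climate zone codes
#'
#' Stable integer codes for the four principal climate zones. Raster outputs
#' use these codes with 0 reserved for nodata.
#'
#' @format named integer vector: desert = 1, arctic_montane = 2,
#'   tropical = 3, temperate = 4.
#' @export
ZONES <- c(desert = 1L, arctic_montane = 2L, tropical = 3L, temperate = 4L)

#' @rdname ZONES
#' @param code integer zone code(s).
#' @export
zone_name <- function(code) names(ZONES)[match(code, ZONES)]

#' Zonation thresholds
#'
#' The fixed conditions that sort a cell into a climate zone. The
#' precipitation-difference and temperature-difference thresholds separate
#' tropical from temperate and are the two thresholds exposed to the
#' calibration search (bounded to 80--130 mm and 3--14 deg C). The
#' remaining three are fixed: deserts are cells whose annual aridity index
#' (annual precipitation / annual PET) falls below 0.2, the UNEP arid
#' boundary; arctic/high-montane cells are those whose mean monthly minimum
#' temperature never exceeds 10 deg C; and a coldest-month midpoint
#' temperature of at least 18 deg C (the Koeppen tropical convention)
#' excludes cold-but-equable maritime climates from the tropics.
#'
#' @param precip_diff_thresh mm; wettest-minus-driest month must exceed this
#'   for a cell to be tropical. Default 81.972.
#' @param temp_diff_thresh deg C; hottest-minus-coldest month midpoint must
#'   fall below this for a cell to be tropical. Default 7.52.
#' @param tropical_min_temp deg C; coldest-month midpoint floor for the
#'   tropics. Default 18.
#' @param arctic_tmin_ceiling deg C; ceiling on the warmest month's mean
#'   minimum temperature for arctic/high-montane cells. Default 10.
#' @param desert_ai_thresh unitless annual aridity below which a cell is
#'   desert. Default 0.2.
#' @return an object of class `zone_thresholds`.
#' @export
zone_thresholds <- function(precip_diff_thresh = 81.972,
                            temp_diff_thresh = 7.52,
                            tropical_min_temp = 18,
                            arctic_tmin_ceiling = 10,
                            desert_ai_thresh = 0.2) {
  stopifnot(precip_diff_thresh > 0, temp_diff_thresh > 0,
            desert_ai_thresh > 0)
  structure(list(precip_diff_thresh = precip_diff_thresh,
                 temp_diff_thresh = temp_diff_thresh,
                 tropical_min_temp = tropical_min_temp,
                 arctic_tmin_ceiling = arctic_tmin_ceiling,
                 desert_ai_thresh = desert_ai_thresh),
            class = "zone_thresholds")
}

#' Annual aridity index of a pixel
#'
#' Ratio of total annual precipitation to total annual potential
#' evapotranspiration; low values denote deserts.
#'
#' @param pixel a [pixel_climate()] object.
#' @return unitless scalar.
#' @export
annual_aridity <- function(pixel) {
  etot <- sum(pixel$pet)
  if (is.finite(etot) && etot > 0) return(sum(pixel$precip) / etot)
  # PET absent: reconstruct monthly PET from the precomputed aridity ratio
  if (all(is.finite(pixel$aridity))) {
    pet_hat <- ifelse(pixel$precip > 0,
                      pixel$precip / pmax(pixel$aridity, 1e-12), 0)
    if (sum(pet_hat) > 0) return(sum(pixel$precip) / sum(pet_hat))
  }
  stop("annual PET is zero or missing: annual aridity undefined")
}

#' Classify one pixel into a climate zone
#'
#' Threshold decision sequence: (1) desert if annual aridity is below the
#' aridity threshold -- aridity pre-empts the cold rule so that arid cold
#' regions (dry tundra, Tibetan plateau, Gobi) classify as cold deserts;
#' (2) else arctic/high-montane if no month's mean minimum temperature
#' exceeds 10 deg C; (3) else tropical if the intra-annual precipitation
#' range is strictly above the precipitation threshold, the midpoint
#' temperature range strictly below the temperature threshold, and the
#' coldest month's midpoint at least 18 deg C; (4) else temperate.
#'
#' @param pixel a [pixel_climate()] object.
#' @param th a [zone_thresholds()] object.
#' @return integer zone code (see [ZONES]).
#' @export
classify_zone <- function(pixel, th = zone_thresholds()) {
  if (annual_aridity(pixel) < th$desert_ai_thresh) return(ZONES[["desert"]])
  if (max(pixel$tmin) <= th$arctic_tmin_ceiling) return(ZONES[["arctic_montane"]])
  prange <- max(pixel$precip) - min(pixel$precip)
  trange <- max(pixel$tmid) - min(pixel$tmid)
  if (prange > th$precip_diff_thresh && trange < th$temp_diff_thresh &&
      min(pixel$tmid) >= th$tropical_min_temp)
    return(ZONES[["tropical"]])
  ZONES[["temperate"]]
}

#' Climate-zone map of a climate stack
#'
#' Applies [classify_zone()] to every unmasked cell.
#'
#' @param stack a [climate_stack()] object.
#' @param th a [zone_thresholds()] object.
#' @return integer matrix (rows x cols) of zone codes with `NA` where
#'   masked, with the stack's grid attached as attribute `grid`.
#' @export
zone_map <- function(stack, th = zone_thresholds()) {
  g <- stack$grid
  out <- matrix(NA_integer_, g$height, g$width)
  for (row in seq_len(g$height)) {
    for (col in seq_len(g$width)) {
      if (!stack$mask[row, col]) next
      out[row, col] <- classify_zone(extract_pixel(stack, col, row), th)
    }
  }
  attr(out, "grid") <- g
  out
}
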
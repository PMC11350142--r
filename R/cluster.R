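#' Season label codes
#'
#' Stable integer codes for the eight season names. Each climate zone draws
#' from its own subset: temperate cells use winter/spring/summer/autumn,
#' arctic cells winter/summer, tropical cells wet/dry, desert cells
#' cooler/hotter. Raster outputs use these codes with 0 reserved for nodata.
#'
#' @format named integer vector.
#' @export
SEASONS <- c(winter = 1L, spring = 2L, summer = 3L, autumn = 4L,
             wet = 5L, dry = 6L, cooler = 7L, hotter = 8L)

#' @rdname SEASONS
#' @param code integer season code(s).
#' @export
season_name <- function(code) names(SEASONS)[match(code, SEASONS)]

#' @rdname SEASONS
#' @param zone integer zone code.
#' @export
zone_season_set <- function(zone) {
  switch(zone_name(zone),
         desert = SEASONS[c("cooler", "hotter")],
         arctic_montane = SEASONS[c("winter", "summer")],
         tropical = SEASONS[c("wet", "dry")],
         temperate = SEASONS[c("winter", "spring", "summer", "autumn")],
         stop("unknown zone code: ", zone))
}

# number of season clusters per zone
zone_k <- function(zone) if (zone == ZONES[["temperate"]]) 4L else 2L

#' Cluster-variable weights
#'
#' Weights applied to the z-normalized cluster variables in the weighted
#' zones. A weight of w makes the variable w times as important as an
#' unweighted variable in the squared cluster distance. Desert and arctic
#' clustering is unweighted (their two variables are strongly correlated).
#' Defaults are the calibrated optimum shipped with the package.
#'
#' @param temperate named numeric: weights for temperature, precipitation
#'   lag, temperature lag, NDVI lag.
#' @param tropical named numeric: weights for temperature, precipitation
#'   lag, NDVI lag (temperature lag is excluded in the tropics, where the
#'   direction of month-to-month temperature change is not a smooth annual
#'   cycle).
#' @return an object of class `weight_set`.
#' @export
weight_set <- function(temperate = c(temperature = 3.521, precip_lag = 3.237,
                                     temp_lag = 2.031, ndvi_lag = 0.312),
                       tropical = c(temperature = 3.958, precip_lag = 3.72,
                                    ndvi_lag = 1.713)) {
  stopifnot(length(temperate) == 4, length(tropical) == 3,
            all(temperate > 0), all(tropical > 0))
  structure(list(temperate = temperate, tropical = tropical),
            class = "weight_set")
}

#' Zone-specific month-by-feature matrix
#'
#' Selects the clustering variables for the pixel's zone, z-normalizes each
#' column, and scales column j by sqrt(w_j) so that a weight w multiplies
#' that variable's contribution to squared Euclidean distance by exactly w.
#' Variable sets: arctic (temperature, solar radiation); desert
#' (temperature, aridity); temperate (temperature, precipitation lag,
#' temperature lag, NDVI lag); tropical (temperature, precipitation lag,
#' NDVI lag).
#'
#' @param pixel a [pixel_climate()] object.
#' @param zone integer zone code.
#' @param w a [weight_set()].
#' @param use_precip_level substitute the precipitation level for the
#'   precipitation lag in the weighted zones (comparison switch).
#' @param weight_scale `"sqrt"` (default; weights act on squared distance)
#'   or `"linear"` (weights act on the coordinate directly).
#' @return 12 x d numeric matrix, one row per month.
#' @export
build_feature_matrix <- function(pixel, zone, w = weight_set(),
                                 use_precip_level = FALSE,
                                 weight_scale = c("sqrt", "linear")) {
  weight_scale <- match.arg(weight_scale)
  zn <- zone_name(zone)
  if (is.na(zn)) stop("unknown zone code: ", zone)
  pcol <- if (use_precip_level) pixel$precip else pixel$lag_precip
  cols <- switch(zn,
    arctic_montane = list(temperature = pixel$tmid, srad = pixel$srad),
    desert = list(temperature = pixel$tmid, aridity = pixel$aridity),
    temperate = list(temperature = pixel$tmid, precip_lag = pcol,
                     temp_lag = pixel$lag_tmid, ndvi_lag = pixel$lag_ndvi),
    tropical = list(temperature = pixel$tmid, precip_lag = pcol,
                    ndvi_lag = pixel$lag_ndvi))
  wts <- switch(zn,
    arctic_montane = c(1, 1), desert = c(1, 1),
    temperate = unname(w$temperate), tropical = unname(w$tropical))
  X <- vapply(cols, znormalize, numeric(12))
  X[!is.finite(X)] <- 0
  f <- if (weight_scale == "sqrt") sqrt(wts) else wts
  X <- sweep(X, 2, f, `*`)
  rownames(X) <- MONTH_KEYS
  X
}

#' Cluster the twelve months by best-of-restarts k-means
#'
#' Lloyd's algorithm restarted from farthest-point and random
#' initializations, keeping the lowest within-cluster sum of squares;
#' deterministic for a given seed. Labels are renumbered 1..k in order of
#' first occurrence. If the matrix has fewer distinct rows than k the
#' result is degenerate (fewer labels than requested) and is flagged via
#' the `"degenerate"` attribute; callers fall back to the contiguous
#' oracle, which always yields k nonempty arcs.
#'
#' @param X 12 x d feature matrix.
#' @param k number of clusters (2 for two-season zones, 4 for temperate).
#' @param seed integer seed for the restart stream.
#' @param restarts number of initializations (default 50).
#' @return integer vector of 12 labels in 1..k with attributes `sse` and
#'   `degenerate`.
#' @export
kmeans_months <- function(X, k, seed = 1L, restarts = 50L) {
  stopifnot(nrow(X) == 12, k >= 1)
  if (k == 1) {
    out <- rep(1L, 12)
    attr(out, "sse") <- .labels_sse_cpp(X, out)
    attr(out, "degenerate") <- FALSE
    return(out)
  }
  ndistinct <- nrow(unique(X))
  keff <- min(k, ndistinct)
  res <- .kmeans_restarts_cpp(X, keff, as.integer(restarts), as.integer(seed))
  out <- as.integer(res$labels)
  attr(out, "sse") <- res$sse
  attr(out, "degenerate") <- (res$k_found < k)
  out
}

#' Exact best circularly contiguous partition of the months
#'
#' Enumerates every partition of the 12 months into k circularly contiguous
#' arcs (66 cut-sets for k = 2, 495 for k = 4) and returns the one with the
#' lowest within-cluster sum of squares; ties are broken by the
#' lexicographically smallest cut-set. Serves both as the exact solver for
#' degenerate pixels and as the reference against which the k-means route
#' is validated.
#'
#' @param X 12 x d feature matrix.
#' @param k number of arcs.
#' @return integer vector of 12 labels (1..k, numbered in cut order) with
#'   attribute `sse`.
#' @export
contiguous_partition_oracle <- function(X, k) {
  stopifnot(nrow(X) == 12, k >= 1, k <= 12)
  if (k == 1) {
    out <- rep(1L, 12)
    attr(out, "sse") <- .labels_sse_cpp(X, out)
    return(out)
  }
  res <- .contiguous_best_cpp(X, as.integer(k))
  out <- as.integer(res$labels)
  attr(out, "sse") <- res$sse
  out
}

# TRUE if every distinct label occupies one circular run
is_circularly_contiguous <- function(labels) {
  nlab <- length(unique(labels))
  boundaries <- sum(labels != labels[c(12, 1:11)])
  boundaries == ifelse(nlab == 1, 0, nlab)
}

#' Project month labels onto a contiguous partition
#'
#' Post-hoc mechanism by which the temporal-contiguity principle -- once a
#' season ends it cannot reappear within the annual cycle -- is enforced
#' outside the tropics. Already contiguous input is returned unchanged.
#' Two projections are offered for non-contiguous input:
#'
#' * `"sse"` (used by the classification pipeline): re-solve the clustering
#'   exactly within the contiguous family, i.e. replace the labeling with
#'   the contiguous k-arc partition of minimum within-cluster sum of
#'   squares (the [contiguous_partition_oracle()]). This projects in the
#'   objective the clustering optimizes; input labels that merely straddle
#'   a boundary are repaired, and the repaired calendar is never a worse
#'   clustering than any contiguous alternative.
#' * `"hamming"`: return the contiguous k-arc partition minimizing Hamming
#'   disagreement with the input labeling (over all arc-to-label
#'   bijections); among equals the partition with the lower SSE on `X`,
#'   then the lexicographically smallest cut-set. This stays as close as
#'   possible to the k-means labels in label space, but can settle on a
#'   substantially worse clustering than the exact contiguous optimum.
#'
#' @param labels integer vector of 12 cluster labels.
#' @param X the 12 x d feature matrix the labels were fitted on.
#' @param method `"hamming"` (label-space projection, the default for
#'   direct calls) or `"sse"` (objective-space projection).
#' @return integer vector of 12 circularly contiguous labels; for
#'   `"hamming"` they are drawn from the input label values.
#' @export
enforce_contiguity <- function(labels, X, method = c("hamming", "sse")) {
  method <- match.arg(method)
  stopifnot(length(labels) == 12)
  if (is_circularly_contiguous(labels)) return(labels)
  vals <- sort(unique(labels))
  k <- length(vals)
  if (method == "sse") return(contiguous_partition_oracle(X, k))
  dense <- match(labels, vals)
  res <- .project_contiguous_cpp(as.integer(dense), X, as.integer(k))
  out <- vals[as.integer(res$labels)]
  attr(out, "sse") <- res$sse
  attr(out, "hamming") <- res$hamming
  out
}

#' Name the clustered months as seasons
#'
#' Two-season zones are named by cluster means: the higher-mean-temperature
#' cluster is summer (arctic) or hotter (desert); the higher-mean-rainfall
#' cluster is wet (tropical). Temperate calendars must be four contiguous
#' arcs: the coldest arc (mean midpoint temperature) is winter and the
#' hottest is summer; the arc lying forward in circular time between
#' winter's end and summer's start is spring and the remaining arc is
#' autumn. If winter and summer are circularly adjacent the two remaining
#' arcs are disambiguated by their mean temperature lag (warming = spring).
#'
#' @param labels integer vector of 12 cluster labels.
#' @param pixel the [pixel_climate()] the labels describe.
#' @param zone integer zone code.
#' @return a `season_calendar`: list with `zone`, integer `labels` (season
#'   codes, see [SEASONS]) and character `names`, both length 12.
#' @export
name_seasons <- function(labels, pixel, zone) {
  zn <- zone_name(zone)
  vals <- sort(unique(labels))
  mean_by <- function(v) vapply(vals, function(g) mean(v[labels == g]), 0)
  if (zn %in% c("arctic_montane", "desert", "tropical")) {
    if (length(vals) != 2)
      stop("two-season zone requires exactly 2 clusters, got ", length(vals))
    key <- if (zn == "tropical") mean_by(pixel$precip) else mean_by(pixel$tmid)
    hi <- vals[which.max(key)]
    pair <- switch(zn, arctic_montane = c("summer", "winter"),
                   desert = c("hotter", "cooler"),
                   tropical = c("wet", "dry"))
    codes <- ifelse(labels == hi, SEASONS[[pair[1]]], SEASONS[[pair[2]]])
  } else {
    if (length(vals) != 4)
      stop("temperate calendar requires exactly 4 clusters, got ", length(vals))
    if (!is_circularly_contiguous(labels))
      stop("temperate labels must be circularly contiguous before naming")
    mt <- mean_by(pixel$tmid)
    winter <- vals[which.min(mt)]
    summer <- vals[which.max(mt)]
    # arcs in circular order of their start month
    starts <- vapply(vals, function(g) {
      prev <- labels[c(12, 1:11)]
      which(labels == g & prev != g)[1]
    }, 0)
    ord <- vals[order(starts)]
    iw <- which(ord == winter)
    rot <- ord[((seq_along(ord) + iw - 2) %% 4) + 1] # winter first
    is_pos <- which(rot == summer)
    codes <- integer(12)
    if (is_pos == 3) { # winter, spring-arc, summer, autumn-arc
      season_of <- setNames(c("winter", "spring", "summer", "autumn"), rot)
    } else {
      # winter and summer adjacent: split remaining arcs by warming/cooling
      others <- setdiff(rot, c(winter, summer))
      lag <- mean_by(pixel$lag_tmid)
      spring <- others[which.max(lag[match(others, vals)])]
      autumn <- setdiff(others, spring)
      season_of <- setNames(character(4), c(winter, spring, summer, autumn))
      season_of[as.character(winter)] <- "winter"
      season_of[as.character(spring)] <- "spring"
      season_of[as.character(summer)] <- "summer"
      season_of[as.character(autumn)] <- "autumn"
    }
    codes <- SEASONS[season_of[as.character(labels)]]
  }
  structure(list(zone = as.integer(zone),
                 labels = as.integer(unname(codes)),
                 names = season_name(codes)),
            class = "season_calendar")
}

#' @export
print.season_calendar <- function(x, ...) {
  cat("<season_calendar> zone:", zone_name(x$zone), "\n")
  print(setNames(x$names, month.abb))
  invisible(x)
}

#' Classify one pixel into a named season calendar
#'
#' The full two-tier pipeline for a single location: zone assignment by
#' thresholds, zone-specific weighted k-means over the twelve months
#' (k = 4 temperate, k = 2 elsewhere), post-hoc temporal-contiguity
#' enforcement outside the tropics (multiple wet seasons are legitimate
#' under the ITCZ), and season naming. Degenerate pixels where k-means
#' cannot form k distinct clusters fall back to the exact contiguous
#' oracle. Deterministic for a given seed.
#'
#' @param pixel a [pixel_climate()] object.
#' @param params a [ws_params()] bundle of thresholds and weights.
#' @param seed,restarts passed to [kmeans_months()].
#' @param use_precip_level,weight_scale passed to [build_feature_matrix()].
#' @return a `season_calendar` (see [name_seasons()]).
#' @export
classify_pixel <- function(pixel, params = default_params(), seed = 1L,
                           restarts = 50L, use_precip_level = FALSE,
                           weight_scale = "sqrt") {
  zone <- classify_zone(pixel, params$thresholds)
  k <- zone_k(zone)
  X <- build_feature_matrix(pixel, zone, params$weights,
                            use_precip_level = use_precip_level,
                            weight_scale = weight_scale)
  labels <- kmeans_months(X, k, seed = seed, restarts = restarts)
  if (isTRUE(attr(labels, "degenerate")) ||
      length(unique(labels)) < k) {
    labels <- contiguous_partition_oracle(X, k)
  } else if (zone != ZONES[["tropical"]]) {
    labels <- enforce_contiguity(labels, X, method = "sse")
  }
  name_seasons(as.integer(labels), pixel, zone)
}

#' Classify every cell of a climate stack
#'
#' Vectorizes [classify_pixel()] over the grid; masked cells stay masked.
#'
#' @param stack a [climate_stack()].
#' @param params a [ws_params()].
#' @param seed,restarts per-pixel clustering controls.
#' @return a `season_raster`: list with `seasons` (height x width x 12
#'   integer array of season codes, `NA` where masked), `zones` (integer
#'   matrix), and `grid`.
#' @export
classify_raster <- function(stack, params = default_params(), seed = 1L,
                            restarts = 50L) {
  g <- stack$grid
  seasons <- array(NA_integer_, c(g$height, g$width, 12))
  zones <- matrix(NA_integer_, g$height, g$width)
  for (row in seq_len(g$height)) {
    for (col in seq_len(g$width)) {
      if (!stack$mask[row, col]) next
      cal <- classify_pixel(extract_pixel(stack, col, row), params,
                            seed = seed, restarts = restarts)
      seasons[row, col, ] <- cal$labels
      zones[row, col] <- cal$zone
    }
  }
  structure(list(seasons = seasons, zones = zones, grid = g),
            class = "season_raster")
}

#' @export
print.season_raster <- function(x, ...) {
  g <- x$grid
  cat("<season_raster>", g$width, "x", g$height, "cells,",
      sum(!is.na(x$zones)), "valid;", "crs:", g$crs, "\n")
  cat("zones:", paste(names(table(zone_name(x$zones))), collapse = ", "), "\n")
  invisible(x)
}
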
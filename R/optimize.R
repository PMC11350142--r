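#' Bounded search space of the nine free parameters
#'
#' The calibration tunes exactly nine bounded real numbers: the
#' temperature-difference threshold (3--14 deg C), the
#' precipitation-difference threshold (80--130 mm), the four temperate
#' cluster weights and the three tropical cluster weights (each 0.25--4).
#' The three remaining thresholds (arctic 10 deg C ceiling, tropical
#' 18 deg C floor, desert aridity 0.2) are fixed and do not participate.
#'
#' @return an object of class `param_space`: a data.frame with columns
#'   `name`, `lower`, `upper`.
#' @export
param_space <- function() {
  structure(data.frame(
    name = c("temp_diff_thresh", "precip_diff_thresh",
             "w_temperate.temperature", "w_temperate.precip_lag",
             "w_temperate.temp_lag", "w_temperate.ndvi_lag",
             "w_tropical.temperature", "w_tropical.precip_lag",
             "w_tropical.ndvi_lag"),
    lower = c(3, 80, rep(0.25, 7)),
    upper = c(14, 130, rep(4, 7)),
    stringsAsFactors = FALSE
  ), class = c("param_space", "data.frame"))
}

#' Classifier parameter bundle
#'
#' Combines the zonation thresholds and the cluster-weight set. The
#' default is the calibrated optimum shipped with the package.
#'
#' @param thresholds a [zone_thresholds()].
#' @param weights a [weight_set()].
#' @return an object of class `ws_params`.
#' @export
ws_params <- function(thresholds = zone_thresholds(),
                      weights = weight_set()) {
  structure(list(thresholds = thresholds, weights = weights),
            class = "ws_params")
}

#' @rdname ws_params
#' @export
default_params <- function() ws_params()

#' @export
print.ws_params <- function(x, ...) {
  cat("<ws_params>\n")
  print(round(coef(x), 4))
  cat("fixed: tropical_min_temp =", x$thresholds$tropical_min_temp,
      "degC; arctic_tmin_ceiling =", x$thresholds$arctic_tmin_ceiling,
      "degC; desert_ai_thresh =", x$thresholds$desert_ai_thresh, "\n")
  invisible(x)
}

#' @export
coef.ws_params <- function(object, ...) {
  c(temp_diff_thresh = object$thresholds$temp_diff_thresh,
    precip_diff_thresh = object$thresholds$precip_diff_thresh,
    setNames(object$weights$temperate,
             paste0("w_temperate.", names(object$weights$temperate))),
    setNames(object$weights$tropical,
             paste0("w_tropical.", names(object$weights$tropical))))
}

# rebuild a ws_params from a 9-vector in param_space order
params_from_vector <- function(v) {
  ws_params(
    thresholds = zone_thresholds(precip_diff_thresh = v[[2]],
                                 temp_diff_thresh = v[[1]]),
    weights = weight_set(
      temperate = c(temperature = v[[3]], precip_lag = v[[4]],
                    temp_lag = v[[5]], ndvi_lag = v[[6]]),
      tropical = c(temperature = v[[7]], precip_lag = v[[8]],
                   ndvi_lag = v[[9]])))
}

#' Sample a parameter bundle uniformly within bounds
#'
#' @param space a [param_space()].
#' @param seed integer seed (deterministic per seed).
#' @return a [ws_params()].
#' @export
sample_params <- function(space = param_space(), seed = 1L) {
  v <- withr_seed(seed, runif(nrow(space), space$lower, space$upper))
  params_from_vector(v)
}

#' Mean reference error of a parameter bundle
#'
#' Classifies the pixel of every reference record under the given
#' parameters and scores against the records with the capped per-city
#' error. Records without pixel data are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param p a [ws_params()].
#' @param records data.frame of reference records (canonical labels).
#' @param pixel_lookup named list mapping `records$city` to
#'   [pixel_climate()] objects.
#' @param seed,restarts per-pixel clustering controls.
#' @return mean error in months (see [mean_error()]).
#' @export
evaluate_params <- function(p, records, pixel_lookup, seed = 1L,
                            restarts = 50L) {
  if (!nrow(records)) stop("empty reference set")
  have <- records$city %in% names(pixel_lookup)
  n_excluded <- sum(!have)
  records <- records[have, , drop = FALSE]
  if (!nrow(records)) stop("no reference record has pixel data")
  preds <- lapply(records$city, function(ct)
    classify_pixel(pixel_lookup[[ct]], p, seed = seed, restarts = restarts))
  out <- mean_error(preds, records)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Budgeted search over the nine-parameter space
#'
#' Iterated random search over the bounded parameter space:
#' a uniform-exploration phase followed by Gaussian
#' perturbation around the running incumbents (truncated to the bounds),
#' every candidate evaluated on the full training set. Deterministic for a
#' given seed. Returns the `n_elites` configurations with the lowest
#' training error for held-out elite selection.
#'
#' @param space a [param_space()].
#' @param train_records training reference records.
#' @param pixel_lookup named list of [pixel_climate()] per city.
#' @param budget total number of configurations evaluated.
#' @param seed integer seed.
#' @param n_elites number of elite configurations retained (default 5).
#' @param explore_frac fraction of the budget spent on uniform exploration
#'   (default 0.5).
#' @param perturb_sd_frac Gaussian perturbation scale as a fraction of each
#'   parameter's range (default 0.1).
#' @return an object of class `ws_elites`: list of
#'   `list(params, train_error)` sorted by non-decreasing training error,
#'   with attribute `trace` (best-so-far error per evaluation).
#' @export
tune_params <- function(space = param_space(), train_records, pixel_lookup,
                        budget = 500L, seed = 1L, n_elites = 5L,
                        explore_frac = 0.5, perturb_sd_frac = 0.1) {
  if (!nrow(train_records)) stop("empty training set")
  if (budget < n_elites) stop("budget must be at least n_elites")
  lo <- space$lower; hi <- space$upper; rng_w <- hi - lo
  n_explore <- max(n_elites, ceiling(budget * explore_frac))
  vecs <- matrix(NA_real_, budget, nrow(space))
  errs <- rep(NA_real_, budget)
  trace <- rep(NA_real_, budget)
  withr_seed(seed, {
    for (i in seq_len(budget)) {
      if (i <= n_explore) {
        v <- runif(nrow(space), lo, hi)
      } else {
        ranked <- order(errs[seq_len(i - 1)])
        base <- vecs[ranked[((i - n_explore - 1) %% n_elites) + 1], ]
        v <- pmin(pmax(base + rnorm(nrow(space), 0, perturb_sd_frac * rng_w),
                       lo), hi)
      }
      vecs[i, ] <- v
      errs[i] <- as.numeric(evaluate_params(params_from_vector(v),
                                            train_records, pixel_lookup))
      trace[i] <- min(errs[seq_len(i)])
    }
  })
  ranked <- order(errs)[seq_len(n_elites)]
  elites <- lapply(ranked, function(i)
    list(params = params_from_vector(vecs[i, ]), train_error = errs[i]))
  structure(elites, class = "ws_elites", trace = trace)
}

#' @export
print.ws_elites <- function(x, ...) {
  cat("<ws_elites>", length(x), "configurations; training errors:",
      paste(round(vapply(x, `[[`, 0, "train_error"), 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Select the final configuration on held-out records
#'
#' Evaluates each elite on the test records and returns the one with the
#' lowest held-out mean error; ties go to the lower training error.
#'
#' @param elites a `ws_elites` from [tune_params()].
#' @param test_records held-out reference records.
#' @param pixel_lookup named list of [pixel_climate()] per city.
#' @return the winning [ws_params()] with attributes `test_error` and
#'   `train_error`.
#' @export
select_final <- function(elites, test_records, pixel_lookup) {
  if (!length(elites)) stop("empty elite set")
  test_err <- vapply(elites, function(e)
    as.numeric(evaluate_params(e$params, test_records, pixel_lookup)), 0)
  train_err <- vapply(elites, `[[`, 0, "train_error")
  best <- order(test_err, train_err)[1]
  p <- elites[[best]]$params
  attr(p, "test_error") <- test_err[best]
  attr(p, "train_error") <- train_err[best]
  p
}

#' Serialize / restore a parameter bundle as a flat YAML file
#'
#' @param p a [ws_params()].
#' @param path YAML path.
#' @return `write_params`: `path` invisibly; `read_params`: a
#'   [ws_params()].
#' @export
write_params <- function(p, path) {
  vals <- as.list(coef(p))
  vals$tropical_min_temp <- p$thresholds$tropical_min_temp
  vals$arctic_tmin_ceiling <- p$thresholds$arctic_tmin_ceiling
  vals$desert_ai_thresh <- p$thresholds$desert_ai_thresh
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  v <- yaml::read_yaml(path)
  p <- params_from_vector(unlist(v[param_space()$name]))
  for (f in c("tropical_min_temp", "arctic_tmin_ceiling", "desert_ai_thresh"))
    if (!is.null(v[[f]])) p$thresholds[[f]] <- v[[f]]
  p
}
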
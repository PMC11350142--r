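# canonical reference vocabulary
CANONICAL_LABELS <- c("winter", "spring", "summer", "autumn", "dry", "wet")
TEMPERATE_VOCAB <- c("winter", "spring", "summer", "autumn")
TROPICAL_VOCAB <- c("dry", "wet")

#' Recode table for heterogeneous tropical season names
#'
#' Local names for tropical seasons are highly heterogeneous (Harmattan,
#' Rainy Season, Hot and Humid, ...). This table maps each raw label,
#' case-insensitively, onto the simplified two-season vocabulary
#' dry / wet; the four temperate names pass through unchanged (lowercased).
#'
#' @return named character vector: `names()` are lowercase raw labels,
#'   values are `"dry"` or `"wet"`.
#' @export
default_recode_table <- function() {
  c("dry season" = "dry",
    "hot and dry" = "dry",
    "harmattan" = "dry",
    "warm and dry" = "dry",
    "hot" = "dry",
    "sunny and dry" = "dry",
    "cool and dry" = "dry",
    "rainy" = "wet",
    "wet season" = "wet",
    "rainy season" = "wet",
    "wet-season" = "wet",
    "warm and humid" = "wet",
    "hot and wet" = "wet",
    "hot and humid" = "wet",
    "short rainy season" = "wet",
    "rain" = "wet",
    "humid" = "wet",
    "warm and wet" = "wet",
    "long rainy season" = "wet")
}

#' Canonicalize a raw season label
#'
#' @param raw character label(s) as produced upstream.
#' @param table recode mapping, lowercase raw -> canonical.
#' @return canonical lowercase label(s); unmapped labels outside the
#'   canonical vocabulary raise an error naming the label.
#' @export
recode_label <- function(raw, table = default_recode_table()) {
  key <- tolower(trimws(raw))
  out <- ifelse(key %in% CANONICAL_LABELS, key, unname(table[key]))
  bad <- unique(raw[is.na(out)])
  if (length(bad))
    stop("unmapped season label(s): ", paste(bad, collapse = ", "))
  out
}

#' Infer whether a reference calendar is temperate-like or tropical-like
#'
#' @param labels 12 canonical labels.
#' @return `"temperate-like"` if the labels are drawn from
#'   winter/spring/summer/autumn, `"tropical-like"` if from dry/wet;
#'   mixed vocabularies are an error.
#' @export
infer_reference_zone <- function(labels) {
  u <- unique(labels)
  if (all(u %in% TROPICAL_VOCAB)) return("tropical-like")
  if (all(u %in% TEMPERATE_VOCAB)) return("temperate-like")
  stop("mixed season vocabularies in reference calendar: ",
       paste(u, collapse = ", "))
}

#' Per-city error of a predicted calendar against a reference record
#'
#' One error point per month whose predicted season differs from the
#' reference season; when the prediction and the reference disagree about
#' whether the city is temperate or tropical (in either direction), the
#' error is capped at 6 months. Desert predictions (cooler/hotter) use a
#' vocabulary absent from the reference data, so all 12 months mismatch
#' and no cap applies; arctic predictions (winter/summer) compare month by
#' month against temperate references.
#'
#' @param pred a `season_calendar` (see [classify_pixel()]).
#' @param ref a list or one-row data.frame with a `labels` field (or
#'   columns jan..dec) of 12 canonical labels.
#' @return integer error in months, 0..12 (0..6 under the cap).
#' @export
city_error <- function(pred, ref) {
  ref_labels <- reference_labels(ref)
  raw <- sum(pred$names != ref_labels)
  ref_zone <- infer_reference_zone(ref_labels)
  confusion <-
    (ref_zone == "temperate-like" && pred$zone == ZONES[["tropical"]]) ||
    (ref_zone == "tropical-like" && pred$zone == ZONES[["temperate"]])
  if (confusion) min(raw, 6L) else raw
}

# pull 12 canonical labels out of a record (list, vector or data.frame row)
reference_labels <- function(ref) {
  if (!is.null(ref$labels)) return(as.character(unlist(ref$labels)))
  if (all(MONTH_KEYS %in% names(ref)))
    return(as.character(unlist(ref[MONTH_KEYS])))
  if (is.character(ref) && length(ref) == 12) return(ref)
  stop("cannot extract 12 month labels from reference record")
}

#' Mean error over paired predictions and reference records
#'
#' @param preds list of `season_calendar`s.
#' @param refs list (or data.frame rows) of reference records, paired by
#'   position.
#' @return mean city error in months, with attribute `histogram`: a named
#'   count of cities at each error score 0..12.
#' @export
mean_error <- function(preds, refs) {
  if (is.data.frame(refs)) refs <- split(refs, seq_len(nrow(refs)))
  if (length(preds) != length(refs))
    stop("preds and refs have different lengths")
  errs <- mapply(city_error, preds, refs)
  hist <- table(factor(errs, levels = 0:12))
  structure(mean(errs), histogram = hist, errors = as.integer(errs))
}

#' Random 70/30-style train/test split
#'
#' Partitions records into a training and a held-out test set without
#' replacement; the training size is `round(train_frac * n)` (nearest
#' integer), deterministic for a given seed.
#'
#' @param records data.frame of reference records.
#' @param train_frac training fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return list with data.frames `train` and `test` (disjoint, exhaustive).
#' @export
train_test_split <- function(records, train_frac = 0.7, seed = 1L) {
  n <- nrow(records)
  if (is.null(n)) n <- length(records)
  if (n < 2) stop("need at least 2 records to split")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)")
  n_train <- round(train_frac * n)
  idx <- withr_seed(seed, sample.int(n, n_train))
  if (is.data.frame(records))
    list(train = records[idx, , drop = FALSE],
         test = records[-idx, , drop = FALSE])
  else
    list(train = records[idx], test = records[-idx])
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a reference-calendar CSV
#'
#' Expected columns: `city`, `country`, `lon`, `lat`, and `jan`..`dec`
#' holding raw or canonical season labels; raw labels are canonicalized
#' through the recode table.
#'
#' @param path CSV path.
#' @param table recode mapping (see [default_recode_table()]).
#' @return data.frame with canonical month labels.
#' @export
read_reference_csv <- function(path, table = default_recode_table()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("city", "country", "lon", "lat", MONTH_KEYS)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("reference CSV missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (m in MONTH_KEYS) df[[m]] <- recode_label(df[[m]], table)
  df
}
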
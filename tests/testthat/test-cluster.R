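test_that("feature matrices select zone variables, normalize, and scale by sqrt(weight)", {
  mp <- make_pixel(archetype_spec("arctic", noise_sd = 0))
  X <- build_feature_matrix(mp$pixel, ZONES[["arctic_montane"]])
  expect_equal(dim(X), c(12L, 2L))
  expect_equal(unname(colMeans(X)), c(0, 0))
  expect_equal(unname(apply(X, 2, sd)), c(1, 1))

  tp <- make_pixel(archetype_spec("temperate", noise_sd = 0))$pixel
  w1 <- weight_set(temperate = c(temperature = 1, precip_lag = 1,
                                 temp_lag = 1, ndvi_lag = 1))
  X1 <- build_feature_matrix(tp, ZONES[["temperate"]], w1)
  plain <- vapply(list(tp$tmid, tp$lag_precip, tp$lag_tmid, tp$lag_ndvi),
                  znormalize, numeric(12))
  expect_equal(unname(X1), unname(plain))

  w4 <- weight_set(temperate = c(temperature = 4, precip_lag = 1,
                                 temp_lag = 1, ndvi_lag = 1))
  X4 <- build_feature_matrix(tp, ZONES[["temperate"]], w4)
  expect_equal(sum(X4[, 1]^2) / sum(X1[, 1]^2), 4)
  expect_error(build_feature_matrix(tp, 9L), "unknown zone")
})

test_that("k-means separates well-separated month blobs and is deterministic", {
  X <- rbind(matrix(rnorm(12, 0, 0.05), 6, 2),
             matrix(rnorm(12, 5, 0.05), 6, 2))
  lab <- kmeans_months(X, 2, seed = 1)
  expect_equal(length(unique(lab[1:6])), 1)
  expect_equal(length(unique(lab[7:12])), 1)
  expect_false(lab[1] == lab[12])

  expect_equal(as.integer(kmeans_months(X, 2, seed = 7)),
               as.integer(kmeans_months(X, 2, seed = 7)))

  expect_equal(as.integer(kmeans_months(X, 1)), rep(1L, 12))

  const <- matrix(1, 12, 2)
  labc <- kmeans_months(const, 2)
  expect_true(attr(labc, "degenerate"))
})

test_that("restarted k-means matches stats::kmeans on its objective", {
  set.seed(21)
  for (i in 1:10) {
    X <- matrix(rnorm(24), 12, 2)
    ours <- kmeans_months(X, 2, seed = i, restarts = 50)
    ref <- stats::kmeans(X, centers = 2, nstart = 50)
    expect_lt(attr(ours, "sse"), ref$tot.withinss + 1e-8)
  }
})

test_that("the contiguous oracle equals exhaustive enumeration and ties lexicographically", {
  X <- rbind(matrix(0, 6, 2), matrix(1, 6, 2))
  orc <- contiguous_partition_oracle(X, 2)
  expect_equal(length(unique(orc[1:6])), 1)
  expect_equal(length(unique(orc[7:12])), 1)
  expect_false(orc[1] == orc[7])

  # constant matrix: every partition ties; lexicographically first cut-set
  # {1,2} gives arcs {1} and {2..12}
  const <- matrix(2, 12, 3)
  tie <- contiguous_partition_oracle(const, 2)
  expect_true(same_partition(as.integer(tie),
                             c(1L, rep(2L, 11))))

  set.seed(5)
  for (i in 1:25) {
    X <- matrix(rnorm(36), 12, 3)
    for (k in c(2, 4)) {
      orc <- contiguous_partition_oracle(X, k)
      ref <- r_best_contiguous(X, k)
      expect_equal(attr(orc, "sse"), ref$sse, tolerance = 1e-9)
      expect_true(same_partition(as.integer(orc), ref$labels))
    }
  }
})

test_that("contiguity enforcement projects by minimum Hamming disagreement", {
  X <- matrix(rnorm(24), 12, 2)
  contig <- c(rep(1L, 5), rep(2L, 7))
  expect_identical(enforce_contiguity(contig, X), contig)

  # single dissenting month: flipping it is the unique 1-flip repair
  lab <- c(1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 2L, 2L, 2L, 2L)
  fixed <- enforce_contiguity(lab, X)
  expect_equal(as.integer(fixed), c(rep(1L, 8), rep(2L, 4)))

  # objective-space projection returns the exact contiguous optimum
  set.seed(31)
  Xr <- matrix(rnorm(24), 12, 2)
  labr <- c(1L, 2L, 1L, 1L, 2L, 2L, 1L, 2L, 2L, 2L, 1L, 1L)
  sse_fix <- enforce_contiguity(labr, Xr, method = "sse")
  expect_true(same_partition(as.integer(sse_fix),
                             r_best_contiguous(Xr, 2)$labels))

  # label-space projection result is always contiguous and never beats the
  # direct minimum-Hamming distance computed by enumeration
  set.seed(9)
  for (i in 1:25) {
    X <- matrix(rnorm(24), 12, 2)
    lab <- sample(1:2, 12, replace = TRUE)
    if (length(unique(lab)) < 2) next
    fixed <- enforce_contiguity(lab, X)
    expect_true(worldseasons:::is_circularly_contiguous(as.integer(fixed)))
    hams <- vapply(r_contiguous_partitions(2), function(p)
      min(sum(p != lab), sum((3 - p) != lab)), 0)
    expect_equal(sum(fixed != lab), min(hams))
  }
})

test_that("season naming follows cluster means and circular order", {
  # northern temperate: DJF/MAM/JJA/SON arcs by construction
  tp <- make_pixel(archetype_spec("temperate", noise_sd = 0))$pixel
  arcs <- c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 1L)
  cal <- name_seasons(arcs, tp, ZONES[["temperate"]])
  expect_equal(cal$names, c("winter", "winter", "spring", "spring", "spring",
                            "summer", "summer", "summer", "autumn", "autumn",
                            "autumn", "winter"))

  # southern mirror: same arcs on a phase-shifted pixel swap the labels
  sp <- make_pixel(archetype_spec("temperate", hemisphere = "S",
                                  noise_sd = 0))$pixel
  arcs_s <- c(3L, 3L, 4L, 4L, 4L, 1L, 1L, 1L, 2L, 2L, 2L, 3L)
  cal_s <- name_seasons(arcs_s, sp, ZONES[["temperate"]])
  expect_equal(cal_s$names[6:8], rep("winter", 3))
  expect_equal(cal_s$names[1:2], rep("summer", 3)[1:2])
  expect_equal(cal_s$names[9:11], rep("spring", 3))

  # tropical naming keys on mean rainfall
  trp <- make_pixel(archetype_spec("tropical_unimodal", noise_sd = 0))$pixel
  lab2 <- ifelse(trp$precip > mean(trp$precip), 1L, 2L)
  cal_t <- name_seasons(lab2, trp, ZONES[["tropical"]])
  expect_equal(unique(cal_t$names[trp$precip > mean(trp$precip)]), "wet")

  # naming is invariant to permuting raw cluster indices
  cal_perm <- name_seasons(c(2L, 2L, 4L, 4L, 4L, 1L, 1L, 1L, 3L, 3L, 3L, 2L),
                           tp, ZONES[["temperate"]])
  expect_equal(cal_perm$names, cal$names)
})

test_that("classify_pixel yields zone-consistent, contiguous, seeded calendars", {
  mp <- make_pixel(archetype_spec("temperate", noise_sd = 0))
  cal <- classify_pixel(mp$pixel)
  expect_equal(cal$zone, ZONES[["temperate"]])
  expect_setequal(unique(cal$names),
                  c("winter", "spring", "summer", "autumn"))
  expect_equal(cal$names[which.min(mp$pixel$tmid)], "winter")
  expect_true(worldseasons:::is_circularly_contiguous(cal$labels))

  bi <- classify_pixel(make_pixel(archetype_spec("tropical_bimodal",
                                                 noise_sd = 0))$pixel)
  runs <- sum(bi$labels != bi$labels[c(12, 1:11)] &
                bi$labels == SEASONS[["wet"]])
  expect_gte(runs, 2)  # two wet seasons are allowed in the tropics

  ar <- classify_pixel(make_pixel(archetype_spec("arctic", noise_sd = 0))$pixel)
  expect_setequal(unique(ar$names), c("winter", "summer"))
  expect_true(worldseasons:::is_circularly_contiguous(ar$labels))

  # affine rescaling of a clustered variable does not change the calendar
  px <- make_pixel(archetype_spec("arctic", noise_sd = 1, seed = 3))$pixel
  px2 <- px
  px2$srad <- 2.5 * px$srad + 40
  expect_equal(classify_pixel(px2)$labels, classify_pixel(px)$labels)

  # near-constant climate: the oracle fallback still yields 4 arcs
  flat <- flat_pixel(tmid = 15 + 0.01 * cos(2 * pi * (1:12 - 7) / 12),
                     precip = rep(60, 12), pet = rep(60, 12))
  calf <- classify_pixel(flat)
  expect_equal(length(unique(calf$labels)), 4)
  expect_true(worldseasons:::is_circularly_contiguous(calf$labels))
})

test_that("classify_raster equals cell-wise classify_pixel and is seed-stable", {
  af <- matrix(c("temperate", "tropical_unimodal", "desert_hot", "arctic"),
               2, 2)
  mr <- make_raster(2, 2, af, seed = 5, noise_sd = 1)
  sr <- classify_raster(mr$stack, seed = 2)
  for (row in 1:2) for (col in 1:2) {
    cal <- classify_pixel(extract_pixel(mr$stack, col, row), seed = 2)
    expect_equal(unname(sr$seasons[row, col, ]), cal$labels)
    expect_equal(sr$zones[row, col], cal$zone)
    expect_true(all(sr$seasons[row, col, ] %in% zone_season_set(cal$zone)))
  }
  sr2 <- classify_raster(mr$stack, seed = 2)
  expect_identical(sr$seasons, sr2$seasons)
})
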
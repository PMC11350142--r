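test_that("the recode table maps every raw tropical label to dry or wet", {
  expected <- c(
    "Dry Season" = "dry", "Hot and Dry" = "dry", "Harmattan" = "dry",
    "Warm and Dry" = "dry", "Hot" = "dry", "Sunny and Dry" = "dry",
    "Cool and Dry" = "dry",
    "Rainy" = "wet", "Wet Season" = "wet", "Rainy Season" = "wet",
    "Wet-Season" = "wet", "Warm and Humid" = "wet", "Hot and Wet" = "wet",
    "Hot and Humid" = "wet", "Short Rainy Season" = "wet", "Rain" = "wet",
    "Humid" = "wet", "Warm and Wet" = "wet", "Long Rainy Season" = "wet")
  expect_length(default_recode_table(), 19)
  for (raw in names(expected))
    expect_equal(recode_label(raw), unname(expected[raw]), label = raw)
  # temperate names pass through lowercased; unknown labels error
  expect_equal(recode_label("Winter"), "winter")
  expect_equal(recode_label("AUTUMN"), "autumn")
  expect_error(recode_label("Typhoon Season"), "Typhoon Season")
})

test_that("reference zone inference rejects mixed vocabularies", {
  expect_equal(infer_reference_zone(rep(c("dry", "wet"), 6)), "tropical-like")
  expect_equal(infer_reference_zone(rep(c("winter", "spring", "summer",
                                          "autumn"), 3)), "temperate-like")
  expect_error(infer_reference_zone(c(rep("wet", 11), "summer")), "mixed")
})

test_that("city error counts mismatched months and caps zone confusion at 6", {
  temperate_ref <- c(rep("winter", 2), rep("spring", 3), rep("summer", 3),
                     rep("autumn", 3), "winter")
  pred_same <- structure(list(zone = ZONES[["temperate"]],
                              labels = unname(SEASONS[temperate_ref]),
                              names = temperate_ref),
                         class = "season_calendar")
  expect_equal(city_error(pred_same, make_record(temperate_ref)), 0)

  pred_one <- pred_same
  pred_one$names[6] <- "spring"
  expect_equal(city_error(pred_one, make_record(temperate_ref)), 1)

  # temperate reference scored against an all-mismatching tropical
  # prediction: raw error 12, capped at 6
  pred_trop <- structure(list(zone = ZONES[["tropical"]],
                              labels = rep(SEASONS[c("wet", "dry")], 6),
                              names = rep(c("wet", "dry"), 6)),
                         class = "season_calendar")
  expect_equal(city_error(pred_trop, make_record(temperate_ref)), 6)

  # the cap is symmetric: tropical reference, temperate prediction
  tropical_ref <- c(rep("dry", 5), rep("wet", 6), "dry")
  expect_equal(city_error(pred_same, make_record(tropical_ref)), 6)

  # desert prediction against a tropical reference: different vocabulary,
  # all 12 months mismatch, but the cap concerns only temperate/tropical
  pred_des <- structure(list(zone = ZONES[["desert"]],
                             labels = rep(SEASONS[c("cooler", "hotter")], 6),
                             names = rep(c("cooler", "hotter"), 6)),
                        class = "season_calendar")
  expect_equal(city_error(pred_des, make_record(tropical_ref)), 12)
})

test_that("mean error averages cities, reports a histogram, ignores order", {
  temperate_ref <- c(rep("winter", 3), rep("spring", 3), rep("summer", 3),
                     rep("autumn", 3))
  pred_exact <- structure(list(zone = ZONES[["temperate"]],
                               labels = unname(SEASONS[temperate_ref]),
                               names = temperate_ref),
                          class = "season_calendar")
  pred_trop <- structure(list(zone = ZONES[["tropical"]],
                              labels = rep(SEASONS[c("wet", "dry")], 6),
                              names = rep(c("wet", "dry"), 6)),
                         class = "season_calendar")
  refs <- rbind(make_record(temperate_ref, city = "a"),
                make_record(temperate_ref, city = "b"))
  me <- mean_error(list(pred_exact, pred_trop), refs)
  expect_equal(as.numeric(me), 3)
  h <- attr(me, "histogram")
  expect_equal(sum(h), 2)
  expect_equal(as.integer(h[c("0", "6")]), c(1L, 1L))
  me_rev <- mean_error(list(pred_trop, pred_exact), refs[2:1, ])
  expect_equal(as.numeric(me_rev), as.numeric(me))
})

test_that("the train/test split rounds to nearest and partitions exactly", {
  recs <- data.frame(city = paste0("c", 1:818), x = rnorm(818))
  sp <- train_test_split(recs, 0.7, seed = 2)
  expect_equal(nrow(sp$train), 573)
  expect_equal(nrow(sp$test), 245)

  sp10 <- train_test_split(recs[1:10, ], 0.7, seed = 2)
  expect_equal(c(nrow(sp10$train), nrow(sp10$test)), c(7, 3))

  expect_setequal(c(sp$train$city, sp$test$city), recs$city)
  expect_length(intersect(sp$train$city, sp$test$city), 0)
  sp_again <- train_test_split(recs, 0.7, seed = 2)
  expect_identical(sp$train$city, sp_again$train$city)
})

test_that("reference CSVs read, recode and validate their columns", {
  f <- tempfile(fileext = ".csv")
  df <- rbind(make_record(c(rep("Dry Season", 4), rep("Rainy Season", 6),
                            rep("Harmattan", 2)), city = "Kano",
                          country = "Nigeria", lon = 8.5, lat = 12),
              make_record(c(rep("Winter", 2), rep("Spring", 3),
                            rep("Summer", 3), rep("Autumn", 3), "Winter"),
                          city = "Graz", country = "Austria",
                          lon = 15.4, lat = 47))
  write.csv(df, f, row.names = FALSE)
  rd <- read_reference_csv(f)
  expect_equal(unname(unlist(rd[1, tolower(month.abb)])),
               c(rep("dry", 4), rep("wet", 6), rep("dry", 2)))
  expect_equal(rd$city, c("Kano", "Graz"))

  df_bad <- df[, setdiff(names(df), "lat")]
  f2 <- tempfile(fileext = ".csv")
  write.csv(df_bad, f2, row.names = FALSE)
  expect_error(read_reference_csv(f2), "lat")
})
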
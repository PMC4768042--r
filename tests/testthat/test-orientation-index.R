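test_that("annualization sums months and enforces completeness", {
  v <- monthly_from_annual(past = c(AA = 0), future = c(AA = 0))
  v$count[v$role == "past"] <- 5
  v$count[v$role == "future"] <- 1:12
  annual <- annualize_volumes(v)
  expect_equal(annual$count[annual$role == "past"], 60)
  expect_equal(annual$count[annual$role == "future"], 78)
  expect_equal(annual$total_volume, rep(12, 2))

  v11 <- v[v$month != 7, ]
  expect_error(annualize_volumes(v11), "missing months")
  expect_warning(annual11 <- annualize_volumes(v11, strict = FALSE),
                 "missing months")
  expect_equal(annual11$count[annual11$role == "past"], 55)
})

test_that("counts-mode normalization rescales the slice maximum to 100", {
  v <- data.frame(region = c("A", "B", "C"), year = 2009L, role = "past",
                  count = c(10, 40, 20), total_volume = 1)
  expect_equal(trends_normalize(v, mode = "counts")$index_value,
               c(25, 100, 50))
  single <- trends_normalize(v[1, ], mode = "counts")
  expect_equal(single$index_value, 100)
  v$count <- c(0, 0, 0)
  expect_error(trends_normalize(v, mode = "counts"), "all counts zero")
  v$count <- c(-1, 2, 3)
  expect_error(trends_normalize(v, mode = "counts"), "negative")
})

test_that("share-mode indices are invariant to a region's overall volume", {
  # Oracle: brute-force recomputation from shares.
  set.seed(42)
  for (rep in 1:5) {
    v <- random_annual_volumes(6)
    base <- trends_normalize(v, mode = "share")
    v2 <- v
    pick <- v2$region == "R03"
    v2$count[pick] <- v2$count[pick] * 2
    v2$total_volume[pick] <- v2$total_volume[pick] * 2
    expect_equal(trends_normalize(v2, mode = "share")$index_value,
                 base$index_value)
    share <- v$count / v$total_volume
    slice <- interaction(v$year, v$role)
    expect_equal(base$index_value,
                 100 * share / ave(share, slice, FUN = max))
  }
})

test_that("orientation ratios behave as documented on hand values", {
  expect_equal(past_orientation(73.2, 73.2), 1)
  expect_equal(past_orientation(50, 40), 1.25)
  expect_equal(future_orientation(73.2, 73.2), 1)
  expect_equal(future_orientation(50, 40), 0.8)
  expect_equal(past_orientation(50, 40, scale = 100), 125)
  expect_error(past_orientation(50, 0), "zero")
  expect_error(future_orientation(0, 40), "zero")
})

test_that("a hand-traced two-region table yields orientations 0.5 and 1.0", {
  v <- monthly_from_annual(past = c(R1 = 30, R2 = 60),
                           future = c(R1 = 40, R2 = 40))
  tab <- orientation_table(v, mode = "counts")
  expect_equal(tab$past_index, c(50, 100))
  expect_equal(tab$future_index, c(100, 100))
  expect_equal(tab$past_orientation, c(0.5, 1.0))
  expect_equal(tab$future_orientation, c(2.0, 1.0))
})

test_that("index values stay in [0, 100] with the slice maximum attained", {
  set.seed(7)
  for (rep in 1:10) {
    v <- random_annual_volumes(8, years = 2009:2011)
    for (mode in c("counts", "share")) {
      cells <- trends_normalize(v, mode = mode)
      expect_true(all(cells$index_value >= 0 & cells$index_value <= 100))
      slice_max <- tapply(cells$index_value,
                          interaction(cells$year, cells$role), max)
      expect_equal(as.numeric(slice_max), rep(100, length(slice_max)))
    }
  }
})

test_that("past and future orientation multiply to the squared scale", {
  st <- simulate_study(generator_config(seed = 5))
  expect_lt(max(abs(st$orientation$past_orientation *
                      st$orientation$future_orientation - 1)), 1e-12)
  tab <- orientation_table(st$volumes, mode = "counts", scale = 100)
  expect_lt(max(abs(tab$past_orientation * tab$future_orientation - 100^2)),
            1e-6)
})

test_that("within-year orientation ranking equals the raw-ratio ranking", {
  set.seed(99)
  for (rep in 1:10) {
    v <- random_annual_volumes(10)
    tab <- merge(v[v$role == "past", c("region", "count")],
                 v[v$role == "future", c("region", "count")],
                 by = "region", suffixes = c("_past", "_future"))
    raw_ratio <- tab$count_past / tab$count_future
    cells <- trends_normalize(v, mode = "counts")
    po <- past_orientation(
      cells$index_value[cells$role == "past"][match(tab$region,
        cells$region[cells$role == "past"])],
      cells$index_value[cells$role == "future"][match(tab$region,
        cells$region[cells$role == "future"])])
    # the per-slice normalizing constants cancel: po is raw_ratio times a
    # common constant, so the ranking (ties included) is identical
    expect_equal(po / raw_ratio, rep(po[1] / raw_ratio[1], length(po)),
                 tolerance = 1e-12)
    # and the statistic is invariant to rescaling a whole slice
    v2 <- v
    v2$count[v2$role == "past"] <- v2$count[v2$role == "past"] * 17
    cells2 <- trends_normalize(v2, mode = "counts")
    expect_equal(cells2$index_value, cells$index_value)
  }
})

test_that("monthly profile averages cells per month and role", {
  cells <- expand.grid(region = c("A", "B"), year = 2009:2010, month = 1:12,
                       role = c("past", "future"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$index_value <- 40
  prof <- monthly_profile(cells)
  expect_equal(nrow(prof), 24L)
  expect_equal(prof$mean_index, rep(40, 24))
  one <- monthly_profile(cells[cells$month == 3, ])
  expect_equal(unique(one$month), 3L)
  expect_error(monthly_profile(cells[0, ]), "empty")
  expect_error(monthly_profile(cells[, setdiff(names(cells), "month")]),
               "month")
})

test_that("seeded synthetic monthly profiles show the seasonal pattern", {
  # Deterministic generator: profile must match the configured mean trends.
  cfg <- generator_config(seed = 1, deterministic = TRUE)
  cells <- trends_normalize(generate_query_volumes(cfg), mode = "share")
  prof <- monthly_profile(cells)
  past <- prof$mean_index[prof$role == "past"]
  future <- prof$mean_index[prof$role == "future"]
  expect_true(all(diff(past) < 0))
  expect_true(all(diff(future) > 0))
  expect_equal(unname(which.max(future)), 12L)
})
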
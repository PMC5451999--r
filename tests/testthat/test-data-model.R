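test_that("daily_average applies the 75% coverage rule", {
  # full day
  expect_equal(daily_average(1:24), 12.5)
  # 17/24 ~ 70.8% present: below the standard
  v <- c(rep(NA, 7), 1:17)
  expect_true(is.na(daily_average(v)))
  # exactly 18/24 = 75%: boundary passes, mean of the present values
  v18 <- c(rep(NA, 6), seq(2, 36, by = 2))
  expect_equal(daily_average(v18), mean(seq(2, 36, by = 2)))
  # permutation invariance
  set.seed(3)
  v <- c(runif(20, 5, 50), rep(NA, 4))
  expect_equal(daily_average(v), daily_average(sample(v)))
  # edge cases
  expect_true(is.na(daily_average(numeric(0))))
  expect_error(daily_average(c(1, -2, 3)), "negative")
  expect_error(daily_average(1:25), "24")
  expect_error(daily_average(1:24, coverage = 0), "coverage")
})

test_that("log and back transforms are exact inverses and validate inputs", {
  p <- toy_panel(4, 6, seed = 2)
  lp <- log_transform(p)
  expect_true(lp$log_scale)
  rt <- back_transform(lp)
  expect_equal(rt$values, p$values, tolerance = 1e-12)
  # scalar behaviour
  expect_equal(back_transform(0), 1)
  expect_equal(log(148), 4.997, tolerance = 1e-3)  # ~5 on the log scale
  # errors name the offending entry
  bad <- p
  bad$values[2, 3] <- -1
  expect_error(log_transform(bad), "A02")
  expect_error(log_transform(lp), "already")
  expect_error(back_transform(p), "not on the log scale")
})

test_that("panel CSV I/O round-trips with deterministic ordering", {
  p <- toy_panel(3, 5, seed = 4, missing = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- read_panel(f)
  expect_equal(p2$stations$id, p$stations$id)
  expect_equal(p2$days, p$days)
  expect_equal(p2$values, p$values, tolerance = 1e-9)
  # writing again from the re-read panel is byte-stable
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(p2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("panel reader rejects malformed input with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station_id,lon,lat,date,value",
               "A,116.1,36.2,1,50", "A,116.1,36.2,2,60",
               "B,116.4,36.5,1,70", "B,116.4,36.5,2,80",
               "A,116.1,36.2,1,55"), f)
  expect_error(read_panel(f), "duplicate")
  writeLines(c("station_id,lon,lat,date,value",
               "A,116.1,36.2,2014-01-01,50",
               "A,116.1,36.2,not-a-date,60"), f)
  expect_error(read_panel(f), "row 2")
  writeLines(c("station_id,lon,value", "A,116.1,50"), f)
  expect_error(read_panel(f), "lat")
})

test_that("panel construction enforces its invariants", {
  st <- data.frame(id = c("A", "B"), lon = c(116, 117), lat = c(36, 37))
  expect_error(pm_panel(st, 1:3, matrix(1, 2, 2)), "2 x 3")
  expect_error(pm_panel(rbind(st, st[1, ]), 1:2, matrix(1, 3, 2)), "duplicate")
  expect_error(pm_panel(st, c(2, 1), matrix(1, 2, 2)), "increasing")
  expect_error(pm_panel(st, 1:2, matrix(c(1, -1, 1, 1), 2, 2)), "nonpositive")
  p <- pm_panel(st, 1:2, matrix(c(1, NA, 2, 4), 2, 2))
  expect_equal(missing_fraction(p), 0.25)
})

test_that("planar projection is deterministic, centred and invertible", {
  lon <- c(115.2, 117.8, 119.1)
  lat <- c(34.9, 36.5, 38.0)
  pr <- project_lonlat(lon, lat)
  origin <- attr(pr, "origin")
  expect_equal(origin, c(mean(range(lon)), mean(range(lat))))
  back <- unproject_xy(pr$x, pr$y, origin)
  expect_equal(back$lon, lon, tolerance = 1e-10)
  expect_equal(back$lat, lat, tolerance = 1e-10)
  # ~1 degree latitude is ~111 km
  pr2 <- project_lonlat(c(117, 117), c(36, 37), origin = c(117, 36.5))
  expect_equal(diff(pr2$y) / 1000, 111.2, tolerance = 0.01)
})

test_that("panel_to_long joins covariates, basis and PM10 by key", {
  p <- toy_panel(3, 4, seed = 5)
  pm10 <- p
  pm10$values <- p$values / 0.57
  pm10$pollutant <- "PM10"
  covs <- covariate_table(
    spatial = data.frame(station_id = p$stations$id, road = c(1, 2, 3)),
    spatiotemporal = data.frame(station_id = rep(p$stations$id, 4),
                                day = rep(1:4, each = 3),
                                temp = seq_len(12)))
  basis <- structure(list(days = 1:4, f1 = c(0.1, 0.2, 0.3, 0.4),
                          f2 = c(0, 0, 0, 0)), class = "pm_temporal_basis")
  long <- panel_to_long(p, covs, basis, pm10)
  expect_equal(nrow(long), 12)
  expect_equal(long$log_pm10, long$log_pm25 - log(0.57), tolerance = 1e-12)
  i <- which(long$station_id == "A02" & long$day == 3)
  expect_equal(long$road[i], 2)
  expect_equal(long$temp[i], 8)
  expect_equal(long$f1[i], 0.3)
})

test_that("prediction writer requires the full column contract", {
  res <- data.frame(x = 1, y = 2, day = 3, mean_log = 4, sd_log = 0.1,
                    residual_log = 0, concentration = exp(4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_predictions(res, f)
  expect_equal(read.csv(f)$concentration, exp(4))
  expect_error(write_predictions(res[, -5], f), "sd_log")
})
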
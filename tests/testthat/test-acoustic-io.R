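test_that("daily records combine effort and detections correctly", {
  p <- write_toy_season()
  rec <- load_daily_records(p$detections, p$effort)
  expect_s3_class(rec, "daily_records")
  expect_equal(nrow(rec), 5)          # one row per sampled site-day
  expect_true(all(rec$sampled))
  # site 2 on 2011-06-19 is in effort but has no detections row: zero clicks
  z <- rec[rec$site_id == "2" & rec$date == as.Date("2011-06-19"), ]
  expect_equal(z$clicks, 0)
  expect_equal(z$dpm, 0)
})

test_that("record validation catches malformed inputs", {
  p <- write_toy_season()
  grid <- site_grid(c(1, 2), c(0, 5), c(0, 0))
  expect_silent(load_daily_records(p$detections, p$effort, grid = grid))

  bad_grid <- site_grid("1", 0, 0)
  expect_error(load_daily_records(p$detections, p$effort, grid = bad_grid),
               "unknown site id")

  det <- read.csv(p$detections)
  det$clicks[1] <- -3
  write.csv(det, file.path(p$dir, "neg.csv"), row.names = FALSE)
  expect_error(load_daily_records(file.path(p$dir, "neg.csv"), p$effort),
               "negative click")

  eff <- read.csv(p$effort)
  write.csv(rbind(eff, eff[1, ]), file.path(p$dir, "dup.csv"),
            row.names = FALSE)
  expect_error(load_daily_records(p$detections, file.path(p$dir, "dup.csv")),
               "duplicate")

  # detections on a day with no effort are inconsistent, not silently kept
  det2 <- read.csv(p$detections)
  det2 <- rbind(det2, data.frame(site_id = 2, date = "2011-08-19",
                                 clicks = 5, dpm = 2))
  write.csv(det2, file.path(p$dir, "orphan.csv"), row.names = FALSE)
  expect_error(load_daily_records(file.path(p$dir, "orphan.csv"), p$effort),
               "no recorded effort")
})

test_that("column mapping adapts foreign headers, including via YAML", {
  dir <- withr::local_tempdir()
  p <- write_toy_season(dir)
  det <- read.csv(p$detections)
  names(det) <- c("Station", "Day", "NClicks", "DPM_total")
  write.csv(det, file.path(dir, "foreign.csv"), row.names = FALSE)
  map <- list(site_id = "Station", date = "Day",
              clicks = "NClicks", dpm = "DPM_total")
  eff <- read.csv(p$effort)
  names(eff) <- c("Station", "Day")
  write.csv(eff, file.path(dir, "eff_f.csv"), row.names = FALSE)

  rec <- load_daily_records(file.path(dir, "foreign.csv"),
                            file.path(dir, "eff_f.csv"), col_map = map)
  expect_equal(sum(rec$clicks), 13)

  ypath <- file.path(dir, "map.yaml")
  yaml::write_yaml(map, ypath)
  rec2 <- load_daily_records(file.path(dir, "foreign.csv"),
                             file.path(dir, "eff_f.csv"), col_map = ypath)
  expect_identical(rec, rec2)
})

test_that("annualize computes effort-window means and never imputes", {
  p <- write_toy_season()
  rec <- load_daily_records(p$detections, p$effort)
  grid <- site_grid(c(1, 2), c(0, 5), c(0, 0))
  ds <- annualize(rec, grid)
  s <- ds$summaries
  expect_equal(s$W[s$site_id == "1"], mean(c(2, 4, 6)))
  expect_equal(s$n[s$site_id == "1"], 3)
  expect_equal(s$W[s$site_id == "2"], mean(c(0, 1)))
  # no imputation: total effort equals the number of sampled in-window days
  expect_equal(sum(s$n), nrow(rec))

  # one site, clicks {2, 4} on two sampled days -> W = 3, n = 2
  g1 <- site_grid("a", 0, 0)
  r1 <- data.frame(site_id = "a",
                   date = as.Date(c("2012-07-01", "2012-07-02")),
                   clicks = c(2, 4), dpm = c(1, 2), sampled = TRUE)
  class(r1) <- c("daily_records", "data.frame")
  a1 <- annualize(r1, g1)
  expect_equal(a1$summaries$W, 3.0)
  expect_equal(a1$summaries$n, 2L)

  expect_error(annualize(r1[0, ], g1), "empty")
})

test_that("sampled days outside the Julian 170-231 window are excluded", {
  # Julian day 170 is 19 June and 231 is 19 August in a non-leap year
  expect_equal(julian_day(as.Date("2011-06-19")), 170L)
  expect_equal(julian_day(as.Date("2011-08-19")), 231L)

  g1 <- site_grid("a", 0, 0)
  r <- data.frame(site_id = "a",
                  date = as.Date(c("2011-06-18", "2011-06-19",
                                   "2011-08-19", "2011-08-20")),
                  clicks = c(100, 2, 4, 100), dpm = 1, sampled = TRUE)
  class(r) <- c("daily_records", "data.frame")
  a <- annualize(r, g1)
  expect_equal(a$summaries$W, 3.0)   # the 100-click days fall outside
  expect_equal(a$summaries$n, 2L)

  # a site-year with no in-window effort is missing, not zero
  r2 <- rbind(r, data.frame(site_id = "a", date = as.Date("2013-05-01"),
                            clicks = 7, dpm = 1, sampled = TRUE))
  class(r2) <- c("daily_records", "data.frame")
  a2 <- annualize(r2, g1)
  expect_false(2013 %in% a2$summaries$year)
})

test_that("raw change matches hand computation and is scale invariant", {
  g <- site_grid(c(1, 2), c(0, 5), c(0, 0))
  s <- data.frame(year = c(2011, 2011, 2012, 2012),
                  site_id = c(1, 2, 1, 2),
                  W = c(4, 6, 2, 3), n = c(10, 10, 10, 10))
  ds <- monitoring_dataset(g, s)
  rc <- raw_change(ds, 2011, 2012)
  expect_equal(rc$ratio, 2.5 / 5)
  expect_equal(rc$percent_decline, 50)

  same <- raw_change(ds, 2011, 2011)
  expect_equal(same$ratio, 1.0)

  for (c_mult in c(0.5, 3, 10)) {
    s2 <- s; s2$W <- s2$W * c_mult
    rc2 <- raw_change(monitoring_dataset(g, s2), 2011, 2012)
    expect_equal(rc2$ratio, rc$ratio)
  }

  s3 <- s; s3$W[s3$year == 2011] <- 0
  expect_warning(rc3 <- raw_change(monitoring_dataset(g, s3), 2011, 2012),
                 "undefined")
  expect_true(is.na(rc3$ratio))
})

test_that("effort series counts active loggers per day", {
  p <- write_toy_season()
  rec <- load_daily_records(p$detections, p$effort)
  es <- effort_series(rec)
  expect_equal(es$n_active[es$julian_day == julian_day(as.Date("2011-06-19"))], 2)
  expect_equal(es$n_active[es$julian_day == julian_day(as.Date("2011-08-19"))], 1)
  expect_equal(nrow(effort_series(rec[0, ])), 0)
})

test_that("datasets round-trip through CSV serialization", {
  sim <- small_sim(seed = 9)
  stem <- file.path(withr::local_tempdir(), "rt")
  write_dataset(sim$dataset, stem)
  back <- read_dataset(stem)
  expect_equal(back$summaries, sim$dataset$summaries)
  expect_equal(as.data.frame(back$grid), as.data.frame(sim$dataset$grid))
})

test_that("geographic coordinates project to sane planar distances", {
  # two points ~0.1 degree of latitude apart: about 11.1 km
  xy <- project_coordinates(c(-114.5, -114.5), c(30.9, 31.0))
  d <- sqrt(diff(xy$easting_km)^2 + diff(xy$northing_km)^2)
  expect_equal(d, 11.132, tolerance = 1e-3)
})
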
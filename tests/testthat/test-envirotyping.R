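test_that("emergence is observed when recorded, predicted otherwise", {
  env_obs <- environment_record("e1", 45, 0, "2021-04-10",
                                const_weather("2021-04-01", 300, 18),
                                emergence_date = "2021-04-18")
  expect_equal(predict_emergence(env_obs, lin8), as.Date("2021-04-18"))

  env <- make_env(tmean = 18)   # 10 degCd/day
  # 76 degCd at 10/day, day-inclusive: reached on the 8th day
  expect_equal(predict_emergence(env, lin8), env$sowing_date + 7)

  # variable weather matches the brute-force scan
  set.seed(5)
  tm <- runif(300, 6, 24)
  wx <- weather_series(as.Date("2021-04-01") + 0:299, tm - 3, tm + 3, tm)
  envv <- environment_record("e2", 40, 0, "2021-04-05", wx)
  expect_equal(predict_emergence(envv, lin8),
               threshold_scan_oracle(wx, as.Date("2021-04-05"), 76, lin8))
})

test_that("environment records demand adequate weather coverage", {
  expect_error(environment_record("e1", 45, 0, "2021-04-10",
                                  const_weather("2021-04-01", 100, 18)),
               "250 days")
  expect_error(environment_record("e1", 45, 0, "2021-04-10",
                                  const_weather("2021-04-01", 300, 18),
                                  emergence_date = "2021-04-01"),
               "precedes sowing")
})

test_that("sensed daylength follows the threshold crossing and CBM model", {
  # equatorial, no twilight: DLs is 12 h whatever the BVP
  env0 <- make_env(latitude = 0, tmean = 18)
  rec0 <- sensed_daylength(env0, 326, lin8, twilight = 0)
  expect_equal(rec0$dls_h, 12, tolerance = 1e-9)

  # constant 10 degCd/day: BVP 326 reached on the 33rd day from emergence
  env <- make_env(latitude = 45, tmean = 18)
  emergence <- predict_emergence(env, lin8)
  rec <- sensed_daylength(env, 326, lin8, twilight = 6)
  expect_equal(rec$sensitization_date, emergence + 32)
  expect_equal(rec$sensitization_date,
               date_at_threshold(env$weather, emergence, 326, lin8))
  doy <- as.integer(strftime(emergence + 32, "%j"))
  expect_equal(rec$dls_h, cbm_daylength(45, doy, 6))
  expect_equal(rec$change_rate_h_per_day, photoperiod_change_rate(45, doy, 6))

  expect_error(sensed_daylength(env, 1e6, lin8), "insufficient weather")
  expect_error(sensed_daylength(env, -5, lin8), "positive")
})

test_that("DLs is bounded by the annual daylength extremes at that latitude", {
  env <- make_env(latitude = 52, sowing = "2021-03-15", tmean = 14)
  annual <- cbm_daylength(52, 1:365, 6)
  for (bvp in c(239, 326, 434)) {
    rec <- sensed_daylength(env, bvp, lin8)
    expect_gte(rec$dls_h, min(annual))
    expect_lte(rec$dls_h, max(annual))
  }
})

test_that("cooling the weather never advances the sensitization date", {
  set.seed(9)
  tm <- runif(300, 10, 24)
  d <- as.Date("2021-04-01") + 0:299
  warm <- environment_record("w", 45, 0, "2021-04-05",
                             weather_series(d, tm - 3, tm + 3, tm))
  cool <- environment_record("c", 45, 0, "2021-04-05",
                             weather_series(d, tm - 6, tm, tm - 3))
  for (bvp in c(200, 326, 450)) {
    expect_gte(as.integer(sensed_daylength(cool, bvp, lin8)$sensitization_date),
               as.integer(sensed_daylength(warm, bvp, lin8)$sensitization_date))
  }
})

test_that("within-environment daylength spread tracks maturity and change rate", {
  # equatorial, no twilight: all maturity classes sense 12 h
  env0 <- make_env(latitude = 0, tmean = 18)
  sp0 <- intra_env_spread(env0, cardinals = lin8, twilight = 0)
  expect_equal(unname(sp0$differences), rep(0, 3), tolerance = 1e-9)

  # mid-latitude spring sowing: sensitization before the solstice, so the
  # late class senses a longer day than the early class
  env <- make_env(latitude = 45, sowing = "2021-04-05", tmean = 16)
  sp <- intra_env_spread(env, cardinals = lin8)
  expect_gt(sp$differences[["late_minus_early"]], 0)
  expect_equal(sp$differences[["late_minus_early"]],
               sp$differences[["late_minus_median"]] +
                 sp$differences[["median_minus_early"]])

  # across a latitude gradient the spread grows with the change rate
  lats <- seq(15, 55, by = 5)
  spread <- change <- numeric(length(lats))
  for (i in seq_along(lats)) {
    e <- make_env(env_id = paste0("L", i), latitude = lats[i],
                  sowing = "2021-04-20", tmean = 16)
    s <- intra_env_spread(e, cardinals = lin8)
    spread[i] <- abs(s$differences[["late_minus_early"]])
    change[i] <- abs(s$records$change_rate_h_per_day[
      s$records$reference == "median"])
  }
  expect_gt(unname(coef(lm(spread ~ change))[2]), 0)
})

test_that("network envirotyping matches per-environment calls and collects failures", {
  envs <- list(make_env("a", 20, "2021-04-01", tmean = 18),
               make_env("b", 48, "2021-04-15", tmean = 15))
  tab <- envirotype_network(envs, cardinals = lin8)
  expect_equal(nrow(tab), 6)
  for (i in 1:2) {
    for (lab in c("early", "median", "late")) {
      ref <- c(early = 239, median = 326, late = 434)[[lab]]
      expect_equal(tab$dls_h[tab$env_id == envs[[i]]$env_id &
                               tab$reference == lab],
                   sensed_daylength(envs[[i]], ref, lin8)$dls_h)
    }
  }
  expect_null(attr(tab, "failures"))

  # an environment too cold to reach the BVP is flagged, not fatal
  cold <- make_env("cold", 55, "2021-04-01", tmean = 7)   # below base temp
  tab2 <- envirotype_network(list(envs[[1]], cold), cardinals = lin8)
  expect_equal(nrow(tab2), 3)
  fails <- attr(tab2, "failures")
  expect_equal(unique(fails$env_id), "cold")
  expect_match(fails$message[1], "insufficient weather")

  expect_error(envirotype_network(list()), "empty")
})

test_that("network summaries report DLs spread and same-site repeats", {
  envs <- list(make_env("y2020", 42.5, "2021-04-01", tmean = 18),
               make_env("y2021", 42.5, "2021-05-01", tmean = 15),
               make_env("other", 20, "2021-04-01", tmean = 18))
  tab <- envirotype_network(envs, refs = c(median = 326), cardinals = lin8)
  s <- summarize_envirotypes(tab, envs)
  expect_equal(s$by_reference$n, 3)
  expect_true(s$by_reference$min <= s$by_reference$median &
                s$by_reference$median <= s$by_reference$max)
  expect_equal(nrow(s$by_site), 1)   # the two same-coordinate years
  expect_gt(s$by_site$dls_range_h, 0)
})

test_that("wider latitude spans widen the DLs range", {
  narrow <- lapply(1:6, function(i) {
    make_env(paste0("n", i), 40 + i, "2021-04-10", tmean = 16)
  })
  wide <- lapply(1:6, function(i) {
    make_env(paste0("w", i), 15 + 7 * i, "2021-04-10", tmean = 16)
  })
  rn <- envirotype_network(narrow, refs = c(median = 326), cardinals = lin8)
  rw <- envirotype_network(wide, refs = c(median = 326), cardinals = lin8)
  expect_gt(diff(range(rw$dls_h)), diff(range(rn$dls_h)))
})

test_that("environment CSVs round-trip with per-environment weather files", {
  dir <- withr::local_tempdir()
  wx <- const_weather("2021-04-01", 300, 18)
  write.csv(data.frame(date = format(wx$date), tmin = wx$tmin,
                       tmax = wx$tmax, tmean = wx$tmean),
            file.path(dir, "e1.csv"), row.names = FALSE)
  writeLines(c("env_id,latitude,longitude,sowing_date,emergence_date",
               "e1,45,3.9,2021-04-10,"),
             file.path(dir, "envs.csv"))
  envs <- read_environments_csv(file.path(dir, "envs.csv"), dir)
  expect_length(envs, 1)
  expect_equal(envs[[1]]$latitude, 45)
  expect_null(envs[[1]]$emergence_date)
  expect_equal(nrow(envs[[1]]$weather), 300)
})
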
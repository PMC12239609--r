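# Independent oracles and small fixture builders shared across tests.
# Each oracle is coded directly from first principles, separately from the
# package implementation it checks.

# CBM daylength, re-derived step by step from the three model equations.
cbm_oracle <- function(lat_deg, day, depression_deg) {
  deg2rad <- function(x) x * pi / 180
  revolution <- 0.2163108 +
    2 * atan(0.9671396 * tan(0.00860 * (day - 186)))
  declination <- asin(0.39795 * cos(revolution))
  num <- sin(deg2rad(depression_deg)) +
    sin(deg2rad(lat_deg)) * sin(declination)
  den <- cos(deg2rad(lat_deg)) * cos(declination)
  24 - (24 / pi) * acos(num / den)
}

# Day-by-day brute-force thermal time accumulation (loop, no cumsum).
accumulate_oracle <- function(wx, start, cardinals) {
  total <- 0
  out <- numeric(0)
  for (i in seq_len(nrow(wx))) {
    if (wx$date[i] < start) next
    total <- total + daily_increment(wx$tmean[i], cardinals)
    out <- c(out, total)
  }
  out
}

# Linear scan for the first day cumulative thermal time reaches a threshold.
threshold_scan_oracle <- function(wx, start, threshold, cardinals) {
  total <- 0
  for (i in seq_len(nrow(wx))) {
    if (wx$date[i] < start) next
    total <- total + daily_increment(wx$tmean[i], cardinals)
    if (total >= threshold) return(wx$date[i])
  }
  NA
}

# Exhaustive dense-grid profile RSS minimization for the hinge model,
# fitted with lm at every grid value of the threshold.
hinge_grid_oracle <- function(dls, tt, step = 0.01, min_side = 3) {
  grid <- seq(min(dls), max(dls), by = step)
  keep <- vapply(grid, function(e) {
    e == min(dls) || (sum(dls < e) >= min_side && sum(dls > e) >= min_side)
  }, logical(1))
  grid <- grid[keep]
  rss <- vapply(grid, function(e) {
    sum(resid(lm(tt ~ pmax(0, dls - e)))^2)
  }, numeric(1))
  best <- which.min(rss)
  fit <- lm(tt ~ pmax(0, dls - grid[best]))
  list(e = grid[best], rss = rss[best],
       alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]))
}

# Constant-temperature weather fixture.
const_weather <- function(start = "2021-04-01", days = 200, tmean = 18) {
  weather_series(as.Date(start) + seq_len(days) - 1, tmin = tmean - 5,
                 tmax = tmean + 5, tmean = tmean)
}

# A compact environment fixture with constant weather.
make_env <- function(env_id = "e1", latitude = 45, sowing = "2021-04-10",
                     tmean = 18, days = 300, lon = 0) {
  environment_record(env_id, latitude, lon, sowing,
                     const_weather(start = as.Date(sowing) - 5, days = days,
                                   tmean = tmean))
}

# Linear GDD cardinals used throughout the arithmetic tests.
lin8 <- cardinal_temps(8, 30, 43, kind = "linear")
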
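#' Cardinal temperatures for a temperature-response function
#'
#' Bundles the base, optimum and ceiling temperatures that define how daily
#' temperature is converted into developmental (thermal) time, together with
#' the functional form used.
#'
#' Two forms are supported. `"linear"` is the classic growing-degree-day
#' response: development accrues in proportion to temperature above the base,
#' capped at the optimum. `"beta"` is the asymmetric beta-type response used
#' in many crop growth models: the rate rises from zero at `t_min` to 1 at
#' `t_opt` and falls back to zero at `t_max`, reflecting the slowdown of
#' enzymatic processes at supra-optimal temperatures.
#'
#' `t_scale` converts the dimensionless beta response into degree-day
#' equivalents per day (`increment = f(T) * t_scale`), so that durations
#' accumulated with either form live on comparable scales. The default,
#' `t_opt - t_min`, makes the beta increment at the optimum equal the linear
#' increment at the optimum.
#'
#' @param t_min Base temperature, deg C. No development at or below it.
#' @param t_opt Optimum temperature, deg C, where the rate is maximal.
#' @param t_max Ceiling temperature, deg C. No development at or above it
#'   (beta form).
#' @param kind `"beta"` or `"linear"`.
#' @param t_scale Scaling span in deg C for converting the normalized beta
#'   response to deg C day per day. Default `t_opt - t_min`.
#'
#' @return An object of class `cardinal_temps`.
#' @examples
#' cardinal_temps()                      # maize defaults, beta form
#' cardinal_temps(kind = "linear")       # classic GDD with optimum cutoff
#' @export
cardinal_temps <- function(t_min = 8, t_opt = 30, t_max = 43,
                           kind = c("beta", "linear"),
                           t_scale = t_opt - t_min) {
  kind <- match.arg(kind)
  if (!is.numeric(t_min) || !is.numeric(t_opt) || !is.numeric(t_max) ||
      length(t_min) != 1L || length(t_opt) != 1L || length(t_max) != 1L) {
    stop("cardinal temperatures must be single numeric values", call. = FALSE)
  }
  if (!(t_min < t_opt && t_opt < t_max)) {
    stop("invalid cardinal temperatures: need t_min < t_opt < t_max (got ",
         t_min, ", ", t_opt, ", ", t_max, ")", call. = FALSE)
  }
  if (!is.numeric(t_scale) || length(t_scale) != 1L || t_scale <= 0) {
    stop("t_scale must be a positive number", call. = FALSE)
  }
  structure(
    list(t_min = t_min, t_opt = t_opt, t_max = t_max,
         kind = kind, t_scale = t_scale),
    class = "cardinal_temps"
  )
}

#' @export
print.cardinal_temps <- function(x, ...) {
  cat(sprintf("<cardinal_temps> %s: t_min=%g t_opt=%g t_max=%g (t_scale=%g degC)\n",
              x$kind, x$t_min, x$t_opt, x$t_max, x$t_scale))
  invisible(x)
}

#' Normalized temperature response
#'
#' Developmental rate at temperature `t`, normalized to `[0, 1]`.
#'
#' For the beta form the response is
#' \deqn{f(T) = \frac{2 (T - T_{min})^a (T_{opt} - T_{min})^a -
#'   (T - T_{min})^{2a}}{(T_{opt} - T_{min})^{2a}}, \quad
#'   a = \frac{\ln 2}{\ln\left[(T_{max} - T_{min}) / (T_{opt} - T_{min})\right]}}
#' with `f = 0` outside `(t_min, t_max)`. For the linear form the response is
#' `(min(T, t_opt) - t_min) / (t_opt - t_min)`, floored at 0 and set to 0
#' above `t_max`.
#'
#' @param t Temperature(s), deg C. Vectorized.
#' @param cardinals A [cardinal_temps()] object.
#' @return Numeric vector of rates in `[0, 1]`.
#' @examples
#' temp_response(20, cardinal_temps())
#' @export
temp_response <- function(t, cardinals = cardinal_temps()) {
  stopifnot(inherits(cardinals, "cardinal_temps"))
  tmin <- cardinals$t_min; topt <- cardinals$t_opt; tmax <- cardinals$t_max
  if (cardinals$kind == "beta") {
    a <- log(2) / log((tmax - tmin) / (topt - tmin))
    u <- (t - tmin)
    v <- (topt - tmin)
    f <- (2 * u^a * v^a - u^(2 * a)) / v^(2 * a)
    f[t <= tmin | t >= tmax] <- 0
    # guard tiny negative values from floating cancellation near t_max
    pmin(pmax(f, 0), 1)
  } else {
    f <- (pmin(t, topt) - tmin) / (topt - tmin)
    f[t >= tmax] <- 0
    pmin(pmax(f, 0), 1)
  }
}

#' Thermal-time increment for one day
#'
#' Converts a daily mean temperature into that day's thermal-time accrual in
#' deg C day. The beta form scales the normalized response by `t_scale`; the
#' linear form is the classic degree-day formula `max(0, min(T, t_opt) -
#' t_min)` (no upper cutoff beyond the optimum cap, matching common GDD
#' practice).
#'
#' @param tmean Daily mean temperature(s), deg C. Vectorized.
#' @inheritParams temp_response
#' @return Increment(s) in deg C day, `>= 0`.
#' @export
daily_increment <- function(tmean, cardinals = cardinal_temps()) {
  stopifnot(inherits(cardinals, "cardinal_temps"))
  if (cardinals$kind == "beta") {
    temp_response(tmean, cardinals) * cardinals$t_scale
  } else {
    pmax(0, pmin(tmean, cardinals$t_opt) - cardinals$t_min)
  }
}

#' Construct and validate a daily weather series
#'
#' A weather series is one environment's daily temperature record: one row
#' per calendar day, gap-free and strictly increasing in date. When `tmean`
#' is absent it is derived as `(tmin + tmax) / 2`.
#'
#' @param date `Date` vector, strictly increasing, no gaps.
#' @param tmin,tmax Daily minimum / maximum temperature, deg C.
#' @param tmean Optional daily mean temperature, deg C. Derived if `NULL`.
#' @return A `data.frame` with columns `date`, `tmin`, `tmax`, `tmean`.
#' @examples
#' weather_series(as.Date("2021-05-01") + 0:4, tmin = 10, tmax = 24)
#' @export
weather_series <- function(date, tmin, tmax, tmean = NULL) {
  date <- as.Date(date)
  n <- length(date)
  tmin <- rep_len(as.numeric(tmin), n)
  tmax <- rep_len(as.numeric(tmax), n)
  if (is.null(tmean)) tmean <- (tmin + tmax) / 2
  tmean <- rep_len(as.numeric(tmean), n)
  wx <- data.frame(date = date, tmin = tmin, tmax = tmax, tmean = tmean)
  validate_weather(wx)
}

#' @rdname weather_series
#' @param wx A data frame with at least `date`, `tmin`, `tmax`.
#' @export
validate_weather <- function(wx) {
  need <- c("date", "tmin", "tmax")
  miss <- setdiff(need, names(wx))
  if (length(miss)) {
    stop("weather series is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  wx$date <- as.Date(wx$date)
  if (anyNA(wx$date)) stop("weather series has unparseable dates", call. = FALSE)
  if (nrow(wx) == 0L) stop("weather series is empty", call. = FALSE)
  d <- diff(as.integer(wx$date))
  if (any(d <= 0)) {
    stop("weather dates must be strictly increasing (violation near row ",
         which(d <= 0)[1] + 1L, ")", call. = FALSE)
  }
  if (any(d != 1)) {
    stop("weather series has a gap after ", wx$date[which(d != 1)[1]],
         " (series must be gap-free)", call. = FALSE)
  }
  if (!"tmean" %in% names(wx)) wx$tmean <- (wx$tmin + wx$tmax) / 2
  bad <- which(!(wx$tmin <= wx$tmean & wx$tmean <= wx$tmax))
  if (length(bad)) {
    stop("weather series violates tmin <= tmean <= tmax at ",
         wx$date[bad[1]], call. = FALSE)
  }
  wx[, c("date", "tmin", "tmax", "tmean")]
}

#' Read a per-environment weather CSV
#'
#' Expects columns `date` (ISO-8601), `tmin`, `tmax` and optionally `tmean`.
#' Schema violations are reported with the offending line number (header is
#' line 1).
#'
#' @param path Path to a CSV file.
#' @return A validated weather `data.frame` (see [weather_series()]).
#' @export
read_weather_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop(path, " line ", which(is.na(dates))[1] + 1L,
         ": unparseable date '", raw$date[which(is.na(dates))[1]], "'",
         call. = FALSE)
  }
  for (col in intersect(c("tmin", "tmax", "tmean"), names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v) && !all(is.na(raw[[col]]) == is.na(v))) {
      stop(path, " line ", which(is.na(v) & !is.na(raw[[col]]))[1] + 1L,
           ": non-numeric value in '", col, "'", call. = FALSE)
    }
    if (anyNA(v)) {
      stop(path, " line ", which(is.na(v))[1] + 1L, ": missing value in '",
           col, "'", call. = FALSE)
    }
    raw[[col]] <- v
  }
  raw$date <- dates
  tryCatch(validate_weather(raw),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Accumulate thermal time over a weather series
#'
#' Cumulative thermal time from `start` (inclusive: the start date's own
#' increment is counted) to the end of the series.
#'
#' @param wx A weather series (see [weather_series()]).
#' @param start Start date; must lie within the series.
#' @inheritParams temp_response
#' @return A `data.frame` with columns `date` and `tt_cd` (cumulative deg C
#'   day), non-decreasing.
#' @export
accumulate_tt <- function(wx, start, cardinals = cardinal_temps()) {
  wx <- validate_weather(wx)
  start <- as.Date(start)
  keep <- wx$date >= start
  if (!any(keep) || wx$date[1] > start) {
    stop("start date ", start, " is outside the weather record (",
         wx$date[1], " to ", wx$date[nrow(wx)], ")", call. = FALSE)
  }
  sub <- wx[keep, , drop = FALSE]
  data.frame(date = sub$date,
             tt_cd = cumsum(daily_increment(sub$tmean, cardinals)))
}

#' Date at which a thermal-time threshold is reached
#'
#' First calendar day, accumulating from `start` inclusive, on which the
#' cumulative thermal time is at least `threshold`. A threshold of zero
#' returns the start date.
#'
#' @inheritParams accumulate_tt
#' @param threshold Thermal-time threshold, deg C day, `>= 0`.
#' @param label Optional environment label used in the error message when the
#'   record is too short.
#' @return A `Date` of length 1.
#' @export
date_at_threshold <- function(wx, start, threshold,
                              cardinals = cardinal_temps(), label = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  acc <- accumulate_tt(wx, start, cardinals)
  if (threshold == 0) return(acc$date[1])
  hit <- which(acc$tt_cd >= threshold)
  if (!length(hit)) {
    who <- if (is.null(label)) "" else paste0(" in environment ", label)
    stop("insufficient weather record", who, ": threshold ", threshold,
         " degC day not reached (shortfall ",
         round(threshold - acc$tt_cd[nrow(acc)], 1), " degC day by ",
         acc$date[nrow(acc)], ")", call. = FALSE)
  }
  acc$date[hit[1]]
}

#' Range-normalized RMSE of thermal times across environments
#'
#' Root mean square deviation of a genotype's thermal times about their
#' across-environment mean, normalized by the range (max - min). Used to
#' compare temperature-response functions: for photoperiod-insensitive
#' material the best response function yields the most consistent thermal
#' time to anthesis across environments, i.e. the smallest value.
#'
#' @param values Numeric vector of thermal times (deg C day), one per
#'   environment; at least 3, not all equal.
#' @return Dimensionless NRMSE.
#' @examples
#' nrmse(c(1, 2, 3))   # sqrt(2/3) / 2
#' @export
nrmse <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  rng <- max(values) - min(values)
  if (rng == 0) {
    stop("NRMSE undefined for constant values (zero range)", call. = FALSE)
  }
  sqrt(mean((values - mean(values))^2)) / rng
}
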
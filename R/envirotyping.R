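#' Construct a field environment
#'
#' An environment is one field trial: a location, a sowing date, an optional
#' observed emergence date, and a daily weather record. The weather must
#' cover the sowing date through a configurable horizon so that downstream
#' thermal-time thresholds can be crossed.
#'
#' @param env_id Environment identifier.
#' @param latitude,longitude Decimal degrees (latitude positive north).
#' @param sowing_date Sowing date.
#' @param weather A weather series (see [weather_series()]).
#' @param emergence_date Optional observed emergence date, `>= sowing_date`.
#' @param horizon_days Required weather coverage after sowing, days.
#' @return An object of class `prn_environment`.
#' @export
environment_record <- function(env_id, latitude, longitude, sowing_date,
                               weather, emergence_date = NULL,
                               horizon_days = 250) {
  sowing_date <- as.Date(sowing_date)
  weather <- validate_weather(weather)
  if (abs(latitude) > 90) stop("latitude must lie in [-90, 90]", call. = FALSE)
  if (weather$date[1] > sowing_date ||
      weather$date[nrow(weather)] < sowing_date + horizon_days) {
    stop("environment ", env_id, ": weather must cover sowing date through ",
         horizon_days, " days after (", sowing_date, " to ",
         sowing_date + horizon_days, ")", call. = FALSE)
  }
  if (!is.null(emergence_date)) {
    emergence_date <- as.Date(emergence_date)
    if (emergence_date < sowing_date) {
      stop("environment ", env_id, ": emergence date precedes sowing date",
           call. = FALSE)
    }
  }
  structure(
    list(env_id = as.character(env_id), latitude = latitude,
         longitude = longitude, sowing_date = sowing_date,
         emergence_date = emergence_date, weather = weather),
    class = "prn_environment"
  )
}

#' @export
print.prn_environment <- function(x, ...) {
  cat(sprintf("<environment %s> lat %.2f lon %.2f, sown %s, weather %s..%s\n",
              x$env_id, x$latitude, x$longitude, x$sowing_date,
              x$weather$date[1], x$weather$date[nrow(x$weather)]))
  invisible(x)
}

#' Predict (or pass through) the crop emergence date
#'
#' Returns the observed emergence date when one is recorded; otherwise the
#' first day on which cumulative thermal time from sowing reaches
#' `tt_sow_em` (default 76 deg C day, an estimate of the sowing-to-emergence
#' duration for maize).
#'
#' @param env A [environment_record()].
#' @param cardinals A [cardinal_temps()] object.
#' @param tt_sow_em Sowing-to-emergence thermal time, deg C day.
#' @return A `Date` of length 1.
#' @export
predict_emergence <- function(env, cardinals = cardinal_temps(),
                              tt_sow_em = 76) {
  stopifnot(inherits(env, "prn_environment"))
  if (!is.null(env$emergence_date)) return(env$emergence_date)
  date_at_threshold(env$weather, env$sowing_date, tt_sow_em, cardinals,
                    label = env$env_id)
}

#' Sensed daylength for one environment and one BVP
#'
#' Determines the calendar day on which cumulative thermal time from
#' emergence first reaches the basic vegetative phase (the predicted day of
#' photoperiod sensitization), then evaluates the CBM daylength and the
#' daily photoperiodic change rate on that day. This is the envirotyping
#' index DLs: the photoperiod a genotype with that BVP actually senses in
#' that environment.
#'
#' @inheritParams predict_emergence
#' @param bvp Basic vegetative phase, deg C day, > 0.
#' @param reference Label recorded in the output (a maturity-class name or a
#'   genotype id).
#' @param twilight Twilight coefficient, degrees (see [cbm_daylength()]).
#' @return A one-row `data.frame`: `env_id`, `reference`,
#'   `sensitization_date`, `dls_h`, `change_rate_h_per_day`.
#' @export
sensed_daylength <- function(env, bvp, cardinals = cardinal_temps(),
                             twilight = 6, tt_sow_em = 76,
                             reference = "custom") {
  stopifnot(inherits(env, "prn_environment"))
  if (!is.numeric(bvp) || length(bvp) != 1L || bvp <= 0) {
    stop("bvp must be a single positive number", call. = FALSE)
  }
  emergence <- predict_emergence(env, cardinals, tt_sow_em)
  sens_date <- date_at_threshold(env$weather, emergence, bvp, cardinals,
                                 label = env$env_id)
  doy <- as.integer(strftime(sens_date, "%j"))
  data.frame(
    env_id = env$env_id,
    reference = as.character(reference),
    sensitization_date = sens_date,
    dls_h = cbm_daylength(env$latitude, doy, twilight),
    change_rate_h_per_day = photoperiod_change_rate(env$latitude, doy,
                                                    twilight),
    stringsAsFactors = FALSE
  )
}

#' Within-environment spread of sensed daylength across maturity classes
#'
#' Envirotypes DLs for several reference BVP values in one environment and
#' reports the pairwise differences. Genotypes with a longer BVP become
#' sensitized later in the season; away from the solstices this shifts the
#' daylength they sense, so the spread grows with the local rate of
#' photoperiodic change.
#'
#' @inheritParams sensed_daylength
#' @param refs Named numeric vector of reference BVPs, deg C day. Defaults
#'   to the early/median/late maturity references.
#' @return A list with `records` (one row per reference, see
#'   [sensed_daylength()]) and `differences` (named numeric vector of DLs
#'   differences in hours: `late_minus_early`, `late_minus_median`,
#'   `median_minus_early` for the default references, otherwise all pairwise
#'   `b_minus_a` in increasing-BVP order).
#' @export
intra_env_spread <- function(env, refs = c(early = 239, median = 326,
                                           late = 434),
                             cardinals = cardinal_temps(), twilight = 6,
                             tt_sow_em = 76) {
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    stop("refs must be a named numeric vector", call. = FALSE)
  }
  refs <- refs[order(refs)]
  recs <- do.call(rbind, lapply(names(refs), function(lab) {
    sensed_daylength(env, refs[[lab]], cardinals, twilight, tt_sow_em,
                     reference = lab)
  }))
  dls <- stats::setNames(recs$dls_h, recs$reference)
  labs <- names(refs)
  diffs <- c()
  for (i in seq_along(labs)) {
    for (j in seq_len(i - 1L)) {
      diffs[paste0(labs[i], "_minus_", labs[j])] <- dls[[labs[i]]] - dls[[labs[j]]]
    }
  }
  list(records = recs, differences = diffs)
}

#' Envirotype a network of environments
#'
#' Computes sensed daylength for every environment x reference combination.
#' Per-environment failures (typically an insufficient weather record) are
#' collected and attached, not fatal.
#'
#' @param envs List of [environment_record()] objects.
#' @param refs Named numeric vector of reference BVPs, deg C day.
#' @inheritParams sensed_daylength
#' @return A `data.frame` of envirotype records (one row per env x ref),
#'   with attribute `failures`: a `data.frame` of `env_id`, `reference`,
#'   `message` for combinations that could not be envirotyped.
#' @export
envirotype_network <- function(envs, refs = c(early = 239, median = 326,
                                              late = 434),
                               cardinals = cardinal_temps(), twilight = 6,
                               tt_sow_em = 76) {
  if (!length(envs)) stop("empty environment list", call. = FALSE)
  rows <- list(); fails <- list()
  for (env in envs) {
    for (lab in names(refs)) {
      res <- tryCatch(
        sensed_daylength(env, refs[[lab]], cardinals, twilight, tt_sow_em,
                         reference = lab),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(
          env_id = env$env_id, reference = lab,
          message = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(env_id = character(), reference = character(),
               sensitization_date = as.Date(character()),
               dls_h = numeric(), change_rate_h_per_day = numeric())
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails) else NULL
  out
}

#' Summarize an envirotype table
#'
#' Network-level summaries of sensed daylength: range, mean and percentiles
#' per reference, plus inter-annual within-site spread when several
#' environments share a site (keyed on rounded coordinates).
#'
#' @param records Envirotype table from [envirotype_network()].
#' @param envs The environment list the records came from (needed for
#'   coordinates; optional — site summaries are skipped without it).
#' @param coord_digits Rounding precision for the site key, decimal degrees.
#' @return A list with `by_reference` (data frame of n, min, mean, max and
#'   5/50/95 percentiles of DLs per reference) and `by_site` (data frame of
#'   per-site DLs ranges for the first reference, `NULL` when `envs` is
#'   missing or no site repeats exist).
#' @export
summarize_envirotypes <- function(records, envs = NULL, coord_digits = 2) {
  if (!nrow(records)) stop("empty envirotype table", call. = FALSE)
  by_ref <- do.call(rbind, lapply(split(records, records$reference),
                                  function(d) {
    q <- stats::quantile(d$dls_h, c(0.05, 0.5, 0.95))
    data.frame(reference = d$reference[1], n = nrow(d),
               min = min(d$dls_h), p05 = q[[1]], median = q[[2]],
               mean = mean(d$dls_h), p95 = q[[3]], max = max(d$dls_h),
               stringsAsFactors = FALSE)
  }))
  rownames(by_ref) <- NULL
  by_site <- NULL
  if (!is.null(envs)) {
    key <- vapply(envs, function(e) {
      paste(round(e$latitude, coord_digits), round(e$longitude, coord_digits))
    }, character(1))
    env_key <- stats::setNames(key, vapply(envs, `[[`, character(1), "env_id"))
    ref1 <- records[records$reference == records$reference[1], ]
    ref1$site <- env_key[ref1$env_id]
    tab <- table(ref1$site)
    rep_sites <- names(tab[tab >= 2])
    if (length(rep_sites)) {
      by_site <- do.call(rbind, lapply(rep_sites, function(s) {
        d <- ref1[ref1$site == s, ]
        data.frame(site = s, n = nrow(d),
                   dls_range_h = max(d$dls_h) - min(d$dls_h),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  list(by_reference = by_ref, by_site = by_site)
}

#' Read an environments CSV and attach per-environment weather
#'
#' Expects columns `env_id`, `latitude`, `longitude`, `sowing_date`, and
#' optionally `emergence_date` and `weather_file` (path relative to
#' `weather_dir`; defaults to `<env_id>.csv`).
#'
#' @param path Path to the environments CSV.
#' @param weather_dir Directory containing per-environment weather CSVs.
#' @param horizon_days Required weather coverage after sowing, days.
#' @return A list of [environment_record()] objects.
#' @export
read_environments_csv <- function(path, weather_dir,
                                  horizon_days = 250) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("env_id", "latitude", "longitude", "sowing_date")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(raw)), function(i) {
    wf <- if ("weather_file" %in% names(raw) && nzchar(raw$weather_file[i])) {
      raw$weather_file[i]
    } else {
      paste0(raw$env_id[i], ".csv")
    }
    wx <- read_weather_csv(file.path(weather_dir, wf))
    em <- if ("emergence_date" %in% names(raw) &&
              !is.na(raw$emergence_date[i]) &&
              nzchar(raw$emergence_date[i])) raw$emergence_date[i] else NULL
    environment_record(raw$env_id[i], raw$latitude[i], raw$longitude[i],
                       raw$sowing_date[i], wx, emergence_date = em,
                       horizon_days = horizon_days)
  })
}
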
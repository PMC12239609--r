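#' Configuration for the trial-network simulator
#'
#' Bundles every knob of the forward simulator: the environment network
#' (number of trials, latitude and sowing-date spans, temperature climate),
#' the genotype panel (development and reaction-norm parameter
#' distributions, fraction of photoperiod-insensitive material), and the
#' noise structure (environment-level latent effects and residual noise on
#' the thermal-time scale). The seed is mandatory: every stochastic call
#' derives its stream from it.
#'
#' Defaults emulate a Northern-Hemisphere maize trial network: latitudes
#' spanning roughly the tropics-to-Baltic range over which maize is grown,
#' spring sowing, a sinusoidal annual temperature cycle whose amplitude
#' scales with latitude, and a panel mixing photoperiod-sensitive material
#' (positive slope) with insensitive material (zero slope).
#'
#' @param n_envs Number of environments.
#' @param latitude_range Latitude span, decimal degrees N.
#' @param sowing_doy_range Sowing day-of-year span.
#' @param temp_mean_annual Annual mean temperature, deg C.
#' @param temp_amplitude Seasonal temperature amplitude at 45 deg latitude,
#'   deg C (scaled by `|latitude| / 45`).
#' @param temp_noise_sd Day-to-day temperature noise SD, deg C.
#' @param n_genotypes Panel size.
#' @param dists Named list of `c(mean, sd)` pairs for the genotype-level
#'   parameters `alpha` (flowering time per se, deg C day), `e` (critical
#'   photoperiod, h), `beta` (photoperiod sensitivity, deg C day/h),
#'   `p_tip` (phyllochron, deg C day/leaf), `lf` (final leaf number).
#' @param latent_sd SD of environment-level latent offsets, deg C day.
#' @param resid_sd Residual SD per observation, deg C day.
#' @param prop_insensitive Fraction of the panel with slope 0.
#' @param seed Integer seed (mandatory).
#' @param year_start Calendar year for sowing dates.
#' @param strata Optional list of sub-networks, each a list with `n`,
#'   `latitude_range`, `sowing_doy_range` and optionally
#'   `temp_mean_annual` / `temp_amplitude` climate overrides, replacing the
#'   top-level network draw (used to emulate daylength-coverage gaps and
#'   warm tropical off-season nurseries).
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(n_envs = 40,
                       latitude_range = c(14, 55),
                       sowing_doy_range = c(60, 150),
                       temp_mean_annual = 14,
                       temp_amplitude = 10,
                       temp_noise_sd = 2,
                       n_genotypes = 30,
                       dists = list(alpha = c(mean = 850, sd = 50),
                                    e = c(mean = 13, sd = 0.5),
                                    beta = c(mean = 60, sd = 15),
                                    p_tip = c(mean = 38, sd = 4),
                                    lf = c(mean = 16, sd = 2)),
                       latent_sd = 40,
                       resid_sd = 20,
                       prop_insensitive = 0.3,
                       seed = NULL,
                       year_start = 2001,
                       strata = NULL) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("sim_config requires a single integer seed", call. = FALSE)
  }
  if (latent_sd < 0 || resid_sd < 0 || temp_noise_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (diff(latitude_range) < 0 || diff(sowing_doy_range) < 0) {
    stop("ranges must be ordered (low, high)", call. = FALSE)
  }
  if (prop_insensitive < 0 || prop_insensitive > 1) {
    stop("prop_insensitive must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("alpha", "e", "beta", "p_tip", "lf")) {
    if (!nm %in% names(dists) || length(dists[[nm]]) != 2L) {
      stop("dists must supply c(mean, sd) for '", nm, "'", call. = FALSE)
    }
  }
  structure(
    list(n_envs = n_envs, latitude_range = latitude_range,
         sowing_doy_range = sowing_doy_range,
         temp_mean_annual = temp_mean_annual,
         temp_amplitude = temp_amplitude, temp_noise_sd = temp_noise_sd,
         n_genotypes = n_genotypes, dists = dists, latent_sd = latent_sd,
         resid_sd = resid_sd, prop_insensitive = prop_insensitive,
         seed = as.integer(seed), year_start = year_start, strata = strata),
    class = "sim_config"
  )
}

#' Named simulation presets
#'
#' `"d4-like"`: a methods-evaluation style network — 14 genotypes (half of
#' them photoperiod-insensitive controls) in 37 environments whose sensed
#' daylengths span short-day and long-day conditions continuously. Maize
#' trial networks achieve short-day coverage through tropical autumn/winter
#' sowings, so the preset mixes a tropical autumn-sown stratum (about 30%
#' of environments) with a temperate spring-sown one.
#'
#' `"d5-like"`: a diversity-panel style network — 236 genotypes in 19
#' environments split into a small low-latitude short-day stratum and a
#' larger high-latitude long-day stratum, reproducing the characteristic
#' coverage gap of sensed daylengths between about 12.4 and 14.5 h that
#' prevents threshold estimation and forces the LD-SD method.
#'
#' @param preset `"d4-like"` or `"d5-like"`.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A [sim_config()] object.
#' @export
sim_preset <- function(preset = c("d4-like", "d5-like"), seed, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "d4-like" = list(n_envs = 37, n_genotypes = 14, prop_insensitive = 0.5),
    "d5-like" = list(n_envs = 19, n_genotypes = 236, prop_insensitive = 0.4,
                     strata = list(
                       # warm tropical off-season nurseries: sensitization in
                       # boreal winter, short sensed days
                       list(n = 3, latitude_range = c(14, 18),
                            sowing_doy_range = c(300, 330),
                            temp_mean_annual = 25, temp_amplitude = 5),
                       list(n = 16, latitude_range = c(38, 50),
                            sowing_doy_range = c(110, 150))))
  )
  over <- list(...)
  args[names(over)] <- over
  if (preset == "d4-like" && is.null(args$strata)) {
    n_sd <- round(0.3 * args$n_envs)
    args$strata <- list(
      list(n = n_sd, latitude_range = c(14, 20),
           sowing_doy_range = c(280, 340)),
      list(n = args$n_envs - n_sd, latitude_range = c(25, 50),
           sowing_doy_range = c(60, 150)))
  }
  args$seed <- seed
  do.call(sim_config, args)
}

#' Simulate a daily weather series
#'
#' Daily mean temperature follows a sinusoidal annual cycle with additive
#' Gaussian noise:
#' `tmean(d) = temp_mean_annual + temp_amplitude * sin(2*pi*(DOY - 105)/365)
#' * (|latitude|/45) + N(0, temp_noise_sd)`,
#' peaking in late July at northern latitudes; `tmin`/`tmax` are placed
#' symmetrically 5 deg C below/above the mean. With `seed = NULL` the draw
#' uses the current RNG stream (so network-level simulation is reproducible
#' from a single seed).
#'
#' @param latitude Latitude, decimal degrees.
#' @param start_date First day of the series.
#' @param n_days Series length, days (>= 1).
#' @param cfg A [sim_config()].
#' @param seed Optional seed for a standalone reproducible series.
#' @return A weather `data.frame` (see [weather_series()]).
#' @export
simulate_weather <- function(latitude, start_date, n_days, cfg,
                             seed = NULL) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.integer(strftime(dates, "%j"))
  tmean <- cfg$temp_mean_annual +
    cfg$temp_amplitude * sin(2 * pi * (doy - 105) / 365) *
      (abs(latitude) / 45) +
    stats::rnorm(n_days, 0, cfg$temp_noise_sd)
  weather_series(dates, tmin = tmean - 5, tmax = tmean + 5, tmean = tmean)
}

#' Simulate a network of field environments
#'
#' Draws latitudes and sowing days of year uniformly from the configured
#' ranges (or per-stratum ranges when `cfg$strata` is set), attaches a
#' simulated weather series starting 10 days before sowing and covering 380
#' days, and returns environment records. Longitudes are drawn uniformly
#' over a Northern-Hemisphere span; they label sites but play no role in
#' daylength.
#'
#' @param cfg A [sim_config()]; `cfg$seed` drives the whole draw.
#' @return A list of [environment_record()] objects of length `cfg$n_envs`.
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(cfg$seed)
  strata <- cfg$strata
  if (is.null(strata)) {
    strata <- list(list(n = cfg$n_envs,
                        latitude_range = cfg$latitude_range,
                        sowing_doy_range = cfg$sowing_doy_range))
  }
  envs <- list()
  i <- 0L
  for (st in strata) {
    for (k in seq_len(st$n)) {
      i <- i + 1L
      lat <- stats::runif(1, st$latitude_range[1], st$latitude_range[2])
      lon <- stats::runif(1, -105, 30)
      doy <- round(stats::runif(1, st$sowing_doy_range[1],
                                st$sowing_doy_range[2]))
      sowing <- as.Date(paste0(cfg$year_start, "-01-01")) + doy - 1L
      cfg_st <- cfg
      for (f in intersect(c("temp_mean_annual", "temp_amplitude"),
                          names(st))) {
        cfg_st[[f]] <- st[[f]]
      }
      wx <- simulate_weather(lat, sowing - 10L, 380L, cfg_st)
      envs[[i]] <- environment_record(
        env_id = sprintf("env%03d", i), latitude = lat, longitude = lon,
        sowing_date = sowing, weather = wx)
    }
  }
  envs
}

#' Simulate a genotype panel with known reaction-norm parameters
#'
#' Draws development traits (phyllochron, final leaf number) and true
#' reaction-norm parameters (flowering time per se `alpha`, critical
#' photoperiod `e`, photoperiod sensitivity `beta`) per genotype from the
#' configured normal distributions. A `prop_insensitive` fraction of the
#' panel is photoperiod-insensitive (`beta = 0`; their `e` is irrelevant and
#' set to `NA`). The basic vegetative phase is derived from the development
#' traits via [predict_bvp()].
#'
#' @param cfg A [sim_config()].
#' @return A `data.frame`: `genotype_id`, `group` (sensitive/insensitive),
#'   `p_tip`, `lf`, `bvp`, `alpha`, `e`, `beta`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genotypes
  d <- cfg$dists
  draw <- function(p, n) stats::rnorm(n, p[["mean"]], p[["sd"]])
  consts <- bvp_constants()
  p_tip <- pmax(draw(d$p_tip, n), 10)
  lf <- pmax(draw(d$lf, n), consts$l_pr_em + 2)
  n_ins <- round(cfg$prop_insensitive * n)
  group <- rep("sensitive", n)
  if (n_ins > 0) group[seq_len(n_ins)] <- "insensitive"
  alpha <- draw(d$alpha, n)
  e <- draw(d$e, n)
  beta <- pmax(draw(d$beta, n), 0)
  beta[group == "insensitive"] <- 0
  e[group == "insensitive"] <- NA_real_
  data.frame(genotype_id = sprintf("g%03d", seq_len(n)), group = group,
             p_tip = p_tip, lf = lf,
             bvp = predict_bvp(p_tip, lf, consts),
             alpha = alpha, e = e, beta = beta,
             stringsAsFactors = FALSE)
}

#' Forward-simulate a multi-environment flowering trial
#'
#' For every genotype x environment pair: envirotype the sensed daylength
#' from the genotype's true BVP, evaluate the generative reaction norm
#' \deqn{Tt^* = \alpha + \beta (DL_s - e)_+ + \lambda_{env} + \varepsilon}
#' (for insensitive genotypes the photoperiod term is zero), then convert
#' the target thermal time into an anthesis date by accumulating thermal
#' time forward from emergence, and report integer days from sowing to
#' anthesis — the phenotype a trial would record. Environment latent
#' offsets \eqn{\lambda_{env} \sim N(0, \sigma_\lambda)} are shared by all
#' genotypes within an environment and centered to mean zero across the
#' network (a latent effect common to every environment is not identifiable
#' and would only shift every intercept); \eqn{\varepsilon \sim N(0,
#' \sigma_\varepsilon)} is per observation.
#'
#' Pairs whose target thermal time is not reached within the weather record
#' are dropped (emulating real trial missingness) and listed in `dropped`.
#'
#' Snapping the anthesis date to whole days means the thermal time later
#' recomputed from the phenotype overshoots the target by up to one day's
#' increment; this discretization is the dominant error floor in
#' parameter-recovery studies.
#'
#' @param envs List of environments from [simulate_network()].
#' @param panel Genotype panel from [simulate_panel()].
#' @param cfg A [sim_config()].
#' @param cardinals A [cardinal_temps()] object.
#' @param twilight Twilight coefficient, degrees.
#' @param tt_sow_em Sowing-to-emergence thermal time, deg C day.
#' @return A list: `met` — phenotype table (`genotype_id`, `env_id`,
#'   `days_to_anthesis`); `truth` — per-observation ground truth
#'   (`genotype_id`, `env_id`, `dls_true`, `lambda_env`, `eps`,
#'   `tt_target`, plus the genotype's `alpha`, `e`, `beta`); `dropped` —
#'   unreachable pairs with reasons (`NULL` if none).
#' @export
simulate_met <- function(envs, panel, cfg, cardinals = cardinal_temps(),
                         twilight = 6, tt_sow_em = 76) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(cfg$seed + 2L)
  n_env <- length(envs)
  lambda <- stats::rnorm(n_env, 0, cfg$latent_sd)
  if (cfg$latent_sd > 0) lambda <- lambda - mean(lambda)
  met <- list(); truth <- list(); dropped <- list()
  for (j in seq_len(n_env)) {
    env <- envs[[j]]
    emergence <- predict_emergence(env, cardinals, tt_sow_em)
    acc <- accumulate_tt(env$weather, emergence, cardinals)
    for (i in seq_len(nrow(panel))) {
      g <- panel[i, ]
      sens <- which(acc$tt_cd >= g$bvp)
      if (!length(sens)) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          genotype_id = g$genotype_id, env_id = env$env_id,
          reason = "bvp not reached", stringsAsFactors = FALSE)
        next
      }
      doy <- as.integer(strftime(acc$date[sens[1]], "%j"))
      dls <- cbm_daylength(env$latitude, doy, twilight)
      photo <- if (g$beta > 0) g$beta * max(0, dls - g$e) else 0
      eps <- stats::rnorm(1, 0, cfg$resid_sd)
      tt_target <- g$alpha + photo + lambda[j] + eps
      anth <- which(acc$tt_cd >= tt_target)
      if (!length(anth)) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          genotype_id = g$genotype_id, env_id = env$env_id,
          reason = "anthesis thermal time not reached",
          stringsAsFactors = FALSE)
        next
      }
      met[[length(met) + 1L]] <- data.frame(
        genotype_id = g$genotype_id, env_id = env$env_id,
        days_to_anthesis = as.integer(acc$date[anth[1]] - env$sowing_date),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        genotype_id = g$genotype_id, env_id = env$env_id, dls_true = dls,
        lambda_env = lambda[j], eps = eps, tt_target = tt_target,
        alpha = g$alpha, e = g$e, beta = g$beta, stringsAsFactors = FALSE)
    }
  }
  list(met = do.call(rbind, met), truth = do.call(rbind, truth),
       dropped = if (length(dropped)) do.call(rbind, dropped) else NULL)
}

#' Convert trial phenotypes to thermal times and attach sensed daylength
#'
#' The analysis-side counterpart of [simulate_met()] (and the entry point
#' for real trial data): for every observation, the anthesis date is sowing
#' date plus `days_to_anthesis`, the response `tt_em_ant` is the cumulative
#' thermal time from (observed or predicted) emergence to anthesis, and the
#' predictor `dls` is the sensed daylength envirotyped either from each
#' genotype's own BVP (`panel` supplied) or from a common reference BVP.
#'
#' @param met Phenotype table: `genotype_id`, `env_id`, `days_to_anthesis`.
#' @param envs List of [environment_record()] objects covering every
#'   `env_id` in `met`.
#' @param panel Optional genotype table with `genotype_id` and `bvp` for
#'   genotype-specific envirotyping.
#' @param reference_bvp_value Common reference BVP, deg C day, used when
#'   `panel` is `NULL`. Default: the median maturity reference.
#' @param cardinals,twilight,tt_sow_em See [sensed_daylength()].
#' @return The input table with `tt_em_ant` (deg C day) and `dls` (hours)
#'   columns appended.
#' @export
envirotype_met <- function(met, envs, panel = NULL,
                           reference_bvp_value = reference_bvp("median")$bvp_value,
                           cardinals = cardinal_temps(), twilight = 6,
                           tt_sow_em = 76) {
  need <- c("genotype_id", "env_id", "days_to_anthesis")
  miss <- setdiff(need, names(met))
  if (length(miss)) {
    stop("met is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  env_ids <- vapply(envs, `[[`, character(1), "env_id")
  absent <- setdiff(unique(met$env_id), env_ids)
  if (length(absent)) {
    stop("no environment record for: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  env_of <- stats::setNames(envs, env_ids)
  bvp_of <- NULL
  if (!is.null(panel)) {
    bvp_of <- stats::setNames(panel$bvp, panel$genotype_id)
    absent_g <- setdiff(unique(met$genotype_id), panel$genotype_id)
    if (length(absent_g)) {
      stop("no BVP for genotype(s): ", paste(absent_g, collapse = ", "),
           call. = FALSE)
    }
  }
  met$tt_em_ant <- NA_real_
  met$dls <- NA_real_
  for (eid in unique(met$env_id)) {
    env <- env_of[[eid]]
    emergence <- predict_emergence(env, cardinals, tt_sow_em)
    acc <- accumulate_tt(env$weather, emergence, cardinals)
    rows <- which(met$env_id == eid)
    anth_dates <- env$sowing_date + met$days_to_anthesis[rows]
    idx <- match(anth_dates, acc$date)
    if (anyNA(idx)) {
      stop("environment ", eid, ": anthesis date outside the weather ",
           "record or before emergence", call. = FALSE)
    }
    met$tt_em_ant[rows] <- acc$tt_cd[idx]
    if (is.null(bvp_of)) {
      rec <- sensed_daylength(env, reference_bvp_value, cardinals, twilight,
                              tt_sow_em)
      met$dls[rows] <- rec$dls_h
    } else {
      for (r in rows) {
        rec <- sensed_daylength(env, bvp_of[[met$genotype_id[r]]], cardinals,
                                twilight, tt_sow_em)
        met$dls[r] <- rec$dls_h
      }
    }
  }
  met
}
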
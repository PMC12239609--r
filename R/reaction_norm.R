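#' Classify an environment as short-day or long-day
#'
#' Environments are labelled LD when the sensed daylength exceeds the fixed
#' threshold, SD otherwise. A value exactly at the threshold is SD (closed
#' lower segment). The default of 13.5 h corresponds to a typical critical
#' photoperiod for photoperiod-sensitive maize.
#'
#' @param dls Sensed daylength(s), hours, in (0, 24). Vectorized.
#' @param threshold Classification threshold, hours.
#' @return Character vector of `"SD"` / `"LD"`.
#' @examples
#' classify_sd_ld(c(12.4, 13.5, 14.5))
#' @export
classify_sd_ld <- function(dls, threshold = 13.5) {
  if (any(dls <= 0 | dls >= 24)) {
    stop("dls must lie in (0, 24) hours", call. = FALSE)
  }
  ifelse(dls > threshold, "LD", "SD")
}

#' Adjust thermal times for latent environmental effects
#'
#' Photoperiod-insensitive control genotypes are expected to show the same
#' thermal time to anthesis in every environment; their per-environment
#' deviations from the across-environment mean estimate latent environmental
#' effects (management, weather-data bias, drought, ...) common to all
#' genotypes in the trial. Those deviations are subtracted from every other
#' genotype's thermal time in the corresponding environment.
#'
#' For each control set the procedure is: (1) per environment, average the
#' control genotypes' `tt_em_ant`; (2) average those per-environment means
#' over the set's environments to get the overall control mean; (3) the
#' per-environment deviation is (per-environment mean) minus (overall mean);
#' (4) non-control observations in that environment are adjusted by
#' subtracting the deviation, and control observations are set to the
#' overall mean. Each environment must be mapped to exactly one control set.
#'
#' @param met Data frame of trial observations with columns `genotype_id`,
#'   `env_id`, `tt_em_ant` (deg C day); other columns pass through.
#' @param controls Data frame mapping control genotypes to sets: columns
#'   `set_id`, `genotype_id`.
#' @param env_map Data frame mapping environments to control sets: columns
#'   `env_id`, `set_id`. Defaults to mapping every environment in `met` to
#'   the single set in `controls` (an error if there are several sets).
#' @return A list: `met` (the adjusted table, same shape as the input) and
#'   `deviations` (data frame `env_id`, `set_id`, `n_control_obs`,
#'   `deviation_cd`). Deviations of each set sum to zero across its
#'   environments.
#' @export
latent_adjust <- function(met, controls, env_map = NULL) {
  need <- c("genotype_id", "env_id", "tt_em_ant")
  miss <- setdiff(need, names(met))
  if (length(miss)) {
    stop("met is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("set_id", "genotype_id") %in% names(controls))) {
    stop("controls needs columns set_id, genotype_id", call. = FALSE)
  }
  if (is.null(env_map)) {
    sets <- unique(controls$set_id)
    if (length(sets) != 1L) {
      stop("env_map is required when controls define several sets",
           call. = FALSE)
    }
    env_map <- data.frame(env_id = unique(met$env_id), set_id = sets)
  }
  if (anyDuplicated(env_map$env_id)) {
    stop("each environment must map to exactly one control set", call. = FALSE)
  }
  unmapped <- setdiff(unique(met$env_id), env_map$env_id)
  if (length(unmapped)) {
    stop("environment(s) not mapped to a control set: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }

  # per-environment mean of the mapped set's control genotypes
  set_of_env <- stats::setNames(env_map$set_id, env_map$env_id)
  met$.set <- set_of_env[met$env_id]
  is_ctrl <- mapply(function(g, s) {
    g %in% controls$genotype_id[controls$set_id == s]
  }, met$genotype_id, met$.set)
  ctrl_obs <- met[is_ctrl, ]
  no_ctrl <- setdiff(unique(met$env_id), unique(ctrl_obs$env_id))
  if (length(no_ctrl)) {
    stop("no control observations for environment(s): ",
         paste(no_ctrl, collapse = ", "), call. = FALSE)
  }
  env_mean <- tapply(ctrl_obs$tt_em_ant, ctrl_obs$env_id, mean)
  dev_tab <- data.frame(env_id = names(env_mean),
                        set_id = unname(set_of_env[names(env_mean)]),
                        n_control_obs = as.integer(
                          table(ctrl_obs$env_id)[names(env_mean)]),
                        env_mean = as.numeric(env_mean),
                        stringsAsFactors = FALSE)
  set_mean <- tapply(dev_tab$env_mean, dev_tab$set_id, mean)
  dev_tab$deviation_cd <- as.numeric(dev_tab$env_mean -
                                       set_mean[dev_tab$set_id])

  dev_of_env <- stats::setNames(dev_tab$deviation_cd, dev_tab$env_id)
  adj <- as.numeric(met$tt_em_ant - dev_of_env[met$env_id])
  # controls are pinned at their set's overall mean
  adj[is_ctrl] <- set_mean[met$.set[is_ctrl]]
  met$tt_em_ant <- as.numeric(adj)
  met$.set <- NULL
  list(met = met,
       deviations = dev_tab[, c("env_id", "set_id", "n_control_obs",
                                "deviation_cd")])
}

# Profile RSS of the hinge model tt = a + b * (dls - e)+ at one candidate
# threshold, via closed-form simple regression. Returns RSS, a, b.
.hinge_ols <- function(dls, tt, e) {
  x <- pmax(0, dls - e)
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(tt^2) - sum(tt)^2 / n
  if (sxx <= 0) {           # hinge basis constant: intercept-only model
    return(c(rss = syy, a = mean(tt), b = 0))
  }
  sxy <- sum(x * tt) - sum(x) * sum(tt) / n
  b <- sxy / sxx
  a <- mean(tt) - b * mean(x)
  c(rss = syy - b * sxy, a = a, b = b)
}

#' Fit the bilinear (hinge) reaction norm
#'
#' Fits \deqn{Tt_{em-ant} = \alpha + \beta (DL_s - e)_+ + \varepsilon} by
#' profile least squares: for each candidate threshold `e` the model is
#' linear in \eqn{(\alpha, \beta)} and solved in closed form; the estimate
#' \eqn{\hat e} minimizes the residual sum of squares over the candidate
#' set. The fitted reaction norm is flat at \eqn{\alpha} below the critical
#' photoperiod \eqn{\hat e} and rises with slope \eqn{\beta} (deg C day per
#' hour) above it, and is continuous at the threshold.
#'
#' Candidate thresholds are the unique observed `dls` values plus the
#' midpoints between consecutive ones (the profile RSS is piecewise smooth
#' with breakpoints at the data values); the winning candidate is then
#' refined by continuous minimization of the profile RSS between its
#' neighboring candidates. A candidate is admissible only when at least
#' `min_side` points lie strictly below and strictly above it, preventing
#' degenerate segment fits. The limit `e = min(dls)`, at which the hinge
#' reduces exactly to a straight line in `dls`, is always evaluated as well,
#' so the bilinear fit never has a larger residual sum of squares than the
#' best straight line; when that limit wins, no threshold is detectable
#' within the observed daylength range and the fit is flagged
#' `boundary_threshold`.
#'
#' Standard errors for \eqn{\alpha} and \eqn{\beta} are the OLS errors
#' conditional on \eqn{\hat e}; the threshold's standard error, which has no
#' closed form, is estimated by a nonparametric bootstrap (resampling
#' observations with replacement and re-profiling) when `boot_B > 0`.
#'
#' @param dls Sensed daylengths, hours (predictor).
#' @param tt Thermal times from emergence to anthesis, deg C day (response).
#' @param min_side Minimum number of points strictly on each side of an
#'   admissible candidate threshold.
#' @param boot_B Bootstrap replicates for the threshold standard error;
#'   0 skips the bootstrap (`se_threshold` is `NA`).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return A one-row `data.frame` of class `prn_fit`: `method`, `intercept`,
#'   `se_intercept`, `threshold`, `se_threshold`, `slope`, `se_slope`,
#'   `rmse` (root mean squared residual of the full bilinear model),
#'   `n_obs`, `flags` (semicolon-separated; `negative_slope` marks a
#'   biologically unexpected downward response).
#' @examples
#' dls <- c(11.5, 12, 12.5, 13, 13.5, 14, 15, 16)
#' tt <- 800 + 50 * pmax(0, dls - 13)
#' fit_hinge(dls, tt)
#' @export
fit_hinge <- function(dls, tt, min_side = 3, boot_B = 0, boot_seed = 1) {
  ok <- is.finite(dls) & is.finite(tt)
  dls <- dls[ok]; tt <- tt[ok]
  n <- length(dls)
  if (n < 2 * min_side + 2 || n < 8) {
    stop("cannot fit bilinear model with ", n, " points; use ld_sd",
         call. = FALSE)
  }
  if (max(dls) == min(dls)) {
    stop("cannot fit bilinear model: no spread in dls", call. = FALSE)
  }
  if (stats::var(tt) == 0) {
    stop("degenerate fit: response has no variation, threshold ",
         "unidentifiable", call. = FALSE)
  }
  cands <- .hinge_candidates(dls, min_side)
  if (!length(cands)) {
    stop("cannot fit bilinear model: fewer than ", min_side, " points on ",
         "each side of every candidate threshold; use ld_sd", call. = FALSE)
  }
  cands <- unique(c(min(dls), cands))   # line limit always admissible
  prof <- vapply(cands, function(e) .hinge_ols(dls, tt, e), numeric(3))
  best <- which.min(prof["rss", ])
  e_hat <- cands[best]
  rss_hat <- prof["rss", best]
  # the profile RSS is smooth between candidates but its minimizer need not
  # sit at a data value or midpoint: refine every inter-candidate segment
  if (length(cands) > 1L && rss_hat > 0) {
    for (k in seq_len(length(cands) - 1L)) {
      opt <- stats::optimize(function(e) .hinge_ols(dls, tt, e)[["rss"]],
                             lower = cands[k], upper = cands[k + 1L])
      if (opt$objective < rss_hat) {
        rss_hat <- opt$objective
        e_hat <- opt$minimum
      }
    }
  }
  # conditional OLS for alpha, beta and their SEs at the profiled threshold
  x <- pmax(0, dls - e_hat)
  fit <- stats::lm(tt ~ x)
  co <- summary(fit)$coefficients
  rss <- sum(stats::resid(fit)^2)
  se_e <- NA_real_
  if (boot_B > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
    set.seed(boot_seed)
    eb <- vapply(seq_len(boot_B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      db <- dls[idx]; tb <- tt[idx]
      cb <- .hinge_candidates(db, min_side)
      if (!length(cb)) return(NA_real_)
      cb <- unique(c(min(db), cb))
      pb <- vapply(cb, function(e) .hinge_ols(db, tb, e)[["rss"]], numeric(1))
      cb[which.min(pb)]
    }, numeric(1))
    se_e <- stats::sd(eb, na.rm = TRUE)
  }
  flags <- character(0)
  if (e_hat <= min(dls)) flags <- c(flags, "boundary_threshold")
  if (co["x", "Estimate"] < 0) {
    flags <- c(flags, "negative_slope")
    warning("fitted photoperiod-sensitivity slope is negative ",
            "(biologically unexpected)", call. = FALSE)
  }
  new_prn_fit(method = "hinge",
              intercept = co["(Intercept)", "Estimate"],
              se_intercept = co["(Intercept)", "Std. Error"],
              threshold = e_hat, se_threshold = se_e,
              slope = co["x", "Estimate"],
              se_slope = co["x", "Std. Error"],
              rmse = sqrt(rss / n), n_obs = n,
              flags = paste(flags, collapse = ";"))
}

# Candidate thresholds: unique observed dls plus midpoints between
# consecutive ones, restricted to >= min_side points strictly on each side.
.hinge_candidates <- function(dls, min_side) {
  u <- sort(unique(dls))
  if (length(u) < 2L) return(numeric(0))
  cands <- sort(c(u, (u[-1] + u[-length(u)]) / 2))
  keep <- vapply(cands, function(e) {
    sum(dls < e) >= min_side && sum(dls > e) >= min_side
  }, logical(1))
  cands[keep]
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", seed, envir = globalenv())
  }
}

new_prn_fit <- function(method, intercept, se_intercept, threshold,
                        se_threshold, slope, se_slope, rmse, n_obs, flags) {
  structure(
    data.frame(method = method, intercept = intercept,
               se_intercept = se_intercept, threshold = threshold,
               se_threshold = se_threshold, slope = slope,
               se_slope = se_slope, rmse = rmse, n_obs = n_obs,
               flags = flags, stringsAsFactors = FALSE),
    class = c("prn_fit", "data.frame")
  )
}

#' Fit the LD-SD linear reaction norm
#'
#' Two-parameter alternative to the hinge model for genotypes or trial
#' networks where the threshold cannot be estimated (sparse coverage of
#' daylengths, or photoperiod-insensitive material). Environments are
#' classified SD/LD at a fixed daylength threshold; each observation's
#' predictor is recoded to its class's mean sensed daylength (computed over
#' the genotype's own observed environments) and shifted so the SD mean is
#' zero. OLS of thermal time on the recoded predictor then gives the
#' intercept at the SD daylength mean (flowering time per se) and the slope
#' in deg C day per hour (photoperiod sensitivity). With the two predictor
#' levels this reduces to \eqn{\hat\alpha = } mean(tt | SD) and
#' \eqn{\hat\beta = } (mean(tt | LD) - mean(tt | SD)) / (mean(dls | LD) -
#' mean(dls | SD)).
#'
#' For sensitive genotypes the slope is biased relative to the hinge slope:
#' upward when the true critical photoperiod lies below the SD daylength
#' mean, downward when above (part of the SD-LD daylength contrast then
#' falls on the flat limb of the true reaction norm).
#'
#' @inheritParams fit_hinge
#' @param threshold SD/LD classification threshold, hours.
#' @return A one-row `prn_fit` data frame (see [fit_hinge()]); `threshold`
#'   and `se_threshold` are `NA` — this method does not estimate a critical
#'   photoperiod.
#' @examples
#' fit_ld_sd(dls = c(12.0, 12.2, 15.4, 15.6), tt = c(800, 820, 900, 940))
#' @export
fit_ld_sd <- function(dls, tt, threshold = 13.5) {
  ok <- is.finite(dls) & is.finite(tt)
  dls <- dls[ok]; tt <- tt[ok]
  cls <- classify_sd_ld(dls, threshold)
  if (sum(cls == "SD") < 2 || sum(cls == "LD") < 2) {
    stop("LD-SD fit needs >= 2 observations in each daylength class ",
         "(got ", sum(cls == "SD"), " SD, ", sum(cls == "LD"), " LD); ",
         "for a single class summarize the intercept only", call. = FALSE)
  }
  grp_mean <- tapply(dls, cls, mean)
  x <- grp_mean[cls] - grp_mean[["SD"]]     # SD mean offset to zero
  fit <- stats::lm(tt ~ x)
  co <- summary(fit)$coefficients
  rss <- sum(stats::resid(fit)^2)
  flags <- if (co["x", "Estimate"] < 0) "negative_slope" else ""
  new_prn_fit(method = "ld_sd",
              intercept = co["(Intercept)", "Estimate"],
              se_intercept = co["(Intercept)", "Std. Error"],
              threshold = NA_real_, se_threshold = NA_real_,
              slope = co["x", "Estimate"],
              se_slope = co["x", "Std. Error"],
              rmse = sqrt(rss / length(tt)), n_obs = length(tt),
              flags = flags)
}

#' Fit reaction norms for every genotype in a trial network
#'
#' Applies [fit_hinge()] or [fit_ld_sd()] genotype by genotype to an
#' envirotyped (and typically latent-adjusted) trial table. Genotypes whose
#' data do not support the requested fit (insufficient environments, no
#' daylength contrast, one-sided coverage) are recorded as failures with the
#' reason, not raised as errors.
#'
#' @param met Data frame with columns `genotype_id`, `env_id`, `dls`
#'   (hours) and `tt_em_ant` (deg C day).
#' @param method `"hinge"` or `"ld_sd"`.
#' @param sd_ld_threshold SD/LD classification threshold for the LD-SD
#'   method, hours.
#' @param min_side,boot_B,boot_seed Passed to [fit_hinge()].
#' @return A list: `fits` — data frame with one `prn_fit` row per genotype
#'   (prefixed by `genotype_id`), also the (alpha, beta) trait space of the
#'   panel; `failures` — data frame `genotype_id`, `message`.
#' @export
fit_panel <- function(met, method = c("hinge", "ld_sd"),
                      sd_ld_threshold = 13.5, min_side = 3, boot_B = 0,
                      boot_seed = 1) {
  method <- match.arg(method)
  need <- c("genotype_id", "env_id", "dls", "tt_em_ant")
  miss <- setdiff(need, names(met))
  if (length(miss)) {
    stop("met is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fits <- list(); fails <- list()
  for (g in unique(met$genotype_id)) {
    d <- met[met$genotype_id == g, ]
    res <- tryCatch(
      withCallingHandlers({
        if (method == "hinge") {
          fit_hinge(d$dls, d$tt_em_ant, min_side = min_side,
                    boot_B = boot_B, boot_seed = boot_seed)
        } else {
          fit_ld_sd(d$dls, d$tt_em_ant, threshold = sd_ld_threshold)
        }
      }, warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        genotype_id = g, message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      fits[[length(fits) + 1L]] <- cbind(genotype_id = g, res)
    }
  }
  list(
    fits = if (length(fits)) do.call(rbind, fits) else NULL,
    failures = if (length(fails)) do.call(rbind, fails) else NULL
  )
}
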
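#' Configuration for a full pipeline run
#'
#' Collects every setting the pipeline depends on, so that a run is a pure
#' function of (inputs, config). All stochastic stages (simulation,
#' bootstrap) derive their streams from `seed`.
#'
#' @param cardinals A [cardinal_temps()] object.
#' @param twilight Twilight coefficient, degrees.
#' @param tt_sow_em Sowing-to-emergence thermal time, deg C day.
#' @param sd_ld_threshold SD/LD classification threshold, hours.
#' @param boot_B Bootstrap replicates for the hinge threshold SE.
#' @param seed Integer seed.
#' @param method Reaction-norm fitting method, `"hinge"` or `"ld_sd"`.
#' @param preset Simulation preset name for simulated runs (see
#'   [sim_preset()]), or `NULL`.
#' @param sim_overrides Named list of [sim_config()] overrides applied on
#'   top of the preset (e.g. `list(resid_sd = 0)` for a noise-free run).
#' @return An object of class `run_config` (a list).
#' @export
run_config <- function(cardinals = cardinal_temps(), twilight = 6,
                       tt_sow_em = 76, sd_ld_threshold = 13.5,
                       boot_B = 0, seed = 1, method = "hinge",
                       preset = "d4-like", sim_overrides = list()) {
  stopifnot(inherits(cardinals, "cardinal_temps"))
  structure(
    list(cardinals = cardinals, twilight = twilight, tt_sow_em = tt_sow_em,
         sd_ld_threshold = sd_ld_threshold, boot_B = boot_B,
         seed = as.integer(seed), method = method, preset = preset,
         sim_overrides = sim_overrides),
    class = "run_config"
  )
}

#' Run the full simulated pipeline
#'
#' Executes the whole analysis end to end on a simulated trial network:
#' simulate environments and a genotype panel, forward-simulate flowering
#' phenotypes, envirotype sensed daylengths and recompute thermal times from
#' the phenotypes, adjust for environment latent effects using the
#' insensitive genotypes as a control group, and fit a reaction norm per
#' genotype. All artifacts are written as UTF-8 CSVs plus a JSON run report
#' under `out_dir`; rerunning with the same config is byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed). `NULL` skips
#'   writing and just returns the artifacts.
#' @return (Invisibly when writing) a list: `envirotypes`, `met`
#'   (envirotyped + adjusted), `deviations`, `fits`, `failures`, `truth`,
#'   `report`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))

  cfg <- do.call(sim_preset,
                 c(list(preset = config$preset, seed = config$seed),
                   config$sim_overrides))
  envs <- simulate_network(cfg)
  panel <- simulate_panel(cfg)
  sim <- simulate_met(envs, panel, cfg, config$cardinals, config$twilight,
                      config$tt_sow_em)
  if (!is.null(sim$dropped)) {
    note(nrow(sim$dropped), " genotype x environment pair(s) dropped ",
         "(thermal-time target unreachable)")
  }

  etab <- envirotype_network(envs, cardinals = config$cardinals,
                             twilight = config$twilight,
                             tt_sow_em = config$tt_sow_em)
  met <- envirotype_met(sim$met, envs, panel = panel,
                        cardinals = config$cardinals,
                        twilight = config$twilight,
                        tt_sow_em = config$tt_sow_em)

  controls <- data.frame(set_id = "set1",
                         genotype_id =
                           panel$genotype_id[panel$group == "insensitive"])
  adj <- latent_adjust(met, controls)

  pf <- fit_panel(adj$met[!adj$met$genotype_id %in% controls$genotype_id, ],
                  method = config$method,
                  sd_ld_threshold = config$sd_ld_threshold,
                  boot_B = config$boot_B, boot_seed = config$seed)
  if (!is.null(pf$failures)) {
    note(nrow(pf$failures), " genotype(s) could not be fitted")
  }

  report <- list(
    package_version = as.character(utils::packageVersion("maizePRN")),
    seed = config$seed, preset = config$preset, method = config$method,
    config = list(
      cardinals = unclass(config$cardinals), twilight = config$twilight,
      tt_sow_em = config$tt_sow_em,
      sd_ld_threshold = config$sd_ld_threshold, boot_B = config$boot_B),
    rows = list(environments = length(envs), panel = nrow(panel),
                met = nrow(met), envirotypes = nrow(etab),
                fits = if (is.null(pf$fits)) 0L else nrow(pf$fits)),
    warnings = warnings_log
  )

  out <- list(envirotypes = etab, met = adj$met, deviations = adj$deviations,
              fits = pf$fits, failures = pf$failures, truth = sim$truth,
              report = report)
  if (is.null(out_dir)) return(out)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(etab, file.path(out_dir, "envirotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(adj$met, file.path(out_dir, "met_adjusted.csv"),
                   row.names = FALSE)
  utils::write.csv(adj$deviations, file.path(out_dir, "deviations.csv"),
                   row.names = FALSE)
  if (!is.null(pf$fits)) {
    utils::write.csv(pf$fits, file.path(out_dir, "fits.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}
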
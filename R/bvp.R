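#' Developmental constants for predicting the basic vegetative phase
#'
#' The basic vegetative phase (BVP) is the thermal time from crop emergence
#' to tassel initiation under short days, and approximates the duration a
#' maize genotype needs to become sensitized to photoperiod. Its prediction
#' from leaf-appearance traits uses two species-level constants:
#'
#' * `alpha_phyll_plast` — the ratio of phyllochron (thermal time between
#'   successive leaf-tip appearances) to plastochron (thermal time between
#'   successive leaf-primordium formations). Literature values for maize
#'   span 1.58-1.85; the default is the literature average, 1.73.
#' * `l_pr_em` — leaf primordia already formed at crop emergence: 4-5 in
#'   the embryo plus roughly 2 formed between germination and emergence,
#'   giving the default 5.5.
#'
#' @param alpha_phyll_plast Phyllochron/plastochron ratio, dimensionless.
#' @param l_pr_em Primordia at emergence, > 0.
#' @return An object of class `bvp_constants`.
#' @export
bvp_constants <- function(alpha_phyll_plast = 1.73, l_pr_em = 5.5) {
  if (!is.numeric(alpha_phyll_plast) || length(alpha_phyll_plast) != 1L ||
      alpha_phyll_plast <= 0) {
    stop("alpha_phyll_plast must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(l_pr_em) || length(l_pr_em) != 1L || l_pr_em <= 0) {
    stop("l_pr_em must be a single positive number", call. = FALSE)
  }
  structure(list(alpha_phyll_plast = alpha_phyll_plast, l_pr_em = l_pr_em),
            class = "bvp_constants")
}

#' Predict the basic vegetative phase from leaf development traits
#'
#' Thermal time from crop emergence to tassel initiation, predicted as
#' \deqn{Tt_{em-TI} = \frac{P_{tip}}{\alpha_{phyll/plast}} (LF - L_{pr,em})}
#' i.e. the plastochron (phyllochron divided by the phyllochron/plastochron
#' ratio) times the number of leaf primordia still to be formed after
#' emergence. Tassel initiation occurs when the last leaf primordium forms,
#' so this counts primordium-formation intervals at the plastochron rate.
#'
#' @param phyllochron Thermal time between successive leaf-tip appearances,
#'   deg C day per leaf, > 0. Vectorized.
#' @param final_leaf_number Final leaf number (may be fractional: trait
#'   values are typically BLUEs). Must exceed `constants$l_pr_em`.
#' @param constants A [bvp_constants()] object.
#' @return Predicted BVP(s) in deg C day.
#' @examples
#' predict_bvp(34.6, 16.5)   # 220 degC day
#' @export
predict_bvp <- function(phyllochron, final_leaf_number,
                        constants = bvp_constants()) {
  stopifnot(inherits(constants, "bvp_constants"))
  phyllochron <- as.numeric(phyllochron)
  final_leaf_number <- as.numeric(final_leaf_number)
  if (any(phyllochron <= 0)) {
    stop("phyllochron must be positive", call. = FALSE)
  }
  if (any(final_leaf_number <= constants$l_pr_em)) {
    stop("invalid genotype: final leaf number must exceed primordia at ",
         "emergence (", constants$l_pr_em, ")", call. = FALSE)
  }
  (phyllochron / constants$alpha_phyll_plast) *
    (final_leaf_number - constants$l_pr_em)
}

# Percentiles of the panel-wide BVP distribution (deg C day) used as common
# maturity references: 5th (early), 50th (median), 95th (late).
.bvp_reference_values <- c(early = 239, median = 326, late = 434)

#' Common maturity reference values for the basic vegetative phase
#'
#' Named reference BVP values corresponding to the 5th (early maturity),
#' 50th (median) and 95th (late maturity) percentiles of the BVP
#' distribution of a diverse maize panel. Used to envirotype sensed
#' daylength when genotype-specific BVPs are unavailable, or to bracket
#' maturity classes within one environment.
#'
#' @param label One of `"early"`, `"median"`, `"late"`.
#' @return A list with `label` and `bvp_value` (deg C day).
#' @examples
#' reference_bvp("median")$bvp_value   # 326
#' @export
reference_bvp <- function(label) {
  if (length(label) != 1L || !label %in% names(.bvp_reference_values)) {
    stop("unknown maturity reference '", paste(label, collapse = ","),
         "'; expected one of: ",
         paste(names(.bvp_reference_values), collapse = ", "), call. = FALSE)
  }
  list(label = label, bvp_value = unname(.bvp_reference_values[label]))
}

#' Empirical percentiles of a BVP distribution
#'
#' Linear-interpolation empirical quantiles (the common type-7 convention)
#' of a set of BVP values, e.g. to derive maturity reference points from a
#' genotype panel.
#'
#' @param bvps Numeric vector of BVP values, length >= 2.
#' @param probs Probabilities in `[0, 1]`.
#' @return Named numeric vector of quantiles.
#' @export
bvp_percentiles <- function(bvps, probs = c(0.05, 0.5, 0.95)) {
  bvps <- as.numeric(bvps)
  if (length(bvps) < 2L) stop("need at least 2 BVP values", call. = FALSE)
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]", call. = FALSE)
  stats::quantile(bvps, probs = probs, type = 7)
}

#' Read a genotype development CSV
#'
#' Expects columns `genotype_id`, `phyllochron`, `final_leaf_number` and
#' optionally `bvp`. When `bvp` is present and non-missing it overrides the
#' prediction (for users supplying measured values); otherwise BVP is
#' predicted via [predict_bvp()].
#'
#' @param path Path to a CSV file.
#' @param constants A [bvp_constants()] object.
#' @return A `data.frame` with columns `genotype_id`, `phyllochron`,
#'   `final_leaf_number`, `bvp`.
#' @export
read_genotypes_csv <- function(path, constants = bvp_constants()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype_id", "phyllochron", "final_leaf_number")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$genotype_id)) {
    stop(path, ": duplicated genotype_id", call. = FALSE)
  }
  pred <- predict_bvp(raw$phyllochron, raw$final_leaf_number, constants)
  if ("bvp" %in% names(raw)) {
    supplied <- !is.na(raw$bvp)
    raw$bvp[!supplied] <- pred[!supplied]
  } else {
    raw$bvp <- pred
  }
  if (any(raw$bvp <= 0)) stop(path, ": bvp must be positive", call. = FALSE)
  raw[, c("genotype_id", "phyllochron", "final_leaf_number", "bvp")]
}
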
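---
title: "Modeling flowering time plasticity as a physiological reaction norm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling flowering time plasticity as a physiological reaction norm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizePRN)
```

## The model

Flowering time in maize multi-environment trials (METs) mixes two
physiological signals. Temperature speeds or slows development throughout
the life cycle; photoperiod acts only after a genotype becomes *sensitized*,
and in this short-day species long days above a critical photoperiod delay
the reproductive transition. maizePRN models the resulting reaction norm on
physiological scales: the response is thermal time from crop emergence to
anthesis, $Tt_{em\text{-}ant}$ (°Cd), and the environmental index is the
*sensed daylength* $DL_s$ (h) — the photoperiod on the calendar day the
genotype reaches its basic vegetative phase (BVP) in that environment. For
a photoperiod-sensitive genotype the reaction norm is the continuous
bilinear (hinge) function

$$Tt_{em\text{-}ant} = \alpha + \beta\,(DL_s - e)_+ + \varepsilon,$$

whose three parameters are physiological components of flowering time:
$\alpha$ is the flowering time *per se* (°Cd, the thermal duration absent
photoperiod delay), $e$ the critical photoperiod (h) and $\beta$ the
photoperiod sensitivity (°Cd h⁻¹).

Fitting this from MET data requires four supporting computations, each a
module of the package:

1. **Thermal time** (`cardinal_temps()`, `accumulate_tt()`,
   `date_at_threshold()`). Daily mean temperature is converted to a
   developmental increment either by the classic linear degree-day rule
   (base 8 °C, optimum cutoff 30 °C) or by an asymmetric beta response that
   falls back to zero at a 43 °C ceiling, scaled by `t_scale` (default
   `t_opt - t_min` = 22 °C) so both forms accumulate on comparable °Cd
   scales. Accumulation is day-inclusive: the start date's increment
   counts, and a threshold is "reached" on the first day the cumulative sum
   equals or exceeds it. These cardinal values are typical for maize and
   fully configurable; any reanalysis intending to match a specific prior
   parameterization must supply its own cardinals.
2. **Daylength** (`cbm_daylength()`, `photoperiod_change_rate()`). The CBM
   astronomical model (revolution angle → solar declination → daylength)
   with a twilight coefficient, default 6° (civil twilight), under which
   plants are generally considered to perceive light. All trigonometry is
   in radians; day 366 is folded onto 365 (a sub-minute effect); polar
   day/night clamp to 24/0 h with a warning rather than erroring, although
   maize environments never reach those latitudes.
3. **Basic vegetative phase** (`predict_bvp()`). The thermal time from
   emergence to tassel initiation under short days, predicted as
   $({P_{tip}}/{\alpha_{phyll/plast}})(LF - L_{pr,em})$ from the
   phyllochron and final leaf number, with the phyllochron/plastochron
   ratio fixed at the literature average 1.73 (reported range 1.58–1.85)
   and 5.5 leaf primordia present at emergence. Panel-level maturity
   references (`reference_bvp()`) are 239/326/434 °Cd for
   early/median/late maturity — the 5th/50th/95th percentiles of the BVP
   distribution of a diverse maize panel.
4. **Envirotyping** (`sensed_daylength()`, `envirotype_network()`).
   Emergence is the observed date when recorded, otherwise the crossing of
   76 °Cd from sowing; sensitization is the crossing of the BVP from
   emergence; $DL_s$ and the daily photoperiodic change rate are evaluated
   on that day. Because sensitization dates are integers, $DL_s$ is a
   piecewise-constant function of the BVP.

## Latent-variable adjustment

Thermal times recomputed from MET phenotypes absorb every
environment-specific influence that is not temperature: management,
drought, weather-data bias. Photoperiod-insensitive control genotypes are
expected to show a constant $Tt_{em\text{-}ant}$ across environments, so
their per-environment deviations from their across-environment mean
estimate these latent effects. `latent_adjust()` subtracts those deviations
from every other genotype in the corresponding environment; control
observations are pinned at the overall mean, and each environment must map
to exactly one control set (trials assembled from different projects
rarely share a single control group). Two identifiability facts shape the
implementation and the simulator:

* deviations of a control set sum to zero across its environments by
  construction, and
* a latent effect *common to every environment* is indistinguishable from
  a shift of every intercept. The simulator therefore centers its drawn
  environment offsets to mean zero, which makes "recover the offset-free
  truth exactly" a well-posed property when controls are noise-free.

## Fitting

`fit_hinge()` estimates $(\alpha, e, \beta)$ by profile least squares: for
any fixed threshold the model is linear and solved in closed form; the
profile RSS is minimized over candidate thresholds consisting of the
observed daylengths and their midpoints, followed by continuous refinement
(1-D minimization) inside every inter-candidate segment, since the
piecewise-smooth profile need not attain its minimum at a data value. A
candidate is admissible only with at least three points strictly on each
side, which prevents degenerate segment fits; the limit $e = \min(DL_s)$,
where the hinge is exactly a reparameterized straight line, is always
evaluated too, so the bilinear fit never has a larger RSS than the best
straight line. If that limit wins, no threshold is detectable in the
observed range and the fit is flagged `boundary_threshold`; fitted negative
slopes are reported but flagged as biologically unexpected rather than
constrained away. Standard errors for $\alpha$ and $\beta$ are conditional
OLS errors at $\hat e$; the threshold SE has no closed form and is
estimated by a seeded nonparametric bootstrap (`boot_B` resamples of
observations). RMSE is the root mean squared residual of the full bilinear
model.

`fit_ld_sd()` is the two-parameter fallback when threshold detection is
impossible (sparse or gapped daylength coverage, insensitive genotypes).
Environments are classified short-day/long-day at a fixed 13.5 h (a value
exactly at the threshold is SD — a closed lower segment, arbitrary but
fixed); each observation's predictor is recoded to its class's mean
daylength over the genotype's own observed environments and shifted so the
SD mean is zero. The OLS intercept is then the flowering time *per se*
evaluated at the SD daylength mean, and the slope is the sensitivity.

### Bias of the LD–SD slope

The two-level slope divides the long-day delay by the daylength contrast
from the *SD mean* rather than from the true critical photoperiod. In the
physiological frame where short days are non-inductive (SD observations sit
at $\alpha$) and the delay accrues from $e$ upward, the estimate is
$\beta\,( \bar{x}_{LD} - e)/(\bar{x}_{LD} - \bar{x}_{SD})$: upward-biased
when $e < \bar{x}_{SD}$ and downward-biased when $e > \bar{x}_{SD}$. A
subtlety worth recording: if data are generated from the *pure* hinge
(short-day observations also rise whenever their daylength exceeds $e$),
the two-level slope can never exceed the true slope — the hinge minus
$\beta \cdot DL_s$ is non-increasing, so the recoded group means always
dilute it. The classic bias-direction statement is therefore a property of
the non-inductive-SD frame, and the package's tests assert both facts
separately.

## The synthetic study system

`sim_config()` / `simulate_network()` / `simulate_panel()` /
`simulate_met()` forward-simulate the whole data-generating process with
known truth, which makes every pipeline stage testable by parameter
recovery. Choices, with rationale:

* **Weather**: daily mean temperature is an annual sinusoid peaking in
  late July, with amplitude scaled by latitude/45 and Gaussian day-to-day
  noise (default mean 14 °C, amplitude 10 °C, noise SD 2 °C); `tmin`/`tmax`
  sit ±5 °C around it. This reproduces the feature that matters here — the
  seasonal pace of thermal-time accumulation and its latitude dependence —
  and deliberately omits autocorrelated weather, spatial correlation among
  sites and elevation effects, so passing tests say nothing about those.
* **Networks**: latitudes and sowing days of year drawn uniformly; the
  `"d4-like"` preset (37 environments, 14 genotypes, half insensitive)
  mixes a tropical autumn-sown stratum (~30% of environments, 14–20°N,
  sowing DOY 280–340) with a temperate spring-sown one (25–50°N, DOY
  60–150), because real maize METs obtain short-day coverage from
  off-season tropical nurseries; spring-only networks never sense below
  ~13.5 h. The `"d5-like"` preset (19 environments, 236 genotypes) gives
  its 3-environment tropical stratum a warm climate (mean 25 °C) so
  sensitization lands in boreal winter, reproducing the characteristic
  daylength-coverage gap (~12.5–14.5 h) that forces the LD–SD method on
  diversity panels.
* **Genotypes**: flowering time *per se* ~ N(850, 50²) °Cd, critical
  photoperiod ~ N(13, 0.5²) h, sensitivity ~ N(60, 15²) °Cd h⁻¹ truncated
  at zero, with a configurable insensitive fraction at $\beta = 0$;
  phyllochron and final leaf number are drawn and converted to BVPs by the
  emergence-to-tassel-initiation formalism, so the simulated panel's BVP
  distribution is internally consistent with its development traits.
* **Observation model**: the target thermal time $\alpha + \beta(DL_s -
  e)_+ + \lambda_{env} + \varepsilon$ (latent offsets shared within an
  environment, centered; residual SD 20 °Cd by default) is converted to an
  anthesis *date* by forward accumulation and reported as integer days
  from sowing — the phenotype a trial records. The day snap makes the
  recomputed thermal time overshoot its target by up to one day's
  increment (typically 5–15 °Cd); this discretization, not the fitting, is
  the dominant error floor in recovery studies, and is the reason
  noise-free end-to-end tests use tolerances of one daily increment rather
  than machine precision.

## Problem sizes and numerical choices

Recovery studies in the tests and in `scripts/acceptance.R` use 100
replicate METs of 40 environments each with a single sensitive genotype —
large enough that mean absolute errors stabilize (≈7 °Cd on $\alpha$,
≈0.2 h on $e$, ≈4 °Cd h⁻¹ on $\beta$) while a full run stays under a
minute. The hinge/dense-grid equivalence check uses 50 random instances
against a 0.01 h exhaustive grid; the two agree to grid resolution except
when two local optima are nearly tied, in which case the continuous profile
must (and does) return the strictly lower RSS. Quantiles are
linear-interpolation (type 7) throughout. Ties at a threshold crossing
cannot occur (cumulative sums are compared with ≥ on the first qualifying
day); ties in the profile RSS resolve to the first candidate, and the
refinement step is skipped when the best candidate already has zero
residual.

## Known limitations

* Sub-daily temperature variation is ignored: the response function is
  applied to the daily mean, one increment per day. Hourly integration
  would differ most in strongly continental climates.
* The sowing-to-emergence duration (76 °Cd) and the cardinal temperatures
  are species-level defaults, not estimated from data.
* The LD–SD method inherits the bias described above; its estimates are
  comparable across genotypes observed in the *same* network but not
  directly between networks with different SD daylength means.
* Control-group adjustment assumes the controls' own residual structure is
  representative; a control set with its own environmental sensitivities
  (e.g. drought escape) would leak bias into every adjusted genotype.
* The simulator does not model vernalization, soil or canopy temperature,
  or photoperiod effects on phases after tassel initiation.
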
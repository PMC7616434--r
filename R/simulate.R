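#' Staircase voltage protocol
#'
#' The experimental protocol that quantizes threshold voltages: the
#' electrode is held at `start` volts for `dwell` seconds and, until the
#' tick lifts, increased in magnitude by `step` volts and reconnected. The
#' recorded threshold is therefore the first protocol voltage at or above
#' the tick's true threshold (an upward-quantized measurement).
#'
#' @param start Starting voltage magnitude, V.
#' @param step Staircase increment, V (> 0).
#' @param dwell Dwell time per step, s (metadata).
#' @param polarity `"+"` or `"-"`.
#' @return A `staircase_protocol`.
#' @export
staircase_protocol <- function(start = 50, step = 50, dwell = 20,
                               polarity = c("+", "-")) {
  polarity <- match.arg(polarity)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  structure(list(start = start, step = step, dwell = dwell,
                 polarity = polarity), class = "staircase_protocol")
}

#' Generative model of between-tick threshold variability
#'
#' Each tick's true threshold field is `threshold_field` times a lognormal
#' multiplier with unit mean and coefficient of variation `cv` (lognormal
#' keeps thresholds positive; no distributional information on the real
#' variability exists, so this is a labelled stand-in). `partial_band` is
#' the fraction below threshold within which a tick is visibly pulled but
#' holds on ("partially lifted"); by default it is derived from `cv` so
#' that, at the calibrated full-lift rate, the partial-lift rate matches
#' the observed one. Humidity covariates are Gaussian.
#'
#' @param threshold_field Mean threshold field E*, V/m (default 258 kV/m,
#'   the study's average threshold).
#' @param cv Between-tick coefficient of variation (default 0.15).
#' @param partial_band Fraction of threshold; `NULL` derives it from `cv`.
#' @param spontaneous_rate Baseline probability of a spontaneous
#'   "partial lift" by locomotion, per trial.
#' @param humidity_median,humidity_sd Relative-humidity covariate, percent.
#' @return A `tick_population_model`.
#' @export
tick_population_model <- function(threshold_field = 258e3, cv = 0.15,
                                  partial_band = NULL,
                                  spontaneous_rate = 0.05,
                                  humidity_median = 58.5, humidity_sd = 3) {
  if (threshold_field <= 0 || cv < 0) stop("E* > 0 and cv >= 0 required", call. = FALSE)
  sdlog <- sqrt(log(1 + cv^2))
  if (is.null(partial_band))
    partial_band <- 1 - exp(-(qnorm(0.90) - qnorm(0.75)) * sdlog)
  structure(list(threshold_field = threshold_field, cv = cv, sdlog = sdlog,
                 meanlog = -sdlog^2 / 2, partial_band = partial_band,
                 spontaneous_rate = spontaneous_rate,
                 humidity_median = humidity_median, humidity_sd = humidity_sd),
            class = "tick_population_model")
}

#' @export
print.tick_population_model <- function(x, ...) {
  cat(sprintf(paste0("<tick_population_model> E* = %.4g kV/m, cv = %g, ",
                     "partial band = %.3g, spontaneous rate = %g\n"),
              x$threshold_field / 1e3, x$cv, x$partial_band, x$spontaneous_rate))
  invisible(x)
}

draw_multiplier <- function(pop, n) {
  if (pop$cv == 0) rep(1, n) else rlnorm(n, pop$meanlog, pop$sdlog)
}

draw_humidity <- function(pop, n) {
  pmin(pmax(rnorm(n, pop$humidity_median, pop$humidity_sd), 20), 95)
}

#' Simulate a staircase threshold experiment
#'
#' Per tick, draws a true threshold voltage V* = E* d (1 + noise) and
#' records the first protocol voltage at or above it, emulating the
#' 50-V staircase design at six electrode distances.
#'
#' @param pop A [tick_population_model()].
#' @param protocol A [staircase_protocol()].
#' @param distances Electrode gaps, m (default 1.5-4.0 mm in 0.5 mm steps).
#' @param n_per_distance Ticks per distance (>= 1; default 12).
#' @param seed Integer seed; output is bit-reproducible.
#' @return A threshold dataset: data.frame with columns `tick_id`,
#'   `distance_mm`, `threshold_voltage_V`, `polarity`, `humidity_pct`.
#' @export
simulate_staircase_experiment <- function(pop = tick_population_model(),
                                          protocol = staircase_protocol(),
                                          distances = seq(1.5e-3, 4e-3, by = 5e-4),
                                          n_per_distance = 12L,
                                          seed = NULL) {
  if (n_per_distance < 1) stop("n_per_distance must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  hi_plausible <- pop$threshold_field * max(distances) *
    exp(pop$meanlog + 3 * pop$sdlog)
  if (protocol$start >= hi_plausible)
    warning("protocol start voltage above all plausible thresholds; ",
            "every recorded value will be the start voltage")
  rows <- lapply(seq_along(distances), function(i) {
    d <- distances[i]
    vstar <- pop$threshold_field * d * draw_multiplier(pop, n_per_distance)
    k <- pmax(0, ceiling((vstar - protocol$start) / protocol$step - 1e-12))
    data.frame(
      tick_id = sprintf("d%02d_t%02d", i, seq_len(n_per_distance)),
      distance_mm = d * 1e3,
      threshold_voltage_V = protocol$start + k * protocol$step,
      polarity = protocol$polarity,
      humidity_pct = draw_humidity(pop, n_per_distance))
  })
  do.call(rbind, rows)
}

# Field-per-(V/d) of the rig at a given gap, taken from the solver (the
# rig's field at the tick is slightly below the parallel-plate V/d); cached
# per geometry since it is voltage-independent by linearity.
.factor_cache <- new.env(parent = emptyenv())

#' Rig geometry factor
#'
#' Ratio of the solved on-axis field at the tick's mid-height (0.5 mm) to
#' the nominal parallel-plate field V/d, for the rig geometry at gap `d`
#' (about 0.89 at d = 3 mm). Computed from the solver, not hard-coded.
#'
#' @param gap Electrode gap, m.
#' @param sphere_diameter Electrode diameter, m.
#' @param probe_height Probe height above the plate, m.
#' @return Dimensionless factor.
#' @export
rig_geometry_factor <- function(gap, sphere_diameter = 0.015,
                                probe_height = 5e-4) {
  key <- paste(signif(gap, 8), signif(sphere_diameter, 8),
               signif(probe_height, 8), sep = "_")
  if (!is.null(.factor_cache[[key]])) return(.factor_cache[[key]])
  vref <- 750
  scene <- build_rig_scene(gap, vref, sphere_diameter = sphere_diameter)
  sol <- solve_axisymmetric(scene, default_rig_grid(gap))
  fac <- probe(sol, c(0, scene$meta$plate_top + probe_height))$Emag / (vref / gap)
  .factor_cache[[key]] <- fac
  fac
}

#' Calibrate a live-tick population to observed lift rates
#'
#' Closed-form calibration of the lognormal threshold population so that at
#' an applied field `E_app` the probability of a full lift is `p_full` and
#' of a full-or-partial lift is `p_full + p_partial` (the fixed-voltage
#' experiment's observed 75% / 15%).
#'
#' @param applied_field Field at the tick, V/m.
#' @param p_full,p_partial Target outcome probabilities.
#' @param cv Between-tick coefficient of variation.
#' @param spontaneous_rate Baseline spontaneous partial-lift rate.
#' @return A [tick_population_model()].
#' @export
calibrate_lift_population <- function(applied_field, p_full = 0.75,
                                      p_partial = 0.15, cv = 0.15,
                                      spontaneous_rate = 0.05) {
  stopifnot(applied_field > 0, p_full > 0, p_full + p_partial < 1)
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2
  estar <- applied_field / exp(meanlog + qnorm(p_full) * sdlog)
  band <- 1 - exp(-(qnorm(p_full + p_partial) - qnorm(p_full)) * sdlog)
  tick_population_model(threshold_field = estar, cv = cv, partial_band = band,
                        spontaneous_rate = spontaneous_rate)
}

#' Simulate fixed-voltage lift trials
#'
#' Emulates the 20 + 20 trial design: treatment ticks experience the rig
#' field at `applied_voltage` across `gap` (V/d scaled by the solver's
#' geometry factor) and fully lift when it exceeds their drawn threshold,
#' partially lift when it falls in the partial-lift band just below
#' threshold, and otherwise may show a spontaneous partial lift; control
#' ticks see no field and only the spontaneous movement. The default
#' population is calibrated to the observed outcome rates (75% fully, 15%
#' partially lifted) at the +750 V reference condition.
#'
#' @param pop A [tick_population_model()]; `NULL` calibrates to the study's
#'   outcome rates via [calibrate_lift_population()].
#' @param applied_voltage Electrode voltage in treatment trials, V.
#' @param gap Electrode gap, m.
#' @param n_treatment,n_control Trial counts (>= 0).
#' @param seed Integer seed.
#' @param geometry_factor Field/(V/d) ratio; `NULL` uses
#'   [rig_geometry_factor()] (solver-derived).
#' @return A [contingency_table()] rows treatment/control, columns
#'   fully/partially/not lifted.
#' @export
simulate_lift_trials <- function(pop = NULL, applied_voltage = 750,
                                 gap = 3e-3, n_treatment = 20L,
                                 n_control = 20L, seed = NULL,
                                 geometry_factor = NULL) {
  stopifnot(n_treatment >= 0, n_control >= 0)
  if (is.null(geometry_factor)) geometry_factor <- rig_geometry_factor(gap)
  if (is.null(pop))
    pop <- calibrate_lift_population(750 / gap * geometry_factor)
  field <- applied_voltage / gap * geometry_factor
  if (!is.null(seed)) set.seed(seed)
  outcome <- function(n, E) {
    if (n == 0) return(c(fully = 0L, partially = 0L, not = 0L))
    thr <- pop$threshold_field * draw_multiplier(pop, n)
    full <- E >= thr
    part <- !full & E >= (1 - pop$partial_band) * thr
    idle <- !full & !part
    part[idle] <- runif(sum(idle)) < pop$spontaneous_rate
    c(fully = sum(full), partially = sum(part), not = sum(!full & !part))
  }
  counts <- rbind(treatment = outcome(n_treatment, field),
                  control = outcome(n_control, 0))
  contingency_table(counts)
}

#' Simulate the polarity-comparison experiment
#'
#' Two groups of ticks tested at the same gap with electrodes of opposite
#' polarity, both drawing |threshold| from the same distribution -- the
#' induced-polarization null under which a Mann-Whitney comparison of the
#' two groups is non-significant at the nominal rate. `negative_scale`
#' rescales the negative group's thresholds to emulate a fixed-charge
#' alternative (e.g. 2 doubles them).
#'
#' @param pop A [tick_population_model()].
#' @param protocol A [staircase_protocol()].
#' @param gap Electrode gap, m (default 2.5 mm).
#' @param n_per_group Ticks per polarity group (>= 1; default 12).
#' @param seed Integer seed.
#' @param negative_scale Threshold multiplier of the negative group (1 =
#'   polarity-symmetric null).
#' @return A threshold dataset (same schema as
#'   [simulate_staircase_experiment()]) with `polarity` +/-; voltages are
#'   magnitudes.
#' @export
simulate_polarity_groups <- function(pop = tick_population_model(),
                                     protocol = staircase_protocol(),
                                     gap = 2.5e-3, n_per_group = 12L,
                                     seed = NULL, negative_scale = 1) {
  if (n_per_group < 1) stop("n_per_group must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  quantize <- function(vstar)
    protocol$start + pmax(0, ceiling((vstar - protocol$start) /
                                       protocol$step - 1e-12)) * protocol$step
  one_group <- function(pol, scale) {
    vstar <- pop$threshold_field * gap * draw_multiplier(pop, n_per_group) * scale
    data.frame(tick_id = sprintf("%s%02d", ifelse(pol == "+", "p", "n"),
                                 seq_len(n_per_group)),
               distance_mm = gap * 1e3,
               threshold_voltage_V = quantize(vstar),
               polarity = pol,
               humidity_pct = draw_humidity(pop, n_per_group))
  }
  rbind(one_group("+", 1), one_group("-", negative_scale))
}
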
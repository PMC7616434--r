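#' Point-particle model of a tick in an electric field
#'
#' The tick (an *Ixodes ricinus* nymph, typical mass about 0.1 mg) is
#' treated as a point particle at the probe height. `charge` is the net
#' surface charge for the fixed-charge coupling; `polarizability` is the
#' effective polarizability of the induced-dipole coupling (no measured
#' value exists -- it is used only for sign/direction arguments, never for
#' quantitative force claims).
#'
#' @param mass Mass, kg (default 1e-7, i.e. 0.1 mg).
#' @param g Gravitational acceleration, m/s^2.
#' @param charge Net charge, C.
#' @param polarizability Effective polarizability, C m^2/V.
#' @return A `particle_model`.
#' @export
particle_model <- function(mass = 1e-7, g = 9.81, charge = 0,
                           polarizability = 0) {
  if (mass <= 0 || g <= 0) stop("mass and g must be positive", call. = FALSE)
  structure(list(mass = mass, g = g, charge = charge,
                 polarizability = polarizability), class = "particle_model")
}

#' @export
print.particle_model <- function(x, ...) {
  cat(sprintf("<particle_model> m = %g mg, q = %g pC, alpha = %g C m^2/V\n",
              x$mass * 1e6, x$charge * 1e12, x$polarizability))
  invisible(x)
}

#' Fit the distance-voltage threshold law
#'
#' Fits the zero-intercept linear law V = G d to per-tick threshold
#' voltages: by definition zero distance needs zero voltage, so the
#' intercept is forced through the origin and the gradient G is the
#' threshold electric field (V/m). The closed form is
#' G = sum(d V) / sum(d^2). R-squared is computed about zero (uncentered),
#' the standard convention for forced-origin regression, and the overall F
#' statistic has (1, n-1) degrees of freedom. A free-intercept model is
#' fitted alongside and compared by ANOVA, with the intercept confidence
#' interval reported, so the forced origin can be checked against the data.
#'
#' @param data A threshold dataset: data.frame with columns `distance_mm`
#'   and `threshold_voltage_V` (the CSV schema of the package; extra
#'   columns such as `tick_id`, `polarity`, `humidity_pct` are carried
#'   along).
#' @return A `threshold_fit` object; see [coef.threshold_fit()],
#'   [predict.threshold_fit()], [plot.threshold_fit()],
#'   [simulate.threshold_fit()].
#' @examples
#' d <- data.frame(distance_mm = c(1, 2, 3),
#'                 threshold_voltage_V = c(290, 580, 870))
#' fit <- fit_threshold_law(d)
#' coef(fit)            # 290 kV/m in V/m
#' predict(fit, distance = 1e-4)  # voltage needed across 0.1 mm
#' @export
fit_threshold_law <- function(data) {
  if (!all(c("distance_mm", "threshold_voltage_V") %in% names(data)))
    stop("data needs columns distance_mm and threshold_voltage_V", call. = FALSE)
  d <- data$distance_mm * 1e-3
  v <- data$threshold_voltage_V
  if (length(unique(d)) < 2)
    stop("rank deficiency: need at least 2 distinct distances", call. = FALSE)
  if (any(v <= 0)) stop("all threshold voltages must be positive", call. = FALSE)
  eng <- regression_through_origin(d, v)
  structure(c(eng, list(data = data)), class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("Zero-intercept threshold law  V = G d\n")
  cat(sprintf("  gradient (threshold field) G = %.4g kV/m\n", x$slope / 1e3))
  cat(sprintf("  R^2 = %.3f (uncentered), F(%d,%d) = %.1f, p = %.3g\n",
              x$r.squared, x$df[1], x$df[2], x$fstatistic, x$p.value))
  invisible(x)
}

#' @export
summary.threshold_fit <- function(object, ...) {
  structure(object, class = c("summary.threshold_fit", class(object)))
}

#' @export
print.summary.threshold_fit <- function(x, ...) {
  print.threshold_fit(x)
  cat("Free-intercept comparison:\n")
  cat(sprintf("  intercept = %.3g V, 95%% CI [%.3g, %.3g] V\n",
              x$free$intercept, x$free$intercept_ci[1], x$free$intercept_ci[2]))
  cat(sprintf("  ANOVA zero- vs free-intercept: p = %.3g\n", x$free$anova_p))
  invisible(x)
}

#' @export
coef.threshold_fit <- function(object, ...) {
  c(gradient_V_per_m = object$slope)
}

#' @export
residuals.threshold_fit <- function(object, ...) {
  object$data$threshold_voltage_V - object$slope * object$data$distance_mm * 1e-3
}

#' Predictions from a threshold fit
#'
#' With `distance` given, returns the threshold voltage G d (volts); with
#' `voltage` given, returns the attraction range voltage / G (metres) -- the
#' largest gap across which a surface voltage can lift a tick.
#'
#' @param object A `threshold_fit`.
#' @param distance Gap(s), m.
#' @param voltage Surface voltage(s), V.
#' @param ... Unused.
#' @export
predict.threshold_fit <- function(object, distance = NULL, voltage = NULL, ...) {
  G <- object$slope
  if (!is.null(distance)) return(predict_threshold_voltage(G, distance))
  if (!is.null(voltage)) return(predict_attraction_range(G, voltage))
  fitted(object)
}

#' @export
fitted.threshold_fit <- function(object, ...) {
  object$slope * object$data$distance_mm * 1e-3
}

#' @export
plot.threshold_fit <- function(x, ...) {
  d <- x$data
  plot(d$distance_mm, d$threshold_voltage_V,
       xlab = "distance to electrode (mm)",
       ylab = "threshold voltage (V)",
       main = "Distance-voltage threshold law", ...)
  abline(0, x$slope * 1e-3, col = "red")
  invisible(x)
}

#' Simulate staircase datasets from a fitted threshold law
#'
#' Draws replicate staircase experiments whose true threshold field is the
#' fitted gradient, using [simulate_staircase_experiment()].
#'
#' @param object A `threshold_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param cv Between-tick coefficient of variation.
#' @param ... Passed to [simulate_staircase_experiment()].
#' @return A list of `nsim` threshold datasets.
#' @export
simulate.threshold_fit <- function(object, nsim = 1, seed = NULL, cv = 0.15, ...) {
  if (is.null(seed)) seed <- 1L
  pop <- tick_population_model(threshold_field = object$slope, cv = cv)
  dists <- sort(unique(object$data$distance_mm)) * 1e-3
  lapply(seq_len(nsim), function(i)
    simulate_staircase_experiment(pop, staircase_protocol(),
                                  distances = dists,
                                  n_per_distance = max(table(object$data$distance_mm)),
                                  seed = seed + i - 1L, ...))
}

#' Threshold voltage at a distance
#'
#' @param gradient Threshold field G, V/m.
#' @param distance Gap d, m.
#' @return G d, volts.
#' @export
predict_threshold_voltage <- function(gradient, distance) {
  stopifnot(gradient > 0, all(distance > 0))
  gradient * distance
}

#' Attraction range of a surface voltage
#'
#' The largest gap across which a host surface voltage can lift a tick:
#' d = V / G. A 30 kV surface voltage with G = 290 kV/m reaches about 10 cm.
#'
#' @param gradient Threshold field G, V/m.
#' @param surface_voltage Host surface voltage, V.
#' @return Gap, metres.
#' @export
predict_attraction_range <- function(gradient, surface_voltage) {
  stopifnot(gradient > 0)
  surface_voltage / gradient
}

#' Average threshold field over the tested distances
#'
#' For each (distance, voltage) pair, builds the rig scene, solves it, and
#' probes the field magnitude on the axis at `probe_height` above the plate
#' (the mid-height of a tick); the mean of these probe fields is the
#' average threshold field for tick attraction. Driving each distance with
#' the fitted law `voltage = G d` reproduces the study's summary value of
#' about 258 kV/m.
#'
#' @param distances Electrode gaps, m.
#' @param voltages Per-distance threshold voltages, V (same length).
#' @param probe_height Probe height above the plate surface, m.
#' @param sphere_diameter Electrode diameter, m.
#' @param grid Optional `grid_spec` (default: [default_rig_grid()] per gap).
#' @return An `avg_threshold_field` object: `$mean_field` (V/m) and
#'   `$table` of per-distance probe fields.
#' @export
average_threshold_field <- function(distances, voltages, probe_height = 5e-4,
                                    sphere_diameter = 0.015, grid = NULL) {
  stopifnot(length(distances) == length(voltages))
  if (any(probe_height >= distances))
    stop("probe_height must be below the smallest gap", call. = FALSE)
  fields <- vapply(seq_along(distances), function(i) {
    if (voltages[i] == 0) return(0)
    scene <- build_rig_scene(distances[i], voltages[i],
                             sphere_diameter = sphere_diameter)
    g <- if (is.null(grid)) default_rig_grid(distances[i]) else grid
    sol <- solve_axisymmetric(scene, g)
    probe(sol, c(0, scene$meta$plate_top + probe_height))$Emag
  }, 0)
  structure(list(mean_field = mean(fields),
                 table = data.frame(distance_mm = distances * 1e3,
                                    voltage_V = voltages,
                                    probe_field_kV_m = fields / 1e3)),
            class = "avg_threshold_field")
}

#' @export
print.avg_threshold_field <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("average threshold field: %.4g kV/m\n", x$mean_field / 1e3))
  invisible(x)
}

#' Lift condition against gravity
#'
#' A particle of mass m and charge q lifts when the electric force exceeds
#' its weight: q E >= m g. The minimum effective charge for lift at field E
#' is q_eff = m g / E (about 3.8 pC for a 0.1 mg tick at 258 kV/m).
#'
#' @param E Field magnitude at the particle, V/m.
#' @param particle A [particle_model()].
#' @param coupling `"fixed_charge"` uses the particle's own charge;
#'   `"effective_charge"` only reports the minimum charge needed.
#' @return `list(lifts = flag, effective_charge_needed = coulombs)`.
#' @export
lift_condition <- function(E, particle = particle_model(),
                           coupling = c("fixed_charge", "effective_charge")) {
  coupling <- match.arg(coupling)
  stopifnot(E >= 0)
  if (E == 0 && coupling == "effective_charge")
    stop("effective charge undefined at zero field", call. = FALSE)
  weight <- particle$mass * particle$g
  q_eff <- if (E > 0) weight / E else Inf
  lifts <- switch(coupling,
    fixed_charge = abs(particle$charge) * E >= weight,
    effective_charge = NA)
  list(lifts = lifts, effective_charge_needed = q_eff)
}

#' Mechanism-discrimination force models
#'
#' Evaluates, at one position in a solved field, the two candidate coupling
#' forces: the induced-dipole (dielectrophoretic) force
#' F = alpha grad(|E|^2) / 2, computed by central finite differences of the
#' probed field, and the fixed-charge force F = q E. Under a sign flip of
#' every boundary voltage the induced-dipole force is unchanged (it depends
#' on E^2) while the fixed-charge force is exactly negated -- the polarity
#' experiment's discriminator: equal attraction at both polarities implies
#' the induced-polarization mechanism.
#'
#' @param solution A `field_solution`.
#' @param particle A [particle_model()] with `charge` and/or
#'   `polarizability` set.
#' @param position Probe position (m), length 2 or 3 to match the solution.
#' @param delta Stencil half-width, m (default: one grid cell).
#' @return `list(induced_dipole_force =, fixed_charge_force =)`, newtons,
#'   vectors in the solution's coordinates.
#' @export
mechanism_forces <- function(solution, particle, position, delta = NULL) {
  nd <- length(solution$coords)
  stopifnot(length(position) == nd)
  if (is.null(delta)) delta <- solution$h
  offsets <- diag(delta, nd)
  pts <- rbind(position,
               do.call(rbind, lapply(seq_len(nd), function(d)
                 rbind(position + offsets[d, ], position - offsets[d, ]))))
  if (nd == 2) pts[, 1] <- abs(pts[, 1])   # mirror symmetry across the axis
  pr <- tryCatch(probe(solution, pts), error = function(e)
    stop("stencil error: ", conditionMessage(e), call. = FALSE))
  e2 <- pr$Emag^2
  grad_e2 <- vapply(seq_len(nd), function(d)
    (e2[2 * d] - e2[2 * d + 1]) / (2 * delta), 0)
  ecols <- if (nd == 2) c("Er", "Ez") else c("Ex", "Ey", "Ez")
  Evec <- as.numeric(pr[1, ecols])
  list(induced_dipole_force = particle$polarizability * grad_e2 / 2,
       fixed_charge_force = particle$charge * Evec)
}
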
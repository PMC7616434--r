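test_that("staircase records the first protocol voltage above threshold", {
  # no between-tick noise: deterministic upward quantization to 50-V steps
  pop <- tick_population_model(threshold_field = 290e3, cv = 0)
  d <- simulate_staircase_experiment(pop, staircase_protocol(start = 50, step = 50),
                                     distances = 2e-3, n_per_distance = 5,
                                     seed = 1)
  expect_true(all(d$threshold_voltage_V == 600))  # first 50-multiple >= 580
  # voltages always sit on the protocol lattice
  d2 <- simulate_staircase_experiment(seed = 4)
  expect_true(all((d2$threshold_voltage_V - 50) %% 50 == 0))
  expect_true(all(d2$threshold_voltage_V >= 50))
  expect_equal(nrow(d2), 6 * 12)
  expect_error(simulate_staircase_experiment(n_per_distance = 0), ">= 1")
  expect_warning(
    simulate_staircase_experiment(pop, staircase_protocol(start = 5000),
                                  distances = 2e-3, n_per_distance = 2,
                                  seed = 1),
    "plausible")
})

test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(simulate_staircase_experiment(seed = 8),
                   simulate_staircase_experiment(seed = 8))
  expect_false(identical(simulate_staircase_experiment(seed = 8),
                         simulate_staircase_experiment(seed = 9)))
  expect_identical(simulate_lift_trials(seed = 3, geometry_factor = 0.89),
                   simulate_lift_trials(seed = 3, geometry_factor = 0.89))
  expect_identical(simulate_polarity_groups(seed = 5),
                   simulate_polarity_groups(seed = 5))
})

test_that("staircase design recovers the threshold field within one step", {
  # upward quantization biases the fitted gradient up by at most
  # step/min(distance); over replicate seeds the recovered gradient stays in
  # [E*, E* + 50 V / 1.5 mm] almost always
  estar <- 258e3
  pop <- tick_population_model(estar, cv = 0.15)
  G <- vapply(1:200, function(s)
    fit_threshold_law(simulate_staircase_experiment(pop, seed = s))$slope, 0)
  in_band <- mean(G >= estar & G <= estar + 50 / 1.5e-3)
  expect_gte(in_band, 0.95)
  # median recovery within the quantization bound plus 2%
  expect_lt(abs(median(G) - estar), 50 / 1.5e-3 + 0.02 * estar)
})

test_that("lift trials reproduce the designed outcome structure", {
  # saturating field with no partial band or spontaneous movement:
  # everything in treatment lifts, nothing in control moves
  pop <- tick_population_model(threshold_field = 1e3, cv = 0.1,
                               partial_band = 0, spontaneous_rate = 0)
  tb <- simulate_lift_trials(pop, applied_voltage = 750, gap = 3e-3,
                             n_treatment = 15, n_control = 15, seed = 2,
                             geometry_factor = 0.89)
  expect_equal(unclass(tb)[, "fully"], c(treatment = 15, control = 0))
  expect_equal(unclass(tb)[, "not"], c(treatment = 0, control = 15))
  # zero applied voltage: the treatment group behaves like a control group
  tb0 <- simulate_lift_trials(applied_voltage = 0, seed = 6,
                              geometry_factor = 0.89)
  expect_equal(unclass(tb0)["treatment", "fully"], 0)
  expect_equal(sum(tb0), 40)
})

test_that("calibrated live-tick population hits the observed outcome rates", {
  fac <- 0.8866
  field <- 750 / 3e-3 * fac
  pop <- calibrate_lift_population(field)
  tb <- simulate_lift_trials(pop, seed = 1, geometry_factor = fac,
                             n_treatment = 20000, n_control = 10)
  p_full <- unclass(tb)["treatment", "fully"] / 20000
  p_part <- unclass(tb)["treatment", "partially"] / 20000
  expect_equal(p_full, 0.75, tolerance = 0.02)
  # field-driven partials plus spontaneous movement among the rest
  expect_equal(p_part, 0.15 + 0.10 * 0.05, tolerance = 0.1)
})

test_that("simulated lift-trial tables give chi-square like the experiment", {
  fac <- 0.8866
  chis <- vapply(1:300, function(s) {
    tb <- simulate_lift_trials(seed = s, geometry_factor = fac)
    tryCatch(unname(chi_square_independence(tb)$statistic),
             error = function(e) NA_real_)
  }, 0)
  expect_lt(abs(mean(chis, na.rm = TRUE) / 29.8 - 1), 0.15)
  ps <- vapply(1:300, function(s) {
    tb <- simulate_lift_trials(seed = s + 1000, geometry_factor = fac)
    tryCatch(chi_square_independence(tb)$p.value, error = function(e) NA_real_)
  }, 0)
  expect_gte(mean(ps < 1e-4, na.rm = TRUE), 0.99)
})

test_that("polarity groups share one threshold distribution under the null", {
  d <- simulate_polarity_groups(seed = 2)
  expect_equal(table(d$polarity)[["+"]], 12)
  expect_equal(table(d$polarity)[["-"]], 12)
  expect_true(all(d$threshold_voltage_V > 0))
  expect_true(all(d$distance_mm == 2.5))
  # type-I error of the Mann-Whitney comparison at nominal alpha = 0.05
  rej <- vapply(1:400, function(s) {
    dd <- simulate_polarity_groups(seed = s)
    x <- dd$threshold_voltage_V[dd$polarity == "+"]
    y <- dd$threshold_voltage_V[dd$polarity == "-"]
    mann_whitney_permutation(x, y, n_perm = 1500, seed = s)$p.value < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
  expect_error(simulate_polarity_groups(n_per_group = 0), ">= 1")
  # degenerate one-per-group dataset is valid and the test is powerless
  d1 <- simulate_polarity_groups(n_per_group = 1, seed = 1)
  expect_equal(nrow(d1), 2)
  expect_equal(mann_whitney_permutation(
    d1$threshold_voltage_V[1], d1$threshold_voltage_V[2])$p.value, 1)
})

test_that("a fixed-charge asymmetry is detected with high power", {
  rej <- vapply(1:150, function(s) {
    dd <- simulate_polarity_groups(seed = s, negative_scale = 2)
    x <- dd$threshold_voltage_V[dd$polarity == "+"]
    y <- dd$threshold_voltage_V[dd$polarity == "-"]
    mann_whitney_permutation(x, y, n_perm = 1000, seed = s)$p.value < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.8)
})

test_that("the rig geometry factor comes from the solver and is cached", {
  f1 <- rig_geometry_factor(3e-3)
  expect_equal(f1, 0.887, tolerance = 0.02)   # probe field just below V/d
  expect_identical(rig_geometry_factor(3e-3), f1)
})
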
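#' Run a configured analysis stage
#'
#' Single entry point wiring scenes -> solver -> attraction model -> stats.
#' The configuration is a named list (or path to a YAML file with the same
#' structure) with a `stage` and stage-specific parameters; every run
#' writes its artifacts plus a plain-text log recording the parameters,
#' package version and seed, so a logged run can be reproduced exactly.
#'
#' Stages and their parameters (lengths in the units of the field's
#' reporting conventions, mm and volts):
#' \describe{
#'   \item{`solve_rig`}{`gap_mm`, `voltage`, optional `sphere_diameter_mm`,
#'     `probe_z_mm` (default 0.5): solves the rig scene, writes the probed
#'     field and the field grid CSV.}
#'   \item{`solve_blade`}{`gap_mm`, `voltage`: nested 3-D single-blade
#'     solve, probed 0.5 mm above the blade tip.}
#'   \item{`fit_threshold`}{`data` (CSV path): zero-intercept threshold fit,
#'     written as JSON.}
#'   \item{`avg_threshold_field`}{`gradient_kvm`, optional `probe_mm`,
#'     `distances_mm`: average probe field under the fitted law.}
#'   \item{`simulate_staircase`}{`e_star_kvm`, `cv`, `seed`: staircase
#'     dataset CSV.}
#'   \item{`simulate_lift`}{`seed`, optional `voltage`, `gap_mm`: lift-trial
#'     contingency table CSV plus chi-square JSON.}
#' }
#'
#' @param config Named list or YAML file path.
#' @param out_dir Output directory (created if needed); default from
#'   `config$out_dir` or a tempdir subdirectory.
#' @return Invisibly, a list with the stage's results and artifact paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$stage))
    stop("usage error: config must name a stage", call. = FALSE)
  stage <- config$stage
  out_dir <- out_dir %||% config$out_dir %||%
    file.path(tempdir(), paste0("electrotick-", stage))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  paths <- character()
  art <- function(name) {
    p <- file.path(out_dir, name); paths[[name]] <<- p; p
  }

  result <- switch(stage,
    solve_rig = {
      gap <- (config$gap_mm %||% 3) * 1e-3
      scene <- build_rig_scene(gap, config$voltage %||% 750,
                               sphere_diameter = (config$sphere_diameter_mm %||% 15) * 1e-3)
      sol <- solve_axisymmetric(scene, default_rig_grid(gap))
      pz <- scene$meta$plate_top + (config$probe_z_mm %||% 0.5) * 1e-3
      pr <- probe(sol, c(0, pz))
      write_field_csv(sol, art("rig_field.csv"))
      jsonlite::write_json(list(probe_z_mm = (pz - scene$meta$plate_top) * 1e3,
                                E_kV_per_m = pr$Emag / 1e3),
                           art("rig_probe.json"), auto_unbox = TRUE, digits = NA)
      list(probe = pr, E_kV_per_m = pr$Emag / 1e3)
    },
    solve_blade = {
      gap <- (config$gap_mm %||% 2.5) * 1e-3
      scene <- build_single_blade_scene(gap, config$voltage %||% 750)
      tip <- scene$meta$blade_tip
      box <- rbind(tip - c(6e-3, 6e-3, 6e-3), tip + c(6e-3, 6e-3, 6e-3))
      sol <- solve_cartesian_3d_nested(scene,
                                       coarse = grid_spec(config$h_coarse %||% 5e-3, tol = 1e-6),
                                       fine = grid_spec(config$h_fine %||% 1e-4,
                                                        refine_box = box))
      pr <- probe(sol, tip + c(0, 0, 5e-4))
      jsonlite::write_json(list(E_kV_per_m = pr$Emag / 1e3),
                           art("blade_probe.json"), auto_unbox = TRUE, digits = NA)
      list(probe = pr, E_kV_per_m = pr$Emag / 1e3)
    },
    fit_threshold = {
      dat <- read.csv(config$data)
      fit <- fit_threshold_law(dat)
      jsonlite::write_json(list(gradient_kV_per_m = fit$slope / 1e3,
                                r_squared = fit$r.squared,
                                F = fit$fstatistic, df = fit$df,
                                p = fit$p.value,
                                intercept_ci_V = fit$free$intercept_ci,
                                anova_p = fit$free$anova_p),
                           art("threshold_fit.json"), auto_unbox = TRUE, digits = NA)
      fit
    },
    avg_threshold_field = {
      dists <- (config$distances_mm %||% seq(1.5, 4, by = 0.5)) * 1e-3
      G <- (config$gradient_kvm %||% 290) * 1e3
      avg <- average_threshold_field(dists, G * dists,
                                     probe_height = (config$probe_mm %||% 0.5) * 1e-3)
      write.csv(avg$table, art("avg_threshold_field.csv"), row.names = FALSE)
      jsonlite::write_json(list(mean_field_kV_per_m = avg$mean_field / 1e3),
                           art("avg_threshold_field.json"), auto_unbox = TRUE,
                           digits = NA)
      avg
    },
    simulate_staircase = {
      pop <- tick_population_model(threshold_field = (config$e_star_kvm %||% 258) * 1e3,
                                   cv = config$cv %||% 0.15)
      dat <- simulate_staircase_experiment(pop, seed = seed)
      write.csv(dat, art("staircase.csv"), row.names = FALSE)
      dat
    },
    simulate_lift = {
      tab <- simulate_lift_trials(applied_voltage = config$voltage %||% 750,
                                  gap = (config$gap_mm %||% 3) * 1e-3,
                                  seed = seed,
                                  geometry_factor = config$geometry_factor)
      test <- chi_square_independence(tab)
      write.csv(as.data.frame(unclass(tab)), art("lift_table.csv"))
      jsonlite::write_json(list(chi_squared = unname(test$statistic),
                                df = test$df, p = test$p.value),
                           art("lift_chi2.json"), auto_unbox = TRUE, digits = NA)
      list(table = tab, test = test)
    },
    stop("usage error: unknown stage '", stage, "'", call. = FALSE)
  )

  log_lines <- c(
    paste0("electrotick ", as.character(utils::packageVersion("electrotick"))),
    paste0("stage: ", stage),
    paste0("seed: ", seed),
    paste0("config: ", jsonlite::toJSON(config[setdiff(names(config), "stage")],
                                        auto_unbox = TRUE)),
    paste0("artifacts: ", paste(names(paths), collapse = ", ")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(stage = stage, result = result, artifacts = paths,
                 out_dir = out_dir, seed = seed))
}
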
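test_that("parallel-plate scene reproduces the closed form V/d everywhere", {
  pp <- fx_parallel_plate()
  sol <- pp$sol
  zr <- pp$scene$meta$gap_zrange
  # every interior node of the air gap carries |E| = 250 kV/m within 0.1%
  inside <- sol$coords$z > zr[1] + 1e-6 & sol$coords$z < zr[2] - 1e-6
  expect_lt(max(abs(sol$Emag[, inside] / 2.5e5 - 1)), 1e-3)
  # arbitrary interior probes see the uniform value
  pr <- probe(sol, rbind(c(1.234e-3, mean(zr)), c(7e-3, zr[1] + 7e-4)))
  expect_equal(pr$Emag, c(2.5e5, 2.5e5), tolerance = 1e-6)
  # zero-voltage control: zero field everywhere
  sol0 <- solve_axisymmetric(build_parallel_plate_scene(3e-3, 0), grid_spec(1.5e-4))
  expect_equal(max(sol0$Emag), 0)
})

test_that("discrete maximum principle holds on solved scenes", {
  pair <- fx_rig_pair()
  eps <- solver_slack(pair$pos)
  expect_gte(min(pair$pos$V), 0 - eps)
  expect_lte(max(pair$pos$V), 750 + eps)
  expect_gte(min(pair$neg$V), -750 - eps)
  expect_lte(max(pair$neg$V), 0 + eps)
  pp <- fx_parallel_plate()
  eps <- solver_slack(pp$sol)
  expect_gte(min(pp$sol$V), 0 - eps)
  expect_lte(max(pp$sol$V), 750 + eps)
})

test_that("solutions are linear in the boundary data and polarity-symmetric", {
  g <- grid_spec(1.5e-4)
  a <- solve_axisymmetric(build_parallel_plate_scene(3e-3, 750), g)
  b <- solve_axisymmetric(build_parallel_plate_scene(3e-3, 375), g)
  expect_lt(max(abs(a$V - 2 * b$V)) / 750, 1e-10)
  pair <- fx_rig_pair()
  # V -> -V negates the potential and leaves |E| unchanged
  expect_equal(pair$pos$V, -pair$neg$V, tolerance = 1e-12)
  expect_equal(pair$pos$Emag, pair$neg$Emag, tolerance = 1e-12)
})

test_that("axisymmetric solver agrees with the image-charge oracle", {
  pair <- fx_rig_pair()
  scene <- pair$pos$scene
  zs <- c(0.5e-3, 1e-3, 1.5e-3, 2e-3)
  fd <- probe(pair$pos, cbind(0, scene$meta$plate_top + zs))$Emag
  oracle <- abs(sphere_plane_axis_field(7.5e-3, 3e-3, 750, zs))
  expect_lt(max(abs(fd / oracle - 1)), 0.02)
})

test_that("probing reproduces node values and rejects bad points", {
  pp <- fx_parallel_plate()
  sol <- pp$sol
  i <- 21L; j <- 18L
  pr <- probe(sol, c(sol$coords$r[i], sol$coords$z[j]))
  expect_equal(pr$Emag, sol$Emag[i, j], tolerance = 1e-12)
  expect_equal(pr$V, sol$V[i, j], tolerance = 1e-12)
  expect_error(probe(sol, c(1, 1)), "out of domain")
  expect_error(probe(sol, c(1e-3, 1e-6)), "conductor")
})

test_that("an isolated-sphere solve approaches the analytic point-charge field", {
  R <- 7.5e-3
  sc <- field_scene(c(0.15, 0.3), "axisymmetric",
                    list(list(shape = shape_sphere(R, 0.15), potential = 750)),
                    meta = list(min_gap = 0.1))
  sol <- solve_axisymmetric(sc, grid_spec(1e-3))
  s <- R + 3e-3
  pr <- probe(sol, c(0, 0.15 - s))
  expect_equal(pr$Emag, 750 * R / s^2, tolerance = 0.1)
})

test_that("nested 3-D solve is linear in voltage and zero when grounded", {
  scene2 <- build_single_blade_scene(2.5e-3, 750)
  tip <- scene2$meta$blade_tip
  box <- rbind(tip - 4e-3, tip + 4e-3)
  coarse <- grid_spec(2e-2, tol = 1e-6)
  fine <- grid_spec(2.5e-4, refine_box = box)
  sol750 <- solve_cartesian_3d_nested(scene2, coarse, fine)
  sol375 <- solve_cartesian_3d_nested(build_single_blade_scene(2.5e-3, 375),
                                      coarse, fine)
  pts <- rbind(tip + c(0, 0, 5e-4), tip + c(0, 0, 1.5e-3), tip + c(1e-3, 0, 1e-3))
  r750 <- probe(sol750, pts)$Emag
  r375 <- probe(sol375, pts)$Emag
  expect_equal(r750 / r375, rep(2, 3), tolerance = 1e-8)
  expect_gte(min(sol750$V), 0); expect_lte(max(sol750$V), 750)
  # all boundaries grounded -> identically zero field
  sol0 <- solve_cartesian_3d_nested(build_single_blade_scene(2.5e-3, 0),
                                    coarse, fine)
  expect_equal(max(sol0$Emag), 0)
  # refinement box must enclose the gap
  expect_error(
    solve_cartesian_3d_nested(scene2, coarse,
                              grid_spec(2.5e-4, refine_box = rbind(tip + 1e-3, tip + 5e-3))),
    "enclose")
})

test_that("grid convergence: probe changes shrink with spacing", {
  scene <- build_rig_scene(3e-3, 750)
  base <- grid_spec(c(5e-4, 1e-4), refine_box = c(0.02, 0.02))
  rep_ <- grid_convergence_report(scene, c(0, scene$meta$plate_top + 5e-4),
                                  spacings = c(1.5e-4, 1e-4, 5e-5),
                                  base_grid = base)
  d <- abs(rep_$delta[-1])
  expect_lt(d[2], d[1])                       # monotone shrinking updates
  expect_lt(d[2] / rep_$Emag[3], 0.01)        # <1% between two finest levels
  expect_gte(attr(rep_, "order"), 1)          # at least first-order observed
  expect_error(grid_convergence_report(scene, c(0, 1e-3), spacings = c(1e-4)),
               "at least 3")
  expect_error(grid_convergence_report(scene, c(0, 1e-3),
                                       spacings = c(1e-4, 2e-4, 3e-4)),
               "decreasing")
})

test_that("under-resolved gaps are flagged and field tables export", {
  scene <- build_rig_scene(3e-3, 750)
  expect_warning(solve_axisymmetric(scene, grid_spec(1e-3)), "under-resolved")
  pp <- fx_parallel_plate()
  df <- as.data.frame(pp$sol)
  expect_named(df, c("r", "z", "V", "Er", "Ez", "Emag"))
  f <- tempfile(fileext = ".csv")
  write_field_csv(pp$sol, f)
  back <- read.csv(f)
  expect_equal(nrow(back), prod(dim(pp$sol$V)))
  unlink(f)
})
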
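#' Grid specification for the finite-volume Laplace solver
#'
#' @param h Grid spacing in metres. A single value requests one uniform
#'   level; `c(h_coarse, h_fine)` together with `refine_box` requests a
#'   nested two-level solve (coarse pass over the whole domain, fine pass on
#'   the refinement box with boundary values interpolated from the coarse
#'   solution).
#' @param tol Relative residual tolerance of the conjugate-gradient solve.
#' @param maxit Iteration budget.
#' @param refine_box For axisymmetric scenes `c(rmax, zmax)` (box from the
#'   axis/plate corner); for 3-D scenes a 2 x 3 matrix `rbind(lower, upper)`.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(h, tol = 1e-8, maxit = 200000L, refine_box = NULL) {
  if (any(h <= 0) || tol <= 0) stop("h and tol must be positive", call. = FALSE)
  if (length(h) > 1 && is.null(refine_box))
    stop("two spacings given but no refine_box", call. = FALSE)
  structure(list(h = h, tol = tol, maxit = as.integer(maxit),
                 refine_box = refine_box), class = "grid_spec")
}

#' Default nested grid for the rig scene
#'
#' Coarse pass at 0.5 mm over the whole model box, fine pass at `gap/60`
#' (capped at 0.05 mm) on a 20 x 20 mm box around the gap.
#'
#' @param gap Air gap of the scene, m.
#' @param tol Fine-level residual tolerance.
#' @return A `grid_spec`.
#' @export
default_rig_grid <- function(gap, tol = 1e-8) {
  grid_spec(h = c(5e-4, min(gap / 60, 5e-5)), tol = tol,
            refine_box = c(0.02, 0.02))
}

axis_coords <- function(extent, h) (0:round(extent / h)) * h

# ---- rasterization ---------------------------------------------------------

# Axisymmetric scenes: mark Dirichlet nodes and their potentials, and the
# per-node relative permittivity of dielectric regions.
rasterize_axi <- function(scene, r, z) {
  nr <- length(r); nz <- length(z)
  V <- matrix(0, nr, nz)
  fix <- matrix(FALSE, nr, nz)
  cond <- matrix(FALSE, nr, nz)
  if (isTRUE(scene$meta$bottom_grounded) && abs(z[1]) < 1e-15) {
    fix[, 1] <- TRUE
  }
  for (cd in scene$conductors) {
    m <- shape_mask_axi(cd$shape, r, z)
    V[m] <- cd$potential
    fix[m] <- TRUE
    cond[m] <- TRUE
  }
  eps <- NULL
  if (length(scene$dielectrics)) {
    eps <- matrix(1, nr, nz)
    for (dl in scene$dielectrics) eps[shape_mask_axi(dl$shape, r, z)] <- dl$eps_r
  }
  list(V = V, fix = fix, cond = cond, eps = eps)
}

# 3-D scenes; shapes are rasterized per z-plane to keep temporaries small.
# min_feature widens thin shapes (the blade ribbon) to at least one node
# column so coarse grids still see them.
rasterize_3d <- function(scene, x, y, z, min_feature = 0) {
  nx <- length(x); ny <- length(y); nz <- length(z)
  V <- array(0, c(nx, ny, nz))
  fix <- array(FALSE, c(nx, ny, nz))
  cond <- array(FALSE, c(nx, ny, nz))
  if (isTRUE(scene$meta$bottom_grounded) && abs(z[1]) < 1e-15)
    fix[, , 1] <- TRUE
  for (cd in scene$conductors) {
    s <- cd$shape
    if (s$kind == "slab") {
      kz <- which(z >= s$zmin & z <= s$zmax)
      if (length(kz)) { V[, , kz] <- cd$potential; fix[, , kz] <- TRUE; cond[, , kz] <- TRUE }
    } else if (s$kind == "ribbon") {
      hw1 <- max(s$thickness / 2, min_feature)
      hw2 <- max(s$width / 2, min_feature)
      ix <- which(abs(x - s$center[1]) <= hw1)
      iy <- which(abs(y - s$center[2]) <= hw2)
      kz <- which(z >= s$zmin & z <= s$zmax)
      if (length(ix) && length(iy) && length(kz)) {
        V[ix, iy, kz] <- cd$potential; fix[ix, iy, kz] <- TRUE; cond[ix, iy, kz] <- TRUE
      }
    } else if (s$kind %in% c("sphere", "ellipsoid")) {
      ax <- if (s$kind == "sphere") rep(s$radius, 3) else s$semiaxes
      u <- ((x - s$center[1]) / ax[1])^2
      v <- ((y - s$center[2]) / ax[2])^2
      w <- ((z - s$center[3]) / ax[3])^2
      for (k in which(w <= 1)) {
        m <- outer(u, v, "+") <= 1 - w[k]
        if (any(m)) {
          plane_v <- V[, , k]; plane_f <- fix[, , k]; plane_c <- cond[, , k]
          plane_v[m] <- cd$potential; plane_f[m] <- TRUE; plane_c[m] <- TRUE
          V[, , k] <- plane_v; fix[, , k] <- plane_f; cond[, , k] <- plane_c
        }
      }
    } else stop("shape kind '", s$kind, "' is not supported in 3-D", call. = FALSE)
  }
  list(V = V, fix = fix, cond = cond, eps = NULL)
}

# ---- interpolation ---------------------------------------------------------

# Bilinear interpolation on a uniform grid (matrix M over coords xg, yg).
interp2 <- function(xg, yg, M, px, py) {
  hx <- xg[2] - xg[1]; hy <- yg[2] - yg[1]
  fx <- (px - xg[1]) / hx; fy <- (py - yg[1]) / hy
  i <- pmin.int(pmax.int(floor(fx), 0), length(xg) - 2L)
  j <- pmin.int(pmax.int(floor(fy), 0), length(yg) - 2L)
  tx <- fx - i; ty <- fy - j
  i <- i + 1L; j <- j + 1L
  M[cbind(i, j)] * (1 - tx) * (1 - ty) + M[cbind(i + 1L, j)] * tx * (1 - ty) +
    M[cbind(i, j + 1L)] * (1 - tx) * ty + M[cbind(i + 1L, j + 1L)] * tx * ty
}

interp3 <- function(xg, yg, zg, A, px, py, pz) {
  hx <- xg[2] - xg[1]; hy <- yg[2] - yg[1]; hz <- zg[2] - zg[1]
  fx <- (px - xg[1]) / hx; fy <- (py - yg[1]) / hy; fz <- (pz - zg[1]) / hz
  i <- pmin.int(pmax.int(floor(fx), 0), length(xg) - 2L)
  j <- pmin.int(pmax.int(floor(fy), 0), length(yg) - 2L)
  k <- pmin.int(pmax.int(floor(fz), 0), length(zg) - 2L)
  tx <- fx - i; ty <- fy - j; tz <- fz - k
  i <- i + 1L; j <- j + 1L; k <- k + 1L
  out <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) * (if (dk) tz else 1 - tz)
    out <- out + w * A[cbind(i + di, j + dj, k + dk)]
  }
  out
}

# ---- field solution --------------------------------------------------------

# Central-difference negative gradient; one-sided at grid edges. On the
# axisymmetric axis E_r = 0 by symmetry.
neg_gradient <- function(V, h, axisym) {
  d <- function(A, dim) {
    n <- dim(A)[dim]
    idx <- function(k) switch(dim, A[k, , drop = FALSE], A[, k, drop = FALSE])
    if (length(dim(A)) == 3)
      idx <- function(k) switch(dim, A[k, , , drop = FALSE], A[, k, , drop = FALSE],
                                A[, , k, drop = FALSE])
    g <- A
    gput <- function(k, val) {
      if (length(dim(A)) == 2) {
        if (dim == 1) g[k, ] <<- val else g[, k] <<- val
      } else {
        if (dim == 1) g[k, , ] <<- val else if (dim == 2) g[, k, ] <<- val else g[, , k] <<- val
      }
    }
    gput(2:(n - 1), (idx(3:n) - idx(1:(n - 2))) / (2 * h))
    gput(1, (idx(2) - idx(1)) / h)
    gput(n, (idx(n) - idx(n - 1)) / h)
    g
  }
  E <- lapply(seq_along(dim(V)), function(k) -d(V, k))
  if (axisym) {
    E[[1]][1, ] <- 0
  }
  E
}

new_field_solution <- function(scene, coords, V, cond, h, info) {
  if (!isTRUE(info$converged))
    stop("solver failure: relative residual ", signif(info$relres, 3),
         " after ", info$iter, " iterations", call. = FALSE)
  axisym <- scene$symmetry == "axisymmetric"
  E <- neg_gradient(V, h, axisym)
  Emag <- sqrt(Reduce(`+`, lapply(E, function(e) e^2)))
  pots <- c(vapply(scene$conductors, `[[`, 0, "potential"),
            if (isTRUE(scene$meta$bottom_grounded)) 0)
  slack <- 1e-6 * max(diff(range(pots)), 1e-12)
  if (min(V) < min(pots) - slack || max(V) > max(pots) + slack)
    warning("discrete maximum principle violated beyond solver slack")
  structure(list(scene = scene, coords = coords, V = V, E = E, Emag = Emag,
                 conductor = cond, h = h, info = info),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  dims <- paste(dim(x$V), collapse = " x ")
  cat(sprintf("<field_solution: %s> %s nodes, h = %g mm\n",
              x$scene$symmetry, dims, x$h * 1e3))
  cat(sprintf("  V in [%.6g, %.6g] V; |E| up to %.4g kV/m\n",
              min(x$V), max(x$V), max(x$Emag) / 1e3))
  cat(sprintf("  CG: %d iterations, relative residual %.2e\n",
              x$info$iter, x$info$relres))
  invisible(x)
}

#' @export
as.data.frame.field_solution <- function(x, row.names = NULL, optional = FALSE, ...) {
  cs <- x$coords
  if (length(cs) == 2) {
    df <- expand.grid(r = cs[[1]], z = cs[[2]], KEEP.OUT.ATTRS = FALSE)
    df$V <- as.vector(x$V)
    df$Er <- as.vector(x$E[[1]]); df$Ez <- as.vector(x$E[[2]])
  } else {
    df <- expand.grid(x = cs[[1]], y = cs[[2]], z = cs[[3]], KEEP.OUT.ATTRS = FALSE)
    df$V <- as.vector(x$V)
    df$Ex <- as.vector(x$E[[1]]); df$Ey <- as.vector(x$E[[2]]); df$Ez <- as.vector(x$E[[3]])
  }
  df$Emag <- as.vector(x$Emag)
  df
}

#' Export a field solution as a structured-grid CSV table
#'
#' @param solution A `field_solution`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(solution, path) {
  write.csv(as.data.frame(solution), path, row.names = FALSE)
  invisible(path)
}

solve_on_grid <- function(scene, V, fix, eps, h, tol, maxit, coords, cond) {
  dims <- dim(V)
  res <- cpp_solve_laplace(as.integer(dims), as.vector(V),
                           as.integer(as.vector(fix)),
                           if (is.null(eps)) NULL else as.vector(eps),
                           scene$symmetry == "axisymmetric", tol, maxit)
  Vout <- res$V
  dim(Vout) <- dims
  info <- list(iter = res$iter, relres = res$relres,
               converged = isTRUE(res$converged) || res$relres == 0)
  new_field_solution(scene, coords, Vout, cond, h, info)
}

#' Solve an axisymmetric scene
#'
#' Finite-volume discretization of the Laplace problem in cylindrical (r, z)
#' coordinates on a uniform grid, solved by matrix-free conjugate gradients.
#' The axis r = 0 carries the symmetry condition dV/dr = 0; the domain
#' bottom is grounded (Dirichlet 0) and sides/top are zero-normal-flux.
#' When `grid` carries two spacings and a `refine_box`, a nested solve is
#' performed: the coarse solution over the whole domain supplies Dirichlet
#' values on the refinement-box boundary and the returned solution is the
#' fine-level field inside the box.
#'
#' @param scene An axisymmetric `field_scene`.
#' @param grid A `grid_spec`; defaults to [default_rig_grid()] when the
#'   scene carries a `min_gap`, else a single level at 1/40 of the domain.
#' @return A `field_solution`.
#' @export
solve_axisymmetric <- function(scene, grid = NULL) {
  stopifnot(inherits(scene, "field_scene"))
  if (scene$symmetry != "axisymmetric")
    stop("scene is not axisymmetric", call. = FALSE)
  if (is.null(grid)) {
    grid <- if (!is.null(scene$meta$min_gap) && identical(scene$meta$kind, "rig"))
      default_rig_grid(scene$meta$min_gap)
    else grid_spec(min(scene$domain_extent) / 40)
  }
  h_eff <- grid$h[length(grid$h)]
  if (!is.null(scene$meta$min_gap) && scene$meta$min_gap / h_eff < 20)
    warning("under-resolved gap: fewer than 20 nodes across the smallest gap")

  if (length(grid$h) == 1L) {
    r <- axis_coords(scene$domain_extent[1], grid$h)
    z <- axis_coords(scene$domain_extent[2], grid$h)
    ras <- rasterize_axi(scene, r, z)
    return(solve_on_grid(scene, ras$V, ras$fix, ras$eps, grid$h,
                         grid$tol, grid$maxit, list(r = r, z = z), ras$cond))
  }

  # nested: coarse full-domain pass feeds the refinement-box boundary
  hc <- grid$h[1]; hf <- grid$h[2]
  rc <- axis_coords(scene$domain_extent[1], hc)
  zc <- axis_coords(scene$domain_extent[2], hc)
  ras <- rasterize_axi(scene, rc, zc)
  coarse <- solve_on_grid(scene, ras$V, ras$fix, ras$eps, hc,
                          max(grid$tol, 1e-6), grid$maxit,
                          list(r = rc, z = zc), ras$cond)

  box <- grid$refine_box
  rf <- axis_coords(box[1], hf)
  zf <- axis_coords(box[2], hf)
  rasf <- rasterize_axi(scene, rf, zf)
  Vf <- rasf$V; fixf <- rasf$fix
  nrf <- length(rf); nzf <- length(zf)
  # outer box faces: Dirichlet from the coarse solution (the axis r = 0 stays
  # Neumann; z = 0 is already the grounded bottom)
  Vf[nrf, ] <- interp2(rc, zc, coarse$V, rep(rf[nrf], nzf), zf)
  fixf[nrf, ] <- TRUE
  Vf[, nzf] <- interp2(rc, zc, coarse$V, rf, rep(zf[nzf], nrf))
  fixf[, nzf] <- TRUE
  # conductor raster takes precedence on the faces
  Vf[rasf$cond] <- rasf$V[rasf$cond]
  sol <- solve_on_grid(scene, Vf, fixf, rasf$eps, hf, grid$tol, grid$maxit,
                       list(r = rf, z = zf), rasf$cond)
  sol$coarse_info <- coarse$info
  sol
}

#' Nested 3-D solve of a cartesian scene
#'
#' Coarse 7-point finite-volume Laplace solve over the full domain, then a
#' fine solve on `fine$refine_box` with Dirichlet boundary values trilinearly
#' interpolated from the coarse solution. The returned solution is the
#' fine-level field inside the box; the scale separation between the metre-
#' scale domain and the millimetre gap makes the two-level approach
#' necessary.
#'
#' @param scene A cartesian3d `field_scene`.
#' @param coarse `grid_spec` for the full-domain pass (tolerance is relaxed
#'   to 1e-6 unless set looser: it only feeds boundary values).
#' @param fine `grid_spec` with `refine_box = rbind(lower, upper)` enclosing
#'   the gap.
#' @return A `field_solution` on the refinement box.
#' @export
solve_cartesian_3d_nested <- function(scene, coarse, fine) {
  stopifnot(inherits(scene, "field_scene"))
  if (scene$symmetry != "cartesian3d") stop("scene is not cartesian3d", call. = FALSE)
  if (is.null(fine$refine_box)) stop("fine grid needs a refine_box", call. = FALSE)
  box <- fine$refine_box
  tip <- scene$meta$blade_tip
  if (!is.null(tip) && !is.null(scene$meta$gap)) {
    seg_hi <- tip + c(0, 0, scene$meta$gap)
    if (any(tip < box[1, ]) || any(seg_hi > box[2, ]))
      stop("refine_box does not enclose the blade-tip/host gap", call. = FALSE)
  }

  hc <- coarse$h[1]
  xc <- axis_coords(scene$domain_extent[1], hc)
  yc <- axis_coords(scene$domain_extent[2], hc)
  zc <- axis_coords(scene$domain_extent[3], hc)
  ras <- rasterize_3d(scene, xc, yc, zc, min_feature = hc / 2)
  sol_c <- solve_on_grid(scene, ras$V, ras$fix, ras$eps, hc,
                         max(coarse$tol, 1e-6), coarse$maxit,
                         list(x = xc, y = yc, z = zc), ras$cond)

  hf <- fine$h[length(fine$h)]
  xf <- box[1, 1] + axis_coords(box[2, 1] - box[1, 1], hf)
  yf <- box[1, 2] + axis_coords(box[2, 2] - box[1, 2], hf)
  zf <- box[1, 3] + axis_coords(box[2, 3] - box[1, 3], hf)
  rasf <- rasterize_3d(scene, xf, yf, zf)
  Vf <- rasf$V; fixf <- rasf$fix
  nx <- length(xf); ny <- length(yf); nz <- length(zf)
  put_face <- function(ix, iy, iz) {
    g <- expand.grid(x = xf[ix], y = yf[iy], z = zf[iz], KEEP.OUT.ATTRS = FALSE)
    vals <- interp3(xc, yc, zc, sol_c$V, g$x, g$y, g$z)
    Vf[ix, iy, iz] <<- array(vals, c(length(ix), length(iy), length(iz)))
    fixf[ix, iy, iz] <<- TRUE
  }
  put_face(1L, seq_len(ny), seq_len(nz)); put_face(nx, seq_len(ny), seq_len(nz))
  put_face(seq_len(nx), 1L, seq_len(nz)); put_face(seq_len(nx), ny, seq_len(nz))
  put_face(seq_len(nx), seq_len(ny), 1L); put_face(seq_len(nx), seq_len(ny), nz)
  Vf[rasf$cond] <- rasf$V[rasf$cond]
  sol <- solve_on_grid(scene, Vf, fixf, rasf$eps, hf, fine$tol, fine$maxit,
                       list(x = xf, y = yf, z = zf), rasf$cond)
  sol$coarse_info <- sol_c$info
  sol
}

#' Probe a field solution at points
#'
#' Multilinear interpolation of the electric field (and potential) at
#' arbitrary points inside the solved region. Points inside or within one
#' cell of a conductor are rejected (the one-sided gradient there is not
#' probe quality), as are points outside the grid.
#'
#' @param solution A `field_solution`.
#' @param points Numeric vector (one point) or matrix with one row per
#'   point: `(r, z)` for axisymmetric solutions, `(x, y, z)` for 3-D.
#' @return A data.frame with the position, field components (V/m), field
#'   magnitude `Emag` (the norm of the interpolated vector) and potential.
#' @export
probe <- function(solution, points) {
  stopifnot(inherits(solution, "field_solution"))
  cs <- solution$coords
  nd <- length(cs)
  if (is.null(dim(points))) points <- matrix(points, ncol = nd, byrow = TRUE)
  if (ncol(points) != nd) stop("points must have ", nd, " columns", call. = FALSE)
  for (d in seq_len(nd)) {
    rng <- range(cs[[d]])
    if (any(points[, d] < rng[1] - 1e-12 | points[, d] > rng[2] + 1e-12))
      stop("out of domain: probe point outside the solved region", call. = FALSE)
  }
  # reject probes whose interpolation cell touches a conductor node
  h <- solution$h
  idx <- lapply(seq_len(nd), function(d)
    pmin.int(pmax.int(floor((points[, d] - cs[[d]][1]) / h), 0),
             length(cs[[d]]) - 2L) + 1L)
  near_cond <- rep(FALSE, nrow(points))
  combos <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (rr in seq_len(nrow(combos))) {
    corner <- mapply(function(ix, off) ix + off, idx, combos[rr, ], SIMPLIFY = FALSE)
    near_cond <- near_cond | solution$conductor[do.call(cbind, corner)]
  }
  if (any(near_cond))
    stop("probe point inside or adjacent to a conductor", call. = FALSE)

  if (nd == 2) {
    comps <- lapply(c(solution$E, list(solution$V)), function(A)
      interp2(cs[[1]], cs[[2]], A, points[, 1], points[, 2]))
    out <- data.frame(r = points[, 1], z = points[, 2],
                      Er = comps[[1]], Ez = comps[[2]], V = comps[[3]])
    out$Emag <- sqrt(out$Er^2 + out$Ez^2)
  } else {
    comps <- lapply(c(solution$E, list(solution$V)), function(A)
      interp3(cs[[1]], cs[[2]], cs[[3]], A, points[, 1], points[, 2], points[, 3]))
    out <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
                      Ex = comps[[1]], Ey = comps[[2]], Ez = comps[[3]],
                      V = comps[[4]])
    out$Emag <- sqrt(out$Ex^2 + out$Ey^2 + out$Ez^2)
  }
  out
}

#' Grid-convergence study at a probe point
#'
#' Solves the same scene on successively finer grids and reports the probed
#' field magnitude, the change between consecutive spacings, and the
#' observed convergence order estimated from the last Richardson triple.
#'
#' @param scene A `field_scene` (axisymmetric).
#' @param probe_point `(r, z)` probe location, m.
#' @param spacings Strictly decreasing vector of at least 3 spacings, m.
#' @param base_grid Optional `grid_spec` template; when it carries a
#'   `refine_box` the spacings vary the fine level, otherwise single-level
#'   solves are used.
#' @return A data.frame `(h, Emag, delta)` of class `convergence_report`
#'   with attribute `order`.
#' @export
grid_convergence_report <- function(scene, probe_point, spacings, base_grid = NULL) {
  if (length(spacings) < 3) stop("need at least 3 spacings", call. = FALSE)
  if (any(diff(spacings) >= 0)) stop("spacings must be strictly decreasing", call. = FALSE)
  vals <- vapply(spacings, function(h) {
    g <- if (is.null(base_grid)) grid_spec(h) else
      grid_spec(c(base_grid$h[1], h), tol = base_grid$tol,
                refine_box = base_grid$refine_box)
    probe(solve_axisymmetric(scene, g), probe_point)$Emag
  }, 0)
  n <- length(vals)
  delta <- c(NA, diff(vals))
  ord <- if (n >= 3 && delta[n] != 0)
    log(abs(delta[n - 1] / delta[n])) /
      log(spacings[n - 1] / spacings[n]) else NA_real_
  structure(data.frame(h = spacings, Emag = vals, delta = delta),
            order = ord, class = c("convergence_report", "data.frame"))
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Grid convergence at probe point\n")
  print.data.frame(transform(x, h_mm = h * 1e3, Emag_kVm = Emag / 1e3,
                             h = NULL, Emag = NULL, delta = delta / 1e3))
  if (is.finite(attr(x, "order")))
    cat(sprintf("observed convergence order: %.2f\n", attr(x, "order")))
  invisible(x)
}
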
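#' Electrostatic scene descriptions
#'
#' A `field_scene` bundles the domain box, the conductor surfaces with their
#' fixed potentials, and any dielectric regions, in SI units (metres, volts).
#' Conductors are treated as pure Dirichlet boundaries: the host surface,
#' electrode, plate, soil and vegetation are equipotentials, so the air-gap
#' problem is a Laplace problem between them and interior material
#' properties (conductivity, permittivity of tissue/soil/grass) do not enter
#' the air-gap solution; they are carried as metadata on dielectric shapes.
#'
#' @param domain_extent Numeric: `c(rmax, zmax)` for axisymmetric scenes or
#'   `c(Lx, Ly, Lz)` for 3-D scenes, metres. The domain starts at the origin.
#' @param symmetry `"axisymmetric"` or `"cartesian3d"`.
#' @param conductors List of `list(shape = <scene_shape>, potential = volts)`.
#' @param dielectrics List of `list(shape =, eps_r =, sigma =)`; optional.
#' @param meta Free-form metadata list (gap, probe hints, ...).
#' @return An object of class `field_scene`.
#' @seealso [build_rig_scene()], [build_single_blade_scene()],
#'   [build_parallel_plate_scene()]
#' @export
field_scene <- function(domain_extent, symmetry = c("axisymmetric", "cartesian3d"),
                        conductors, dielectrics = list(), meta = list()) {
  symmetry <- match.arg(symmetry)
  ndim <- if (symmetry == "axisymmetric") 2L else 3L
  if (length(domain_extent) != ndim || any(domain_extent <= 0))
    stop("invalid geometry: domain_extent must be ", ndim,
         " positive lengths", call. = FALSE)
  if (!length(conductors)) stop("a scene needs at least one conductor", call. = FALSE)
  for (cd in conductors) {
    if (!inherits(cd$shape, "scene_shape") || !is.numeric(cd$potential))
      stop("each conductor must be list(shape = <scene_shape>, potential = volts)",
           call. = FALSE)
    check_inside_domain(cd$shape, domain_extent, symmetry)
  }
  for (dl in dielectrics) check_inside_domain(dl$shape, domain_extent, symmetry)
  nc <- length(conductors)
  if (nc > 1) {
    for (a in seq_len(nc - 1)) for (b in seq(a + 1, nc)) {
      if (shapes_intersect(conductors[[a]]$shape, conductors[[b]]$shape, symmetry))
        stop("invalid geometry: conductors ", a, " and ", b, " intersect",
             call. = FALSE)
    }
  }
  pots <- vapply(conductors, `[[`, 0, "potential")
  if (is.null(meta$bottom_grounded)) meta$bottom_grounded <- TRUE
  if (!any(pots == 0) && !isTRUE(meta$bottom_grounded))
    stop("no ground reference: at least one conductor must be at 0 V", call. = FALSE)
  structure(list(domain_extent = domain_extent, symmetry = symmetry,
                 conductors = conductors, dielectrics = dielectrics,
                 meta = meta),
            class = "field_scene")
}

check_inside_domain <- function(shape, extent, symmetry) {
  bb <- shape_bbox(shape, symmetry)
  lo <- bb[1, ]; hi <- bb[2, ]
  lo[!is.finite(lo)] <- 0; hi[!is.finite(hi)] <- extent[!is.finite(hi)]
  tol <- 1e-12
  if (any(lo < -tol) || any(hi > extent + tol))
    stop("invalid geometry: shape '", shape$kind,
         "' extends outside the domain box", call. = FALSE)
  invisible(TRUE)
}

# Conservative pairwise intersection test: bounding boxes first, then a
# point sample of the overlap region for curved shapes. Touching at a face
# (zero-measure overlap) does not count as intersection.
shapes_intersect <- function(a, b, symmetry) {
  ba <- shape_bbox(a, symmetry); bb <- shape_bbox(b, symmetry)
  lo <- pmax(ba[1, ], bb[1, ]); hi <- pmin(ba[2, ], bb[2, ])
  if (any(hi - lo <= 1e-12)) return(FALSE)
  lo[!is.finite(lo)] <- 0
  hi[!is.finite(hi)] <- lo[!is.finite(hi)] + 1e-3
  grids <- lapply(seq_along(lo), function(d) seq(lo[d], hi[d], length.out = 9))
  if (symmetry == "axisymmetric") {
    ina <- shape_mask_axi(a, grids[[1]], grids[[2]])
    inb <- shape_mask_axi(b, grids[[1]], grids[[2]])
  } else {
    ina <- shape_mask_3d(a, grids[[1]], grids[[2]], grids[[3]])
    inb <- shape_mask_3d(b, grids[[1]], grids[[2]], grids[[3]])
  }
  any(ina & inb)
}

#' @export
print.field_scene <- function(x, ...) {
  cat(sprintf("<field_scene: %s> domain %s m\n",
              x$symmetry, paste(signif(x$domain_extent, 4), collapse = " x ")))
  for (cd in x$conductors)
    cat(sprintf("  conductor %-9s @ %+g V\n", cd$shape$kind, cd$potential))
  for (dl in x$dielectrics)
    cat(sprintf("  dielectric %-8s eps_r=%g\n", dl$shape$kind, dl$eps_r))
  if (!is.null(x$meta$kind)) cat("  scene kind:", x$meta$kind, "\n")
  invisible(x)
}

#' Laboratory rig scene: charged sphere over a grounded plate
#'
#' Axisymmetric model of the experimental apparatus: a grounded aluminium
#' plate (the rectangular 200 x 130 mm plate is represented as a disc of
#' equal area, radius ~91 mm -- the probe sits on the axis, millimetres from
#' the plate, so far-edge shape is negligible) at the bottom of a 0.3 m
#' model box, and a spherical electrode whose lowest point sits `gap` metres
#' above the plate surface, held at `voltage`. The wooden support rod behind
#' the electrode is excluded by default (it sits far from the probe region);
#' `include_rod = TRUE` adds it as a dielectric cylinder (eps_r = 2).
#'
#' @param gap Air gap between plate surface and the sphere's lowest point, m.
#' @param voltage Electrode potential, volts (0 for control trials).
#' @param sphere_diameter Electrode diameter, m (default 1.5 cm).
#' @param plate_radius Equal-area disc radius, m.
#' @param include_rod Add the dielectric support rod above the sphere?
#' @param domain_size Edge length of the model box, m.
#' @return A `field_scene` (axisymmetric). `meta$plate_top` is the z of the
#'   plate surface; probe heights are measured from it.
#' @export
build_rig_scene <- function(gap, voltage, sphere_diameter = 0.015,
                            plate_radius = sqrt(0.2 * 0.13 / pi),
                            include_rod = FALSE, domain_size = 0.3) {
  if (!is.finite(gap) || gap <= 0 || !is.finite(sphere_diameter) || sphere_diameter <= 0)
    stop("invalid geometry: gap and sphere_diameter must be positive", call. = FALSE)
  R <- sphere_diameter / 2
  plate_top <- 1e-3                        # 1 mm plate thickness
  zc <- plate_top + gap + R
  conductors <- list(
    list(shape = shape_disc(plate_radius, 0, plate_top), potential = 0),
    list(shape = shape_sphere(R, zc), potential = voltage))
  dielectrics <- list()
  if (include_rod) {
    rod_lo <- zc + R - 1.5e-3              # 1.5 mm overlap with the sphere
    rod_hi <- min(rod_lo + 0.15, domain_size)
    dielectrics <- list(list(shape = shape_cylinder(0.005, rod_lo, rod_hi),
                             eps_r = 2, sigma = 0))
  }
  field_scene(c(domain_size / 2, domain_size), "axisymmetric",
              conductors, dielectrics,
              meta = list(kind = "rig", gap = gap, voltage = voltage,
                          sphere_radius = R, plate_top = plate_top,
                          min_gap = gap))
}

#' Vegetation scene: grounded grass blade near a charged host
#'
#' 3-D model of the magnified host-vegetation configuration: a 1 m box with
#' a grounded soil layer, a single grounded vertical grass blade (thin
#' ribbon) standing on the soil, and a charged ellipsoid representing the
#' host, its nearest surface point `gap` metres above the blade tip. The
#' blade cross-section is only loosely constrained by the physical system
#' ("about 1 mm thick"); the default is a 1 mm x 5 mm ribbon and both
#' dimensions are parameters.
#'
#' @param gap Air gap between blade tip and host surface, m.
#' @param voltage Host surface potential, volts.
#' @param blade_height Blade height above the soil, m.
#' @param blade_cross_section `c(thickness, width)`, m.
#' @param ellipsoid_semiaxes Host semi-axes `c(a, b, c)`, m (c vertical).
#' @param domain_size Edge length of the model box, m.
#' @param soil_depth Grounded soil layer thickness, m.
#' @return A `field_scene` (cartesian3d). `meta$blade_tip` is the blade-tip
#'   centre; the tip-to-host line is vertical above it.
#' @export
build_single_blade_scene <- function(gap, voltage, blade_height = 0.30,
                                     blade_cross_section = c(0.001, 0.005),
                                     ellipsoid_semiaxes = c(0.4, 0.4, 0.2),
                                     domain_size = 1, soil_depth = 0.1) {
  if (!is.finite(gap) || gap <= 0)
    stop("invalid geometry: host ellipsoid may not overlap the blade (gap <= 0)",
         call. = FALSE)
  tip_z <- soil_depth + blade_height
  if (tip_z >= domain_size)
    stop("invalid geometry: blade taller than the domain", call. = FALSE)
  cx <- domain_size / 2
  ell_c <- c(cx, cx, tip_z + gap + ellipsoid_semiaxes[3])
  conductors <- list(
    list(shape = shape_slab(0, soil_depth), potential = 0),
    list(shape = shape_ribbon(blade_cross_section[1], blade_cross_section[2],
                              soil_depth, tip_z, c(cx, cx)), potential = 0),
    list(shape = shape_ellipsoid(ellipsoid_semiaxes, ell_c), potential = voltage))
  field_scene(rep(domain_size, 3), "cartesian3d", conductors,
              meta = list(kind = "single_blade", gap = gap, voltage = voltage,
                          blade_tip = c(cx, cx, tip_z), min_gap = gap))
}

#' Parallel-plate validation scene
#'
#' Two horizontal Dirichlet plates spanning the whole (axisymmetric) domain,
#' separated by `gap`: the interior field is the closed form V/d, making
#' this the analytic fixture for solver validation.
#'
#' @param gap Plate separation, m.
#' @param voltage Top-plate potential, volts (bottom plate grounded).
#' @param rmax Domain radius, m.
#' @param plate_thickness Plate slab thickness, m.
#' @return A `field_scene` (axisymmetric). `meta$gap_zrange` gives the z
#'   interval of the air gap.
#' @export
build_parallel_plate_scene <- function(gap, voltage, rmax = 5 * gap,
                                       plate_thickness = gap / 10) {
  if (!is.finite(gap) || gap <= 0)
    stop("invalid geometry: gap must be positive", call. = FALSE)
  t <- plate_thickness
  conductors <- list(
    list(shape = shape_slab(0, t), potential = 0),
    list(shape = shape_slab(gap + t, gap + 2 * t), potential = voltage))
  field_scene(c(rmax, gap + 2 * t), "axisymmetric", conductors,
              meta = list(kind = "parallel_plate", gap = gap, voltage = voltage,
                          gap_zrange = c(t, gap + t), min_gap = gap))
}

#' Scene serialization
#'
#' Scenes round-trip through a plain YAML (or JSON) description: shape kind,
#' lengths in metres, potentials in volts.
#'
#' @param scene A `field_scene`.
#' @param path File path; extension `.json` selects JSON, otherwise YAML.
#' @return `write_scene` returns `path` invisibly; `read_scene` the scene.
#' @export
write_scene <- function(scene, path) {
  x <- unclass(scene)
  x$conductors <- lapply(x$conductors, function(cd)
    list(shape = unclass(cd$shape), potential = cd$potential))
  x$dielectrics <- lapply(x$dielectrics, function(dl)
    list(shape = unclass(dl$shape), eps_r = dl$eps_r, sigma = dl$sigma))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  restore <- function(sh) do.call(new_shape, c(sh["kind"], sh[setdiff(names(sh), "kind")]))
  conductors <- lapply(x$conductors, function(cd)
    list(shape = restore(cd$shape), potential = cd$potential))
  dielectrics <- lapply(x$dielectrics, function(dl)
    list(shape = restore(dl$shape), eps_r = dl$eps_r, sigma = dl$sigma))
  field_scene(unlist(x$domain_extent), x$symmetry, conductors, dielectrics,
              meta = x$meta)
}
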
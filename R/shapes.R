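#' Geometric primitives for electrostatic scenes
#'
#' Shapes are simple tagged lists carrying SI lengths (metres). They are the
#' building blocks of [field_scene()] objects: each conductor or dielectric
#' region in a scene is one shape. Supported kinds: sphere, disc (axisymmetric
#' annular plate), slab (full horizontal layer), cylinder (coaxial,
#' axisymmetric), ellipsoid (3-D, axis-aligned) and ribbon (3-D vertical
#' blade with rectangular cross-section).
#'
#' @param radius,semiaxes,thickness,width Lengths in metres; all must be
#'   strictly positive.
#' @param center Centre position: `c(r, z)` is not used (axisymmetric shapes
#'   are coaxial); spheres use `c(0, z)` via `z`; 3-D shapes use `c(x, y, z)`
#'   or `c(x, y)` for vertical ribbons.
#' @param z,zmin,zmax Vertical placement in metres.
#' @name scene_shape
NULL

new_shape <- function(kind, ...) {
  s <- list(kind = kind, ...)
  lens <- unlist(s[setdiff(names(s), c("kind", "center", "z", "zmin", "zmax"))])
  if (length(lens) && any(!is.finite(lens) | lens <= 0))
    stop("invalid geometry: all shape lengths must be strictly positive", call. = FALSE)
  structure(s, class = "scene_shape")
}

#' @rdname scene_shape
#' @export
shape_sphere <- function(radius, z) new_shape("sphere", radius = radius, z = z)

#' @rdname scene_shape
#' @export
shape_disc <- function(radius, zmin, zmax) {
  if (zmax <= zmin) stop("invalid geometry: disc needs zmax > zmin", call. = FALSE)
  new_shape("disc", radius = radius, zmin = zmin, zmax = zmax)
}

#' @rdname scene_shape
#' @export
shape_slab <- function(zmin, zmax) {
  if (zmax <= zmin) stop("invalid geometry: slab needs zmax > zmin", call. = FALSE)
  new_shape("slab", zmin = zmin, zmax = zmax)
}

#' @rdname scene_shape
#' @export
shape_cylinder <- function(radius, zmin, zmax) {
  if (zmax <= zmin) stop("invalid geometry: cylinder needs zmax > zmin", call. = FALSE)
  new_shape("cylinder", radius = radius, zmin = zmin, zmax = zmax)
}

#' @rdname scene_shape
#' @export
shape_ellipsoid <- function(semiaxes, center) {
  stopifnot(length(semiaxes) == 3, length(center) == 3)
  new_shape("ellipsoid", semiaxes = semiaxes, center = center)
}

#' @rdname scene_shape
#' @export
shape_ribbon <- function(thickness, width, zmin, zmax, center) {
  if (zmax <= zmin) stop("invalid geometry: ribbon needs zmax > zmin", call. = FALSE)
  stopifnot(length(center) == 2)
  new_shape("ribbon", thickness = thickness, width = width,
            zmin = zmin, zmax = zmax, center = center)
}

# Axis-aligned bounding box of a shape; rows lower/upper.
# Axisymmetric shapes report (r, z) bounds with r from 0.
shape_bbox <- function(s, symmetry) {
  if (symmetry == "axisymmetric") {
    switch(s$kind,
      sphere   = rbind(c(0, s$z - s$radius), c(s$radius, s$z + s$radius)),
      disc     = rbind(c(0, s$zmin), c(s$radius, s$zmax)),
      slab     = rbind(c(0, s$zmin), c(Inf, s$zmax)),
      cylinder = rbind(c(0, s$zmin), c(s$radius, s$zmax)),
      stop("shape kind '", s$kind, "' is not axisymmetric", call. = FALSE))
  } else {
    switch(s$kind,
      sphere    = rbind(s$center - s$radius, s$center + s$radius),
      ellipsoid = rbind(s$center - s$semiaxes, s$center + s$semiaxes),
      slab      = rbind(c(-Inf, -Inf, s$zmin), c(Inf, Inf, s$zmax)),
      ribbon    = rbind(c(s$center[1] - s$thickness / 2, s$center[2] - s$width / 2, s$zmin),
                        c(s$center[1] + s$thickness / 2, s$center[2] + s$width / 2, s$zmax)),
      stop("shape kind '", s$kind, "' is not supported in 3-D", call. = FALSE))
  }
}

# Logical mask of grid nodes inside a shape.
# Axisymmetric grids: r, z coordinate vectors -> matrix length(r) x length(z).
shape_mask_axi <- function(s, r, z) {
  nr <- length(r); nz <- length(z)
  switch(s$kind,
    sphere = outer(r^2, (z - s$z)^2, "+") <= s$radius^2,
    disc = outer(r <= s$radius, z >= s$zmin & z <= s$zmax, "&"),
    slab = matrix(rep(z >= s$zmin & z <= s$zmax, each = nr), nr, nz),
    cylinder = outer(r <= s$radius, z >= s$zmin & z <= s$zmax, "&"),
    stop("shape kind '", s$kind, "' is not axisymmetric", call. = FALSE))
}

# 3-D grids: x, y, z vectors -> array nx x ny x nz.
shape_mask_3d <- function(s, x, y, z) {
  nx <- length(x); ny <- length(y); nz <- length(z)
  switch(s$kind,
    sphere = {
      u <- (x - s$center[1])^2; v <- (y - s$center[2])^2; w <- (z - s$center[3])^2
      outer(outer(u, v, "+"), w, "+") <= s$radius^2
    },
    ellipsoid = {
      u <- ((x - s$center[1]) / s$semiaxes[1])^2
      v <- ((y - s$center[2]) / s$semiaxes[2])^2
      w <- ((z - s$center[3]) / s$semiaxes[3])^2
      outer(outer(u, v, "+"), w, "+") <= 1
    },
    slab = {
      inz <- z >= s$zmin & z <= s$zmax
      aperm(array(rep(inz, each = nx * ny), c(nx, ny, nz)), c(1, 2, 3))
    },
    ribbon = {
      inx <- abs(x - s$center[1]) <= s$thickness / 2
      iny <- abs(y - s$center[2]) <= s$width / 2
      inz <- z >= s$zmin & z <= s$zmax
      outer(outer(inx, iny, "&"), inz, "&")
    },
    stop("shape kind '", s$kind, "' is not supported in 3-D", call. = FALSE))
}

#' @export
print.scene_shape <- function(x, ...) {
  pars <- x[setdiff(names(x), "kind")]
  cat(sprintf("<shape: %s> %s\n", x$kind,
              paste(names(pars), vapply(pars, function(p) paste(signif(p, 6), collapse = ","),
                                        ""), sep = "=", collapse = " ")))
  invisible(x)
}
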
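#' Analytic on-axis field of the sphere-plane capacitor
#'
#' Classical image-charge construction for a conducting sphere at potential
#' `voltage` whose lowest point sits `gap` above a grounded plane: the
#' charge q0 = 4 pi eps0 R V at the sphere centre is mirrored in the plane,
#' each mirror corrected by a Kelvin image inside the sphere, and so on;
#' the alternating construction leaves the sphere at V and the plane at 0 in
#' the limit. The series converges geometrically and is truncated when a
#' term falls below `rtol` of the leading one.
#'
#' Serves as the independent oracle for the finite-volume solver on the rig
#' axis.
#'
#' @param sphere_radius Sphere radius, m.
#' @param gap Plane-to-sphere air gap, m.
#' @param voltage Sphere potential, V.
#' @param z On-axis height(s) above the plane, m, with `0 <= z <= gap`.
#' @param rtol Relative truncation threshold of the series.
#' @param max_terms Term budget; exceeding it is a convergence error.
#' @return Signed axial field component E_z at each `z`, V/m (sign follows
#'   `voltage`; magnitude is `abs()`).
#' @export
sphere_plane_axis_field <- function(sphere_radius, gap, voltage, z,
                                    rtol = 1e-12, max_terms = 10000L) {
  stopifnot(sphere_radius > 0, gap > 0)
  if (any(z < 0 | z > gap)) stop("z must lie in [0, gap]", call. = FALSE)
  cc <- gap + sphere_radius
  k_coul <- 1 / (4 * pi * 8.8541878128e-12)
  q <- voltage * sphere_radius / k_coul
  p <- cc
  qs <- q; ps <- p
  for (n in seq_len(max_terms)) {
    qn <- q * sphere_radius / (p + cc)
    pn <- cc - sphere_radius^2 / (p + cc)
    qs <- c(qs, qn); ps <- c(ps, pn)
    if (abs(qn) < rtol * abs(qs[1])) break
    q <- qn; p <- pn
    if (n == max_terms)
      stop("image-charge series did not converge within max_terms", call. = FALSE)
  }
  vapply(z, function(zz)
    sum(k_coul * qs * (1 / (ps - zz)^2 + 1 / (ps + zz)^2)), 0)
}
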
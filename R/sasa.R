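#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals spheres of a set of atoms:
#' each atom's solvent-expanded sphere of radius `r_i + probe` is covered by
#' a deterministic quasi-uniform point set (golden-section spiral), and the
#' accessible area is the fraction of points not inside any other atom's
#' expanded sphere times the sphere area `4 pi (r_i + probe)^2`. For a
#' single isolated atom the result equals the closed form exactly up to the
#' quadrature weight (all points accessible).
#'
#' @param atoms a [fibril_model()], or a data.frame with columns `x`, `y`,
#'   `z`, `radius`
#' @param probe probe radius, Angstrom (default 1.4, a water molecule)
#' @param n_points quadrature points per atom (>= 92; default 960)
#' @return numeric vector of per-atom accessible areas, Angstrom^2
#' @export
#' @examples
#' a <- data.frame(x = 0, y = 0, z = 0, radius = 1.9)
#' shrake_rupley(a)              # ~ 4*pi*3.3^2 = 136.85
shrake_rupley <- function(atoms, probe = 1.4, n_points = 960L) {
  if (inherits(atoms, "fibril_model")) atoms <- atoms$atoms
  stopifnot(all(c("x", "y", "z", "radius") %in% names(atoms)))
  if (n_points < 92) stop("n_points must be >= 92 for a usable quadrature")
  if (any(atoms$radius <= 0)) stop("radii must be positive")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (anyDuplicated(xyz) > 0)
    stop("degenerate input: two atoms share the same position")
  sasa_cpp(xyz, atoms$radius, probe, as.integer(n_points))
}
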
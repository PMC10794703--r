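#' Helical symmetry parameters of a fibril
#'
#' The helical operator relating consecutive layers of a fibril: a rotation
#' (twist, degrees per subunit; negative = left-handed, the convention for
#' amyloid fibrils) combined with an axial translation (rise, Angstrom per
#' subunit). The crossover distance -- the axial length over which the
#' fibril's projection rotates by 180 degrees, the quantity measured directly
#' from micrographs -- is derived as `(180 / |twist|) * rise`.
#'
#' @param twist degrees per subunit, signed; must be nonzero for a twisted
#'   fibril (use `untwisted = TRUE` for straight fibrils)
#' @param rise Angstrom per subunit, > 0
#' @param twist_sd,rise_sd optional dispersion (as reported by
#'   [estimate_helical_parameters()])
#' @param untwisted logical flag for straight fibrils (twist 0; crossover
#'   undefined)
#' @return object of class `helical_parameters` with fields `twist`, `rise`,
#'   `crossover` (NA when untwisted), `untwisted`
#' @export
#' @examples
#' helical_parameters(-1.3, 4.93)  # crossover 683 A
helical_parameters <- function(twist, rise, twist_sd = NA_real_,
                               rise_sd = NA_real_, untwisted = FALSE) {
  stopifnot(is.finite(rise), rise > 0)
  if (!untwisted && (!is.finite(twist) || twist == 0))
    stop("twist must be nonzero for a twisted fibril; ",
         "use untwisted = TRUE for straight fibrils")
  structure(list(twist = if (untwisted) 0 else twist, rise = rise,
                 crossover = if (untwisted) NA_real_
                             else crossover_distance(twist, rise),
                 twist_sd = twist_sd, rise_sd = rise_sd,
                 untwisted = untwisted),
            class = "helical_parameters")
}

#' @export
print.helical_parameters <- function(x, ...) {
  if (x$untwisted) {
    cat(sprintf("helical_parameters: untwisted, rise %.3f A\n", x$rise))
  } else {
    cat(sprintf(
      "helical_parameters: twist %.3f deg/subunit, rise %.3f A/subunit, crossover %.0f A\n",
      x$twist, x$rise, x$crossover))
  }
  invisible(x)
}

#' Crossover distance from twist and rise
#'
#' `crossover = (180 / |twist|) * rise`: the number of subunits per
#' half-turn times the rise per subunit. For the absent-gate ATTRv-I84S fold
#' (twist -1.3 deg, rise 4.93 A) this gives 683 A.
#'
#' @param twist degrees per subunit (signed, nonzero)
#' @param rise Angstrom per subunit (> 0)
#' @return crossover distance in Angstrom
#' @export
#' @examples
#' round(crossover_distance(-1.3, 4.93))  # 683
crossover_distance <- function(twist, rise) {
  stopifnot(is.finite(twist), is.finite(rise), rise > 0)
  if (twist == 0)
    stop("untwisted fibril: crossover distance is infinite ",
         "(straight fibrils lack a twist)")
  (180 / abs(twist)) * rise
}

#' Expand one fibril layer by helical symmetry
#'
#' Applies the helical operator k times to generate a stack: layer k is the
#' input layer rotated by `k * twist` about the helical axis and translated
#' by `k * rise` along it. The axis is the z direction through the centroid
#' of the input layer's C-alpha atoms (the convention in which deposited
#' fibril models are framed).
#'
#' @param layer a single-layer [fibril_model()]
#' @param params [helical_parameters()]
#' @param n_layers number of layers in the output stack (>= 1)
#' @return a [fibril_model()] with `n_layers` layers; layer 0 is the input
#'   unchanged, and the atom count is `n_layers` times the input's
#' @export
expand_symmetry <- function(layer, params, n_layers) {
  stopifnot(n_layers >= 1)
  if (layer$layers != 1) stop("expand_symmetry expects a single-layer model")
  a <- layer$atoms
  if (nrow(a) == 0) stop("empty input layer")
  ca <- a[a$name == "CA", c("x", "y"), drop = FALSE]
  if (nrow(ca) == 0) ca <- a[, c("x", "y"), drop = FALSE]
  ctr <- colMeans(ca)

  out <- vector("list", n_layers)
  for (k in seq_len(n_layers) - 1L) {
    b <- a
    if (k > 0) {
      th <- k * params$twist * pi / 180
      dx <- a$x - ctr[1]; dy <- a$y - ctr[2]
      b$x <- ctr[1] + cos(th) * dx - sin(th) * dy
      b$y <- ctr[2] + sin(th) * dx + cos(th) * dy
      b$z <- a$z + k * params$rise
    }
    b$layer <- k
    out[[k + 1L]] <- b
  }
  fibril_model(do.call(rbind, out), fold = layer$fold, helical = params,
               check = FALSE)
}

#' Estimate twist and rise from a stacked fibril model
#'
#' Inverts the helical operator: each consecutive layer pair is superposed by
#' least squares ([kabsch_superpose()]), the rigid transform is decomposed as
#' a screw motion (rotation angle about the best-fit axis, translation along
#' it), and the per-pair estimates are averaged. The axis is taken from the
#' rotation matrix's unit-eigenvalue eigenvector, oriented so the rise is
#' positive. Twist magnitudes below `untwisted_tol` are reported as an
#' untwisted (straight) fibril.
#'
#' Atoms are matched between layers by (fragment, residue number, atom
#' name); a mismatch in the matched sets is an error.
#'
#' @param model a [fibril_model()] with at least 2 layers
#' @param untwisted_tol degrees; |twist| below this maps to the untwisted
#'   branch (default 0.01)
#' @return [helical_parameters()] with `twist_sd`/`rise_sd` dispersion over
#'   consecutive pairs (NA with < 3 layers)
#' @export
estimate_helical_parameters <- function(model, untwisted_tol = 0.01) {
  if (model$layers < 2) stop("need at least 2 layers")
  a <- model$atoms
  key <- function(d) paste(d$fragment, d$resno, d$name)
  twists <- rises <- numeric(model$layers - 1L)
  for (k in seq_len(model$layers - 1L) - 1L) {
    la <- a[a$layer == k, , drop = FALSE]
    lb <- a[a$layer == k + 1L, , drop = FALSE]
    ka <- key(la); kb <- key(lb)
    if (length(ka) != length(kb) || !setequal(ka, kb))
      stop("layers ", k, " and ", k + 1,
           " have mismatched atom sets; cannot establish correspondence")
    lb <- lb[match(ka, kb), , drop = FALSE]
    fit <- kabsch_superpose(as.matrix(la[, c("x", "y", "z")]),
                            as.matrix(lb[, c("x", "y", "z")]))
    sc <- screw_decompose(fit$rotation, fit$translation)
    twists[k + 1L] <- sc$angle_deg
    rises[k + 1L] <- sc$rise
  }
  tw <- mean(twists); ri <- mean(rises)
  tw_sd <- if (length(twists) > 1) stats::sd(twists) else NA_real_
  ri_sd <- if (length(rises) > 1) stats::sd(rises) else NA_real_
  if (abs(tw) < untwisted_tol)
    helical_parameters(0, ri, tw_sd, ri_sd, untwisted = TRUE)
  else
    helical_parameters(tw, ri, tw_sd, ri_sd)
}

# Decompose a rigid transform x -> R x + t into a screw motion: signed
# rotation angle about the rotation's invariant axis and translation along
# that axis. Axis oriented so the translation component (rise) is positive;
# with that orientation the angle's sign encodes handedness (negative =
# left-handed for a fibril rising along its axis).
screw_decompose <- function(R, t) {
  tr <- sum(diag(R))
  cos_th <- max(-1, min(1, (tr - 1) / 2))
  # axis from the antisymmetric part; near theta = 0 fall back to t direction
  m <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  if (sqrt(sum(m^2)) < 1e-12) {
    u <- t / sqrt(sum(t^2))
    sin_th <- 0
  } else {
    u <- m / sqrt(sum(m^2))
    sin_th <- sqrt(sum(m^2))
  }
  rise <- sum(u * t)
  if (rise < 0) {          # orient axis along the translation
    u <- -u
    sin_th <- -sin_th
    rise <- -rise
  }
  list(angle_deg = atan2(sin_th, cos_th) * 180 / pi, rise = rise, axis = u)
}
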
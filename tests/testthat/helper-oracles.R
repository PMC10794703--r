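# Independent oracles and small fixture builders shared across the suite.

# --- SASA oracle: latitude-longitude surface quadrature ---------------------
# Integrates each atom's accessible area on its solvent-expanded sphere with
# a lat-long grid of ~`spacing` Angstrom arc resolution and sin(theta) area
# weights. Independent of the golden-spiral quadrature in the package.
sasa_latlong_oracle <- function(atoms, probe = 1.4, spacing = 0.1) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  er <- atoms$radius + probe
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- er[i]
    n_th <- ceiling(pi * r / spacing)
    th <- (seq_len(n_th) - 0.5) * pi / n_th
    area_i <- 0
    for (t in th) {
      n_ph <- max(1, ceiling(2 * pi * r * sin(t) / spacing))
      ph <- (seq_len(n_ph) - 0.5) * 2 * pi / n_ph
      pts <- cbind(xyz[i, 1] + r * sin(t) * cos(ph),
                   xyz[i, 2] + r * sin(t) * sin(ph),
                   xyz[i, 3] + r * cos(t))
      w <- r^2 * sin(t) * (pi / n_th) * (2 * pi / n_ph)
      acc <- rep(TRUE, n_ph)
      for (j in seq_len(n)) {
        if (j == i) next
        d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        acc <- acc & d2 >= er[j]^2
      }
      area_i <- area_i + sum(acc) * w
    }
    out[i] <- area_i
  }
  out
}

# exact accessible area of two overlapping solvent-expanded spheres
# (isolated area minus the spherical cap hidden inside the neighbour)
two_sphere_exact <- function(r1, r2, d, probe = 1.4) {
  e1 <- r1 + probe; e2 <- r2 + probe
  cap <- function(ra, rb) {
    if (d >= ra + rb) return(0)
    h <- (rb^2 - (d - ra)^2) / (2 * d)   # cap height on sphere a
    2 * pi * ra * h
  }
  c(4 * pi * e1^2 - cap(e1, e2), 4 * pi * e2^2 - cap(e2, e1))
}

# --- Mann-Whitney oracle: full enumeration ----------------------------------
# Exact two-sided p by enumerating every assignment of the pooled values to
# group A (no ties assumed).
mw_enumerate <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(av, bv) sum(outer(av, bv, `>`))
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pooled), n1)
  u_null <- apply(idx, 2, function(k) u_of(pooled[k], pooled[-k]))
  p <- 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs))
  list(U = u_obs, p = min(1, p))
}

# --- rotation oracle: nested Euler-angle grid search ------------------------
# Minimizes rmsd over SO(3) x translations by grid search with three
# refinement levels; translation is optimal (centroid match) per rotation.
grid_rmsd_oracle <- function(a, b, levels = 3, n0 = 13) {
  a <- as.matrix(a); b <- as.matrix(b)
  A <- sweep(a, 2, colMeans(a)); B <- sweep(b, 2, colMeans(b))
  rot <- function(al, be, ga) {
    Rz1 <- matrix(c(cos(al), sin(al), 0, -sin(al), cos(al), 0, 0, 0, 1), 3)
    Ry <- matrix(c(cos(be), 0, -sin(be), 0, 1, 0, sin(be), 0, cos(be)), 3)
    Rz2 <- matrix(c(cos(ga), sin(ga), 0, -sin(ga), cos(ga), 0, 0, 0, 1), 3)
    Rz1 %*% Ry %*% Rz2
  }
  score <- function(al, be, ga)
    sqrt(mean(rowSums((A %*% t(rot(al, be, ga)) - B)^2)))
  ctr <- c(pi, pi / 2, pi)
  span <- c(pi, pi / 2, pi)
  best <- c(ctr, Inf)
  for (lv in seq_len(levels)) {
    als <- seq(ctr[1] - span[1], ctr[1] + span[1], length.out = n0)
    bes <- seq(max(0, ctr[2] - span[2]), min(pi, ctr[2] + span[2]),
               length.out = n0)
    gas <- seq(ctr[3] - span[3], ctr[3] + span[3], length.out = n0)
    for (al in als) for (be in bes) for (ga in gas) {
      s <- score(al, be, ga)
      if (s < best[4]) best <- c(al, be, ga, s)
    }
    ctr <- best[1:3]
    span <- span / (n0 / 2.5)
  }
  best[4]
}

# --- fixture builders -------------------------------------------------------
toy_atoms <- function(xyz, radius = 1.9, element = "C") {
  data.frame(element = element, name = "CA", resno = seq_len(nrow(xyz)),
             resid = "ALA", fragment = "N", layer = 0L,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], radius = radius,
             stringsAsFactors = FALSE)
}

# small two-fragment layer: a short straight N piece and C piece side by side
mini_layer <- function(n = 6) {
  layer_spec(list(
    layer_piece("N", 1:n, rep("A", n), anchor = c(0, 0)),
    layer_piece("C", (n + 2):(2 * n + 1), rep("V", n), anchor = c(0, 5))))
}

rigid_transform <- function(xyz, axis = c(0, 0, 1), angle_deg = 30,
                            shift = c(1, -2, 3)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(as.matrix(xyz) %*% t(R), 2, shift, `+`)
}
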
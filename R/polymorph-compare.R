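#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' sum ||R a_i + t - b_i||^2 via SVD of the covariance matrix, with the
#' determinant sign corrected so reflections are never returned.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices in correspondence
#'   (n >= 3, not all collinear)
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) such
#'   that `coords_a %*% t(rotation) + translation` best fits `coords_b`, and
#'   `rmsd` (Angstrom)
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b))
    stop("coordinate sets differ in length (", nrow(coords_a), " vs ",
         nrow(coords_b), "); no correspondence")
  n <- nrow(coords_a)
  if (n < 3) stop("need at least 3 points for superposition")
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  # collinear input leaves the rotation about the line undetermined
  if (qr(A, tol = 1e-8)$rank < 2 || qr(B, tol = 1e-8)$rank < 2)
    stop("degenerate geometry: points are collinear, superposition ill-conditioned")
  H <- crossprod(A, B)                 # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cb - as.vector(R %*% ca)
  fitted <- A %*% t(R)                 # centered fit
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Apply a rigid transform from [kabsch_superpose()] to coordinates
#' @param coords n x 3 matrix
#' @param fit list with `rotation` and `translation`
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Residue correspondence between two fibril models
#'
#' Pairs residues by identical residue number (same protein, so no sequence
#' alignment is needed), restricted to residues whose C-alpha is present in
#' both models; each pair is flagged as common-core or not. The default core
#' is the region shared by all ATTRv-I84S folds, Leu12-Lys35 and
#' Gly67-Val122.
#'
#' @param model_a,model_b [fibril_model()]s
#' @param core residue ranges defining the common core
#'   (default [ttr_common_core()])
#' @param layer layer to inspect for presence (default 0)
#' @return data.frame with columns `resno`, `core` (logical); attribute
#'   `excluded` lists residues present in only one model
#' @export
common_core <- function(model_a, model_b, core = ttr_common_core(),
                        layer = 0L) {
  ca_a <- model_a$atoms[model_a$atoms$name == "CA" &
                          model_a$atoms$layer == layer, "resno"]
  ca_b <- model_b$atoms[model_b$atoms$name == "CA" &
                          model_b$atoms$layer == layer, "resno"]
  shared <- sort(intersect(ca_a, ca_b))
  core_res <- residue_set(core)
  if (sum(shared %in% core_res) < 3)
    stop("insufficient overlap: fewer than 3 shared core residues")
  out <- data.frame(resno = shared, core = shared %in% core_res)
  attr(out, "excluded") <- sort(union(setdiff(ca_a, ca_b),
                                      setdiff(ca_b, ca_a)))
  out
}

#' Superpose two fibril folds and profile per-residue deviations
#'
#' One Kabsch fit is computed on the fit set (common-core or all shared
#' residues) across `layers` consecutive layers, then per-residue C-alpha
#' distances are reported for ALL shared residues under that single fit --
#' so regions outside the fit set (e.g. a displaced gate) can deviate far
#' beyond the overall r.m.s.d. The overall r.m.s.d. is taken over the fit
#' set, matching how overall values are quoted for fold alignments.
#'
#' @param model_a,model_b [fibril_model()]s with at least `layers` layers
#'   (a single-layer model with helical parameters is expanded)
#' @param layers number of consecutive layers aligned (default 3; layer
#'   stacking captures inter-fold differences in layer tilt)
#' @param fit_set "common_core" or "all_shared"
#' @param core core ranges used when `fit_set = "common_core"` and for the
#'   core flag (default [ttr_common_core()])
#' @return object of class `deviation_profile`: list with `rmsd` (overall,
#'   Angstrom), `per_residue` (data.frame resno, core, distance -- RMS over
#'   the layer copies of each residue), `fit_set`, `layers`, `n_fit_atoms`
#' @export
fold_rmsd <- function(model_a, model_b, layers = 3L,
                      fit_set = c("all_shared", "common_core"),
                      core = ttr_common_core()) {
  fit_set <- match.arg(fit_set)
  model_a <- ensure_layers(model_a, layers)
  model_b <- ensure_layers(model_b, layers)
  corr <- common_core(model_a, model_b, core = core)
  fit_res <- if (fit_set == "common_core") corr$resno[corr$core] else corr$resno

  coords <- function(m, res) {
    do.call(rbind, lapply(seq_len(layers) - 1L, function(k)
      select_calpha(m, res, layer = k)))
  }
  A_fit <- coords(model_a, fit_res); B_fit <- coords(model_b, fit_res)
  if (nrow(A_fit) != nrow(B_fit))
    stop("fit-set atoms differ between models across layers")
  fit <- kabsch_superpose(A_fit, B_fit)

  A_all <- coords(model_a, corr$resno); B_all <- coords(model_b, corr$resno)
  d <- sqrt(rowSums((apply_transform(A_all, fit) - B_all)^2))
  resno_all <- rep(corr$resno, layers)
  per_res <- vapply(split(d, resno_all),
                    function(v) sqrt(mean(v^2)), numeric(1))
  ord <- match(as.character(corr$resno), names(per_res))
  structure(list(rmsd = fit$rmsd,
                 per_residue = data.frame(resno = corr$resno,
                                          core = corr$core,
                                          distance = unname(per_res[ord])),
                 fit_set = fit_set, layers = layers,
                 n_fit_atoms = nrow(A_fit),
                 excluded = attr(corr, "excluded")),
            class = "deviation_profile")
}

ensure_layers <- function(model, layers) {
  if (model$layers >= layers) return(model)
  if (model$layers == 1 && !is.null(model$helical))
    return(expand_symmetry(model, model$helical, layers))
  stop("model has ", model$layers, " layer(s), needs ", layers,
       " and no helical parameters to expand with")
}

#' @export
print.deviation_profile <- function(x, ...) {
  cat(sprintf(
    "deviation_profile: overall r.m.s.d. %.2f A (%s fit, %d layer(s), %d atoms)\n",
    x$rmsd, x$fit_set, x$layers, x$n_fit_atoms))
  cat(sprintf("  per-residue range %.2f-%.2f A over %d residues\n",
              min(x$per_residue$distance), max(x$per_residue$distance),
              nrow(x$per_residue)))
  invisible(x)
}

#' Pairwise deviation matrix over a set of fibril models
#'
#' All-against-all [fold_rmsd()]: a symmetric overall-r.m.s.d. matrix with a
#' zero diagonal, plus the per-residue profiles for heatmap rendering.
#' Residues missing from any pair are recorded per profile.
#'
#' @param models named list of [fibril_model()]s (>= 2)
#' @param ... passed to [fold_rmsd()]
#' @return list with `rmsd` (symmetric matrix) and `profiles` (named list of
#'   `deviation_profile`s, names "a|b")
#' @export
deviation_matrix <- function(models, ...) {
  stopifnot(length(models) >= 2)
  nm <- names(models)
  if (is.null(nm)) nm <- paste0("model", seq_along(models))
  M <- matrix(0, length(models), length(models), dimnames = list(nm, nm))
  profiles <- list()
  for (i in seq_along(models)) for (j in seq_along(models)) {
    if (j <= i) next
    p <- fold_rmsd(models[[i]], models[[j]], ...)
    M[i, j] <- M[j, i] <- p$rmsd
    profiles[[paste(nm[i], nm[j], sep = "|")]] <- p
  }
  list(rmsd = M, profiles = profiles)
}
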
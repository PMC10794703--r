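#' Atomic solvation parameter (ASP) tables
#'
#' An ASP table maps atom classes -- apolar carbon "C", neutral nitrogen
#' "N", neutral oxygen "O", carboxylate/charged oxygen "O-", charged
#' nitrogen "N+", sulfur "S" -- to solvation parameters sigma in
#' cal/(mol*Angstrom^2). Tables are always loaded from a config file so the
#' parameter set is swappable and its provenance travels with the results;
#' the shipped default is the classic five-class set of the
#' Eisenberg-McLachlan type.
#'
#' @param path YAML file with a `sigma` mapping and a `provenance` string
#' @return object of class `asp_table`: list with `sigma` (named numeric)
#'   and `provenance`
#' @export
read_asp_table <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$sigma)) stop("ASP config must contain a `sigma` mapping")
  sig <- unlist(y$sigma)
  storage.mode(sig) <- "double"
  structure(list(sigma = sig,
                 provenance = y$provenance %||% "unspecified"),
            class = "asp_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_asp_table
#' @export
default_asp_table <- function() {
  read_asp_table(system.file("extdata", "asp_eisenberg.yaml",
                             package = "fibrilstab"))
}

#' Classify atoms into solvation classes
#'
#' Assigns each atom to an ASP class from its element, atom name and residue
#' type: Asp/Glu carboxylate oxygens and the C-terminal OXT are charged
#' "O-"; Lys NZ, Arg guanidinium nitrogens and (optionally) the free
#' N-terminal amine of each fragment are charged "N+"; everything else maps
#' by element (C, N, O, S).
#'
#' @param atoms atom data.frame (as in a [fibril_model()])
#' @param terminal_charges treat the backbone N of each fragment's first
#'   residue as charged (fragments are proteolytic products with free
#'   termini; default TRUE)
#' @return character vector of class labels
#' @export
classify_atoms <- function(atoms, terminal_charges = TRUE) {
  cls <- atoms$element
  o_neg <- (atoms$resid == "ASP" & atoms$name %in% c("OD1", "OD2")) |
           (atoms$resid == "GLU" & atoms$name %in% c("OE1", "OE2")) |
           atoms$name == "OXT"
  n_pos <- (atoms$resid == "LYS" & atoms$name == "NZ") |
           (atoms$resid == "ARG" & atoms$name %in% c("NE", "NH1", "NH2"))
  if (terminal_charges) {
    grp <- paste(atoms$layer, atoms$fragment)
    first_res <- stats::ave(atoms$resno, grp, FUN = min)
    n_pos <- n_pos | (atoms$name == "N" & atoms$resno == first_res)
  }
  cls[o_neg] <- "O-"
  cls[n_pos] <- "N+"
  cls
}

#' Per-atom buried area of one fibril layer in its stack
#'
#' The area buried for each atom is the difference between its accessible
#' area in a reference state and in the full assembly:
#' `dA_i = A_i(reference) - A_i(assembly)`. Two reference states are
#' supported: `isolated_chain` (the target layer alone, in the same
#' conformation -- burial then measures inter-chain contacts only) and
#' `fully_extended` (each atom scored against only its own residue and the
#' two sequence neighbours within the fragment, the standard
#' unfolded-reference approximation -- burial then also counts
#' intra-chain folding contacts).
#'
#' A target layer at the stack boundary is only half-buried; a warning
#' recommends scoring a central layer.
#'
#' @param model a stacked [fibril_model()]
#' @param target_layer 0-based layer to score
#' @param reference "isolated_chain" (default) or "fully_extended"
#' @param probe probe radius, Angstrom
#' @param n_points quadrature points per atom
#' @return the target layer's atom data.frame with added columns
#'   `area_ref`, `area_assembly`, `buried` (all Angstrom^2)
#' @export
buried_area <- function(model, target_layer = NULL,
                        reference = c("isolated_chain", "fully_extended"),
                        probe = 1.4, n_points = 960L) {
  reference <- match.arg(reference)
  if (is.null(target_layer)) target_layer <- (model$layers - 1L) %/% 2L
  a <- model$atoms
  if (!target_layer %in% a$layer)
    stop("layer ", target_layer, " not present in model")
  if (model$layers > 1 &&
      (target_layer == 0L || target_layer == model$layers - 1L))
    warning("target layer ", target_layer,
            " is at the stack boundary; burial is underestimated - ",
            "score a central layer")
  in_layer <- a$layer == target_layer
  area_full <- shrake_rupley(a, probe = probe, n_points = n_points)[in_layer]
  tl <- a[in_layer, , drop = FALSE]
  area_ref <- switch(reference,
    isolated_chain = shrake_rupley(tl, probe = probe, n_points = n_points),
    fully_extended = extended_reference_area(tl, probe, n_points))
  out <- tl
  out$area_ref <- area_ref
  out$area_assembly <- area_full
  out$buried <- area_ref - area_full
  out
}

# tripeptide-context reference: each residue's atoms scored against residues
# resno-1 .. resno+1 of the same fragment only
extended_reference_area <- function(tl, probe, n_points) {
  area <- numeric(nrow(tl))
  for (fr in unique(tl$fragment)) {
    sel_f <- tl$fragment == fr
    sub <- tl[sel_f, , drop = FALSE]
    for (r in unique(sub$resno)) {
      ctx <- sub[abs(sub$resno - r) <= 1, , drop = FALSE]
      res_area <- shrake_rupley(ctx, probe = probe, n_points = n_points)
      idx_global <- which(sel_f)[sub$resno == r]
      area[idx_global] <- res_area[ctx$resno == r]
    }
  }
  area
}

#' Solvation stabilization energy of a fibril chain
#'
#' Scores the central chain (layer) of a helically expanded stack: the
#' buried area of each atom is multiplied by its atomic solvation parameter
#' and summed per residue and per chain. The sign convention is that of a
#' burial free energy -- burying apolar surface is stabilizing and negative
#' in kcal/mol, burying charged surface is destabilizing and positive --
#' i.e. `e_i = -sigma_i * dA_i / 1000` with sigma in cal/(mol*Angstrom^2).
#' Per-chain energy is the sum over both fragments of one layer, matching
#' the "per chain" quantity quoted for fibril stability comparisons.
#'
#' @param model a [fibril_model()]; a single-layer model with helical
#'   parameters is expanded to an odd stack of `stack_layers`
#' @param asp an [read_asp_table()] object (default [default_asp_table()])
#' @param stack_layers stack size for expansion (default 5; the scored layer
#'   is the central one)
#' @param reference reference state, see [buried_area()]
#' @param probe,n_points SASA settings
#' @param terminal_charges see [classify_atoms()]
#' @return object of class `energy_profile`: list with `atoms` (per-atom
#'   table with `class`, `sigma`, `buried`, `energy`), `residues`
#'   (per-residue energies, kcal/mol), `chain_energy` (kcal/mol), and
#'   `context` metadata (stack size, probe, point count, reference,
#'   ASP provenance, sign convention)
#' @export
stabilization_energy <- function(model, asp = default_asp_table(),
                                 stack_layers = 5L,
                                 reference = c("isolated_chain",
                                               "fully_extended"),
                                 probe = 1.4, n_points = 960L,
                                 terminal_charges = TRUE) {
  reference <- match.arg(reference)
  if (model$layers == 1) {
    if (is.null(model$helical))
      stop("single-layer model without helical parameters cannot be stacked")
    n <- 2L * (as.integer(stack_layers) %/% 2L) + 1L
    model <- expand_symmetry(model, model$helical, n)
  }
  central <- (model$layers - 1L) %/% 2L
  ba <- buried_area(model, central, reference = reference,
                    probe = probe, n_points = n_points)
  cls <- classify_atoms(ba, terminal_charges = terminal_charges)
  sigma <- asp$sigma[cls]
  if (anyNA(sigma)) {
    bad <- which(is.na(sigma))[1]
    stop("no solvation parameter for atom class \"", cls[bad],
         "\" (atom ", ba$name[bad], " of ", ba$resid[bad], " ",
         ba$resno[bad], "); extend the ASP config")
  }
  ba$class <- cls
  ba$sigma <- unname(sigma)
  ba$energy <- -ba$sigma * ba$buried / 1000   # cal -> kcal, burial sign

  key <- paste(ba$fragment, ba$resno)
  res_split <- split(ba$energy, factor(key, levels = unique(key)))
  first <- !duplicated(key)
  residues <- data.frame(resno = ba$resno[first],
                         resid = ba$resid[first],
                         fragment = ba$fragment[first],
                         energy = vapply(res_split, sum, numeric(1)),
                         row.names = NULL)
  structure(list(atoms = ba, residues = residues,
                 chain_energy = sum(ba$energy),
                 context = list(stack_layers = model$layers,
                                scored_layer = central,
                                probe = probe, n_points = n_points,
                                reference = reference,
                                asp_provenance = asp$provenance,
                                sign_convention =
                                  "energy = -sigma * buried_area; stabilizing burial is negative kcal/mol",
                                units = "kcal/mol")),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf(
    "energy_profile: chain energy %.1f kcal/mol over %d residues (%d atoms)\n",
    x$chain_energy, nrow(x$residues), nrow(x$atoms)))
  cat(sprintf("  context: %d-layer stack, central layer %d, %s reference, ASP: %s\n",
              x$context$stack_layers, x$context$scored_layer,
              x$context$reference, x$context$asp_provenance))
  invisible(x)
}

#' Map per-residue energies to color bins
#'
#' Deterministic binning of per-residue energies for structure coloring:
#' strongly stabilizing residues map to the red end, destabilizing residues
#' to the blue end, following the usual convention for solvation energy
#' maps. Returned as a table usable to set per-residue colors (or B-factor
#' encodings) in a viewer.
#'
#' @param profile an [stabilization_energy()] result
#' @param breaks bin edges in kcal/mol (default 11 symmetric bins over
#'   +/- the largest |energy|, so an all-zero profile lands in one neutral
#'   central bin)
#' @param palette vector of colors, one per bin (default red-white-blue)
#' @return data.frame with `resno`, `fragment`, `energy`, `bin`, `color`
#' @export
residue_energy_colormap <- function(profile, breaks = NULL, palette = NULL) {
  e <- profile$residues$energy
  if (is.null(breaks)) {
    lim <- max(abs(e), 1e-9)
    breaks <- seq(-lim, lim, length.out = 12)
  }
  n_bins <- length(breaks) - 1
  if (is.null(palette))
    palette <- grDevices::colorRampPalette(
      c("#b2182b", "#ffffff", "#2166ac"))(n_bins)
  if (length(palette) != n_bins)
    stop("palette must provide one color per bin (", n_bins, ")")
  bin <- cut(e, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  bin[is.na(bin) & e <= breaks[1]] <- 1L
  bin[is.na(bin)] <- n_bins
  data.frame(resno = profile$residues$resno,
             fragment = profile$residues$fragment,
             energy = e, bin = bin, color = palette[bin])
}
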
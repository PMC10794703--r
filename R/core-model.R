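#' Construct a fibril model
#'
#' A `fibril_model` is the central container of the package: an ordered atom
#' table grouped into layers (rungs of the cross-beta stack) and fragments
#' (the N- and C-terminal proteolytic fragments of transthyretin that make up
#' each layer at a 1:1 ratio), plus optional fold and helical-parameter
#' annotations.
#'
#' Residue numbers follow the mature-transthyretin convention (1-127) and are
#' never renumbered by this package: they are taken verbatim from input files
#' so that residue ranges quoted in the structural literature (e.g. the common
#' core Leu12-Lys35 and Gly67-Val122) apply directly.
#'
#' @param atoms data.frame with columns `element` (symbol), `name` (atom
#'   name, e.g. "CA"), `resno` (integer residue number), `resid` (3-letter
#'   residue code), `fragment` ("N" or "C"), `layer` (integer, 0 = reference
#'   layer), `x`, `y`, `z` (Angstrom) and optionally `radius` (van der Waals
#'   radius, Angstrom; filled from `radii` when absent).
#' @param fold optional [fold_definition()].
#' @param helical optional [helical_parameters()].
#' @param radii named numeric vector of united-atom van der Waals radii per
#'   element, used to fill a missing `radius` column. See [vdw_radii()].
#' @param check validate invariants (default TRUE). Checks cover: positive
#'   radii, finite coordinates, residue numbers in 1..127 when
#'   `ttr_numbering`, contiguous layer indices, strictly increasing residue
#'   numbers within each (layer, fragment), and both fragments present in
#'   every layer when more than one fragment is used.
#' @param ttr_numbering enforce the 1..127 mature-TTR residue-number range
#'   (default TRUE).
#' @return object of class `fibril_model`: a list with elements `atoms`
#'   (data.frame), `layers` (count), `fold`, `helical`.
#' @export
#' @examples
#' a <- data.frame(element = "C", name = "CA", resno = 12, resid = "LEU",
#'                 fragment = "N", layer = 0L, x = 0, y = 0, z = 0)
#' m <- fibril_model(a)
#' n_atoms(m)
fibril_model <- function(atoms, fold = NULL, helical = NULL,
                         radii = vdw_radii(), check = TRUE,
                         ttr_numbering = TRUE) {
  req <- c("element", "name", "resno", "resid", "fragment", "layer",
           "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0)
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  atoms$resno <- as.integer(atoms$resno)
  atoms$layer <- as.integer(atoms$layer)
  atoms$fragment <- as.character(atoms$fragment)
  if (!"radius" %in% names(atoms)) {
    atoms$radius <- unname(radii[atoms$element])
    atoms$radius[is.na(atoms$radius)] <- radii[[".default"]]
  }
  rownames(atoms) <- NULL

  m <- structure(list(atoms = atoms,
                      layers = if (nrow(atoms)) max(atoms$layer) + 1L else 0L,
                      fold = fold, helical = helical),
                 class = "fibril_model")
  if (check) validate_fibril_model(m, ttr_numbering = ttr_numbering)
  m
}

validate_fibril_model <- function(m, ttr_numbering = TRUE) {
  a <- m$atoms
  if (nrow(a) == 0) stop("fibril model contains no atoms")
  if (any(!is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(!is.finite(a$radius)) || any(a$radius <= 0))
    stop("all van der Waals radii must be positive")
  if (ttr_numbering && any(a$resno < 1 | a$resno > 127))
    stop("residue numbers outside mature-TTR range 1..127 ",
         "(use ttr_numbering = FALSE for non-TTR models)")
  if (!all(a$fragment %in% c("N", "C")))
    stop("fragment must be \"N\" or \"C\"")
  lays <- sort(unique(a$layer))
  if (!identical(lays, seq(0L, max(lays))))
    stop("layer indices must be contiguous from 0")
  # residue order within each (layer, fragment): strictly increasing
  sp <- split(a$resno, list(a$layer, a$fragment), drop = TRUE)
  for (nm in names(sp)) {
    r <- unique(sp[[nm]])  # atoms of one residue are adjacent repetitions
    if (any(diff(r) <= 0))
      stop("residue numbers not strictly increasing within layer/fragment ", nm)
  }
  # 1:1 fragment ratio per layer when both fragments are in play
  if (length(unique(a$fragment)) == 2) {
    tab <- table(a$layer, a$fragment)
    if (any(tab == 0))
      stop("every layer must contain both N and C fragments (1:1 per layer)")
  }
  invisible(m)
}

#' @export
print.fibril_model <- function(x, ...) {
  a <- x$atoms
  cat("fibril_model:", nrow(a), "atoms,", x$layers, "layer(s)\n")
  for (fr in intersect(c("N", "C"), unique(a$fragment))) {
    r <- range(a$resno[a$fragment == fr])
    cat(sprintf("  %s fragment: residues %d-%d\n", fr, r[1], r[2]))
  }
  if (!is.null(x$fold)) cat("  fold:", x$fold$name, "\n")
  if (!is.null(x$helical))
    cat(sprintf("  helical: twist %.3f deg, rise %.3f A, crossover %.0f A\n",
                x$helical$twist, x$helical$rise, x$helical$crossover))
  invisible(x)
}

#' Number of atoms in a fibril model
#' @param model a [fibril_model()]
#' @return integer atom count
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Extract one layer of a fibril model as a new single-layer model
#' @param model a [fibril_model()]
#' @param layer 0-based layer index
#' @return `fibril_model` whose single layer is re-indexed to 0
#' @export
get_layer <- function(model, layer) {
  a <- model$atoms[model$atoms$layer == layer, , drop = FALSE]
  if (nrow(a) == 0) stop("layer ", layer, " not present in model")
  a$layer <- 0L
  fibril_model(a, fold = model$fold, helical = model$helical,
               check = FALSE)
}

#' United-atom van der Waals radii
#'
#' Default heavy-atom radius table used for solvent-accessible surface area.
#' United-atom radii absorb the hydrogens that cryo-EM models at typical
#' fibril resolutions (3-4 Angstrom) do not carry. The table is a
#' configuration value, not a constant: pass your own named vector (element
#' symbol -> radius in Angstrom, with a `.default` entry) anywhere a `radii`
#' argument is accepted, or load one from a YAML file with
#' [read_radius_table()].
#'
#' @return named numeric vector of radii in Angstrom with a `.default` entry.
#' @export
vdw_radii <- function() {
  c(C = 1.9, N = 1.7, O = 1.4, S = 1.8, P = 1.8, H = 1.0, .default = 1.7)
}

#' Read a radius table from a YAML config file
#' @param path YAML file mapping element symbols to radii (Angstrom);
#'   an optional `.default` entry covers unlisted elements.
#' @return named numeric vector as in [vdw_radii()]
#' @export
read_radius_table <- function(path) {
  v <- unlist(yaml::read_yaml(path))
  v <- v[!names(v) %in% "provenance"]
  storage.mode(v) <- "double"
  if (!".default" %in% names(v)) v[".default"] <- 1.7
  v
}

#' Select C-alpha coordinates from one layer
#'
#' Pulls the C-alpha coordinate of each requested residue present in the
#' model's given layer, in residue order (N fragment first, then C fragment).
#' Residues requested but absent are omitted from the result and reported in
#' the `omitted` attribute, so selected + omitted always partitions the
#' request against what the model holds.
#'
#' @param model a [fibril_model()]
#' @param residues integer vector of residue numbers, or a list of
#'   `c(lo, hi)` inclusive ranges (see [residue_set()]).
#' @param layer 0-based layer index (default 0)
#' @return numeric matrix (n x 3) of coordinates with rownames = residue
#'   numbers, attribute `omitted` = requested residues with no C-alpha, and
#'   attribute `resno` = selected residue numbers in order.
#' @export
select_calpha <- function(model, residues, layer = 0L) {
  if (!layer %in% model$atoms$layer)
    stop("layer ", layer, " not present in model")
  want <- residue_set(residues)
  a <- model$atoms
  ca <- a[a$layer == layer & a$name == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("model layer has no C-alpha atoms")
  # preserve fragment order N then C, residue order within fragment
  ca <- ca[order(match(ca$fragment, c("N", "C")), ca$resno), , drop = FALSE]
  keep <- ca[ca$resno %in% want, , drop = FALSE]
  xyz <- as.matrix(keep[, c("x", "y", "z")])
  rownames(xyz) <- keep$resno
  attr(xyz, "resno") <- keep$resno
  attr(xyz, "omitted") <- setdiff(want, keep$resno)
  xyz
}

#' Expand a residue-range specification into a residue-number vector
#' @param residues integer vector, or list of `c(lo, hi)` inclusive ranges
#' @return sorted unique integer vector
#' @export
residue_set <- function(residues) {
  if (is.list(residues))
    residues <- unlist(lapply(residues, function(r) seq(r[1], r[2])))
  sort(unique(as.integer(residues)))
}
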
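#' Canonical chain mapping for stacked fibril models
#'
#' Deposited fibril entries label every stacked chain separately; this
#' package relates chain ids to (layer, fragment) through an explicit,
#' user-overridable mapping. The canonical scheme used when writing models is
#' two chains per layer: layer k's N fragment gets chain `2k+1` and its C
#' fragment chain `2k+2` from the sequence A, B, C, ... Z, a, ... z.
#'
#' @param n_layers number of layers
#' @return data.frame with columns `chain`, `layer`, `fragment`
#' @export
canonical_chain_mapping <- function(n_layers) {
  ids <- c(LETTERS, letters)
  if (2 * n_layers > length(ids))
    stop("canonical chain alphabet exhausted (> ", length(ids) %/% 2,
         " layers); supply an explicit mapping")
  data.frame(chain = ids[seq_len(2 * n_layers)],
             layer = rep(seq_len(n_layers) - 1L, each = 2),
             fragment = rep(c("N", "C"), n_layers),
             stringsAsFactors = FALSE)
}

#' Read a chain-mapping config file
#'
#' Plain key-value format, one line per chain: `chain = layer,fragment`
#' (e.g. `A = 0,N`). Lines starting with `#` are comments.
#'
#' @param path config file path
#' @return data.frame with columns `chain`, `layer`, `fragment`
#' @export
read_chain_mapping <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  parts <- strsplit(ln, "=", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed chain-mapping line: ", ln[bad][1])
  chain <- trimws(vapply(parts, `[`, "", 1))
  rhs <- strsplit(trimws(vapply(parts, `[`, "", 2)), ",", fixed = TRUE)
  if (any(lengths(rhs) != 2)) stop("chain-mapping values must be layer,fragment")
  data.frame(chain = chain,
             layer = as.integer(trimws(vapply(rhs, `[`, "", 1))),
             fragment = toupper(trimws(vapply(rhs, `[`, "", 2))),
             stringsAsFactors = FALSE)
}

#' Read a fibril structure from PDB or mmCIF
#'
#' All ATOM records are retained with author residue numbers (no
#' renumbering); hydrogens are dropped, and for alternate locations only the
#' highest-occupancy conformer is kept. Chains are mapped to
#' (layer, fragment) through `mapping`.
#'
#' @param path input file
#' @param format "pdb", "cif" or "auto" (by extension; default)
#' @param mapping chain mapping: a data.frame as from
#'   [canonical_chain_mapping()] or [read_chain_mapping()], a path to a
#'   mapping file, or "canonical" to infer the canonical two-chains-per-layer
#'   scheme from the chains present.
#' @param ttr_numbering enforce the 1..127 residue range (default TRUE)
#' @param radii radius table for the `radius` column (see [vdw_radii()])
#' @return a [fibril_model()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           mapping = "canonical", ttr_numbering = TRUE,
                           radii = vdw_radii()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("could not parse ", path, " as ", format,
                             ": ", conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)

  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == ""))
    elem <- element_from_name(at$elety)
  elem <- toupper(trimws(elem))
  keep <- elem != "H" & elem != "D"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]

  # altloc: keep highest occupancy per (chain, resno, atom name)
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$elety)
    ord <- order(key, -occ)
    at <- at[ord, , drop = FALSE]
    elem <- elem[ord]
    dup <- duplicated(paste(at$chain, at$resno, at$elety))
    at <- at[!dup, , drop = FALSE]
    elem <- elem[!dup]
  }

  map <- resolve_mapping(mapping, unique(at$chain))
  idx <- match(at$chain, map$chain)
  if (anyNA(idx)) {
    missing_chain <- unique(at$chain[is.na(idx)])
    stop("chain(s) not in mapping: ", paste(missing_chain, collapse = ", "))
  }
  atoms <- data.frame(element = elem,
                      name = trimws(at$elety),
                      resno = as.integer(at$resno),
                      resid = trimws(at$resid),
                      fragment = map$fragment[idx],
                      layer = map$layer[idx],
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms <- atoms[order(atoms$layer, match(atoms$fragment, c("N", "C")),
                       atoms$resno), , drop = FALSE]
  fibril_model(atoms, radii = radii, ttr_numbering = ttr_numbering)
}

resolve_mapping <- function(mapping, chains) {
  if (is.data.frame(mapping)) return(mapping)
  if (is.character(mapping) && length(mapping) == 1) {
    if (identical(mapping, "canonical")) {
      ids <- c(LETTERS, letters)
      pos <- match(chains, ids)
      if (anyNA(pos))
        stop("chain(s) not in mapping: ",
             paste(chains[is.na(pos)], collapse = ", "),
             " (canonical scheme covers A-Z, a-z)")
      n_layers <- ceiling(max(pos) / 2)
      return(canonical_chain_mapping(n_layers))
    }
    return(read_chain_mapping(mapping))
  }
  stop("mapping must be a data.frame, a file path, or \"canonical\"")
}

element_from_name <- function(name) {
  nm <- trimws(name)
  first <- substr(gsub("[0-9']", "", nm), 1, 1)
  toupper(first)
}

#' Write a fibril structure to PDB or mmCIF
#'
#' Chains are assigned by the canonical two-chains-per-layer scheme
#' ([canonical_chain_mapping()]); coordinates survive a write/read
#' round-trip to 1e-3 Angstrom (the PDB fixed-format precision). Residue
#' numbers are written verbatim. Models with more than 99,999 atoms exceed
#' the PDB fixed-width serial field and are refused in PDB format; use mmCIF.
#'
#' @param model a [fibril_model()]
#' @param path output file
#' @param format "pdb" or "cif" (default by extension, falling back to pdb)
#' @return invisibly, the path
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (n_atoms(model) == 0) stop("refusing to write an empty model")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  a <- model$atoms
  map <- canonical_chain_mapping(model$layers)
  chain <- map$chain[match(paste(a$layer, a$fragment),
                           paste(map$layer, map$fragment))]
  if (format == "pdb") {
    if (nrow(a) > 99999)
      stop("model has ", nrow(a),
           " atoms; PDB serial field overflows above 99,999 - write mmCIF")
    xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$name,
                     chain = chain, elesy = a$element,
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  } else {
    write_mmcif_atoms(a, chain, path)
  }
  invisible(path)
}

# minimal mmCIF atom_site writer (the installed structure toolkit reads but
# does not write mmCIF)
write_mmcif_atoms <- function(a, chain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_fibrilstab",
               "#",
               "loop_",
               "_atom_site.group_PDB",
               "_atom_site.id",
               "_atom_site.type_symbol",
               "_atom_site.label_atom_id",
               "_atom_site.label_alt_id",
               "_atom_site.label_comp_id",
               "_atom_site.label_asym_id",
               "_atom_site.label_entity_id",
               "_atom_site.label_seq_id",
               "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x",
               "_atom_site.Cartn_y",
               "_atom_site.Cartn_z",
               "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv",
               "_atom_site.auth_seq_id",
               "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id",
               "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
    seq_len(nrow(a)), a$element, a$name, a$resid, chain, a$resno,
    a$x, a$y, a$z, a$resno, a$resid, chain, a$name)
  writeLines(rows, con)
  writeLines("#", con)
}
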
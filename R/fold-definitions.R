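#' Define a fibril polymorph (fold)
#'
#' A fold names one backbone conformation of the ATTR fibril and records the
#' residue spans of its two fragments plus the gate annotation. The "gate" is
#' the C-terminal segment around Leu58-Gly67 that closes, extends, or is
#' missing from the polar channel, and is what distinguishes the four
#' polymorphs resolved from ATTRv-I84S patients.
#'
#' @param name one of "closed_gate", "open_gate", "absent_gate",
#'   "broken_gate", "custom"
#' @param n_range inclusive `c(lo, hi)` residue interval of the N fragment
#' @param c_range inclusive `c(lo, hi)` residue interval of the C fragment
#' @param gate_range inclusive residue interval of the gate, or NULL when the
#'   gate is unmodelled
#' @return object of class `fold_definition`
#' @export
fold_definition <- function(name, n_range, c_range, gate_range = NULL) {
  name <- match.arg(name, c("closed_gate", "open_gate", "absent_gate",
                            "broken_gate", "custom"))
  stopifnot(length(n_range) == 2, length(c_range) == 2,
            n_range[1] <= n_range[2], c_range[1] <= c_range[2])
  if (n_range[2] >= c_range[1])
    stop("n_range must precede c_range and not overlap it")
  if (!is.null(gate_range)) {
    stopifnot(length(gate_range) == 2, gate_range[1] <= gate_range[2])
    if (gate_range[1] <= n_range[2])
      stop("gate_range overlaps the N fragment")
  }
  structure(list(name = name,
                 n_range = as.integer(n_range),
                 c_range = as.integer(c_range),
                 gate_range = if (is.null(gate_range)) NULL
                              else as.integer(gate_range)),
            class = "fold_definition")
}

#' Built-in fold definitions of the four ATTRv-I84S polymorphs
#'
#' Residue spans as modelled in the depositions: closed gate Pro11-Lys35 +
#' Gly57-Asn124; open gate Pro11-Lys35 + Thr60-Asn124; absent gate
#' Leu12-Lys35 + Ile68-Asn124; broken gate Leu12-Lys35 + Phe64-Val122. The
#' channel gate spans Leu58-Glu62 (exposed segment) up to the Gly67 hinge
#' where modelled.
#'
#' @param name fold name (see [fold_definition()]) or "all" for the full list
#' @return a `fold_definition`, or a named list of all four
#' @export
ttr_folds <- function(name = c("all", "closed_gate", "open_gate",
                               "absent_gate", "broken_gate")) {
  name <- match.arg(name)
  folds <- list(
    closed_gate = fold_definition("closed_gate", c(11, 35), c(57, 124),
                                  gate_range = c(58, 66)),
    open_gate   = fold_definition("open_gate", c(11, 35), c(60, 124),
                                  gate_range = c(60, 66)),
    absent_gate = fold_definition("absent_gate", c(12, 35), c(68, 124),
                                  gate_range = NULL),
    broken_gate = fold_definition("broken_gate", c(12, 35), c(64, 122),
                                  gate_range = c(64, 66)))
  if (name == "all") folds else folds[[name]]
}

#' The common core shared by all ATTRv-I84S fibril folds
#'
#' All four polymorphs share an N-terminal fragment Leu12-Lys35 and a
#' C-terminal fragment Gly67-Val122; differences concentrate in the gate
#' preceding Gly67.
#'
#' @return list of two inclusive residue ranges, usable wherever a
#'   `residues` argument accepts ranges
#' @export
ttr_common_core <- function() list(c(12L, 35L), c(67L, 122L))

#' Measured helical parameters of the four ATTRv-I84S polymorphs
#'
#' Twist and rise as reported for each fold's reconstruction: closed gate
#' -1.26 deg / 4.81 A; open gate -1.41 deg / 4.8 A; absent gate -1.3 deg /
#' 4.93 A; broken gate -1.3 deg / 4.96 A. All left-handed (negative twist).
#' Note the crossover distances derived from these triples can differ by a
#' few per cent from the crossover lengths measured directly on micrographs,
#' since the printed twists are rounded.
#'
#' @param name fold name, as in [ttr_folds()]
#' @return a [helical_parameters()] object
#' @export
ttr_helical_params <- function(name = c("closed_gate", "open_gate",
                                        "absent_gate", "broken_gate")) {
  name <- match.arg(name)
  switch(name,
         closed_gate = helical_parameters(-1.26, 4.81),
         open_gate   = helical_parameters(-1.41, 4.80),
         absent_gate = helical_parameters(-1.30, 4.93),
         broken_gate = helical_parameters(-1.30, 4.96))
}

#' @export
print.fold_definition <- function(x, ...) {
  cat(sprintf("fold_definition: %s  N %d-%d  C %d-%d", x$name,
              x$n_range[1], x$n_range[2], x$c_range[1], x$c_range[2]))
  if (!is.null(x$gate_range))
    cat(sprintf("  gate %d-%d", x$gate_range[1], x$gate_range[2]))
  cat("\n")
  invisible(x)
}
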
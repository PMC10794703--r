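# Synthetic fibril layers and particle tables: idealized stand-ins carrying
# the structural and statistical features the analysis stages assume, so the
# whole pipeline is exercisable without downloading depositions.

#' Mature transthyretin sequence
#' @return 1-letter amino acid string, residues 1-127 (mature numbering)
#' @param mutation "WT" or "I84S" (serine at position 84)
#' @export
ttr_sequence <- function(mutation = c("I84S", "WT")) {
  mutation <- match.arg(mutation)
  s <- paste0("GPTGTGESKCPLMVKVLDAVRGSPAINVAVHVFRKAADDTWEPFASGKTSE",
              "SGELHGLTTEEEFVEGIYKVEIDTKSYWKALGISPFHEHAEVVFTANDSGP",
              "RRYTIAALLSPYSYSTTAVVTNPKE")
  if (mutation == "I84S") substr(s, 84, 84) <- "S"
  s
}

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' One trace piece of a synthetic fibril layer
#'
#' A piece is a contiguous run of residues whose C-alpha atoms walk a 2D
#' turtle trace in the layer plane (z = 0): start at `anchor` with the given
#' `heading`, and before each step turn by the next entry of `turns`
#' (degrees, positive = counter-clockwise) then advance `step` Angstrom
#' (3.8, the trans C-alpha-C-alpha distance, by default).
#'
#' @param fragment "N" or "C"
#' @param resno residue numbers of the piece (increasing)
#' @param aa 1-letter residue codes, same length
#' @param anchor `c(x, y)` of the first residue
#' @param heading initial heading, degrees (0 = +x)
#' @param turns heading changes per step, degrees (length `length(resno)-1`)
#' @param step step length, Angstrom
#' @param keep optional subset of `resno` to retain after the walk: the
#'   trace is computed over the full `resno` range so that retained
#'   residues keep identical coordinates whichever subset is used
#' @return object of class `layer_piece`
#' @export
layer_piece <- function(fragment, resno, aa, anchor = c(0, 0), heading = 0,
                        turns = rep(0, length(resno) - 1), step = 3.8,
                        keep = NULL) {
  stopifnot(length(aa) == length(resno),
            length(turns) == length(resno) - 1,
            all(diff(resno) > 0))
  structure(list(fragment = fragment, resno = as.integer(resno), aa = aa,
                 anchor = anchor, heading = heading, turns = turns,
                 step = step, keep = keep),
            class = "layer_piece")
}

#' Specification of a synthetic fibril layer
#'
#' Combines trace pieces with an optional gate sub-trace. The gate models
#' the C-terminal channel-gate segment that precedes the Gly67 hinge: it is
#' walked BACKWARD from the first residue of the C piece, so changing or
#' removing the gate never moves the rest of the layer. Gate styles:
#' `"curl"` (pentagon-like closure, the closed-gate conformation) and
#' `"straight"` (extended, the open/broken-gate conformation).
#'
#' @param pieces list of [layer_piece()]s
#' @param gate NULL, or list with `resno`, `aa` (ordered increasing; the
#'   highest gate residue attaches to the C piece start), `style`
#'   ("curl"/"straight"), and optional `turn` (degrees per step for "curl",
#'   default 25)
#' @param gate_state label recorded on the model ("closed", "open",
#'   "absent", "broken", or NA)
#' @param min_separation self-avoidance limit: non-adjacent C-alpha pairs
#'   closer than this (Angstrom) are a geometry error (default 3.5)
#' @return object of class `layer_spec`
#' @export
layer_spec <- function(pieces, gate = NULL, gate_state = NA_character_,
                       min_separation = 3.5) {
  stopifnot(all(vapply(pieces, inherits, TRUE, "layer_piece")))
  structure(list(pieces = pieces, gate = gate, gate_state = gate_state,
                 min_separation = min_separation),
            class = "layer_spec")
}

#' Idealized transthyretin fibril layer specs for the four gate states
#'
#' Builds a serpentine (meander) layer: the N fragment (two beta-strands
#' joined by a U-turn) above, the C-fragment core (Gly67 onward, four
#' strands) below, and the gate segment walked backward from Gly67's
#' neighbour per state -- closed: residues 57-66 curling into a
#' pentagon-like arc; open: 60-66 extended; absent: no gate residues;
#' broken: 64-66 extended, with the C terminus ending at Val122. Residue
#' spans match the four fold definitions ([ttr_folds()]); all residues
#' shared between two states sit at identical coordinates, so comparing two
#' states isolates the gate.
#'
#' @param gate_state "closed", "open", "absent" or "broken"
#' @param mutation passed to [ttr_sequence()]
#' @param strand_length residues per serpentine strand (default 12)
#' @param turn_length steps in a U-turn (default 4; 45 degrees each)
#' @return a [layer_spec()]
#' @export
ttr_layer_spec <- function(gate_state = c("closed", "open", "absent",
                                          "broken"),
                           mutation = "I84S", strand_length = 12L,
                           turn_length = 4L) {
  gate_state <- match.arg(gate_state)
  fold <- ttr_folds(paste0(gate_state, "_gate"))
  seq1 <- strsplit(ttr_sequence(mutation), "")[[1]]

  serp <- function(n) {         # serpentine turn schedule for n residues
    turns <- numeric(n - 1)
    i <- strand_length           # index of last residue of current strand
    dir <- -1                    # first U-turn bends clockwise (downwards)
    while (i < n) {
      k <- seq(i, min(i + turn_length - 1, n - 1))
      turns[k] <- dir * 180 / turn_length
      i <- i + turn_length + strand_length
      dir <- -dir
    }
    turns
  }

  # walk maximal ranges (N 11-35, C core 67-124) and subset to the fold's
  # spans afterward, so residues shared between states coincide exactly
  n_max <- 11:35
  c_max <- 67:124
  pieces <- list(
    layer_piece("N", n_max, seq1[n_max], anchor = c(0, 0), heading = 0,
                turns = serp(length(n_max)),
                keep = seq(fold$n_range[1], fold$n_range[2])),
    layer_piece("C", c_max, seq1[c_max], anchor = c(0, -20), heading = 0,
                turns = serp(length(c_max)),
                keep = seq(max(fold$c_range[1], 67L), fold$c_range[2])))
  gate_res <- if (fold$c_range[1] < 67L) seq(fold$c_range[1], 66L) else NULL
  gate <- if (is.null(gate_res)) NULL else
    list(resno = gate_res, aa = seq1[gate_res],
         style = if (gate_state == "closed") "curl" else "straight",
         turn = 36)
  layer_spec(pieces, gate = gate, gate_state = gate_state)
}

walk_trace <- function(anchor, heading, turns, step) {
  n <- length(turns) + 1
  xy <- matrix(0, n, 2)
  xy[1, ] <- anchor
  h <- heading * pi / 180
  for (i in seq_len(n - 1)) {
    h <- h + turns[i] * pi / 180
    xy[i + 1, ] <- xy[i, ] + step * c(cos(h), sin(h))
  }
  attr(xy, "final_heading") <- h * 180 / pi
  xy
}

#' Build a single fibril layer from a spec
#'
#' Places C-alpha atoms on the 2D trace at z = 0, then completes an
#' idealized backbone: N and C(=O) along the local chain tangent, carbonyl O
#' in-plane, and C-beta alternating above/below the layer plane as
#' beta-strand side chains do. Glycines get no C-beta. The trace must be
#' self-avoiding: any non-adjacent C-alpha pair closer than the spec's
#' `min_separation` raises a geometry error.
#'
#' @param spec a [layer_spec()]
#' @return single-layer [fibril_model()]
#' @export
make_layer <- function(spec) {
  stopifnot(inherits(spec, "layer_spec"))
  res <- list()
  for (p in spec$pieces) {
    xy <- walk_trace(p$anchor, p$heading, p$turns, p$step)
    d <- data.frame(fragment = p$fragment, resno = p$resno, aa = p$aa,
                    x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
    if (!is.null(p$keep)) d <- d[d$resno %in% p$keep, , drop = FALSE]
    res[[length(res) + 1]] <- d
  }
  if (!is.null(spec$gate)) {
    g <- spec$gate
    cpiece <- spec$pieces[[which(vapply(spec$pieces, `[[`, "", "fragment")
                                 == "C")[1]]]
    # walk backward from the C piece start, opposite its initial heading
    n_g <- length(g$resno)
    turns <- switch(g$style,
                    straight = rep(0, n_g),
                    # pentagon-like closure: escape the layer body for three
                    # steps, then arc back toward the hinge
                    curl = c(rep(0, min(3, n_g)),
                             rep(-(g$turn %||% 36), max(0, n_g - 3))),
                    stop("unknown gate style: ", g$style))
    xy <- walk_trace(cpiece$anchor, cpiece$heading + 180, turns,
                     cpiece$step)[-1, , drop = FALSE]  # first point = anchor
    res[[length(res) + 1]] <-
      data.frame(fragment = "C", resno = rev(g$resno), aa = rev(g$aa),
                 x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
  }
  ca <- do.call(rbind, res)
  ca <- ca[order(match(ca$fragment, c("N", "C")), ca$resno), , drop = FALSE]

  # self-avoidance over non-adjacent residues (chain adjacency = consecutive
  # residue numbers within a fragment)
  d <- as.matrix(stats::dist(ca[, c("x", "y")]))
  adj <- outer(seq_len(nrow(ca)), seq_len(nrow(ca)), function(i, j)
    ca$fragment[i] == ca$fragment[j] & abs(ca$resno[i] - ca$resno[j]) <= 1)
  viol <- d < spec$min_separation & !adj
  if (any(viol))
    stop("self-intersecting trace: non-adjacent C-alpha pairs closer than ",
         spec$min_separation, " A")

  atoms <- build_backbone(ca)
  fold <- if (!is.na(spec$gate_state))
    tryCatch(ttr_folds(paste0(spec$gate_state, "_gate")),
             error = function(e) NULL) else NULL
  fibril_model(atoms, fold = fold,
               ttr_numbering = max(ca$resno) <= 127)
}

# idealized backbone + C-beta around in-plane C-alpha positions
build_backbone <- function(ca) {
  out <- list()
  for (fr in unique(ca$fragment)) {
    s <- ca[ca$fragment == fr, , drop = FALSE]
    n <- nrow(s)
    P <- as.matrix(s[, c("x", "y")])
    tang <- matrix(0, n, 2)
    if (n == 1) tang[1, ] <- c(1, 0) else {
      tang[1, ] <- P[2, ] - P[1, ]
      tang[n, ] <- P[n, ] - P[n - 1, ]
      if (n > 2) tang[2:(n - 1), ] <- P[3:n, ] - P[1:(n - 2), ]
    }
    tang <- tang / sqrt(rowSums(tang^2))
    norm2d <- cbind(-tang[, 2], tang[, 1])
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      aa3 <- AA1TO3[[s$aa[i]]]
      # alternate CB above/below the plane by residue number, so shared
      # residues get the same side whichever fold subset is walked
      flip <- if (s$resno[i] %% 2 == 0) 1 else -1
      at <- rbind(
        c(P[i, ] - 1.20 * tang[i, ] + 0.45 * norm2d[i, ], 0),        # N
        c(P[i, ], 0),                                                # CA
        c(P[i, ] + 1.25 * tang[i, ] + 0.40 * norm2d[i, ], 0),        # C
        c(P[i, ] + 1.45 * tang[i, ] + 1.55 * norm2d[i, ], 0))        # O
      name <- c("N", "CA", "C", "O")
      elem <- c("N", "C", "C", "O")
      if (aa3 != "GLY") {
        at <- rbind(at, c(P[i, ] - 0.55 * norm2d[i, ], flip * 1.45)) # CB
        name <- c(name, "CB"); elem <- c(elem, "C")
      }
      rows[[i]] <- data.frame(element = elem, name = name,
                              resno = s$resno[i], resid = aa3,
                              fragment = fr, layer = 0L,
                              x = at[, 1], y = at[, 2], z = at[, 3],
                              stringsAsFactors = FALSE)
    }
    out[[fr]] <- do.call(rbind, rows)
  }
  do.call(rbind, out[order(match(names(out), c("N", "C")))])
}

#' Generate a full synthetic fibril
#'
#' [make_layer()] followed by [expand_symmetry()], with optional i.i.d.
#' Gaussian coordinate noise added after expansion. Deterministic for a
#' fixed seed.
#'
#' @param spec a [layer_spec()]
#' @param params [helical_parameters()] (default: twist -1.26 deg, rise
#'   4.81 A, the closed-gate fold's values)
#' @param n_layers stack size (default 5)
#' @param noise_sd per-coordinate Gaussian noise, Angstrom (default 0)
#' @param seed RNG seed used when `noise_sd > 0` (default 1)
#' @return a [fibril_model()]
#' @export
make_fibril <- function(spec, params = helical_parameters(-1.26, 4.81),
                        n_layers = 5L, noise_sd = 0, seed = 1L) {
  model <- expand_symmetry(make_layer(spec), params, n_layers)
  if (noise_sd > 0) {
    a <- model$atoms
    noise <- with_seed(seed, matrix(stats::rnorm(3 * nrow(a), 0, noise_sd),
                                    ncol = 3))
    a$x <- a$x + noise[, 1]; a$y <- a$y + noise[, 2]
    a$z <- a$z + noise[, 3]
    model$atoms <- a
  }
  model
}

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic particle table
#'
#' Emulates the particle metadata of a helical reconstruction: fibril
#' segments picked along filaments in micrographs, each filament carrying a
#' polymorph composition, with a fraction of segments dropped from the
#' class-labeled subset (the "subpar" segments that do not survive
#' refinement, which make filament coverage incomplete).
#'
#' @param n_micrographs number of micrographs (default 15)
#' @param filaments_per_micrograph filaments per micrograph (default 10)
#' @param segments_per_filament picked segments per filament (default 20)
#' @param p_mixed probability a filament contains both polymorphs
#'   (default 0.3)
#' @param classes polymorph class labels (default 1:2)
#' @param switch_prob per-segment class switch probability along a mixed
#'   filament (default 0.1)
#' @param unassigned_fraction fraction of segments without a class label
#'   (default 0.3)
#' @param micrograph_size pixel dimensions `c(nx, ny)` (default 4096)
#' @param box_spacing inter-segment spacing, pixels (default 40)
#' @param seed RNG seed
#' @return object of class `star_spec`
#' @export
star_spec <- function(n_micrographs = 15L, filaments_per_micrograph = 10L,
                      segments_per_filament = 20L, p_mixed = 0.3,
                      classes = 1:2, switch_prob = 0.1,
                      unassigned_fraction = 0.3,
                      micrograph_size = c(4096, 4096), box_spacing = 40,
                      seed = 1L) {
  stopifnot(p_mixed >= 0, p_mixed <= 1,
            unassigned_fraction >= 0, unassigned_fraction <= 1,
            switch_prob >= 0, switch_prob <= 1,
            n_micrographs >= 0, filaments_per_micrograph >= 0,
            segments_per_filament >= 0, length(classes) >= 1)
  structure(as.list(environment()), class = "star_spec")
}

#' Generate a synthetic particle table with ground truth
#'
#' Lays smooth filament curves into micrographs, assigns each filament a
#' polymorph composition (pure or mixed per the spec's mixture model; a
#' "mixed" filament is guaranteed to realize at least two classes), samples
#' segment coordinates along each curve, and removes the class label from
#' `unassigned_fraction` of segments. Byte-identical output under a fixed
#' seed.
#'
#' @param spec a [star_spec()]
#' @return list with `particles` (data.frame: micrograph, tube, x, y, class
#'   with NA = unassigned, seg), `truth` (per-filament ground truth:
#'   micrograph, tube, n_segments, classes realized, mixed flag), and `spec`
#' @export
make_star_fixture <- function(spec) {
  stopifnot(inherits(spec, "star_spec"))
  with_seed(spec$seed, {
    parts <- list(); truths <- list()
    for (m in seq_len(spec$n_micrographs)) {
      mic <- sprintf("mic_%03d.mrc", m)
      for (f in seq_len(spec$filaments_per_micrograph)) {
        n <- spec$segments_per_filament
        # smooth curve: start inside the frame, slowly wandering heading
        margin <- n * spec$box_spacing
        start <- stats::runif(2, margin * 0.3,
                              spec$micrograph_size - margin * 0.3)
        h <- stats::runif(1, 0, 2 * pi)
        dh <- stats::rnorm(n, 0, 0.03)   # gentle curvature
        xy <- matrix(0, n, 2)
        xy[1, ] <- start
        for (i in seq_len(n - 1)) {
          h <- h + dh[i]
          xy[i + 1, ] <- xy[i, ] + spec$box_spacing * c(cos(h), sin(h))
        }
        xy[, 1] <- pmin(pmax(xy[, 1], 0), spec$micrograph_size[1])
        xy[, 2] <- pmin(pmax(xy[, 2], 0), spec$micrograph_size[2])

        mixed <- stats::runif(1) < spec$p_mixed
        if (mixed) {
          repeat {
            cl <- numeric(n)
            cl[1] <- sample(spec$classes, 1)
            for (i in seq_len(n - 1)) {
              cl[i + 1] <- if (stats::runif(1) < spec$switch_prob)
                sample(setdiff(spec$classes, cl[i]), 1) else cl[i]
            }
            if (length(unique(cl)) >= 2) break
          }
        } else {
          cl <- rep(sample(spec$classes, 1), n)
        }
        lab <- cl
        drop <- stats::runif(n) < spec$unassigned_fraction
        lab[drop] <- NA
        parts[[length(parts) + 1]] <-
          data.frame(micrograph = mic, tube = f, seg = seq_len(n),
                     x = xy[, 1], y = xy[, 2], class = lab,
                     stringsAsFactors = FALSE)
        truths[[length(truths) + 1]] <-
          data.frame(micrograph = mic, tube = f, n_segments = n,
                     classes = paste(sort(unique(cl)), collapse = "+"),
                     mixed = length(unique(cl)) >= 2,
                     stringsAsFactors = FALSE)
      }
    }
    list(particles = if (length(parts)) do.call(rbind, parts) else
           data.frame(micrograph = character(), tube = integer(),
                      seg = integer(), x = numeric(), y = numeric(),
                      class = numeric()),
         truth = if (length(truths)) do.call(rbind, truths) else NULL,
         spec = spec)
  })
}
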
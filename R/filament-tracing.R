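# Filament tracing: map refined-particle class assignments back to the
# filaments they were picked from, and quantify polymorph co-occurrence
# within single fibrils. Tracing is metadata-only (STAR tables, never
# micrograph images).

#' Read a STAR particle table
#'
#' Parses the loop-structured STAR text format used for cryo-EM particle
#' metadata (e.g. a run_data.star). The particles block is located as the
#' first data block whose loop carries coordinate columns (rlnCoordinateX/Y)
#' -- so files with a leading optics block work. Recognized columns are
#' mapped to canonical names (`micrograph`, `x`, `y`, `tube`, `class`);
#' all other columns are preserved verbatim.
#'
#' @param path STAR file
#' @return data.frame, one row per particle; `tube`/`class` are NA-filled
#'   when the corresponding columns are absent. The original column names
#'   are kept in attribute `star_columns`.
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  blocks <- parse_star_blocks(lines)
  if (length(blocks) == 0)
    stop("no loop_ data block found in ", path, ": not a particles STAR file")
  has_xy <- vapply(blocks, function(b)
    all(c("rlnCoordinateX", "rlnCoordinateY") %in% names(b)), TRUE)
  if (!any(has_xy)) {
    missing <- setdiff(c("rlnCoordinateX", "rlnCoordinateY"),
                       unlist(lapply(blocks, names)))
    stop("no block with coordinate columns ",
         paste(missing, collapse = ", "), " in ", path)
  }
  tab <- blocks[[which(has_xy)[1]]]
  out <- data.frame(
    micrograph = if ("rlnMicrographName" %in% names(tab))
      tab$rlnMicrographName else NA_character_,
    x = as.numeric(tab$rlnCoordinateX),
    y = as.numeric(tab$rlnCoordinateY),
    tube = if ("rlnHelicalTubeID" %in% names(tab))
      as.integer(tab$rlnHelicalTubeID) else NA_integer_,
    class = if ("rlnClassNumber" %in% names(tab))
      suppressWarnings(as.numeric(tab$rlnClassNumber)) else NA_real_,
    stringsAsFactors = FALSE)
  extra <- setdiff(names(tab), c("rlnMicrographName", "rlnCoordinateX",
                                 "rlnCoordinateY", "rlnHelicalTubeID",
                                 "rlnClassNumber"))
  for (e in extra) out[[e]] <- tab[[e]]
  attr(out, "star_columns") <- names(tab)
  out
}

parse_star_blocks <- function(lines) {
  lines <- sub("#.*$", "", lines)       # strip comments
  lines <- trimws(lines)
  blocks <- list()
  i <- 1
  while (i <= length(lines)) {
    if (lines[i] == "loop_") {
      i <- i + 1
      cols <- character()
      while (i <= length(lines) && startsWith(lines[i], "_")) {
        cols <- c(cols, sub("^_", "", strsplit(lines[i], "[ \t]+")[[1]][1]))
        i <- i + 1
      }
      rows <- list()
      while (i <= length(lines) && nzchar(lines[i]) &&
             !startsWith(lines[i], "data_") && lines[i] != "loop_") {
        rows[[length(rows) + 1]] <- strsplit(lines[i], "[ \t]+")[[1]]
        i <- i + 1
      }
      if (length(cols) > 0 && length(rows) > 0) {
        bad <- lengths(rows) != length(cols)
        if (any(bad))
          stop("STAR loop row has ", lengths(rows)[bad][1],
               " fields, expected ", length(cols))
        m <- do.call(rbind, rows)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- cols
        blocks[[length(blocks) + 1]] <- df
      }
    } else i <- i + 1
  }
  blocks
}

#' Write a particle table as a STAR file
#'
#' Inverse of [read_star()] for the canonical columns; output is
#' byte-deterministic (fixed column order and number formatting), so a
#' fixture written twice from the same table is identical.
#'
#' @param particles data.frame with columns `micrograph`, `x`, `y` and
#'   optionally `tube`, `class` (NA class rows are written without a class
#'   column value only if the whole column is NA; otherwise NA becomes -1,
#'   the conventional "unassigned" sentinel recovered as NA by
#'   [read_star()]... see Details)
#' @param path output path
#' @details Unassigned segments (class NA) are written as `-1` and read back
#'   as NA, keeping round-trips lossless.
#' @return invisibly, the path
#' @export
write_star <- function(particles, path) {
  stopifnot(all(c("micrograph", "x", "y") %in% names(particles)))
  con <- file(path, "w")
  on.exit(close(con))
  cols <- c("_rlnMicrographName", "_rlnCoordinateX", "_rlnCoordinateY")
  vals <- list(particles$micrograph,
               sprintf("%.6f", particles$x), sprintf("%.6f", particles$y))
  if ("tube" %in% names(particles) && !all(is.na(particles$tube))) {
    cols <- c(cols, "_rlnHelicalTubeID")
    vals <- c(vals, list(sprintf("%d", particles$tube)))
  }
  if ("class" %in% names(particles) && !all(is.na(particles$class))) {
    cols <- c(cols, "_rlnClassNumber")
    cl <- particles$class
    cl[is.na(cl)] <- -1
    vals <- c(vals, list(sprintf("%d", as.integer(cl))))
  }
  writeLines(c("data_particles", "", "loop_",
               sprintf("%s #%d", cols, seq_along(cols))), con)
  writeLines(do.call(paste, vals), con)
  invisible(path)
}

#' Group particle segments into filaments
#'
#' TUBE_ID mode groups by (micrograph, helical tube id), the bookkeeping a
#' helical reconstruction carries. PROXIMITY mode chains segments within a
#' micrograph by single linkage under a distance threshold, for tables that
#' lost their tube ids; because only well-defined segments survive
#' refinement, segments of one filament may be interspersed with gaps, so
#' the threshold should comfortably exceed the picking spacing. In both
#' modes segments are ordered by arc position along the filament (projection
#' onto the filament's principal axis).
#'
#' @param records particle table (from [read_star()] or
#'   [make_star_fixture()]`$particles`)
#' @param linking "auto" (tube ids when present, else proximity), "tube" or
#'   "proximity"
#' @param threshold linkage distance in pixels (required for proximity mode)
#' @return object of class `traced_filaments`: list with `segments` (the
#'   input plus `filament` id and `order`), and `filaments` (per-filament
#'   summary: micrograph, filament, n_segments, n_labeled, coverage, one
#'   count column per class)
#' @export
group_filaments <- function(records, linking = c("auto", "tube", "proximity"),
                            threshold = NULL) {
  linking <- match.arg(linking)
  recs <- as.data.frame(records)
  if (linking == "auto")
    linking <- if (!all(is.na(recs$tube))) "tube" else "proximity"
  if (linking == "tube") {
    if (all(is.na(recs$tube)))
      stop("tube linking requested but no tube ids present")
    fid <- paste(recs$micrograph, recs$tube, sep = "//")
  } else {
    if (is.null(threshold))
      stop("proximity linking requires a distance threshold (pixels)")
    fid <- rep(NA_character_, nrow(recs))
    for (m in unique(recs$micrograph)) {
      idx <- which(recs$micrograph == m)
      if (length(idx) == 1) {
        fid[idx] <- paste(m, 1, sep = "//")
        next
      }
      hc <- stats::hclust(stats::dist(recs[idx, c("x", "y")]),
                          method = "single")
      cl <- stats::cutree(hc, h = threshold)
      fid[idx] <- paste(m, cl, sep = "//")
    }
  }
  recs$filament <- fid
  # arc order: projection on the principal axis of each filament
  recs$order <- NA_integer_
  for (f in unique(fid)) {
    idx <- which(fid == f)
    xy <- as.matrix(recs[idx, c("x", "y")])
    if (length(idx) > 1) {
      xc <- sweep(xy, 2, colMeans(xy))
      v <- svd(xc, nu = 0, nv = 1)$v[, 1]
      recs$order[idx] <- rank(xc %*% v, ties.method = "first")
    } else recs$order[idx] <- 1L
  }
  classes <- sort(unique(recs$class[!is.na(recs$class)]))
  summ <- do.call(rbind, lapply(split(recs, recs$filament), function(s) {
    counts <- vapply(classes, function(k)
      sum(!is.na(s$class) & s$class == k), integer(1))
    d <- data.frame(micrograph = s$micrograph[1],
                    filament = s$filament[1],
                    n_segments = nrow(s),
                    n_labeled = sum(!is.na(s$class)),
                    coverage = sum(!is.na(s$class)) / nrow(s),
                    stringsAsFactors = FALSE)
    for (k in seq_along(classes)) d[[paste0("class_", classes[k])]] <- counts[k]
    d
  }))
  rownames(summ) <- NULL
  structure(list(segments = recs, filaments = summ, classes = classes,
                 linking = linking),
            class = "traced_filaments")
}

#' @export
print.traced_filaments <- function(x, ...) {
  cat("traced_filaments:", nrow(x$filaments), "filaments,",
      nrow(x$segments), "segments (", x$linking, "linking )\n")
  invisible(x)
}

#' Summarize polymorph co-occurrence within filaments
#'
#' Classifies every filament as pure in one class, mixed (at least one
#' labeled segment of at least two distinct classes), or unassigned (no
#' labeled segment), and reports global counts and fractions. Because only
#' labeled segments are informative, the mixed count is a LOWER BOUND
#' whenever coverage is incomplete: an apparently pure filament may contain
#' one type or both. The returned `caveat` field restates this.
#'
#' @param filaments a [group_filaments()] result
#' @return list with `per_filament` (filament, status, classes seen),
#'   `counts` (pure per class, mixed, unassigned), `mixed_fraction` (mixed /
#'   classified filaments), `mean_coverage`, `lower_bound` (TRUE when any
#'   coverage < 1) and `caveat`
#' @export
cooccurrence_summary <- function(filaments) {
  stopifnot(inherits(filaments, "traced_filaments"))
  segs <- filaments$segments
  per <- do.call(rbind, lapply(split(segs, segs$filament), function(s) {
    seen <- sort(unique(s$class[!is.na(s$class)]))
    data.frame(filament = s$filament[1],
               status = if (length(seen) == 0) "unassigned"
                        else if (length(seen) == 1) "pure" else "mixed",
               classes = paste(seen, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  n_mixed <- sum(per$status == "mixed")
  n_pure <- sum(per$status == "pure")
  n_unassigned <- sum(per$status == "unassigned")
  pure_by_class <- table(per$classes[per$status == "pure"])
  mean_cov <- mean(filaments$filaments$coverage)
  list(per_filament = per,
       counts = c(pure = n_pure, mixed = n_mixed,
                  unassigned = n_unassigned),
       pure_by_class = pure_by_class,
       mixed_fraction = if (n_mixed + n_pure > 0)
         n_mixed / (n_mixed + n_pure) else NA_real_,
       mean_coverage = mean_cov,
       lower_bound = mean_cov < 1,
       caveat = paste("Only labeled segments are informative: with",
                      "incomplete coverage the mixed count is a lower",
                      "bound, and filaments classified as pure cannot be",
                      "ruled out to contain one type or both."))
}

#' Export plot-ready trace coordinates for one micrograph
#'
#' Returns the per-class coordinate series of all filaments in a
#' micrograph, in the micrograph pixel frame, with the axis ranges set to
#' the micrograph dimensions -- the XY-graph representation used to overlay
#' polymorph assignments on a micrograph.
#'
#' @param filaments a [group_filaments()] result
#' @param micrograph micrograph id
#' @param micrograph_size `c(nx, ny)` pixel dimensions for the axis ranges
#'   (default 4096 x 4096)
#' @return data.frame (x, y, class, filament, order) sorted by filament and
#'   arc order, with attributes `xlim`/`ylim`; zero rows for an empty
#'   micrograph that exists in the table
#' @export
export_trace_plot <- function(filaments, micrograph,
                              micrograph_size = c(4096, 4096)) {
  stopifnot(inherits(filaments, "traced_filaments"))
  segs <- filaments$segments
  if (!micrograph %in% segs$micrograph)
    stop("unknown micrograph: ", micrograph)
  s <- segs[segs$micrograph == micrograph, , drop = FALSE]
  s <- s[order(s$filament, s$order), c("x", "y", "class", "filament",
                                       "order")]
  rownames(s) <- NULL
  attr(s, "xlim") <- c(0, micrograph_size[1])
  attr(s, "ylim") <- c(0, micrograph_size[2])
  s
}
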
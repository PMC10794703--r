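#' Two-sided Mann-Whitney U comparison of two groups
#'
#' Nonparametric comparison used for the fibril-versus-cohort stability
#' contrast. Reports the U statistic, the two-sided p-value, and the
#' box-plot summary (median, 25th-75th percentiles, whiskers at minimum and
#' maximum) for each group.
#'
#' Modes: `exact` enumerates the permutation null (valid without ties);
#' `normal_approx_tie_corrected` uses the normal approximation with the tie
#' correction in the variance; `auto` (default) picks exact when
#' `n1 * n2 <= 1e4` and there are no ties, else the tie-corrected
#' approximation.
#'
#' @param group_a,group_b numeric vectors (non-empty)
#' @param mode "auto", "exact" or "normal_approx_tie_corrected"
#' @return object of class `group_comparison`: list with `n` (c(n1, n2)),
#'   `U` (for `group_a`), `p_value`, `mode_used`, and `summary`
#'   (data.frame of median/quartiles/whiskers per group)
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney <- function(group_a, group_b,
                         mode = c("auto", "exact",
                                  "normal_approx_tie_corrected")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  n1 <- length(group_a); n2 <- length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx_tie_corrected = FALSE,
    auto = (n1 * n2 <= 1e4) && !ties)
  if (use_exact && ties) {
    warning("ties present; falling back to tie-corrected normal approximation")
    use_exact <- FALSE
  }
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = use_exact, correct = !use_exact))
  box <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(q25 = q[1], median = q[2], q75 = q[3],
               whisker_min = min(x), whisker_max = max(x))
  }
  structure(list(n = c(n1, n2),
                 U = unname(wt$statistic),
                 p_value = wt$p.value,
                 mode_used = if (use_exact) "exact"
                             else "normal_approx_tie_corrected",
                 summary = cbind(group = c("a", "b"),
                                 rbind(box(group_a), box(group_b)))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison: n = %d vs %d, U = %g, two-sided p = %.4g (%s)\n",
              x$n[1], x$n[2], x$U, x$p_value, x$mode_used))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare fibril stabilization energies against a cohort snapshot
#'
#' Runs the two-sided Mann-Whitney comparison of a set of fibril energies
#' against a cohort table of per-chain and per-residue stabilization
#' energies (such as a snapshot of the curated amyloid-structure
#' compilation), both by chain and by residue. The shipped snapshot is a
#' synthetic stand-in -- see the package vignette.
#'
#' @param chain_energies numeric vector of per-chain energies (kcal/mol)
#'   for the fibril group, or a list of [stabilization_energy()] profiles
#' @param snapshot path to a TSV with columns `id`, `group`,
#'   `energy_per_chain`, `energy_per_residue`, or a data.frame; the fibril
#'   group rows (`group == group_label`) provide per-residue energies for
#'   the fibril side when profiles are not given
#' @param group_label snapshot group treated as the fibril group
#'   (default "ATTR")
#' @return list with `by_chain` and `by_residue` [mann_whitney()] results
#'   and the group sizes
#' @export
atlas_comparison <- function(chain_energies = NULL,
                             snapshot = default_atlas_snapshot(),
                             group_label = "ATTR") {
  tab <- if (is.data.frame(snapshot)) snapshot
         else utils::read.delim(snapshot, stringsAsFactors = FALSE)
  need <- c("id", "group", "energy_per_chain", "energy_per_residue")
  if (!all(need %in% names(tab)))
    stop("snapshot must have columns: ", paste(need, collapse = ", "))
  is_grp <- tab$group == group_label
  others <- tab[!is_grp, , drop = FALSE]
  grp <- tab[is_grp, , drop = FALSE]
  if (is.null(chain_energies)) {
    chain <- grp$energy_per_chain
    per_res <- grp$energy_per_residue
  } else if (is.list(chain_energies) &&
             all(vapply(chain_energies, inherits, TRUE, "energy_profile"))) {
    chain <- vapply(chain_energies, `[[`, numeric(1), "chain_energy")
    per_res <- vapply(chain_energies,
                      function(p) p$chain_energy / nrow(p$residues),
                      numeric(1))
  } else {
    chain <- as.numeric(chain_energies)
    per_res <- grp$energy_per_residue
  }
  list(by_chain = mann_whitney(chain, others$energy_per_chain),
       by_residue = mann_whitney(per_res, others$energy_per_residue),
       n_group = length(chain), n_others = nrow(others))
}

#' @rdname atlas_comparison
#' @export
default_atlas_snapshot <- function() {
  system.file("extdata", "amyloid_atlas_snapshot_synthetic.tsv",
              package = "fibrilstab")
}
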
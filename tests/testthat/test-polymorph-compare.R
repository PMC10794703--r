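test_that("superposing a set onto itself is the identity", {
  set.seed(4)
  a <- matrix(rnorm(30), 10)
  fit <- kabsch_superpose(a, a)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, rep(0, 3), tolerance = 1e-10)
})

test_that("a rigidly moved copy is recovered with zero rmsd", {
  set.seed(8)
  a <- matrix(rnorm(24), 8)
  b <- rigid_transform(a, axis = c(1, 2, 0.5), angle_deg = 63,
                       shift = c(-4, 2, 9))
  fit <- kabsch_superpose(a, b)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_transform(a, fit), b, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)  # proper rotation
})

test_that("rmsd matches an independent rotation-grid search", {
  # 4-point toy with one displaced point: minimum found by nested grid
  a <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 1))
  for (d in c(0.5, 2.0)) {
    b <- a; b[4, 3] <- b[4, 3] + d
    b <- rigid_transform(b, axis = c(0, 1, 1), angle_deg = 40)
    k <- kabsch_superpose(a, b)$rmsd
    g <- grid_rmsd_oracle(a, b)
    expect_lte(k, g + 1e-9)          # least squares never beaten by search
    expect_equal(k, g, tolerance = 0.02)   # grid resolution limits the oracle
  }
})

test_that("degenerate and mismatched inputs fail loudly", {
  line <- cbind(seq(0, 10, length.out = 5), 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
  expect_error(kabsch_superpose(matrix(rnorm(9), 3), matrix(rnorm(12), 4)),
               "correspondence|length")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
})

test_that("rmsd is invariant to rigid pre-transformations", {
  ma <- make_fibril(ttr_layer_spec("closed"),
                    ttr_helical_params("closed_gate"), 3)
  mb <- make_fibril(ttr_layer_spec("open"),
                    ttr_helical_params("open_gate"), 3)
  base <- fold_rmsd(ma, mb, layers = 3)$rmsd
  mb2 <- mb
  xyz <- rigid_transform(mb$atoms[, c("x", "y", "z")], axis = c(1, 0, 2),
                         angle_deg = 115, shift = c(30, -12, 7))
  mb2$atoms$x <- xyz[, 1]; mb2$atoms$y <- xyz[, 2]; mb2$atoms$z <- xyz[, 3]
  expect_equal(fold_rmsd(ma, mb2, layers = 3)$rmsd, base,
               tolerance = 1e-9)
})

test_that("common core pairs residues present in both models", {
  mc <- make_layer(ttr_layer_spec("closed"))
  mb <- make_layer(ttr_layer_spec("absent"))
  corr <- common_core(mc, mb)
  expect_true(all(corr$resno %in% c(12:35, 67:124)))
  # gate residues of the closed fold are excluded (absent model lacks them)
  expect_true(all(attr(corr, "excluded") %in% c(11, 57:67)))
  expect_true(all(corr$core == (corr$resno %in% residue_set(ttr_common_core()))))

  ident <- common_core(mc, mc)
  ca <- mc$atoms[mc$atoms$name == "CA", ]
  expect_identical(nrow(ident), nrow(ca))        # all residues paired

  # disjoint residue sets: no correspondence possible
  off <- mb
  off$atoms$resno <- off$atoms$resno - 200L
  off <- fibril_model(off$atoms, ttr_numbering = FALSE, check = FALSE)
  expect_error(common_core(mc, off), "insufficient overlap")
})

test_that("self-comparison gives zero everywhere; gates dominate deviations", {
  mc <- make_fibril(ttr_layer_spec("closed"),
                    ttr_helical_params("closed_gate"), 3)
  self <- fold_rmsd(mc, mc, layers = 3)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_true(all(self$per_residue$distance < 1e-9))

  mo <- make_fibril(ttr_layer_spec("open"),
                    ttr_helical_params("open_gate"), 3)
  pr <- fold_rmsd(mc, mo, layers = 3, fit_set = "common_core")
  core <- pr$per_residue$distance[pr$per_residue$core]
  gate <- pr$per_residue$distance[!pr$per_residue$core]
  expect_gt(max(gate), max(core))   # displaced gate exceeds any core residue
  # under the single core fit, per-residue deviations may exceed the overall
  expect_gt(max(gate), pr$rmsd)
})

test_that("the deviation matrix is symmetric with a zero diagonal", {
  trio <- lapply(c("closed", "open", "absent"), function(s)
    make_fibril(ttr_layer_spec(s), ttr_helical_params(paste0(s, "_gate")),
                3))
  names(trio) <- c("closed", "open", "absent")
  dm <- deviation_matrix(trio, layers = 3)
  expect_equal(dm$rmsd, t(dm$rmsd))
  expect_equal(unname(diag(dm$rmsd)), rep(0, 3))
  expect_identical(length(dm$profiles), 3L)
  # identical models give a zero off-diagonal entry
  dup <- deviation_matrix(list(a = trio$closed, b = trio$closed))
  expect_equal(dup$rmsd["a", "b"], 0, tolerance = 1e-10)
})
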
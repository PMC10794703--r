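test_that("an isolated layer buries nothing against itself", {
  m <- make_layer(mini_layer())
  ba <- buried_area(m, 0)
  expect_equal(ba$buried, rep(0, nrow(ba)))
})

test_that("stacking buries area, monotonically per atom", {
  layer <- make_layer(mini_layer())
  hp <- helical_parameters(-1.26, 4.81)
  st5 <- expand_symmetry(layer, hp, 5)
  ba5 <- buried_area(st5, 2)
  expect_true(any(ba5$buried > 0))
  expect_true(all(ba5$buried >= -1e-9))
  expect_true(all(ba5$buried <= ba5$area_ref + 1e-9))

  # monotone burial: adding neighbours never increases the central layer's
  # SASA; compare the 5-stack's middle layer against the same layer alone
  # and inside the 3-layer sub-stack so the quadrature frame is identical
  mid <- st5$atoms[st5$atoms$layer == 2, ]
  sub3 <- st5$atoms[st5$atoms$layer %in% 1:3, ]
  a1 <- shrake_rupley(mid)
  a3 <- shrake_rupley(sub3)[sub3$layer == 2]
  a5c <- shrake_rupley(st5)[st5$atoms$layer == 2]
  expect_true(all(a3 <= a1 + 1e-9))
  expect_true(all(a5c <= a3 + 1e-9))

  # boundary layer triggers the central-layer warning
  st3 <- expand_symmetry(layer, hp, 3)
  expect_warning(buried_area(st3, 0), "boundary")
})

test_that("central-layer energy converges by a 5-layer stack", {
  layer <- make_layer(ttr_layer_spec("absent"))
  hp <- ttr_helical_params("absent_gate")
  e <- vapply(c(5L, 7L), function(n) {
    st <- expand_symmetry(layer, hp, n)
    stabilization_energy(st, n_points = 480)$chain_energy
  }, numeric(1))
  expect_lt(abs(e[2] - e[1]) / abs(e[1]), 0.01)
})

test_that("energies are additive and a zero ASP table zeroes them", {
  m <- make_fibril(ttr_layer_spec("open"), ttr_helical_params("open_gate"),
                   n_layers = 5)
  p <- stabilization_energy(m, n_points = 480)
  expect_equal(p$chain_energy, sum(p$residues$energy),
               tolerance = 1e-12)
  expect_equal(p$chain_energy, sum(p$atoms$energy), tolerance = 1e-12)
  expect_lt(abs(p$chain_energy - sum(p$residues$energy)),
            1e-9 * abs(p$chain_energy))

  zero <- structure(list(sigma = c(C = 0, "N" = 0, "O" = 0, "O-" = 0,
                                   "N+" = 0, S = 0),
                         provenance = "all-zero"), class = "asp_table")
  p0 <- stabilization_energy(m, asp = zero, n_points = 480)
  expect_equal(p0$chain_energy, 0)
  expect_equal(p0$residues$energy, rep(0, nrow(p0$residues)))
})

test_that("the pipeline energy equals a hand sum over buried areas", {
  # hand-built 3-residue fixture scored end to end
  sp <- layer_spec(list(layer_piece("N", 1:2, c("A", "K")),
                        layer_piece("C", 4:4, "D", anchor = c(0, 4.6),
                                    turns = numeric(0))))
  layer <- make_layer(sp)
  layer$helical <- helical_parameters(-1.26, 4.81)
  asp <- default_asp_table()
  p <- stabilization_energy(layer, asp = asp, stack_layers = 5)

  st <- expand_symmetry(get_layer(layer, 0), layer$helical, 5)
  ba <- buried_area(st, 2)
  cls <- classify_atoms(ba)
  hand <- sum(-asp$sigma[cls] * ba$buried) / 1000
  expect_equal(p$chain_energy, hand, tolerance = 1e-6)
  expect_identical(nrow(p$residues), 3L)
})

test_that("missing ASP classes fail with the atom named", {
  m <- make_fibril(ttr_layer_spec("absent"), n_layers = 3)
  partial <- structure(list(sigma = c(C = 16), provenance = "partial"),
                       class = "asp_table")
  expect_error(stabilization_energy(m, asp = partial, stack_layers = 3,
                                    n_points = 240),
               "no solvation parameter")
})

test_that("reference state and conventions are recorded in the context", {
  m <- make_fibril(ttr_layer_spec("open"), n_layers = 3)
  p <- stabilization_energy(m, stack_layers = 3, n_points = 240,
                            reference = "fully_extended")
  expect_identical(p$context$reference, "fully_extended")
  expect_match(p$context$asp_provenance, "Eisenberg")
  expect_match(p$context$sign_convention, "negative")
  # the extended reference frees more area than the isolated chain, so
  # burial (and stabilization) grows in magnitude
  p_iso <- stabilization_energy(m, stack_layers = 3, n_points = 240)
  expect_gt(sum(p$atoms$buried), sum(p_iso$atoms$buried))
})

test_that("residue colormap bins deterministically", {
  m <- make_fibril(ttr_layer_spec("absent"), n_layers = 3)
  p <- stabilization_energy(m, stack_layers = 3, n_points = 240)
  cm <- residue_energy_colormap(p)
  expect_identical(nrow(cm), nrow(p$residues))
  expect_true(all(cm$bin >= 1 & cm$bin <= 11))
  # monotone energies map to monotone bins
  ord <- order(cm$energy)
  expect_true(all(diff(cm$bin[ord]) >= 0))
  # all-zero profile lands in a single neutral bin
  p0 <- p; p0$residues$energy <- rep(0, nrow(p$residues))
  cm0 <- residue_energy_colormap(p0)
  expect_identical(length(unique(cm0$bin)), 1L)
  # configured bin edges are honored
  cm2 <- residue_energy_colormap(p, breaks = c(-10, 0, 10),
                                 palette = c("red", "blue"))
  expect_identical(sort(unique(cm2$color[cm2$energy <= 0])), "red")
})
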
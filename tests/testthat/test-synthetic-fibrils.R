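test_that("a straight trace lays collinear C-alphas at bond spacing", {
  sp <- layer_spec(list(layer_piece("N", 1:10, rep("G", 10))))
  m <- make_layer(sp)
  ca <- m$atoms[m$atoms$name == "CA", ]
  expect_identical(nrow(ca), 10L)
  d <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  expect_equal(d, rep(3.8, 9))
  expect_equal(ca$y, rep(0, 10))          # collinear along +x
  expect_equal(ca$z, rep(0, 10))
  expect_false("CB" %in% m$atoms$name)    # glycine gets no C-beta
})

test_that("self-intersecting traces are rejected", {
  # a 170-degree turn folds the trace back onto itself
  sp <- layer_spec(list(layer_piece("N", 1:8, rep("A", 8),
                                    turns = c(0, 0, 0, 170, 0, 0, 0))))
  expect_error(make_layer(sp), "self-intersecting")
})

test_that("gate states share coordinates outside the gate", {
  states <- c("closed", "open", "absent", "broken")
  layers <- lapply(states, function(s) make_layer(ttr_layer_spec(s)))
  names(layers) <- states
  # absent is smallest; every other state contains it with equal coordinates
  key <- function(m) paste(m$atoms$fragment, m$atoms$resno, m$atoms$name)
  ka <- key(layers$absent)
  for (s in c("closed", "open", "broken")) {
    ks <- key(layers[[s]])
    shared <- intersect(ks, ka)
    expect_gt(length(shared), 0)
    i <- match(shared, ks); j <- match(shared, ka)
    expect_equal(as.matrix(layers[[s]]$atoms[i, c("x", "y", "z")]),
                 as.matrix(layers$absent$atoms[j, c("x", "y", "z")]),
                 ignore_attr = TRUE)
    expect_gt(n_atoms(layers[[s]]), n_atoms(layers$absent))
  }
  # residue spans match the fold definitions
  for (s in states) {
    fold <- ttr_folds(paste0(s, "_gate"))
    ca <- layers[[s]]$atoms[layers[[s]]$atoms$name == "CA", ]
    expect_identical(range(ca$resno[ca$fragment == "C"]),
                     c(fold$c_range[1], fold$c_range[2]))
  }
})

test_that("hairpin strands sit at the serpentine inter-strand spacing", {
  m <- make_layer(ttr_layer_spec("closed"))
  ca <- m$atoms[m$atoms$name == "CA" & m$atoms$fragment == "N", ]
  # strand 1 = first 12 residues, strand 2 = last residues after the turn
  s1 <- as.matrix(ca[1:10, c("x", "y")])
  s2 <- as.matrix(ca[18:24, c("x", "y")])
  dmin <- min(as.matrix(stats::dist(rbind(s1, s2)))[1:10, 11:17])
  expect_gt(dmin, 8)       # clearly separated strands
  expect_lt(dmin, 11)      # ... at beta-arch-like spacing
})

test_that("make_fibril is deterministic and counts scale with layers", {
  sp <- ttr_layer_spec("absent")
  m1 <- make_fibril(sp, n_layers = 5, noise_sd = 0.3, seed = 42)
  m2 <- make_fibril(sp, n_layers = 5, noise_sd = 0.3, seed = 42)
  expect_identical(m1$atoms, m2$atoms)
  m3 <- make_fibril(sp, n_layers = 5, noise_sd = 0.3, seed = 43)
  expect_false(identical(m1$atoms, m3$atoms))

  ca <- m1$atoms[m1$atoms$name == "CA", ]
  n_per_layer <- nrow(make_layer(sp)$atoms[make_layer(sp)$atoms$name ==
                                             "CA", , drop = FALSE])
  expect_identical(nrow(ca), 5L * n_per_layer)   # residues scale with layers

  # noise-free fibril returns the generator's parameters
  m0 <- make_fibril(sp, helical_parameters(-1.3, 4.93), n_layers = 4)
  est <- estimate_helical_parameters(m0)
  expect_equal(est$twist, -1.3, tolerance = 1e-8)
  expect_equal(est$rise, 4.93, tolerance = 1e-8)
})

test_that("generated fibrils satisfy the model invariants", {
  for (s in c("closed", "broken")) {
    m <- make_fibril(ttr_layer_spec(s), n_layers = 3)
    expect_silent(fibrilstab:::validate_fibril_model(m))
  }
})

test_that("star fixtures honor their mixture model and are reproducible", {
  # pure filaments only: no co-occurrence possible
  pure <- make_star_fixture(star_spec(n_micrographs = 3, p_mixed = 0,
                                      unassigned_fraction = 0, seed = 5))
  expect_false(any(pure$truth$mixed))
  s <- cooccurrence_summary(group_filaments(pure$particles))
  expect_identical(unname(s$counts["mixed"]), 0L)

  # known mixture fraction recovered within binomial error at large n
  big <- make_star_fixture(star_spec(n_micrographs = 40,
                                     filaments_per_micrograph = 10,
                                     p_mixed = 0.3,
                                     unassigned_fraction = 0, seed = 9))
  n <- nrow(big$truth)
  expect_lt(abs(mean(big$truth$mixed) - 0.3), 3 * sqrt(0.3 * 0.7 / n))

  # byte-identical STAR under a fixed seed
  fx <- function() make_star_fixture(star_spec(n_micrographs = 2, seed = 77))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_star(fx()$particles, f1)
  write_star(fx()$particles, f2)
  expect_identical(readLines(f1), readLines(f2))

  # mixed filaments always realize at least two classes
  mixed_truth <- big$truth[big$truth$mixed, ]
  expect_true(all(grepl("\\+", mixed_truth$classes)))
})

test_that("star fixture coordinates stay inside the micrograph", {
  fx <- make_star_fixture(star_spec(n_micrographs = 4, seed = 2))
  expect_true(all(fx$particles$x >= 0 & fx$particles$x <= 4096))
  expect_true(all(fx$particles$y >= 0 & fx$particles$y <= 4096))
})
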
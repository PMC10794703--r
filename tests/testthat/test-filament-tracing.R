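test_that("hand-written STAR fixtures parse with coordinates echoed", {
  f <- withr::local_tempfile(lines = c(
    "data_particles", "", "loop_",
    "_rlnMicrographName #1", "_rlnCoordinateX #2", "_rlnCoordinateY #3",
    "mic_001.mrc 100.5 200.25",
    "mic_001.mrc 140.5 240.25",
    "mic_002.mrc 10.0 20.0"))
  tab <- read_star(f)
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$x, c(100.5, 140.5, 10.0))
  expect_equal(tab$y, c(200.25, 240.25, 20.0))
  expect_true(all(is.na(tab$tube)))
  expect_true(all(is.na(tab$class)))
})

test_that("the particles block is found behind an optics block", {
  f <- withr::local_tempfile(lines = c(
    "data_optics", "", "loop_",
    "_rlnOpticsGroup #1", "_rlnVoltage #2",
    "1 300",
    "",
    "data_particles", "", "loop_",
    "_rlnMicrographName #1", "_rlnCoordinateX #2", "_rlnCoordinateY #3",
    "_rlnHelicalTubeID #4", "_rlnClassNumber #5", "_rlnAnglePsi #6",
    "mic_001.mrc 1 2 1 1 45.0",
    "mic_001.mrc 3 4 1 2 46.0"))
  tab <- read_star(f)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$tube, c(1L, 1L))
  expect_equal(tab$class, c(1, 2))
  expect_identical(tab$rlnAnglePsi, c("45.0", "46.0"))  # opaque passthrough
})

test_that("malformed STAR input fails with a schema message", {
  no_loop <- withr::local_tempfile(lines = c("data_x", "_rlnFoo 1"))
  expect_error(read_star(no_loop), "loop_")
  no_xy <- withr::local_tempfile(lines = c(
    "data_particles", "loop_", "_rlnMicrographName #1", "mic.mrc"))
  expect_error(read_star(no_xy), "rlnCoordinate")
})

test_that("synthetic particle tables round-trip through STAR", {
  fx <- make_star_fixture(star_spec(n_micrographs = 3, seed = 12))
  f <- withr::local_tempfile(fileext = ".star")
  write_star(fx$particles, f)
  back <- read_star(f)
  expect_identical(nrow(back), nrow(fx$particles))
  expect_equal(back$x, fx$particles$x, tolerance = 1e-6)
  expect_equal(back$y, fx$particles$y, tolerance = 1e-6)
  expect_identical(back$tube, as.integer(fx$particles$tube))
  # class NA encodes as -1 and is restored
  back$class[back$class == -1] <- NA
  expect_identical(is.na(back$class), is.na(fx$particles$class))
})

test_that("tube grouping recovers the generated filaments exactly", {
  fx <- make_star_fixture(star_spec(n_micrographs = 4,
                                    filaments_per_micrograph = 6, seed = 3))
  tf <- group_filaments(fx$particles, linking = "tube")
  expect_identical(nrow(tf$filaments), nrow(fx$truth))       # F filaments
  # conservation: no segment lost or duplicated
  expect_identical(sum(tf$filaments$n_segments), nrow(fx$particles))
  # grouping is idempotent
  tf2 <- group_filaments(tf$segments, linking = "tube")
  expect_identical(sort(table(tf2$segments$filament)),
                   sort(table(tf$segments$filament)))
  # single filament when everything shares a tube
  one <- fx$particles; one$tube <- 1L; one$micrograph <- "m.mrc"
  expect_identical(nrow(group_filaments(one, "tube")$filaments), 1L)
})

test_that("proximity linking chains neighbours but not distant filaments", {
  # two parallel filaments far apart relative to the threshold
  seg <- data.frame(micrograph = "m.mrc", tube = NA_integer_,
                    seg = rep(1:10, 2),
                    x = rep(seq(0, 360, by = 40), 2),
                    y = rep(c(0, 500), each = 10),
                    class = NA_real_)
  tf <- group_filaments(seg, linking = "proximity", threshold = 100)
  expect_identical(nrow(tf$filaments), 2L)
  expect_error(group_filaments(seg, linking = "proximity"), "threshold")
  # arc order follows the filament direction
  s1 <- tf$segments[tf$segments$y == 0, ]
  expect_identical(s1$x[order(s1$order)], sort(s1$x))
})

test_that("co-occurrence is exact under full coverage", {
  fx <- make_star_fixture(star_spec(n_micrographs = 10, p_mixed = 0.3,
                                    unassigned_fraction = 0, seed = 21))
  s <- cooccurrence_summary(group_filaments(fx$particles))
  expect_equal(s$mixed_fraction, mean(fx$truth$mixed))
  expect_false(s$lower_bound)
  expect_identical(unname(s$counts["unassigned"]), 0L)
})

test_that("partial coverage gives a flagged lower bound on mixing", {
  n_rep <- 30
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    fx <- make_star_fixture(star_spec(n_micrographs = 10,
                                      filaments_per_micrograph = 20,
                                      unassigned_fraction = 0.5,
                                      seed = 100 + r))
    s <- cooccurrence_summary(group_filaments(fx$particles))
    expect_true(s$lower_bound)
    ok[r] <- s$mixed_fraction <= mean(fx$truth$mixed) + 1e-12
  }
  expect_gte(mean(ok), 0.95)
})

test_that("trace plots export per-class series in the micrograph frame", {
  fx <- make_star_fixture(star_spec(n_micrographs = 15, seed = 6))
  tf <- group_filaments(fx$particles)
  mics <- unique(fx$particles$micrograph)
  expect_identical(length(mics), 15L)
  plots <- lapply(mics, function(m) export_trace_plot(tf, m))
  expect_true(all(vapply(plots, nrow, 1L) > 0))
  p1 <- plots[[1]]
  expect_identical(attr(p1, "xlim"), c(0, 4096))
  expect_gt(length(unique(p1$class[!is.na(p1$class)])), 1)
  expect_error(export_trace_plot(tf, "nope.mrc"), "unknown micrograph")
})
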
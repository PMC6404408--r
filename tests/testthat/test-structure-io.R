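test_that("minimal PDB text is parsed into heavy atoms and C-alpha trace", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  HB1 ALA A   1       2.200   1.900   0.800  1.00  0.00           H",
    "ATOM      5  N   ALA A   2       2.000  -1.200   0.500  1.00  0.00           N",
    "ATOM      6  CA  ALA A   2       3.400  -1.500   0.700  1.00  0.00           C",
    "ATOM      7  CB  ALA A   2       4.000  -2.900   0.700  1.00  0.00           C",
    "END")
  st <- read_structure(lines)
  expect_s3_class(st, "fibril_structure")
  expect_equal(nrow(st$residues), 2)
  expect_equal(nrow(st$atoms), 6)          # hydrogens dropped
  expect_false(any(st$atoms$elesy == "H"))
  ca <- calpha_coords(st)
  expect_equal(dim(ca), c(2, 3))
  expect_equal(ca[1, ], c(1.458, 0, 0))
})

test_that("only the first MODEL of a multi-model file is used", {
  mk_model <- function(id, x) c(
    sprintf("MODEL     %4d", id),
    sprintf("ATOM      1  CA  GLY A   1    %8.3f   0.000   0.000  1.00  0.00           C", x),
    sprintf("ATOM      2  CA  GLY A   2    %8.3f   0.000   0.000  1.00  0.00           C", x + 3.8),
    "ENDMDL")
  txt <- c(mk_model(1, 0), mk_model(2, 50), mk_model(3, 100), "END")
  st <- read_structure(txt)
  expect_equal(nrow(st$residues), 2)
  expect_equal(calpha_coords(st)[1, 1], 0)   # model 1, not 50 or 100
})

test_that("residues lacking a C-alpha are dropped with a warning", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END")
  expect_warning(st <- read_structure(lines), "C-alpha")
  expect_equal(nrow(st$residues), 2)
})

test_that("unusable inputs raise format/content errors", {
  expect_error(read_structure(c("garbage line", "more garbage")))
  expect_error(read_structure(c(
    "ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END")))
})

test_that("synthetic fibril has the requested chains, residues and determinism", {
  st <- generate_synthetic_fibril(4, 1, 10, rise = 4.8, seed = 1)
  expect_equal(st$n_chains, 4)
  expect_equal(nrow(st$residues), 40)
  expect_equal(st$source, "synthetic")
  st2 <- generate_synthetic_fibril(4, 1, 10, rise = 4.8, seed = 1)
  expect_identical(st$atoms, st2$atoms)            # bitwise reproducible
  st3 <- generate_synthetic_fibril(4, 1, 10, rise = 4.8, seed = 2)
  expect_false(identical(st$atoms, st3$atoms))
  expect_error(generate_synthetic_fibril(1, 1, 10), "n_layers")
  expect_error(generate_synthetic_fibril(4, 1, 3), "residues_per_chain")
  expect_error(generate_synthetic_fibril(4, 1, 10, rise = -1), "positive")
})

test_that("layer centroids are spaced by the requested rise", {
  rise <- 4.8
  st <- generate_synthetic_fibril(5, 1, 10, rise = rise, seed = 3)
  ca <- calpha_coords(st)
  cents <- t(vapply(st$chains, function(ch)
    colMeans(ca[st$residues$chain == ch, , drop = FALSE]), numeric(3)))
  dz <- diff(sort(cents[, 3]))
  expect_true(all(abs(dz - rise) < 0.1))
})

test_that("PDB write -> read round trip preserves coordinates to 1e-3 A", {
  st <- generate_synthetic_fibril(4, 1, 10, seed = 1)
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(st, path)
  st2 <- read_structure(path)
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  expect_equal(as.matrix(st2$atoms[, c("x", "y", "z")]),
               as.matrix(st$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  unlink(path)
})

test_that("fibril frame finds the stacking axis and contiguous layers", {
  st <- generate_synthetic_fibril(4, 1, 10, seed = 1)   # built along z
  fr <- fibril_frame(st)
  expect_equal(abs(fr$axis[3]), 1, tolerance = 1e-2)
  expect_equal(sqrt(sum(fr$axis^2)), 1, tolerance = 1e-9)
  expect_setequal(unname(fr$layer_of_chain), 0:3)
  # layer index increases along the axis orientation
  ca <- calpha_coords(st)
  proj <- vapply(st$chains, function(ch)
    mean(ca[st$residues$chain == ch, , drop = FALSE] %*% fr$axis), numeric(1))
  expect_true(all(diff(proj[order(fr$layer_of_chain)]) > 0))
})

test_that("fibril frame is equivariant under a known rotation", {
  st <- generate_synthetic_fibril(4, 1, 10, seed = 1)
  th <- 0.7; ph <- 1.1
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3, 3, byrow = TRUE)
  R <- Rx %*% Rz
  st_rot <- st
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R)
  st_rot$atoms$x <- xyz[, 1] + 5; st_rot$atoms$y <- xyz[, 2] - 2
  st_rot$atoms$z <- xyz[, 3] + 1
  fr0 <- fibril_frame(st)
  fr1 <- fibril_frame(st_rot)
  expected <- as.numeric(R %*% fr0$axis)
  # axis defined up to sign
  err <- min(max(abs(fr1$axis - expected)), max(abs(fr1$axis + expected)))
  expect_lt(err, 1e-2)
  expect_identical(fr1$layer_of_chain, fr0$layer_of_chain)
})

test_that("single-chain input yields a one-layer frame with a warning", {
  sys <- fx_chain()
  expect_warning(fr <- fibril_frame(sys$structure), "single chain")
  expect_identical(unname(fr$layer_of_chain), 0L)
})

test_that("XYZ writer emits parseable frames", {
  frames <- list(matrix(rnorm(9), 3), matrix(rnorm(9), 3))
  path <- tempfile(fileext = ".xyz")
  write_xyz(frames, path)
  ln <- readLines(path)
  expect_equal(length(ln), 2 * (2 + 3))
  expect_equal(ln[1], "3")
  unlink(path)
})
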
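test_that("bonded-term counts follow chain combinatorics", {
  sys <- fx_chain(10)
  bt <- build_bonded_terms(sys$structure)
  expect_equal(nrow(bt$bonds), 9)
  expect_equal(nrow(bt$angles), 8)
  expect_equal(nrow(bt$dihedrals), 7)
  expect_true(all(abs(bt$bonds$r0 - 3.8) < 1e-9))
  # collinear trace: all equilibrium angles are pi
  expect_true(all(abs(bt$angles$theta0 - pi) < 1e-6))
})

test_that("bonded terms never span chain breaks", {
  sys <- fx_small()
  bt <- build_bonded_terms(sys$structure)
  res <- sys$structure$residues
  expect_true(all(res$chain[bt$bonds$i] == res$chain[bt$bonds$j]))
  expect_true(all(res$chain[bt$angles$i] == res$chain[bt$angles$k]))
  expect_true(all(res$chain[bt$dihedrals$i] == res$chain[bt$dihedrals$l]))
})

test_that("a hand-built 90-degree dihedral is recovered", {
  p1 <- c(1, 0, 0); p2 <- c(0, 0, 0); p3 <- c(0, 0, 1); p4 <- c(0, 1, 1)
  expect_equal(dihedral_angle(p1, p2, p3, p4), pi / 2, tolerance = 1e-9)
  # through the topology builder
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    1:4, 1:4, c(1, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 1, 1))
  st <- suppressWarnings(read_structure(c(lines, "END")))
  bt <- build_bonded_terms(st)
  expect_equal(abs(bt$dihedrals$phi0), pi / 2, tolerance = 1e-9)
})

test_that("overlap criterion is strict sphere overlap with enlargement", {
  a <- c(0, 0, 0)
  # threshold = 1.24 * (1.8 + 1.8) = 4.464 A
  expect_true(overlap_contact(a, c(4.0, 0, 0), 1.8, 1.8, 1.24))
  expect_false(overlap_contact(a, c(4.6, 0, 0), 1.8, 1.8, 1.24))
  expect_false(overlap_contact(a, c(4.464, 0, 0), 1.8, 1.8, 1.24))  # boundary
})

test_that("radius table lookup classifies atoms and falls back with warning", {
  expect_equal(atom_radius("CA", "C", "ALA"), 1.88)
  expect_equal(atom_radius("C", "C", "ALA"), 1.76)     # backbone carbonyl C
  expect_equal(atom_radius("CZ", "C", "PHE"), 1.61)    # aromatic ring
  expect_equal(atom_radius("OD1", "O", "ASP"), 1.42)
  expect_equal(atom_radius("SG", "S", "CYS"), 1.77)
  expect_warning(r <- atom_radius("X1", "SE", "MSE", warn_unknown = TRUE),
                 "default")
  expect_equal(r, 1.80)
})

test_that("contact map obeys the |i-j| > 4 intrachain rule", {
  # horseshoe chain: residues 1 and 5 overlap (|i-j| = 4, excluded),
  # residues 1 and 6 overlap (|i-j| = 5, kept)
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(7.6, 3.5, 0),
               c(0.5, 3.5, 0), c(-3.0, 3.5, 0))
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    1:6, 1:6, xyz[, 1], xyz[, 2], xyz[, 3])
  st <- suppressWarnings(read_structure(c(lines, "END")))
  fr <- suppressWarnings(fibril_frame(st))
  cm <- build_contact_map(st, model_params(), fr)
  expect_false(any(cm$i == 1 & cm$j == 5))
  expect_true(any(cm$i == 1 & cm$j == 6))
  expect_true(all(abs(cm$j - cm$i) > 4))
  expect_true(all(cm$i < cm$j))
})

test_that("an isolated extended strand has no native contacts", {
  sys <- fx_chain(10)
  expect_equal(nrow(sys$topology$contacts), 0)
})

test_that("contact classes follow chain and layer membership", {
  fr <- structure(list(axis = c(0, 0, 1), origin = c(0, 0, 0),
                       layer_of_chain = c(A = 0L, B = 0L, C = 1L)),
                  class = "fibril_frame")
  expect_equal(unname(classify_contact("A", "A", fr)), "intrachain")
  expect_equal(unname(classify_contact("A", "B", fr)), "interchain")
  expect_equal(unname(classify_contact("A", "C", fr)), "intersheet")
})

test_that("fixture contact maps contain the expected classes", {
  topo1 <- fx_small()$topology       # single protofilament
  tab1 <- table(topo1$contacts$class)
  expect_gt(tab1[["intersheet"]], 0)
  expect_gt(tab1[["intrachain"]], 0)
  expect_false("interchain" %in% names(tab1))   # single chain per cross-section
  topo2 <- fx_two_proto()$topology
  tab2 <- table(topo2$contacts$class)
  expect_true(all(c("intrachain", "interchain", "intersheet") %in% names(tab2)))
  # every residue of a 2-layer fibril touches the adjacent layer
  st2 <- generate_synthetic_fibril(2, 1, 8, rise = 4.8, seed = 4)
  topo <- build_topology(st2)
  inter <- topo$contacts[topo$contacts$class == "intersheet", ]
  expect_true(all(seq_len(topo$n_beads) %in% c(inter$i, inter$j)))
})

test_that("sigma relates to r0 by the Lennard-Jones minimum condition", {
  cs <- fx_two_proto()$topology$contacts
  expect_equal(cs$sigma, cs$r0 / 2^(1 / 6), tolerance = 1e-12)
})

test_that("brute-force all-pairs oracle reproduces the contact map", {
  st <- generate_synthetic_fibril(3, 2, 8, seed = 5)
  pars <- model_params()
  fr <- fibril_frame(st)
  cm <- build_contact_map(st, pars, fr)
  at <- st$atoms
  res <- st$residues
  rad <- atom_radius(at$elety, at$elesy, at$resid, pars$radius_table)
  key <- paste(at$chain, at$ridx)
  bead_of <- match(key, paste(res$chain, res$ridx))
  found <- list()
  for (i in seq_len(nrow(res) - 1)) {
    for (j in (i + 1):nrow(res)) {
      if (res$chain[i] == res$chain[j] && abs(res$ridx[i] - res$ridx[j]) <= 4) next
      ai <- which(bead_of == i); aj <- which(bead_of == j)
      hit <- FALSE
      for (a in ai) for (b in aj) {
        d <- sqrt((at$x[a] - at$x[b])^2 + (at$y[a] - at$y[b])^2 +
                  (at$z[a] - at$z[b])^2)
        if (d < pars$enlargement * (rad[a] + rad[b])) { hit <- TRUE; break }
      }
      if (hit) found[[length(found) + 1]] <- c(i, j)
    }
  }
  oracle <- do.call(rbind, found)
  expect_equal(nrow(cm), nrow(oracle))
  expect_setequal(paste(cm$i, cm$j), paste(oracle[, 1], oracle[, 2]))
})

test_that("contact count is invariant under rigid-body motion", {
  st <- generate_synthetic_fibril(3, 2, 8, seed = 6)
  n0 <- nrow(build_topology(st)$contacts)
  th <- 0.9
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R)
  st$atoms$x <- xyz[, 1] + 12; st$atoms$y <- xyz[, 2] + 3; st$atoms$z <- xyz[, 3] - 7
  expect_equal(nrow(build_topology(st)$contacts), n0)
})

test_that("topology serialization round-trips through JSON and text table", {
  topo <- fx_small()$topology
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".txt")
  write_topology_json(topo, jf)
  js <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(js$n_beads, topo$n_beads)
  expect_equal(length(js$contacts$i), nrow(topo$contacts))
  expect_equal(js$params$epsilon, 1.5)
  write_contact_table(topo, tf)
  tab <- utils::read.table(tf, header = TRUE)
  expect_equal(nrow(tab), nrow(topo$contacts))
  expect_true(all(c("i", "j", "r0", "class") %in% names(tab)))
  unlink(c(jf, tf))
})
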
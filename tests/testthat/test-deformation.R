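test_that("tensile anchor slabs sit at opposite fibril ends", {
  sys <- fx_small()
  sets <- select_anchor_sets(sys, "tensile", d_anchor = 2)
  lay <- sys$frame$layer_of_chain[sys$structure$residues$chain]
  expect_true(all(lay[sets$bottom] == min(lay)))
  expect_true(all(lay[sets$top] == max(lay)))
  expect_error(select_anchor_sets(sys, "tensile", d_anchor = 50), "too large")
})

test_that("shear top set is the residue segment replicated over chains", {
  sys <- fx_two_proto()
  seg <- 3:7
  sets <- select_anchor_sets(sys, "shear", d_anchor = 2, shear_segment = seg)
  res <- sys$structure$residues
  expect_true(all(res$ridx[sets$top] %in% seg))
  in_seg <- which(res$ridx %in% seg)
  expect_setequal(sets$top, setdiff(in_seg, sets$bottom))
  expect_error(select_anchor_sets(sys, "shear", d_anchor = 2), "shear_segment")
})

test_that("recorded control displacement equals speed times time", {
  rec <- fx_tensile_rec()
  s <- rec$series
  expect_equal(s$control, rec$metadata$v_pull * s$time, tolerance = 1e-9)
  expect_true(all(diff(s$time) > 0))
})

test_that("zero pulling speed leaves strain and mean force at thermal noise", {
  sys <- fx_small()
  rec <- run_tensile(sys, v_pull = 0, k_top = 0.1, max_strain = 0.1,
                     t_equil = 30, record_every = 200, max_time = 30, seed = 5)
  s <- rec$series
  expect_lt(abs(mean(s$strain)), 0.02)
  expect_lt(abs(mean(s$force)), 1.0)
})

test_that("quasi-static stretching of a harmonic chain follows springs in series", {
  sys <- fx_chain()
  rec <- run_tensile(sys, v_pull = 0.005, k_bottom = 100, k_top = 10,
                     max_strain = 0.03, temperature = 0, d_anchor = 1,
                     t_equil = 10, record_every = 200, seed = 1)
  A_declared <- 10
  fit <- fit_linear_modulus(stress_strain(rec, area = A_declared),
                            window = c(0.002, 0.03))
  k_chain <- 2 * sys$params$K_r / 10      # 10 bonds in series
  y_expect <- kcal_mol_A3_to_gpa(k_chain * rec$metadata$L0 / A_declared)
  expect_equal(fit$value, y_expect, tolerance = 0.02)
})

test_that("shear strain is displacement over plane separation and thickness is preserved", {
  rec <- fx_shear_rec()
  s <- rec$series
  # strain definition x / y against the record's own frames: x is the axial
  # displacement of the top-plane centroid, y the plane separation
  topc <- function(f) mean(f[rec$metadata$top, , drop = FALSE] %*% rec$metadata$axis)
  expect_equal(s$strain[1], 0, tolerance = 1e-9)
  expect_equal(s$strain[10],
               (topc(rec$metadata$frames[[10]]) - topc(rec$metadata$frames[[1]])) /
                 rec$metadata$height,
               tolerance = 1e-6)
  # fibril thickness (extent along the shear normal) is preserved: compare
  # window-averaged extents near strain 0.025 and near zero strain
  thick <- function(f) diff(range(f %*% rec$metadata$tdir))
  i025 <- order(abs(s$strain - 0.025))[1:5]
  i0 <- order(abs(s$strain))[1:5]
  expect_lt(abs(mean(sapply(rec$metadata$frames[i025], thick)) /
                mean(sapply(rec$metadata$frames[i0], thick)) - 1), 0.02)
})

test_that("indenter exerts no force before first contact", {
  rec <- fx_indent_rec()
  s <- rec$series
  pre <- is.na(s$h)
  expect_gt(sum(pre), 0)
  expect_lt(max(abs(s$force[pre])), 0.1)
  expect_gt(max(s$force, na.rm = TRUE), 1)
})

test_that("force on a single pinned bead follows the inverse-10 tip law", {
  topo <- bare_topology(1)
  A <- 0.525; R <- 10; v <- 0.05; dt <- 0.002
  restr <- restraint_set(anchor_idx = 1, anchor_k = 500,
                         anchor_pos = matrix(0, 1, 3),
                         indenter = list(center = c(0, 0, R + 3), vel = c(0, 0, -v),
                                         R = R, A = A))
  tr <- run_dynamics(matrix(0, 1, 3), topo, 15000, dt = dt, temperature = 0,
                     record_every = 1, restraints = restr)
  ks <- seq(2000, 14000, by = 2000)
  for (s in ks) {
    bead <- tr$frames[[s + 1]][1, ]
    center <- c(0, 0, R + 3 - v * (s - 1) * dt)   # target at force evaluation
    d <- sqrt(sum((bead - center)^2))
    f_expect <- 10 * A * (d - R)^(-11) * (center[3] - bead[3]) / d
    expect_equal(tr$f_tip[s + 1], f_expect, tolerance = 1e-6)
  }
})

test_that("force-depth response of a fibril is monotone at small depth", {
  rec <- fx_indent_rec()
  s <- rec$series[!is.na(rec$series$h) & rec$series$h <= 1.5, ]
  b <- tapply(s$force, cut(s$h, 4), mean)
  expect_true(all(diff(b) > 0))
})

test_that("a bond dragged past 3 r0 truncates the run with a rupture flag", {
  topo <- bare_topology(2, bonds = data.frame(i = 1L, j = 2L, r0 = 3.8))
  topo$chain_index <- c(1L, 1L)
  x <- rbind(c(0, 0, 0), c(3.8, 0, 0))
  restr <- restraint_set(anchor_idx = 1, anchor_k = 100, anchor_pos = x[1, , drop = FALSE],
                         pull_idx = 2, pull_k = 50, pull_vel = c(0.5, 0, 0),
                         pull_pos0 = x[2, , drop = FALSE])
  n_steps <- 60000
  tr <- run_dynamics(x, topo, n_steps, dt = 0.002, temperature = 0,
                     record_every = 500, restraints = restr)
  expect_true(tr$ruptured)
  expect_lt(length(tr$frames), n_steps / 500 + 1)
  # every surviving frame respects the 3 r0 guard up to one recording interval
  lens <- vapply(tr$frames, function(f) sqrt(sum((f[2, ] - f[1, ])^2)), numeric(1))
  expect_lt(max(lens[-length(lens)]), 3 * 3.8 + 1)
})
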
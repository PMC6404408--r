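test_that("RMSD of identical and rigidly moved structures is zero", {
  set.seed(31)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(P, P), 0, tolerance = 1e-12)
  expect_equal(rmsd(sweep(P, 2, c(5, 0, 0), "+"), P), 0, tolerance = 1e-9)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  expect_equal(rmsd(P %*% t(R) + 3, P), 0, tolerance = 1e-9)
  expect_error(rmsd(P[1:5, ], P), "mismatch")
})

test_that("single displaced bead gives the hand-computed RMSD", {
  P <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0))
  Q <- P; Q[2, 3] <- Q[2, 3] + 2
  expect_equal(rmsd(Q, P, fit = FALSE), sqrt(2^2 / 4), tolerance = 1e-12)
  # optimal superposition can only lower the deviation
  expect_lte(rmsd(Q, P), 1.0 + 1e-12)
  expect_gt(rmsd(Q, P), 0.5)
})

test_that("superposed RMSD agrees with the bio3d reference implementation", {
  set.seed(32)
  P <- matrix(rnorm(36, sd = 4), 12, 3)
  Q <- P + matrix(rnorm(36, sd = 0.6), 12, 3)
  ours <- rmsd(Q, P)
  ref <- bio3d::rmsd(as.numeric(t(P)), as.numeric(t(Q)), fit = TRUE)
  expect_lt(abs(ours - ref), 5e-4)   # bio3d rounds to 3 decimals
})

test_that("RMSF is zero for a frozen trajectory and exact for two-point motion", {
  set.seed(33)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsf(list(P, P, P), P), rep(0, 10), tolerance = 1e-9)
  expect_error(rmsf(list(P), P), "2 frames")
  # a large rigid body with one residue oscillating +-1 A along x; the body is
  # heavy enough that superposition is essentially unchanged
  ref <- cbind(seq(0, 240, length.out = 100), rep(c(0, 1), 50), 0)
  A <- ref; B <- ref
  A[20, 1] <- A[20, 1] + 1; B[20, 1] <- B[20, 1] - 1
  r <- rmsf(list(A, B), ref)
  expect_equal(r[20], 1.0, tolerance = 0.02)
  expect_lt(max(r[-20]), 0.1)
})

test_that("native-state probability counts frames with all contacts formed", {
  sys <- fx_small()
  cs <- sys$topology$contacts
  x <- sys$positions
  expect_equal(native_state_probability(rep(list(x), 5), sys$topology), 1)
  expect_equal(native_state_probability(list(x * 2), sys$topology), 0)
  # 3 of 10 frames have exactly one contact stretched to 1.6 r0
  stretch_one <- function(x) {
    i <- cs$i[1]; j <- cs$j[1]
    dir <- x[j, ] - x[i, ]; dir <- dir / sqrt(sum(dir^2))
    x[j, ] <- x[i, ] + dir * 1.6 * cs$r0[1]
    x
  }
  frames <- c(rep(list(stretch_one(x)), 3), rep(list(x), 7))
  expect_equal(native_state_probability(frames, sys$topology), 0.7)
  expect_error(native_state_probability(list(), sys$topology), "no frames")
  # RMSD criterion behind the same interface
  far <- lapply(1:4, function(i) x + if (i <= 1) 5 * matrix(rnorm(length(x)), ncol = 3) else 0)
  p <- native_state_probability(far, sys$topology, criterion = "rmsd",
                                reference = x, rmsd_max = 3)
  expect_equal(p, 0.75)
  expect_error(native_state_probability(frames, sys$topology, criterion = "rmsd"),
               "reference")
})

test_that("P0 is non-increasing as the formed criterion tightens", {
  sys <- fx_small()
  set.seed(34)
  tr <- run_dynamics(sys$positions, sys$topology, 20000, dt = 0.002,
                     temperature = 0.5, record_every = 500)
  fac <- c(1.1, 1.2, 1.35, 1.5, 2.0)
  p <- vapply(fac, function(f)
    native_state_probability(tr$frames[-1], sys$topology, f), numeric(1))
  expect_true(all(diff(p) >= 0))   # looser criterion, higher P0
})

test_that("folding temperature interpolates the P0 = 1/2 crossing", {
  tab <- data.frame(temperature = c(0.36, 0.40, 0.44, 0.48),
                    P0 = c(0.8, 0.6, 0.4, 0.2))
  expect_equal(folding_temperature(tab), 0.42, tolerance = 1e-12)
  expect_error(folding_temperature(
    data.frame(temperature = c(0.1, 0.2), P0 = c(1, 1))), "cross")
  # multiple crossings: lowest reported with a warning
  tab2 <- data.frame(temperature = c(0.3, 0.4, 0.5, 0.6),
                     P0 = c(0.9, 0.4, 0.7, 0.1))
  expect_warning(tf <- folding_temperature(tab2), "multiple")
  expect_lt(tf, 0.4)
})

test_that("a sampled sigmoid recovers its midpoint to 0.005", {
  Tg <- seq(0.1, 0.7, length.out = 35)
  tab <- data.frame(temperature = Tg, P0 = 1 / (1 + exp((Tg - 0.45) / 0.01)))
  expect_equal(folding_temperature(tab), 0.45, tolerance = 0.005)
})

test_that("temperature scan returns consistent tables and cold-limit P0 = 1", {
  sys <- fx_small()
  Tg <- c(0.05, 0.3)
  scan <- temperature_scan(sys, Tg, t_equil = 4, t_prod = 20,
                           record_every = 400, seed = 35)
  expect_s3_class(scan, "thermo_scan")
  expect_equal(nrow(scan$table), 2)
  expect_true(all(scan$table$P0 >= 0 & scan$table$P0 <= 1))
  expect_equal(scan$table$P0[1], 1)                    # deep native well
  expect_equal(dim(scan$rmsf), c(2, nrow(sys$positions)))
  expect_error(temperature_scan(sys, c(0.3, 0.2)), "increasing")
})

test_that("terminal tail residues fluctuate more than the folded core", {
  sys <- cg_system(generate_synthetic_fibril(4, 1, 10, seed = 3, n_tail = 4))
  set.seed(36)
  eq <- run_dynamics(sys$positions, sys$topology, 10000, dt = 0.002,
                     temperature = 0.35, record_every = 10000)
  tr <- run_dynamics(eq$positions, sys$topology, 50000, dt = 0.002,
                     temperature = 0.35, record_every = 500)
  r <- rmsf(tr$frames[-1], sys$positions)
  res <- sys$structure$residues
  tail_r <- r[res$ridx > 10]
  core_r <- r[res$ridx <= 10]
  expect_gt(mean(tail_r), mean(core_r))
  # fluctuations grow toward the free end; the terminus is far above the core
  expect_gt(max(tail_r), 2 * mean(core_r))
})
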
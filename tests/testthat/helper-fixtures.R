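# Shared fixtures and independent oracles for the test suite.

# memoise the standard fixtures: building topologies repeatedly is wasteful
.fx_cache <- new.env(parent = emptyenv())
fx <- function(key, builder) {
  if (is.null(.fx_cache[[key]])) .fx_cache[[key]] <- builder()
  .fx_cache[[key]]
}

fx_small <- function() fx("small", function()
  cg_system(generate_synthetic_fibril(4, 1, 10, seed = 1)))

fx_two_proto <- function() fx("two_proto", function()
  cg_system(generate_synthetic_fibril(4, 2, 10, seed = 2)))

fx_mech <- function() fx("mech", function()
  cg_system(generate_synthetic_fibril(10, 2, 16, seed = 1)))

# straight 11-bead C-alpha chain along z (bonds only; no native contacts)
fx_chain <- function(n = 11, step = 3.8) {
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n), 0, 0, (seq_len(n) - 1) * step)
  st <- suppressWarnings(read_structure(c(lines, "END")))
  suppressWarnings(cg_system(st))
}

# minimal hand-built topology (for single/double-bead closed-form checks)
bare_topology <- function(n_beads, bonds = NULL, contacts = NULL,
                          params = model_params()) {
  empty_b <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0))
  structure(list(
    bonds = if (is.null(bonds)) empty_b else bonds,
    angles = data.frame(i = integer(0), j = integer(0), k = integer(0),
                        theta0 = numeric(0)),
    dihedrals = data.frame(i = integer(0), j = integer(0), k = integer(0),
                           l = integer(0), phi0 = numeric(0)),
    contacts = if (is.null(contacts))
      data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                 sigma = numeric(0), class = character(0)) else contacts,
    n_beads = as.integer(n_beads),
    chain_index = seq_len(n_beads),  # every bead its own chain: no exclusions
    params = params), class = "fibril_topology")
}

# independent convex-hull oracle: gift wrapping (Jarvis march) + shoelace
hull_area_oracle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- setdiff(seq_len(n), p)
    q <- cand[1]
    for (r in cand[-1]) {
      cross <- (pts[q, 1] - pts[p, 1]) * (pts[r, 2] - pts[p, 2]) -
               (pts[q, 2] - pts[p, 2]) * (pts[r, 1] - pts[p, 1])
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      d_r <- sum((pts[r, ] - pts[p, ])^2)
      if (cross < 0 || (abs(cross) < 1e-12 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("gift wrap failed")
  }
  xs <- pts[hull, 1]; ys <- pts[hull, 2]
  abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
}

# central-difference force oracle on selected coordinates
numgrad_check <- function(positions, topology, n_probe = 8, h = 1e-5,
                          seed = 1) {
  f <- compute_forces(positions, topology)
  set.seed(seed)
  ij <- cbind(sample(nrow(positions), n_probe, replace = TRUE),
              sample(3, n_probe, replace = TRUE))
  vapply(seq_len(n_probe), function(k) {
    i <- ij[k, 1]; d <- ij[k, 2]
    xa <- positions; xa[i, d] <- xa[i, d] + h
    xb <- positions; xb[i, d] <- xb[i, d] - h
    g <- -(compute_energy(xa, topology)[["total"]] -
           compute_energy(xb, topology)[["total"]]) / (2 * h)
    abs(g - f[i, d]) / max(abs(g), 1e-6)
  }, numeric(1))
}

# quick equilibrate + production P0 probe used by the thermo tests
p0_probe <- function(sys, Tk, seed, t_equil = 20, t_prod = 100, dt = 0.002) {
  set.seed(seed)
  eq <- run_dynamics(sys$positions, sys$topology, round(t_equil / dt), dt = dt,
                     temperature = Tk, record_every = round(t_equil / dt))
  pr <- run_dynamics(eq$positions, sys$topology, round(t_prod / dt), dt = dt,
                     temperature = Tk, record_every = 500)
  native_state_probability(pr$frames[-1], sys$topology)
}

# memoised small deformation records shared across test files
fx_tensile_rec <- function() fx("tensile_rec", function()
  run_tensile(fx_two_proto(), v_pull = 0.02, max_strain = 0.04,
              t_equil = 20, record_every = 400, seed = 21))

fx_shear_rec <- function() fx("shear_rec", function()
  run_shear(fx_two_proto(), shear_segment = 6:10, v_pull = 0.02,
            max_strain = 0.05, d_anchor = 3, t_equil = 20,
            record_every = 400, seed = 22))

fx_indent_rec <- function() fx("indent_rec", function()
  run_indentation(fx_two_proto(), R_ind = 15, v_ind = 0.02, max_depth = 3,
                  t_equil = 20, record_every = 200, seed = 23))
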
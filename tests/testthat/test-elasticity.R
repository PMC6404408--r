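test_that("convex-hull areas of simple shapes are exact", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  expect_equal(cross_section_area(sq, c(0, 0, 1)), 1.0)
  tri <- cbind(c(0, 3, 0), c(0, 0, 4), 5)
  expect_equal(cross_section_area(tri, c(0, 0, 1)), 6.0)
  expect_error(cross_section_area(cbind(0:5, 0, 0), c(0, 0, 1)), "degenerate|collinear")
  expect_error(cross_section_area(sq[1:2, ], c(0, 0, 1)), "3 points")
})

test_that("hull area matches the gift-wrapping oracle on random point sets", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    pts <- cbind(runif(n, -10, 10), runif(n, -10, 10))
    a <- cross_section_area(cbind(pts, rnorm(n)), c(0, 0, 1))
    expect_equal(a, hull_area_oracle(pts), tolerance = 1e-9)
  }
})

test_that("projection plane is perpendicular to the requested axis", {
  # points on a cylinder around x: projected area along x is the disc hull
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  pts <- cbind(runif(32, 0, 50), 3 * cos(th), 3 * sin(th))
  a <- cross_section_area(pts, c(1, 0, 0))
  expect_equal(a, hull_area_oracle(cbind(3 * cos(th), 3 * sin(th))),
               tolerance = 1e-9)
})

test_that("stress is force over area with mean or per-frame convention", {
  rec <- fx_tensile_rec()
  cur <- stress_strain(rec, area = 100)
  expect_equal(cur$stress, rec$series$force / 100)
  cm <- stress_strain(rec, "mean")
  cf <- stress_strain(rec, "frame")
  expect_equal(cm$stress, rec$series$force / mean(rec$series$area))
  expect_equal(cf$stress, rec$series$force / rec$series$area)
  # area varies little, so the two conventions agree closely
  fm <- fit_linear_modulus(cm); ff <- fit_linear_modulus(cf)
  expect_lt(abs(fm$value / ff$value - 1), 0.02)
  expect_error(stress_strain(fx_indent_rec()), "tensile or shear")
})

test_that("an exact line is converted slope-to-GPa without loss", {
  strain <- seq(0, 0.05, length.out = 60)
  cur <- data.frame(strain = strain, stress = 2 * strain)
  fit <- fit_linear_modulus(cur)
  expect_equal(fit$value, 13.8954, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1)
  # any sub-window gives the same slope
  fit2 <- fit_linear_modulus(cur, window = c(0.01, 0.04))
  expect_equal(fit2$value, fit$value, tolerance = 1e-9)
})

test_that("unit conversion round trip is exact", {
  x <- c(0.001, 0.29, 2.41, 17)
  expect_equal(gpa_to_kcal_mol_A3(kcal_mol_A3_to_gpa(x)), x, tolerance = 1e-12)
  expect_equal(kcal_mol_A3_to_gpa(1), 6.9477)
})

test_that("pure noise yields a poor-fit warning", {
  set.seed(3)
  cur <- data.frame(strain = seq(0, 0.05, length.out = 80), stress = rnorm(80))
  expect_warning(fit <- fit_linear_modulus(cur), "poor")
  expect_true(fit$poor_fit)
})

test_that("Hertz forward-generated curves are recovered to 1 percent", {
  R <- 100; nu <- 0.5
  YT_gpa <- 5
  YT_int <- gpa_to_kcal_mol_A3(YT_gpa)
  h <- seq(0.01, 3, length.out = 120)
  F <- (4 / 3) * (YT_int / (1 - nu^2)) * sqrt(R) * h^1.5
  fit <- fit_hertz(data.frame(h = h, force = F), R_ind = R, nu = nu)
  expect_equal(fit$value, YT_gpa, tolerance = 0.01)
  expect_equal(fit$exponent_n, 1.5, tolerance = 0.02)
})

test_that("a linear contact law yields exponent 1 and degenerate data fail", {
  h <- seq(0.05, 2, length.out = 60)
  fit <- fit_hertz(data.frame(h = h, force = 3 * h), R_ind = 50)
  expect_equal(fit$exponent_n, 1.0, tolerance = 0.02)
  expect_error(fit_hertz(data.frame(h = h, force = rep(0, 60)), R_ind = 50),
               "usable")
})

test_that("replica aggregation tightens the estimate and bootstrap runs", {
  set.seed(17)
  mk <- function() {
    strain <- seq(0, 0.05, length.out = 100)
    data.frame(strain = strain, stress = 1.5 * strain + rnorm(100, 0, 0.01))
  }
  reps <- replicate(5, mk(), simplify = FALSE)
  fit <- fit_linear_modulus(reps[[1]], replicas = reps, n_boot = 100, seed = 2)
  expect_equal(fit$value, kcal_mol_A3_to_gpa(1.5), tolerance = 0.1)
  expect_gt(fit$stderr, 0)
  expect_equal(fit$replicas_used, 5)
})

test_that("contact-length distributions are massed at native lengths", {
  sys <- fx_two_proto()
  d <- contact_length_distributions(sys$positions, sys$topology)
  cs <- sys$topology$contacts
  for (cl in c("intrachain", "interchain", "intersheet")) {
    expect_equal(d[[cl]]$mean_length, mean(cs$r0[cs$class == cl]),
                 tolerance = 1e-9)
    # histogram integrates to one
    expect_equal(sum(d[[cl]]$density) * 0.05, 1, tolerance = 1e-6)
  }
})

test_that("uniform scaling shifts every distribution by the same factor", {
  sys <- fx_two_proto()
  d0 <- contact_length_distributions(sys$positions, sys$topology)
  d1 <- contact_length_distributions(sys$positions * 1.02, sys$topology)
  for (cl in c("intrachain", "interchain", "intersheet"))
    expect_equal(d1[[cl]]$mean_length, 1.02 * d0[[cl]]$mean_length,
                 tolerance = 1e-9)
})

test_that("a class with no contacts yields an empty histogram, not an error", {
  sys <- fx_small()   # single protofilament: no interchain contacts
  d <- contact_length_distributions(sys$positions, sys$topology)
  expect_equal(d$interchain$n, 0)
  expect_true(is.na(d$interchain$mean_length))
  expect_gt(d$intersheet$n, 0)
})

test_that("frame_at retrieves the frame nearest a control value", {
  rec <- fx_tensile_rec()
  s <- rec$series
  target <- 0.02
  f <- frame_at(rec, target)
  i <- which.min(abs(s$strain - target))
  expect_identical(f, rec$metadata$frames[[i]])
  expect_error(frame_at(rec, 10), "outside")
})
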
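test_that("parameter domains are enforced with the offending field named", {
  expect_error(hg_phase_function(1), "gHG")
  expect_error(mhg_phase_function(0.5, 1.2), "alpha")
  expect_error(tthg_phase_function(0.5, 1.0, -0.3), "gf")
  expect_error(tthg_phase_function(0.5, 0.9, 0.3), "gb")
  expect_error(rmc_phase_function(-1, 0.5), "alpha")
  expect_error(rmc_phase_function(1, 1.2), "gR")
  expect_error(pf_density(hg_phase_function(0.5), -0.1), "theta")
})

test_that("densities match closed forms and degeneracies", {
  iso <- hg_phase_function(0)
  th <- seq(0, pi, length.out = 11)
  expect_equal(pf_density(iso, th), rep(1 / (4 * pi), 11))

  # MHG with alpha = 1 reduces exactly to HG
  expect_equal(pf_density(mhg_phase_function(0.7, 1), th),
               pf_density(hg_phase_function(0.7), th))

  # forward peak of a sharp HG lobe: (1/4pi)(1+g)/(1-g)^2
  g <- 0.9
  expect_equal(pf_density(hg_phase_function(g), 0),
               (1 / (4 * pi)) * (1 + g) / (1 - g)^2, tolerance = 1e-12)
})

test_that("every family is normalised over the sphere", {
  for (pf in random_models(10)) {
    expect_lt(abs(sphere_integral(pf) - 1), 1e-6)
    expect_true(all(pf_density(pf, seq(0, pi, length.out = 181)) >= 0))
  }
})

test_that("quadrature Legendre moments agree with closed forms", {
  g <- 0.6
  expect_equal(unname(legendre_moments(hg_phase_function(g), 3)), g^(1:3),
               tolerance = 1e-8)

  # MHG: g1 = a g, g2 = a g^2 + (1 - a) * 2/5
  m <- legendre_moments(mhg_phase_function(0.9, 0.8), 2)
  expect_equal(unname(m), c(0.72, 0.728), tolerance = 1e-8)

  # TTHG: convex combination of the lobe moments
  m <- legendre_moments(tthg_phase_function(0.9, 0.9, -0.3), 3)
  expect_equal(unname(m), 0.9 * 0.9^(1:3) + 0.1 * (-0.3)^(1:3),
               tolerance = 1e-8)
  expect_equal(unname(m[1:2]), c(0.78, 0.738), tolerance = 1e-8)

  # mixtures across random draws: quadrature vs analytic mixture moments
  set.seed(11)
  for (i in 1:10) {
    a <- runif(1); gf <- runif(1, 0.3, 0.95); gb <- runif(1, -0.95, -0.05)
    expect_equal(unname(legendre_moments(tthg_phase_function(a, gf, gb), 4)),
                 a * gf^(1:4) + (1 - a) * gb^(1:4), tolerance = 1e-8)
  }
})

test_that("moments are bounded and stable under quadrature refinement", {
  for (pf in example_models()) {
    m <- legendre_moments(pf, 8, order = 256)
    expect_true(all(abs(m) <= 1 + 1e-12))
    expect_equal(m, legendre_moments(pf, 8, order = 2048), tolerance = 1e-9)
  }
})

test_that("partial integrals reproduce closed forms and partition the sphere", {
  iso <- hg_phase_function(0)
  expect_equal(partial_integral(iso, 23, "forward", degrees = TRUE),
               (1 - cos(23 * pi / 180)) / 2, tolerance = 1e-9)
  expect_equal(partial_integral(iso, 1, "backward", degrees = TRUE),
               (1 - cos(pi / 180)) / 2, tolerance = 1e-9)
  expect_error(partial_integral(iso, 0, "forward"), "theta_lim")
  expect_error(partial_integral(iso, 100, "forward", degrees = TRUE),
               "theta_lim")

  # closed-form HG partial integral as an independent oracle
  g <- 0.85
  hg_forward <- function(th) {
    F <- function(mu) -(1 - g^2) / (2 * g) / sqrt(1 + g^2 - 2 * g * mu)
    F(cos(th)) - F(1)
  }
  expect_equal(partial_integral(hg_phase_function(g), 0.4, "forward"),
               hg_forward(0.4), tolerance = 1e-9)

  for (pf in example_models()) {
    s <- partial_integral(pf, pi / 2, "forward") +
      partial_integral(pf, pi / 2, "backward")
    expect_lt(abs(s - 1), 1e-6)
    th <- 0.3
    expect_lte(partial_integral(pf, th, "forward") +
                 partial_integral(pf, th, "backward"), 1 + 1e-9)
  }
})

test_that("angle sampling reproduces the quadrature moments", {
  n <- 1e6
  ang <- sample_scattering_angles(hg_phase_function(0.8), n, seed = 1)
  expect_true(all(ang >= 0 & ang <= pi))
  expect_equal(mean(cos(ang)), 0.8, tolerance = 0.002)
  # reproducible under the same seed, new draw otherwise
  expect_identical(ang, sample_scattering_angles(hg_phase_function(0.8), n,
                                                 seed = 1))

  # isotropic: cos(theta) uniform on [-1, 1]
  mu <- cos(sample_scattering_angles(hg_phase_function(0), n, seed = 2))
  ks <- max(abs(sort((mu + 1) / 2) - (seq_len(n) - 0.5) / n))
  expect_lt(ks, 0.002)

  # first three sampled moments vs quadrature for each family
  for (pf in example_models()) {
    m <- legendre_moments(pf, 3)
    mu <- cos(sample_scattering_angles(pf, n, seed = 3))
    p2 <- (3 * mu^2 - 1) / 2
    p3 <- (5 * mu^3 - 3 * mu) / 2
    for (k in 1:3) {
      emp <- switch(k, mean(mu), mean(p2), mean(p3))
      se <- switch(k, sd(mu), sd(p2), sd(p3)) / sqrt(n)
      expect_lt(abs(emp - m[k]), 4 * se + 1e-4)
    }
  }
})
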
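test_that("simulations are bit-reproducible in the seed and bookkeeping is
           exact", {
  pf <- tthg_phase_function(0.9, 0.85, -0.5)
  probe <- probe_config(100, 0.22)
  a <- run_simulation(pf, 35, probe, n_photons = 1e5, seed = 9)
  b <- run_simulation(pf, 35, probe, n_photons = 1e5, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_identical(a$tags, b$tags)
  expect_identical(a$angle_hist, b$angle_hist)

  c <- run_simulation(pf, 35, probe, n_photons = 1e5, seed = 10)
  expect_false(identical(a$counts, c$counts))

  # launched photons are fully accounted for
  expect_equal(unname(a$counts["launched"]),
               unname(sum(a$counts[c("detected", "escaped", "terminated")])))
  expect_equal(a$R0_hat, unname(a$counts["detected"] / a$counts["launched"]))
})

test_that("without scattering no photon returns to the fiber", {
  sim <- run_simulation(hg_phase_function(0.9), mus = 1e-4,
                        probe = probe_config(), n_photons = 1e4, seed = 1,
                        termination = 1)
  expect_equal(sim$n_detected, 0)
  expect_equal(unname(sim$counts["terminated"]), 1e4)
})

test_that("the effective phase function is normalised with the backward
           onset at 180 - 2 theta_acc", {
  pf <- tthg_phase_function(0.9, 0.85, -0.5)
  probe <- probe_config(100, 0.22)
  sim <- run_simulation(pf, 35, probe, n_photons = 6e5, seed = 21)
  epf <- effective_phase_function(sim)
  expect_equal(sum(epf$frequency), 1, tolerance = 1e-12)
  expect_equal(nrow(epf), 180)

  onset <- 180 - 2 * probe$theta_acc * 180 / pi  # ~161 deg at NA 0.22
  below <- mean(epf$frequency[epf$angle_deg > onset - 22 &
                                epf$angle_deg < onset - 4])
  above <- mean(epf$frequency[epf$angle_deg > onset + 4])
  expect_gt(above / below, 3)

  # photons detected after a single scattering event must have turned by
  # at least 180 - 2 theta_acc
  single <- sim$tags$n_scatter_events == 1
  expect_gt(sum(single), 0)
  expect_equal(sum(sim$tags$n_backscatter_events[single] == 1),
               sum(single))

  expect_error(effective_phase_function(sim, bin_width = 7), "bin_width")

  empty <- run_simulation(hg_phase_function(0.9), mus = 1e-4,
                          probe = probe, n_photons = 100, seed = 2,
                          termination = 1)
  expect_error(effective_phase_function(empty), "no detected photons")
})

test_that("the forward effective phase function barely depends on the NA", {
  pf <- mhg_phase_function(0.9, 0.7)
  mus <- 10 / (1 - unname(legendre_moments(pf, 1)))
  hists <- lapply(c(0.10, 0.50), function(na) {
    sim <- run_simulation(pf, mus, probe_config(100, na),
                          n_photons = 8e5, seed = 31)
    list(epf = effective_phase_function(sim, bin_width = 10),
         n = sim$n_detected)
  })
  f1 <- hists[[1]]$epf$frequency
  f2 <- hists[[2]]$epf$frequency
  fwd <- hists[[1]]$epf$angle_deg < 90
  se <- sqrt(f1 * (1 - f1) / hists[[1]]$n + f2 * (1 - f2) / hists[[2]]$n)
  expect_lt(max(abs(f1[fwd] - f2[fwd]) - 4 * se[fwd]), 0.01)
})

test_that("termination validation applies the 99.9% / 75% rule", {
  fake <- structure(list(
    n_detected = 1000,
    tags = data.frame(max_distance = rep(0.1, 1000)),
    termination = 1
  ), class = "sfr_mc")
  chk <- validate_termination(fake)
  expect_true(chk$pass)
  expect_equal(chk$limit, 0.75)

  # 0.5% of detected photons beyond the limit fails and doubles
  fake$tags$max_distance[1:5] <- 0.9
  chk2 <- validate_termination(fake)
  expect_false(chk2$pass)
  expect_equal(chk2$recommended, 2)

  # the auto-tuned distance passes its own check
  sim <- run_simulation(tthg_phase_function(0.9, 0.85, -0.5), 35,
                        probe_config(), n_photons = 2e5, seed = 41)
  expect_true(validate_termination(sim)$pass)

  # an explicitly too-small distance raises the rerun error
  expect_error(
    run_simulation(tthg_phase_function(0.9, 0.85, -0.5), 35,
                   probe_config(), n_photons = 2e5, seed = 41,
                   termination = 0.02),
    "termination")
})

test_that("detected fraction tracks the diffusion model at moderate
           optical depth", {
  # musp.d = 20: diffuse transport dominates but runs fast enough for a
  # routine test; the deep-diffusion check lives in the acceptance suite
  pf <- hg_phase_function(0.5)
  probe <- probe_config(1000, 0.22)
  m <- 20
  sim <- run_simulation(pf, 2 * m / probe$d, probe, n_photons = 4e4,
                        seed = 51)
  expected <- predict_R0(m, psb = psb(pf), probe = probe)$R0
  expect_lt(abs(sim$R0_hat - expected), 4 * sim$se + 0.03 * expected)
})
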
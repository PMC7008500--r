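test_that("relative dispersion has its boundary values and invariances", {
  R0 <- c(1, 1.02, 0.98, 2, 3, 5) * 1e-3
  # identical in-band parameter values: zero dispersion
  par1 <- c(4, 4, 4, 8, 9, 10) * 1e-4
  expect_equal(relative_dispersion(R0, par1, 1e-3), 0)
  # in-band spread equal to the full spread: upper bound 1
  par2 <- c(1, 5, 9, 3, 6, 7)
  expect_equal(relative_dispersion(R0, par2, 1e-3), 1)
  # scale invariance: the measure works on log-range ratios
  par3 <- c(2, 3, 5, 1, 9, 4) * 1e-5
  expect_equal(relative_dispersion(R0, par3, 1e-3),
               relative_dispersion(R0, 1e4 * par3, 1e-3))
  expect_gte(relative_dispersion(R0, par3, 1e-3), 0)
  expect_lte(relative_dispersion(R0, par3, 1e-3), 1)
  # an empty band is an error naming the target
  expect_error(relative_dispersion(R0, par3, 1), "target reflectance")
})

test_that("partial-integral tables agree with adaptive quadrature", {
  models <- example_models()
  tabs <- sfrsub:::partial_integral_tables(models, theta_deg = c(1, 23, 45))
  for (j in seq_along(models)) {
    expect_equal(tabs$pb[1, j],
                 partial_integral(models[[j]], 1, "backward",
                                  degrees = TRUE), tolerance = 5e-4)
    expect_equal(tabs$pf[2, j],
                 partial_integral(models[[j]], 23, "forward",
                                  degrees = TRUE), tolerance = 1e-5)
    expect_equal(tabs$pf[3, j],
                 partial_integral(models[[j]], 45, "forward",
                                  degrees = TRUE), tolerance = 1e-5)
  }
})

test_that("the angle scan recovers a synthetic defining pair", {
  # construct reflectances as an exact monotone function of Rp(1, 23):
  # the dispersion at the defining pair is then limited to the band width
  # and the scan must score it (near-)optimal
  pt <- candidate_parameters()
  models <- pt$model
  R0 <- 1e-3 * (pt$psb / median(pt$psb))^0.75
  scan <- scan_integration_angles(models, R0, n_targets = 3,
                                  theta_deg = c(1, 5, 10, 23, 40, 60))
  d_def <- scan$dispersion["1", "23"]
  expect_lte(d_def, min(scan$dispersion) + 1e-9)
  expect_true(all(scan$dispersion >= 0 & scan$dispersion <= 1, na.rm = TRUE))
})

test_that("calibration recovers known constants from model-generated data", {
  # noiseless synthetic data from the forward model itself
  make_data <- function(na, a1, a2, a3, noise = 0, seed = 1) {
    cst <- sfr_constants(na, a1 = a1, a2 = a2, a3 = a3)
    probe <- suppressWarnings(probe_config(na = na))
    g <- expand.grid(musp_d = c(0.1, 0.3, 1, 3, 9, 30),
                     psb = 10^seq(-5.5, -2.5, length.out = 8))
    R0 <- predict_R0(g$musp_d, psb = g$psb, probe = probe,
                     constants = cst)$R0
    if (noise > 0) {
      set.seed(seed)
      R0 <- R0 * (1 + noise * rnorm(length(R0)))
    }
    data.frame(na = na, musp_d = g$musp_d, psb = g$psb, R0 = R0)
  }

  truth <- list(`0.1` = c(1.13, 4427, 0.785), `0.22` = c(1.119, 3065, 0.75))
  data <- rbind(make_data(0.10, 1.13, 4427, 0.785),
                make_data(0.22, 1.119, 3065, 0.750))
  cal <- calibrate_constants(data, A = boundary_parameter_A(1.35, 1.45))
  for (i in 1:2) {
    tr <- truth[[as.character(cal$stage1$na[i])]]
    expect_equal(cal$stage1$a1[i], tr[1], tolerance = 1e-4)
    expect_equal(cal$stage1$a2[i], tr[2], tolerance = 1e-4)
    expect_equal(cal$stage1$a3[i], tr[3], tolerance = 1e-4)
  }
  # stage 2 imposes one a1 across NAs and refits the semiballistic pair
  expect_equal(cal$shared_a1, round(mean(c(1.13, 1.119)), 2))
  expect_true(all(cal$stage2$a1 == cal$shared_a1))

  # 2% multiplicative noise: recovery within 3 CI half-widths
  noisy <- rbind(make_data(0.10, 1.13, 4427, 0.785, noise = 0.02, seed = 5),
                 make_data(0.22, 1.119, 3065, 0.750, noise = 0.02, seed = 6))
  caln <- calibrate_constants(noisy, A = boundary_parameter_A(1.35, 1.45))
  for (i in 1:2) {
    tr <- truth[[as.character(caln$stage1$na[i])]]
    expect_lt(abs(caln$stage1$a1[i] - tr[1]), 3 * caln$stage1$a1_ci[i])
    expect_lt(abs(caln$stage1$a2[i] - tr[2]), 3 * caln$stage1$a2_ci[i])
    expect_lt(abs(caln$stage1$a3[i] - tr[3]), 3 * caln$stage1$a3_ci[i])
  }
})

test_that("error statistics summarise relative errors in percent", {
  ref <- c(1e-4, 2e-4, 1e-3)
  expect_equal(error_statistics(ref, ref),
               list(median = 0, sd = 0, max = 0))
  est <- error_statistics(ref * c(1.02, 0.97, 1.10), ref)
  expect_equal(est$median, 3)
  expect_equal(est$max, 10, tolerance = 1e-9)
  byg <- error_statistics(ref * c(1.02, 0.97, 1.10), ref,
                          group = c("a", "a", "b"))
  expect_equal(byg$by_group["b", "median"], 10, tolerance = 1e-9)
})
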
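# shared fixtures, built once per test run and cached in this environment
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

candidate_grid <- function() {
  fixture("grid", tissue_phase_function_grid)
}

candidate_parameters <- function() {
  fixture("grid_params", function() {
    subdiffuse_parameter_table(candidate_grid())
  })
}

# one representative of each family, mid-range anisotropy
example_models <- function() {
  list(
    hg = hg_phase_function(0.8),
    mhg = mhg_phase_function(0.9, 0.8),
    tthg = tthg_phase_function(0.9, 0.9, -0.3),
    rmc = rmc_phase_function(1.5, 0.4)
  )
}

# random in-domain parameter draws per family (fixed seed)
random_models <- function(n_per_family = 10, seed = 402) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_per_family)) {
    out <- c(out, list(
      hg_phase_function(runif(1, -0.9, 0.95)),
      mhg_phase_function(runif(1, 0.05, 0.95), runif(1)),
      tthg_phase_function(runif(1), runif(1, 0.05, 0.95),
                          runif(1, -0.95, -0.05)),
      rmc_phase_function(runif(1, 0.05, 2.5), runif(1, 0.05, 0.9))
    ))
  }
  out
}

sphere_integral <- function(pf) {
  2 * pi * integrate(function(mu) sfrsub:::pf_density_mu(pf, mu), -1, 1,
                     rel.tol = 1e-10)$value
}

# stratified Monte Carlo ensemble at musp.d = 0.1, NA 0.22 (shared across
# the experiment and acceptance tests; built on first use)
mc_ensemble_01 <- function(n_models = 20, n_photons = 4e5) {
  key <- sprintf("mc01_%d_%g", n_models, n_photons)
  fixture(key, function() {
    pt <- candidate_parameters()
    pt <- pt[order(pt$psb), ]
    pick <- pt[round(seq(2, nrow(pt) - 6, length.out = n_models)), ]
    probe <- probe_config(diameter_um = 100, na = 0.22)
    sims <- lapply(seq_len(n_models), function(i) {
      run_simulation(pick$model[[i]], mus = 10 / (1 - pick$g1[i]),
                     probe = probe, n_photons = n_photons, seed = 7000 + i)
    })
    list(params = pick, sims = sims, probe = probe,
         R0 = vapply(sims, `[[`, numeric(1), "R0_hat"))
  })
}
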
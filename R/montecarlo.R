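#' Single-fiber reflectance Monte Carlo
#'
#' Absorption-free photon-transport simulation of a semi-infinite turbid
#' medium probed by one fiber acting as source and detector. Photons are
#' launched uniformly over the fiber face with directions inside the
#' acceptance cone, propagate with exponential step lengths (mean
#' \eqn{1/\mu_s}), scatter by angles drawn from the supplied phase function,
#' and are detected when they return to the fiber face within the
#' acceptance angle \eqn{\theta_{acc} = \arcsin(NA/n_{sample})} and are
#' transmitted through the tissue-fiber interface. Photons reaching the
#' surface outside the fiber footprint face the tissue-external interface
#' (Fresnel reflection, including total internal reflection); transmitted
#' ones are lost. Because no absorption means no roulette, photons are
#' terminated once their distance from the fiber-face centre exceeds the
#' termination distance; validity of that truncation is checked with the
#' rule that at least 99.9% of detected photons stayed within 75% of it.
#'
#' Detected photons carry per-photon tags: number of scattering events,
#' number of backscatter events (polar angle > 90 degrees), total pathlength
#' and maximum distance from the fiber-face centre. A detected photon with
#' exactly one backscatter event is semiballistic.
#'
#' @param model A [phase_function].
#' @param mus Scattering coefficient \eqn{\mu_s} (1/cm).
#' @param probe A [probe_config].
#' @param n_photons Number of photons to launch.
#' @param seed Integer seed (the simulation is bit-reproducible in it).
#' @param termination Termination distance in cm. `NULL` (default) picks
#'   \eqn{\max(2/\mu_s', 20 d)} and doubles it until the termination check
#'   passes.
#' @param launch `"uniform_polar"` draws the launch polar angle uniformly on
#'   \eqn{[0, \theta_{acc}]}; `"uniform_solid_angle"` draws it uniformly
#'   over the solid angle of the cone.
#' @param on_termination_failure With a user-supplied `termination`, whether
#'   a failed termination check raises an error or a warning.
#' @return Object of class `sfr_mc`: `R0_hat` (detected fraction), `se`
#'   (binomial standard error), `n_detected`, `counts` (launched / detected
#'   / escaped / terminated), `tags` (per-detected-photon data frame),
#'   `angle_hist` (counts of scattering angles of detected photons in
#'   1-degree bins), `semiballistic_fraction`, `termination`, and the
#'   configuration.
#' @export
run_simulation <- function(model, mus, probe = probe_config(),
                           n_photons = 1e6, seed = 1, termination = NULL,
                           launch = c("uniform_polar",
                                      "uniform_solid_angle"),
                           on_termination_failure = c("error", "warn")) {
  stopifnot(inherits(model, "phase_function"),
            inherits(probe, "probe_config"),
            mus > 0, n_photons >= 1)
  launch <- match.arg(launch)
  on_termination_failure <- match.arg(on_termination_failure)

  g1 <- unname(legendre_moments(model, 1))
  musp <- mus * (1 - g1)
  auto <- is.null(termination)
  if (auto) termination <- max(2 / musp, 20 * probe$d)
  if (termination <= probe$d) {
    stop("`termination` must exceed the fiber diameter", call. = FALSE)
  }
  tab <- pf_quantile_table(model)

  attempts <- 0
  repeat {
    raw <- .mc_run(n_photons, mus, probe$d / 2, probe$theta_acc,
                   probe$n_sample, probe$n_fiber, probe$n_external,
                   tab, termination, match(launch, c("uniform_polar",
                                                     "uniform_solid_angle")) - 1L,
                   as.double(seed))
    res <- build_sfr_mc(raw, model, mus, musp, probe, n_photons, seed,
                        termination, launch)
    chk <- validate_termination(res)
    if (chk$pass || res$n_detected == 0) break
    if (!auto) {
      msg <- sprintf(paste0("termination check failed: 99.9%% quantile of ",
                            "detected max distance (%.4g cm) exceeds 75%% ",
                            "of the termination distance (%.4g cm); rerun ",
                            "with termination >= %.4g cm"),
                     chk$q999, chk$limit, chk$recommended)
      if (on_termination_failure == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
      break
    }
    attempts <- attempts + 1
    if (attempts > 8) {
      stop("termination auto-tuning did not converge", call. = FALSE)
    }
    termination <- 2 * termination
  }
  res
}

build_sfr_mc <- function(raw, model, mus, musp, probe, n_photons, seed,
                         termination, launch) {
  p <- raw$n_detected / raw$n_launched
  tags <- data.frame(n_scatter_events = raw$det_nscatter,
                     n_backscatter_events = raw$det_nback,
                     total_pathlength = raw$det_path,
                     max_distance = raw$det_maxdist)
  structure(list(
    R0_hat = p,
    se = sqrt(p * (1 - p) / raw$n_launched),
    n_detected = raw$n_detected,
    counts = c(launched = raw$n_launched, detected = raw$n_detected,
               escaped = raw$n_escaped, terminated = raw$n_terminated),
    tags = tags,
    angle_hist = raw$angle_hist,
    semiballistic_fraction = if (raw$n_detected > 0) {
      mean(tags$n_backscatter_events == 1)
    } else NA_real_,
    model = model, mus = mus, musp = musp, probe = probe,
    n_photons = n_photons, seed = seed, termination = termination,
    launch = launch
  ), class = "sfr_mc")
}

#' @export
print.sfr_mc <- function(x, ...) {
  cat(sprintf(paste0("<sfr_mc> %s, mus = %g/cm (musp.d = %.3g), ",
                     "NA %g, d = %g um\n  %s photons: R0 = %.4g ",
                     "(se %.2g), %d detected, semiballistic fraction ",
                     "%.3f\n"),
              format(x$model), x$mus, x$musp * x$probe$d, x$probe$na,
              x$probe$diameter_um, format(x$n_photons, big.mark = ","),
              x$R0_hat, x$se, x$n_detected, x$semiballistic_fraction))
  invisible(x)
}

#' Termination-distance check
#'
#' Passes when the 99.9% quantile of the detected photons' maximum distance
#' from the fiber-face centre is below 75% of the termination distance, so
#' that truncating photon histories at the termination distance cannot have
#' removed more than a sliver of the detected signal.
#'
#' @param result An `sfr_mc` object.
#' @param termination Termination distance (cm); defaults to the one used in
#'   the simulation.
#' @return List with `pass`, `q999`, `limit` (0.75 x termination) and
#'   `recommended` (doubled distance, for a failed check).
#' @export
validate_termination <- function(result, termination = result$termination) {
  stopifnot(inherits(result, "sfr_mc"))
  if (result$n_detected == 0) {
    return(list(pass = NA, q999 = NA_real_, limit = 0.75 * termination,
                recommended = termination))
  }
  q999 <- unname(quantile(result$tags$max_distance, 0.999, type = 1))
  pass <- q999 < 0.75 * termination
  list(pass = pass, q999 = q999, limit = 0.75 * termination,
       recommended = if (pass) termination else 2 * termination)
}

#' Effective phase function of detected photons
#'
#' Normalised frequency distribution of all scattering angles experienced by
#' detected photons. Its backward lobe switches on near
#' \eqn{180^\circ - 2\theta_{acc}}: a photon launched at the edge of the
#' acceptance cone needs a scattering angle of at least that to turn around
#' into the detection cone with a single event.
#'
#' @param result An `sfr_mc` object with detected photons.
#' @param bin_width Bin width in degrees (must divide 180).
#' @return Data frame with `angle_deg` (bin midpoints) and `frequency`
#'   (sums to 1).
#' @export
effective_phase_function <- function(result, bin_width = 1) {
  stopifnot(inherits(result, "sfr_mc"))
  if (result$n_detected == 0) {
    stop("no detected photons: effective phase function is undefined",
         call. = FALSE)
  }
  if (180 %% bin_width != 0) {
    stop("`bin_width` must divide 180", call. = FALSE)
  }
  counts <- result$angle_hist
  if (bin_width > 1) {
    counts <- colSums(matrix(counts, nrow = bin_width))
  }
  data.frame(
    angle_deg = seq(bin_width / 2, 180 - bin_width / 2, by = bin_width),
    frequency = counts / sum(counts)
  )
}
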
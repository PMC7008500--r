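#' Moment-based subdiffuse parameters
#'
#' Scalar phase-function summaries built from Legendre moments that have been
#' proposed to capture the phase-function influence on subdiffuse
#' reflectance:
#' \deqn{\gamma = \frac{1 - g_2}{1 - g_1}, \qquad
#'       \delta = \frac{1 - g_3}{1 - g_1}, \qquad
#'       \sigma = \sum_{i=2}^{\infty} (-0.5)^{i-2}\,\frac{1 - g_i}{1 - g_1}.}
#' The \eqn{\sigma} series is summed until the next term falls below `tol`;
#' the \eqn{(-0.5)^{i-2}} factor makes the tail geometric, so roughly 40
#' moments suffice for `tol = 1e-10`.
#'
#' @param g Numeric vector of Legendre moments `g1, g2, ...` (from
#'   [legendre_moments()]); supply enough moments for the series to converge.
#' @param tol Truncation tolerance for the \eqn{\sigma} series.
#' @return Named list with `gamma`, `delta`, `sigma`.
#' @export
moment_summaries <- function(g, tol = 1e-10) {
  stopifnot(is.numeric(g), length(g) >= 3)
  if (g[1] >= 1) {
    stop("degenerate forward scattering: g1 must be < 1", call. = FALSE)
  }
  g <- unname(g)
  gamma <- (1 - g[2]) / (1 - g[1])
  delta <- (1 - g[3]) / (1 - g[1])
  sigma <- 0
  converged <- FALSE
  for (i in 2:length(g)) {
    term <- (-0.5)^(i - 2) * (1 - g[i]) / (1 - g[1])
    sigma <- sigma + term
    if (abs(term) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(paste0("sigma series not converged within the supplied ",
                        "moment budget (%d moments); partial sum = %.10g"),
                 length(g), sigma), call. = FALSE)
  }
  list(gamma = gamma, delta = delta, sigma = sigma)
}

#' Backward/forward partial-integral ratio Rp
#'
#' The semiballistic phase-function ratio
#' \deqn{R_p(\theta_b, \theta_f) = \frac{p_b(\theta_b)}{1 - p_f(\theta_f)}}
#' with \eqn{p_b, p_f} the backward/forward partial integrals of the phase
#' function (see [partial_integral()]). [rp_na()] evaluates it at the probe
#' acceptance angle in both directions; [psb()] at the fixed angles 1 degree
#' backward and 23 degrees forward that minimise the relative dispersion of
#' the parameter across tissue phase functions (optimised for NA 0.22 probes
#' but effective across NAs).
#'
#' @param pf A [phase_function].
#' @param theta_b,theta_f Backward / forward integration angles in degrees,
#'   both in (0, 90].
#' @return Dimensionless positive ratio.
#' @export
rp_parameter <- function(pf, theta_b, theta_f) {
  pb <- partial_integral(pf, theta_b, "backward", degrees = TRUE)
  pfw <- partial_integral(pf, theta_f, "forward", degrees = TRUE)
  if (1 - pfw <= 0) {
    stop("forward integral equals 1: Rp is degenerate", call. = FALSE)
  }
  pb / (1 - pfw)
}

#' @rdname rp_parameter
#' @param probe A [probe_config] supplying the acceptance angle.
#' @export
rp_na <- function(pf, probe) {
  stopifnot(inherits(probe, "probe_config"))
  acc <- rad2deg(probe$theta_acc)
  rp_parameter(pf, acc, acc)
}

#' @rdname rp_parameter
#' @export
psb <- function(pf) {
  rp_parameter(pf, 1, 23)
}

#' All subdiffuse parameters of a phase function
#'
#' Convenience wrapper returning \eqn{\gamma}, \eqn{\delta}, \eqn{\sigma},
#' \eqn{R_{pNA}} (probe-dependent) and \eqn{p_{sb}} (probe-independent) for
#' one phase function.
#'
#' @param pf A [phase_function].
#' @param probe A [probe_config].
#' @param n_moments Number of Legendre moments for the series parameters.
#' @return Named list of class `subdiffuse_parameters`.
#' @export
subdiffuse_parameters <- function(pf, probe = probe_config(),
                                  n_moments = 48) {
  g <- legendre_moments(pf, n_moments)
  ms <- moment_summaries(g)
  structure(c(ms, list(rpna = rp_na(pf, probe), psb = psb(pf),
                       g1 = unname(g[1]), g2 = unname(g[2]),
                       g3 = unname(g[3]))),
            class = "subdiffuse_parameters")
}

#' @export
print.subdiffuse_parameters <- function(x, ...) {
  cat(sprintf(paste0("<subdiffuse_parameters> g1 = %.4f  gamma = %.4f  ",
                     "delta = %.4f  sigma = %.4f\n  RpNA = %.4g  ",
                     "psb = %.4g\n"),
              x$g1, x$gamma, x$delta, x$sigma, x$rpna, x$psb))
  invisible(x)
}

#' Batch subdiffuse parameters for a grid
#'
#' Computes the subdiffuse parameter set for every member of a
#' phase-function grid, optionally for several probe NAs (the `rpna` column
#' is repeated per NA).
#'
#' @param grid Data frame from [tissue_phase_function_grid()] (must carry the
#'   `model` list column).
#' @param probes A list of [probe_config] objects (one `rpna_<NA>` column
#'   each).
#' @param n_moments Moment budget for the series parameters.
#' @return The grid with columns `gamma`, `delta`, `sigma`, `psb` and one
#'   `rpna_*` column per probe appended.
#' @export
subdiffuse_parameter_table <- function(grid, probes = list(probe_config()),
                                       n_moments = 48) {
  stopifnot(!is.null(grid$model))
  n <- nrow(grid)
  gamma <- delta <- sigma <- psb_v <- numeric(n)
  rpna <- matrix(0, n, length(probes))
  for (i in seq_len(n)) {
    pf <- grid$model[[i]]
    ms <- moment_summaries(legendre_moments(pf, n_moments))
    gamma[i] <- ms$gamma; delta[i] <- ms$delta; sigma[i] <- ms$sigma
    psb_v[i] <- psb(pf)
    for (j in seq_along(probes)) rpna[i, j] <- rp_na(pf, probes[[j]])
  }
  out <- grid
  out$gamma <- gamma; out$delta <- delta; out$sigma <- sigma
  out$psb <- psb_v
  for (j in seq_along(probes)) {
    out[[paste0("rpna_", probes[[j]]$na)]] <- rpna[, j]
  }
  out
}
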
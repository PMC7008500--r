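#' Calibrated model constants
#'
#' The SFR scattering model carries three calibration constants obtained by
#' fitting the diffuse + semiballistic decomposition to Monte Carlo
#' ensembles: a shared collection-efficiency scale `a1 = 1.11` and per-NA
#' semiballistic constants
#'
#' | NA   | a2   | a3    |
#' |------|------|-------|
#' | 0.10 | 4370 | 0.780 |
#' | 0.22 | 3046 | 0.748 |
#' | 0.50 | 1475 | 0.688 |
#'
#' Constants are calibrated per NA and are deliberately not interpolated:
#' requesting an unsupported NA without supplying all three constants is an
#' error.
#'
#' @param na Probe numerical aperture.
#' @param a1,a2,a3 Optional overrides (all three of `a2`,`a3` plus `a1`
#'   required for an NA outside the calibrated set).
#' @return Object of class `sfr_constants` with fields `na`, `a1`, `a2`,
#'   `a3`.
#' @export
sfr_constants <- function(na = 0.22, a1 = NULL, a2 = NULL, a3 = NULL) {
  table <- list(`0.1` = c(a2 = 4370, a3 = 0.780),
                `0.22` = c(a2 = 3046, a3 = 0.748),
                `0.5` = c(a2 = 1475, a3 = 0.688))
  key <- as.character(na)
  if (is.null(a2) || is.null(a3)) {
    if (is.null(table[[key]])) {
      stop(sprintf(paste0("no calibrated constants for NA = %s (calibrated: ",
                          "0.10, 0.22, 0.50); supply a1, a2 and a3 ",
                          "explicitly"), na), call. = FALSE)
    }
    if (is.null(a2)) a2 <- unname(table[[key]]["a2"])
    if (is.null(a3)) a3 <- unname(table[[key]]["a3"])
  }
  if (is.null(a1)) a1 <- 1.11
  stopifnot(a1 > 0, a2 > 0, a3 > 0)
  structure(list(na = na, a1 = a1, a2 = a2, a3 = a3),
            class = "sfr_constants")
}

#' @export
print.sfr_constants <- function(x, ...) {
  cat(sprintf("<sfr_constants> NA = %g: a1 = %g, a2 = %g, a3 = %g\n",
              x$na, x$a1, x$a2, x$a3))
  invisible(x)
}

#' Semiballistic-to-diffuse reflectance ratio
#'
#' The ratio between the semiballistic and the diffuse contribution to the
#' SFR signal:
#' \deqn{X = a_2 \left[\frac{p_{sb}}{(\mu_s' d)^2}\right]^{a_3}.}
#' The \eqn{(\mu_s' d)^2} in the denominator mirrors the small-argument
#' scaling of the diffuse reflectance; `a3` absorbs the different scaling of
#' the semiballistic component.
#'
#' @param psb Semiballistic phase-function parameter (see [psb()]).
#' @param musp_d Dimensionless \eqn{\mu_s' d}.
#' @param constants An [sfr_constants] object.
#' @return The dimensionless ratio X (vectorised over `psb` / `musp_d`).
#' @export
semiballistic_ratio <- function(psb, musp_d, constants = sfr_constants()) {
  stopifnot(inherits(constants, "sfr_constants"),
            all(psb > 0), all(musp_d > 0))
  constants$a2 * (psb / musp_d^2)^constants$a3
}

#' Predict SFR reflectance in the absence of absorption
#'
#' Forward model for the reflectance collected by a single overlapping
#' source/detector fiber:
#' \deqn{R_0 = (1 + X)\, R_{SFR,dif}, \qquad
#'       R_{SFR,dif} = a_1 \sin^2\theta_{acc}\, R_{dif}(\mu_s' d),}
#' with \eqn{X} from [semiballistic_ratio()]. The phase function enters only
#' through `psb`, which may be given directly (e.g. during spectral fitting)
#' or derived from a [phase_function]. The diffusion-based component loses
#' accuracy below \eqn{\mu_s' d = 0.1}; such points are flagged (and a
#' warning is emitted) but still evaluated.
#'
#' @param musp_d Dimensionless \eqn{\mu_s' d} (vectorised).
#' @param psb Semiballistic parameter value(s); scalar or same length as
#'   `musp_d`. Ignored when `model` is given.
#' @param model Optional [phase_function] from which `psb` is computed.
#' @param probe A [probe_config]; its NA must match `constants$na`.
#' @param constants An [sfr_constants] object (defaults to the calibrated
#'   table for the probe NA).
#' @return Data frame with columns `musp_d`, `psb`, `X`, `R_dif` (diffuse
#'   component \eqn{R_{SFR,dif}}), `R_sb` (semiballistic component), `R0`
#'   and `below_validity_limit`.
#' @export
predict_R0 <- function(musp_d, psb = NULL, model = NULL,
                       probe = probe_config(),
                       constants = sfr_constants(probe$na)) {
  stopifnot(inherits(probe, "probe_config"),
            inherits(constants, "sfr_constants"), all(musp_d > 0))
  if (!is.null(model)) {
    stopifnot(inherits(model, "phase_function"))
    psb <- psb(model)
  }
  if (is.null(psb)) stop("supply either `psb` or `model`", call. = FALSE)
  if (!isTRUE(all.equal(probe$na, constants$na))) {
    stop("probe NA and constants NA disagree", call. = FALSE)
  }
  n <- max(length(musp_d), length(psb))
  musp_d <- rep_len(musp_d, n)
  psb <- rep_len(psb, n)

  X <- semiballistic_ratio(psb, musp_d, constants)
  ## de-duplicate the quadrature over repeated musp_d values
  um <- unique(musp_d)
  rdif <- diffuse_reflectance(um, A = probe$A)[match(musp_d, um)]
  R_dif <- constants$a1 * sin(probe$theta_acc)^2 * rdif
  R_sb <- X * R_dif
  flag <- musp_d < 0.1
  if (any(flag)) {
    warning(sprintf(paste0("%d of %d musp_d values are below the model ",
                           "validity limit of 0.1"), sum(flag), n),
            call. = FALSE)
  }
  data.frame(musp_d = musp_d, psb = psb, X = X, R_dif = R_dif, R_sb = R_sb,
             R0 = R_dif + R_sb, below_validity_limit = flag)
}

#' Reference gamma-based SFR model
#'
#' The previously available SFR reflectance model, parameterised by
#' \eqn{\gamma = (1 - g_2)/(1 - g_1)} (derived from Monte Carlo simulations
#' of MHG phase functions):
#' \deqn{R_0 = \left(\frac{NA}{n_{sample}}\right)^2
#'  \left(1 + 0.632\,\gamma^2 e^{-2.308\gamma^2\,\mu_s' d}\right)
#'  \frac{(\mu_s' d)^{0.574\gamma}}{2.308\gamma^2 + (\mu_s' d)^{0.574\gamma}}.}
#' Provided as the comparison baseline for the diffuse + semiballistic
#' model.
#'
#' @param gamma Phase-function parameter \eqn{\gamma > 0}.
#' @param musp_d Dimensionless \eqn{\mu_s' d} (vectorised).
#' @param probe A [probe_config].
#' @return Reflectance fraction(s).
#' @export
kanick_R0 <- function(gamma, musp_d, probe = probe_config()) {
  stopifnot(all(gamma > 0), all(musp_d > 0),
            inherits(probe, "probe_config"))
  eta <- (probe$na / probe$n_sample)^2
  md_g <- musp_d^(0.574 * gamma)
  eta * (1 + 0.632 * gamma^2 * exp(-2.308 * gamma^2 * musp_d)) *
    md_g / (2.308 * gamma^2 + md_g)
}
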
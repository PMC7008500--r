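#' Reduced-scattering power law
#'
#' Wavelength model \eqn{\mu_s'(\lambda) = a (\lambda/\lambda_0)^{-b}} with
#' amplitude `a` (1/cm at the reference wavelength), slope `b`
#' (dimensionless) and reference wavelength `lambda0` (nm).
#'
#' @param a Scattering amplitude (1/cm), > 0.
#' @param b Scattering slope.
#' @param lambda0 Reference wavelength (nm).
#' @return Object of class `scattering_power_law`.
#' @export
scattering_power_law <- function(a, b, lambda0 = 600) {
  stopifnot(a > 0, lambda0 > 0)
  structure(list(a = a, b = b, lambda0 = lambda0),
            class = "scattering_power_law")
}

#' @rdname scattering_power_law
#' @param pl A `scattering_power_law`.
#' @param lambda Wavelengths (nm).
#' @export
musp_power_law <- function(pl, lambda) {
  stopifnot(inherits(pl, "scattering_power_law"))
  pl$a * (lambda / pl$lambda0)^(-pl$b)
}

#' @export
print.scattering_power_law <- function(x, ...) {
  cat(sprintf("<scattering_power_law> musp = %g (lambda/%g)^-%g 1/cm\n",
              x$a, x$lambda0, x$b))
  invisible(x)
}

#' Synthesize multidiameter SFR spectra
#'
#' Builds noiseless or noisy reflectance spectra for two fiber diameters
#' from the forward model, given a reduced-scattering power law and a
#' \eqn{p_{sb}(\lambda)} curve. This is the package's synthetic-data
#' generator for the two-diameter inversion: 400-900 nm in 5-nm steps for
#' 300- and 600-um fibers by default. Optional measurement noise is
#' multiplicative Gaussian with the stated fractional standard deviation.
#'
#' @param power_law A [scattering_power_law].
#' @param psb_values Either a function of wavelength (nm) or a numeric
#'   vector matched to `wavelengths`; values must be positive.
#' @param wavelengths Wavelength grid (nm).
#' @param diameters_um Two fiber diameters (micrometers).
#' @param na,n_sample,n_fiber,n_external Probe parameters shared by both
#'   fibers.
#' @param constants An [sfr_constants] for the probe NA.
#' @param noise_fraction Fractional standard deviation of multiplicative
#'   Gaussian noise (0 = noiseless).
#' @param seed Optional seed for the noise draw.
#' @return Data frame of class `sfr_spectra` with columns `wavelength_nm`,
#'   `fiber_diameter_um`, `reflectance`, `musp_d` and
#'   `below_validity_limit`; the generating truth is attached as attributes
#'   `power_law` and `psb_values`.
#' @export
synthesize_spectra <- function(power_law, psb_values,
                               wavelengths = seq(400, 900, by = 5),
                               diameters_um = c(300, 600), na = 0.22,
                               n_sample = 1.35, n_fiber = 1.45,
                               n_external = 1.0,
                               constants = sfr_constants(na),
                               noise_fraction = 0, seed = NULL) {
  stopifnot(inherits(power_law, "scattering_power_law"),
            length(diameters_um) == 2, noise_fraction >= 0)
  psb_l <- if (is.function(psb_values)) {
    psb_values(wavelengths)
  } else {
    rep_len(psb_values, length(wavelengths))
  }
  stopifnot(all(psb_l > 0))
  musp <- musp_power_law(power_law, wavelengths)

  rows <- lapply(diameters_um, function(dum) {
    probe <- probe_config(diameter_um = dum, na = na, n_sample = n_sample,
                          n_fiber = n_fiber, n_external = n_external)
    md <- musp * probe$d
    pred <- withCallingHandlers(
      predict_R0(md, psb = psb_l, probe = probe, constants = constants),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(wavelength_nm = wavelengths, fiber_diameter_um = dum,
               reflectance = pred$R0, musp_d = md,
               below_validity_limit = pred$below_validity_limit)
  })
  out <- do.call(rbind, rows)
  if (any(out$below_validity_limit)) {
    bad <- sort(unique(out$wavelength_nm[out$below_validity_limit]))
    warning(sprintf(paste0("musp.d < 0.1 at %d wavelength/diameter ",
                           "combinations (wavelengths %s...)"),
                    sum(out$below_validity_limit),
                    paste(utils::head(bad, 5), collapse = ", ")),
            call. = FALSE)
  }
  if (noise_fraction > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    out$reflectance <- out$reflectance *
      (1 + noise_fraction * stats::rnorm(nrow(out)))
    out$reflectance <- pmax(out$reflectance, 1e-12)
  }
  attr(out, "power_law") <- power_law
  attr(out, "psb_values") <- psb_l
  class(out) <- c("sfr_spectra", "data.frame")
  out
}

#' Read / write SFR spectra as CSV
#'
#' Plain CSV with columns `wavelength_nm`, `fiber_diameter_um`,
#' `reflectance` at full precision.
#'
#' @param spectra Data frame with the three columns above.
#' @param path File path.
#' @export
write_spectra <- function(spectra, path) {
  cols <- c("wavelength_nm", "fiber_diameter_um", "reflectance")
  stopifnot(all(cols %in% names(spectra)))
  write_full_precision_csv(as.data.frame(spectra)[cols], path)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("wavelength_nm", "fiber_diameter_um", "reflectance")
                %in% names(df)))
  df
}

#' Fit the two-diameter (MDSFR) spectral model
#'
#' Joint inversion of reflectance spectra measured with two fiber diameters
#' for the reduced-scattering power law \eqn{\mu_s'(\lambda) =
#' a(\lambda/\lambda_0)^{-b}} and a free \eqn{p_{sb}} per wavelength. With
#' one fiber the system has \eqn{\lambda_n} data points and
#' \eqn{2 + \lambda_n} parameters and is refused as underdetermined; with
#' two fibers there are \eqn{2\lambda_n} points for the same parameters.
#'
#' The least-squares problem (on \eqn{\log} reflectance, since measurement
#' noise is multiplicative) is solved by variable projection: for any
#' \eqn{(a, b)} the optimal \eqn{p_{sb}(\lambda)} splits into independent
#' one-dimensional solves per wavelength, and the outer two-parameter
#' problem is minimised with Nelder-Mead.
#'
#' @param spectra Data frame with columns `wavelength_nm`,
#'   `fiber_diameter_um`, `reflectance` covering exactly two diameters on a
#'   common wavelength grid (>= 3 wavelengths).
#' @param na,n_sample Probe NA and sample index shared by both fibers.
#' @param lambda0 Reference wavelength (nm).
#' @param constants An [sfr_constants] for the NA.
#' @param init Optional named start values `c(a = , b = )`.
#' @param psb_bounds Positivity bounds for the per-wavelength
#'   \eqn{p_{sb}}.
#' @return Object of class `mdsfr_fit`: `power_law` (fitted), `psb` (data
#'   frame per wavelength), `residuals` (relative, per diameter),
#'   `convergence` diagnostics, and the objective value.
#' @export
fit_mdsfr <- function(spectra, na = 0.22, n_sample = 1.35, lambda0 = 600,
                      constants = sfr_constants(na), init = NULL,
                      psb_bounds = c(1e-8, 1)) {
  stopifnot(all(c("wavelength_nm", "fiber_diameter_um", "reflectance")
                %in% names(spectra)), all(spectra$reflectance > 0))
  diam <- sort(unique(spectra$fiber_diameter_um))
  if (length(diam) < 2) {
    stop(paste0("a single fiber diameter gives lambda_n data points for ",
                "2 + lambda_n parameters: the system is underdetermined; ",
                "supply spectra for two diameters"), call. = FALSE)
  }
  if (length(diam) > 2) {
    stop("supply spectra for exactly two fiber diameters", call. = FALSE)
  }
  lam <- sort(unique(spectra$wavelength_nm))
  if (length(lam) < 3) stop("need at least 3 wavelengths", call. = FALSE)
  R <- vapply(diam, function(dd) {
    s <- spectra[spectra$fiber_diameter_um == dd, ]
    s$reflectance[match(lam, s$wavelength_nm)]
  }, numeric(length(lam)))
  if (anyNA(R)) {
    stop("both diameters must cover the same wavelength grid",
         call. = FALSE)
  }
  d_cm <- diam * 1e-4
  probe <- probe_config(diameter_um = diam[1], na = na,
                        n_sample = n_sample)
  eta <- constants$a1 * sin(probe$theta_acc)^2
  logR <- log(R)
  lpb <- log10(psb_bounds)

  ## per-wavelength profile: given the diffuse components C[l, k], the
  ## optimal psb solves two stacked log-residuals in one unknown
  profile <- function(Cmat) {
    n <- length(lam)
    psb_hat <- numeric(n)
    sse <- 0
    for (l in seq_len(n)) {
      m2 <- (Cmat$md[l, ])^2
      Cd <- Cmat$C[l, ]
      obj <- function(lp) {
        X <- constants$a2 * (10^lp / m2)^constants$a3
        sum((log(Cd * (1 + X)) - logR[l, ])^2)
      }
      op <- optimize(obj, lower = lpb[1], upper = lpb[2], tol = 1e-10)
      psb_hat[l] <- 10^op$minimum
      sse <- sse + op$objective
    }
    list(psb = psb_hat, sse = sse)
  }
  components <- function(a, b) {
    musp <- a * (lam / lambda0)^(-b)
    md <- outer(musp, d_cm)
    um <- unique(as.vector(md))
    rd <- diffuse_reflectance(um, A = probe$A)
    list(md = md, C = eta * matrix(rd[match(as.vector(md), um)],
                                   nrow = length(lam)))
  }
  outer_obj <- function(par) {
    a <- exp(par[1]); b <- par[2]
    if (!is.finite(a) || a <= 0) return(1e10)
    profile(components(a, b))$sse
  }
  if (is.null(init)) init <- c(a = 15, b = 1)
  opt <- optim(c(log(init[["a"]]), init[["b"]]), outer_obj,
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  a_hat <- exp(opt$par[1]); b_hat <- opt$par[2]
  cm <- components(a_hat, b_hat)
  prof <- profile(cm)
  X <- constants$a2 * (prof$psb / cm$md^2)^constants$a3
  fitted <- cm$C * (1 + X)
  resid <- (fitted - R) / R
  colnames(resid) <- paste0("d", diam)

  structure(list(
    power_law = scattering_power_law(a_hat, b_hat, lambda0),
    psb = data.frame(wavelength_nm = lam, psb = prof$psb),
    residuals = data.frame(wavelength_nm = lam, resid),
    fitted = data.frame(wavelength_nm = lam, fitted),
    sse = prof$sse, convergence = opt$convergence,
    n_data = 2 * length(lam), n_par = 2 + length(lam),
    diameters_um = diam
  ), class = "mdsfr_fit")
}

#' @export
print.mdsfr_fit <- function(x, ...) {
  cat(sprintf(paste0("<mdsfr_fit> a = %.4g 1/cm, b = %.4g (lambda0 = %g ",
                     "nm); %d wavelengths x 2 diameters (%g/%g um)\n  ",
                     "max |relative residual| = %.3g; psb range %.3g - ",
                     "%.3g\n"),
              x$power_law$a, x$power_law$b, x$power_law$lambda0,
              nrow(x$psb), x$diameters_um[1], x$diameters_um[2],
              max(abs(as.matrix(x$residuals[-1]))),
              min(x$psb$psb), max(x$psb$psb)))
  invisible(x)
}
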
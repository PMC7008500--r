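#' Fiber probe configuration
#'
#' Describes the single fiber that both delivers and collects light, in
#' contact with the sample. The acceptance angle inside the sample is
#' \eqn{\theta_{acc} = \arcsin(NA / n_{sample})} and the diffusion-theory
#' internal-reflection parameter `A` defaults to the value for the
#' sample-fiber index mismatch (see [boundary_parameter_A()]).
#'
#' @param diameter_um Fiber core diameter in micrometers.
#' @param na Numerical aperture (must be < `n_sample`).
#' @param n_sample,n_fiber,n_external Refractive index of the sample, the
#'   fiber face and the medium above the sample outside the fiber.
#' @param A Optional override of the internal-reflection boundary parameter.
#' @return An object of class `probe_config` with fields `d` (cm),
#'   `theta_acc` (radians) and the inputs.
#' @examples
#' probe_config(diameter_um = 100, na = 0.22)
#' @export
probe_config <- function(diameter_um = 100, na = 0.22, n_sample = 1.35,
                         n_fiber = 1.45, n_external = 1.0, A = NULL) {
  stopifnot(diameter_um > 0, n_sample > 0, n_fiber > 0, n_external > 0)
  if (!(na > 0 && na < n_sample)) {
    stop("`na` must satisfy 0 < na < n_sample", call. = FALSE)
  }
  if (is.null(A)) A <- boundary_parameter_A(n_sample, n_fiber)
  stopifnot(A > 0)
  structure(list(
    d = diameter_um * 1e-4, diameter_um = diameter_um, na = na,
    n_sample = n_sample, n_fiber = n_fiber, n_external = n_external,
    A = A, theta_acc = asin(na / n_sample)
  ), class = "probe_config")
}

#' @export
print.probe_config <- function(x, ...) {
  cat(sprintf(paste0("<probe_config> d = %g um, NA = %g, n = %g/%g/%g ",
                     "(sample/fiber/external)\n  theta_acc = %.3f deg, ",
                     "A = %.4f\n"),
              x$diameter_um, x$na, x$n_sample, x$n_fiber, x$n_external,
              rad2deg(x$theta_acc), x$A))
  invisible(x)
}

unpolarised_fresnel <- function(theta_i, n1, n2) {
  st <- n1 / n2 * sin(theta_i)
  R <- rep(1, length(theta_i))
  ok <- st < 1
  tt <- asin(st[ok])
  ci <- cos(theta_i[ok]); ct <- cos(tt)
  rs <- (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct)
  rp <- (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci)
  R[ok] <- 0.5 * (rs^2 + rp^2)
  R
}

#' Internal-reflection boundary parameter A
#'
#' Diffusion-theory boundary parameter for the refractive-index mismatch at
#' the probed surface, from the effective reflection coefficient built out of
#' the hemispheric Fresnel integrals of fluence and flux:
#' \deqn{R_\Phi = \int_0^{\pi/2} 2\sin\theta\cos\theta R_F(\theta)d\theta,
#' \quad R_J = \int_0^{\pi/2} 3\sin\theta\cos^2\theta R_F(\theta)d\theta,}
#' \eqn{R_{eff} = (R_\Phi + R_J) / (2 - R_\Phi + R_J)} and
#' \eqn{A = (1 + R_{eff}) / (1 - R_{eff})}. For matched indices \eqn{A = 1};
#' for a 1.35 sample against a 1.45 fiber face \eqn{A \approx 1.027}.
#'
#' @param n_sample Refractive index of the scattering sample.
#' @param n_contact Refractive index of the medium in contact (the fiber
#'   face for an SFR probe).
#' @return The dimensionless boundary parameter.
#' @export
boundary_parameter_A <- function(n_sample, n_contact) {
  stopifnot(n_sample > 0, n_contact > 0)
  if (abs(n_sample - n_contact) < 1e-12) return(1)
  rphi <- integrate(function(t) {
    2 * sin(t) * cos(t) * unpolarised_fresnel(t, n_sample, n_contact)
  }, 0, pi / 2, rel.tol = 1e-10)$value
  rj <- integrate(function(t) {
    3 * sin(t) * cos(t)^2 * unpolarised_fresnel(t, n_sample, n_contact)
  }, 0, pi / 2, rel.tol = 1e-10)$value
  reff <- (rphi + rj) / (2 - rphi + rj)
  (1 + reff) / (1 - reff)
}

#' Pencil-beam diffuse reflectance (no absorption)
#'
#' Spatially resolved diffuse reflectance for a pencil-beam source on a
#' semi-infinite medium in the absence of absorption (the Farrell dipole
#' solution with \eqn{\mu_a = 0}):
#' \deqn{R(\rho) = \frac{1}{4\pi}\left\{
#'   \frac{\mu_s'^2}{[1 + (\mu_s'\rho)^2]^{3/2}} +
#'   \frac{(1 + 4A/3)\,\mu_s'^2}{[(1 + 4A/3)^2 + (\mu_s'\rho)^2]^{3/2}}
#' \right\}.}
#'
#' @param rho Radial distance from the source (cm); vectorised.
#' @param musp Reduced scattering coefficient (1/cm).
#' @param A Internal-reflection boundary parameter.
#' @return Reflectance per unit area (1/cm^2).
#' @export
pencil_beam_reflectance <- function(rho, musp, A = 1.027) {
  stopifnot(all(rho >= 0), musp > 0, A > 0)
  k <- 1 + 4 * A / 3
  mr2 <- (musp * rho)^2
  (musp^2 / (4 * pi)) * ((1 + mr2)^-1.5 + k * (k^2 + mr2)^-1.5)
}

#' Chord-length density of a disk
#'
#' Probability density of the distance between two independent uniformly
#' distributed points on a disk of diameter `d` (the distribution of
#' source-detector separations over an overlapping fiber face):
#' \deqn{p(\rho, d) = \frac{16\rho}{\pi d^2}\cos^{-1}(\rho/d) -
#'   \frac{16}{\pi d}\left(\frac{\rho}{d}\right)^2
#'   \sqrt{1 - (\rho/d)^2}.}
#'
#' @param rho Distance(s) in cm, in \eqn{[0, d]}.
#' @param d Disk (fiber) diameter in cm.
#' @return Density values (1/cm).
#' @export
chord_length_pdf <- function(rho, d) {
  stopifnot(d > 0)
  if (any(rho < 0 | rho > d)) {
    stop("`rho` must lie in [0, d]", call. = FALSE)
  }
  t <- rho / d
  (16 * rho / (pi * d^2)) * acos(t) - (16 / (pi * d)) * t^2 * sqrt(1 - t^2)
}

## dimensionless integrand of the overlapping-fiber diffuse reflectance:
## Rdif(m) = (m^2/pi) * int_0^1 F(m t) h(t) dt with h the scaled chord pdf
rdif_scalar <- function(m, A) {
  k <- 1 + 4 * A / 3
  f <- function(t) {
    w2 <- (m * t)^2
    ((1 + w2)^-1.5 + k * (k^2 + w2)^-1.5) *
      (t * acos(t) - t^2 * sqrt(pmax(1 - t^2, 0)))
  }
  ## split at the kernel width for large m so adaptive quadrature resolves
  ## the peak near t = 0
  brk <- if (m > 30) min(30 / m, 1) else 1
  val <- integrate(f, 0, brk, rel.tol = 1e-10, abs.tol = 1e-300)$value
  if (brk < 1) {
    val <- val + integrate(f, brk, 1, rel.tol = 1e-10, abs.tol = 1e-300)$value
  }
  m^2 / pi * val
}

#' Diffuse reflectance of an overlapping source/detector fiber
#'
#' Fraction of photons that arrive back anywhere on the fiber face after
#' diffuse propagation, from the pencil-beam solution averaged over the
#' chord-length distribution of the fiber face:
#' \deqn{R_{dif}(\mu_s' d) = \frac{\pi}{4} d^2 \int_0^d
#'   R_{\mu_a=0}(\rho, \mu_s')\, p(\rho, d)\, d\rho.}
#' The result depends on \eqn{\mu_s'} and \eqn{d} only through the product
#' \eqn{\mu_s' d}; it grows as \eqn{(\mu_s' d)^2} for small arguments and
#' saturates at 1.
#'
#' @param musp_d Dimensionless reduced scattering, \eqn{\mu_s' d};
#'   vectorised.
#' @param A Internal-reflection boundary parameter.
#' @return Diffuse reflectance fraction(s) in (0, 1).
#' @export
diffuse_reflectance <- function(musp_d, A = 1.027) {
  stopifnot(all(musp_d > 0), A > 0)
  vapply(musp_d, rdif_scalar, numeric(1), A = A)
}

#' Fiber collection efficiency
#'
#' For a Lambertian angular profile the fraction of photons arriving at the
#' fiber face that fall within its acceptance cone is
#' \eqn{\eta_{c,L} = \sin^2\theta_{acc} = (NA/n_{sample})^2}. Because the
#' true angular profile of subdiffuse reflectance is not exactly Lambertian,
#' the model scales this by the calibration constant `a1`:
#' \eqn{\eta_c = a_1 \sin^2\theta_{acc}}.
#'
#' @param probe A [probe_config].
#' @param a1 Collection-efficiency scaling constant (1 for the pure
#'   Lambertian value; the calibrated model uses 1.11).
#' @return Collection efficiency (fraction).
#' @export
collection_efficiency <- function(probe, a1 = 1.11) {
  stopifnot(inherits(probe, "probe_config"), a1 > 0)
  a1 * sin(probe$theta_acc)^2
}
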
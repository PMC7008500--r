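#' Scattering phase functions
#'
#' Constructors for the four phase-function families used to describe single
#' scattering in tissue: Henyey-Greenstein (HG), modified Henyey-Greenstein
#' (MHG, an HG mixed with a Rayleigh-like \eqn{\cos^2\theta} lobe), two-term
#' Henyey-Greenstein (TTHG, a forward and a backward HG lobe) and
#' Reynolds-McCormick (RMC, also known as the Gegenbauer-kernel phase
#' function). A phase function \eqn{p(\theta)} is the probability density of
#' the polar scattering angle per unit solid angle, normalised so that
#' \eqn{2\pi\int_0^\pi p(\theta)\sin\theta\,d\theta = 1}.
#'
#' Parameter domains: HG \eqn{g \in (-1, 1)}; MHG \eqn{\alpha \in [0, 1]}
#' (weight of the HG term); TTHG \eqn{\alpha \in [0, 1]} (weight of the
#' forward term), \eqn{g_f \in (0, 1)}, \eqn{g_b \in (-1, 0)}; RMC
#' \eqn{\alpha > 0} (kernel exponent), \eqn{g_R \in (0, 1)}.
#'
#' @param g,gHG Henyey-Greenstein anisotropy parameter.
#' @param alpha Family-specific mixing weight (MHG, TTHG) or kernel exponent
#'   (RMC).
#' @param gf,gb Anisotropy of the forward / backward TTHG lobe.
#' @param gR Asymmetry parameter of the Gegenbauer kernel.
#' @return An object of class `phase_function`.
#' @examples
#' pf <- hg_phase_function(0.8)
#' pf_density(pf, pi / 2)
#' legendre_moments(pf, 3)
#' @name phase_function
NULL

new_phase_function <- function(family, params) {
  structure(list(family = family, params = params), class = "phase_function")
}

check_param <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid phase-function parameter `%s`: %s", field, msg),
         call. = FALSE)
  }
}

#' @rdname phase_function
#' @export
hg_phase_function <- function(g) {
  check_param(is.numeric(g) && length(g) == 1 && abs(g) < 1, "gHG",
              "must be a single value in (-1, 1)")
  new_phase_function("HG", list(g = g))
}

#' @rdname phase_function
#' @export
mhg_phase_function <- function(g, alpha) {
  check_param(is.numeric(g) && length(g) == 1 && abs(g) < 1, "gHG",
              "must be a single value in (-1, 1)")
  check_param(is.numeric(alpha) && length(alpha) == 1 &&
                alpha >= 0 && alpha <= 1, "alpha", "must be in [0, 1]")
  new_phase_function("MHG", list(g = g, alpha = alpha))
}

#' @rdname phase_function
#' @export
tthg_phase_function <- function(alpha, gf, gb) {
  check_param(is.numeric(alpha) && length(alpha) == 1 &&
                alpha >= 0 && alpha <= 1, "alpha", "must be in [0, 1]")
  check_param(is.numeric(gf) && length(gf) == 1 && gf > 0 && gf < 1, "gf",
              "must be in (0, 1)")
  check_param(is.numeric(gb) && length(gb) == 1 && gb > -1 && gb < 0, "gb",
              "must be in (-1, 0)")
  new_phase_function("TTHG", list(alpha = alpha, gf = gf, gb = gb))
}

#' @rdname phase_function
#' @export
rmc_phase_function <- function(alpha, gR) {
  check_param(is.numeric(alpha) && length(alpha) == 1 && alpha > 0, "alpha",
              "must be > 0")
  check_param(is.numeric(gR) && length(gR) == 1 && gR > 0 && gR < 1, "gR",
              "must be in (0, 1)")
  new_phase_function("RMC", list(alpha = alpha, gR = gR))
}

#' @export
print.phase_function <- function(x, ...) {
  pars <- paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                collapse = ", ")
  cat(sprintf("<phase_function> %s(%s)\n", x$family, pars))
  invisible(x)
}

#' @export
format.phase_function <- function(x, ...) {
  paste0(x$family, "(", paste(sprintf("%s=%g", names(x$params),
                                      unlist(x$params)), collapse = ","), ")")
}

hg_density_mu <- function(mu, g) {
  (1 / (4 * pi)) * (1 - g^2) / (1 + g^2 - 2 * g * mu)^1.5
}

## density as a function of mu = cos(theta); vectorised over mu
pf_density_mu <- function(pf, mu) {
  p <- pf$params
  switch(pf$family,
    HG = hg_density_mu(mu, p$g),
    MHG = p$alpha * hg_density_mu(mu, p$g) +
      (1 - p$alpha) * (3 / (4 * pi)) * mu^2,
    TTHG = p$alpha * hg_density_mu(mu, p$gf) +
      (1 - p$alpha) * hg_density_mu(mu, p$gb),
    RMC = {
      a <- p$alpha; g <- p$gR
      K <- a * g * (1 - g^2)^(2 * a) /
        (pi * ((1 + g)^(2 * a) - (1 - g)^(2 * a)))
      K * (1 + g^2 - 2 * g * mu)^(-(a + 1))
    },
    stop("unknown phase-function family: ", pf$family))
}

#' Evaluate a phase function
#'
#' Returns the scattering probability density per steradian at polar angle
#' `theta` (radians).
#'
#' @param pf A [phase_function] object.
#' @param theta Polar scattering angle(s) in radians, in \eqn{[0, \pi]}.
#' @return Numeric vector of densities (1/sr).
#' @export
pf_density <- function(pf, theta) {
  stopifnot(inherits(pf, "phase_function"))
  if (any(theta < 0 | theta > pi)) {
    stop("`theta` must lie in [0, pi] (radians)", call. = FALSE)
  }
  pf_density_mu(pf, cos(theta))
}

legendre_polynomials <- function(mu, n_max) {
  ## rows: order 1..n_max at the nodes mu (recurrence in the order)
  out <- matrix(0, n_max, length(mu))
  Pm1 <- rep(1, length(mu))
  Pn <- mu
  for (k in seq_len(n_max)) {
    out[k, ] <- Pn
    Pp1 <- ((2 * k + 1) * mu * Pn - k * Pm1) / (k + 1)
    Pm1 <- Pn
    Pn <- Pp1
  }
  out
}

gauss_legendre_cache <- new.env(parent = emptyenv())

gauss_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(gauss_legendre_cache[[key]])) {
    gauss_legendre_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  }
  gauss_legendre_cache[[key]]
}

#' Legendre moments of a phase function
#'
#' Computes \eqn{g_n = 2\pi \int_0^\pi p(\theta) P_n(\cos\theta)
#' \sin\theta\,d\theta} for \eqn{n = 1 \ldots n_{max}} by fixed-order
#' Gauss-Legendre quadrature in \eqn{\cos\theta}. The quadrature order is
#' doubled until two successive orders agree, which guards the sharply
#' forward-peaked kernels (narrow HG lobes, large-exponent Gegenbauer).
#'
#' @param pf A [phase_function].
#' @param n_max Highest moment order (>= 1).
#' @param order Initial quadrature order (>= 256 recommended).
#' @param tol Agreement tolerance between successive quadrature orders.
#' @return Numeric vector `g1 ... g<n_max>`.
#' @export
legendre_moments <- function(pf, n_max = 3, order = 512, tol = 1e-10) {
  stopifnot(inherits(pf, "phase_function"), n_max >= 1)
  quad <- function(n) {
    gl <- gauss_nodes(n)
    f <- pf_density_mu(pf, gl$x)
    drop(legendre_polynomials(gl$x, n_max) %*% (gl$w * f)) * 2 * pi
  }
  g <- quad(order)
  converged <- FALSE
  for (n in order * c(2L, 4L, 8L)) {
    g2 <- quad(n)
    ok <- max(abs(g2 - g)) < tol
    g <- g2
    if (ok) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("Legendre-moment quadrature did not converge for ", format(pf),
         call. = FALSE)
  }
  setNames(g, paste0("g", seq_len(n_max)))
}

#' Partial integrals of a phase function
#'
#' Probability of a single scattering event falling within `theta_lim` of the
#' exact forward (\eqn{\theta = 0}) or exact backward (\eqn{\theta = \pi})
#' direction: forward returns \eqn{2\pi\int_0^{\theta_{lim}}
#' p\sin\theta\,d\theta}, backward returns
#' \eqn{2\pi\int_{\pi-\theta_{lim}}^{\pi} p\sin\theta\,d\theta}.
#'
#' @param pf A [phase_function].
#' @param theta_lim Half-angle of the cone; radians unless `degrees = TRUE`.
#'   Must lie in (0, 90] degrees.
#' @param direction `"forward"` or `"backward"`.
#' @param degrees Interpret `theta_lim` in degrees.
#' @return Probability in \eqn{[0, 1]}.
#' @export
partial_integral <- function(pf, theta_lim,
                             direction = c("forward", "backward"),
                             degrees = FALSE) {
  stopifnot(inherits(pf, "phase_function"))
  direction <- match.arg(direction)
  th <- if (degrees) deg2rad(theta_lim) else theta_lim
  if (length(th) != 1 || th <= 0 || th > pi / 2 + 1e-12) {
    stop("`theta_lim` must lie in (0, pi/2] radians (0, 90] degrees)",
         call. = FALSE)
  }
  lims <- if (direction == "forward") c(cos(th), 1) else c(-1, -cos(th))
  val <- 2 * pi * integrate(function(mu) pf_density_mu(pf, mu),
                            lims[1], lims[2],
                            rel.tol = 1e-11, abs.tol = 1e-14)$value
  min(max(val, 0), 1)
}

## inverse-CDF table of the polar scattering angle on a uniform theta grid;
## equiprobable representation so sampling is a single linear interpolation
pf_quantile_table <- function(pf, n_grid = 2^14) {
  theta <- seq(0, pi, length.out = n_grid + 1)
  f <- 2 * pi * pf_density(pf, theta) * sin(theta)
  cdf <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(theta)))
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  approx(cdf[keep], theta[keep], xout = seq(0, 1, length.out = n_grid + 1),
         rule = 2, ties = "ordered")$y
}

#' Sample scattering angles
#'
#' Draws polar scattering angles from a phase function by inversion of a
#' tabulated cumulative distribution (the classical approach for
#' arbitrary tabulated phase functions), using a dense uniform-angle grid so
#' that forward-peaked kernels are resolved.
#'
#' @param pf A [phase_function].
#' @param n Number of angles to draw.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Numeric vector of `n` angles in \eqn{[0, \pi]} (radians).
#' @export
sample_scattering_angles <- function(pf, n, seed = NULL) {
  stopifnot(inherits(pf, "phase_function"), n >= 1)
  tab <- pf_quantile_table(pf)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  u <- runif(n) * (length(tab) - 1)
  i <- pmin(floor(u), length(tab) - 2)
  frac <- u - i
  tab[i + 1] * (1 - frac) + tab[i + 2] * frac
}
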
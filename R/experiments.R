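#' Relative dispersion of a phase-function parameter
#'
#' Suitability measure for a candidate phase-function parameter: across an
#' ensemble of simulations, the spread of \eqn{\log_{10}} of the parameter
#' among the simulations whose reflectance falls within +/- 10% of a chosen
#' value, divided by the spread over the whole ensemble. A small value means
#' the parameter nearly determines the reflectance; taking the spread on a
#' log scale and dividing by the full range makes the measure invariant to
#' rescaling the parameter.
#'
#' @param R0_values Simulated reflectance per ensemble member.
#' @param param_values Positive parameter values, same length.
#' @param target_R0 Reflectance value defining the band.
#' @param tolerance_fraction Half-width of the band as a fraction of
#'   `target_R0`.
#' @return Dimensionless dispersion in \eqn{[0, 1]}.
#' @export
relative_dispersion <- function(R0_values, param_values, target_R0,
                                tolerance_fraction = 0.10) {
  stopifnot(length(R0_values) == length(param_values),
            all(param_values > 0), target_R0 > 0)
  band <- abs(R0_values - target_R0) <= tolerance_fraction * target_R0
  if (sum(band) < 2) {
    stop(sprintf(paste0("fewer than two simulations fall within +/-%g%% of ",
                        "the target reflectance %g"),
                 100 * tolerance_fraction, target_R0), call. = FALSE)
  }
  lp <- log10(param_values)
  full <- diff(range(lp))
  if (full == 0) return(0)
  diff(range(lp[band])) / full
}

## cumulative backward/forward partial integrals pb(theta), pf(theta) on a
## 1-degree grid for a list of models (trapezoid on a 0.05-degree mesh)
partial_integral_tables <- function(models, theta_deg = 1:90) {
  fine <- seq(0, 180, by = 0.05)
  th <- deg2rad(fine)
  idx <- match(theta_deg, fine)
  pb <- pf <- matrix(0, length(theta_deg), length(models))
  for (j in seq_along(models)) {
    f <- 2 * pi * pf_density(models[[j]], th) * sin(th)
    cum <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(th)))
    total <- cum[length(cum)]
    pf[, j] <- cum[idx] / total
    pb[, j] <- (total - cum[length(cum) + 1 - idx]) / total
  }
  list(pb = pb, pf = pf, theta_deg = theta_deg)
}

#' Optimise the Rp integration angles
#'
#' Scans all backward/forward integration-angle pairs (1-degree steps) of
#' the ratio \eqn{R_p(\theta_b, \theta_f)} and returns the pair minimising
#' the mean relative dispersion over a set of target reflectances (by
#' default five, equally spaced on a log scale between the 5th and 95th
#' percentile of the ensemble reflectance).
#'
#' @param models List of [phase_function] objects.
#' @param R0_values Simulated reflectance for each model (same order), at
#'   fixed \eqn{\mu_s' d} and NA.
#' @param targets Optional explicit target reflectances; otherwise derived
#'   from `n_targets` and `target_probs`.
#' @param n_targets,target_probs Number of log-spaced targets and the
#'   percentile range they span.
#' @param tolerance_fraction Band half-width passed to
#'   [relative_dispersion()].
#' @param theta_deg Candidate integration angles (degrees).
#' @return List with `optimal` (named vector `theta_b`, `theta_f`),
#'   `dispersion` (matrix over angle pairs; rows = backward), `targets`,
#'   and the partial-integral tables.
#' @export
scan_integration_angles <- function(models, R0_values, targets = NULL,
                                    n_targets = 5,
                                    target_probs = c(0.05, 0.95),
                                    tolerance_fraction = 0.10,
                                    theta_deg = 1:90) {
  stopifnot(length(models) == length(R0_values))
  if (is.null(targets)) {
    q <- quantile(R0_values, target_probs)
    targets <- 10^seq(log10(q[[1]]), log10(q[[2]]), length.out = n_targets)
  }
  bands <- lapply(targets, function(t0) {
    which(abs(R0_values - t0) <= tolerance_fraction * t0)
  })
  if (any(lengths(bands) < 2)) {
    stop("each target reflectance band must contain at least two models",
         call. = FALSE)
  }
  tabs <- partial_integral_tables(models, theta_deg)
  nb <- length(theta_deg)
  disp <- matrix(NA_real_, nb, nb,
                 dimnames = list(theta_b = theta_deg, theta_f = theta_deg))
  for (jf in seq_len(nb)) {
    lp <- log10(tabs$pb) - rep(log10(1 - tabs$pf[jf, ]), each = nb)
    full <- apply(lp, 1, max) - apply(lp, 1, min)
    band_disp <- vapply(bands, function(ix) {
      apply(lp[, ix, drop = FALSE], 1, max) -
        apply(lp[, ix, drop = FALSE], 1, min)
    }, numeric(nb))
    disp[, jf] <- rowMeans(band_disp / full)
  }
  best <- arrayInd(which.min(disp), dim(disp))
  list(optimal = c(theta_b = theta_deg[best[1]],
                   theta_f = theta_deg[best[2]]),
       dispersion = disp, targets = targets, tables = tabs)
}

#' Calibrate the model constants against Monte Carlo results
#'
#' Two-stage least-squares calibration of the constants \eqn{a_1}-\eqn{a_3}
#' on \eqn{\log_{10} R_0} (errors are relative and span decades). Stage 1
#' fits all three constants independently per NA; stage 2 fixes a single
#' shared \eqn{a_1} (by default the stage-1 mean rounded to two decimals)
#' and refits \eqn{a_2}, \eqn{a_3} per NA. 95% confidence intervals come
#' from the fit covariance.
#'
#' @param data Data frame with columns `na`, `musp_d`, `psb` and `R0`
#'   (Monte Carlo reflectance), several `musp_d` values per NA.
#' @param n_sample Sample refractive index used for the acceptance angle.
#' @param A Boundary parameter for the diffuse component.
#' @param shared_a1 Value of \eqn{a_1} to impose in stage 2; `NULL` uses
#'   the rounded stage-1 mean.
#' @param start Optional named start values (`a1`, `a2`, `a3`).
#' @return List of class `sfr_calibration` with data frames `stage1`
#'   (`na`, `a1`, `a2`, `a3` and `*_ci` 95% half-widths), `stage2`, and
#'   `shared_a1`.
#' @export
calibrate_constants <- function(data, n_sample = 1.35, A = 1.027,
                                shared_a1 = NULL, start = NULL) {
  stopifnot(all(c("na", "musp_d", "psb", "R0") %in% names(data)),
            all(data$R0 > 0))
  if (is.null(start)) start <- c(a1 = 1, a2 = 3000, a3 = 0.75)

  prep <- function(d) {
    um <- unique(d$musp_d)
    d$rdif <- diffuse_reflectance(um, A = A)[match(d$musp_d, um)]
    d$eta_l <- (d$na / n_sample)^2
    d$y <- log10(d$R0)
    d
  }
  fit_na <- function(d, fix_a1 = NULL) {
    if (is.null(fix_a1)) {
      fml <- y ~ log10((1 + a2 * (psb / musp_d^2)^a3) * a1 * eta_l * rdif)
      st <- as.list(start)
    } else {
      d$a1 <- fix_a1
      fml <- y ~ log10((1 + a2 * (psb / musp_d^2)^a3) * a1 * eta_l * rdif)
      st <- as.list(start[c("a2", "a3")])
    }
    fit <- minpack.lm::nlsLM(fml, data = d, start = st,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-12))
    est <- coef(fit)
    ci <- 1.96 * sqrt(diag(vcov(fit)))
    list(est = est, ci = ci,
         rss = sum(stats::residuals(fit)^2))
  }

  nas <- sort(unique(data$na))
  stage1 <- do.call(rbind, lapply(nas, function(nav) {
    f <- fit_na(prep(data[data$na == nav, ]))
    data.frame(na = nav, a1 = f$est["a1"], a1_ci = f$ci["a1"],
               a2 = f$est["a2"], a2_ci = f$ci["a2"],
               a3 = f$est["a3"], a3_ci = f$ci["a3"], rss = f$rss,
               row.names = NULL)
  }))
  if (is.null(shared_a1)) shared_a1 <- round(mean(stage1$a1), 2)
  stage2 <- do.call(rbind, lapply(nas, function(nav) {
    f <- fit_na(prep(data[data$na == nav, ]), fix_a1 = shared_a1)
    data.frame(na = nav, a1 = shared_a1,
               a2 = f$est["a2"], a2_ci = f$ci["a2"],
               a3 = f$est["a3"], a3_ci = f$ci["a3"], rss = f$rss,
               row.names = NULL)
  }))
  structure(list(stage1 = stage1, stage2 = stage2, shared_a1 = shared_a1),
            class = "sfr_calibration")
}

#' @export
print.sfr_calibration <- function(x, ...) {
  cat("<sfr_calibration> stage 2 (shared a1 =", x$shared_a1, "):\n")
  print(x$stage2, digits = 4)
  invisible(x)
}

#' Relative prediction-error statistics
#'
#' Percentage statistics of \eqn{|R_{0,model} - R_{0,MC}| / R_{0,MC}} over
#' matched prediction/reference pairs, with an optional per-group
#' breakdown.
#'
#' @param predicted,reference Matched reflectance vectors.
#' @param group Optional grouping factor (e.g. NA) for a breakdown.
#' @return List with `median`, `sd`, `max` (percent) and, when `group` is
#'   given, a data frame `by_group`.
#' @export
error_statistics <- function(predicted, reference, group = NULL) {
  stopifnot(length(predicted) == length(reference), all(reference > 0))
  err <- 100 * abs(predicted - reference) / reference
  out <- list(median = median(err), sd = sd(err), max = max(err))
  if (!is.null(group)) {
    out$by_group <- do.call(rbind, lapply(split(err, group), function(e) {
      data.frame(median = median(e), sd = sd(e), max = max(e))
    }))
    out$by_group$group <- rownames(out$by_group)
  }
  out
}
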
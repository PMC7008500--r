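#' Tissue phase-function candidate grid
#'
#' Enumerates the published MHG / TTHG / RMC parameter grids used to span the
#' range of phase functions measured in tissue, computes the first three
#' Legendre moments of every candidate, and keeps the biologically reasonable
#' ones: \eqn{g_1 \ge 0.5} and \eqn{g_2 < 0.9}.
#'
#' The grids (all values equally spaced, endpoints included):
#' * MHG: \eqn{g_{HG}} 0.01-0.95 (10 values), \eqn{\alpha} 0.01-0.99 (10
#'   values).
#' * TTHG: \eqn{\alpha} 0.5-0.9 (5 values) and 0.91-0.99 (5 values),
#'   \eqn{g_f} 0.05-0.95 (10 values), \eqn{g_b} -0.95 to -0.05 (5 values).
#' * RMC: \eqn{\alpha} 0.01-2.5 (10 values), \eqn{g_R} 0.01 to
#'   \eqn{0.95 - 0.2\alpha} (10 values per \eqn{\alpha}).
#'
#' With exact mixture moments the filter keeps 206 candidates (15 MHG,
#' 145 TTHG, 46 RMC). One further TTHG cluster (\eqn{g_f = 0.95},
#' \eqn{g_b = -0.95}) sits exactly at \eqn{g_2 = 0.9025} and is excluded by
#' the \eqn{g_2 < 0.9} rule; see the methods vignette for a discussion of
#' this knife edge.
#'
#' @param g1_min,g2_max Selection thresholds.
#' @return A data frame with one row per surviving candidate: `id`, `family`,
#'   the family parameters (`g`, `alpha`, `gf`, `gb`, `gR`, `NA` where not
#'   applicable), moments `g1`-`g3`, and a list column `model` holding the
#'   [phase_function] objects.
#' @export
tissue_phase_function_grid <- function(g1_min = 0.5, g2_max = 0.9) {
  lin <- function(a, b, n) seq(a, b, length.out = n)

  cand <- list()
  for (g in lin(0.01, 0.95, 10)) {
    for (a in lin(0.01, 0.99, 10)) {
      cand[[length(cand) + 1]] <- mhg_phase_function(g, a)
    }
  }
  tthg_alpha <- c(lin(0.5, 0.9, 5), lin(0.91, 0.99, 5))
  for (a in tthg_alpha) {
    for (gf in lin(0.05, 0.95, 10)) {
      for (gb in lin(-0.95, -0.05, 5)) {
        cand[[length(cand) + 1]] <- tthg_phase_function(a, gf, gb)
      }
    }
  }
  for (a in lin(0.01, 2.5, 10)) {
    for (gR in lin(0.01, 0.95 - 0.2 * a, 10)) {
      cand[[length(cand) + 1]] <- rmc_phase_function(a, gR)
    }
  }

  mom <- t(vapply(cand, grid_moments, numeric(3)))
  keep <- mom[, 1] >= g1_min & mom[, 2] < g2_max

  cand <- cand[keep]
  mom <- mom[keep, , drop = FALSE]
  par_cols <- c("g", "alpha", "gf", "gb", "gR")
  pars <- t(vapply(cand, function(pf) {
    out <- setNames(rep(NA_real_, length(par_cols)), par_cols)
    out[names(pf$params)] <- unlist(pf$params)
    out
  }, numeric(length(par_cols))))

  out <- data.frame(
    id = seq_along(cand),
    family = vapply(cand, function(pf) pf$family, character(1)),
    pars,
    g1 = mom[, 1], g2 = mom[, 2], g3 = mom[, 3],
    stringsAsFactors = FALSE
  )
  out$model <- I(cand)
  out
}

## moments g1..g3; closed forms for the HG mixtures, quadrature for RMC
grid_moments <- function(pf) {
  p <- pf$params
  switch(pf$family,
    HG = p$g^(1:3),
    MHG = p$alpha * p$g^(1:3) + (1 - p$alpha) * c(0, 2 / 5, 0),
    TTHG = p$alpha * p$gf^(1:3) + (1 - p$alpha) * p$gb^(1:3),
    RMC = unname(legendre_moments(pf, 3)))
}

#' Write / read a phase-function grid as CSV
#'
#' The CSV stores the family and parameter columns plus the moments at full
#' precision; `read_phase_function_grid()` rebuilds the `model` list column
#' from the parameters.
#'
#' @param grid A data frame from [tissue_phase_function_grid()].
#' @param path File path.
#' @return `read_phase_function_grid()` returns the grid data frame.
#' @export
write_phase_function_grid <- function(grid, path) {
  df <- grid[setdiff(names(grid), "model")]
  write_full_precision_csv(df, path)
  invisible(path)
}

#' @rdname write_phase_function_grid
#' @export
read_phase_function_grid <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$model <- I(lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    switch(row$family,
      HG = hg_phase_function(row$g),
      MHG = mhg_phase_function(row$g, row$alpha),
      TTHG = tthg_phase_function(row$alpha, row$gf, row$gb),
      RMC = rmc_phase_function(row$alpha, row$gR),
      stop("unknown family in grid file: ", row$family))
  }))
  df
}

#' Tabulate a phase function for export
#'
#' Two-column table (angle in degrees, density per steradian), e.g. for use
#' as a tabulated phase function in external Monte Carlo configurations.
#'
#' @param pf A [phase_function].
#' @param step Angular step in degrees.
#' @return Data frame with columns `theta_deg`, `p`.
#' @export
tabulate_phase_function <- function(pf, step = 0.5) {
  theta_deg <- seq(0, 180, by = step)
  data.frame(theta_deg = theta_deg, p = pf_density(pf, deg2rad(theta_deg)))
}
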
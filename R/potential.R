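# One-dimensional model potentials for umbrella-sampling validation.
#
# A potential is a sum of Gaussian terms plus a constant offset: smooth,
# finite everywhere, with analytic gradient, and the exact Boltzmann
# density (hence the exact PMF) is available by quadrature.  This is the
# ground truth against which the WHAM estimator is validated.

#' Define a sum-of-Gaussians potential U(z)
#'
#' `U(z) = offset + sum_i height_i * exp(-(z - center_i)^2 / (2 width_i^2))`
#'
#' @param heights Gaussian heights, kcal mol-1 (negative = well)
#' @param centers Gaussian centers, Angstrom
#' @param widths Gaussian standard-deviation widths, Angstrom (> 0)
#' @param offset constant offset, kcal mol-1
#' @return object of class `"potential_spec"`
#' @export
potential_spec <- function(heights = numeric(), centers = numeric(),
                           widths = numeric(), offset = 0) {
  stopifnot(length(heights) == length(centers),
            length(centers) == length(widths))
  if (length(widths) && any(widths <= 0)) stop("Gaussian widths must be > 0")
  structure(list(heights = as.numeric(heights), centers = as.numeric(centers),
                 widths = as.numeric(widths), offset = as.numeric(offset)),
            class = "potential_spec")
}

#' Evaluate a potential
#' @param pot a [potential_spec()]
#' @param z positions, Angstrom (vectorised)
#' @return U(z), kcal mol-1
#' @export
potential_energy <- function(pot, z) {
  u <- rep(pot$offset, length(z))
  for (g in seq_along(pot$heights)) {
    u <- u + pot$heights[g] *
      exp(-(z - pot$centers[g])^2 / (2 * pot$widths[g]^2))
  }
  u
}

#' Evaluate the gradient dU/dz
#' @inheritParams potential_energy
#' @return dU/dz, kcal mol-1 A-1
#' @export
potential_grad <- function(pot, z) {
  du <- rep(0, length(z))
  for (g in seq_along(pot$heights)) {
    d <- z - pot$centers[g]
    du <- du - pot$heights[g] * d / pot$widths[g]^2 *
      exp(-d^2 / (2 * pot$widths[g]^2))
  }
  du
}

#' Exact free-energy profile by Boltzmann inversion of the analytic density
#'
#' Normalises `exp(-U(z)/kBT)` by quadrature over `[z_lo, z_hi]` and returns
#' `F(z) = -kBT ln rho(z)`.  Up to an additive constant this equals U(z);
#' it is the independent oracle for the WHAM estimator.
#'
#' @param pot a [potential_spec()]
#' @param z positions at which to report F, Angstrom
#' @param temperature K
#' @param z_lo,z_hi integration range (defaults: range of `z` padded 5 A)
#' @return data.frame with columns `z`, `F` (kcal mol-1)
#' @export
exact_pmf <- function(pot, z, temperature, z_lo = min(z) - 5,
                      z_hi = max(z) + 5) {
  kT <- kB_kcal * temperature
  Z <- stats::integrate(function(x) exp(-potential_energy(pot, x) / kT),
                        z_lo, z_hi, rel.tol = 1e-10,
                        subdivisions = 2000L)$value
  data.frame(z = z, F = potential_energy(pot, z) + kT * log(Z))
}
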
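#' Chemostat habitat parameters
#'
#' Describes the continuous-culture vessel shared by both models: a unit-volume
#' (1 ml) vessel receiving medium with the limiting resource at concentration
#' `A` from a reservoir at dilution rate `w`; bacteria grow on the resource by
#' Monod kinetics with half-saturation constant `k` and conversion efficiency
#' `e`. Two numerical-event settings travel with the habitat: `refuge_density`,
#' the host density below which phage cannot adsorb (bounds predator-prey
#' oscillations), and `phage_extinction_threshold`, the free-phage density
#' below which the phage population is declared lost and set to zero.
#'
#' @param A Resource concentration in the reservoir (µg/ml). Must be > 0.
#' @param w Dilution (washout) rate (hr^-1). Must be >= 0.
#' @param k Monod constant: resource concentration at half-maximal growth
#'   (µg/ml). Must be > 0.
#' @param e Conversion efficiency (µg of resource per new cell). Must be > 0.
#' @param refuge_density Host density (cells/ml) below which phage adsorption
#'   to that host population is switched off.
#' @param phage_extinction_threshold Free-phage density (particles/ml) below
#'   which the phage are considered lost.
#'
#' @return An object of class `chemostat_env`.
#' @examples
#' env <- chemostat_env()
#' env$A
#' @export
chemostat_env <- function(A = 50, w = 0.2, k = 0.25, e = 5e-7,
                          refuge_density = 100,
                          phage_extinction_threshold = 0.1) {
  stopifnot(is.numeric(A), length(A) == 1L,
            is.numeric(w), length(w) == 1L,
            is.numeric(k), length(k) == 1L,
            is.numeric(e), length(e) == 1L)
  if (!is.finite(A) || A <= 0) stop("'A' must be a positive resource concentration")
  if (!is.finite(w) || w < 0)  stop("'w' must be a nonnegative dilution rate")
  if (!is.finite(k) || k <= 0) stop("'k' must be a positive Monod constant")
  if (!is.finite(e) || e <= 0) stop("'e' must be a positive conversion efficiency")
  if (refuge_density < 0) stop("'refuge_density' must be >= 0")
  if (phage_extinction_threshold < 0)
    stop("'phage_extinction_threshold' must be >= 0")
  structure(
    list(A = A, w = w, k = k, e = e,
         refuge_density = refuge_density,
         phage_extinction_threshold = phage_extinction_threshold),
    class = "chemostat_env"
  )
}

#' @export
print.chemostat_env <- function(x, ...) {
  cat("Chemostat habitat\n")
  cat(sprintf("  reservoir A = %g ug/ml, dilution w = %g /hr\n", x$A, x$w))
  cat(sprintf("  Monod k = %g ug/ml, efficiency e = %g ug/cell\n", x$k, x$e))
  cat(sprintf("  phage refuge below %g cells/ml; phage lost below %g /ml\n",
              x$refuge_density, x$phage_extinction_threshold))
  invisible(x)
}

# Smooth low-density refuge switch: ~0 well below the refuge density, ~1
# well above it, half way at the refuge itself. A steep Hill sigmoid is used
# instead of a hard indicator so the protected boundary is not a sliding
# surface for the integrator.
refuge_factor <- function(host, refuge_density, sharpness = 4) {
  if (refuge_density <= 0) return(rep(1, length(host)))
  hh <- (host / refuge_density)^sharpness
  hh / (1 + hh)
}

#' Monod resource-limited growth rate
#'
#' Realized per-capita growth rate `V * R / (k + R)`: a saturating, monotone
#' nondecreasing function of the resource concentration, equal to half the
#' maximum `V` when `R == k`.
#'
#' @param V Maximum growth rate (hr^-1), >= 0.
#' @param k Monod constant (µg/ml), > 0.
#' @param R Resource concentration (µg/ml), >= 0. May be a vector.
#'
#' @return Realized growth rate(s) (hr^-1), bounded above by `V`.
#' @examples
#' monod_growth(1, 0.25, 0.25)  # half saturation: 0.5
#' @export
monod_growth <- function(V, k, R) {
  if (any(!is.finite(V)) || any(V < 0)) stop("'V' must be nonnegative")
  if (any(!is.finite(k)) || any(k <= 0)) stop("'k' must be positive")
  if (any(!is.finite(R)) || any(R < 0)) stop("'R' must be nonnegative")
  V * R / (k + R)
}

#' Net rate of change of the resource concentration
#'
#' Inflow minus washout of the resource, minus uptake by the growing bacterial
#' populations: `w * (A - R) - e * sum(psi_i * X_i)`, where `psi_i` are
#' realized Monod growth rates and `X_i` population densities.
#'
#' @param env A [chemostat_env()].
#' @param R Current resource concentration (µg/ml).
#' @param growth_rates Realized per-capita growth rates (hr^-1), one per
#'   population (may be empty).
#' @param densities Population densities (cells/ml), matching `growth_rates`.
#'
#' @return dR/dt (µg/ml/hr).
#' @export
resource_flux <- function(env, R, growth_rates = numeric(), densities = numeric()) {
  stopifnot(inherits(env, "chemostat_env"),
            length(growth_rates) == length(densities))
  if (any(densities < 0)) stop("densities must be nonnegative")
  env$w * (env$A - R) - env$e * sum(growth_rates * densities)
}
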
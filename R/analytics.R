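#' Resource concentration at the single-population chemostat equilibrium
#'
#' The resource level `R*` at which a population with maximum growth rate `V`
#' grows exactly at the dilution rate: `monod_growth(V, k, R*) = w`, i.e.
#' `R* = k w / (V - w)`.
#'
#' @param V Maximum growth rate (hr^-1), must exceed `w`.
#' @param k Monod constant (µg/ml).
#' @param w Dilution rate (hr^-1).
#' @return `R*` (µg/ml).
#' @export
resource_equilibrium <- function(V, k, w) {
  if (k <= 0) stop("'k' must be positive")
  if (w < 0) stop("'w' must be nonnegative")
  if (w >= V) {
    stop(structure(
      class = c("crisprdyn_washout_error", "error", "condition"),
      list(message = sprintf(
        "washout: dilution rate w = %g is not below the maximum growth rate V = %g; no positive equilibrium exists",
        w, V), call = sys.call(-1))))
  }
  k * w / (V - w)
}

#' Bacterial density at the single-population chemostat equilibrium
#'
#' All resource inflow above the equilibrium residual is converted to cells:
#' `N* = (A - R*) / e` with `R*` from [resource_equilibrium()].
#'
#' @param env A [chemostat_env()] supplying `A`, `w`, `k`, `e`.
#' @param V Maximum growth rate of the resident population (hr^-1).
#' @return `N*` (cells/ml).
#' @examples
#' bacterial_equilibrium(chemostat_env(), V = 1.0)  # ~1e8 cells/ml
#' @export
bacterial_equilibrium <- function(env, V) {
  stopifnot(inherits(env, "chemostat_env"))
  Rstar <- resource_equilibrium(V, env$k, env$w)
  max((env$A - Rstar) / env$e, 0)
}

#' Critical adsorption-rate x burst-size product for phage establishment
#'
#' A lytic phage introduced into a resident sensitive population at its
#' chemostat equilibrium density `N*` establishes when phage production
#' outruns washout: `delta_N * beta_N * N* > w`. The critical value of the
#' product `delta_N * beta_N` is therefore `w / N*`.
#'
#' @param w Dilution rate (hr^-1), >= 0.
#' @param N_star Resident equilibrium density (cells/ml), > 0.
#' @return Critical `delta_N * beta_N` product (ml hr^-1).
#' @examples
#' phage_establishment_threshold(w = 0.2, N_star = 1e8)  # 2e-9
#' @export
phage_establishment_threshold <- function(w, N_star) {
  if (!is.finite(N_star) || N_star <= 0) stop("'N_star' must be positive")
  if (w < 0) stop("'w' must be nonnegative")
  w / N_star
}

#' Critical conjugational transfer rate for plasmid maintenance
#'
#' A deleterious conjugative plasmid is maintained in an `N`/`N_P` population
#' when infectious transfer at the resident equilibrium outweighs the loss of
#' plasmid-bearing cells to growth-rate selection, segregation, and washout.
#' At the resident equilibrium the plasmid-free population grows at `w`, so
#' plasmid carriage imposes a growth deficit `w * (1 - V_NP / V_N)`, and the
#' critical transfer rate constant is
#'
#' \deqn{\gamma^* = \frac{w\,(1 - V_{NP}/V_N) + \tau_N}{N^*}}
#'
#' @param V_N,V_NP Maximum growth rates of plasmid-free and plasmid-bearing
#'   cells (hr^-1); `V_N > 0`.
#' @param w Dilution rate (hr^-1).
#' @param tau_N Vegetative segregation rate (hr^-1).
#' @param N_star Resident plasmid-free equilibrium density (cells/ml), > 0.
#' @return Critical `gamma_NN` (ml per cell per hour).
#' @examples
#' critical_gamma(1.0, 0.95, 0.2, 1e-3, 1e8)  # 1.1e-10
#' @export
critical_gamma <- function(V_N, V_NP, w, tau_N, N_star) {
  if (!is.finite(N_star) || N_star <= 0) stop("'N_star' must be positive")
  if (V_N <= 0) stop("'V_N' must be positive")
  if (w < 0 || tau_N < 0) stop("'w' and 'tau_N' must be nonnegative")
  (w * (1 - V_NP / V_N) + tau_N) / N_star
}

#' Decline of free phage on an exponentially growing immune culture
#'
#' In batch culture (no washout), phage adsorbing at the maximum rate
#' `delta_MAX` to an immune CRISPR culture growing exponentially at `V_R`
#' are lost without replicating:
#' `dP/dt = -delta_MAX * C_R0 * exp(V_R t) * P`, whose solution is
#'
#' \deqn{P(t) = P_0 \exp\!\left(-\delta_{MAX}\, C_{R0}\,
#'   \frac{e^{V_R t} - 1}{V_R}\right)}
#'
#' with the `V_R = 0` limit `P0 * exp(-delta_MAX * C_R0 * t)`. This is the
#' predicted kill curve for validating that phage infecting immune cells are
#' lost rather than replicating.
#'
#' @param P0 Initial phage density (particles/ml).
#' @param C_R0 Initial immune-cell density (cells/ml).
#' @param V_R Maximum growth rate of the immune culture (hr^-1).
#' @param delta_MAX Maximum adsorption rate constant (ml/hr).
#' @param t Time(s) (hr); may be a vector.
#' @return Phage density `P(t)` (particles/ml).
#' @export
immune_decline_curve <- function(P0, C_R0, V_R, delta_MAX, t) {
  if (any(c(P0, C_R0, V_R, delta_MAX) < 0) || any(t < 0))
    stop("all arguments must be nonnegative")
  exposure <- if (V_R == 0) C_R0 * t else C_R0 * (exp(V_R * t) - 1) / V_R
  P0 * exp(-delta_MAX * exposure)
}

#' Analytic threshold report for a parameterized model
#'
#' Evaluates the establishment/maintenance criterion relevant to a model
#' against a supplied parameter set: for the phage model, whether
#' `delta_N * beta_N` exceeds `w / N*`; for the plasmid model, whether
#' `gamma_NN` exceeds [critical_gamma()]. `N*` is the resident equilibrium
#' density from `env` and `V_N`.
#'
#' @param params A [phage_params()] or [plasmid_params()].
#' @param env A [chemostat_env()].
#' @return An object of class `threshold_report` with fields `criterion`,
#'   `threshold`, `units`, `actual`, `satisfied`, `N_star`, `params`.
#' @examples
#' threshold_report(phage_params(), chemostat_env())
#' @export
threshold_report <- function(params, env) {
  stopifnot(inherits(env, "chemostat_env"))
  N_star <- bacterial_equilibrium(env, params$V_N)
  if (inherits(params, "phage_params")) {
    thr <- phage_establishment_threshold(env$w, N_star)
    actual <- params$delta_N * params$beta_N
    rep <- list(criterion = "phage_establishment",
                threshold = thr, units = "ml hr^-1",
                actual = actual, satisfied = actual > thr,
                N_star = N_star, params = params)
  } else if (inherits(params, "plasmid_params")) {
    thr <- critical_gamma(params$V_N, params$V_NP, env$w, params$tau_N, N_star)
    rep <- list(criterion = "plasmid_maintenance",
                threshold = thr, units = "ml cell^-1 hr^-1",
                actual = params$gamma_NN, satisfied = params$gamma_NN > thr,
                N_star = N_star, params = params)
  } else {
    stop("'params' must be a phage_params or plasmid_params object")
  }
  structure(rep, class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("Criterion: %s\n", x$criterion))
  cat(sprintf("  resident equilibrium N* = %.4g cells/ml\n", x$N_star))
  cat(sprintf("  analytic threshold = %.4g %s\n", x$threshold, x$units))
  cat(sprintf("  supplied parameters give %.4g -> %s\n", x$actual,
              if (x$satisfied) "SATISFIED (invader establishes)"
              else "not satisfied (invader is lost)"))
  invisible(x)
}
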
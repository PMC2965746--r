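#' Parameter set for the lytic-phage model
#'
#' Complete parameterization of the five-population phage model: sensitive
#' non-CRISPR cells `N`, envelope-resistant cells `N_R` (phage cannot adsorb),
#' phage-sensitive CRISPR cells `C`, phage-immune CRISPR cells `C_R`, and free
#' phage `P`. Immunity of `C_R` can be overridden at high multiplicity of
#' infection: the effective adsorption/killing rate on `C_R` rises from
#' `delta_MIN` toward `delta_MIN + x * (delta_MAX - delta_MIN)` as a Hill
#' function of MOI with half-effect `q` and exponent `n`
#' (see [effective_adsorption()]).
#'
#' Defaults mirror the simulated invasion scenarios: growth costs of CRISPR
#' carriage (`V_C`, `V_CR` below `V_N`), equal adsorption to `N` and `C`, and
#' equal burst sizes on all hosts. `m` is the probability that a phage
#' infection of `C` is aborted and yields an immune `C_R` cell; `v` is the
#' per-hour rate of immunity loss `C_R -> C`; `mu` the mutation rate
#' `N -> N_R` (per division when `mu_growth_coupled`, else per hour).
#'
#' @param V_N,V_NR,V_C,V_CR Maximum growth rates (hr^-1).
#' @param delta_N,delta_C Adsorption rate constants of phage to `N` and `C`
#'   (ml per phage per cell per hour).
#' @param delta_MIN,delta_MAX Minimum and maximum effective adsorption/killing
#'   rates of phage on immune `C_R` cells; phage are removed by adsorption to
#'   `C_R` at `delta_MAX` regardless of MOI.
#' @param x Magnitude of the MOI effect, in \[0, 1\]; `x = 0` means immunity is
#'   never overridden.
#' @param q MOI at which the effective adsorption rate is half its maximum.
#' @param n Hill exponent shaping the MOI response.
#' @param beta_N,beta_C,beta_CR Burst sizes (phage per lysed cell, net of the
#'   adsorbed particle).
#' @param mu Mutation rate `N -> N_R`.
#' @param m Probability an infection of `C` is aborted, producing `C_R`.
#' @param v Rate of immunity loss `C_R -> C` (hr^-1).
#' @param mu_growth_coupled If `TRUE` (default) mutation is per division,
#'   entering as `mu * psi_N * N`; if `FALSE`, a constant per-hour rate
#'   `mu * N`.
#'
#' @return An object of class `phage_params`.
#' @export
phage_params <- function(V_N = 1.0, V_NR = 0.85, V_C = 0.95, V_CR = 0.90,
                         delta_N = 5e-9, delta_C = 5e-9,
                         delta_MIN = 1e-14, delta_MAX = 5e-9,
                         x = 0, q = 1e2, n = 2,
                         beta_N = 150, beta_C = 150, beta_CR = 150,
                         mu = 1e-8, m = 0.1, v = 1e-3,
                         mu_growth_coupled = TRUE) {
  p <- list(V_N = V_N, V_NR = V_NR, V_C = V_C, V_CR = V_CR,
            delta_N = delta_N, delta_C = delta_C,
            delta_MIN = delta_MIN, delta_MAX = delta_MAX,
            x = x, q = q, n = n,
            beta_N = beta_N, beta_C = beta_C, beta_CR = beta_CR,
            mu = mu, m = m, v = v,
            mu_growth_coupled = isTRUE(mu_growth_coupled))
  num <- unlist(p[setdiff(names(p), "mu_growth_coupled")])
  if (any(!is.finite(num)) || any(num < 0))
    stop("all phage model parameters must be finite and nonnegative")
  if (x > 1) stop("'x' must lie in [0, 1]")
  if (m > 1) stop("'m' must lie in [0, 1]")
  if (delta_MIN > delta_MAX) stop("'delta_MIN' must not exceed 'delta_MAX'")
  structure(p, class = "phage_params")
}

#' Parameter set for the conjugative-plasmid model
#'
#' Parameterizes the five-population plasmid model: plasmid-free and
#' plasmid-bearing non-CRISPR cells `N`, `N_P`; plasmid-free and
#' plasmid-bearing CRISPR cells `C`, `C_P`; and `C_X`, CRISPR cells carrying
#' plasmid-derived spacer sequences that make them fully immune to receipt of
#' the plasmid. Conjugation is mass action with donor-recipient specific rate
#' constants `gamma_NN` (`N_P` donor to `N`), `gamma_NC` (`N_P` to `C`),
#' `gamma_CN` (`C_P` to `N`) and `gamma_CC` (`C_P` to `C`). A fraction `m` of
#' transfers into `C` abort and immunize the recipient directly to `C_X`.
#' Plasmids segregate vegetatively at per-hour rates `tau_N` (`N_P -> N`) and
#' `tau_C` (`C_P -> C`); `C_X` loses its plasmid-immunity region at rate `v`
#' (`C_X -> C`); and the CRISPR element itself is lost at rate `z`
#' (`C -> N`, `C_P -> N_P`). `C_X` carries no complete plasmid and is not a
#' conjugation donor.
#'
#' @param V_N,V_NP,V_C,V_CP,V_X Maximum growth rates (hr^-1).
#' @param gamma_NN,gamma_NC,gamma_CN,gamma_CC Conjugational transfer rate
#'   constants (ml per cell per hour).
#' @param tau_N,tau_C Vegetative segregation rates (hr^-1).
#' @param m Probability a transfer into `C` yields immune `C_X`, in \[0, 1\].
#' @param v Immunity-loss rate `C_X -> C` (hr^-1).
#' @param z CRISPR-loss rate `C -> N` and `C_P -> N_P` (hr^-1).
#' @param z_includes_CX If `TRUE`, `C_X` also loses the CRISPR element at rate
#'   `z`, becoming `N`. Default `FALSE`.
#'
#' @return An object of class `plasmid_params`.
#' @export
plasmid_params <- function(V_N = 1.0, V_NP = 0.95, V_C = 0.97, V_CP = 0.88,
                           V_X = 0.96,
                           gamma_NN = 1e-9, gamma_NC = 1e-9,
                           gamma_CN = 1e-9, gamma_CC = 1e-9,
                           tau_N = 1e-3, tau_C = 1e-3,
                           m = 0.2, v = 1e-3, z = 1e-8,
                           z_includes_CX = FALSE) {
  p <- list(V_N = V_N, V_NP = V_NP, V_C = V_C, V_CP = V_CP, V_X = V_X,
            gamma_NN = gamma_NN, gamma_NC = gamma_NC,
            gamma_CN = gamma_CN, gamma_CC = gamma_CC,
            tau_N = tau_N, tau_C = tau_C,
            m = m, v = v, z = z,
            z_includes_CX = isTRUE(z_includes_CX))
  num <- unlist(p[setdiff(names(p), "z_includes_CX")])
  if (any(!is.finite(num)) || any(num < 0))
    stop("all plasmid model parameters must be finite and nonnegative")
  if (m > 1) stop("'m' must lie in [0, 1]")
  structure(p, class = "plasmid_params")
}

#' @export
print.phage_params <- function(x, ...) {
  cat("Phage model parameters (populations N, N_R, C, C_R, P)\n")
  cat(sprintf("  V: N=%g N_R=%g C=%g C_R=%g /hr\n", x$V_N, x$V_NR, x$V_C, x$V_CR))
  cat(sprintf("  delta_N=%g delta_C=%g; C_R range [%g, %g], x=%g q=%g n=%g\n",
              x$delta_N, x$delta_C, x$delta_MIN, x$delta_MAX, x$x, x$q, x$n))
  cat(sprintf("  beta: N=%g C=%g C_R=%g; mu=%g m=%g v=%g\n",
              x$beta_N, x$beta_C, x$beta_CR, x$mu, x$m, x$v))
  invisible(x)
}

#' @export
print.plasmid_params <- function(x, ...) {
  cat("Plasmid model parameters (populations N, N_P, C, C_P, C_X)\n")
  cat(sprintf("  V: N=%g N_P=%g C=%g C_P=%g C_X=%g /hr\n",
              x$V_N, x$V_NP, x$V_C, x$V_CP, x$V_X))
  cat(sprintf("  gamma: NN=%g NC=%g CN=%g CC=%g ml/cell/hr\n",
              x$gamma_NN, x$gamma_NC, x$gamma_CN, x$gamma_CC))
  cat(sprintf("  tau_N=%g tau_C=%g; m=%g v=%g z=%g\n",
              x$tau_N, x$tau_C, x$m, x$v, x$z))
  invisible(x)
}

#' Initial state for the phage model
#'
#' @param N,N_R,C,C_R Bacterial densities (cells/ml).
#' @param P Free-phage density (particles/ml).
#' @param R Resource concentration (µg/ml).
#' @return Named numeric vector in roster order `N, N_R, C, C_R, P, R`.
#' @export
phage_state <- function(N = 0, N_R = 0, C = 0, C_R = 0, P = 0, R = 0) {
  s <- c(N = N, N_R = N_R, C = C, C_R = C_R, P = P, R = R)
  if (any(!is.finite(s)) || any(s < 0))
    stop("all densities and the resource concentration must be finite and >= 0")
  s
}

#' Initial state for the plasmid model
#'
#' @param N,N_P,C,C_P,C_X Bacterial densities (cells/ml).
#' @param R Resource concentration (µg/ml).
#' @return Named numeric vector in roster order `N, N_P, C, C_P, C_X, R`.
#' @export
plasmid_state <- function(N = 0, N_P = 0, C = 0, C_P = 0, C_X = 0, R = 0) {
  s <- c(N = N, N_P = N_P, C = C, C_P = C_P, C_X = C_X, R = R)
  if (any(!is.finite(s)) || any(s < 0))
    stop("all densities and the resource concentration must be finite and >= 0")
  s
}

phage_roster   <- c("N", "N_R", "C", "C_R", "P")
plasmid_roster <- c("N", "N_P", "C", "C_P", "C_X")
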
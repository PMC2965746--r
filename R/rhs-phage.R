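#' Multiplicity of infection
#'
#' Ratio of free phage to immune CRISPR cells, `M = P / C_R`. To keep the MOI
#' finite (and the `C_R` killing term smooth) as `C_R -> 0`, the denominator
#' is floored at `eps` (1 cell/ml by default): below `eps` the MOI takes its
#' value at `C_R = eps`.
#'
#' @param P Free-phage density (particles/ml), >= 0.
#' @param C_R Immune CRISPR cell density (cells/ml), >= 0.
#' @param eps Guard density (cells/ml) flooring the denominator.
#' @return The multiplicity of infection (dimensionless).
#' @export
moi <- function(P, C_R, eps = 1) {
  if (any(P < 0) || any(C_R < 0)) stop("'P' and 'C_R' must be nonnegative")
  P / pmax(C_R, eps)
}

#' MOI-dependent effective adsorption/killing rate on immune CRISPR cells
#'
#' At low multiplicity of infection immune CRISPR cells abort phage infections
#' and are effectively resistant; at high MOI the immune machinery is
#' overwhelmed and the phage replicate and kill. The effective rate constant
#' interpolates between `delta_MIN` and `delta_MIN + x * (delta_MAX -
#' delta_MIN)` as a Hill function of MOI:
#'
#' \deqn{\delta_{CR}(M) = \delta_{MIN} + x\,(\delta_{MAX}-\delta_{MIN})
#'   \frac{M^n}{q^n + M^n}}
#'
#' It is monotone nondecreasing in `M`, equals `delta_MIN` at `M = 0` (and for
#' all `M` when `x = 0`), and is half way up its range at `M = q`.
#'
#' @param M Multiplicity of infection, >= 0. May be a vector.
#' @param params A [phage_params()] supplying `delta_MIN`, `delta_MAX`, `x`,
#'   `q`, `n`.
#' @return Effective adsorption rate constant(s), same units as `delta_N`.
#' @export
effective_adsorption <- function(M, params) {
  stopifnot(inherits(params, "phage_params"))
  if (any(M < 0)) stop("'M' must be nonnegative")
  Mn <- M^params$n
  hill <- ifelse(M == 0, 0, Mn / (params$q^params$n + Mn))
  params$delta_MIN + params$x * (params$delta_MAX - params$delta_MIN) * hill
}

#' Time derivatives of the lytic-phage model
#'
#' Evaluates the right-hand side of the phage model at one state. With
#' `psi_i = monod_growth(V_i, k, R)` and `dCR = effective_adsorption(moi(P,
#' C_R), params)`:
#'
#' \preformatted{
#' dN/dt   = psi_N N (1 - mu) - delta_N N P - w N
#' dN_R/dt = psi_NR N_R + mu psi_N N - w N_R
#' dC/dt   = psi_C C - delta_C C P + v C_R - w C
#' dC_R/dt = psi_CR C_R + m delta_C C P - dCR C_R P - v C_R - w C_R
#' dP/dt   = beta_N delta_N N P + beta_C (1-m) delta_C C P - m delta_C C P
#'           + beta_CR dCR C_R P - delta_MAX C_R P - w P
#' dR/dt   = w (A - R) - e (psi_N N + psi_NR N_R + psi_C C + psi_CR C_R)
#' }
#'
#' Envelope-resistant `N_R` cells are never adsorbed. Aborted infections of
#' `C` (fraction `m`) consume the adsorbed phage; for productive infections
#' the adsorbed particle is already netted out of the burst sizes. Phage are
#' removed by adsorption to `C_R` at the full `delta_MAX` even when the
#' killing of `C_R` runs at the lower MOI-dependent rate. Every adsorption
#' term `delta * host * P` is switched off while that host population is
#' below `env$refuge_density` (the low-density refuge that bounds
#' predator-prey oscillations).
#'
#' @param state Named numeric vector from [phage_state()] (`N, N_R, C, C_R,
#'   P, R`). Negative entries are treated as 0.
#' @param params A [phage_params()].
#' @param env A [chemostat_env()].
#' @return Named numeric vector of time derivatives, same order as `state`.
#' @export
phage_rhs <- function(state, params, env) {
  stopifnot(inherits(params, "phage_params"), inherits(env, "chemostat_env"))
  s <- pmax(state[c(phage_roster, "R")], 0)
  if (any(is.na(s))) stop("state must contain N, N_R, C, C_R, P, R")
  N <- s[["N"]]; N_R <- s[["N_R"]]; C <- s[["C"]]; C_R <- s[["C_R"]]
  P <- s[["P"]]; R <- s[["R"]]
  p <- params; w <- env$w

  psi_N  <- monod_growth(p$V_N,  env$k, R)
  psi_NR <- monod_growth(p$V_NR, env$k, R)
  psi_C  <- monod_growth(p$V_C,  env$k, R)
  psi_CR <- monod_growth(p$V_CR, env$k, R)

  # refuge: hosts below refuge_density are not adsorbed. The switch is a
  # steep smooth sigmoid rather than a hard indicator: a discontinuous
  # switch makes the protected boundary a sliding surface (host densities
  # chatter on it and variable-step solvers stall).
  in_reach <- function(host) refuge_factor(host, env$refuge_density)
  adsN  <- p$delta_N * N * P * in_reach(N)
  adsC  <- p$delta_C * C * P * in_reach(C)
  dCR   <- effective_adsorption(moi(P, C_R), p)
  killCR <- dCR * C_R * P * in_reach(C_R)
  sinkCR <- p$delta_MAX * C_R * P * in_reach(C_R)

  mut <- if (p$mu_growth_coupled) p$mu * psi_N * N else p$mu * N

  c(
    N   = psi_N * N - mut - adsN - w * N,
    N_R = psi_NR * N_R + mut - w * N_R,
    C   = psi_C * C - adsC + p$v * C_R - w * C,
    C_R = psi_CR * C_R + p$m * adsC - killCR - p$v * C_R - w * C_R,
    P   = p$beta_N * adsN + p$beta_C * (1 - p$m) * adsC - p$m * adsC +
          p$beta_CR * killCR - sinkCR - w * P,
    R   = resource_flux(env, R,
                        c(psi_N, psi_NR, psi_C, psi_CR),
                        c(N, N_R, C, C_R))
  )
}
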
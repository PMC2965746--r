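#' Time derivatives of the conjugative-plasmid model
#'
#' Evaluates the right-hand side of the plasmid model at one state. With
#' `psi_i = monod_growth(V_i, k, R)` and the mass-action transfer fluxes
#' `T_N = (gamma_NN N_P + gamma_CN C_P) N` (into `N`) and
#' `T_C = (gamma_NC N_P + gamma_CC C_P) C` (into `C`):
#'
#' \preformatted{
#' dN/dt   = psi_N N - T_N + tau_N N_P + z C - w N
#' dN_P/dt = psi_NP N_P + T_N - tau_N N_P + z C_P - w N_P
#' dC/dt   = psi_C C - T_C + tau_C C_P + v C_X - z C - w C
#' dC_P/dt = psi_CP C_P + (1 - m) T_C - tau_C C_P - z C_P - w C_P
#' dC_X/dt = psi_X C_X + m T_C - v C_X - w C_X
#' dR/dt   = w (A - R) - e * sum(psi_i X_i)
#' }
#'
#' A fraction `m` of plasmid transfers into `C` (from either donor type)
#' abort and immunize the recipient directly to `C_X`; `C_X` is immune to
#' receipt, carries no complete plasmid, and donates nothing. Segregation
#' (`tau`), immunity loss (`v`) and CRISPR loss (`z`) are constant per-hour
#' rates. If `params$z_includes_CX` is set, `C_X` additionally loses the
#' CRISPR element at rate `z` and becomes `N`.
#'
#' @param state Named numeric vector from [plasmid_state()] (`N, N_P, C,
#'   C_P, C_X, R`). Negative entries are treated as 0.
#' @param params A [plasmid_params()].
#' @param env A [chemostat_env()].
#' @return Named numeric vector of time derivatives, same order as `state`.
#' @export
plasmid_rhs <- function(state, params, env) {
  stopifnot(inherits(params, "plasmid_params"), inherits(env, "chemostat_env"))
  s <- pmax(state[c(plasmid_roster, "R")], 0)
  if (any(is.na(s))) stop("state must contain N, N_P, C, C_P, C_X, R")
  N <- s[["N"]]; N_P <- s[["N_P"]]; C <- s[["C"]]; C_P <- s[["C_P"]]
  C_X <- s[["C_X"]]; R <- s[["R"]]
  p <- params; w <- env$w

  psi_N  <- monod_growth(p$V_N,  env$k, R)
  psi_NP <- monod_growth(p$V_NP, env$k, R)
  psi_C  <- monod_growth(p$V_C,  env$k, R)
  psi_CP <- monod_growth(p$V_CP, env$k, R)
  psi_X  <- monod_growth(p$V_X,  env$k, R)

  T_N <- (p$gamma_NN * N_P + p$gamma_CN * C_P) * N
  T_C <- (p$gamma_NC * N_P + p$gamma_CC * C_P) * C

  zX <- if (p$z_includes_CX) p$z * C_X else 0

  c(
    N   = psi_N * N - T_N + p$tau_N * N_P + p$z * C + zX - w * N,
    N_P = psi_NP * N_P + T_N - p$tau_N * N_P + p$z * C_P - w * N_P,
    C   = psi_C * C - T_C + p$tau_C * C_P + p$v * C_X - p$z * C - w * C,
    C_P = psi_CP * C_P + (1 - p$m) * T_C - p$tau_C * C_P - p$z * C_P - w * C_P,
    C_X = psi_X * C_X + p$m * T_C - p$v * C_X - zX - w * C_X,
    R   = resource_flux(env, R,
                        c(psi_N, psi_NP, psi_C, psi_CP, psi_X),
                        c(N, N_P, C, C_P, C_X))
  )
}
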
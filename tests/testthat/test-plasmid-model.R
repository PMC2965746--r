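test_that("without CRISPR classes the model collapses to the classic plasmid pair", {
  env <- ref_env()
  p <- plasmid_params(z = 0)
  N <- 1e7; NP <- 1e5; R <- 0.5
  d <- plasmid_rhs(plasmid_state(N = N, N_P = NP, R = R), p, env)
  psiN  <- monod_growth(p$V_N, env$k, R)
  psiNP <- monod_growth(p$V_NP, env$k, R)
  expect_equal(d[["N"]],
               psiN * N - p$gamma_NN * NP * N + p$tau_N * NP - env$w * N,
               tolerance = 1e-12)
  expect_equal(d[["N_P"]],
               psiNP * NP + p$gamma_NN * NP * N - p$tau_N * NP - env$w * NP,
               tolerance = 1e-12)
  expect_equal(d[["C"]], 0)
  expect_equal(d[["C_P"]], 0)
  expect_equal(d[["C_X"]], 0)
})

test_that("with all coupling off the five populations wash out independently", {
  env <- ref_env()
  p <- plasmid_params(gamma_NN = 0, gamma_NC = 0, gamma_CN = 0, gamma_CC = 0,
                      tau_N = 0, tau_C = 0, z = 0, v = 0, m = 0)
  s <- plasmid_state(N = 1e5, N_P = 2e5, C = 3e5, C_P = 4e5, C_X = 5e5, R = 1)
  d <- plasmid_rhs(s, p, env)
  Vs <- c(p$V_N, p$V_NP, p$V_C, p$V_CP, p$V_X)
  for (i in seq_along(Vs)) {
    psi <- monod_growth(Vs[i], env$k, 1)
    expect_equal(d[[i]], (psi - env$w) * s[[i]], tolerance = 1e-12)
  }
})

test_that("one full plasmid RHS evaluation matches an independently coded term-sum oracle", {
  env <- ref_env()
  # deleterious plasmid invading a CRISPR resident
  p <- plasmid_params(V_N = 1.0, V_NP = 0.95, V_C = 0.97, V_CP = 0.88,
                      V_X = 0.96)
  s <- plasmid_state(N = 1e7, N_P = 1e4, C = 9e7, C_P = 0, C_X = 0, R = 0.07)
  d <- plasmid_rhs(s, p, env)

  # oracle: plain arithmetic from scratch
  A <- 50; w <- 0.2; k <- 0.25; e <- 5e-7
  N <- 1e7; NP <- 1e4; C <- 9e7; CP <- 0; CX <- 0; R <- 0.07
  g <- 1e-9; tauN <- 1e-3; tauC <- 1e-3; m <- 0.2; v <- 1e-3; z <- 1e-8
  pN  <- 1.00 * R / (k + R); pNP <- 0.95 * R / (k + R)
  pC  <- 0.97 * R / (k + R); pCP <- 0.88 * R / (k + R)
  pX  <- 0.96 * R / (k + R)
  TN <- (g * NP + g * CP) * N
  TC <- (g * NP + g * CP) * C
  oracle <- c(
    N   = pN * N - TN + tauN * NP + z * C - w * N,
    N_P = pNP * NP + TN - tauN * NP + z * CP - w * NP,
    C   = pC * C - TC + tauC * CP + v * CX - z * C - w * C,
    C_P = pCP * CP + (1 - m) * TC - tauC * CP - z * CP - w * CP,
    C_X = pX * CX + m * TC - v * CX - w * CX,
    R   = w * (A - R) - e * (pN * N + pNP * NP + pC * C + pCP * CP + pX * CX)
  )
  expect_equal(unname(d), unname(oracle), tolerance = 1e-12)
})

test_that("conjugation and segregation move cells within lineages without creating or destroying them", {
  env <- ref_env()
  s <- plasmid_state(N = 1e6, N_P = 1e6, C = 1e6, C_P = 1e6, C_X = 1e6, R = 5)
  crispr_sum <- function(p) {
    d <- plasmid_rhs(s, p, env)
    d[["C"]] + d[["C_P"]] + d[["C_X"]]
  }
  # with z = 0 the CRISPR lineage total changes only through growth and
  # washout: transfer, immunization, segregation and immunity loss all cancel
  base <- crispr_sum(plasmid_params(z = 0))
  expect_equal(crispr_sum(plasmid_params(z = 0, gamma_NN = 0, gamma_NC = 0,
                                         gamma_CN = 0, gamma_CC = 0)),
               base, tolerance = 1e-12)
  expect_equal(crispr_sum(plasmid_params(z = 0, m = 0.9)), base,
               tolerance = 1e-12)
  expect_equal(crispr_sum(plasmid_params(z = 0, tau_C = 0.5, v = 0.5)), base,
               tolerance = 1e-12)
  # likewise the non-CRISPR lineage with z = 0
  noncrispr_sum <- function(p) {
    d <- plasmid_rhs(s, p, env)
    d[["N"]] + d[["N_P"]]
  }
  expect_equal(noncrispr_sum(plasmid_params(z = 0, gamma_NN = 0,
                                            gamma_CN = 0, tau_N = 0)),
               noncrispr_sum(plasmid_params(z = 0)), tolerance = 1e-12)
})

test_that("plasmid trajectories stay nonnegative under random parameter draws", {
  set.seed(11)
  env <- ref_env()
  for (i in 1:5) {
    p <- plasmid_params(V_N = stats::runif(1, 0.9, 1.1),
                        V_NP = stats::runif(1, 0.8, 1.2),
                        V_C = stats::runif(1, 0.85, 1.05),
                        V_CP = stats::runif(1, 0.8, 1.15),
                        V_X = stats::runif(1, 0.85, 1.05),
                        gamma_NN = 10^stats::runif(1, -11, -9),
                        gamma_NC = 10^stats::runif(1, -11, -9),
                        gamma_CN = 10^stats::runif(1, -11, -9),
                        gamma_CC = 10^stats::runif(1, -11, -9),
                        tau_N = 10^stats::runif(1, -4, -2.3),
                        tau_C = 10^stats::runif(1, -4, -2.3),
                        m = stats::runif(1, 0.01, 0.3))
    tr <- simulate_plasmid(p, env,
                           plasmid_state(N = 1e7, N_P = 1e3, C = 1e7,
                                         C_P = 10, C_X = 10, R = env$A),
                           t_end = 100, report_dt = 2)
    expect_true(all(is.finite(tr$state)))
    expect_true(all(tr$state >= 0))
  }
})
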
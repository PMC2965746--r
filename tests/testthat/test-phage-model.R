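test_that("MOI is the phage:target ratio, guarded near zero targets", {
  expect_equal(moi(0, 1e5), 0)
  expect_equal(moi(1e7, 1e5), 100)
  # guard: vanishing C_R returns the value at the guard density, no blow-up
  expect_equal(moi(1e7, 0), 1e7)
  expect_true(is.finite(moi(1e7, 0)))
  expect_error(moi(-1, 1), "nonnegative")
})

test_that("MOI-dependent adsorption interpolates delta_MIN..delta_MAX as a Hill curve", {
  p <- phage_params(delta_MIN = 1e-14, delta_MAX = 5e-9, x = 0.5, q = 1e2, n = 2)
  # no phage pressure: fully immune
  expect_equal(effective_adsorption(0, p), p$delta_MIN)
  # at M = q the Hill term is 1/2, so the rate sits a quarter of the way up
  # the full range when x = 0.5 (independent arithmetic)
  expect_equal(effective_adsorption(1e2, p),
               1e-14 + 0.5 * (5e-9 - 1e-14) * 0.5, tolerance = 1e-12)
  expect_equal(effective_adsorption(1e2, p), 1.25e-9, tolerance = 1e-4)
  # saturation limit
  expect_equal(effective_adsorption(1e12, p),
               p$delta_MIN + p$x * (p$delta_MAX - p$delta_MIN),
               tolerance = 1e-6)
  # x = 0 switches the MOI effect off entirely
  p0 <- phage_params(x = 0)
  M <- c(0, 1, 1e2, 1e6, 1e12)
  expect_equal(effective_adsorption(M, p0), rep(p0$delta_MIN, length(M)))
})

test_that("effective adsorption is monotone nondecreasing in MOI for random parameter draws", {
  set.seed(42)
  for (i in 1:25) {
    p <- phage_params(delta_MIN = 10^stats::runif(1, -15, -10),
                      delta_MAX = 10^stats::runif(1, -10, -8),
                      x = stats::runif(1), q = 10^stats::runif(1, 0, 4),
                      n = stats::runif(1, 0.5, 4))
    M <- sort(10^stats::runif(50, -3, 8))
    expect_true(all(diff(effective_adsorption(M, p)) >= 0))
  }
})

test_that("phage dynamics without hosts reduce to washout", {
  env <- ref_env()
  p <- phage_params()
  d <- phage_rhs(phage_state(P = 1e6, R = 10), p, env)
  expect_equal(d[["P"]], -env$w * 1e6)
  expect_equal(d[["R"]], env$w * (env$A - 10))
  expect_equal(d[["N"]], 0)
})

test_that("with no CRISPR, resistance or immunity the model collapses to the classic bacteria-phage pair", {
  env <- ref_env()
  p <- phage_params(mu = 0, m = 0, v = 0)
  N <- 1e7; P <- 1e6; R <- 2
  d <- phage_rhs(phage_state(N = N, P = P, R = R), p, env)
  psi <- monod_growth(p$V_N, env$k, R)
  expect_equal(d[["N"]], psi * N - p$delta_N * N * P - env$w * N,
               tolerance = 1e-12)
  expect_equal(d[["P"]], p$beta_N * p$delta_N * N * P - env$w * P,
               tolerance = 1e-12)
  expect_equal(d[["N_R"]], 0)
  expect_equal(d[["C"]], 0)
  expect_equal(d[["C_R"]], 0)
})

test_that("one full phage RHS evaluation matches an independently coded term-sum oracle", {
  env <- ref_env()
  # strong-MOI invasion scenario parameters
  p <- phage_params(V_N = 1.0, V_C = 0.95, V_CR = 0.90,
                    delta_N = 5e-9, delta_C = 5e-9,
                    delta_MIN = 1e-14, delta_MAX = 5e-9,
                    x = 0.5, n = 2, q = 1e2, mu = 0)
  s <- phage_state(N = 1e7, N_R = 0, C = 1e6, C_R = 1e6, P = 1e7, R = 1)
  d <- phage_rhs(s, p, env)

  # oracle: every term written out from scratch, plain arithmetic only
  A <- 50; w <- 0.2; k <- 0.25; e <- 5e-7; rho <- 100
  N <- 1e7; NR <- 0; C <- 1e6; CR <- 1e6; P <- 1e7; R <- 1
  pN  <- 1.0  * R / (k + R)
  pNR <- 0.85 * R / (k + R)
  pC  <- 0.95 * R / (k + R)
  pCR <- 0.90 * R / (k + R)
  reach <- function(h) (h / rho)^4 / (1 + (h / rho)^4)
  M <- P / max(CR, 1)
  dCR_rate <- 1e-14 + 0.5 * (5e-9 - 1e-14) * M^2 / (1e2^2 + M^2)
  aN <- 5e-9 * N * P * reach(N)
  aC <- 5e-9 * C * P * reach(C)
  kCR <- dCR_rate * CR * P * reach(CR)
  sCR <- 5e-9 * CR * P * reach(CR)
  mut <- 0 * pN * N
  oracle <- c(
    N   = pN * N - mut - aN - w * N,
    N_R = pNR * NR + mut - w * NR,
    C   = pC * C - aC + 1e-3 * CR - w * C,
    C_R = pCR * CR + 0.1 * aC - kCR - 1e-3 * CR - w * CR,
    P   = 150 * aN + 150 * 0.9 * aC - 0.1 * aC + 150 * kCR - sCR - w * P,
    R   = w * (A - R) - e * (pN * N + pNR * NR + pC * C + pCR * CR)
  )
  expect_equal(unname(d), unname(oracle), tolerance = 1e-12)
})

test_that("nonnegativity: phage trajectories stay nonnegative under random parameter draws", {
  set.seed(7)
  env <- ref_env()
  for (i in 1:5) {
    p <- phage_params(V_N = stats::runif(1, 0.8, 1.2),
                      V_NR = stats::runif(1, 0.6, 1.0),
                      V_C = stats::runif(1, 0.7, 1.1),
                      V_CR = stats::runif(1, 0.7, 1.1),
                      delta_N = 10^stats::runif(1, -9.5, -8.3),
                      delta_C = 10^stats::runif(1, -9.5, -8.3),
                      x = stats::runif(1), m = stats::runif(1, 0.01, 0.3),
                      beta_N = stats::runif(1, 30, 200),
                      beta_C = stats::runif(1, 30, 200),
                      beta_CR = stats::runif(1, 30, 200))
    tr <- simulate_phage(p, env,
                         phage_state(N = 1e7, N_R = 10, C = 1e4, C_R = 10,
                                     P = 1e5, R = env$A),
                         t_end = 60, report_dt = 1)
    expect_true(all(is.finite(tr$state)))
    expect_true(all(tr$state >= 0))
  }
})
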
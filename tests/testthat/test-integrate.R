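test_that("a lone bacterial population settles on the closed-form chemostat equilibrium", {
  env <- ref_env()
  p <- phage_params(mu = 0, m = 0)
  tr <- simulate_phage(p, env, phage_state(N = 1e3, R = env$A), t_end = 300)
  fin <- tr$state[nrow(tr$state), ]
  expect_equal(fin[["N"]], bacterial_equilibrium(env, p$V_N), tolerance = 1e-3)
  expect_equal(fin[["R"]], resource_equilibrium(p$V_N, env$k, env$w),
               tolerance = 1e-3)
})

test_that("a sterile vessel relaxes to the reservoir concentration", {
  env <- ref_env()
  tr <- simulate_phage(phage_params(), env, phage_state(R = 1), t_end = 120)
  expect_equal(unname(tr$state[nrow(tr$state), "R"]), env$A, tolerance = 1e-6)
  expect_true(all(tr$state[, c("N", "N_R", "C", "C_R", "P")] == 0))
})

test_that("trajectories start at the initial condition with strictly increasing times", {
  env <- ref_env()
  init <- phage_state(N = 1e6, C = 1e3, P = 1e4, R = 2)
  tr <- simulate_phage(phage_params(), env, init, t_end = 10)
  expect_equal(tr$state[1, ], init[colnames(tr$state)])
  expect_equal(tr$time[1], 0)
  expect_true(all(diff(tr$time) > 0))
})

test_that("phage initialized below the loss threshold are zeroed immediately", {
  env <- ref_env()
  tr <- simulate_phage(phage_params(), env,
                       phage_state(N = 1e6, P = 0.05, R = env$A), t_end = 10)
  expect_equal(tr$events$event, "phage_extinct")
  expect_equal(tr$events$time, 0)
  expect_true(all(tr$state[, "P"] == 0))
})

test_that("phage crossing the loss threshold mid-run are zeroed from the event onward", {
  env <- ref_env()
  # no hosts: P declines by washout alone, crossing 0.1/ml at t = ln(100)/w
  tr <- simulate_phage(phage_params(), env, phage_state(P = 10, R = env$A),
                       t_end = 40)
  expect_equal(nrow(tr$events), 1)
  expect_equal(tr$events$event, "phage_extinct")
  expect_equal(tr$events$time, log(10 / 0.1) / env$w, tolerance = 0.05)
  after <- tr$time >= tr$events$time
  expect_true(all(tr$state[after, "P"] == 0))
  expect_gt(tr$state[1, "P"], 0)
})

test_that("populations growing slower than the dilution rate wash out", {
  env <- chemostat_env(w = 1.2)  # exceeds every maximum growth rate below
  p <- phage_params(V_N = 1.0, V_NR = 0.85, V_C = 0.95, V_CR = 0.90)
  tr <- simulate_phage(p, env,
                       phage_state(N = 1e7, N_R = 1e6, C = 1e6, C_R = 1e6,
                                   R = env$A),
                       t_end = 50 / env$w)
  fin <- tr$state[nrow(tr$state), ]
  expect_lt(sum(fin[c("N", "N_R", "C", "C_R")]), 0.01 * 1e7)
  expect_equal(fin[["R"]], env$A, tolerance = 0.01)
})

test_that("halving solver tolerances leaves final states essentially unchanged", {
  cfg <- preset("fig4a")
  obj <- config_objects(cfg)
  tr1 <- simulate_phage(obj$params, obj$env, obj$initial, t_end = 150)
  tr2 <- simulate_phage(obj$params, obj$env, obj$initial, t_end = 150,
                        rtol = 5e-9, atol = 5e-11)
  f1 <- tr1$state[nrow(tr1$state), ]
  f2 <- tr2$state[nrow(tr2$state), ]
  live <- f1 > 1
  expect_true(all(rel_diff(f2[live], f1[live]) < 1e-3))
})

test_that("stiff and non-stiff solvers agree on the bacteria-phage limit cycle", {
  cfg <- preset("fig4a")
  obj <- config_objects(cfg)
  tr1 <- simulate_phage(obj$params, obj$env, obj$initial, t_end = 150)
  tr2 <- simulate_phage(obj$params, obj$env, obj$initial, t_end = 150,
                        method = "ode45")
  f1 <- tr1$state[nrow(tr1$state), ]
  f2 <- tr2$state[nrow(tr2$state), ]
  live <- f1 > 1
  expect_true(all(rel_diff(f2[live], f1[live]) < 5e-3))
})

test_that("trajectory export writes t, R, populations and event flags", {
  env <- ref_env()
  tr <- simulate_phage(phage_params(), env, phage_state(P = 10, R = env$A),
                       t_end = 40)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  df <- utils::read.csv(f)
  expect_equal(names(df),
               c("t", "R", "N", "N_R", "C", "C_R", "P", "phage_extinct"))
  expect_equal(nrow(df), length(tr$time))
  expect_true(all(df$phage_extinct %in% 0:1))
  expect_equal(sum(df$phage_extinct == 0),
               sum(tr$time < tr$events$time))
  unlink(f)
})
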
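test_that("growth-stop time follows the closed form and the consumption identity", {
  p <- crm_params(0.1, 0.05, 2, gamma = 4)
  ts <- growth_stop_time(p)
  expect_equal(ts, log(3) / 4, tolerance = 1e-12)
  # cumulative consumption at t* equals the limiting resource
  expect_equal(p$x0_tilde * (exp(p$gamma * ts) - 1) / p$gamma,
               min(p$A0, p$C0_tilde), tolerance = 1e-12)

  p2 <- crm_params(0.001, 2, 2, gamma = 4)
  expect_equal(growth_stop_time(p2), log(8001) / 4, tolerance = 1e-12)
  # nitrate is nearly exhausted at t* when it is the limiting resource
  # (the ODE lags the leading-order clock slightly when both resources
  # deplete together, so "nearly" means within 10% of the input)
  A_at_tstar <- crm_simulate(p2, c(0, growth_stop_time(p2)),
                             method = "ode")$A[2L]
  expect_lt(A_at_tstar, 0.1 * p2$A0)

  expect_equal(growth_stop_time(crm_params(0.1, 0, 2, gamma = 4)), 0)
  expect_warning(ts0 <- growth_stop_time(crm_params(0, 1, 2, gamma = 4)),
                 "no growth")
  expect_identical(ts0, Inf)
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(crm_params(-0.1, 1, 2), "non-negative")
  expect_error(crm_params(0.1, 1, 2, KA = 0), "strictly positive")
  expect_error(crm_params(0.1, NA, 2), "finite")
  p <- crm_params(0.1, 1, 2)
  expect_error(crm_simulate(p, c(0, 1, 1)), "strictly increasing")
  expect_error(crm_simulate(p, c(-1, 0, 1)), "non-negative")
})

test_that("numeric solver matches an independent fine-step Euler oracle", {
  for (p in list(crm_params(0.1, 0.05, 2, gamma = 4),
                 crm_params(0.01, 0.5, 2, gamma = 4.8))) {
    for (chl in c(FALSE, TRUE)) {
      A_ode <- crm_simulate(p, grid_days, chl = chl, method = "ode")$A
      A_eul <- euler_nitrate(p, grid_days, chl = chl)
      expect_equal(A_ode, A_eul, tolerance = 1e-3)
    }
  }
})

test_that("growth-arrested (CHL+) nitrate declines linearly at rate x0_tilde", {
  p <- crm_params(0.1, 0.05, 2, gamma = 4)
  tr <- crm_simulate(p, grid_days, chl = TRUE, method = "ode")
  keep <- tr$A > 10 * p$KA
  expect_equal(tr$A[keep], 2 - 0.1 * tr$time[keep], tolerance = 1e-3)
  expect_true(all(tr$x_tilde == p$x0_tilde))
})

test_that("zero biomass means no nitrate consumption", {
  p <- crm_params(0, 0.5, 2)
  for (m in c("ode", "analytic"))
    expect_equal(crm_simulate(p, grid_days, method = m)$A, rep(2, 10))
})

test_that("closed form matches the ODE within 1% of A0 on the reference scenarios", {
  for (p in reference_scenarios()) {
    A_ode <- crm_simulate(p, grid_days, method = "ode")$A
    A_ana <- crm_simulate(p, grid_days, method = "analytic")$A
    expect_lt(max(abs(A_ode - A_ana)), 0.01 * p$A0)
  }
})

test_that("exponential depletion scenario exhausts nitrate near t*", {
  p <- crm_params(0.001, 2, 2, gamma = 4)
  ts <- growth_stop_time(p)
  tt <- sort(unique(c(grid_days, ts * c(0.9, 1, 1.1))))
  A <- crm_simulate(p, tt, method = "ode")$A
  expect_gt(A[which.min(abs(tt - 0.9 * ts))], 0.3)   # still falling
  expect_lt(A[which.min(abs(tt - 1.1 * ts))], 0.05)  # gone just after t*
})

test_that("late-time nitrate slope after t* equals gamma*C0 + x0", {
  p <- crm_params(0.05, 0.3, 2, gamma = 4.8)
  ts <- growth_stop_time(p)
  t_end <- ts + (p$A0 - p$C0_tilde) / (p$gamma * p$C0_tilde + p$x0_tilde)
  tt <- seq(ts * 1.05, min(t_end * 0.95, ts * 3), length.out = 12)
  A <- crm_simulate(p, c(0, tt), method = "ode")$A[-1L]
  slope <- coef(lm(A ~ tt))[[2L]]
  expect_equal(-slope, p$gamma * p$C0_tilde + p$x0_tilde, tolerance = 0.02)
})

test_that("gamma = 0 reduces the growing arm to the growth-arrested solution", {
  p <- crm_params(0.2, 0.5, 2, A0c = 2, gamma = 0)
  A_minus <- crm_simulate(p, grid_days, chl = FALSE, method = "analytic")$A
  A_plus <- crm_simulate(p, grid_days, chl = TRUE, method = "analytic")$A
  expect_equal(A_minus, A_plus, tolerance = 1e-12)
})

test_that("trajectories are monotone and non-negative over random parameters", {
  set.seed(101)
  for (i in 1:100) {
    p <- crm_params(x0_tilde = 10^runif(1, -4, 0),
                    C0_tilde = 10^runif(1, -3, 0.5),
                    A0 = runif(1, 1, 3), gamma = runif(1, 0, 6))
    m <- if (i %% 2) "ode" else "analytic"
    tr <- crm_simulate(p, grid_days, chl = i %% 3 == 0, method = m)
    expect_true(all(diff(tr$A) <= 1e-8))
    expect_true(all(tr$A >= 0) && all(tr$C_tilde >= 0) &&
                all(tr$x_tilde >= 0))
  }
})

test_that("trajectory CSV round-trip preserves values and units", {
  p <- crm_params(0.1, 0.05, 2, gamma = 4)
  tr <- crm_simulate(p, grid_days, chl = TRUE)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$time, tr$time, tolerance = 1e-12)
  expect_equal(tr2$A, tr$A, tolerance = 1e-12)
  expect_true(attr(tr2, "chl"))
  unlink(f)
})
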
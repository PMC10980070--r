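test_that("the loss reproduces hand-computed arithmetic", {
  # linear curves (gamma = 0, tiny affinities) so model values are exact:
  # model A = 2 - 0.1 t at t = 0, 5, 10, 15 -> 2, 1.5, 1.0, 0.5
  p <- crm_params(0.1, 5, 2, gamma = 0, KA = 1e-9, KC_tilde = 1e-9)
  tt <- c(0, 5, 10, 15)
  model <- c(2, 1.5, 1.0, 0.5)
  data <- model + c(0, 0.1, -0.1, 0)
  pair <- sample_pair(tt, data, tt, data)
  # L = (1/(2*4)) * 2 * (0.01 + 0.01) = 0.005
  expect_equal(crm_loss(p, pair), 0.005, tolerance = 1e-6)

  # a constant offset delta on both arms gives L = delta^2
  delta <- 0.2
  pair2 <- sample_pair(tt, pmax(model + delta, 0), tt, pmax(model + delta, 0))
  expect_equal(crm_loss(p, pair2), delta^2, tolerance = 1e-6)

  # evaluated at its own generating parameters the loss vanishes
  pair3 <- make_pair(p, tt, method = "analytic")
  expect_lt(crm_loss(p, pair3), 1e-12)

  # mismatched arm lengths are rejected
  bad <- sample_pair(tt, data, c(0, 5, 10, 15, 20), c(2, 1.5, 1, 0.5, 0))
  expect_error(crm_loss(p, bad), "equal numbers of timepoints")
})

test_that("noiseless parameter recovery is near-exact", {
  truth <- crm_params(0.1, 0.05, 2, gamma = 4.8)
  pair <- make_pair(truth, method = "analytic")
  fit <- crm_fit(pair)
  expect_true(fit$converged)
  expect_equal(coef(fit)[["x0_tilde"]], 0.1, tolerance = 1e-3)
  expect_equal(coef(fit)[["C0_tilde"]], 0.05, tolerance = 1e-3)
  expect_lt(fit$rmse_pct_of_input, 0.05)
})

test_that("flat nitrate in both arms drives the fitted biomass to zero", {
  pair <- sample_pair(grid_days, rep(2, 10), grid_days, rep(2, 10))
  fit <- crm_fit(pair)
  expect_lt(coef(fit)[["x0_tilde"]], 1e-3)
  expect_error(crm_fit(sample_pair(grid_days, rep(0, 10),
                                   grid_days, rep(0, 10))),
               "degenerate")
})

test_that("fits of noisy nutrient-limited data stay within the per-point error contract", {
  truth <- crm_params(0.1, 0.05, 2, gamma = 4.8)
  pair <- make_pair(truth, noise_sd = 0.05, seed = 7)
  fit <- crm_fit(pair)
  # every |residual| below 10% of the 2 mM input
  expect_true(all(fit$per_point_errors < 0.1 * 2))
})

test_that("fitting is deterministic", {
  truth <- crm_params(0.03, 0.4, 2, gamma = 4.8)
  pair <- make_pair(truth, noise_sd = 0.05, seed = 3)
  f1 <- crm_fit(pair)
  f2 <- crm_fit(pair)
  expect_identical(coef(f1), coef(f2))
})

test_that("fit methods expose predictions, residuals and simulation", {
  truth <- crm_params(0.1, 0.3, 2, gamma = 4.8)
  pair <- make_pair(truth, noise_sd = 0.02, seed = 9)
  fit <- crm_fit(pair)
  expect_named(coef(fit), c("x0_tilde", "C0_tilde", "A0", "A0c", "gamma",
                            "KA", "KC_tilde", "gammaC0_tilde"))
  pr <- predict(fit, times = grid_days, chl = TRUE)
  expect_length(pr, 10L)
  expect_true(all(diff(pr) <= 0))
  r <- residuals(fit)
  expect_equal(fitted(fit)$minus - r$minus, pair$nitrate_minus)
  sims <- simulate(fit, nsim = 3, seed = 1, noise_sd = 0.05)
  expect_length(sims, 3L)
  expect_s3_class(sims[[1L]], "sample_pair")
  s <- summary(fit)
  expect_true(s$regime %in% c("I", "II", "III"))
})

test_that("the amendment stoichiometry ratio is recovered from synthetic dose series", {
  # amendments below ~0.8 mM nutrient keep the rescaled nutrient under the
  # 2 mM nitrate budget, where the curve shape still identifies the ratio;
  # larger additions saturate (nitrate runs out first) and carry no
  # information about the stoichiometry
  gamma <- 4.8
  base <- crm_params(0.1, 0.05, 2, gamma = gamma)
  base_pair <- make_pair(base, noise_sd = 0.02, seed = 21)
  baseline <- crm_fit(base_pair)
  ratio_truth <- 2.5
  dC <- c(0.1, 0.2, 0.5, 1)
  set.seed(22)
  amended <- lapply(dC, function(d) {
    p <- crm_params(base$x0_tilde, base$C0_tilde + ratio_truth * d, 2,
                    gamma = gamma)
    make_pair(p, noise_sd = 0.05)
  })
  res <- fit_amendment_ratio(baseline, amended, dC)
  expect_true(res$identifiable)
  expect_equal(res$ratio, ratio_truth, tolerance = 0.1)

  expect_warning(res0 <- fit_amendment_ratio(baseline, amended[1:2],
                                             c(0, 0)),
                 "unidentifiable")
  expect_true(is.na(res0$ratio))
  expect_error(fit_amendment_ratio(baseline, list(), numeric(0)), "empty")
})

test_that("panel fitting and median aggregation produce one row per condition", {
  spec <- soil_panel_spec(n_soils = 2, n_ph_levels = 5, replicates = 2)
  truth <- make_soil_panel(spec)
  series <- simulate_experiment(truth, seed = 5)
  fits <- fit_panel(series)
  expect_equal(nrow(fits), 2 * 5 * 2)
  agg <- aggregate_fits(fits)
  expect_equal(nrow(agg), 2 * 5)
  expect_true(all(agg$n_replicates == 2))
})
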
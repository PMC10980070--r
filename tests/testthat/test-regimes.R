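test_that("regime classification follows the two-threshold quadrants", {
  expect_equal(as.character(classify_regime(0.2, 0.1)), "II")
  expect_equal(as.character(classify_regime(0.01, 2.0)), "III")
  expect_equal(as.character(classify_regime(0, 0)), "I")
  # biomass test takes precedence: high biomass with high nutrient is II
  expect_equal(as.character(classify_regime(0.2, 3)), "II")
  # ties go to the higher-activity regime
  expect_equal(as.character(classify_regime(0.05, 0)), "II")
  expect_equal(as.character(classify_regime(0.01, 1.5)), "III")
  expect_error(classify_regime(NaN, 1), "NA/NaN")
  expect_error(classify_regime(-0.1, 1), "non-negative")
})

test_that("every non-negative parameter pair receives exactly one label", {
  set.seed(11)
  x <- c(0, 0.05, runif(200, 0, 1))
  g <- c(1.5, 1.5, runif(202, 0, 5))[1:202]
  lab <- classify_regime(x, g)
  expect_false(anyNA(lab))
  expect_true(all(lab %in% c("I", "II", "III")))
})

test_that("boundary location is the midpoint of the flanking conditions", {
  b <- regime_boundaries(c(3.5, 3.9, 4.3, 5, 6, 7, 8),
                         c("I", "I", "II", "II", "II", "III", "III"))
  expect_equal(b$boundary_I_II, 4.1)
  expect_equal(b$err_I_II, 0.4, tolerance = 1e-12)
  expect_equal(b$boundary_II_III, 6.5)
  b2 <- regime_boundaries(c(4, 5, 6), c("II", "II", "II"))
  expect_true(is.na(b2$boundary_I_II) && is.na(b2$boundary_II_III))
  expect_warning(regime_boundaries(c(3, 4, 5, 6), c("I", "II", "I", "II")),
                 "non-monotone")
})

test_that("weighted boundary trend recovers a planted slope", {
  set.seed(12)
  native <- seq(4.7, 8.3, length.out = 15)
  truth_slope <- 0.7
  bnd <- truth_slope * native + 0.8 + rnorm(15, 0, 0.15)
  err <- runif(15, 0.3, 0.6)
  fit <- boundary_trend_fit(native, bnd, err)
  expect_true(fit$ci[1L] < truth_slope && truth_slope < fit$ci[2L])
  # equal errors reduce to ordinary least squares
  f_eq <- boundary_trend_fit(native, bnd, rep(0.4, 15))
  f_ols <- boundary_trend_fit(native, bnd)
  expect_equal(f_eq$slope, f_ols$slope, tolerance = 1e-12)
  expect_warning(boundary_trend_fit(native[1:3], bnd[1:3], c(0, 0.4, 0.4)),
                 "equal weights")
  # two points: exact interpolation with an unbounded interval, flagged
  f2 <- boundary_trend_fit(native[1:2], bnd[1:2], err[1:2])
  expect_true(f2$exact)
  expect_equal(f2$ci, c(-Inf, Inf))
})

test_that("titration interpolation is monotone and inverts to 1e-6 in dose", {
  doses <- sort(c(0, -exp(seq(log(1), log(100), length.out = 11)),
                  exp(seq(log(1), log(100), length.out = 11))))
  ph <- 6 + 1.6 * tanh(doses / 35)
  tc <- titration_curve(doses, ph)
  expect_equal(predict(tc, 0), 6, tolerance = 1e-9)
  d0 <- dose_for_ph(tc, 6)
  expect_equal(d0, 0, tolerance = 1e-6)
  targets <- predict(tc, c(-40, -5, 10, 60))
  expect_equal(dose_for_ph(tc, targets), c(-40, -5, 10, 60),
               tolerance = 1e-6)
  expect_warning(out <- dose_for_ph(tc, 9.9), "unreachable")
  expect_true(is.na(out))
  expect_error(titration_curve(doses[1:4], ph[1:4]), "at least 5")
  expect_error(titration_curve(doses, rev(ph)), "non-decreasing")
})

test_that("the standard 13-level dose panel includes the unperturbed condition", {
  tru <- make_soil_panel(soil_panel_spec(n_soils = 4))
  pts <- titration_points(tru, 2)
  tc <- titration_curve(pts$dose, pts$endpoint_pH)
  pd <- perturbation_doses(tc)
  expect_equal(nrow(pd), 13L)
  expect_true(any(pd$dose == 0))
  expect_equal(pd$target_pH[pd$dose == 0], tc$ph_of_dose(0))
  expect_true(all(diff(pd$target_pH) > 0))
})

test_that("a fixed acid dose moves a neutral soil further than an acidic one", {
  tru <- make_soil_panel(soil_panel_spec(n_soils = 10))
  acidic <- tru$titration[[1L]]   # native 4.7
  neutral <- tru$titration[[10L]] # native 8.3
  for (d in c(-5, -20, -60)) {
    dph_acid <- abs(acidic$ph_of_dose(d) - acidic$ph_of_dose(0))
    dph_neut <- abs(neutral$ph_of_dose(d) - neutral$ph_of_dose(0))
    expect_gt(dph_neut, dph_acid)
  }
})

test_that("the rate fold-change collapses linearly with base dose by construction", {
  tru <- make_soil_panel(soil_panel_spec())
  cond <- tru$conditions
  rf <- rate_fold_collapse(cond$x0_tilde, cond$gammaC0_tilde, cond$dose,
                           cond$regime)
  expect_gt(rf$r_squared, 0.9)
  expect_gt(rf$slope, 0)
  # without nutrient release the fold is 1 at every dose
  expect_equal((0.2 + 0) / 0.2, 1)
  rf0 <- rate_fold_collapse(rep(0.2, 5), rep(0, 5), c(0, 5, 10, 15, 20),
                            rep("II", 5))
  expect_equal(rf0$slope, 0, tolerance = 1e-12)
  expect_true(all(rf0$data$fold == 1))
  # acidic side: acid releases no nutrient, so the growth term stays at the
  # background level and typical folds stay near one
  acid <- cond[cond$dose < 0, ]
  expect_lt(max(acid$gammaC0_tilde), 0.2)
  acid_II <- acid[acid$regime == "II", ]
  folds <- (acid_II$x0_tilde + acid_II$gammaC0_tilde) / acid_II$x0_tilde
  expect_lt(median(folds), 1.6)
  expect_error(rate_fold_collapse(0.1, 0.1, 1, "II"), "at least 3")
})
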
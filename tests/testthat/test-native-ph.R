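test_that("single-predictor LASSO equals the closed-form soft threshold", {
  set.seed(51)
  n <- 60
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))  # mean 0, mean square 1
  y <- 0.8 * x + rnorm(n, 0, 0.3)
  z <- mean(x * (y - mean(y)))
  for (lam in c(0.05, 0.2, 0.5, 1)) {
    fit <- lasso_fit(cbind(p1 = x), y, lam)
    expect_equal(unname(fit$coef[1L]), soft_threshold(z, lam),
                 tolerance = 1e-4)
  }
})

test_that("degenerate designs reduce to the intercept-only model", {
  y <- c(5, 6, 7, 8)
  X <- matrix(0, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- lasso_fit(X, y, 0.1)
  expect_equal(unname(fit$predict(X)), rep(mean(y), 4))
  # huge penalty kills every coefficient
  d <- make_presence_design()
  f_inf <- lasso_fit(d$X, d$y, 1e6)
  expect_true(all(f_inf$coef == 0))
})

test_that("the active set shrinks as the penalty grows", {
  d <- make_presence_design()
  nnz <- sapply(c(0.001, 0.01, 0.05, 0.2, 1),
                function(l) sum(lasso_fit(d$X, d$y, l)$coef != 0))
  expect_true(all(diff(nnz) <= 0))
})

test_that("cross-validation finds signal when planted and assigns soil folds", {
  d <- make_presence_design()
  cv <- cv_select_lambda(d$X, d$y, seed = 2, soil_ids = d$soil)
  fit <- lasso_fit(d$X, d$y, cv$lambda)
  resid <- d$y - fit$predict(d$X)
  expect_lt(mean(resid^2), 0.1 * var(d$y))
})

test_that("R^2 on soil means matches hand-computed values", {
  # 3-soil toy: observed means 5,6,7; predicted means 5.5,6,6.5
  obs <- c(5, 5, 6, 6, 7, 7)
  pred <- c(5.5, 5.5, 6, 6, 6.5, 6.5)
  soil <- c("a", "a", "b", "b", "c", "c")
  expect_equal(r2_on_soil_means(pred, obs, soil), 1 - 0.5 / 2)
  expect_equal(r2_on_soil_means(obs, obs, soil), 1)
  expect_equal(r2_on_soil_means(rep(6, 6), obs, soil), 0)
  expect_error(r2_on_soil_means(1:2, 1:2, c("a", "a")), "at least 2")
})

test_that("leave-one-soil-out predicts held-out soils and never peeks at them", {
  d <- make_presence_design()
  loso <- loso_predict(d$X, d$y, d$soil, seed = 3)
  r2 <- r2_on_soil_means(loso$predicted, loso$observed, loso$soil_id)
  expect_gt(r2, 0)
  sm <- tapply(loso$predicted, loso$soil_id, mean)
  om <- tapply(loso$observed, loso$soil_id, mean)
  expect_gt(cor(sm, om, method = "spearman"), 0.7)
  # in-sample predictions are at least as good (optimism)
  cv <- cv_select_lambda(d$X, d$y, seed = 3, soil_ids = d$soil)
  fit <- lasso_fit(d$X, d$y, cv$lambda)
  r2_in <- r2_on_soil_means(fit$predict(d$X), d$y, d$soil)
  expect_gte(r2_in, r2)
  # poisoning the held-out soil's responses changes nothing: it is unseen
  y_poison <- d$y
  y_poison[d$soil == "s1"] <- 99
  loso_p <- loso_predict(d$X, y_poison, d$soil, seed = 3)
  expect_equal(loso_p$predicted[loso_p$soil_id == "s1"],
               loso$predicted[loso$soil_id == "s1"], tolerance = 1e-12)
  # constant response predicts the constant
  loso_c <- loso_predict(d$X, rep(6.5, nrow(d$X)), d$soil, seed = 3)
  expect_equal(loso_c$predicted, rep(6.5, nrow(d$X)), tolerance = 1e-6)
  expect_error(loso_predict(d$X[1:8, ], d$y[1:8], d$soil[1:8]), "3 distinct")
})

test_that("soil-level permutation keeps samples of a soil together", {
  d <- make_presence_design(n_soils = 6, reps = 3)
  perm <- permutation_threshold(d$X, d$y, d$soil, n_perm = 25, seed = 4,
                                lambda = 0.05)
  # every permuted R^2 came from a y that is constant within soils:
  # re-run with the same seed reproduces the threshold exactly
  perm2 <- permutation_threshold(d$X, d$y, d$soil, n_perm = 25, seed = 4,
                                 lambda = 0.05)
  expect_identical(perm$threshold, perm2$threshold)
  expect_length(perm$r2_perm, 25L)
  expect_error(permutation_threshold(d$X, d$y, d$soil, n_perm = 10),
               "unreliable")
})

test_that("a planted signal clears the permutation threshold; pure noise does not", {
  d <- make_presence_design()
  cv <- cv_select_lambda(d$X, d$y, seed = 5, soil_ids = d$soil)
  fit <- lasso_fit(d$X, d$y, cv$lambda)
  r2_obs <- r2_on_soil_means(fit$predict(d$X), d$y, d$soil)
  perm <- permutation_threshold(d$X, d$y, d$soil, n_perm = 60, seed = 5,
                                lambda = cv$lambda)
  expect_gt(r2_obs, perm$threshold)
})
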
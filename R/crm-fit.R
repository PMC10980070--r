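#' Paired CHL-/CHL+ nitrate time series
#'
#' Container for one microcosm condition: the nitrate series measured
#' without chloramphenicol (growth permitted, "minus" arm) and the matched
#' series with chloramphenicol (growth arrested, "plus" arm).
#'
#' @param times_minus,nitrate_minus CHL- timepoints and nitrate (mM).
#' @param times_plus,nitrate_plus CHL+ timepoints and nitrate (mM).
#' @param unit Unit of the supplied times; `"hours"` are converted to days
#'   on construction (model rates are per day).
#' @param soil_id,native_pH,perturbed_pH,replicate Optional condition
#'   metadata carried through to fit outputs.
#' @return An object of class `"sample_pair"`.
#' @export
sample_pair <- function(times_minus, nitrate_minus, times_plus, nitrate_plus,
                        unit = c("days", "hours"),
                        soil_id = NA, native_pH = NA_real_,
                        perturbed_pH = NA_real_, replicate = NA_integer_) {
  unit <- match.arg(unit)
  conv <- if (unit == "hours") 1 / 24 else 1
  check_arm <- function(t, a, arm) {
    if (length(t) != length(a))
      stop("times and nitrate lengths differ in the ", arm, " arm")
    if (length(t) < 4L)
      stop("need at least 4 timepoints per arm (", arm, " has ", length(t), ")")
    if (anyNA(t) || anyNA(a)) stop("NA values in the ", arm, " arm")
    if (any(a < 0)) stop("negative nitrate in the ", arm, " arm")
    if (is.unsorted(t, strictly = TRUE))
      stop("times must be strictly increasing in the ", arm, " arm")
  }
  check_arm(times_minus, nitrate_minus, "CHL-")
  check_arm(times_plus, nitrate_plus, "CHL+")
  structure(list(times_minus = times_minus * conv,
                 nitrate_minus = nitrate_minus,
                 times_plus = times_plus * conv,
                 nitrate_plus = nitrate_plus,
                 meta = list(soil_id = soil_id, native_pH = native_pH,
                             perturbed_pH = perturbed_pH,
                             replicate = replicate)),
            class = "sample_pair")
}

#' @export
print.sample_pair <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Sample pair: soil %s, native pH %s, perturbed pH %s, rep %s\n",
              m$soil_id, m$native_pH, m$perturbed_pH, m$replicate))
  cat(sprintf("  CHL-: %d points, %.2f -> %.2f mM over %.2f d\n",
              length(x$times_minus), x$nitrate_minus[1L],
              x$nitrate_minus[length(x$nitrate_minus)], max(x$times_minus)))
  cat(sprintf("  CHL+: %d points, %.2f -> %.2f mM over %.2f d\n",
              length(x$times_plus), x$nitrate_plus[1L],
              x$nitrate_plus[length(x$nitrate_plus)], max(x$times_plus)))
  invisible(x)
}

#' Mean-squared-error loss of a parameter set against a sample pair
#'
#' \deqn{L = \frac{1}{2N}\left[\sum_k (A(t_k^-) - a_k^-)^2 +
#'       \sum_k (A_c(t_k^+) - a_k^+)^2\right]}
#' where `A` is the CHL- model solution (from `A0`) and `A_c` the CHL+
#' solution (from `A0c`, growth arrested). The two arms must have the same
#' number of timepoints `N`.
#'
#' @param params A [crm_params()] object.
#' @param pair A [sample_pair()].
#' @param method Trajectory evaluation method, see [crm_simulate()].
#' @return The loss in mM^2.
#' @export
crm_loss <- function(params, pair, method = c("analytic", "ode")) {
  stopifnot(inherits(pair, "sample_pair"))
  method <- match.arg(method)
  N <- length(pair$times_minus)
  if (length(pair$times_plus) != N)
    stop("the loss requires equal numbers of timepoints in both arms (got ",
         N, " and ", length(pair$times_plus), ")")
  r <- crm_residuals(params, pair, method)
  (sum(r$minus^2) + sum(r$plus^2)) / (2 * N)
}

# residuals (model - data) per arm
crm_residuals <- function(params, pair, method) {
  Am <- crm_simulate(params, pair$times_minus, chl = FALSE, method = method)$A
  Ap <- crm_simulate(params, pair$times_plus, chl = TRUE, method = method)$A
  list(minus = Am - pair$nitrate_minus, plus = Ap - pair$nitrate_plus)
}

#' Fit the consumer-resource model to a paired nitrate time series
#'
#' Minimizes the mean-squared-error loss [crm_loss()] over the four free
#' parameters `x0_tilde`, `C0_tilde`, `A0`, `A0c`, holding `gamma`, `KA` and
#' `KC_tilde` fixed (defaults 4.8 /day and 0.01 mM, justified by
#' [sensitivity_scan()]). Optimization is bounded L-BFGS-B on
#' log10-transformed `x0_tilde` and `C0_tilde`, started from a deterministic
#' grid of multi-starts log-spaced across the biomass/nutrient bounds.
#'
#' The reported RMSE is normalized by the nominal 2 mM nitrate input.
#'
#' @param pair A [sample_pair()].
#' @param gamma,KA,KC_tilde Fixed model parameters.
#' @param bounds Named list of length-2 ranges for the free parameters.
#' @param n_restarts Number of deterministic multi-starts (default 8).
#' @param method Trajectory evaluation used inside the loss: the closed form
#'   (`"analytic"`, valid at the default small affinities) or the ODE
#'   integrator (`"ode"`, required when affinities are clamped large).
#' @param extra_starts Optional matrix of additional starts with columns
#'   `x0_tilde`, `C0_tilde` (natural scale).
#' @return An object of class `"crm_fit"` with components `params`
#'   ([crm_params()] at the optimum), `loss`, `rmse`, `rmse_pct_of_input`,
#'   `per_point_errors`, `converged`, `n_restarts_used`, `pair`, `method`.
#' @examples
#' p <- crm_params(0.1, 0.05, 2, gamma = 4.8)
#' t_d <- c(0, 4, 8, 19, 25, 31, 43, 55, 67, 91) / 24
#' pair <- sample_pair(t_d, crm_simulate(p, t_d)$A,
#'                     t_d, crm_simulate(p, t_d, chl = TRUE)$A)
#' fit <- crm_fit(pair)
#' coef(fit)
#' @export
crm_fit <- function(pair,
                    gamma = 4.8, KA = 0.01, KC_tilde = 0.01,
                    bounds = list(x0_tilde = c(1e-5, 1),
                                  C0_tilde = c(1e-4, 10),
                                  A0 = c(1, 3), A0c = c(1, 3)),
                    n_restarts = 8, method = c("analytic", "ode"),
                    extra_starts = NULL) {
  stopifnot(inherits(pair, "sample_pair"))
  method <- match.arg(method)
  if (all(pair$nitrate_minus == 0) && all(pair$nitrate_plus == 0))
    stop("degenerate input: all nitrate measurements are zero")

  lo <- c(log10(bounds$x0_tilde[1L]), log10(bounds$C0_tilde[1L]),
          bounds$A0[1L], bounds$A0c[1L])
  hi <- c(log10(bounds$x0_tilde[2L]), log10(bounds$C0_tilde[2L]),
          bounds$A0[2L], bounds$A0c[2L])

  N <- length(pair$times_minus)
  if (length(pair$times_plus) != N)
    stop("the loss requires equal numbers of timepoints in both arms")
  tm <- pair$times_minus; am <- pair$nitrate_minus
  tp <- pair$times_plus; ap <- pair$nitrate_plus
  obj <- function(theta) {
    x0 <- 10^theta[1L]; C0 <- 10^theta[2L]
    if (method == "analytic") {
      Am <- fast_A_analytic(x0, C0, theta[3L], theta[4L], gamma, tm, FALSE,
                            KA, KC_tilde)
      Ap <- fast_A_analytic(x0, C0, theta[3L], theta[4L], gamma, tp, TRUE,
                            KA, KC_tilde)
    } else {
      Am <- fast_A_ode(x0, C0, theta[3L], theta[4L], gamma, KA, KC_tilde,
                       tm, FALSE)
      Ap <- fast_A_ode(x0, C0, theta[3L], theta[4L], gamma, KA, KC_tilde,
                       tp, TRUE)
    }
    (sum((Am - am)^2) + sum((Ap - ap)^2)) / (2 * N)
  }

  # deterministic multi-start grid, log-spaced over the (x0, C0) bounds
  nx <- max(2L, ceiling(n_restarts / 2))
  nc <- max(1L, floor(n_restarts / nx))
  x0s <- 10^seq(log10(bounds$x0_tilde[1L]) + 0.5,
                log10(bounds$x0_tilde[2L]) - 0.5, length.out = nx)
  c0s <- 10^seq(log10(bounds$C0_tilde[1L]) + 1,
                log10(bounds$C0_tilde[2L]) - 1, length.out = nc)
  starts <- as.matrix(expand.grid(x0_tilde = x0s, C0_tilde = c0s))
  starts <- starts[seq_len(min(nrow(starts), n_restarts)), , drop = FALSE]
  if (!is.null(extra_starts))
    starts <- rbind(starts, extra_starts[, c("x0_tilde", "C0_tilde"),
                                         drop = FALSE])
  a0_start <- min(max(pair$nitrate_minus[1L], bounds$A0[1L]), bounds$A0[2L])
  a0c_start <- min(max(pair$nitrate_plus[1L], bounds$A0c[1L]), bounds$A0c[2L])

  best <- NULL
  conv_any <- FALSE
  for (i in seq_len(nrow(starts))) {
    th0 <- c(log10(starts[i, 1L]), log10(starts[i, 2L]), a0_start, a0c_start)
    res <- try(stats::optim(th0, obj, method = "L-BFGS-B",
                            lower = lo, upper = hi,
                            control = list(maxit = 300, factr = 1e7)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (res$convergence == 0) conv_any <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimization restarts failed")

  th <- best$par
  p_opt <- crm_params(x0_tilde = 10^th[1L], C0_tilde = 10^th[2L],
                      A0 = th[3L], A0c = th[4L],
                      gamma = gamma, KA = KA, KC_tilde = KC_tilde)
  r <- crm_residuals(p_opt, pair, method)
  rmse <- sqrt(best$value)
  structure(list(params = p_opt,
                 loss = best$value,
                 rmse = rmse,
                 rmse_pct_of_input = 100 * rmse / 2,
                 per_point_errors = c(abs(r$minus), abs(r$plus)),
                 residuals = r,
                 converged = conv_any,
                 n_restarts_used = nrow(starts),
                 pair = pair, method = method),
            class = "crm_fit")
}

#' @export
print.crm_fit <- function(x, ...) {
  p <- x$params
  cat("Consumer-resource model fit\n")
  cat(sprintf("  x0_tilde = %.4g mM/day   C0_tilde = %.4g mM   gamma*C0_tilde = %.4g mM/day\n",
              p$x0_tilde, p$C0_tilde, p$gamma * p$C0_tilde))
  cat(sprintf("  A0 = %.3f mM   A0c = %.3f mM (fixed: gamma = %g, KA = %g, KC_tilde = %g)\n",
              p$A0, p$A0c, p$gamma, p$KA, p$KC_tilde))
  cat(sprintf("  RMSE = %.4f mM (%.2f%% of the 2 mM input), converged: %s\n",
              x$rmse, x$rmse_pct_of_input, x$converged))
  invisible(x)
}

#' @export
summary.crm_fit <- function(object, ...) {
  p <- object$params
  out <- list(coef = coef(object),
              regime = classify_regime(p$x0_tilde, p$gamma * p$C0_tilde),
              rmse = object$rmse,
              rmse_pct_of_input = object$rmse_pct_of_input,
              per_point = summary(object$per_point_errors),
              growth_stop_days = if (p$x0_tilde > 0 && p$gamma > 0)
                growth_stop_time(p) else Inf,
              converged = object$converged,
              meta = object$pair$meta)
  class(out) <- "summary.crm_fit"
  out
}

#' @export
print.summary.crm_fit <- function(x, ...) {
  cat("Consumer-resource model fit summary\n")
  print(round(x$coef, 5))
  cat(sprintf("Regime: %s   t* = %.3f d   RMSE %.2f%% of input\n",
              x$regime, x$growth_stop_days, x$rmse_pct_of_input))
  cat("Per-point |error| (mM):\n"); print(x$per_point)
  invisible(x)
}

#' @export
coef.crm_fit <- function(object, ...) {
  p <- object$params
  c(x0_tilde = p$x0_tilde, C0_tilde = p$C0_tilde, A0 = p$A0, A0c = p$A0c,
    gamma = p$gamma, KA = p$KA, KC_tilde = p$KC_tilde,
    gammaC0_tilde = p$gamma * p$C0_tilde)
}

#' @export
predict.crm_fit <- function(object, times = NULL, chl = FALSE,
                            method = NULL, ...) {
  if (is.null(times))
    times <- if (chl) object$pair$times_plus else object$pair$times_minus
  if (is.null(method)) method <- object$method
  crm_simulate(object$params, times, chl = chl, method = method)$A
}

#' @export
fitted.crm_fit <- function(object, ...) {
  list(minus = object$pair$nitrate_minus + object$residuals$minus,
       plus = object$pair$nitrate_plus + object$residuals$plus)
}

#' @export
residuals.crm_fit <- function(object, ...) object$residuals

#' @export
plot.crm_fit <- function(x, ...) {
  pair <- x$pair
  tmax <- max(pair$times_minus, pair$times_plus)
  tt <- seq(0, tmax, length.out = 200L)
  Am <- crm_simulate(x$params, tt, chl = FALSE, method = x$method)$A
  Ap <- crm_simulate(x$params, tt, chl = TRUE, method = x$method)$A
  graphics::plot(pair$times_minus, pair$nitrate_minus, pch = 16,
                 col = "black", xlab = "time (days)", ylab = "nitrate (mM)",
                 ylim = c(0, max(pair$nitrate_minus,
                                 pair$nitrate_plus) * 1.05), ...)
  graphics::points(pair$times_plus, pair$nitrate_plus, pch = 17,
                   col = "red3")
  graphics::lines(tt, Am, col = "black")
  graphics::lines(tt, Ap, col = "red3")
  graphics::legend("bottomleft",
                   c("CHL- data", "CHL+ data", "CHL- fit", "CHL+ fit"),
                   pch = c(16, 17, NA, NA), lty = c(NA, NA, 1, 1),
                   col = c("black", "red3", "black", "red3"), bty = "n")
  invisible(x)
}

#' Simulate replicate sample pairs from a fitted model
#'
#' Generates `nsim` noisy paired series from the fitted parameters, with iid
#' Gaussian measurement noise clipped at zero.
#'
#' @param object A `"crm_fit"`.
#' @param nsim Number of replicate pairs.
#' @param seed Optional RNG seed.
#' @param noise_sd Measurement noise standard deviation, mM.
#' @param ... Unused.
#' @return A list of [sample_pair()] objects.
#' @export
simulate.crm_fit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  pair <- object$pair
  Am <- crm_simulate(object$params, pair$times_minus, chl = FALSE,
                     method = object$method)$A
  Ap <- crm_simulate(object$params, pair$times_plus, chl = TRUE,
                     method = object$method)$A
  lapply(seq_len(nsim), function(i) {
    sample_pair(pair$times_minus,
                pmax(Am + stats::rnorm(length(Am), 0, noise_sd), 0),
                pair$times_plus,
                pmax(Ap + stats::rnorm(length(Ap), 0, noise_sd), 0),
                soil_id = pair$meta$soil_id,
                native_pH = pair$meta$native_pH,
                perturbed_pH = pair$meta$perturbed_pH, replicate = i)
  })
}

#' Fit every sample pair of a tidy time-series table
#'
#' Groups a tidy table (columns `soil_id`, `native_pH`, `perturbed_pH`,
#' `replicate`, `chl`, `time_hr`, `nitrate_mM`) into [sample_pair()]s via
#' [pair_timeseries()] and fits each with [crm_fit()].
#'
#' @param data Tidy data frame, or a list of [sample_pair()] objects.
#' @param ... Passed to [crm_fit()].
#' @return A data frame with one row per replicate pair: metadata, the
#'   fitted `x0_tilde`, `C0_tilde`, `gammaC0_tilde`, `A0`, `A0c`,
#'   `rmse_pct`, `converged`.
#' @export
fit_panel <- function(data, ...) {
  pairs <- if (is.data.frame(data)) pair_timeseries(data) else data
  rows <- lapply(pairs, function(pr) {
    f <- crm_fit(pr, ...)
    p <- f$params
    data.frame(soil_id = pr$meta$soil_id, native_pH = pr$meta$native_pH,
               perturbed_pH = pr$meta$perturbed_pH,
               replicate = pr$meta$replicate,
               x0_tilde = p$x0_tilde, C0_tilde = p$C0_tilde,
               gammaC0_tilde = p$gamma * p$C0_tilde,
               A0 = p$A0, A0c = p$A0c,
               rmse_pct = f$rmse_pct_of_input, converged = f$converged)
  })
  do.call(rbind, rows)
}

#' Median-aggregate replicate fits per condition
#'
#' Downstream analyses (regime classification, boundaries) use the median
#' fitted value of the biological replicates of each soil x perturbed-pH
#' condition.
#'
#' @param fits Data frame from [fit_panel()].
#' @return One row per (soil_id, perturbed_pH) with median parameters.
#' @export
aggregate_fits <- function(fits) {
  key <- interaction(fits$soil_id, fits$perturbed_pH, drop = TRUE)
  rows <- lapply(split(fits, key), function(d) {
    data.frame(soil_id = d$soil_id[1L], native_pH = d$native_pH[1L],
               perturbed_pH = d$perturbed_pH[1L],
               n_replicates = nrow(d),
               x0_tilde = stats::median(d$x0_tilde),
               C0_tilde = stats::median(d$C0_tilde),
               gammaC0_tilde = stats::median(d$gammaC0_tilde),
               rmse_pct = stats::median(d$rmse_pct))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$soil_id, out$perturbed_pH), ]
  rownames(out) <- NULL
  out
}
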
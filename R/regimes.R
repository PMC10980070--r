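#' Classify fitted conditions into functional regimes
#'
#' The two fitted summary parameters — initial functional biomass
#' `x0_tilde` (mM/day) and available limiting nutrient `gammaC0_tilde`
#' (mM/day) — partition conditions into three regimes:
#'
#' * **II** (nutrient limitation): `x0_tilde >= 0.05` — a large active
#'   biomass consumes nitrate linearly once the scarce nutrient is gone.
#' * **III** (resurgent growth): `x0_tilde < 0.05` and
#'   `gammaC0_tilde >= 1.5` — rare survivors grow exponentially on
#'   abundant released nutrient.
#' * **I** (acidic death): both small — little biomass, little nutrient,
#'   nitrate reduction ceases.
#'
#' Exact threshold ties go to the higher-activity regime (II at the
#' `x0_tilde` line; III at the `gammaC0_tilde` line). A condition with both
#' `x0_tilde >= 0.05` and large `gammaC0_tilde` is II: the biomass test
#' takes precedence, resurgent growth occupying only the low-biomass,
#' high-nutrient quadrant.
#'
#' @param x0_tilde,gammaC0_tilde Numeric vectors, mM/day, non-negative.
#' @param thresholds Named vector with elements `x` (biomass threshold,
#'   default 0.05) and `c` (nutrient threshold, default 1.5).
#' @return A factor with levels `"I"`, `"II"`, `"III"`.
#' @examples
#' classify_regime(c(0.2, 0.01, 0), c(0.1, 2, 0))
#' @export
classify_regime <- function(x0_tilde, gammaC0_tilde,
                            thresholds = c(x = 0.05, c = 1.5)) {
  if (anyNA(x0_tilde) || anyNA(gammaC0_tilde))
    stop("NA/NaN inputs to classify_regime")
  if (any(x0_tilde < 0) || any(gammaC0_tilde < 0))
    stop("regime inputs must be non-negative")
  n <- max(length(x0_tilde), length(gammaC0_tilde))
  x <- rep_len(x0_tilde, n); g <- rep_len(gammaC0_tilde, n)
  lab <- ifelse(x >= thresholds[["x"]], "II",
                ifelse(g >= thresholds[["c"]], "III", "I"))
  factor(lab, levels = c("I", "II", "III"))
}

#' Locate regime-boundary pH values for one soil
#'
#' Given regime labels ordered along the perturbed-pH grid (ascending, one
#' label per condition from median-of-replicates fits), the I-II boundary is
#' the midpoint between the last (highest-pH) Regime-I condition and the
#' first Regime-II condition, and the II-III boundary likewise between the
#' last II and the first III. The reported error is the pH difference
#' between the two flanking conditions. A transition that does not occur
#' yields `NA`. A non-monotone label sequence triggers a warning and the
#' first transition is used.
#'
#' @param perturbed_pH Ascending numeric vector.
#' @param regime Regime labels (factor or character) of the same length.
#' @param soil_id,native_pH Optional metadata copied to the output.
#' @return A one-row data frame: `boundary_I_II`, `err_I_II`,
#'   `boundary_II_III`, `err_II_III` plus metadata.
#' @examples
#' regime_boundaries(c(3.5, 3.9, 4.3, 5), c("I", "I", "II", "II"))
#' @export
regime_boundaries <- function(perturbed_pH, regime,
                              soil_id = NA, native_pH = NA_real_) {
  stopifnot(length(perturbed_pH) == length(regime))
  if (is.unsorted(perturbed_pH))
    stop("'perturbed_pH' must be sorted ascending")
  regime <- as.character(regime)
  find_transition <- function(from, to) {
    idx <- which(regime[-length(regime)] == from & regime[-1L] == to)
    if (length(idx) == 0L) return(c(NA_real_, NA_real_))
    if (length(idx) > 1L)
      warning("non-monotone regime sequence: multiple ", from, "->", to,
              " transitions; using the first")
    i <- idx[1L]
    c((perturbed_pH[i] + perturbed_pH[i + 1L]) / 2,
      perturbed_pH[i + 1L] - perturbed_pH[i])
  }
  b12 <- find_transition("I", "II")
  b23 <- find_transition("II", "III")
  data.frame(soil_id = soil_id, native_pH = native_pH,
             boundary_I_II = b12[1L], err_I_II = b12[2L],
             boundary_II_III = b23[1L], err_II_III = b23[2L])
}

#' Weighted trend of regime-boundary pH against native pH
#'
#' Weighted least squares of boundary pH on soil native pH with weights
#' inversely proportional to each boundary's error. A slope of 1 would mean
#' a constant pH offset from native to the boundary for all soils; slopes
#' below 1 mean natively acidic soils transition after smaller perturbations.
#'
#' @param native_pH,boundary,error Numeric vectors (one entry per soil);
#'   rows with `NA` boundaries are dropped.
#' @return List with `slope`, `intercept`, `ci` (95% interval on the slope),
#'   `exact` (TRUE when only two points were available, making the fit an
#'   interpolation with an unbounded interval) and the underlying `lm` fit.
#' @export
boundary_trend_fit <- function(native_pH, boundary, error = NULL) {
  keep <- is.finite(native_pH) & is.finite(boundary)
  native_pH <- native_pH[keep]; boundary <- boundary[keep]
  if (!is.null(error)) error <- error[keep]
  n <- length(native_pH)
  if (n < 2L) stop("need at least two soils with a defined boundary")
  if (is.null(error) || any(!is.finite(error)) || any(error == 0)) {
    if (!is.null(error) && any(error == 0))
      warning("zero boundary errors: falling back to equal weights")
    w <- rep(1, n)
  } else {
    w <- 1 / error
  }
  fit <- stats::lm(boundary ~ native_pH, weights = w)
  if (n == 2L) {
    return(list(slope = unname(coef(fit)[2L]),
                intercept = unname(coef(fit)[1L]),
                ci = c(-Inf, Inf), exact = TRUE, fit = fit))
  }
  ci <- stats::confint(fit, "native_pH", level = 0.95)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       ci = as.numeric(ci), exact = FALSE, fit = fit)
}

#' Titration curve of a soil slurry
#'
#' Endpoint pH as a monotone function of acid/base dose (signed mM; negative
#' = HCl, positive = NaOH). A shape-preserving monotone cubic interpolant
#' (Hyman-filtered spline) is used so that the curve is invertible:
#' unconstrained cubic splines can overshoot and lose monotonicity.
#'
#' @param dose Signed dose values, mM; strictly increasing.
#' @param endpoint_pH Measured endpoint pH; must be non-decreasing in dose.
#' @param soil_id,native_pH Optional metadata.
#' @return Object of class `"titration_curve"` with `ph_of_dose` and the
#'   data; use [predict.titration_curve()], [dose_for_ph()] and
#'   [perturbation_doses()].
#' @export
titration_curve <- function(dose, endpoint_pH, soil_id = NA,
                            native_pH = NA_real_) {
  stopifnot(length(dose) == length(endpoint_pH))
  if (length(dose) < 5L) stop("need at least 5 titration points")
  o <- order(dose)
  dose <- dose[o]; endpoint_pH <- endpoint_pH[o]
  if (anyDuplicated(dose)) stop("duplicate dose values")
  if (is.unsorted(endpoint_pH))
    stop("endpoint pH must be non-decreasing in dose")
  f <- stats::splinefun(dose, endpoint_pH, method = "hyman")
  structure(list(dose = dose, endpoint_pH = endpoint_pH,
                 ph_of_dose = f, soil_id = soil_id,
                 native_pH = if (is.na(native_pH)) f(0) else native_pH),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve (soil %s): %d points, dose %g..%g mM, pH %.2f..%.2f (pH at dose 0: %.2f)\n",
              x$soil_id, length(x$dose), min(x$dose), max(x$dose),
              min(x$endpoint_pH), max(x$endpoint_pH), x$ph_of_dose(0)))
  invisible(x)
}

#' @param object A `"titration_curve"`.
#' @param dose Doses at which to evaluate the pH, mM.
#' @param ... Unused.
#' @rdname titration_curve
#' @export
predict.titration_curve <- function(object, dose, ...) object$ph_of_dose(dose)

#' Invert a titration curve: dose required to reach a target pH
#'
#' @param curve A [titration_curve()].
#' @param target_pH Target pH values.
#' @param tol Root-finding tolerance on pH.
#' @return Doses in mM; `NA` with a warning for targets outside the
#'   achievable pH range of the curve ("unreachable pH").
#' @export
dose_for_ph <- function(curve, target_pH, tol = 1e-3) {
  stopifnot(inherits(curve, "titration_curve"))
  rng <- range(curve$endpoint_pH)
  out <- vapply(target_pH, function(ph) {
    if (ph < rng[1L] || ph > rng[2L]) return(NA_real_)
    stats::uniroot(function(d) curve$ph_of_dose(d) - ph,
                   range(curve$dose), tol = tol * 1e-3)$root
  }, numeric(1L))
  if (anyNA(out))
    warning("unreachable pH target(s): ",
            paste(signif(target_pH[is.na(out)], 3), collapse = ", "),
            " outside [", signif(rng[1L], 3), ", ", signif(rng[2L], 3), "]")
  out
}

#' Doses for the standard perturbed-pH panel
#'
#' Computes the acid/base doses needed to reach `n_levels` target pH values
#' evenly spanning `range`, with the grid point nearest the soil's own
#' (dose 0) pH replaced by that native pH so that the unperturbed condition
#' (dose exactly 0) is one of the levels.
#'
#' @param curve A [titration_curve()].
#' @param n_levels Number of pH levels (default 13).
#' @param range Target span (default pH 3 to 9).
#' @return Data frame with `target_pH`, `dose` (NA when unreachable) and
#'   `reachable`.
#' @export
perturbation_doses <- function(curve, n_levels = 13, range = c(3, 9)) {
  targets <- seq(range[1L], range[2L], length.out = n_levels)
  ph0 <- curve$ph_of_dose(0)
  targets[which.min(abs(targets - ph0))] <- ph0
  doses <- suppressWarnings(dose_for_ph(curve, targets))
  doses[abs(targets - ph0) < 1e-12] <- 0
  data.frame(target_pH = targets, dose = doses, reachable = !is.na(doses))
}

#' Collapse of the nitrate-rate fold-change against base dose
#'
#' In the nutrient-limiting regime the fold-change between the late CHL-
#' nitrate reduction rate (`x0_tilde + gammaC0_tilde`) and the growth-free
#' CHL+ rate (`x0_tilde`) grows linearly with the NaOH dose, because base
#' addition releases the growth-limiting nutrient in proportion to dose.
#' This fits that line across conditions, restricted by default to Regime II
#' and doses of 0--25 mM NaOH.
#'
#' @param x0_tilde,gammaC0_tilde Fitted parameters per condition, mM/day.
#' @param dose Signed dose, mM (positive = NaOH).
#' @param regime Regime labels per condition.
#' @param dose_range Dose window to include.
#' @return List with `slope`, `intercept`, `r_squared`, `n`, the fold data
#'   and the `lm` fit.
#' @export
rate_fold_collapse <- function(x0_tilde, gammaC0_tilde, dose, regime,
                               dose_range = c(0, 25)) {
  stopifnot(length(x0_tilde) == length(gammaC0_tilde),
            length(dose) == length(x0_tilde),
            length(regime) == length(x0_tilde))
  fold <- (x0_tilde + gammaC0_tilde) / x0_tilde
  keep <- as.character(regime) == "II" &
    dose >= dose_range[1L] & dose <= dose_range[2L] & is.finite(fold)
  if (sum(keep) < 3L)
    stop("need at least 3 Regime-II conditions in the dose window (got ",
         sum(keep), ")")
  d <- data.frame(dose = dose[keep], fold = fold[keep])
  fit <- stats::lm(fold ~ dose, data = d)
  tss <- sum((d$fold - mean(d$fold))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = r2, n = nrow(d), data = d, fit = fit)
}
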
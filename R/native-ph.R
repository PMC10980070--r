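#' Presence/absence matrix of resurgent-growth taxa
#'
#' Builds the binary design matrix used to predict a soil's native pH from
#' which taxa grow in the resurgent-growth regime. Relative abundance is
#' computed per sample, summed within the chosen taxonomic rank, and a taxon
#' is called present when its relative abundance exceeds `threshold`.
#'
#' @param counts ASV x sample count matrix (analyte counts, spike-ins
#'   removed).
#' @param taxonomy Data frame with `asv` plus the rank columns (e.g.
#'   `phylum`, `family`, `genus`, `asv`).
#' @param taxa Character vector of taxa (at `rank`) to use as columns —
#'   typically the regime-III enriched set after no-nitrate filtering.
#' @param rank Taxonomy column to aggregate at (default `"asv"`, i.e. no
#'   aggregation).
#' @param threshold Relative-abundance presence threshold; one of the
#'   conventional values 0, 0.001, 0.005 (others allowed).
#' @return Binary matrix, samples x taxa.
#' @export
presence_matrix <- function(counts, taxonomy, taxa, rank = "asv",
                            threshold = 0) {
  counts <- as.matrix(counts)
  rel <- sweep(counts, 2L, pmax(colSums(counts), 1), "/")
  if (rank != "asv") {
    grp <- taxonomy[[rank]][match(rownames(rel), taxonomy$asv)]
    grp[is.na(grp) | grp == ""] <- "unassigned"
    rel <- rowsum(rel, group = grp)
  }
  taxa <- intersect(taxa, rownames(rel))
  X <- t(rel[taxa, , drop = FALSE] > threshold) * 1
  X
}

# drop-in single fit; handles the degenerate designs glmnet rejects
lasso_glmnet <- function(X, y, lambda) {
  if (is.null(dim(X)) || ncol(X) < 1L || all(X == 0) ||
      stats::var(y) == 0)
    return(list(intercept = mean(y),
                coef = stats::setNames(numeric(ncol(X)), colnames(X))))
  if (ncol(X) == 1L) X <- cbind(X, .dummy = 0)  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lambda,
                        standardize = FALSE)
  b <- as.numeric(stats::coef(fit))
  cf <- stats::setNames(b[-1L], colnames(X))
  cf <- cf[names(cf) != ".dummy"]
  list(intercept = b[1L], coef = cf)
}

#' LASSO fit of native pH on taxon presence
#'
#' Solves \deqn{\min_{\beta_0, \beta}\; \frac{1}{2n}\|y - \beta_0 -
#' X\beta\|_2^2 + \lambda \|\beta\|_1} (additive terms only, L1 penalty;
#' no predictor standardization, so binary presence columns are penalized
#' on their natural scale). An empty design yields the intercept-only
#' model.
#'
#' @param X Binary samples x taxa matrix from [presence_matrix()].
#' @param y Native pH per sample.
#' @param lambda Penalty value.
#' @return List with `intercept`, `coef` (named), `lambda`, and
#'   `predict(newX)` convenience closure.
#' @export
lasso_fit <- function(X, y, lambda) {
  res <- lasso_glmnet(X, y, lambda)
  res$lambda <- lambda
  res$predict <- function(newX)
    drop(res$intercept + as.matrix(newX)[, names(res$coef), drop = FALSE]
         %*% res$coef)
  res
}

#' Select the LASSO penalty by cross-validation
#'
#' Tenfold cross-validation over a log-spaced lambda path. When the samples
#' come from exactly `nfolds` distinct soils, folds are the soils (all
#' samples of a soil share a fold); otherwise folds are assigned at random
#' with the given seed. If fewer distinct groups than `nfolds` exist, the
#' fold count is reduced with a warning.
#'
#' @param X,y Design and response as in [lasso_fit()].
#' @param nfolds Number of folds (default 10).
#' @param seed RNG seed for random fold assignment.
#' @param soil_ids Optional grouping vector (length `nrow(X)`).
#' @return List with `lambda` (CV minimizer), `lambda_path`, `cvm` (mean CV
#'   squared error per path value).
#' @export
cv_select_lambda <- function(X, y, nfolds = 10, seed = 1, soil_ids = NULL) {
  X <- as.matrix(X)
  if (stats::var(y) == 0)  # constant response: any penalty gives the mean
    return(list(lambda = 1, lambda_path = 1, cvm = 0))
  if (nrow(X) < nfolds) {
    warning("fewer samples than folds; reducing fold count")
    nfolds <- max(3L, nrow(X) %/% 2L)
  }
  if (!is.null(soil_ids)) {
    u <- unique(soil_ids)
    if (length(u) < nfolds) {
      warning("fewer soils than folds; using one fold per soil")
      nfolds <- length(u)
    }
    if (length(u) == nfolds) {
      foldid <- match(soil_ids, u)
    } else {
      set.seed(seed)
      fold_of_soil <- sample(rep_len(seq_len(nfolds), length(u)))
      foldid <- fold_of_soil[match(soil_ids, u)]
    }
  } else {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(nfolds), nrow(X)))
  }
  if (ncol(X) == 1L) X <- cbind(X, .dummy = 0)
  cv <- glmnet::cv.glmnet(X, y, alpha = 1, standardize = FALSE,
                          foldid = foldid, lambda.min.ratio = 1e-3,
                          nlambda = 100)
  list(lambda = cv$lambda.min, lambda_path = cv$lambda, cvm = cv$cvm)
}

#' Leave-one-soil-out prediction of native pH
#'
#' For each soil, all its samples are held out, the penalty is re-selected
#' by cross-validation on the remaining soils, the LASSO is refit on the
#' training soils only, and the held-out samples are predicted
#' (out-of-sample). Held-out samples whose presence rows are all zero carry
#' no taxon information and are predicted at the training intercept; they
#' are flagged.
#'
#' @param X,y Design and response as in [lasso_fit()].
#' @param soil_ids Soil of origin per sample (at least 3 distinct).
#' @param seed Seed forwarded to [cv_select_lambda()].
#' @return Data frame: `sample`, `soil_id`, `observed`, `predicted`,
#'   `all_zero_row`, plus attribute `lambdas` (per held-out soil).
#' @export
loso_predict <- function(X, y, soil_ids, seed = 1) {
  X <- as.matrix(X)
  soils <- unique(soil_ids)
  if (length(soils) < 3L) stop("need at least 3 distinct soils for LOSO")
  out <- vector("list", length(soils))
  lambdas <- stats::setNames(numeric(length(soils)), soils)
  for (i in seq_along(soils)) {
    test <- soil_ids == soils[i]
    cv <- cv_select_lambda(X[!test, , drop = FALSE], y[!test],
                           nfolds = min(10L, length(soils) - 1L),
                           seed = seed, soil_ids = soil_ids[!test])
    fit <- lasso_fit(X[!test, , drop = FALSE], y[!test], cv$lambda)
    lambdas[i] <- cv$lambda
    pred <- fit$predict(X[test, , drop = FALSE])
    out[[i]] <- data.frame(sample = which(test), soil_id = soils[i],
                           observed = y[test], predicted = pred,
                           all_zero_row = rowSums(X[test, , drop = FALSE]) == 0)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "lambdas") <- lambdas
  res
}

#' Coefficient of determination on per-soil means
#'
#' Predictions and observations are first averaged within each soil; the
#' reported \eqn{R^2 = 1 - SSE/SST} is computed over those per-soil mean
#' pairs. Negative values mean the predictions are worse than predicting
#' every soil at the grand mean.
#'
#' @param predictions,observations Sample-level vectors.
#' @param soil_ids Soil of origin per sample.
#' @return The \eqn{R^2} value.
#' @export
r2_on_soil_means <- function(predictions, observations, soil_ids) {
  stopifnot(length(predictions) == length(observations),
            length(soil_ids) == length(predictions))
  p <- tapply(predictions, soil_ids, mean)
  o <- tapply(observations, soil_ids, mean)
  if (length(o) < 2L) stop("R^2 on soil means needs at least 2 soils")
  1 - sum((p - o)^2) / sum((o - mean(o))^2)
}

#' Permutation null for the native-pH prediction quality
#'
#' Permutes the soil-to-native-pH assignment (all samples of a soil move
#' together), refits the in-sample LASSO with a CV-selected penalty for
#' each permutation, and records the in-sample \eqn{R^2} on soil means.
#' The significance threshold is the `ceiling(alpha * n_perm)`-th largest
#' permuted \eqn{R^2} (the top-50th of 1000 at `alpha = 0.05`).
#'
#' @param X,y,soil_ids As in [loso_predict()].
#' @param n_perm Number of permutations (>= 20; default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed RNG seed.
#' @param lambda Optional fixed penalty; when `NULL` (default) the penalty
#'   is re-selected by CV within every permutation.
#' @return List with `threshold`, the vector `r2_perm`, `alpha`, `n_perm`.
#' @export
permutation_threshold <- function(X, y, soil_ids, n_perm = 1000,
                                  alpha = 0.05, seed = 1, lambda = NULL) {
  if (n_perm < 20) stop("n_perm < 20 makes the tail quantile unreliable")
  X <- as.matrix(X)
  soils <- unique(soil_ids)
  soil_y <- vapply(soils, function(s) y[match(s, soil_ids)], numeric(1L))
  set.seed(seed)
  r2 <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm_y_soil <- sample(soil_y)
    yb <- perm_y_soil[match(soil_ids, soils)]
    lam <- if (is.null(lambda))
      cv_select_lambda(X, yb, seed = seed + b, soil_ids = soil_ids)$lambda
    else lambda
    fit <- lasso_fit(X, yb, lam)
    r2[b] <- r2_on_soil_means(fit$predict(X), yb, soil_ids)
  }
  k <- ceiling(alpha * n_perm)
  list(threshold = sort(r2, decreasing = TRUE)[k], r2_perm = r2,
       alpha = alpha, n_perm = n_perm)
}
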
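#' Read a tidy nitrate time-series table
#'
#' Expects a CSV with columns `soil_id`, `native_pH`, `perturbed_pH`,
#' `replicate`, `chl` (0/1), `time_hr`, `nitrate_mM`. Rows with negative
#' nitrate are rejected (their count is reported); a missing column is a
#' schema error naming it.
#'
#' @param path CSV path.
#' @return The validated data frame (times still in hours; conversion to
#'   days happens when pairs are built by [pair_timeseries()]).
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path)
  need <- c("soil_id", "native_pH", "perturbed_pH", "replicate", "chl",
            "time_hr", "nitrate_mM")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("time-series file is missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- df$nitrate_mM < 0
  if (any(bad)) {
    message("rejecting ", sum(bad), " row(s) with negative nitrate")
    df <- df[!bad, , drop = FALSE]
  }
  if (!all(df$chl %in% c(0L, 1L))) stop("'chl' must be 0 or 1")
  df
}

#' @rdname read_timeseries
#' @param data Tidy time-series data frame.
#' @param path Output CSV path.
#' @export
write_timeseries <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Group a tidy time-series table into sample pairs
#'
#' Splits by (soil, perturbed pH, replicate) and pairs the CHL- and CHL+
#' arms; replicate i is paired with replicate i. If the two arms of a
#' condition have different replicate sets they are paired by sorted order
#' with a warning; a condition with only one arm is an error naming it.
#' Hours are converted to days.
#'
#' @param data Data frame as returned by [read_timeseries()].
#' @return List of [sample_pair()] objects.
#' @export
pair_timeseries <- function(data) {
  key <- interaction(data$soil_id, data$perturbed_pH, drop = TRUE)
  pairs <- list()
  for (cond in split(data, key)) {
    id <- sprintf("soil %s at pH %s", cond$soil_id[1L],
                  cond$perturbed_pH[1L])
    minus <- cond[cond$chl == 0L, ]
    plus <- cond[cond$chl == 1L, ]
    if (nrow(minus) == 0L || nrow(plus) == 0L)
      stop("condition ", id, " lacks a CHL",
           if (nrow(minus) == 0L) "-" else "+", " arm")
    rm_ <- sort(unique(minus$replicate))
    rp_ <- sort(unique(plus$replicate))
    if (length(rm_) != length(rp_))
      stop("condition ", id, " has unmatched replicate counts (",
           length(rm_), " CHL- vs ", length(rp_), " CHL+)")
    if (!all(rm_ == rp_))
      warning("condition ", id,
              ": replicate labels differ between arms; pairing by sorted order")
    for (k in seq_along(rm_)) {
      m <- minus[minus$replicate == rm_[k], ]
      p <- plus[plus$replicate == rp_[k], ]
      m <- m[order(m$time_hr), ]; p <- p[order(p$time_hr), ]
      pairs[[length(pairs) + 1L]] <-
        sample_pair(m$time_hr, m$nitrate_mM, p$time_hr, p$nitrate_mM,
                    unit = "hours", soil_id = as.character(cond$soil_id[1L]),
                    native_pH = cond$native_pH[1L],
                    perturbed_pH = cond$perturbed_pH[1L],
                    replicate = rm_[k])
    }
  }
  pairs
}

#' Write / read an ASV count table as plain text
#'
#' Counts go to a TSV (ASVs x samples), sample metadata and taxonomy to
#' CSVs, spike-in counts as a column of the metadata.
#'
#' @param table A [count_table()].
#' @param prefix Path prefix; files `<prefix>_counts.tsv`,
#'   `<prefix>_meta.csv`, `<prefix>_taxonomy.csv` are written.
#' @return `write_count_table` invisibly returns `prefix`;
#'   `read_count_table` returns a [count_table()].
#' @export
write_count_table <- function(table, prefix) {
  stopifnot(inherits(table, "count_table"))
  utils::write.table(table$counts, paste0(prefix, "_counts.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  meta <- table$meta
  meta$spike_in <- table$spike_in
  utils::write.csv(meta, paste0(prefix, "_meta.csv"), row.names = FALSE)
  if (!is.null(table$taxonomy))
    utils::write.csv(table$taxonomy, paste0(prefix, "_taxonomy.csv"),
                     row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(prefix) {
  counts <- as.matrix(utils::read.table(paste0(prefix, "_counts.tsv"),
                                        sep = "\t", header = TRUE,
                                        row.names = 1L, check.names = FALSE))
  meta <- utils::read.csv(paste0(prefix, "_meta.csv"))
  spike <- stats::setNames(meta$spike_in, meta$sample)
  meta$spike_in <- NULL
  tax_path <- paste0(prefix, "_taxonomy.csv")
  tax <- if (file.exists(tax_path)) utils::read.csv(tax_path) else NULL
  count_table(counts, spike, taxonomy = tax, meta = meta)
}

#' Run the full synthetic analysis pipeline
#'
#' End-to-end driver over a synthetic panel: generates ground truth and
#' data, fits the consumer-resource model to every replicate pair,
#' classifies regimes from the median fits, locates per-soil regime
#' boundaries and their trend against native pH, simulates and analyzes
#' count tables (noise model, enrichment, growth folds, rank-2 NMF), and
#' predicts native pH from resurgent-growth taxa (in-sample and
#' leave-one-soil-out). Writes CSV/JSON outputs when `out_dir` is given.
#'
#' @param spec A [soil_panel_spec()]; reduce its sizes for quick runs.
#' @param seed Seed for all stochastic stages.
#' @param out_dir Optional output directory.
#' @param sequence_soils Soils to include in the count-table stages
#'   (default: up to the first 10).
#' @param n_perm Permutations for the native-pH null (default 200).
#' @return List with `truth`, `fits`, `condition_fits`, `regimes`,
#'   `boundaries`, `trend`, `noise`, `nmf`, `native_ph`.
#' @export
run_pipeline <- function(spec = soil_panel_spec(), seed = spec$seed,
                         out_dir = NULL, sequence_soils = NULL,
                         n_perm = 200) {
  truth <- make_soil_panel(spec)
  series <- simulate_experiment(truth, seed = seed)
  fits <- fit_panel(series)
  cond <- aggregate_fits(fits)
  cond$regime <- classify_regime(cond$x0_tilde, cond$gammaC0_tilde)

  bnd <- do.call(rbind, lapply(split(cond, cond$soil_id), function(d) {
    d <- d[order(d$perturbed_pH), ]
    regime_boundaries(d$perturbed_pH, d$regime, soil_id = d$soil_id[1L],
                      native_pH = d$native_pH[1L])
  }))
  trend <- if (sum(is.finite(bnd$boundary_I_II)) >= 3L)
    boundary_trend_fit(bnd$native_pH, bnd$boundary_I_II, bnd$err_I_II)
  else NULL

  if (is.null(sequence_soils))
    sequence_soils <- utils::head(truth$soils$soil_id,
                                  min(10L, nrow(truth$soils)))
  sim <- simulate_counts(truth, soils = sequence_soils, seed = seed + 1L)
  ct <- sim$table
  meta <- ct$meta
  t0 <- meta$timepoint == "T0" & meta$soil_id == sequence_soils[1L]
  noise <- estimate_noise_model(ct$counts[, meta$sample[t0], drop = FALSE])

  abund <- normalize_spike_in(ct)$abundance
  phy <- phylum_abundance(abund, ct$taxonomy)
  conds <- unique(meta[meta$timepoint == "end" & meta$nitrate,
                       c("soil_id", "perturbed_pH")])
  g_cols <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- function(chl) meta$sample[meta$soil_id == conds$soil_id[i] &
      meta$perturbed_pH == conds$perturbed_pH[i] & meta$chl == chl &
      meta$timepoint == "end" & meta$nitrate]
    list(minus = rowMeans(phy[, sel(0L), drop = FALSE]),
         plus = rowMeans(phy[, sel(1L), drop = FALSE]))
  })
  G <- growth_fold_matrix(
    sapply(g_cols, `[[`, "minus"), sapply(g_cols, `[[`, "plus"))
  colnames(G) <- paste(conds$soil_id, conds$perturbed_pH, sep = "@")
  nmf_fit <- nmf_rank2(G, seed = seed)

  np <- native_ph_from_counts(sim, cond, n_perm = n_perm, seed = seed)

  res <- list(truth = truth, fits = fits, condition_fits = cond,
              regimes = cond[, c("soil_id", "perturbed_pH", "regime",
                                 "x0_tilde", "gammaC0_tilde")],
              boundaries = bnd, trend = trend, noise = noise,
              growth_matrix = G, nmf = nmf_fit, native_ph = np)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    utils::write.csv(res$regimes, file.path(out_dir, "regimes.csv"),
                     row.names = FALSE)
    utils::write.csv(bnd, file.path(out_dir, "boundaries.csv"),
                     row.names = FALSE)
    utils::write.csv(np$predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    summ <- list(seed = seed,
                 regime_counts = as.list(table(res$regimes$regime)),
                 boundary_slope = if (!is.null(trend)) trend$slope else NA,
                 noise = list(c_frac = noise$c_frac, c0 = noise$c0),
                 nmf_variance_explained = nmf_fit$variance_explained,
                 r2_insample = np$r2_insample, r2_loso = np$r2_loso,
                 permutation_threshold = np$permutation_threshold)
    writeLines(to_json(summ), file.path(out_dir, "summary.json"))
  }
  res
}

# minimal JSON writer for the pipeline summary (numbers, strings, lists)
to_json <- function(x) {
  enc <- function(v) {
    if (is.list(v)) {
      if (is.null(names(v)))
        paste0("[", paste(vapply(v, enc, character(1L)), collapse = ","), "]")
      else paste0("{", paste(sprintf('"%s":%s', names(v),
                                     vapply(v, enc, character(1L))),
                             collapse = ","), "}")
    } else if (is.numeric(v)) {
      if (length(v) == 1L)
        if (is.na(v)) "null" else format(v, digits = 15)
      else enc(as.list(v))
    } else if (is.character(v)) {
      if (length(v) == 1L) paste0('"', v, '"') else enc(as.list(v))
    } else if (is.logical(v)) {
      tolower(as.character(v))
    } else "null"
  }
  enc(x)
}

# native-pH prediction stage of the pipeline: build the presence matrix of
# resurgent-regime samples over the enriched taxa and run in-sample, LOSO
# and permutation analyses.
native_ph_from_counts <- function(sim, condition_fits, n_perm = 200,
                                  seed = 1) {
  ct <- sim$table
  meta <- ct$meta
  cf <- condition_fits
  key <- function(s, p) paste(s, round(p, 3))
  regime_of <- stats::setNames(as.character(cf$regime),
                               key(cf$soil_id, cf$perturbed_pH))
  meta$regime <- regime_of[key(meta$soil_id, meta$perturbed_pH)]
  rows <- meta$timepoint == "end" & meta$nitrate & meta$chl == 0L &
    !is.na(meta$regime) & meta$regime == "III"
  if (sum(rows) < 6L || length(unique(meta$soil_id[rows])) < 3L)
    return(NULL)
  # enriched resurgent taxa per soil, no-nitrate responders removed
  noise_by_soil <- lapply(split(meta[meta$timepoint == "T0", ],
                                meta$soil_id[meta$timepoint == "T0"]),
                          function(m)
    estimate_noise_model(ct$counts[, m$sample, drop = FALSE]))
  enriched <- character(0)
  for (s in unique(meta$soil_id[rows])) {
    nm <- noise_by_soil[[s]]
    sub <- meta[rows & meta$soil_id == s, ]
    for (p in unique(sub$perturbed_pH)) {
      mi <- meta$sample[rows & meta$soil_id == s & meta$perturbed_pH == p]
      pl <- meta$sample[meta$timepoint == "end" & meta$nitrate &
                          meta$chl == 1L & meta$soil_id == s &
                          meta$perturbed_pH == p]
      z <- enrichment_zscores(ct$counts[, mi, drop = FALSE],
                              ct$counts[, pl, drop = FALSE], nm)
      enriched <- union(enriched, z$asv[z$enriched])
    }
    nn_m <- meta$sample[meta$soil_id == s & !meta$nitrate & meta$chl == 0L]
    nn_p <- meta$sample[meta$soil_id == s & !meta$nitrate & meta$chl == 1L]
    if (length(nn_m) && length(nn_p)) {
      zn <- enrichment_zscores(ct$counts[, nn_m, drop = FALSE],
                               ct$counts[, nn_p, drop = FALSE], nm)
      enriched <- filter_nn_responders(enriched, zn$asv[zn$enriched])
    }
  }
  if (length(enriched) < 2L) return(NULL)
  X <- presence_matrix(ct$counts[, meta$sample[rows], drop = FALSE],
                       ct$taxonomy, enriched, rank = "asv", threshold = 0)
  y <- meta$native_pH[rows]
  soil_ids <- meta$soil_id[rows]
  lam <- cv_select_lambda(X, y, seed = seed, soil_ids = soil_ids)$lambda
  fit <- lasso_fit(X, y, lam)
  ins <- fit$predict(X)
  loso <- loso_predict(X, y, soil_ids, seed = seed)
  perm <- permutation_threshold(X, y, soil_ids, n_perm = max(n_perm, 20L),
                                seed = seed, lambda = lam)
  list(X = X, y = y, soil_ids = soil_ids, lambda = lam,
       enriched = enriched,
       predictions = data.frame(sample = meta$sample[rows],
                                soil_id = soil_ids, observed = y,
                                in_sample = ins,
                                loso = loso$predicted[match(seq_along(y),
                                                            loso$sample)]),
       r2_insample = r2_on_soil_means(ins, y, soil_ids),
       r2_loso = r2_on_soil_means(loso$predicted, loso$observed,
                                  loso$soil_id),
       permutation_threshold = perm$threshold)
}
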
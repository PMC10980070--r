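make_ct <- function(counts, spike) {
  count_table(counts, spike)
}

test_that("spike-in normalization matches hand arithmetic and is scale-free", {
  counts <- matrix(c(100L, 0L, 40L, 10L), 2, 2,
                   dimnames = list(c("a1", "a2"), c("s1", "s2")))
  ct <- count_table(counts, c(s1 = 50, s2 = 20))
  ab <- normalize_spike_in(ct)
  expect_equal(ab$abundance["a1", "s1"], 100.5 / 50)
  expect_equal(ab$abundance["a2", "s1"], 0.5 / 50)  # pseudocount floor
  expect_equal(ab$total_biomass[["s1"]], 100 / 50)
  # scaling counts and spike-ins together leaves abundances unchanged
  ct2 <- count_table(counts * 10L, c(s1 = 500, s2 = 200))
  ab2 <- normalize_spike_in(ct2, pseudocount = 0)
  ab0 <- normalize_spike_in(ct, pseudocount = 0)
  expect_equal(ab2$abundance, ab0$abundance, tolerance = 1e-12)
  # zero-spike samples are dropped with a warning
  expect_warning(ct3 <- count_table(counts, c(s1 = 50, s2 = 0)), "zero spike")
  expect_equal(ncol(ct3$counts), 1L)
})

test_that("critical z matches the printed values and a bisection oracle", {
  expect_equal(round(critical_z(0.05, 2000), 1), 4.2)
  expect_equal(round(critical_z(0.05, 2500), 1), 4.3)
  expect_equal(critical_z(1, 1), 0)
  # brute-force bisection of the normal CDF
  bisect_z <- function(alpha, n) {
    target <- 1 - alpha / 2 / n
    lo <- 0; hi <- 10
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (pnorm(mid) < target) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (n in c(10, 2000, 2500))
    expect_equal(critical_z(0.05, n), bisect_z(0.05, n), tolerance = 1e-6)
})

test_that("noise model degenerates gracefully and recovers planted parameters", {
  # identical replicates -> no noise
  m0 <- matrix(rep(c(10L, 200L, 4000L), 3), ncol = 3)
  nm0 <- estimate_noise_model(m0)
  expect_equal(nm0$c_frac, 0)
  expect_equal(nm0$c0, 0)
  # planted two-component noise is recovered within the stated uncertainties
  m <- simulate_replicate_counts(c_frac = 0.21, c0 = 4.5, seed = 1)
  nm <- estimate_noise_model(m)
  expect_equal(nm$c_frac, 0.21, tolerance = 0.04 / 0.21)
  expect_lt(abs(nm$c0 - 4.5), 0.7)
  # sigma(n) accessor
  expect_equal(noise_sigma(nm, 0), nm$c0)
  expect_gt(noise_sigma(nm, 1000), noise_sigma(nm, 100))
  # the literal uncorrected rule is available and more conservative
  nm_lit <- estimate_noise_model(m, rule = "literal")
  expect_gt(nm_lit$c0, nm$c0)
  # no usable high-count slice -> clear error
  low <- matrix(sample(0:20, 60, TRUE), ncol = 3)
  expect_error(estimate_noise_model(low), "inestimable")
})

test_that("doubling all counts leaves the fractional noise invariant", {
  m <- simulate_replicate_counts(n_asv = 1500, c_frac = 0.15, c0 = 3,
                                 seed = 4)
  nm1 <- estimate_noise_model(m)
  nm2 <- estimate_noise_model(m * 2L)
  expect_equal(nm2$c_frac, nm1$c_frac, tolerance = 0.15)
  # while the noise floor scales up with the counts
  expect_gt(nm2$c0, nm1$c0)
})

test_that("enrichment z-scores detect planted growers and nothing else", {
  set.seed(31)
  n_asv <- 2000
  mu <- exp(runif(n_asv, log(50), log(5000)))
  growers <- sample(n_asv, 20)
  mu_minus <- mu
  mu_minus[growers] <- mu[growers] * 8
  c_frac <- 0.1; c0 <- 4.5
  draw <- function(m) {
    s <- sqrt((c_frac * m)^2 + c0^2)
    sapply(1:3, function(i) pmax(0, round(rnorm(length(m), m, s))))
  }
  cm <- draw(mu_minus); cp <- draw(mu)
  rownames(cm) <- rownames(cp) <- paste0("asv", seq_len(n_asv))
  nm <- estimate_noise_model(cp)
  z <- enrichment_zscores(cm, cp, nm)
  called <- which(z$enriched)
  expect_gte(mean(growers %in% called), 0.9)          # recall
  expect_lte(length(setdiff(called, growers)), 1L)    # false positives
  # identical arms yield zero z-scores and no calls
  z0 <- enrichment_zscores(cp, cp, nm)
  expect_true(all(z0$median_z == 0))
  expect_false(any(z0$enriched))
})

test_that("no-nitrate responders are subtracted from the enriched union", {
  expect_equal(filter_nn_responders(c("a", "b", "c"), c("b", "d")),
               c("a", "c"))
  expect_equal(filter_nn_responders(character(0), "b"), character(0))
})

test_that("false-call rate under the null stays within the Bonferroni budget", {
  set.seed(33)
  n_asv <- 2000
  mu <- exp(runif(n_asv, log(20), log(5000)))
  c_frac <- 0.12; c0 <- 4
  nm <- structure(list(c_frac = c_frac, c0 = c0, rule = "calibrated"),
                  class = "noise_model")
  n_rep_mc <- 200
  calls <- 0
  for (b in seq_len(n_rep_mc)) {
    s <- sqrt((c_frac * mu)^2 + c0^2)
    cm <- sapply(1:3, function(i) pmax(0, round(rnorm(n_asv, mu, s))))
    cp <- sapply(1:3, function(i) pmax(0, round(rnorm(n_asv, mu, s))))
    rownames(cm) <- rownames(cp) <- paste0("a", seq_len(n_asv))
    z <- enrichment_zscores(cm, cp, nm)
    calls <- calls + sum(z$enriched)
  }
  # expected false calls per condition family is at most alpha = 0.05
  expect_lte(calls / n_rep_mc, 0.05)
})

test_that("growth folds follow the stated log formula with clipping", {
  am <- matrix(c(0.1, 0.5, 0.001), 3, 1,
               dimnames = list(c("p1", "p2", "p3"), "c1"))
  ap <- matrix(c(0.001, 0.5, 0.1), 3, 1,
               dimnames = list(c("p1", "p2", "p3"), "c1"))
  G <- growth_fold_matrix(am, ap)
  expect_equal(G["p1", 1], log(0.101 / 0.002), tolerance = 1e-12)
  expect_equal(G["p2", 1], 0)       # equal abundances
  expect_equal(G["p3", 1], 0)       # negative fold clipped
  expect_true(all(G >= 0))
})

test_that("phylum aggregation sums member abundances and catches strays", {
  ab <- matrix(c(1, 2, 3, 4), 2, 2,
               dimnames = list(c("a1", "a2"), c("s1", "s2")))
  tax <- data.frame(asv = "a1", phylum = "Firmicutes")
  phy <- phylum_abundance(ab, tax)
  expect_equal(rownames(phy), c("Firmicutes", "unassigned"))
  expect_equal(phy["Firmicutes", "s1"], 1)
  expect_equal(phy["unassigned", "s2"], 4)
})

test_that("survival folds are one without death and track the generating biomass", {
  expect_equal(survival_folds(c(a = 1, b = 2), c(a = 1, b = 2)),
               c(a = 1, b = 1))
  tru <- make_soil_panel(soil_panel_spec(n_soils = 3, n_ph_levels = 13))
  sim <- simulate_counts(tru, soils = "soil1", seed = 6)
  m <- sim$table$meta
  ab <- normalize_spike_in(sim$table)$abundance
  phy <- phylum_abundance(ab, sim$table$taxonomy)
  t0 <- rowMeans(phy[, m$sample[m$timepoint == "T0"], drop = FALSE])
  cond <- tru$conditions[tru$conditions$soil_id == "soil1", ]
  cond <- cond[order(cond$perturbed_pH), ]
  sf <- sapply(cond$perturbed_pH, function(p) {
    sel <- m$sample[m$perturbed_pH == p & m$chl == 1 & m$timepoint == "end" &
                    m$nitrate]
    mean(survival_folds(rowMeans(phy[, sel, drop = FALSE]), t0)
         [!rownames(phy) %in% "Firmicutes"])
  })
  # survival falls toward acidic perturbations and rises with biomass
  expect_lt(mean(sf[1:3]), mean(sf[6:9]))
  expect_gt(cor(sf, cond$x0_tilde), 0.8)
})
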
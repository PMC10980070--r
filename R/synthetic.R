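#' Design of a synthetic soil microcosm panel
#'
#' Captures the full factorial design of the pH-perturbation experiment:
#' `n_soils` soils spanning a native pH range, each perturbed to 13 target
#' pH levels between 3 and 9 (the level nearest the soil's own pH replaced
#' by the unperturbed, dose-0 condition), in triplicate, with and without
#' chloramphenicol, sampled at 10 timepoints over 4 days with 2 mM initial
#' nitrate.
#'
#' @param n_soils Number of soils (default 20).
#' @param native_ph_range Range of native pH across soils (default
#'   4.7--8.3; soils are evenly spaced).
#' @param n_ph_levels Number of perturbed pH levels (default 13).
#' @param ph_range Perturbed pH span (default 3--9).
#' @param replicates Biological replicates per condition (default 3).
#' @param timepoints_hr Sampling times in hours.
#' @param A0 Initial nitrate, mM (default 2).
#' @param noise_sd Gaussian measurement noise on nitrate, mM (default 0.05).
#' @param seed Default RNG seed for the simulation steps (the ground truth
#'   itself is seed-independent).
#' @return Object of class `"soil_panel_spec"`.
#' @export
soil_panel_spec <- function(n_soils = 20, native_ph_range = c(4.7, 8.3),
                            n_ph_levels = 13, ph_range = c(3, 9),
                            replicates = 3,
                            timepoints_hr = c(0, 4, 8, 19, 25, 31, 43, 55, 67, 91),
                            A0 = 2, noise_sd = 0.05, seed = 1) {
  stopifnot(n_soils >= 1, n_ph_levels >= 2, replicates >= 1,
            length(timepoints_hr) >= 4, noise_sd >= 0, A0 > 0)
  structure(list(n_soils = n_soils, native_ph_range = native_ph_range,
                 n_ph_levels = n_ph_levels, ph_range = ph_range,
                 replicates = replicates, timepoints_hr = timepoints_hr,
                 A0 = A0, noise_sd = noise_sd, seed = seed),
            class = "soil_panel_spec")
}

# Analytic titration model of one soil: pH as a monotone asinh response to
# signed dose, pinned at pH 9.8 (base) and 2.2 (acid) at +/-100 mM. The
# acid-side buffering strengthens toward acidic native pH, so a fixed acid
# dose moves a neutral soil further than an acidic one.
titration_fun <- function(native_pH) {
  s_base <- 12
  s_acid <- 30 - 2.2 * (native_pH - 4.7)
  b_base <- (9.8 - native_pH) / asinh(100 / s_base)
  b_acid <- (native_pH - 2.2) / asinh(100 / s_acid)
  ph_of_dose <- function(d)
    ifelse(d >= 0, native_pH + b_base * asinh(d / s_base),
           native_pH - b_acid * asinh(-d / s_acid))
  dose_of_ph <- function(p)
    ifelse(p >= native_pH, s_base * sinh((p - native_pH) / b_base),
           -s_acid * sinh((native_pH - p) / b_acid))
  list(ph_of_dose = ph_of_dose, dose_of_ph = dose_of_ph)
}

#' Construct the ground truth of a synthetic soil panel
#'
#' Builds the deterministic parameter surfaces underlying a panel: for every
#' soil x perturbed-pH condition, the generating consumer-resource
#' parameters, the acid/base dose implied by the soil's titration curve, and
#' the resulting regime label. The surfaces are closed-form functions of the
#' soil's native pH and carry no randomness — different seeds later produce
#' different measurement noise on identical truth.
#'
#' Shapes: initial functional biomass `x0_tilde` sits on a plateau around
#' the native pH, collapses logistically below an acid-death edge whose pH
#' rises with native pH (planted trend: 0.7 x native + 0.8), and collapses
#' sharply above the basic edge where resurgent growth takes over; the
#' rescaled nutrient `C0_tilde` is a small background plus a term
#' proportional to the positive (NaOH) dose, so the nutrient threshold
#' `gamma * C0_tilde = 1.5` is crossed at a fixed dose on every soil and the
#' corresponding pH follows from each soil's titration curve.
#'
#' @param spec A [soil_panel_spec()].
#' @return Object of class `"soil_panel_truth"`: `spec`, `soils` (per-soil
#'   table with planted boundaries), `conditions` (per-condition generating
#'   parameters and regime), `counts` (count-generator defaults), plus the
#'   per-soil titration functions.
#' @export
make_soil_panel <- function(spec = soil_panel_spec()) {
  stopifnot(inherits(spec, "soil_panel_spec"))
  gamma <- 4.8
  x_floor <- 0.002
  plateau <- 0.35
  w_acid <- 0.25   # smooth I->II edge (pH units)
  w_base <- 0.08   # abrupt II->III edge
  C_base <- 0.03   # background nutrient, mM
  d_star <- 26     # NaOH dose at the nutrient threshold, mM (same per soil)
  c_rel <- (1.5 / gamma - C_base) / d_star  # released nutrient per mM NaOH

  native <- seq(spec$native_ph_range[1L], spec$native_ph_range[2L],
                length.out = spec$n_soils)
  titr <- lapply(native, titration_fun)

  soils <- data.frame(soil_id = paste0("soil", seq_len(spec$n_soils)),
                      native_pH = native,
                      b_I_II = 0.7 * native + 0.8,
                      b_II_III = vapply(seq_along(native), function(i)
                        titr[[i]]$ph_of_dose(d_star), numeric(1L)))

  conds <- list()
  for (i in seq_len(spec$n_soils)) {
    targets <- seq(spec$ph_range[1L], spec$ph_range[2L],
                   length.out = spec$n_ph_levels)
    targets[which.min(abs(targets - native[i]))] <- native[i]
    dose <- titr[[i]]$dose_of_ph(targets)
    x0 <- x_floor + plateau *
      stats::plogis((targets - soils$b_I_II[i]) / w_acid) *
      (1 - stats::plogis((targets - soils$b_II_III[i]) / w_base))
    C0 <- C_base + c_rel * pmax(dose, 0)
    conds[[i]] <- data.frame(soil_id = soils$soil_id[i],
                             native_pH = native[i],
                             perturbed_pH = targets, dose = dose,
                             x0_tilde = x0, C0_tilde = C0,
                             gammaC0_tilde = gamma * C0,
                             A0 = spec$A0, A0c = spec$A0,
                             gamma = gamma)
  }
  conditions <- do.call(rbind, conds)
  conditions$regime <- classify_regime(conditions$x0_tilde,
                                       conditions$gammaC0_tilde)
  structure(list(spec = spec, soils = soils, conditions = conditions,
                 titration = titr,
                 counts = list(n_asv = 2000, c_frac = 0.1, c0 = 4.5,
                               spike_frac = 0.089, growth_fold_II = 8,
                               growth_fold_III = 50, nn_fold = 8),
                 params = list(gamma = gamma, x_floor = x_floor,
                               plateau = plateau, w_acid = w_acid,
                               w_base = w_base, C_base = C_base,
                               c_rel = c_rel, d_star = d_star)),
            class = "soil_panel_truth")
}

#' @export
print.soil_panel_truth <- function(x, ...) {
  cat(sprintf("Synthetic soil panel truth: %d soils (native pH %.1f..%.1f), %d pH levels, %d conditions\n",
              nrow(x$soils), min(x$soils$native_pH), max(x$soils$native_pH),
              x$spec$n_ph_levels, nrow(x$conditions)))
  print(table(regime = x$conditions$regime))
  invisible(x)
}

#' Sampled titration points for one soil
#'
#' Emulates the titration assay: endpoint pH measured at `n_levels` HCl and
#' NaOH doses between 0 and 100 mM each (plus dose 0), optionally with
#' Gaussian pH read noise.
#'
#' @param truth A `"soil_panel_truth"`.
#' @param soil Soil index or id.
#' @param n_levels Dose levels per side (default 11, i.e. 23 points total).
#' @param ph_noise_sd pH measurement noise (default 0, exact curve).
#' @return Data frame `dose`, `endpoint_pH` suitable for
#'   [titration_curve()].
#' @export
titration_points <- function(truth, soil, n_levels = 11, ph_noise_sd = 0) {
  i <- if (is.character(soil)) match(soil, truth$soils$soil_id) else soil
  doses <- sort(unique(c(-exp(seq(log(1), log(100), length.out = n_levels)),
                         0,
                         exp(seq(log(1), log(100), length.out = n_levels)))))
  ph <- truth$titration[[i]]$ph_of_dose(doses)
  if (ph_noise_sd > 0) {
    noisy <- ph + stats::rnorm(length(ph), 0, ph_noise_sd)
    ph <- cummax(noisy)  # keep monotone
  }
  data.frame(dose = doses, endpoint_pH = ph)
}

#' Simulate the paired nitrate time-series panel
#'
#' Forward-simulates every condition of the panel with the consumer-resource
#' ODE model (both chloramphenicol arms), then adds iid Gaussian measurement
#' noise per replicate and clips at zero.
#'
#' @param truth A `"soil_panel_truth"` from [make_soil_panel()].
#' @param seed RNG seed (default: the spec's seed).
#' @param noise_sd Measurement noise sd, mM (default: the spec's).
#' @return Tidy data frame with columns `soil_id`, `native_pH`,
#'   `perturbed_pH`, `replicate`, `chl` (0/1), `time_hr`, `nitrate_mM`.
#' @export
simulate_experiment <- function(truth, seed = truth$spec$seed,
                                noise_sd = truth$spec$noise_sd) {
  stopifnot(inherits(truth, "soil_panel_truth"))
  set.seed(seed)
  spec <- truth$spec
  tt <- spec$timepoints_hr / 24
  conds <- truth$conditions
  out <- vector("list", nrow(conds) * 2L * spec$replicates)
  k <- 0L
  for (ci in seq_len(nrow(conds))) {
    p <- crm_params(x0_tilde = conds$x0_tilde[ci],
                    C0_tilde = conds$C0_tilde[ci],
                    A0 = conds$A0[ci], A0c = conds$A0c[ci],
                    gamma = conds$gamma[ci])
    for (chl in c(0L, 1L)) {
      A <- crm_simulate(p, tt, chl = chl == 1L, method = "ode")$A
      for (r in seq_len(spec$replicates)) {
        k <- k + 1L
        a <- if (noise_sd > 0)
          pmax(A + stats::rnorm(length(A), 0, noise_sd), 0) else A
        out[[k]] <- data.frame(soil_id = conds$soil_id[ci],
                               native_pH = conds$native_pH[ci],
                               perturbed_pH = conds$perturbed_pH[ci],
                               replicate = r, chl = chl,
                               time_hr = spec$timepoints_hr,
                               nitrate_mM = a)
      }
    }
  }
  do.call(rbind, out)
}

#' Triplicate replicate count tables under the two-component noise model
#'
#' Draws `n_rep` replicate measurements of `n_asv` ASVs whose true mean
#' counts are log-uniform over `mean_range`, each measurement Gaussian with
#' sd \eqn{\sigma(n) = \sqrt{(c_{frac} n)^2 + c_0^2}}, rounded to integers
#' and floored at zero. Used to exercise [estimate_noise_model()].
#'
#' @param n_asv Number of ASVs (default 2000).
#' @param mean_range Range of true mean counts (default 1--5000).
#' @param c_frac,c0 Generating noise parameters.
#' @param n_rep Replicates (default 3).
#' @param seed RNG seed.
#' @return Integer matrix, ASVs x replicates, with attribute `mean_counts`.
#' @export
simulate_replicate_counts <- function(n_asv = 2000, mean_range = c(1, 5000),
                                      c_frac = 0.21, c0 = 4.5, n_rep = 3,
                                      seed = 1) {
  set.seed(seed)
  mu <- exp(stats::runif(n_asv, log(mean_range[1L]), log(mean_range[2L])))
  sig <- sqrt((c_frac * mu)^2 + c0^2)
  m <- vapply(seq_len(n_rep),
              function(i) pmax(0, round(stats::rnorm(n_asv, mu, sig))),
              numeric(n_asv))
  dimnames(m) <- list(paste0("asv", seq_len(n_asv)),
                      paste0("rep", seq_len(n_rep)))
  attr(m, "mean_counts") <- mu
  m
}

# deterministic ASV universe shared by all count simulations:
# phylum assignment cycles through a fixed composition so every phylum
# spans the abundance range; baseline mean counts are log-spaced.
asv_universe <- function(n_asv) {
  comp <- c(Proteobacteria = 30, Bacteroidota = 15, Firmicutes = 10,
            Actinobacteriota = 12, Acidobacteriota = 10, Chloroflexi = 8,
            Planctomycetota = 6, Verrucomicrobiota = 5, Myxococcota = 4)
  cycle <- rep(names(comp), comp)
  phylum <- rep_len(cycle, n_asv)
  baseline <- 10^seq(log10(2), log10(2000), length.out = n_asv)
  # shuffle deterministically (golden-ratio stride) to decouple abundance
  # from phylum blocks
  ord <- order((seq_len(n_asv) * 0.6180339887) %% 1)
  data.frame(asv = paste0("asv", seq_len(n_asv)), phylum = phylum,
             baseline = baseline[ord])
}

#' Simulate spike-in count tables for the sequenced panel
#'
#' Generates T0, endpoint CHL- and CHL+ (all perturbed pH levels) and
#' no-nitrate control samples for a subset of soils, with planted growth:
#' Proteobacteria/Bacteroidota ASVs grow in nutrient-limiting (Regime II)
#' conditions, a soil-specific window of rare Firmicutes ASVs — positioned
#' along the taxon pool by the soil's native pH rank, so neighbouring-pH
#' soils share resurgent taxa — grows in resurgent (Regime III) conditions,
#' and a fixed set of no-nitrate responders grows in unperturbed CHL-
#' conditions regardless of nitrate. Survival in the CHL+ arm scales with
#' the condition's generating biomass, so acid-perturbed communities die
#' back (Firmicutes exempt). Counts get two-component Gaussian noise
#' (rounded, floored at zero) and every sample carries two spike-in
#' reference taxa of equal input with multiplicative sample-to-sample
#' variation.
#'
#' @param truth A `"soil_panel_truth"`.
#' @param soils Soil ids (or indices) to sequence; default the first 10.
#' @param n_asv Number of analyte ASVs.
#' @param seed RNG seed.
#' @return List with `table` (a [count_table()]), `spike_counts` (2 x
#'   samples matrix of the individual spike-in ASVs) and `planted` (per-soil
#'   truly-growing ASV sets and the no-nitrate responder set).
#' @export
simulate_counts <- function(truth, soils = NULL, n_asv = truth$counts$n_asv,
                            seed = truth$spec$seed) {
  stopifnot(inherits(truth, "soil_panel_truth"))
  set.seed(seed)
  cp <- truth$counts
  if (is.null(soils)) soils <- utils::head(truth$soils$soil_id, 10L)
  if (is.numeric(soils)) soils <- truth$soils$soil_id[soils]
  uni <- asv_universe(n_asv)

  firm <- which(uni$phylum == "Firmicutes")
  actino <- which(uni$phylum == "Actinobacteriota")
  grow_II <- which(uni$phylum %in% c("Proteobacteria", "Bacteroidota"))
  nn_set <- actino[seq_len(min(30L, length(actino)))]

  # pH-ordered resurgent pools: window of the Firmicutes list per soil
  rank_of <- rank(truth$soils$native_pH)[match(soils, truth$soils$soil_id)]
  width <- max(10L, length(firm) %/% 3L)
  centers <- 1 + (rank_of - 1) / max(nrow(truth$soils) - 1, 1) *
    (length(firm) - width)
  planted_III <- lapply(seq_along(soils), function(i) {
    idx <- firm[seq(floor(centers[i]), length.out = width)]
    uni$asv[idx[!is.na(idx)]]
  })
  names(planted_III) <- soils

  # Firmicutes outside every soil's window stay rare background; within a
  # soil only its own window is present at baseline
  meta_rows <- list(); cols <- list(); spike1 <- spike2 <- numeric(0)
  x_scale <- truth$params$x_floor + truth$params$plateau
  conds <- truth$conditions

  # the spike-in is a fixed gDNA input per sample, independent of how much
  # the community grew: its expected reads are tied to the nominal
  # baseline library, not to the realized sample reads
  s_input <- sum(uni$baseline) * cp$spike_frac / (1 - cp$spike_frac)

  add_sample <- function(mean_vec, id, soil_id, native_pH, perturbed_pH,
                         replicate, chl, timepoint, nitrate) {
    sig <- sqrt((cp$c_frac * mean_vec)^2 + cp$c0^2)
    cnt <- pmax(0, round(stats::rnorm(length(mean_vec), mean_vec, sig)))
    cnt[mean_vec <= 0] <- 0  # absent taxa yield no reads
    s_common <- s_input / 2 * exp(stats::rnorm(1, 0, 0.3))
    s1 <- max(1, round(s_common * exp(stats::rnorm(1, 0, 0.05))))
    s2 <- max(1, round(s_common * exp(stats::rnorm(1, 0, 0.05))))
    cols[[id]] <<- cnt
    spike1[id] <<- s1; spike2[id] <<- s2
    meta_rows[[id]] <<- data.frame(sample = id, soil_id = soil_id,
                                   native_pH = native_pH,
                                   perturbed_pH = perturbed_pH,
                                   replicate = replicate, chl = chl,
                                   timepoint = timepoint, nitrate = nitrate)
  }

  for (si in seq_along(soils)) {
    s <- soils[si]
    srow <- truth$soils[truth$soils$soil_id == s, ]
    base <- uni$baseline
    # soil's Firmicutes complement: only its own pool present
    absent_firm <- setdiff(uni$asv[firm], planted_III[[si]])
    base[match(absent_firm, uni$asv)] <- 0
    sc <- conds[conds$soil_id == s, ]
    unpert <- which.min(abs(sc$perturbed_pH - srow$native_pH))
    for (r in seq_len(truth$spec$replicates))
      add_sample(base, sprintf("%s_T0_r%d", s, r), s, srow$native_pH,
                 srow$native_pH, r, 0L, "T0", TRUE)
    for (ci in seq_len(nrow(sc))) {
      reg <- as.character(sc$regime[ci])
      surv <- pmin(1, pmax(0.05, sc$x0_tilde[ci] / x_scale))
      m_plus <- base * surv
      m_plus[firm] <- base[firm]  # acid-tolerant
      m_minus <- m_plus
      if (reg == "II") m_minus[grow_II] <- m_minus[grow_II] * cp$growth_fold_II
      if (reg == "III") {
        iii <- match(planted_III[[si]], uni$asv)
        m_minus[iii] <- pmax(m_minus[iii], 0.5) * cp$growth_fold_III
      }
      if (ci == unpert) m_minus[nn_set] <- m_minus[nn_set] * cp$nn_fold
      for (r in seq_len(truth$spec$replicates)) {
        add_sample(m_minus, sprintf("%s_pH%0.1f_CHLm_r%d", s,
                                    sc$perturbed_pH[ci], r),
                   s, srow$native_pH, sc$perturbed_pH[ci], r, 0L, "end", TRUE)
        add_sample(m_plus, sprintf("%s_pH%0.1f_CHLp_r%d", s,
                                   sc$perturbed_pH[ci], r),
                   s, srow$native_pH, sc$perturbed_pH[ci], r, 1L, "end", TRUE)
      }
    }
    # no-nitrate controls at the unperturbed condition: no regime growth,
    # but the NN responders grow in the CHL- arm
    m_nn_plus <- base
    m_nn_minus <- base
    m_nn_minus[nn_set] <- m_nn_minus[nn_set] * cp$nn_fold
    for (r in seq_len(truth$spec$replicates)) {
      add_sample(m_nn_minus, sprintf("%s_NN_CHLm_r%d", s, r), s,
                 srow$native_pH, srow$native_pH, r, 0L, "end", FALSE)
      add_sample(m_nn_plus, sprintf("%s_NN_CHLp_r%d", s, r), s,
                 srow$native_pH, srow$native_pH, r, 1L, "end", FALSE)
    }
  }

  counts <- do.call(cbind, cols)
  rownames(counts) <- uni$asv
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  spike <- rbind(spike_Ecoli = spike1[colnames(counts)],
                 spike_Para = spike2[colnames(counts)])
  ct <- count_table(counts, colSums(spike),
                    taxonomy = uni[, c("asv", "phylum")], meta = meta)
  list(table = ct, spike_counts = spike,
       planted = list(regime_III = planted_III, regime_II = uni$asv[grow_II],
                      nn_responders = uni$asv[nn_set]))
}
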
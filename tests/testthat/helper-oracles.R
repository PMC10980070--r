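# shared fixtures and independent oracles

# the microcosm sampling grid, in days
grid_days <- c(0, 4, 8, 19, 25, 31, 43, 55, 67, 91) / 24

# independent fixed-step Euler integration of the rescaled system,
# used as an oracle for the adaptive solver
euler_nitrate <- function(params, times, chl = FALSE, dt = 2e-5) {
  A <- if (chl) params$A0c else params$A0
  C <- params$C0_tilde
  x <- params$x0_tilde
  out <- numeric(length(times))
  j <- 1L
  t <- 0
  tmax <- max(times)
  while (t <= tmax + dt) {
    while (j <= length(times) && times[j] <= t + 1e-12) {
      out[j] <- A
      j <- j + 1L
    }
    mA <- A / (A + params$KA)
    mC <- C / (C + params$KC_tilde)
    A <- max(A - dt * x * mA, 0)
    C <- max(C - dt * x * mC, 0)
    if (!chl) x <- x + dt * params$gamma * x * mA * mC
    t <- t + dt
  }
  out
}

# build a noiseless or noisy sample pair from generating parameters
make_pair <- function(params, times = grid_days, noise_sd = 0,
                      method = "ode", seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  Am <- crm_simulate(params, times, chl = FALSE, method = method)$A
  Ap <- crm_simulate(params, times, chl = TRUE, method = method)$A
  if (noise_sd > 0) {
    Am <- pmax(Am + rnorm(length(Am), 0, noise_sd), 0)
    Ap <- pmax(Ap + rnorm(length(Ap), 0, noise_sd), 0)
  }
  sample_pair(times_minus = times, nitrate_minus = Am,
              times_plus = times, nitrate_plus = Ap, ...)
}

# closed-form soft-threshold oracle for the single-predictor LASSO
soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

# small deterministic presence-design generator: soils with pH-ordered
# taxon windows so that neighbouring-pH soils share taxa
make_presence_design <- function(n_soils = 10, reps = 4, n_taxa = 60,
                                 width = 18, noise = 0.05, seed = 1) {
  set.seed(seed)
  native <- seq(4.7, 8.3, length.out = n_soils)
  rows <- list()
  for (i in seq_len(n_soils)) {
    start <- 1 + round((i - 1) / (n_soils - 1) * (n_taxa - width))
    base <- rep(0, n_taxa)
    base[start:(start + width - 1)] <- 1
    for (r in seq_len(reps)) {
      row <- base
      flip <- runif(n_taxa) < noise
      row[flip] <- 1 - row[flip]
      rows[[length(rows) + 1L]] <- row
    }
  }
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("t", seq_len(n_taxa))
  list(X = X, y = rep(native, each = reps),
       soil = rep(paste0("s", seq_len(n_soils)), each = reps))
}
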
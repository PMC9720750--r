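# Independent oracles used across the test files.  These deliberately avoid
# the package's own code paths.

# Second, independent evaluation of the Garcia-Gordon saturation fit
# (Horner form) and vapour-pressure correction.
oracle_so2 <- function(temp_c, salinity_psu) {
  ts <- log((298.15 - temp_c) / (273.15 + temp_c))
  ln_c <- ((((3.88767 * ts - 0.256847) * ts + 4.94457) * ts + 4.05010) *
             ts + 3.22014) * ts + 2.00907 +
    salinity_psu * (((-8.17083e-3 * ts - 1.03410e-2) * ts - 7.37614e-3) *
                      ts - 6.24523e-3) -
    4.88682e-7 * salinity_psu^2
  c_umol_l <- exp(ln_c) * 1000 / 22.3916
  tk <- temp_c + 273.15
  pv_torr <- 760 * exp(24.4543 - 67.4509 * 100 / tk -
                         4.8489 * log(tk / 100) - 0.000544 * salinity_psu)
  c_umol_l / (0.20946 * (760 - pv_torr))
}

# Brute-force LMG: explicitly enumerate admissible orderings, refit with
# lm() at every step, and average the sequential R2 increments.
oracle_lmg <- function(y, groups, parents = NULL) {
  p <- length(groups)
  nms <- names(groups)
  r2_of <- function(members) {
    if (!length(members)) return(0)
    x <- do.call(cbind, lapply(groups[members], as.matrix))
    summary(lm(y ~ x))$r.squared
  }
  perms <- gtools_permutations(p)
  shares <- setNames(numeric(p), nms)
  n_adm <- 0
  for (i in seq_len(nrow(perms))) {
    ord <- perms[i, ]
    ok <- TRUE
    if (!is.null(parents)) {
      for (j in seq_len(p)) {
        req <- parents[[nms[ord[j]]]]
        if (!is.null(req) &&
              !all(req %in% nms[ord[seq_len(j - 1)]])) {
          ok <- FALSE
          break
        }
      }
    }
    if (!ok) next
    n_adm <- n_adm + 1
    prev <- 0
    for (j in seq_len(p)) {
      cur <- r2_of(ord[seq_len(j)])
      shares[ord[j]] <- shares[ord[j]] + (cur - prev)
      prev <- cur
    }
  }
  shares / n_adm
}

gtools_permutations <- function(p) {
  if (p == 1) return(matrix(1L, 1, 1))
  do.call(rbind, lapply(seq_len(p), function(k) {
    sub <- gtools_permutations(p - 1L)
    cbind(k, matrix(setdiff(seq_len(p), k)[sub], nrow(sub)))
  }))
}

# Random multi-group regression design for LMG property tests.
random_lmg_design <- function(n_groups, n = 50) {
  groups <- list()
  for (g in seq_len(n_groups)) {
    ncol_g <- sample(1:2, 1)
    groups[[paste0("g", g)]] <- matrix(rnorm(n * ncol_g), n)
  }
  x_all <- do.call(cbind, groups)
  beta <- rnorm(ncol(x_all))
  # correlate the groups a little so orderings matter
  x_all <- x_all + rnorm(n)
  groups <- local({
    idx <- 1
    out <- list()
    for (nm in names(groups)) {
      k <- ncol(groups[[nm]])
      out[[nm]] <- x_all[, idx:(idx + k - 1), drop = FALSE]
      idx <- idx + k
    }
    out
  })
  y <- x_all %*% beta + rnorm(n, sd = 2)
  list(y = as.numeric(y), groups = groups)
}

# Metabolic records generated directly from the Arrhenius model, without
# the package generator: one site, explicit temperatures and energies.
direct_arrhenius_records <- function(temps_c, e_ev, n_per_temp = 20,
                                     intercept = -1, sigma = 0,
                                     k = 8.617333e-5) {
  df <- expand.grid(temp_level_c = temps_c, i = seq_len(n_per_temp))
  x <- 1 / (k * (df$temp_level_c + 273.15))
  ln_rate <- intercept - e_ev * x + rnorm(nrow(df), 0, sigma)
  data.frame(site = "S1", temp_level_c = df$temp_level_c,
             dry_mass_mg = 1, mass_specific_smr = exp(ln_rate),
             smr_j_per_day = exp(ln_rate))
}
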
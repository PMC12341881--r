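# shared fixtures: small simulated cohorts and brute-force oracles

small_design <- function(n_batches = 4, batch_size = 40, ...) {
  cohort_design(n_batches = n_batches, batch_sizes = batch_size,
                n_companies = 2, ...)
}

small_study <- function(seed, n_snps = 400, n_chr = 4, design = NULL, ...) {
  p <- sim_params(n_snps = n_snps, n_chromosomes = n_chr, seed = seed, ...)
  set.seed(seed)
  if (is.null(design)) design <- small_design()
  simulate_study(p, design, seed = seed)
}

# full-size study matching the recovery-analysis conditions
recovery_study <- function(seed, ...) {
  set.seed(seed)
  d <- cohort_design(n_batches = 12, batch_sizes = 67)
  simulate_study(sim_params(seed = seed, ...), d, seed = seed)
}

# brute-force VanRaden method-1 G, written as plain loops so it shares no
# code path with vanraden_g()
oracle_vanraden <- function(M, freqs = NULL) {
  if (is.null(freqs)) freqs <- colMeans(M) / 2
  keep <- freqs > 0 & freqs < 1
  M <- M[, keep, drop = FALSE]
  freqs <- freqs[keep]
  n <- nrow(M)
  G <- matrix(0, n, n)
  denom <- 0
  for (j in seq_along(freqs)) denom <- denom + 2 * freqs[j] * (1 - freqs[j])
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      s <- 0
      for (j in seq_along(freqs)) {
        s <- s + (M[i, j] - 2 * freqs[j]) * (M[k, j] - 2 * freqs[j])
      }
      G[i, k] <- s / denom
    }
  }
  G
}

# brute-force per-iteration window variance of genomic values from stored
# effect samples (independent of the C++ accumulation)
oracle_window_vars <- function(M, beta_mat, delta_mat, window_of_snp,
                               n_windows) {
  n_it <- nrow(beta_mat)
  out <- matrix(0, n_it, n_windows)
  tot <- numeric(n_it)
  for (it in seq_len(n_it)) {
    a <- beta_mat[it, ] * delta_mat[it, ]
    g_tot <- as.vector(M %*% a)
    tot[it] <- var(g_tot)
    for (w in seq_len(n_windows)) {
      snps <- which(window_of_snp == w)
      gw <- as.vector(M[, snps, drop = FALSE] %*% a[snps])
      out[it, w] <- var(gw)
    }
  }
  list(var_window = out, var_genomic = tot)
}

# brute-force GSEA running sum (re-derivation, kept independent of
# .gsea_es): returns the full running-sum vector
oracle_gsea_running <- function(scores, hit_pos, p = 1) {
  n <- length(scores)
  is_hit <- seq_len(n) %in% hit_pos
  w <- abs(scores)^p
  nr <- sum(w[is_hit])
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (is_hit[i]) {
      cur <- cur + (if (nr > 0) w[i] / nr else 1 / sum(is_hit))
    } else {
      cur <- cur - 1 / (n - sum(is_hit))
    }
    run[i] <- cur
  }
  run
}
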
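shared_qtl_params <- function(seed, egv2 = 0.4) {
  sim_params(qtl = tibble::tibble(snp = NA_integer_, effect = -0.35,
                                  effect2 = -0.30, egv_frac = 0.453,
                                  egv_frac2 = egv2,
                                  freq_landrace = 0.12,
                                  freq_yorkshire = 0.082),
             seed = seed)
}

test_that("ad_statistic computes |PP_pos - PP_neg| with range validation", {
  expect_equal(ad_statistic(0.3, 0.3), 0)
  expect_equal(ad_statistic(0, 1), 1)
  expect_equal(ad_statistic(0.05, 0.01), 0.04)
  # boundary: 0.021 exceeds the 0.02 flag threshold strictly
  expect_gt(ad_statistic(0.021, 0), 0.02)
  expect_true(ad_statistic(0.3, 0.1) == ad_statistic(0.1, 0.3))
  expect_error(ad_statistic(1.2, 0), "\\[0, 1\\]")
  expect_error(ad_statistic(0.7, 0.6), "exceed")
})

test_that("window sign probabilities follow their definitions on a hand-built chain", {
  ch <- list(
    traits = c("a", "b"), n_kept = 100L,
    windows = tibble::tibble(window = 1:3, chr = 1,
                             start = c(0, 0.25, 0.5) * 1e6,
                             end = c(0.25, 0.5, 0.75) * 1e6),
    window_of_snp = c(1L, 2L, 3L),
    cov_window = cbind(rep(1, 100),                  # always positive
                       c(rep(0.5, 5), rep(-0.5, 1), rep(0, 94)),
                       rep(0, 100)),                 # never in the model
    var_window1 = matrix(1, 100, 3), var_window2 = matrix(1, 100, 3),
    window_bp = 0.25e6)
  class(ch) <- "bayesb_bv_chain"
  pw <- window_sign_probs(ch)
  expect_equal(pw$pp_pos, c(1, 0.05, 0))
  expect_equal(pw$pp_neg, c(0, 0.01, 0))
  expect_equal(pw$ad, c(1, 0.04, 0))
  expect_equal(pw$flagged, c(TRUE, TRUE, FALSE))
  expect_true(all(pw$pp_pos + pw$pp_neg <= 1))
  # the statistic is exactly symmetric in trait order: relabelling the
  # traits leaves every window covariance, hence every Ad, unchanged
  ch_sw <- ch
  ch_sw$traits <- rev(ch$traits)
  ch_sw$var_window1 <- ch$var_window2
  ch_sw$var_window2 <- ch$var_window1
  expect_identical(window_sign_probs(ch_sw)$ad, pw$ad)
})

test_that("a planted shared QTL is detected and trait order does not matter", {
  set.seed(61)
  d <- cohort_design(n_batches = 6, batch_sizes = 67)
  p <- shared_qtl_params(61)
  st <- simulate_study(p, d, seed = 61)
  cfg <- bayesb_config("desk", chain_length = 4000, burnin = 800,
                       store_effects_every = 10L)
  ch <- run_bivariate_bayesb(st$phenotypes, c("ln_cortisol", "ln_hormone2"),
                             st$genotypes, cfg, seed = 62)
  pw <- window_sign_probs(ch)
  qtl_window <- ch$window_of_snp[st$genotypes$qtl$snp[1]]
  expect_equal(pw$window[which.max(pw$ad)], qtl_window)
  expect_true(pw$flagged[pw$window == qtl_window])
  # joint inclusion beats single-trait-only inclusion at the shared SNP
  j <- st$genotypes$qtl$snp[1]
  expect_gt(ch$snps$pip_both[j],
            max(ch$snps$pip1[j] - ch$snps$pip_both[j],
                ch$snps$pip2[j] - ch$snps$pip_both[j]))

  # swapped trait order: same window wins, Ad close in Monte Carlo error
  ch_sw <- run_bivariate_bayesb(st$phenotypes,
                                c("ln_hormone2", "ln_cortisol"),
                                st$genotypes, cfg, seed = 62)
  pw_sw <- window_sign_probs(ch_sw)
  expect_equal(pw_sw$window[which.max(pw_sw$ad)], qtl_window)
  expect_equal(pw_sw$ad[pw_sw$window == qtl_window],
               pw$ad[pw$window == qtl_window], tolerance = 0.1)
})

test_that("per-iteration window covariances match a brute-force recomputation", {
  set.seed(63)
  d <- cohort_design(n_batches = 3, batch_sizes = 40, n_companies = 2)
  p <- shared_qtl_params(63)
  p$n_snps <- 200; p$n_chromosomes <- 2
  st <- simulate_study(p, d, seed = 63)
  cfg <- bayesb_config("desk", chain_length = 600, burnin = 150,
                       store_effects_every = 5L)
  ch <- run_bivariate_bayesb(st$phenotypes, c("ln_cortisol", "ln_hormone2"),
                             st$genotypes, cfg, seed = 64)
  M <- st$genotypes$dosage[ch$pigs, ]
  kept <- seq(1, ch$n_kept, by = 5L)
  for (row_i in seq_along(kept)) {
    a1 <- ch$beta1_samples[row_i, ]
    a2 <- ch$beta2_samples[row_i, ]
    for (w in sample(nrow(ch$windows), 5)) {
      snps <- which(ch$window_of_snp == w)
      w1 <- as.vector(M[, snps, drop = FALSE] %*% a1[snps])
      w2 <- as.vector(M[, snps, drop = FALSE] %*% a2[snps])
      expect_equal(ch$cov_window[kept[row_i], w], cov(w1, w2),
                   tolerance = 1e-10)
    }
  }
})

test_that("a genotype-independent second trait stays out of the model", {
  set.seed(65)
  d <- cohort_design(n_batches = 6, batch_sizes = 67)
  st <- simulate_study(sim_params(seed = 65), d, seed = 65)
  dat <- st$phenotypes
  dat$pure_noise <- rnorm(nrow(dat))
  cfg <- bayesb_config("desk", chain_length = 3000, burnin = 600,
                       store_effects_every = 0)
  ch <- run_bivariate_bayesb(dat, c("ln_cortisol", "pure_noise"),
                             st$genotypes, cfg, seed = 66)
  expect_lt(max(ch$snps$pip2), 0.3)
  expect_lt(mean(ch$snps$pip2), 0.005)
  # trait-1 margin still finds the planted QTL
  j <- st$genotypes$qtl$snp[1]
  expect_gt(ch$snps$pip1[j], 0.8)
})

test_that("identical traits give nonnegative window covariances throughout", {
  set.seed(67)
  d <- cohort_design(n_batches = 4, batch_sizes = 50, n_companies = 2)
  p <- shared_qtl_params(67)
  p$n_snps <- 300; p$n_chromosomes <- 3
  st <- simulate_study(p, d, seed = 67)
  dat <- dplyr::mutate(st$phenotypes, ln_copy = ln_cortisol)
  cfg <- bayesb_config("desk", chain_length = 1500, burnin = 300,
                       store_effects_every = 0)
  ch <- run_bivariate_bayesb(dat, c("ln_cortisol", "ln_copy"),
                             st$genotypes, cfg, seed = 68)
  pw <- window_sign_probs(ch)
  expect_equal(sum(pw$pp_neg), 0)
  expect_gte(min(ch$cov_window), 0)
})
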
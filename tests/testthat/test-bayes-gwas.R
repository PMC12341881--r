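test_that("the default configuration matches the analysis protocol", {
  cfg <- bayesb_config()
  expect_equal(cfg$pi, 0.999)
  expect_equal(cfg$chain_length, 80000L)
  expect_equal(cfg$burnin, 5000L)
  desk <- bayesb_config("desk")
  expect_equal(desk$chain_length, 8000L)
  expect_equal(desk$burnin, 1000L)
  expect_error(bayesb_config(pi = 1), "pi")
  expect_error(bayesb_config(chain_length = 100, burnin = 200), "burnin")
})

test_that("genome windows tile each chromosome half-open without overlap", {
  map <- tibble::tibble(chr = c(1, 1, 1, 2, 2),
                        pos = c(0, 999999, 1000000, 500000, 2500000))
  tw <- genome_windows(map, 1e6)
  expect_equal(tw$window_of_snp, c(1, 1, 2, 3, 4))
  expect_true(all(tw$windows$end - tw$windows$start == 1e6))
  # nonoverlap within chromosome
  for (cc in unique(tw$windows$chr)) {
    w <- tw$windows[tw$windows$chr == cc, ]
    expect_true(all(w$start[-1] >= head(w$end, -1)))
  }
})

test_that("the effect sampler reproduces the conjugate single-SNP posterior", {
  set.seed(51)
  n <- 400
  m <- rbinom(n, 2, 0.3)
  sigma_b2 <- 0.04; sigma_e2 <- 0.9
  beta_true <- 0.25
  y <- m * beta_true + rnorm(n, 0, sqrt(sigma_e2))
  res <- hairqtl:::.bayesb_chain_cpp(
    y, matrix(0, n, 0), matrix(as.numeric(m), n, 1),
    list(), integer(0), 0L, 1L,
    1e-6, FALSE, FALSE, 6000L, 1000L, 1L,
    4, sigma_b2 / 2,          # scaled-inv-chi2 with nu=4 has mean nu*S/(nu-2)
    4, 0, 4, 0,
    FALSE, FALSE, sigma_e2, 1L)
  c0 <- sum(m^2)
  prec <- c0 + sigma_e2 / sigma_b2
  post_mean <- sum(m * y) / prec
  post_sd <- sqrt(sigma_e2 / prec)
  draws <- res$beta_samples[, 1]
  expect_equal(mean(draws), post_mean, tolerance = 4 * post_sd / sqrt(200))
  expect_equal(sd(draws), post_sd, tolerance = 0.2 * post_sd)
})

test_that("chains are bit-reproducible under a fixed seed", {
  st <- small_study(5200)
  cfg <- bayesb_config("desk", chain_length = 1500, burnin = 300)
  ch1 <- run_bayesb(st$phenotypes, "ln_cortisol", st$genotypes, cfg, seed = 5)
  ch2 <- run_bayesb(st$phenotypes, "ln_cortisol", st$genotypes, cfg, seed = 5)
  expect_identical(ch1$snps$pip, ch2$snps$pip)
  expect_identical(ch1$var_window, ch2$var_window)
  expect_true(all(ch1$snps$pip >= 0 & ch1$snps$pip <= 1))
})

test_that("a planted QTL window dominates the %EGV ranking in one desk chain", {
  st <- recovery_study(5300)
  ch <- run_bayesb(st$phenotypes, "ln_cortisol", st$genotypes,
                   bayesb_config("desk", chain_length = 4000, burnin = 800),
                   seed = 53)
  ws <- window_egv(ch)
  qtl_window <- ch$window_of_snp[st$genotypes$qtl$snp[1]]
  expect_equal(ws$window[which.max(ws$pct_egv)], qtl_window)
  expect_true(ws$qtl[ws$window == qtl_window])
  expect_gt(ws$pct_egv[ws$window == qtl_window], 20)
})

test_that("per-iteration window variances match a brute-force recomputation", {
  st <- small_study(5400, n_snps = 200, n_chr = 2)
  cfg <- bayesb_config("desk", chain_length = 800, burnin = 200,
                       store_effects_every = 5L)
  ch <- run_bayesb(st$phenotypes, "ln_cortisol", st$genotypes, cfg, seed = 54)
  M <- st$genotypes$dosage[ch$pigs, ]
  orc <- oracle_window_vars(M, ch$beta_samples, ch$delta_samples,
                            ch$window_of_snp, nrow(ch$windows))
  kept_rows <- seq(1, ch$n_kept, by = 5L)
  expect_equal(unname(ch$var_window[kept_rows, ]), unname(orc$var_window),
               tolerance = 1e-10)
  expect_equal(ch$var_genomic[kept_rows], orc$var_genomic, tolerance = 1e-10)
})

test_that("window %EGV handles degenerate chains and is SNP-order invariant", {
  # hand-constructed chain: 3 windows, 4 retained iterations
  base <- list(
    response = "y", n_kept = 4L,
    windows = tibble::tibble(window = 1:3, chr = 1, start = c(0, 1, 2) * 1e6,
                             end = c(1, 2, 3) * 1e6),
    window_of_snp = c(1L, 2L, 3L),
    snps = tibble::tibble(snp = 1:3, id = paste0("s", 1:3), chr = 1,
                          pos = c(1, 1e6 + 1, 2e6 + 1), pip = c(0, 1, 0),
                          beta_mean = 0),
    var_window = matrix(0, 4, 3), var_genomic = rep(0, 4),
    window_bp = 1e6)
  class(base) <- "bayesb_chain"
  ws0 <- suppressWarnings(window_egv(base))
  expect_equal(ws0$pct_egv, rep(0, 3))

  one <- base
  one$var_window <- cbind(0, c(2, 2, 2, 2), 0)
  one$var_genomic <- rep(2, 4)
  ws1 <- suppressWarnings(window_egv(one))
  expect_equal(ws1$pct_egv, c(0, 100, 0))
  expect_equal(ws1$lead_snp[2], "s2")
})

test_that("null phenotypes yield bounded PIPs and a near-zero genetic share", {
  set.seed(55)
  d <- cohort_design(n_batches = 12, batch_sizes = 67)
  st <- simulate_study(sim_params(qtl = NULL, seed = 55), d, seed = 55)
  cfg <- bayesb_config("desk", chain_length = 3000, burnin = 500,
                       store_effects_every = 0)
  maxpip <- vg_share <- numeric(8)
  for (r in 1:8) {
    dat <- tibble::tibble(pig = st$design$pig, y = rnorm(nrow(st$design)))
    ch <- run_bayesb(dat, "y", st$genotypes, cfg, fixed = ~1,
                     random = character(0), seed = 9100 + r)
    maxpip[r] <- max(ch$snps$pip)
    vg_share[r] <- mean(ch$var_genomic) / var(dat$y)
  }
  expect_gte(sum(maxpip < 0.2), 6)
  expect_true(all(vg_share < 0.05))
})

test_that("BayesCpi recovers the exclusion probability", {
  st <- small_study(5600, n_snps = 2000, n_chr = 10,
                    design = cohort_design(n_batches = 8, batch_sizes = 60,
                                           n_companies = 2),
                    qtl = NULL)
  M <- st$genotypes$dosage
  set.seed(56)
  causal <- sample(ncol(M), 10)
  b <- rnorm(10, 0, 0.4)
  dat <- st$phenotypes
  dat$y_sparse <- as.vector(M[dat$pig, causal] %*% b) + rnorm(nrow(dat), 0, 1)
  cfg <- bayesb_config("desk", chain_length = 4000, burnin = 800)
  est <- estimate_pi_bayescpi(dat, "y_sparse", st$genotypes, cfg,
                              fixed = ~1, random = character(0), seed = 57)
  expect_gte(est$pi_mean, 0.98)
  expect_lte(est$pi_mean, 0.9995)

  dat$y_null <- rnorm(nrow(dat))
  est0 <- estimate_pi_bayescpi(dat, "y_null", st$genotypes, cfg,
                               fixed = ~1, random = character(0), seed = 58)
  expect_gte(est0$pi_mean, 0.99)
})

test_that("chain diagnostics return finite summaries", {
  st <- small_study(5700, n_snps = 200, n_chr = 2)
  ch <- run_bayesb(st$phenotypes, "ln_cortisol", st$genotypes,
                   bayesb_config("desk", chain_length = 1500, burnin = 300),
                   seed = 59)
  dg <- suppressWarnings(chain_diagnostics(ch))
  expect_true(is.finite(dg$geweke_z))
  expect_true(is.finite(dg$ess) && dg$ess > 0)
})
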
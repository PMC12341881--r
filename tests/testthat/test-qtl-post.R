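test_that("log-scale effects convert to original-scale percent changes", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(-0.35), 100 * (exp(-0.35) - 1))
  # forward and backward changes multiply back to no change exactly
  set.seed(71)
  for (b in rnorm(20)) {
    p1 <- percent_change(b); p2 <- percent_change(-b)
    expect_equal((1 + p1 / 100) * (1 + p2 / 100), 1)
  }
  gm <- implied_genotype_means(11.9, -0.35)
  expect_equal(gm$mean[gm$genotype == "minor_hom"], 11.9 * exp(-0.35))
  expect_equal(gm$mean[gm$genotype == "het"], 11.9)
})

test_that("parental-line frequencies scale linearly from F1 haplotype frequencies", {
  expect_equal(parental_freq_from_f1(0.060), 0.120)
  expect_equal(parental_freq_from_f1(0.041), 0.082)
  expect_equal(parental_freq_from_f1(0), 0)
  # exact linearity
  f <- runif(10, 0, 0.5)
  expect_equal(parental_freq_from_f1(f), f / 0.5)
  expect_error(parental_freq_from_f1(0.6), "origin_share")
  # round trip with the generator's breed pools closes to machine precision
  st <- small_study(7100)
  g <- st$genotypes
  j <- g$qtl$snp[1]
  f1_landrace <- mean(g$hap_landrace[, j]) / 2   # share among all F1 haplotypes
  expect_equal(parental_freq_from_f1(f1_landrace), mean(g$hap_landrace[, j]),
               tolerance = 1e-12)
})

test_that("composite LD r2 matches hand arithmetic and its invariances", {
  g1 <- c(0, 0, 1, 1, 2, 2, 1, 0)
  g2 <- c(0, 1, 1, 2, 2, 2, 0, 0)
  expect_equal(ld_r2(g1, g2), cor(g1, g2)^2)
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)
  expect_equal(ld_r2(g1, g2), ld_r2(g2, g1))
  expect_equal(ld_r2(2 - g1, g2), ld_r2(g1, g2))
  expect_error(ld_r2(rep(1, 8), g2), "monomorphic")
})

test_that("lead-SNP covariate fits recover the planted substitution effect", {
  st <- recovery_study(7200)
  j <- st$genotypes$qtl$snp[1]
  snp_id <- st$genotypes$map$id[j]
  g_loo <- company_grm(st$genotypes$dosage[, -j],
                       company = st$genotypes$company)
  f <- fit_snp_covariate(st$phenotypes, "ln_cortisol", snp_id,
                         st$genotypes, g_loo)
  true_eff <- -0.35 * st$truths$qtl_effect_scale
  expect_lt(abs(f$estimate - true_eff), 3 * f$std.error)
  expect_lt(f$p.value, 1e-4)
  expect_equal(f$percent_change, percent_change(f$estimate))
  # implied genotype means differ by exactly exp(beta) per allele copy
  gm <- f$genotype_means
  expect_equal(gm$mean[3] / gm$mean[2], exp(f$estimate))
  expect_equal(gm$mean[2] / gm$mean[1], exp(f$estimate))
  expect_error(fit_snp_covariate(dplyr::mutate(st$phenotypes,
                                               ln_cortisol = ln_cortisol),
                                 "ln_cortisol", "nonexistent",
                                 st$genotypes, g_loo), "not found")
})

test_that("breed-origin covariates separate Landrace and Yorkshire effects", {
  set.seed(73)
  d <- cohort_design(n_batches = 12, batch_sizes = 67)
  p <- sim_params(qtl = tibble::tibble(snp = NA_integer_, effect = -0.35,
                                       effect2 = 0, egv_frac = 0.453,
                                       effect_landrace = -0.39,
                                       effect_yorkshire = -0.30,
                                       freq_landrace = 0.12,
                                       freq_yorkshire = 0.082),
                  seed = 73)
  st <- simulate_study(p, d, seed = 73)
  j <- st$genotypes$qtl$snp[1]
  g_loo <- company_grm(st$genotypes$dosage[, -j],
                       company = st$genotypes$company)
  b <- breed_origin_effects(st$phenotypes, "ln_cortisol",
                            st$genotypes$map$id[j], st$genotypes, g_loo)
  s <- st$truths$qtl_effect_scale
  el <- b$effects[b$effects$origin == "landrace", ]
  ey <- b$effects[b$effects$origin == "yorkshire", ]
  expect_lt(abs(el$estimate - (-0.39 * s)), 3 * el$std.error)
  expect_lt(abs(ey$estimate - (-0.30 * s)), 3 * ey$std.error)
  expect_true(is.finite(b$difference$p.value))
})

test_that("an all-one-origin QTL reports the other origin as inestimable", {
  set.seed(74)
  d <- small_design()
  p <- sim_params(qtl = tibble::tibble(snp = 200L, effect = -0.4,
                                       effect2 = 0, egv_frac = 0.4,
                                       freq_landrace = 0.2,
                                       freq_yorkshire = 0),
                  n_snps = 400, n_chromosomes = 4, seed = 74)
  st <- simulate_study(p, d, seed = 74)
  g <- company_grm(st$genotypes)
  b <- breed_origin_effects(st$phenotypes, "ln_cortisol",
                            st$genotypes$map$id[200], st$genotypes, g)
  expect_true(is.na(b$effects$estimate[b$effects$origin == "yorkshire"]))
  expect_false(is.na(b$effects$estimate[b$effects$origin == "landrace"]))
  expect_null(b$difference)
})

test_that("conditioning on the causal SNP collapses its window and a null SNP does not", {
  set.seed(75)
  d <- cohort_design(n_batches = 6, batch_sizes = 67)
  p <- sim_params(n_snps = 1000, n_chromosomes = 5, seed = 75)
  st <- simulate_study(p, d, seed = 75)
  j <- st$genotypes$qtl$snp[1]
  cfg <- bayesb_config("desk", chain_length = 3000, burnin = 600,
                       store_effects_every = 0)
  base <- run_bayesb(st$phenotypes, "ln_cortisol", st$genotypes, cfg,
                     seed = 76)
  vr <- variance_removed(st$phenotypes, "ln_cortisol", j, st$genotypes, cfg,
                         baseline = base, seed = 76)
  expect_lt(vr$focal_pct_egv[2], 0.2 * vr$focal_pct_egv[1])
  expect_lt(vr$genetic_variance[2], vr$genetic_variance[1])
  expect_lt(vr$h2[2], vr$h2[1])

  # conditioning on a polymorphic null SNP far from the QTL changes little
  off_chr <- st$genotypes$map$chr != st$genotypes$map$chr[j]
  mafs <- colMeans(st$genotypes$dosage) / 2
  null_snp <- which(off_chr & mafs > 0.2 & mafs < 0.8)[5]
  vr0 <- variance_removed(st$phenotypes, "ln_cortisol", null_snp,
                          st$genotypes, cfg, baseline = base, seed = 76)
  expect_equal(vr0$genetic_variance[2], vr0$genetic_variance[1],
               tolerance = 0.25)
  qtl_w <- base$window_of_snp[j]
  r_base <- base$var_window[, qtl_w] / base$var_genomic
  expect_gt(100 * mean(r_base[is.finite(r_base)]), 20)
})

test_that("SNP-by-company interaction test is well behaved under both hypotheses", {
  st <- recovery_study(7700)
  j <- st$genotypes$qtl$snp[1]
  g <- company_grm(st$genotypes)
  # homogeneous effects: no significant interaction expected at this seed
  res <- snp_company_interaction(st$phenotypes, "ln_cortisol",
                                 st$genotypes$map$id[j], st$genotypes, g)
  expect_gt(res$p.value, 0.01)
  expect_gte(length(res$companies_used), 2)

  # one strongly deviant company: interaction detected
  dat <- st$phenotypes
  dose <- st$genotypes$dosage[dat$pig, j]
  dev <- dat$company == dat$company[1]
  dat$y_dev <- dat$ln_cortisol + ifelse(dev, 0.6 * dose, 0)
  res2 <- snp_company_interaction(dat, "y_dev", st$genotypes$map$id[j],
                                  st$genotypes, g)
  expect_lt(res2$p.value, 0.05)
})

test_that("expression covariate fits recover dosage effects net of cell composition", {
  st <- recovery_study(7800)
  j <- st$genotypes$qtl$snp[1]
  dat <- st$phenotypes
  dose <- st$genotypes$dosage[dat$pig, j]
  set.seed(78)
  comp <- matrix(runif(nrow(dat) * 3, 0.05, 0.4), ncol = 3,
                 dimnames = list(NULL, c("lymph", "neut", "mono")))
  comp[1, 1] <- 0    # exercise the zero-offset policy
  dat <- dplyr::bind_cols(dat, tibble::as_tibble(comp))
  gamma <- 0.5
  dat$expr <- gamma * dose + 0.3 * log2_props(dat$lymph) +
    rnorm(nrow(dat), 0, 0.5)
  g_loo <- company_grm(st$genotypes$dosage[, -j],
                       company = st$genotypes$company)
  f <- expression_covariate_fit(dat, "expr", st$genotypes$map$id[j],
                                st$genotypes, g_loo,
                                celltype_cols = c("lymph", "neut", "mono"))
  expect_lt(abs(f$estimate - gamma), 3 * f$std.error)
  expect_lt(f$p.value, 1e-6)

  # null expression: no effect called
  dat$expr0 <- rnorm(nrow(dat))
  f0 <- expression_covariate_fit(dat, "expr0", st$genotypes$map$id[j],
                                 st$genotypes, g_loo,
                                 celltype_cols = c("lymph", "neut", "mono"))
  expect_gt(f0$p.value, 0.01)
  expect_error(log2_props(c(-0.1, 0.5)), "nonnegative")
})
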
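#' Build a crossbred-cohort design table
#'
#' Lays out the structure of a multi-batch F1 (Yorkshire x Landrace) nursery
#' cohort: batches of barrows sourced from a set of breeding companies, pens
#' within batch, full-sib litters of 2-4 pigs, and at least `sires_per_batch`
#' sires per batch. Ages at entry and sample storage days are drawn so that
#' fixed-covariate estimation is exercised downstream. Uses the current RNG
#' state; [simulate_study()] seeds it once for the whole simulation.
#'
#' @param n_batches Number of batches (default 15).
#' @param batch_sizes Batch sizes, recycled across batches (default
#'   alternating 60 and 75 barrows).
#' @param n_companies Number of breeding companies; each batch belongs to
#'   exactly one company (default 7).
#' @param pens_per_batch Pens available within each batch (default 10).
#' @param sires_per_batch Minimum sires represented per batch (default 9).
#' @param litter_sizes Allowed litter sizes (default 2:4).
#' @param age_mean,age_sd Age at entry (days), normal draw per pig.
#' @param storage_range Range (days) for per-pig assay storage time.
#' @return A `cohort_design` tibble with one row per pig: `pig`, `batch`,
#'   `company`, `pen`, `litter`, `sire`, `age`, `storage_days`.
#' @export
cohort_design <- function(n_batches = 15, batch_sizes = c(60, 75),
                          n_companies = 7, pens_per_batch = 10,
                          sires_per_batch = 9, litter_sizes = 2:4,
                          age_mean = 40, age_sd = 3,
                          storage_range = c(30, 180)) {
  stopifnot(n_batches >= 1, all(batch_sizes >= 4), sires_per_batch >= 1,
            all(litter_sizes >= 2))
  sizes <- rep_len(batch_sizes, n_batches)
  company_of_batch <- rep_len(seq_len(n_companies), n_batches)
  rows <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    n <- sizes[b]
    # partition the batch into litters of 2-4 pigs
    ls <- integer(0)
    while (sum(ls) < n) ls <- c(ls, sample(litter_sizes, 1L))
    excess <- sum(ls) - n
    if (excess > 0) {
      k <- length(ls)
      if (ls[k] - excess >= min(litter_sizes)) {
        ls[k] <- ls[k] - excess
      } else {
        # drop the overshooting litter and grow earlier litters instead
        ls <- ls[-k]
        i <- 1L
        while (sum(ls) < n) {
          if (ls[i] < max(litter_sizes)) ls[i] <- ls[i] + 1L
          i <- i %% length(ls) + 1L
        }
      }
    }
    n_lit <- length(ls)
    n_sires <- max(sires_per_batch, ceiling(n_lit / 3))
    sire_of_litter <- sample(rep_len(seq_len(n_sires), n_lit))
    litter_id <- rep(seq_len(n_lit), ls)
    rows[[b]] <- tibble::tibble(
      batch = sprintf("b%02d", b),
      company = sprintf("c%d", company_of_batch[b]),
      pen = sprintf("b%02d_p%02d", b, sample.int(pens_per_batch, n, replace = TRUE)),
      litter = sprintf("b%02d_l%02d", b, litter_id),
      sire = sprintf("b%02d_s%02d", b, sire_of_litter[litter_id]),
      age = round(rnorm(n, age_mean, age_sd)),
      storage_days = sample(storage_range[1]:storage_range[2], n, replace = TRUE)
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- tibble::add_column(out, pig = sprintf("pig%04d", seq_len(nrow(out))),
                            .before = 1)
  class(out) <- c("cohort_design", class(out))
  out
}

#' Simulation parameters for the synthetic cohort
#'
#' Bundles every tunable of the generator with defaults matching the study
#' conditions the package is exercised under: a log-normal hair-cortisol
#' trait with heritability 0.33 and a common-litter fraction 0.16 of the
#' (pen-free) phenotypic variance 0.12 on the natural-log scale, one planted
#' minor-frequency QTL explaining 45.3% of the genetic variance whose minor
#' allele segregates at 12.0% in the Landrace and 8.2% in the Yorkshire
#' founder pools, an over-dispersed vocalisation count, and a 5-point
#' ordinal score. Two hormone-like traits are generated with polygenic
#' effect correlation `rg` so bivariate machinery can be tested.
#'
#' @param n_snps,n_chromosomes,snp_spacing_bp Marker panel layout; SNPs are
#'   spread evenly over chromosomes at fixed bp spacing.
#' @param maf_range Interval in (0, 0.5] for base allele frequencies.
#' @param n_founder_hap Founder haplotypes per breed pool (default 40).
#' @param block_snps,n_block_haps Haplotype-block length (SNPs) and number of
#'   distinct block haplotypes per breed, which set the local LD level.
#' @param qtl Tibble of planted QTL: `snp` (index, NA = centre of the panel),
#'   `effect`, `effect2` (log-scale allele substitution effects on the two
#'   traits), `egv_frac` (target share of trait-1 genetic variance; an
#'   optional `egv_frac2` column sets the trait-2 share),
#'   `freq_landrace`, `freq_yorkshire` (carrier-haplotype frequencies in the
#'   founder pools; 0 restricts the QTL to one breed origin).
#' @param h2,litter_frac,pen_frac Target variance fractions; `h2` and
#'   `litter_frac` are relative to the genetic + litter + residual variance,
#'   matching the heritability denominator used downstream.
#' @param total_var Reference phenotypic variance (genetic+litter+residual)
#'   on the log scale (default 0.12).
#' @param rg Polygenic effect correlation between the two hormone traits.
#' @param env_rg Between-trait correlation of the litter and pen effects
#'   (default 0.5: common-environment effects on two hormones are related
#'   but not identical).
#' @param mu,mu2 Log-scale intercepts of the two hormone traits.
#' @param batch_sd,age_slope,storage_slope Fixed-effect generators.
#' @param count_mean,nb_dispersion Negative-binomial count trait: marginal
#'   mean and variance/mean dispersion (default 6.3).
#' @param ordinal_thresholds Strictly increasing latent cut points for the
#'   5-point ordinal trait.
#' @param cv_assay Within-assay replicate CV (fraction, log-normal noise).
#' @param assay_replicates 2 (duplicate) or 3 (triplicate) assay readings.
#' @param outlier_frac,outlier_factor Fraction of assay samples corrupted by
#'   a multiplicative factor, for testing the outlier filter.
#' @param seed Integer seed; all randomness flows from one generator.
#' @return A `sim_params` list, validated.
#' @export
sim_params <- function(n_snps = 2000, n_chromosomes = 10,
                       snp_spacing_bp = 25000L,
                       maf_range = c(0.05, 0.5),
                       n_founder_hap = 40, block_snps = 20, n_block_haps = 6,
                       qtl = tibble::tibble(
                         snp = NA_integer_, effect = -0.35, effect2 = 0,
                         egv_frac = 0.453,
                         freq_landrace = 0.12, freq_yorkshire = 0.082),
                       h2 = 0.33, litter_frac = 0.16, pen_frac = 0.05,
                       total_var = 0.12, rg = 0.6, env_rg = 0.5,
                       mu = 2.7, mu2 = 3.0,
                       batch_sd = 0.2, age_slope = 0.005,
                       storage_slope = -0.002,
                       count_mean = 5, nb_dispersion = 6.3,
                       ordinal_thresholds = c(-1.5, -0.5, 0.5, 1.5),
                       cv_assay = 0.05, assay_replicates = 2,
                       outlier_frac = 0, outlier_factor = 20,
                       seed = 20250514L) {
  stopifnot(n_snps >= 1, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (h2 + litter_frac > 1) stop("h2 + litter_frac must be <= 1")
  if (pen_frac < 0 || h2 < 0 || litter_frac < 0) stop("variance fractions must be >= 0")
  if (any(diff(ordinal_thresholds) <= 0)) stop("ordinal thresholds must be strictly increasing")
  if (!assay_replicates %in% 2:3) stop("assay_replicates must be 2 or 3")
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate F1 genotypes from two breed haplotype pools
#'
#' Each breed (Landrace dams, Yorkshire sires) contributes a pool of
#' `n_founder_hap` founder haplotypes built from a limited set of block
#' haplotypes, which creates realistic local LD without an explicit
#' recombination map. Each sire carries two Yorkshire haplotypes and each
#' litter's dam two Landrace haplotypes; every pig inherits one haplotype
#' from its sire and one from its dam by Mendelian sampling, so littermates
#' and paternal half-sibs share haplotypes. Planted QTL alleles are placed
#' on founder haplotypes at the requested pool frequencies, so the expected
#' F1 carrier frequency is the mean of the two pool frequencies.
#'
#' @param params A [sim_params()] object.
#' @param design A [cohort_design()] table.
#' @return A `genotype_matrix`: list with `dosage` (pigs x SNPs, 0/1/2),
#'   `map` (tibble: `snp`, `id`, `chr`, `pos`), `pigs`, `company`,
#'   `hap_landrace`/`hap_yorkshire` (per-pig breed-origin haplotype alleles),
#'   `pools`, and `qtl` (with realized pool carrier frequencies).
#' @export
simulate_genotypes <- function(params, design) {
  p <- params$n_snps
  n <- nrow(design)
  n_chr <- params$n_chromosomes
  per_chr <- ceiling(p / n_chr)
  chr <- rep(seq_len(n_chr), each = per_chr)[seq_len(p)]
  idx_in_chr <- stats::ave(seq_len(p), chr, FUN = seq_along)
  pos <- (idx_in_chr - 1L) * params$snp_spacing_bp + params$snp_spacing_bp %/% 2L
  map <- tibble::tibble(snp = seq_len(p), id = sprintf("snp%05d", seq_len(p)),
                        chr = chr, pos = as.integer(pos))

  qtl <- params$qtl
  if (!is.null(qtl) && nrow(qtl) > 0) {
    qtl$snp[is.na(qtl$snp)] <- p %/% 2L
    if (any(qtl$freq_landrace <= 0 & qtl$freq_yorkshire <= 0 &
            (qtl$effect != 0 | qtl$effect2 != 0))) {
      stop("planted QTL is monomorphic in both breed pools")
    }
  }

  build_pool <- function() {
    base_p <- runif(p, params$maf_range[1], params$maf_range[2])
    pool <- matrix(0L, params$n_founder_hap, p)
    for (cc in seq_len(n_chr)) {
      snps <- which(chr == cc)
      blocks <- split(snps, ceiling(seq_along(snps) / params$block_snps))
      for (blk in blocks) {
        bh <- matrix(rbinom(params$n_block_haps * length(blk), 1L, base_p[blk]),
                     params$n_block_haps, length(blk), byrow = TRUE)
        pick <- sample.int(params$n_block_haps, params$n_founder_hap, replace = TRUE)
        pool[, blk] <- bh[pick, , drop = FALSE]
      }
    }
    pool
  }
  pool_l <- build_pool()
  pool_y <- build_pool()

  # plant QTL carriers on founder haplotypes at the requested pool frequencies
  if (!is.null(qtl) && nrow(qtl) > 0) {
    qtl$realized_freq_landrace <- NA_real_
    qtl$realized_freq_yorkshire <- NA_real_
    for (j in seq_len(nrow(qtl))) {
      plant <- function(pool, f) {
        carriers <- runif(params$n_founder_hap) < f
        if (f > 0 && !any(carriers)) carriers[sample.int(params$n_founder_hap, 1L)] <- TRUE
        pool[, qtl$snp[j]] <- as.integer(carriers)
        list(pool = pool, freq = mean(carriers))
      }
      pl <- plant(pool_l, qtl$freq_landrace[j]); pool_l <- pl$pool
      py <- plant(pool_y, qtl$freq_yorkshire[j]); pool_y <- py$pool
      qtl$realized_freq_landrace[j] <- pl$freq
      qtl$realized_freq_yorkshire[j] <- py$freq
      if (pl$freq == 0 && py$freq == 0) stop("planted QTL is monomorphic in both breed pools")
    }
  }

  sires <- unique(design$sire)
  litters <- unique(design$litter)
  sire_haps <- matrix(sample.int(params$n_founder_hap, 2L * length(sires),
                                 replace = TRUE), ncol = 2)
  rownames(sire_haps) <- sires
  dam_haps <- matrix(sample.int(params$n_founder_hap, 2L * length(litters),
                                replace = TRUE), ncol = 2)
  rownames(dam_haps) <- litters

  pick_s <- sire_haps[cbind(match(design$sire, sires),
                            sample.int(2L, n, replace = TRUE))]
  pick_d <- dam_haps[cbind(match(design$litter, litters),
                           sample.int(2L, n, replace = TRUE))]
  hap_y <- pool_y[pick_s, , drop = FALSE]
  hap_l <- pool_l[pick_d, , drop = FALSE]
  dosage <- hap_y + hap_l
  dimnames(dosage) <- list(design$pig, map$id)

  structure(list(dosage = dosage, map = map, pigs = design$pig,
                 company = setNames(design$company, design$pig),
                 hap_landrace = hap_l, hap_yorkshire = hap_y,
                 pools = list(landrace = pool_l, yorkshire = pool_y),
                 qtl = qtl),
            class = "genotype_matrix")
}

#' Simulate phenotypes on a simulated cohort
#'
#' Generates two log-normal hormone traits, an over-dispersed count, and a
#' 5-point ordinal trait from the linear model the downstream analyses
#' assume: batch + age and storage covariates + planted QTL + polygenic
#' term + litter + pen + residual on the natural-log scale. The polygenic
#' term assigns normal effects to a random 10% of non-QTL SNPs, then the
#' genetic vector is rescaled so the realized (sample) genetic variance
#' equals `h2 * total_var` exactly, and the planted QTL's realized share of
#' the genetic variance equals its target exactly; this makes per-replicate
#' truths exact and parameter-recovery tests sharp. Litter, pen, and
#' residual effects are drawn (not rescaled) at their target variances.
#'
#' @param geno A `genotype_matrix` from [simulate_genotypes()].
#' @param design The matching [cohort_design()].
#' @param params The [sim_params()] used.
#' @return A list with `phenotypes` (tibble: design columns, `cortisol`,
#'   `hormone2` on the original pg/mg scale, `ln_cortisol`, `ln_hormone2`,
#'   `vn` count, `vi` ordinal) and `truths` (per-trait effect vectors and
#'   realized variance fractions).
#' @export
simulate_phenotypes <- function(geno, design, params) {
  n <- nrow(design)
  M <- geno$dosage
  p <- ncol(M)
  qtl <- geno$qtl
  tv <- params$total_var
  if (params$h2 + params$litter_frac > 1) stop("infeasible variance fractions")

  qtl_term <- function(effcol) {
    if (is.null(qtl) || nrow(qtl) == 0) return(rep(0, n))
    as.vector(M[, qtl$snp, drop = FALSE] %*% qtl[[effcol]])
  }
  # origin-specific substitution effects replace the shared dosage effect
  # for trait 1 when effect_landrace / effect_yorkshire columns are given
  if (!is.null(qtl) && nrow(qtl) > 0 &&
      all(c("effect_landrace", "effect_yorkshire") %in% names(qtl))) {
    q1 <- as.vector(geno$hap_landrace[, qtl$snp, drop = FALSE] %*%
                      qtl$effect_landrace +
                    geno$hap_yorkshire[, qtl$snp, drop = FALSE] %*%
                      qtl$effect_yorkshire)
  } else {
    q1 <- qtl_term("effect")
  }
  q2 <- qtl_term("effect2")
  non_qtl <- setdiff(seq_len(p), if (is.null(qtl)) integer(0) else qtl$snp)
  idx <- sort(sample(non_qtl, max(1L, round(0.1 * length(non_qtl)))))
  b1 <- rnorm(length(idx))
  b2 <- params$rg * b1 + sqrt(max(0, 1 - params$rg^2)) * rnorm(length(idx))
  p1 <- as.vector(M[, idx, drop = FALSE] %*% b1)
  p2 <- as.vector(M[, idx, drop = FALSE] %*% b2)

  # scale the polygenic part so the QTL's realized share of genetic variance
  # hits its target, then scale the whole genetic vector to h2 * total_var
  combine <- function(q, pg, f_target) {
    vq <- var(q)
    if (vq == 0 || f_target <= 0) {
      g <- pg - mean(pg)
      if (var(g) > 0) g <- g * sqrt(params$h2 * tv / var(g))
      return(list(g = g, qterm = rep(0, n), share = 0))
    }
    vp <- var(pg); cqp <- cov(q, pg); f <- f_target
    disc <- (f * cqp)^2 + f * vp * (1 - f) * vq
    cc <- (-f * cqp + sqrt(disc)) / (f * vp)
    g <- q + cc * pg
    g <- g - mean(g)
    s <- sqrt(params$h2 * tv / var(g))
    list(g = g * s, qterm = s * (q - mean(q)), share = vq / var(q + cc * pg),
         scale = s)
  }
  f1 <- if (!is.null(qtl) && nrow(qtl) > 0) sum(qtl$egv_frac) else 0
  f2 <- if (!is.null(qtl) && nrow(qtl) > 0 && "egv_frac2" %in% names(qtl))
    sum(qtl$egv_frac2) else 0
  c1 <- combine(q1, p1, if (params$h2 > 0) f1 else 0)
  if (all(q2 == 0) && var(c1$g) > 0) {
    # no trait-2 QTL: build g2 so the realized genetic correlation equals
    # rg exactly (same philosophy as the exact-variance rescaling)
    u <- c1$g
    p2c <- p2 - mean(p2)
    w <- p2c - (sum(p2c * u) / sum(u * u)) * u
    s2t <- sqrt(params$h2 * tv)
    g2 <- if (var(w) > 0) {
      params$rg * (s2t / sd(u)) * u +
        sqrt(max(0, 1 - params$rg^2)) * (s2t / sd(w)) * w
    } else params$rg * (s2t / sd(u)) * u
    c2 <- list(g = g2, share = 0)
  } else {
    c2 <- combine(q2, p2, if (params$h2 > 0) f2 else 0)
  }
  g2 <- c2$g

  lit <- unique(design$litter); pen <- unique(design$pen); bat <- unique(design$batch)
  corr_pair <- function(m, sd_eff, r) {
    a <- rnorm(m, 0, sd_eff)
    b <- r * a + sqrt(max(0, 1 - r^2)) * rnorm(m, 0, sd_eff)
    list(a = a, b = b)
  }
  le <- corr_pair(length(lit), sqrt(params$litter_frac * tv), params$env_rg)
  pe <- corr_pair(length(pen), sqrt(params$pen_frac * tv), params$env_rg)
  litter_eff <- setNames(le$a, lit); litter_eff2 <- setNames(le$b, lit)
  pen_eff <- setNames(pe$a, pen); pen_eff2 <- setNames(pe$b, pen)
  batch_eff <- setNames(rnorm(length(bat), 0, params$batch_sd), bat)
  var_e <- max(0, (1 - params$h2 - params$litter_frac)) * tv
  e1 <- rnorm(n, 0, sqrt(var_e)); e2 <- rnorm(n, 0, sqrt(var_e))

  fixed <- batch_eff[design$batch] + params$age_slope * design$age +
    params$storage_slope * design$storage_days
  lp1 <- fixed + c1$g + litter_eff[design$litter] + pen_eff[design$pen]
  lp2 <- fixed + g2 + litter_eff2[design$litter] + pen_eff2[design$pen]
  ln1 <- unname(params$mu + lp1 + e1)
  ln2 <- unname(params$mu2 + lp2 + e2)

  # count trait: NB with log link on the (residual-free) linear predictor
  eta <- log(params$count_mean) + (lp1 - mean(lp1))
  size <- params$count_mean / max(params$nb_dispersion - 1, 1e-6)
  vn <- rnbinom(n, size = size, mu = exp(eta))
  # ordinal trait: thresholded latent Gaussian sharing the genetic basis
  zlat <- (lp1 - mean(lp1)) / max(sd(lp1), 1e-12) * 0.6 + rnorm(n, 0, 0.8)
  vi <- as.integer(cut(zlat, c(-Inf, params$ordinal_thresholds, Inf)))

  lit1 <- litter_eff[design$litter]; lit2 <- litter_eff2[design$litter]
  den1 <- var(c1$g) + var(lit1) + var(e1)
  den2 <- var(g2) + var(lit2) + var(e2)
  realized <- tibble::tibble(
    trait = c("ln_cortisol", "ln_hormone2"),
    h2_realized = c(var(c1$g) / den1, var(g2) / den2),
    litter_frac_realized = c(var(lit1) / den1, var(lit2) / den2),
    qtl_share_realized = c(c1$share, c2$share)
  )

  phenotypes <- dplyr::bind_cols(
    tibble::as_tibble(design),
    tibble::tibble(ln_cortisol = ln1, ln_hormone2 = ln2,
                   cortisol = exp(ln1), hormone2 = exp(ln2),
                   vn = vn, vi = vi)
  )
  list(phenotypes = phenotypes,
       truths = list(g1 = c1$g, g2 = g2, qtl_term1 = c1$qterm,
                     qtl_effect_scale = c1$scale,
                     litter_eff = litter_eff, litter_eff2 = litter_eff2,
                     pen_eff = pen_eff, pen_eff2 = pen_eff2,
                     batch_eff = batch_eff, resid1 = e1, resid2 = e2,
                     poly_snps = idx, realized = realized))
}

#' Simulate replicate assay readings from true hormone levels
#'
#' Inverts the concentration formula: for a true level `C` (pg/mg) the
#' underlying mean reading is `S = C * Em / (Rv * df)`, and replicate
#' readings are drawn around it with log-normal multiplicative noise at the
#' configured within-assay CV. A configurable fraction of samples is
#' corrupted by a large multiplicative factor to exercise the outlier
#' filter; in triplicate mode one replicate per corrupted sample can be
#' inflated instead to exercise the best-2-of-3 rule.
#'
#' @param true_levels Named numeric vector of true concentrations (pg/mg).
#' @param params A [sim_params()]; uses `cv_assay`, `assay_replicates`,
#'   `outlier_frac`, `outlier_factor`.
#' @param rv,em,df Assay protocol constants.
#' @param corrupt_one_replicate In triplicate mode, corrupt a single
#'   replicate of every sample instead of whole samples (default FALSE).
#' @return A tibble of assay records (`pig`, `hormone`, `replicate`,
#'   `reading`, `rv`, `em`, `df`) with an `injected` attribute listing the
#'   pigs whose sample (or replicate) was corrupted.
#' @export
simulate_assay <- function(true_levels, params, rv = 0.4, em = 25, df = 1,
                           corrupt_one_replicate = FALSE) {
  stopifnot(all(true_levels > 0))
  n <- length(true_levels)
  pigs <- names(true_levels)
  if (is.null(pigs)) pigs <- sprintf("pig%04d", seq_len(n))
  nrep <- params$assay_replicates
  sdlog <- sqrt(log(1 + params$cv_assay^2))
  lev <- true_levels
  injected <- character(0)
  if (!corrupt_one_replicate && params$outlier_frac > 0) {
    hit <- runif(n) < params$outlier_frac
    lev[hit] <- lev[hit] * params$outlier_factor
    injected <- pigs[hit]
  }
  s_true <- lev * em / (rv * df)
  out <- tibble::tibble(
    pig = rep(pigs, each = nrep),
    hormone = "cortisol",
    replicate = rep(seq_len(nrep), n),
    reading = rep(s_true, each = nrep) *
      if (params$cv_assay > 0) exp(rnorm(n * nrep, -sdlog^2 / 2, sdlog)) else 1,
    rv = rv, em = em, df = df
  )
  if (corrupt_one_replicate) {
    stopifnot(nrep == 3L)
    bad <- (seq_len(n) - 1L) * nrep + sample.int(nrep, n, replace = TRUE)
    out$reading[bad] <- out$reading[bad] * params$outlier_factor
    injected <- pigs
  }
  attr(out, "injected") <- injected
  out
}

#' Simulate a complete study
#'
#' Seeds the generator once and runs design, genotype, and phenotype
#' simulation, so the whole study is bit-reproducible from `seed`.
#'
#' @param params A [sim_params()].
#' @param design Optional [cohort_design()]; built with defaults (and the
#'   same seeded stream) if omitted.
#' @param seed Overrides `params$seed` when given.
#' @return A `sim_study` list: `params`, `design`, `genotypes`,
#'   `phenotypes`, `truths`.
#' @export
simulate_study <- function(params = sim_params(), design = NULL, seed = NULL) {
  set.seed(if (is.null(seed)) params$seed else seed)
  if (is.null(design)) design <- cohort_design()
  geno <- simulate_genotypes(params, design)
  ph <- simulate_phenotypes(geno, design, params)
  structure(list(params = params, design = design, genotypes = geno,
                 phenotypes = ph$phenotypes, truths = ph$truths),
            class = "sim_study")
}
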
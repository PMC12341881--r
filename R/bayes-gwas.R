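#' Configuration for BayesB / BayesCpi chains
#'
#' The `"study"` profile is the full-length analysis protocol: 80,000
#' iterations with the first 5,000 discarded as burn-in and the prior
#' exclusion probability fixed at `pi = 0.999`. The `"desk"` profile
#' (8,000 / 1,000) is for interactive work and simulation studies on
#' cohorts of a few hundred pigs and a few thousand SNPs.
#'
#' @param profile `"study"` (full protocol, default) or `"desk"`.
#' @param chain_length,burnin,thin MCMC length controls; overrides the
#'   profile when supplied.
#' @param pi Prior probability that a SNP has zero effect.
#' @param estimate_pi Estimate `pi` (BayesCpi) instead of fixing it.
#' @param nu_beta Degrees of freedom of the scaled-inv-chi-square prior on
#'   locus effect variances.
#' @param vg_prior Prior guess of the genetic variance used to derive the
#'   locus-variance scale; default half the phenotypic variance (set at
#'   run time when `NULL`).
#' @param nu_e,nu_r Degrees of freedom for the residual and iid random-term
#'   variance priors.
#' @param store_effects_every Keep every k-th retained iteration's full
#'   effect/indicator vectors (0 disables; default 10).
#' @return A `bayesb_config` list.
#' @export
bayesb_config <- function(profile = c("study", "desk"),
                          chain_length = NULL, burnin = NULL, thin = 1L,
                          pi = 0.999, estimate_pi = FALSE,
                          nu_beta = 4, vg_prior = NULL,
                          nu_e = 4, nu_r = 4,
                          store_effects_every = 10L) {
  profile <- match.arg(profile)
  if (is.null(chain_length)) chain_length <- if (profile == "study") 80000L else 8000L
  if (is.null(burnin)) burnin <- if (profile == "study") 5000L else 1000L
  stopifnot(pi > 0, pi < 1, burnin < chain_length, thin >= 1)
  structure(list(profile = profile, chain_length = as.integer(chain_length),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 pi = pi, estimate_pi = estimate_pi, nu_beta = nu_beta,
                 vg_prior = vg_prior, nu_e = nu_e, nu_r = nu_r,
                 store_effects_every = as.integer(store_effects_every)),
            class = "bayesb_config")
}

#' Tile a genome map into nonoverlapping windows
#'
#' Windows are 0-based half-open bp intervals `[0, width)`, `[width,
#' 2*width)`, ... per chromosome, so every SNP belongs to exactly one
#' window.
#'
#' @param map Tibble with columns `chr` and `pos` (and usually `snp`, `id`).
#' @param width_bp Window width in bp (1e6 for QTL windows, 0.25e6 for
#'   pleiotropy windows).
#' @return A list with `windows` (tibble: `window`, `chr`, `start`, `end`)
#'   and `window_of_snp` (1-based window index per map row).
#' @export
genome_windows <- function(map, width_bp) {
  bin <- floor(map$pos / width_bp)
  key <- paste(map$chr, bin, sep = ":")
  uk <- unique(key[order(map$chr, bin)])
  idx <- match(key, uk)
  parts <- do.call(rbind, strsplit(uk, ":", fixed = TRUE))
  windows <- tibble::tibble(
    window = seq_along(uk),
    chr = as.integer(parts[, 1]),
    start = as.numeric(parts[, 2]) * width_bp,
    end = (as.numeric(parts[, 2]) + 1) * width_bp
  )
  list(windows = windows, window_of_snp = idx)
}

# shared run-time prep for the samplers
.gwas_prepare <- function(data, response, geno, fixed, random, id,
                          window_bp, responses = NULL) {
  M <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  map <- if (inherits(geno, "genotype_matrix")) geno$map else
    attr(geno, "map")
  if (is.null(map)) stop("genotypes must carry a map (chr, pos)")
  resp_cols <- if (is.null(responses)) response else responses
  keep <- complete.cases(data[, c(resp_cols, all.vars(fixed), random, id)])
  data <- data[keep, , drop = FALSE]
  ids <- data[[id]]
  if (!all(ids %in% rownames(M))) stop("phenotype pigs missing from genotypes")
  M <- M[ids, , drop = FALSE]
  if (anyNA(M)) stop("dosages must be pre-imputed (no missing values)")
  X <- .fixed_design(fixed, data)
  groups <- lapply(random, function(r) {
    f <- factor(data[[r]])
    list(idx = as.integer(f) - 1L, nlev = nlevels(f))
  })
  tiling <- genome_windows(map, window_bp)
  list(data = data, M = M, X = X, map = map, groups = groups,
       windows = tiling$windows, window_of_snp = tiling$window_of_snp)
}

#' Run a univariate BayesB (or BayesC) GWAS chain
#'
#' Single-site Gibbs sampler for the whole-genome regression model:
#' phenotype = fixed effects + iid random terms + sum of SNP effects with
#' per-SNP inclusion indicators + residual. For each SNP the indicator is
#' sampled from its full conditional with the effect integrated out, then
#' the effect from its normal full conditional; locus variances follow a
#' scaled inverse chi-square prior (BayesB) or a single common variance
#' (BayesC / BayesCpi). The locus-variance scale is derived from a prior
#' genetic-variance guess (default half the phenotypic variance) spread
#' over the expected number of included SNPs. Per-window variances of the
#' genomic values across pigs are accumulated for every retained iteration
#' so window summaries do not require storing the full chain.
#'
#' @param data Phenotype/covariate data frame.
#' @param response Response column name.
#' @param geno `genotype_matrix` (or dosage matrix with a `map` attribute).
#' @param config A [bayesb_config()].
#' @param fixed One-sided fixed-effects formula.
#' @param random Character vector of iid random-term columns.
#' @param id Pig id column.
#' @param window_bp Window width tracked inside the chain (default 1 Mb).
#' @param common_variance Use a common effect variance (BayesC) instead of
#'   locus-specific variances (BayesB).
#' @param seed Optional seed applied just before sampling.
#' @return A `bayesb_chain` object: per-SNP `snps` tibble (PIP, posterior
#'   mean effect), stored window variances, residual-variance and pi
#'   samples, the window tiling, and the configuration.
#' @export
run_bayesb <- function(data, response, geno, config = bayesb_config("desk"),
                       fixed = ~ batch + age + storage_days,
                       random = c("litter", "pen"), id = "pig",
                       window_bp = 1e6, common_variance = FALSE,
                       seed = NULL) {
  prep <- .gwas_prepare(data, response, geno, fixed, random, id, window_bp)
  y <- prep$data[[response]]
  if (sd(y) == 0) stop("response is constant")
  vy <- var(y)
  vg <- if (is.null(config$vg_prior)) 0.5 * vy else config$vg_prior
  freqs <- colMeans(prep$M) / 2
  sum2pq <- sum(2 * freqs * (1 - freqs))
  sigma_b0 <- vg / ((1 - config$pi) * max(sum2pq, 1e-12))
  s_beta <- sigma_b0 * (config$nu_beta - 2) / config$nu_beta
  s_e <- 0.5 * vy * (config$nu_e - 2) / config$nu_e
  s_r <- 0.1 * vy * (config$nu_r - 2) / config$nu_r
  if (!is.null(seed)) set.seed(seed)
  res <- .bayesb_chain_cpp(
    y, prep$X, prep$M,
    lapply(prep$groups, `[[`, "idx"),
    vapply(prep$groups, `[[`, integer(1), "nlev"),
    prep$window_of_snp - 1L, nrow(prep$windows),
    config$pi, config$estimate_pi, common_variance,
    config$chain_length, config$burnin, config$thin,
    config$nu_beta, s_beta, config$nu_e, s_e, config$nu_r, s_r,
    TRUE, TRUE, 0.5 * vy, config$store_effects_every)
  structure(list(
    response = response,
    snps = tibble::tibble(snp = prep$map$snp, id = prep$map$id,
                          chr = prep$map$chr, pos = prep$map$pos,
                          pip = res$pip, beta_mean = res$beta_mean),
    var_window = res$var_window, var_genomic = res$var_genomic,
    sigma2_e = res$sigma2_e, pi = res$pi,
    rand_var = if (length(random))
      structure(res$rand_var, dimnames = list(NULL, random)) else NULL,
    n_kept = res$n_kept,
    beta_samples = res$beta_samples, delta_samples = res$delta_samples,
    windows = prep$windows, window_of_snp = prep$window_of_snp,
    window_bp = window_bp, map = prep$map, config = config,
    n = length(y), pigs = prep$data[[id]]
  ), class = "bayesb_chain")
}

#' @export
print.bayesb_chain <- function(x, ...) {
  cat(sprintf("BayesB chain for '%s': %d pigs, %d SNPs, %d retained draws\n",
              x$response, x$n, nrow(x$snps), x$n_kept))
  cat(sprintf("max PIP = %.3f at %s\n", max(x$snps$pip),
              x$snps$id[which.max(x$snps$pip)]))
  invisible(x)
}

#' Estimate the SNP exclusion probability with BayesCpi
#'
#' Runs a BayesC chain (common effect variance) in which `pi` is sampled
#' from its Beta full conditional, `Beta(#excluded + 1, #included + 1)`,
#' each iteration.
#'
#' @inheritParams run_bayesb
#' @return A list with `pi_mean`, `pi_ci` (central 95% interval),
#'   `pi_samples`, and the underlying `bayesb_chain`.
#' @export
estimate_pi_bayescpi <- function(data, response, geno,
                                 config = bayesb_config("desk"),
                                 fixed = ~ batch + age + storage_days,
                                 random = c("litter", "pen"), id = "pig",
                                 seed = NULL) {
  config$estimate_pi <- TRUE
  chain <- run_bayesb(data, response, geno, config, fixed, random, id,
                      common_variance = TRUE, seed = seed)
  list(pi_mean = mean(chain$pi),
       pi_ci = unname(quantile(chain$pi, c(0.025, 0.975))),
       pi_samples = chain$pi, chain = chain)
}

#' Window summaries of the percentage of genetic variance
#'
#' For each retained iteration the genomic value of a window is the sum of
#' its included SNP effects times dosages per pig; the window's share of
#' genetic variance in that iteration is the variance of those values
#' across pigs divided by the variance of total genomic values. The
#' reported %EGV is the posterior mean of that per-iteration percentage
#' (iterations with no genomic variance contribute zero). Windows need not
#' sum to 100% because window genomic values covary. A window is flagged
#' as a QTL when its %EGV exceeds `qtl_threshold` (1% for 1-Mb windows).
#'
#' @param chain A `bayesb_chain`.
#' @param qtl_threshold %EGV above which the window is called a QTL.
#' @return A `window_summary` tibble: `window`, `chr`, `start`, `end`,
#'   `n_snps`, `pct_egv`, `qtl`, `lead_snp` (highest-PIP member SNP),
#'   `lead_pip`.
#' @export
window_egv <- function(chain, qtl_threshold = 1) {
  stopifnot(inherits(chain, "bayesb_chain"))
  if (chain$n_kept < 100L) {
    warning("fewer than 100 retained iterations; window summaries are noisy")
  }
  ratio <- sweep(chain$var_window, 1, chain$var_genomic, "/")
  ratio[!is.finite(ratio)] <- 0
  pct <- 100 * colMeans(ratio)
  snps <- chain$snps
  lead <- vapply(seq_len(nrow(chain$windows)), function(w) {
    members <- which(chain$window_of_snp == w)
    if (!length(members)) return(NA_integer_)
    members[which.max(snps$pip[members])]
  }, integer(1))
  out <- chain$windows
  out$n_snps <- tabulate(chain$window_of_snp, nbins = nrow(out))
  out$pct_egv <- pct
  out$qtl <- pct > qtl_threshold
  out$lead_snp <- snps$id[lead]
  out$lead_pip <- ifelse(is.na(lead), NA_real_, snps$pip[lead])
  class(out) <- c("window_summary", class(out))
  out
}

#' Chain mixing diagnostics (warn-only)
#'
#' Geweke-style z-score (first 10% vs last 50% of the retained series,
#' variances from batch means) and an autocorrelation-based effective
#' sample size for the genomic-variance series. Thresholds only warn;
#' they never stop an analysis.
#'
#' @param chain A `bayesb_chain` (or any numeric series via `series`).
#' @param series Optional numeric vector to diagnose instead.
#' @return Tibble with `geweke_z` and `ess`.
#' @export
chain_diagnostics <- function(chain, series = NULL) {
  x <- if (!is.null(series)) series else chain$var_genomic
  n <- length(x)
  a <- x[seq_len(max(2, floor(0.1 * n)))]
  b <- x[seq.int(floor(0.5 * n) + 1, n)]
  bm_var <- function(v) {
    nb <- max(2, floor(sqrt(length(v))))
    m <- tapply(v, ceiling(seq_along(v) / ceiling(length(v) / nb)), mean)
    var(m) / length(m)
  }
  z <- (mean(a) - mean(b)) / sqrt(bm_var(a) + bm_var(b))
  rho <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(rho < 0)[1]
  rho <- if (is.na(pos)) rho else rho[seq_len(pos - 1)]
  ess <- n / (1 + 2 * sum(rho))
  if (is.finite(z) && abs(z) > 3) warning("Geweke z = ", signif(z, 3),
                                          ": chain may not be stationary")
  if (is.finite(ess) && ess < 50) warning("effective sample size ",
                                          round(ess), " < 50")
  tibble::tibble(geweke_z = z, ess = ess)
}
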
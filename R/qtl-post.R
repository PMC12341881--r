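#' Percent change on the original scale from a log-scale effect
#'
#' A substitution effect `beta` estimated on the natural-log scale
#' corresponds to a multiplicative change `exp(beta)` per extra copy of
#' the allele, i.e. `100 * (exp(beta) - 1)` percent on the original scale;
#' a negative effect is a reduction. The changes implied by `beta` and
#' `-beta` multiply back to no change exactly.
#'
#' @param beta Log-scale effect(s).
#' @return Percent change(s) on the original scale.
#' @examples
#' percent_change(-0.35)  # about -29.5: a ~30% reduction
#' @export
percent_change <- function(beta) 100 * (exp(beta) - 1)

#' Genotype means implied by a heterozygote mean and a log-scale effect
#'
#' @param het_mean Model-implied heterozygote mean on the original scale
#'   (e.g. pg/mg).
#' @param beta Log-scale allele substitution effect (per copy of the minor
#'   allele).
#' @return Tibble with implied means for the major homozygote,
#'   heterozygote, and minor homozygote.
#' @examples
#' implied_genotype_means(11.9, -0.35)  # minor homozygote about 8.4 pg/mg
#' @export
implied_genotype_means <- function(het_mean, beta) {
  tibble::tibble(genotype = c("major_hom", "het", "minor_hom"),
                 mean = c(het_mean * exp(-beta), het_mean,
                          het_mean * exp(beta)))
}

# pull a dosage vector (and its map row) for one SNP by id or index
.snp_dosage <- function(geno, snp) {
  M <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  j <- if (is.character(snp)) match(snp, colnames(M)) else snp
  if (is.na(j) || j < 1 || j > ncol(M)) stop("SNP not found: ", snp)
  setNames(M[, j], rownames(M))
}

#' Fit a lead SNP as a fixed covariate in the animal model
#'
#' Adds the SNP dosage (0/1/2 copies of the counted allele) as a fixed
#' covariate to the univariate genomic animal model and reports the
#' substitution effect with its Wald test. For traits analysed on the
#' natural-log scale, the effect is also expressed as a percent change on
#' the original scale and as implied genotype means (the heterozygote mean
#' is the model prediction at dosage 1 with all other fixed effects at
#' their sample average).
#'
#' @inheritParams fit_univariate_reml
#' @param snp SNP id (column name) or index into the genotype matrix.
#' @param geno A `genotype_matrix` or dosage matrix with pig row names.
#' @param log_scale Is the response a natural-log trait (enables percent
#'   change and implied genotype means)?
#' @return A `snp_effect_fit` list: `estimate`, `std.error`, `p.value`,
#'   `percent_change`, `genotype_means`, and the underlying `fit`.
#' @export
fit_snp_covariate <- function(data, response, snp, geno, grm,
                              fixed = ~ batch + age + storage_days,
                              random = c("litter", "pen"), id = "pig",
                              log_scale = TRUE) {
  dose <- .snp_dosage(geno, snp)
  data$snp_dosage <- unname(dose[data[[id]]])
  if (length(unique(data$snp_dosage[!is.na(data[[response]])])) < 2L) {
    stop("SNP is monomorphic in the analysed records")
  }
  fixed2 <- stats::update(fixed, ~ . + snp_dosage)
  fit <- fit_univariate_reml(data, response, grm, fixed2, random, id)
  row <- fit$fixed[fit$fixed$term == "snp_dosage", ]
  est <- row$estimate; se <- row$std.error
  gm <- NULL; pc <- NA_real_
  if (log_scale) {
    pc <- percent_change(est)
    X <- model.matrix(fixed2, data[!is.na(data[[response]]), , drop = FALSE])
    X <- X[, fit$fixed$term, drop = FALSE]
    xbar <- colMeans(X)
    xbar["snp_dosage"] <- 1
    het_mean <- exp(sum(xbar * fit$fixed$estimate))
    gm <- implied_genotype_means(het_mean, est)
  }
  structure(list(snp = if (is.character(snp)) snp else colnames(geno$dosage)[snp],
                 estimate = est, std.error = se,
                 statistic = row$statistic, p.value = row$p.value,
                 percent_change = pc, genotype_means = gm, fit = fit),
            class = "snp_effect_fit")
}

#' @export
print.snp_effect_fit <- function(x, ...) {
  cat(sprintf("SNP covariate fit: %s\n", x$snp))
  cat(sprintf("effect = %.4f (SE %.4f), p = %.3g\n",
              x$estimate, x$std.error, x$p.value))
  if (!is.na(x$percent_change)) {
    cat(sprintf("original-scale change per allele copy: %.1f%%\n",
                x$percent_change))
  }
  invisible(x)
}

#' Breed-origin-specific allele substitution effects
#'
#' In an F1 cross each pig carries one haplotype from each parental breed,
#' so the minor-allele dosage splits into copies carried on Landrace-origin
#' versus Yorkshire-origin haplotypes. Both origin-specific dosages are
#' fitted jointly as fixed covariates; a Wald test compares the two
#' effects. If all minor alleles trace to one origin the other covariate
#' is inestimable and reported as such.
#'
#' @inheritParams fit_snp_covariate
#' @return A `breed_origin_fit`: tibble `effects` (origin, estimate, SE,
#'   p), `difference` (estimate, SE, p of Landrace - Yorkshire), `fit`.
#' @export
breed_origin_effects <- function(data, response, snp, geno, grm,
                                 fixed = ~ batch + age + storage_days,
                                 random = c("litter", "pen"), id = "pig") {
  if (!inherits(geno, "genotype_matrix") || is.null(geno$hap_landrace)) {
    stop("breed-origin phase is not available in these genotypes")
  }
  j <- if (is.character(snp)) match(snp, geno$map$id) else snp
  dl <- setNames(geno$hap_landrace[, j], geno$pigs)
  dy <- setNames(geno$hap_yorkshire[, j], geno$pigs)
  data$dose_landrace <- unname(dl[data[[id]]])
  data$dose_yorkshire <- unname(dy[data[[id]]])
  est_l <- length(unique(data$dose_landrace)) > 1L
  est_y <- length(unique(data$dose_yorkshire)) > 1L
  if (!est_l && !est_y) stop("SNP is monomorphic on both breed origins")
  terms <- c(if (est_l) "dose_landrace", if (est_y) "dose_yorkshire")
  fixed2 <- stats::update(fixed, paste("~ . +", paste(terms, collapse = " + ")))
  fit <- fit_univariate_reml(data, response, grm, fixed2, random, id)
  eff <- fit$fixed[fit$fixed$term %in% terms, ]
  eff$origin <- sub("dose_", "", eff$term)
  missing_origin <- setdiff(c("landrace", "yorkshire"), eff$origin)
  if (length(missing_origin)) {
    eff <- dplyr::bind_rows(eff, tibble::tibble(
      term = paste0("dose_", missing_origin), estimate = NA_real_,
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_,
      origin = missing_origin))
  }
  difference <- NULL
  if (est_l && est_y) {
    bc <- fit$beta_cov[c("dose_landrace", "dose_yorkshire"),
                       c("dose_landrace", "dose_yorkshire")]
    d <- eff$estimate[eff$origin == "landrace"] -
      eff$estimate[eff$origin == "yorkshire"]
    sed <- sqrt(bc[1, 1] + bc[2, 2] - 2 * bc[1, 2])
    difference <- tibble::tibble(estimate = d, std.error = sed,
                                 p.value = 2 * pnorm(-abs(d / sed)))
  }
  structure(list(effects = eff[, c("origin", "estimate", "std.error",
                                   "p.value")],
                 difference = difference, fit = fit),
            class = "breed_origin_fit")
}

#' Composite linkage disequilibrium r-squared between two SNPs
#'
#' The squared Pearson correlation of the dosage vectors (composite LD),
#' which needs no haplotype phase and equals haplotype r-squared under
#' random mating. Symmetric and invariant to allele relabelling
#' (`g -> 2 - g`).
#'
#' @param g1,g2 Dosage vectors over the same pigs.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sd(g1[ok]) == 0 || sd(g2[ok]) == 0) stop("monomorphic SNP")
  cor(g1[ok], g2[ok])^2
}

#' Haplotype-based LD r-squared (phase known)
#'
#' With known phase, r-squared from haplotype allele correlations across
#' all haplotypes; available for synthetic data where the breed-origin
#' phase is stored, as a cross-check of the composite estimate.
#'
#' @param geno A `genotype_matrix` with phase.
#' @param snp1,snp2 SNP ids or indices.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2_haplotype <- function(geno, snp1, snp2) {
  stopifnot(inherits(geno, "genotype_matrix"))
  j1 <- if (is.character(snp1)) match(snp1, geno$map$id) else snp1
  j2 <- if (is.character(snp2)) match(snp2, geno$map$id) else snp2
  h1 <- c(geno$hap_landrace[, j1], geno$hap_yorkshire[, j1])
  h2 <- c(geno$hap_landrace[, j2], geno$hap_yorkshire[, j2])
  if (sd(h1) == 0 || sd(h2) == 0) stop("monomorphic SNP")
  cor(h1, h2)^2
}

#' Genetic variance removed by conditioning on a SNP
#'
#' Reruns the BayesB GWAS with the focal SNP's dosage moved from the
#' random SNP set to a fixed covariate, and compares the posterior mean
#' genetic variance, the focal window's %EGV, and a chain-based
#' heritability (genetic / (genetic + litter + residual) per iteration)
#' before and after conditioning.
#'
#' @inheritParams run_bayesb
#' @param snp SNP id or index to condition on.
#' @param baseline Optional precomputed `bayesb_chain` for the
#'   unconditioned model (rerun when omitted).
#' @return A tibble with one row per model (`baseline`, `conditioned`):
#'   genetic variance, heritability, and the focal window's %EGV.
#' @export
variance_removed <- function(data, response, snp, geno,
                             config = bayesb_config("desk"),
                             fixed = ~ batch + age + storage_days,
                             random = c("litter", "pen"), id = "pig",
                             baseline = NULL, seed = NULL) {
  j <- if (is.character(snp)) match(snp, geno$map$id) else snp
  if (is.null(baseline)) {
    baseline <- run_bayesb(data, response, geno, config, fixed, random, id,
                           seed = seed)
  }
  focal_window <- baseline$window_of_snp[j]
  dose <- .snp_dosage(geno, j)
  data$snp_dosage <- unname(dose[data[[id]]])
  fixed2 <- stats::update(fixed, ~ . + snp_dosage)
  geno2 <- geno
  geno2$dosage <- geno$dosage[, -j, drop = FALSE]
  geno2$map <- geno$map[-j, , drop = FALSE]
  cond <- run_bayesb(data, response, geno2, config, fixed2, random, id,
                     seed = seed)
  chain_h2 <- function(ch) {
    den <- ch$var_genomic + ch$sigma2_e
    if (!is.null(ch$rand_var) && "litter" %in% colnames(ch$rand_var)) {
      den <- den + ch$rand_var[, "litter"]
    }
    mean(ch$var_genomic / den)
  }
  wpct <- function(ch, w) {
    r <- ch$var_window[, w] / ch$var_genomic
    r[!is.finite(r)] <- 0
    100 * mean(r)
  }
  # the conditioned chain keeps the same tiling (window ids align)
  tibble::tibble(
    model = c("baseline", "conditioned"),
    genetic_variance = c(mean(baseline$var_genomic), mean(cond$var_genomic)),
    h2 = c(chain_h2(baseline), chain_h2(cond)),
    focal_window = focal_window,
    focal_pct_egv = c(wpct(baseline, focal_window), wpct(cond, focal_window))
  )
}

#' Wald test for a SNP-by-company interaction
#'
#' Fits the animal model with the SNP dosage and dosage-by-company
#' interaction covariates, restricted to companies in which the SNP
#' segregates, and tests the interaction terms jointly with a Wald
#' chi-squared statistic.
#'
#' @inheritParams fit_snp_covariate
#' @param company Company column name.
#' @return A list with `statistic`, `df`, `p.value`, `companies_used`, and
#'   the underlying `fit`.
#' @export
snp_company_interaction <- function(data, response, snp, geno, grm,
                                    fixed = ~ batch + age + storage_days,
                                    random = c("litter", "pen"),
                                    id = "pig", company = "company") {
  dose <- .snp_dosage(geno, snp)
  data$snp_dosage <- unname(dose[data[[id]]])
  seg <- vapply(split(data$snp_dosage, data[[company]]),
                function(d) length(unique(d[!is.na(d)])) > 1L, logical(1))
  used <- names(seg)[seg]
  if (length(used) < 2L) stop("SNP segregates in fewer than 2 companies")
  sub <- data[data[[company]] %in% used, , drop = FALSE]
  sub$.company <- factor(sub[[company]])
  ref <- levels(sub$.company)[1]
  for (cc in setdiff(levels(sub$.company), ref)) {
    sub[[paste0("snp_x_", cc)]] <- sub$snp_dosage * (sub$.company == cc)
  }
  int_terms <- paste0("snp_x_", setdiff(levels(sub$.company), ref))
  fixed2 <- stats::update(fixed, paste("~ . + snp_dosage +",
                                       paste(int_terms, collapse = " + ")))
  fit <- fit_univariate_reml(sub, response, grm, fixed2, random, id)
  keep <- intersect(int_terms, fit$fixed$term)
  if (!length(keep)) stop("interaction terms were aliased with the design")
  b <- fit$fixed$estimate[match(keep, fit$fixed$term)]
  C <- fit$beta_cov[keep, keep, drop = FALSE]
  stat <- as.numeric(t(b) %*% solve(C, b))
  list(statistic = stat, df = length(b),
       p.value = pchisq(stat, df = length(b), lower.tail = FALSE),
       companies_used = used, fit = fit)
}

#' Parental-line allele frequency from an F1 haplotype frequency
#'
#' In an F1 cross, haplotypes of a given breed origin make up a share
#' `origin_share` (one half) of all haplotypes, so a haplotype found at
#' frequency `f` among F1 pigs segregates at `f / origin_share` in the
#' corresponding parental line.
#'
#' @param f1_haplotype_freq Frequency among F1 haplotypes (0 to
#'   `origin_share`).
#' @param origin_share Share of F1 haplotypes from that breed (default 0.5).
#' @return Parental-line frequency.
#' @examples
#' parental_freq_from_f1(0.060)  # 0.12
#' parental_freq_from_f1(0.041)  # 0.082
#' @export
parental_freq_from_f1 <- function(f1_haplotype_freq, origin_share = 0.5) {
  if (any(f1_haplotype_freq < 0) || any(f1_haplotype_freq > origin_share)) {
    stop("F1 haplotype frequency must lie in [0, origin_share]")
  }
  f1_haplotype_freq / origin_share
}

#' log2 cell-type proportions with a zero offset
#'
#' Zero proportions are replaced by half the smallest positive value in
#' the vector before taking log2.
#'
#' @param p Vector of proportions in `[0, 1]`.
#' @return log2-transformed proportions.
#' @export
log2_props <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stop("proportions must be nonnegative")
  pos <- p[!is.na(p) & p > 0]
  if (!length(pos)) stop("no positive proportions")
  p[!is.na(p) & p == 0] <- min(pos) / 2
  log2(p)
}

#' Fit a SNP effect on gene expression with cell-type covariates
#'
#' The animal model augmented with log2 white-blood-cell-type proportion
#' covariates, so that a dosage effect on whole-tissue expression is not
#' driven by cell-composition differences. Proportions of zero are offset
#' by half the minimum positive value before log2.
#'
#' @inheritParams fit_snp_covariate
#' @param expression Name of the expression column (response).
#' @param celltype_cols Names of the cell-type proportion columns.
#' @return A `snp_effect_fit` (percent change suppressed: expression is
#'   not a log-normal concentration).
#' @export
expression_covariate_fit <- function(data, expression, snp, geno, grm,
                                     celltype_cols,
                                     fixed = ~ batch + age,
                                     random = c("litter", "pen"),
                                     id = "pig") {
  for (cc in celltype_cols) {
    data[[paste0("log2_", cc)]] <- log2_props(data[[cc]])
  }
  fixed2 <- stats::update(fixed, paste("~ . +",
                                       paste(paste0("log2_", celltype_cols),
                                             collapse = " + ")))
  fit_snp_covariate(data, expression, snp, geno, grm, fixed2, random, id,
                    log_scale = FALSE)
}
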
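#' Back-calculate a hair hormone concentration from an assay reading
#'
#' Converts a mean ELISA reading (pg/ml of reconstituted extract) into a hair
#' concentration (pg/mg). The extract is obtained from `em` mg of powdered
#' hair, reconstituted in `rv` ml of assay buffer, and possibly diluted by a
#' factor `df` before being read; a stronger dilution therefore implies a
#' proportionally higher concentration in the original hair:
#' \deqn{C = S \cdot Rv \cdot df / Em.}
#'
#' Some laboratory write-ups are ambiguous about whether the dilution factor
#' multiplies or divides; `df_in_numerator = FALSE` switches to the divisor
#' reading for comparison, but the numerator placement is the only one
#' consistent with back-calculating a diluted extract and is the default.
#'
#' @param s Numeric vector of mean assay readings, pg/ml.
#' @param rv Reconstitution volume in ml (protocol default 0.4 ml).
#' @param em Extraction mass in mg (protocol default 25 mg of powdered hair).
#' @param df Dilution factor, `>= 1` for diluted samples, 1 if undiluted.
#' @param df_in_numerator Place `df` in the numerator (default) or denominator.
#' @return Numeric vector of concentrations in pg/mg.
#' @examples
#' concentration(1, rv = 0.4, em = 25, df = 1)    # 0.016 pg/mg
#' concentration(50, rv = 0.4, em = 25, df = 16)  # 12.8 pg/mg
#' @export
concentration <- function(s, rv = 0.4, em = 25, df = 1, df_in_numerator = TRUE) {
  if (any(em <= 0)) stop("extraction mass `em` must be positive")
  if (any(df <= 0)) stop("dilution factor `df` must be positive")
  if (df_in_numerator) s * rv * df / em else s * rv / (em * df)
}

#' Summarise replicate assay readings
#'
#' Duplicate assays are averaged directly. Triplicate assays run under the
#' `"best2of3"` policy return the mean of the two replicates with the lowest
#' within-sample coefficient of variation (CV), the rule used for hormones
#' whose assay is prone to erratic single wells.
#'
#' @param readings Numeric vector of replicate readings (pg/ml); at least two.
#' @param policy `"duplicate"` (mean and CV of all readings) or `"best2of3"`
#'   (requires exactly three readings).
#' @return A list with elements `mean`, `cv` (CV as a fraction, `sd/mean`),
#'   and `used` (indices of the readings entering the mean).
#' @examples
#' replicate_summary(c(8, 12))                       # mean 10
#' replicate_summary(c(10, 10, 40), "best2of3")      # picks {10, 10}
#' @export
replicate_summary <- function(readings, policy = c("duplicate", "best2of3")) {
  policy <- match.arg(policy)
  if (length(readings) < 2L) stop("need at least two replicate readings")
  if (policy == "duplicate") {
    m <- mean(readings)
    return(list(mean = m, cv = if (m == 0) NA_real_ else sd(readings) / m,
                used = seq_along(readings)))
  }
  if (length(readings) != 3L) stop("policy 'best2of3' requires exactly 3 readings")
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  cvs <- vapply(pairs, function(ix) {
    m <- mean(readings[ix])
    if (m == 0) Inf else sd(readings[ix]) / m
  }, numeric(1))
  best <- pairs[[which.min(cvs)]]
  list(mean = mean(readings[best]), cv = min(cvs), used = best)
}

#' Upper-tail modified-IQR outlier filter
#'
#' Flags observations strictly above `Q3 + k * IQR`, with quartiles computed
#' by linear interpolation (`stats::quantile()` type 7). Only the upper tail
#' is screened: hair steroid levels are bounded below by zero and their
#' distributions are right-skewed, so implausible values are high ones. The
#' multiplier defaults to `k = 4.5`, far more permissive than the textbook
#' 1.5, so that only extreme assay artefacts are removed.
#'
#' @param values Numeric vector of concentrations (pg/mg); at least 4 values.
#' @param k Boundary multiplier (default 4.5).
#' @param ids Optional identifiers aligned with `values` (defaults to indices).
#' @return An object of class `hairqtl_qc`: a list with `boundary`, `q1`,
#'   `q3`, `k`, a tibble `report` (`id`, `value`, `outlier`), and
#'   `removed_ids`.
#' @examples
#' qc <- iqr_outlier_filter(c(1, 2, 3, 4, 5, 100))
#' qc$removed_ids
#' @export
iqr_outlier_filter <- function(values, k = 4.5, ids = NULL) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) stop("need at least 4 non-missing values")
  if (is.null(ids)) ids <- seq_along(values)
  q <- quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  boundary <- q[2] + k * (q[2] - q[1])
  flag <- !is.na(values) & values > boundary
  structure(list(
    boundary = boundary, q1 = q[1], q3 = q[2], k = k,
    report = tibble::tibble(id = ids, value = values, outlier = flag),
    removed_ids = ids[flag]
  ), class = "hairqtl_qc")
}

#' @export
print.hairqtl_qc <- function(x, ...) {
  cat(sprintf("Upper-tail IQR filter: Q3 = %.4g, k = %.3g, boundary = %.4g\n",
              x$q3, x$k, x$boundary))
  cat(sprintf("%d of %d values flagged as outliers\n",
              sum(x$report$outlier), nrow(x$report)))
  invisible(x)
}

.hairqtl_hormones <- c("cortisol", "cortisone", "dhea", "dheas")

.hairqtl_ratios <- list(
  cortisol_dhea      = c("cortisol", "dhea"),
  cortisol_cortisone = c("cortisol", "cortisone"),
  cortisone_dhea     = c("cortisone", "dhea"),
  cortisol_dheas     = c("cortisol", "dheas"),
  cortisone_dheas    = c("cortisone", "dheas"),
  dhea_dheas         = c("dhea", "dheas"),
  sog_sod            = c("sog", "sod"),
  sog_dheas          = c("sog", "dheas")
)

#' Derive composite hormone traits, ratios, and log transforms
#'
#' From per-pig hormone concentrations (after outlier filtering) builds the
#' composites SOG (cortisol + cortisone, the glucocorticoid sum) and SOD
#' (DHEA + DHEA-S), the eight hormone ratios of the standard trait panel,
#' and natural-log transforms of every level and ratio. A composite or ratio
#' is missing whenever any component is missing; logs are defined only for
#' positive values. Log ratios are antisymmetric in the pair order, so the
#' choice of numerator is a labelling convention only.
#'
#' @param levels A data frame with one row per pig and columns `cortisol`,
#'   `cortisone`, `dhea`, `dheas` (pg/mg); other columns are passed through.
#' @return A tibble with the input columns plus `sog`, `sod`, the ratio
#'   columns (`cortisol_dhea`, `cortisol_cortisone`, `cortisone_dhea`,
#'   `cortisol_dheas`, `cortisone_dheas`, `dhea_dheas`, `sog_sod`,
#'   `sog_dheas`) and `ln_*` versions of every level and ratio.
#' @examples
#' derive_traits(tibble::tibble(pig = 1, cortisol = 15, cortisone = 20,
#'                              dhea = 10, dheas = 200))
#' @export
derive_traits <- function(levels) {
  stopifnot(all(.hairqtl_hormones %in% names(levels)))
  out <- tibble::as_tibble(levels)
  out$sog <- out$cortisol + out$cortisone
  out$sod <- out$dhea + out$dheas
  for (nm in names(.hairqtl_ratios)) {
    pair <- .hairqtl_ratios[[nm]]
    den <- out[[pair[2]]]
    out[[nm]] <- ifelse(!is.na(den) & den == 0, NA_real_,
                        out[[pair[1]]] / den)
  }
  for (nm in c(.hairqtl_hormones, "sog", "sod", names(.hairqtl_ratios))) {
    v <- out[[nm]]
    out[[paste0("ln_", nm)]] <- ifelse(!is.na(v) & v > 0, log(v), NA_real_)
  }
  out
}

#' Summarise assay records into per-pig concentrations with QC
#'
#' Applies [replicate_summary()] per sample, back-calculates concentrations
#' via [concentration()], and flags samples whose within-sample CV exceeds
#' `cv_flag`. High-CV samples are flagged but retained: dropping them is a
#' downstream choice, and retaining them mirrors the practice of keeping
#' samples whose repeat assays also show high CV.
#'
#' @param assays A data frame of raw assay records with columns `pig`,
#'   `hormone`, `reading` (one row per replicate), `rv`, `em`, `df`, and
#'   optionally `grind_date`, `extraction_date`, `storage_days`.
#' @param policy Replicate policy passed to [replicate_summary()]; a named
#'   character vector keyed by hormone is accepted (e.g. best-2-of-3 for
#'   cortisone only).
#' @param cv_flag CV threshold (fraction) above which a sample is flagged.
#' @return A tibble with one row per pig x hormone: `s_mean`, `cv`,
#'   `concentration`, `high_cv`, plus carried-through design columns.
#' @export
summarise_assays <- function(assays, policy = "duplicate", cv_flag = 0.15) {
  stopifnot(all(c("pig", "hormone", "reading", "rv", "em", "df") %in% names(assays)))
  carry <- intersect(c("grind_date", "extraction_date", "storage_days"),
                     names(assays))
  assays |>
    dplyr::group_by(.data$pig, .data$hormone) |>
    dplyr::group_modify(function(df, key) {
      pol <- if (length(policy) > 1L || !is.null(names(policy))) {
        p <- policy[[as.character(key$hormone)]]
        if (is.null(p) || is.na(p)) "duplicate" else p
      } else policy
      rs <- replicate_summary(df$reading, pol)
      res <- tibble::tibble(
        s_mean = rs$mean, cv = rs$cv,
        concentration = concentration(rs$mean, df$rv[1], df$em[1], df$df[1])
      )
      for (col in carry) res[[col]] <- df[[col]][1]
      res
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(high_cv = !is.na(.data$cv) & .data$cv > cv_flag)
}

#' Overdispersion test for count traits
#'
#' Cameron-Trivedi auxiliary-regression (Lagrange-multiplier style) test of
#' the Poisson variance assumption against negative-binomial overdispersion.
#' A Poisson GLM (intercept-only unless covariates are supplied) provides
#' fitted means \eqn{\mu_i}; the auxiliary regression of
#' \eqn{((y_i-\mu_i)^2 - y_i)/\mu_i} on \eqn{\mu_i} (no intercept) yields a
#' slope whose one-sided t-test detects variance exceeding the mean. The
#' reported dispersion is the Pearson statistic over its degrees of freedom,
#' a variance/mean-type ratio (about 1 under Poisson).
#'
#' @param counts Vector of non-negative integer counts, `n >= 30`.
#' @param x Optional model matrix of covariates for the Poisson mean.
#' @return A list with `dispersion`, `statistic` (auxiliary t), `p.value`
#'   (one-sided, overdispersed alternative), and `alpha` (NB2 slope).
#' @export
overdispersion_test <- function(counts, x = NULL) {
  if (length(counts) < 30L) stop("need at least 30 counts")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (all(counts == 0)) stop("all counts are zero")
  fit <- if (is.null(x)) glm(counts ~ 1, family = poisson()) else
    glm(counts ~ x, family = poisson())
  mu <- fitted(fit)
  disp <- sum((counts - mu)^2 / mu) / fit$df.residual
  z <- ((counts - mu)^2 - counts) / mu
  aux <- lm(z ~ 0 + mu)
  sm <- suppressWarnings(summary(aux))$coefficients
  tval <- sm[1, "t value"]
  list(dispersion = disp, statistic = tval,
       p.value = pt(tval, df = aux$df.residual, lower.tail = FALSE),
       alpha = sm[1, "Estimate"])
}

#' Kolmogorov-Smirnov normality check with bootstrap p-value
#'
#' One-sample KS distance to a normal distribution with mean and sd
#' estimated from the data. Because the reference parameters are estimated,
#' the classical KS p-value is invalid; a Lilliefors-style p-value is
#' obtained by parametric bootstrap (resampling normal data of the same size
#' and re-estimating parameters each time).
#'
#' @param values Numeric vector, `n >= 10`, non-constant.
#' @param n_boot Number of bootstrap replicates for the p-value.
#' @return A list with `statistic` (D) and `p.value`.
#' @export
ks_normality <- function(values, n_boot = 500L) {
  values <- values[!is.na(values)]
  if (length(values) < 10L) stop("need at least 10 values")
  if (sd(values) == 0) stop("constant input")
  d_obs <- .ks_d_est(values)
  n <- length(values)
  d_null <- vapply(seq_len(n_boot),
                   function(i) .ks_d_est(rnorm(n)), numeric(1))
  list(statistic = d_obs,
       p.value = (1 + sum(d_null >= d_obs)) / (n_boot + 1))
}

# KS distance to N(mean(x), sd(x)); standard one-sample D on sorted values
.ks_d_est <- function(x) {
  n <- length(x)
  z <- pnorm(sort(x), mean = mean(x), sd = sd(x))
  max(pmax(seq_len(n) / n - z, z - (seq_len(n) - 1) / n))
}
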
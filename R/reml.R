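# Average-information REML for genomic animal models.
#
# The engine works on an arbitrary list of n x n covariance kernels (a
# genomic relationship matrix for the additive term, group-indicator
# cross-products for iid terms such as litter and pen, identity for the
# residual). Free fits use AI updates with step-halving and an EM-scaled
# fallback; variance parameters are kept nonnegative by boundary
# projection. Constrained bivariate fits (genetic correlation pinned to
# 0, 1, or -1) reuse the same restricted likelihood through a bounded
# quasi-Newton optimiser, because under the rank-1 constraint dV/dtheta
# depends on the parameters themselves.

.reml_floor_frac <- 1e-8

# restricted log-likelihood for V = sum theta_i K_i; -Inf when V or X'VinvX
# fails to factorise
.reml_ll_eval <- function(y, X, Ks, theta) {
  V <- Reduce(`+`, Map(`*`, Ks, theta))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  Vinv <- chol2inv(ch)
  W <- Vinv %*% X
  XtVX <- crossprod(X, W)
  chx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chx)) return(list(ll = -Inf))
  P <- Vinv - W %*% chol2inv(chx) %*% t(W)
  Py <- as.vector(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) + sum(y * Py))
  list(ll = ll, P = P, Py = Py, Vinv = Vinv, XtVX_inv = chol2inv(chx))
}

# univariate AI-REML core; Ks must include the residual identity as the
# last element
.reml_uni <- function(y, X, Ks, tol_ll = 1e-6, tol_gr = 1e-4,
                      max_iter = 100L, init = NULL) {
  n <- length(y)
  nt <- length(Ks)
  vy <- var(y)
  floor_v <- .reml_floor_frac * vy
  theta <- if (is.null(init)) rep(vy / nt, nt) else pmax(init, floor_v)
  st <- .reml_ll_eval(y, X, Ks, theta)
  if (!is.finite(st$ll)) stop("initial variance parameters give a singular model")
  ll <- st$ll
  converged <- FALSE
  grad_norm <- NA_real_
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    Py <- st$Py
    KPy <- vapply(Ks, function(K) as.vector(K %*% Py), numeric(n))
    score <- vapply(seq_len(nt), function(i) {
      -0.5 * (sum(st$P * Ks[[i]]) - sum(Py * KPy[, i]))
    }, numeric(1))
    # pinned parameters with inward-pointing gradients stay at the floor
    pinned <- theta <= floor_v * 1.01 & score < 0
    AI <- 0.5 * crossprod(KPy, st$P %*% KPy)
    grad_norm <- sqrt(sum(score[!pinned]^2)) / max(1, abs(ll))
    free <- which(!pinned)
    delta <- rep(0, nt)
    ai_ok <- length(free) > 0
    if (ai_ok) {
      d <- tryCatch(solve(AI[free, free, drop = FALSE], score[free]),
                    error = function(e) NULL)
      if (is.null(d)) ai_ok <- FALSE else delta[free] <- d
    }
    if (!ai_ok) {
      # EM-scaled gradient step (exact EM update when K = ZZ')
      delta <- theta^2 * 2 * score / n
      delta[pinned] <- 0
    }
    step <- 1
    accepted <- FALSE
    for (h in seq_len(12L)) {
      cand <- pmax(theta + step * delta, floor_v)
      st_new <- .reml_ll_eval(y, X, Ks, cand)
      if (is.finite(st_new$ll) && st_new$ll >= ll - 1e-10) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      # fall back to a short EM step before giving up on this iteration
      cand <- pmax(theta + theta^2 * 2 * score / n, floor_v)
      st_new <- .reml_ll_eval(y, X, Ks, cand)
      if (!is.finite(st_new$ll) || st_new$ll < ll - 1e-6) {
        converged <- grad_norm < tol_gr
        break
      }
    }
    ll_new <- st_new$ll
    theta <- cand
    st <- st_new
    if (abs(ll_new - ll) < tol_ll && grad_norm < tol_gr) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  se <- rep(NA_real_, nt)
  vc <- matrix(NA_real_, nt, nt)
  inv <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(inv)) {
    vc <- inv
    se <- sqrt(pmax(diag(inv), 0))
  }
  beta_cov <- st$XtVX_inv
  beta <- as.vector(beta_cov %*% crossprod(X, st$Vinv %*% y))
  list(theta = setNames(theta, names(Ks)), se = setNames(se, names(Ks)),
       vcov = vc, loglik = ll, converged = converged, iterations = iter,
       grad_norm = grad_norm, beta = beta, beta_cov = beta_cov,
       pinned = theta <= floor_v * 1.01, n = n)
}

# build fixed-effect design from a one-sided formula, dropping aliased
# columns with a warning
.fixed_design <- function(fixed, data) {
  X <- model.matrix(fixed, data)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("dropping aliased fixed-effect columns: ",
            paste(drop, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  X
}

# iid group kernel: 1 where two records share the grouping level
.group_kernel <- function(f) {
  Z <- model.matrix(~ 0 + factor(f))
  tcrossprod(Z)
}

.get_grm <- function(grm, ids) {
  G <- if (inherits(grm, "grm_set")) grm$combined else grm
  if (is.null(rownames(G))) stop("GRM must carry pig ids as dimnames")
  missing <- setdiff(ids, rownames(G))
  if (length(missing)) stop("GRM does not cover pigs: ",
                            paste(head(missing, 5), collapse = ", "))
  G[ids, ids]
}

#' Fit a univariate genomic animal model by AI-REML
#'
#' Fits `trait = fixed effects + genomic animal effect + iid random terms +
#' residual` with the animal effect covariance proportional to a genomic
#' relationship matrix. Estimation is restricted maximum likelihood with
#' average-information updates, step-halving, an EM-scaled fallback, and
#' nonnegativity by boundary projection. Heritability and the litter
#' fraction are reported against the genetic + litter + residual variance
#' (pen and assay-date variances are estimated but excluded from that
#' denominator), with delta-method standard errors.
#'
#' @param data Data frame with the response, fixed-effect covariates, the
#'   pig id column, and the grouping columns of the iid random terms.
#' @param response Name of the response column.
#' @param grm A `grm_set` from [company_grm()] or a relationship matrix
#'   with pig ids as dimnames; `NULL` omits the genomic term.
#' @param fixed One-sided formula of fixed effects.
#' @param random Character vector of iid random-term grouping columns.
#' @param id Pig id column name used to index the GRM.
#' @param tol_ll,tol_gr,max_iter Convergence controls: successive
#'   log-likelihood change, relative gradient norm, iteration cap.
#' @return A `reml_fit` object; see [tidy.reml_fit()] and
#'   [glance.reml_fit()].
#' @export
fit_univariate_reml <- function(data, response, grm = NULL,
                                fixed = ~ batch + age + storage_days,
                                random = c("litter", "pen"), id = "pig",
                                tol_ll = 1e-6, tol_gr = 1e-4,
                                max_iter = 100L) {
  keep <- !is.na(data[[response]]) & complete.cases(
    data[, intersect(c(all.vars(fixed), random, id), names(data)), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  y <- data[[response]]
  if (sd(y) == 0) stop("response is constant")
  for (r in random) {
    if (length(unique(data[[r]])) < 2L) stop("random term '", r,
                                             "' has fewer than 2 levels")
  }
  X <- .fixed_design(fixed, data)
  Ks <- list()
  if (!is.null(grm)) Ks$genomic <- .get_grm(grm, data[[id]])
  for (r in random) Ks[[r]] <- .group_kernel(data[[r]])
  Ks$residual <- diag(length(y))
  fit <- .reml_uni(y, X, Ks, tol_ll, tol_gr, max_iter)
  if (!fit$converged) {
    warning("REML did not meet convergence tolerances after ",
            fit$iterations, " iterations (relative gradient ",
            signif(fit$grad_norm, 3), ")")
  }
  ratio_terms <- intersect(c("genomic", "litter", "residual"), names(Ks))
  out <- structure(list(
    response = response, theta = fit$theta, se = fit$se, vcov = fit$vcov,
    loglik = fit$loglik, converged = fit$converged,
    iterations = fit$iterations, grad_norm = fit$grad_norm,
    pinned = fit$pinned, n = fit$n,
    fixed = tibble::tibble(term = colnames(X), estimate = fit$beta,
                           std.error = sqrt(pmax(diag(fit$beta_cov), 0))),
    beta_cov = structure(fit$beta_cov, dimnames = list(colnames(X),
                                                       colnames(X))),
    ratio_terms = ratio_terms,
    kernels = names(Ks)
  ), class = "reml_fit")
  out$fixed$statistic <- out$fixed$estimate / out$fixed$std.error
  out$fixed$p.value <- 2 * pnorm(-abs(out$fixed$statistic))
  out
}

# delta-method SE of theta[num]/sum(theta[den]) given the parameter
# covariance matrix
.ratio_se <- function(theta, vcov, num, den) {
  s <- sum(theta[den])
  r <- theta[num] / s
  grad <- setNames(rep(0, length(theta)), names(theta))
  grad[den] <- -theta[num] / s^2
  grad[num] <- grad[num] + 1 / s
  v <- as.numeric(t(grad) %*% vcov %*% grad)
  c(estimate = r, se = sqrt(max(v, 0)))
}

#' Heritability and litter-fraction estimates from a REML fit
#'
#' @param fit A `reml_fit`.
#' @return A tibble with rows `h2` and `litter_frac` (those whose terms were
#'   fitted), estimates and delta-method standard errors.
#' @export
genetic_params <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  den <- match(fit$ratio_terms, names(fit$theta))
  rows <- list()
  if ("genomic" %in% names(fit$theta)) {
    r <- .ratio_se(fit$theta, fit$vcov, match("genomic", names(fit$theta)), den)
    rows$h2 <- tibble::tibble(param = "h2", estimate = r[1], std.error = r[2])
  }
  if ("litter" %in% names(fit$theta)) {
    r <- .ratio_se(fit$theta, fit$vcov, match("litter", names(fit$theta)), den)
    rows$lit <- tibble::tibble(param = "litter_frac", estimate = r[1],
                               std.error = r[2])
  }
  dplyr::bind_rows(rows)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("Univariate AI-REML fit of '%s' (n = %d)\n", x$response, x$n))
  vc <- tibble::tibble(term = names(x$theta), variance = unname(x$theta),
                       std.error = unname(x$se))
  print(as.data.frame(vc), row.names = FALSE)
  gp <- genetic_params(x)
  if (nrow(gp)) {
    for (i in seq_len(nrow(gp))) {
      cat(sprintf("%s = %.3f (SE %.3f)\n", gp$param[i], gp$estimate[i],
                  gp$std.error[i]))
    }
  }
  cat(sprintf("logLik = %.3f, converged = %s (%d iterations)\n",
              x$loglik, x$converged, x$iterations))
  invisible(x)
}

#' @rdname fit_univariate_reml
#' @param x,... S3 method arguments.
#' @export
tidy.reml_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = names(x$theta), type = "variance",
                   estimate = unname(x$theta), std.error = unname(x$se)),
    genetic_params(x) |>
      dplyr::transmute(term = .data$param, type = "ratio",
                       estimate = .data$estimate, std.error = .data$std.error)
  )
}

#' @rdname fit_univariate_reml
#' @export
glance.reml_fit <- function(x, ...) {
  gp <- genetic_params(x)
  tibble::tibble(
    nobs = x$n, logLik = x$loglik, converged = x$converged,
    iterations = x$iterations,
    h2 = if ("h2" %in% gp$param) gp$estimate[gp$param == "h2"] else NA_real_,
    litter_frac = if ("litter_frac" %in% gp$param)
      gp$estimate[gp$param == "litter_frac"] else NA_real_
  )
}

# ---- bivariate machinery -------------------------------------------------

# assemble the stacked covariance matrix from per-term 2x2 matrices Sig and
# pig-space kernels restricted to the observed rows of the two traits
.mt_build_v <- function(Sig, Ksub) {
  n1 <- nrow(Ksub[[1]]$K11); n2 <- nrow(Ksub[[1]]$K22)
  V <- matrix(0, n1 + n2, n1 + n2)
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  for (k in seq_along(Ksub)) {
    S <- Sig[[k]]
    V[i1, i1] <- V[i1, i1] + S[1, 1] * Ksub[[k]]$K11
    V[i2, i2] <- V[i2, i2] + S[2, 2] * Ksub[[k]]$K22
    V[i1, i2] <- V[i1, i2] + S[1, 2] * Ksub[[k]]$K12
  }
  V[i2, i1] <- t(V[i1, i2])
  V
}

.mt_ll_eval <- function(y, X, Sig, Ksub) {
  V <- .mt_build_v(Sig, Ksub)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  Vinv <- chol2inv(ch)
  W <- Vinv %*% X
  XtVX <- crossprod(X, W)
  chx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chx)) return(list(ll = -Inf))
  P <- Vinv - W %*% chol2inv(chx) %*% t(W)
  Py <- as.vector(P %*% y)
  list(ll = -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                      sum(y * Py)),
       P = P, Py = Py, Vinv = Vinv, XtVX_inv = chol2inv(chx))
}

# theta layout: 3 per term, (v1, c, v2)
.mt_theta_to_sig <- function(theta, nterm) {
  lapply(seq_len(nterm), function(k) {
    v <- theta[(3 * k - 2):(3 * k)]
    matrix(c(v[1], v[2], v[2], v[3]), 2, 2)
  })
}

# project each 2x2 to the PSD cone with a variance floor
.mt_project <- function(theta, nterm, floor_v) {
  for (k in seq_len(nterm)) {
    i <- 3 * k - 2
    theta[i] <- max(theta[i], floor_v)
    theta[i + 2] <- max(theta[i + 2], floor_v)
    cmax <- 0.999 * sqrt(theta[i] * theta[i + 2])
    theta[i + 1] <- max(min(theta[i + 1], cmax), -cmax)
  }
  theta
}

# dV/dtheta %*% v for term k, basis b (1: v1, 2: c, 3: v2)
.mt_dv_mult <- function(Ksub, k, b, v, n1, n2) {
  v1 <- v[seq_len(n1)]; v2 <- v[n1 + seq_len(n2)]
  if (b == 1) c(Ksub[[k]]$K11 %*% v1, rep(0, n2))
  else if (b == 3) c(rep(0, n1), Ksub[[k]]$K22 %*% v2)
  else c(Ksub[[k]]$K12 %*% v2, crossprod(Ksub[[k]]$K12, v1))
}

.mt_tr_pdv <- function(P, Ksub, k, b, n1, n2) {
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  if (b == 1) sum(P[i1, i1] * Ksub[[k]]$K11)
  else if (b == 3) sum(P[i2, i2] * Ksub[[k]]$K22)
  else 2 * sum(P[i1, i2] * Ksub[[k]]$K12)
}

.reml_mt <- function(y, X, Ksub, rg_zero_term = NULL,
                     tol_ll = 1e-6, tol_gr = 1e-4, max_iter = 200L,
                     init = NULL, trace = FALSE) {
  n1 <- nrow(Ksub[[1]]$K11); n2 <- nrow(Ksub[[1]]$K22)
  nterm <- length(Ksub)
  np <- 3L * nterm
  vy <- var(y)
  floor_v <- .reml_floor_frac * vy
  theta <- if (is.null(init)) {
    as.vector(vapply(seq_len(nterm),
                     function(k) c(vy / nterm, 0, vy / nterm), numeric(3)))
  } else init
  mask <- rep(FALSE, np)          # TRUE = held fixed
  if (!is.null(rg_zero_term)) {
    theta[3 * rg_zero_term - 1] <- 0
    mask[3 * rg_zero_term - 1] <- TRUE
  }
  theta <- .mt_project(theta, nterm, floor_v)
  if (!is.null(rg_zero_term)) theta[3 * rg_zero_term - 1] <- 0
  st <- .mt_ll_eval(y, X, .mt_theta_to_sig(theta, nterm), Ksub)
  if (!is.finite(st$ll)) stop("initial bivariate parameters give a singular model")
  ll <- st$ll
  converged <- FALSE
  grad_norm <- NA_real_
  AI <- NULL
  stall <- 0L
  kb <- cbind(rep(seq_len(nterm), each = 3), rep(1:3, nterm))
  for (iter in seq_len(max_iter)) {
    Py <- st$Py
    dVPy <- vapply(seq_len(np), function(j) {
      .mt_dv_mult(Ksub, kb[j, 1], kb[j, 2], Py, n1, n2)
    }, numeric(n1 + n2))
    score <- vapply(seq_len(np), function(j) {
      -0.5 * (.mt_tr_pdv(st$P, Ksub, kb[j, 1], kb[j, 2], n1, n2) -
                sum(Py * dVPy[, j]))
    }, numeric(1))
    pin_var <- kb[, 2] != 2 & theta <= floor_v * 1.01 & score < 0
    fixed <- mask | pin_var
    AI <- 0.5 * crossprod(dVPy, st$P %*% dVPy)
    free <- which(!fixed)
    grad_norm <- sqrt(sum(score[free]^2)) / max(1, abs(ll))
    delta <- rep(0, np)
    lambda <- 0
    accepted <- FALSE
    proj_active <- FALSE
    for (try in seq_len(8L)) {
      Af <- AI[free, free, drop = FALSE]
      if (lambda > 0) diag(Af) <- diag(Af) * (1 + lambda)
      d <- tryCatch(solve(Af, score[free]), error = function(e) NULL)
      if (!is.null(d)) {
        delta[free] <- d
        step <- 1
        for (h in seq_len(10L)) {
          raw <- theta + step * delta
          cand <- .mt_project(raw, nterm, floor_v)
          proj_active <- any(abs(cand - raw) > 1e-12)
          if (!is.null(rg_zero_term)) cand[3 * rg_zero_term - 1] <- 0
          st_new <- .mt_ll_eval(y, X, .mt_theta_to_sig(cand, nterm), Ksub)
          if (is.finite(st_new$ll) && st_new$ll >= ll - 1e-10) {
            accepted <- TRUE
            break
          }
          step <- step / 2
        }
      }
      if (accepted) break
      lambda <- if (lambda == 0) 0.1 else lambda * 10
    }
    if (!accepted) { converged <- grad_norm < tol_gr; break }
    if (trace) {
      message(sprintf("it %3d ll %.6f grad %.3g step %.3g lambda %.3g",
                      iter, st_new$ll, grad_norm, step, lambda))
    }
    theta <- cand
    ll_new <- st_new$ll
    st <- st_new
    if (abs(ll_new - ll) < tol_ll && grad_norm < tol_gr) {
      ll <- ll_new; converged <- TRUE; break
    }
    # boundary convergence: the PSD projection can leave a residual
    # gradient that no feasible step reduces; repeated no-progress accepted
    # steps terminate the fit, but only while the projection is active
    stall <- if (proj_active && abs(ll_new - ll) < tol_ll) stall + 1L else 0L
    if (stall >= 3L) { ll <- ll_new; converged <- TRUE; break }
    ll <- ll_new
  }
  inv <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, np, np))
  list(theta = theta, vcov = inv, loglik = ll, converged = converged,
       iterations = iter, grad_norm = grad_norm, nterm = nterm,
       Sig = .mt_theta_to_sig(theta, nterm))
}

# warm start for the bivariate engine: univariate variance components per
# trait, covariances initialised from the observed phenotypic correlation
.mt_init <- function(data, traits, grm, fixed, random, id, prep) {
  u1 <- tryCatch(fit_univariate_reml(data, traits[1], grm, fixed, random, id,
                                     max_iter = 50L),
                 warning = function(w) suppressWarnings(
                   fit_univariate_reml(data, traits[1], grm, fixed, random,
                                       id, max_iter = 50L)),
                 error = function(e) NULL)
  u2 <- tryCatch(fit_univariate_reml(data, traits[2], grm, fixed, random, id,
                                     max_iter = 50L),
                 warning = function(w) suppressWarnings(
                   fit_univariate_reml(data, traits[2], grm, fixed, random,
                                       id, max_iter = 50L)),
                 error = function(e) NULL)
  if (is.null(u1) || is.null(u2)) return(NULL)
  r_obs <- suppressWarnings(cor(data[[traits[1]]], data[[traits[2]]],
                                use = "pairwise.complete.obs"))
  if (!is.finite(r_obs)) r_obs <- 0
  r_obs <- max(min(r_obs, 0.9), -0.9)
  as.vector(vapply(prep$terms, function(tm) {
    v1 <- unname(u1$theta[tm]); v2 <- unname(u2$theta[tm])
    c(v1, 0.5 * r_obs * sqrt(v1 * v2), v2)
  }, numeric(3)))
}

.mt_prepare <- function(data, traits, grm, fixed, random, id) {
  vars <- unique(c(all.vars(fixed), random, id))
  ok_cov <- complete.cases(data[, intersect(vars, names(data)), drop = FALSE])
  keep1 <- which(!is.na(data[[traits[1]]]) & ok_cov)
  keep2 <- which(!is.na(data[[traits[2]]]) & ok_cov)
  pigs <- data[[id]]
  d1 <- data[keep1, , drop = FALSE]; d2 <- data[keep2, , drop = FALSE]
  y <- c(scale(d1[[traits[1]]], scale = FALSE),
         scale(d2[[traits[2]]], scale = FALSE))
  X1 <- .fixed_design(fixed, d1); X2 <- .fixed_design(fixed, d2)
  X <- rbind(cbind(X1, matrix(0, nrow(X1), ncol(X2))),
             cbind(matrix(0, nrow(X2), ncol(X1)), X2))
  # pig-space kernels, then restrict to observed rows per trait
  alldat <- data
  Kp <- list()
  if (!is.null(grm)) Kp$genomic <- .get_grm(grm, pigs)
  for (r in random) Kp[[r]] <- .group_kernel(alldat[[r]])
  Kp$residual <- diag(length(pigs))
  Ksub <- lapply(Kp, function(K) {
    list(K11 = K[keep1, keep1, drop = FALSE],
         K12 = K[keep1, keep2, drop = FALSE],
         K22 = K[keep2, keep2, drop = FALSE])
  })
  list(y = y, X = X, Ksub = Ksub, terms = names(Kp),
       n1 = length(keep1), n2 = length(keep2))
}

#' Fit a bivariate genomic animal model by REML
#'
#' Two-trait REML with unstructured 2x2 genetic, iid-term, and residual
#' covariance matrices; records are used pairwise-complete (a pig may be
#' observed for one trait only). Count traits should be supplied already
#' log(1 + count)-transformed. Returns genetic and phenotypic correlations
#' with delta-method standard errors; the phenotypic covariance sums the
#' genetic, litter, and residual components (the same denominator used for
#' heritability). The genetic correlation can be constrained to 0, 1, or
#' -1 for likelihood-ratio testing; the constrained fits maximise the same
#' restricted likelihood through a bounded quasi-Newton parameterisation.
#'
#' @inheritParams fit_univariate_reml
#' @param traits Character vector of the two response columns.
#' @param constrain_rg `"none"` (default), `"zero"`, `"one"`, or
#'   `"minus_one"`.
#' @param init Optional starting values: the `theta` vector of a previous
#'   fit on the same model (used e.g. to warm-start a constrained fit from
#'   the free fit).
#' @return A `reml_fit_bv` object with per-term 2x2 covariance matrices,
#'   `rg`, `rp`, their standard errors, and the restricted log-likelihood.
#' @export
fit_bivariate_reml <- function(data, traits, grm = NULL,
                               fixed = ~ batch + age + storage_days,
                               random = c("litter", "pen"), id = "pig",
                               constrain_rg = c("none", "zero", "one",
                                                "minus_one"),
                               tol_ll = 1e-6, tol_gr = 1e-4,
                               max_iter = 200L, init = NULL) {
  constrain_rg <- match.arg(constrain_rg)
  stopifnot(length(traits) == 2L)
  prep <- .mt_prepare(data, traits, grm, fixed, random, id)
  gterm <- match("genomic", prep$terms)
  if (constrain_rg %in% c("one", "minus_one") && is.na(gterm)) {
    stop("rank-1 constraint requires a genomic term")
  }
  if (constrain_rg %in% c("none", "zero")) {
    if (is.null(init)) init <- .mt_init(data, traits, grm, fixed, random, id,
                                        prep)
    if (constrain_rg == "zero" && !is.na(gterm)) init[3 * gterm - 1] <- 0
    fit <- .reml_mt(prep$y, prep$X, prep$Ksub,
                    rg_zero_term = if (constrain_rg == "zero") gterm else NULL,
                    tol_ll = tol_ll, tol_gr = tol_gr, max_iter = max_iter,
                    init = init)
  } else {
    fit <- .mt_rank1_fit(prep, gterm, sign = if (constrain_rg == "one") 1 else -1)
  }
  Sig <- setNames(fit$Sig, prep$terms)
  gi <- gterm
  rg <- if (!is.na(gi)) {
    s <- Sig[["genomic"]]
    s[1, 2] / sqrt(s[1, 1] * s[2, 2])
  } else NA_real_
  rg <- max(min(rg, 1), -1)
  pt <- intersect(c("genomic", "litter", "residual"), prep$terms)
  Sp <- Reduce(`+`, Sig[pt])
  rp <- Sp[1, 2] / sqrt(Sp[1, 1] * Sp[2, 2])
  # delta-method SEs from the AI covariance (free fits only)
  rg_se <- rp_se <- NA_real_
  if (constrain_rg == "none" && all(is.finite(fit$vcov))) {
    th <- fit$theta
    if (!is.na(gi)) {
      g <- rep(0, length(th))
      i <- 3 * gi - 2
      g[i] <- -th[i + 1] / (2 * th[i]^1.5 * sqrt(th[i + 2]))
      g[i + 1] <- 1 / sqrt(th[i] * th[i + 2])
      g[i + 2] <- -th[i + 1] / (2 * th[i + 2]^1.5 * sqrt(th[i]))
      rg_se <- sqrt(max(0, as.numeric(t(g) %*% fit$vcov %*% g)))
    }
    gp <- rep(0, length(th))
    for (k in match(pt, prep$terms)) {
      i <- 3 * k - 2
      gp[i] <- gp[i] - Sp[1, 2] / (2 * Sp[1, 1]^1.5 * sqrt(Sp[2, 2]))
      gp[i + 1] <- gp[i + 1] + 1 / sqrt(Sp[1, 1] * Sp[2, 2])
      gp[i + 2] <- gp[i + 2] - Sp[1, 2] / (2 * Sp[2, 2]^1.5 * sqrt(Sp[1, 1]))
    }
    rp_se <- sqrt(max(0, as.numeric(t(gp) %*% fit$vcov %*% gp)))
  }
  structure(list(traits = traits, Sig = Sig, theta = fit$theta,
                 rg = rg, rg_se = rg_se,
                 rp = rp, rp_se = rp_se, loglik = fit$loglik,
                 converged = fit$converged, iterations = fit$iterations,
                 constraint = constrain_rg, n1 = prep$n1, n2 = prep$n2),
            class = "reml_fit_bv")
}

# rank-1 (|r_g| = 1) constrained fit: genetic Sigma = (a, s*ab; s*ab, b^2)
# with s = +/-1; all parameters optimised on transformed scales
.mt_rank1_fit <- function(prep, gterm, sign = 1) {
  nterm <- length(prep$Ksub)
  others <- setdiff(seq_len(nterm), gterm)
  vy <- var(prep$y)
  # par: log a^2, log b^2, then per other term (log v1, atanh r, log v2)
  par0 <- c(log(vy / nterm), log(vy / nterm),
            as.vector(vapply(others, function(k)
              c(log(vy / nterm), 0, log(vy / nterm)), numeric(3))))
  to_sig <- function(par) {
    Sig <- vector("list", nterm)
    a2 <- exp(par[1]); b2 <- exp(par[2])
    Sig[[gterm]] <- matrix(c(a2, sign * sqrt(a2 * b2),
                             sign * sqrt(a2 * b2), b2), 2, 2)
    for (j in seq_along(others)) {
      p <- par[2 + (3 * j - 2):(3 * j)]
      v1 <- exp(p[1]); v2 <- exp(p[3]); r <- tanh(p[2]) * 0.999
      Sig[[others[j]]] <- matrix(c(v1, r * sqrt(v1 * v2),
                                   r * sqrt(v1 * v2), v2), 2, 2)
    }
    Sig
  }
  obj <- function(par) {
    ll <- .mt_ll_eval(prep$y, prep$X, to_sig(par), prep$Ksub)$ll
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- nlminb(par0, obj, control = list(iter.max = 400, rel.tol = 1e-10))
  list(Sig = to_sig(opt$par), theta = NA, vcov = matrix(NA_real_, 1, 1),
       loglik = -opt$objective, converged = opt$convergence == 0,
       iterations = opt$iterations)
}

#' @export
print.reml_fit_bv <- function(x, ...) {
  cat(sprintf("Bivariate AI-REML fit of (%s, %s); constraint: %s\n",
              x$traits[1], x$traits[2], x$constraint))
  cat(sprintf("r_g = %.3f (SE %.3f), r_p = %.3f (SE %.3f)\n",
              x$rg, x$rg_se, x$rp, x$rp_se))
  cat(sprintf("logLik = %.3f, converged = %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @rdname fit_bivariate_reml
#' @param x,... S3 method arguments.
#' @export
tidy.reml_fit_bv <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$Sig), function(tm) {
    S <- x$Sig[[tm]]
    tibble::tibble(term = tm,
                   component = c("var1", "cov", "var2"),
                   estimate = c(S[1, 1], S[1, 2], S[2, 2]))
  })) |>
    dplyr::bind_rows(tibble::tibble(
      term = "correlation", component = c("rg", "rp"),
      estimate = c(x$rg, x$rp)))
}

#' @rdname fit_bivariate_reml
#' @export
glance.reml_fit_bv <- function(x, ...) {
  tibble::tibble(n1 = x$n1, n2 = x$n2, logLik = x$loglik,
                 converged = x$converged, rg = x$rg, rp = x$rp,
                 constraint = x$constraint)
}

#' Likelihood-ratio test for a constrained genetic correlation
#'
#' Compares a free bivariate fit with one whose genetic correlation is
#' pinned to 0, 1, or -1; the statistic `2 * (llik_free - llik_constrained)`
#' (clipped at zero) is referred to a chi-squared distribution with one
#' degree of freedom. At the parameter-space boundary (|r| = 1) this
#' reference is known to be conservative.
#'
#' @param fit_free,fit_constrained `reml_fit_bv` objects on the same data
#'   and fixed effects.
#' @return A list with `statistic`, `df`, and `p.value`.
#' @export
lrt_correlation <- function(fit_free, fit_constrained) {
  stopifnot(inherits(fit_free, "reml_fit_bv"),
            inherits(fit_constrained, "reml_fit_bv"))
  if (!identical(fit_free$traits, fit_constrained$traits)) {
    stop("fits are for different trait pairs")
  }
  if (fit_free$constraint != "none") stop("first fit must be unconstrained")
  stat <- max(0, 2 * (fit_free$loglik - fit_constrained$loglik))
  list(statistic = stat, df = 1L,
       p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}
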
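# Longitudinal kinship mixed model
#
# Marginal covariance of observations (individual i, day d):
#   Cov(Y_ij, Y_i'j') = K0[i,i'] + K5[i,i'] (d_j + d_j') + K3[i,i'] d_j d_j'
#                       + sigma_sq * I
# with K0 = s1 Gn + s2 I, K5 = s5 Gn + s6 I, K3 = s3 Gn + s4 I.
#
# For balanced designs (every individual observed on the same day grid) the
# model is fit on the eigenbasis of Gn: rotating individuals by U (Gn = U L U')
# block-diagonalizes V into T x T blocks  V_l = sigma_sq I_T + F D_l F'  with
# F = [1 d] and D_l the 2x2 matrix [[s1 l + s2, s5 l + s6], [s5 l + s6,
# s3 l + s4]].  Rank-2 Woodbury identities reduce every REML evaluation to 2x2
# arithmetic vectorized over eigenvalues, so evaluations cost O(n p^2) rather
# than O((nT)^3).  Unbalanced data fall back to a dense-covariance path.

theta_to_vc <- function(par) {
  s1 <- exp(par[1]); s2 <- exp(par[2]); s3 <- exp(par[3]); s4 <- exp(par[4])
  rg <- tanh(par[5]); re <- tanh(par[6]); ss <- exp(par[7])
  list(sigma1_sq = s1, sigma2_sq = s2, sigma3_sq = s3, sigma4_sq = s4,
       sigma5_sq = rg * sqrt(s1 * s3), sigma6_sq = re * sqrt(s2 * s4),
       sigma_sq = ss)
}

vc_to_theta <- function(vc) {
  clamp <- function(x) log(pmax(x, 1e-8))
  rg <- if (vc$sigma1_sq * vc$sigma3_sq > 0)
    vc$sigma5_sq / sqrt(vc$sigma1_sq * vc$sigma3_sq) else 0
  re <- if (vc$sigma2_sq * vc$sigma4_sq > 0)
    vc$sigma6_sq / sqrt(vc$sigma2_sq * vc$sigma4_sq) else 0
  c(clamp(vc$sigma1_sq), clamp(vc$sigma2_sq), clamp(vc$sigma3_sq),
    clamp(vc$sigma4_sq), atanh(pmin(pmax(rg, -0.99), 0.99)),
    atanh(pmin(pmax(re, -0.99), 0.99)), clamp(vc$sigma_sq))
}

build_pheno_design <- function(pheno, endpoint, covariates, center_day = FALSE) {
  stopifnot(all(c("mouse_id", "strain", "day") %in% names(pheno)),
            endpoint %in% names(pheno))
  pheno <- pheno[!is.na(pheno[[endpoint]]), , drop = FALSE] %>%
    arrange(.data$mouse_id, .data$day)
  covariates <- intersect(covariates, names(pheno))
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(pheno[[v]])) > 1, logical(1))]
  dayv <- if (center_day) pheno$day - mean(unique(pheno$day)) else pheno$day
  df <- pheno %>% mutate(.day = dayv)
  rhs <- paste(c(".day", covariates), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = df)
  # drop aliased columns so generalized least squares stays full rank
  qx <- qr(X)
  if (qx$rank < ncol(X)) X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  ind <- factor(pheno$mouse_id, levels = unique(pheno$mouse_id))
  strain_of_ind <- pheno$strain[!duplicated(pheno$mouse_id)]
  day_by_ind <- split(dayv, ind)
  balanced <- length(unique(vapply(day_by_ind, length, integer(1)))) == 1 &&
    all(vapply(day_by_ind, function(d) identical(d, day_by_ind[[1]]), logical(1)))
  list(y = pheno[[endpoint]], X = X, ind = as.integer(ind),
       n_ind = nlevels(ind), mouse_ids = levels(ind),
       strain_of_ind = strain_of_ind, day = dayv,
       days = day_by_ind[[1]], balanced = balanced, endpoint = endpoint)
}

# Precompute the rotated sufficient statistics for the spectral path.
spectral_system <- function(y, X, ind, n_ind, days, day_obs, Gn) {
  T_ <- length(days)
  eg <- eigen(Gn, symmetric = TRUE)
  U <- eg$vectors
  lam <- pmax(eg$values, 0)
  p <- ncol(X)
  # per-individual sums and day-weighted sums (rows of F' Xtilde per block)
  S1 <- rowsum(X, ind)                      # n_ind x p
  Sd <- rowsum(X * day_obs, ind)
  s1y <- rowsum_vec(y, ind)
  sdy <- rowsum_vec(y * day_obs, ind)
  list(U = U, lam = lam, T_ = T_, p = p, N = length(y), days = days,
       K = crossprod(cbind(1, days)),       # [[T, sum d], [sum d, sum d^2]]
       A1 = crossprod(U, S1), A2 = crossprod(U, Sd),
       b1 = as.numeric(crossprod(U, s1y)), b2 = as.numeric(crossprod(U, sdy)),
       XtX = crossprod(X), Xty = as.numeric(crossprod(X, y)),
       yty = sum(y^2))
}

rowsum_vec <- function(v, ind) as.numeric(rowsum(v, ind))

# 2x2 Woodbury pieces, vectorized over eigenvalues.
block_weights <- function(sys, vc) {
  lam <- sys$lam
  a <- vc$sigma1_sq * lam + vc$sigma2_sq
  b <- vc$sigma5_sq * lam + vc$sigma6_sq
  cc <- vc$sigma3_sq * lam + vc$sigma4_sq
  k11 <- sys$K[1, 1]; k12 <- sys$K[1, 2]; k22 <- sys$K[2, 2]
  s2 <- vc$sigma_sq
  m11 <- s2 + a * k11 + b * k12
  m12 <- a * k12 + b * k22
  m21 <- b * k11 + cc * k12
  m22 <- s2 + b * k12 + cc * k22
  det <- m11 * m22 - m12 * m21
  if (any(!is.finite(det)) || any(det <= 0) || !is.finite(s2) || s2 <= 0) {
    return(NULL)  # inadmissible or overflowed point
  }
  list(
    w11 = (m22 * a - m12 * b) / det,
    w12 = (m22 * b - m12 * cc) / det,
    w21 = (m11 * b - m21 * a) / det,
    w22 = (m11 * cc - m21 * b) / det,
    logdet = (sys$T_ - 2) * log(s2) + log(det),
    s2 = s2
  )
}

# X' V^-1 X, X' V^-1 y, y' V^-1 y and log|V| at the given components.
system_quadratics <- function(sys, vc) {
  w <- block_weights(sys, vc)
  if (is.null(w)) return(NULL)
  A1 <- sys$A1; A2 <- sys$A2
  corr_XX <- crossprod(A1, w$w11 * A1) + crossprod(A1, w$w12 * A2) +
    crossprod(A2, w$w21 * A1) + crossprod(A2, w$w22 * A2)
  corr_Xy <- crossprod(A1, w$w11 * sys$b1 + w$w12 * sys$b2) +
    crossprod(A2, w$w21 * sys$b1 + w$w22 * sys$b2)
  corr_yy <- sum(sys$b1 * (w$w11 * sys$b1 + w$w12 * sys$b2)) +
    sum(sys$b2 * (w$w21 * sys$b1 + w$w22 * sys$b2))
  list(XtVX = (sys$XtX - corr_XX) / w$s2,
       XtVy = as.numeric(sys$Xty - corr_Xy) / w$s2,
       ytVy = (sys$yty - corr_yy) / w$s2,
       logdetV = sum(w$logdet),
       weights = w)
}

reml_neg_loglik <- function(par, sys) {
  vc <- theta_to_vc(par)
  q <- system_quadratics(sys, vc)
  if (is.null(q)) return(1e10)
  ch <- tryCatch(chol(q$XtVX), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), q$XtVy))
  yPy <- q$ytVy - sum(q$XtVy * alpha)
  if (!is.finite(yPy) || yPy < 0) return(1e10)
  0.5 * (q$logdetV + 2 * sum(log(diag(ch))) + yPy +
           (sys$N - sys$p) * log(2 * pi))
}

# Dense path (unbalanced designs / reference implementation).
dense_V <- function(vc, Gn, ind, day) {
  Gobs <- Gn[ind, ind, drop = FALSE]
  Iobs <- diag(length(ind)) * 1.0
  Iind <- outer(ind, ind, "==") * 1.0
  K0 <- vc$sigma1_sq * Gobs + vc$sigma2_sq * Iind
  K5 <- vc$sigma5_sq * Gobs + vc$sigma6_sq * Iind
  K3 <- vc$sigma3_sq * Gobs + vc$sigma4_sq * Iind
  dd <- outer(day, day, "+")
  K0 + K5 * dd + K3 * tcrossprod(day) + vc$sigma_sq * Iobs
}

reml_neg_loglik_dense <- function(par, y, X, Gn, ind, day) {
  vc <- theta_to_vc(par)
  V <- dense_V(vc, Gn, ind, day)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtVX <- crossprod(X, Vi_X)
  XtVy <- as.numeric(crossprod(X, Vi_y))
  ch2 <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch2)) return(1e10)
  alpha <- backsolve(ch2, forwardsolve(t(ch2), XtVy))
  yPy <- sum(y * Vi_y) - sum(XtVy * alpha)
  0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(ch2))) + yPy +
           (length(y) - ncol(X)) * log(2 * pi))
}

default_start <- function(des) {
  # moment starts from per-individual ordinary least squares
  sp <- split(seq_along(des$y), des$ind)
  coefs <- vapply(sp, function(idx) {
    d <- des$day[idx]
    f <- stats::lm.fit(cbind(1, d), des$y[idx])
    c(f$coefficients, var(f$residuals))
  }, numeric(3))
  v_int <- max(var(coefs[1, ]), 1e-3)
  v_slo <- max(var(coefs[2, ]), 1e-4)
  v_res <- max(mean(coefs[3, ], na.rm = TRUE), 1e-3)
  vc <- list(sigma1_sq = v_int / 2, sigma2_sq = v_int / 2,
             sigma3_sq = v_slo / 2, sigma4_sq = v_slo / 2,
             sigma5_sq = 0, sigma6_sq = 0, sigma_sq = v_res)
  vc_to_theta(vc)
}

#' Fit the longitudinal kinship mixed model under the null (no SNP)
#'
#' Estimates the seven (co)variance parameters of the longitudinal model by
#' REML, with fixed effects (intercept, day, and the supplied covariates)
#' profiled out by generalized least squares. Balanced designs (every mouse
#' observed on the same day grid) are fit on the eigenbasis of the
#' individual-level kinship, which reduces each likelihood evaluation to 2x2
#' arithmetic per eigenvalue; unbalanced designs use a dense covariance.
#'
#' @param pheno Long-format tibble with `mouse_id`, `strain`, `day`, the
#'   endpoint (already normalized per day), and covariate columns.
#' @param kinship Strain-level [compute_kinship()] matrix.
#' @param endpoint Endpoint column to model.
#' @param covariates Covariate columns used as fixed effects (absent or
#'   constant columns are dropped automatically).
#' @param center_day If `TRUE`, center the day covariate before fitting.
#' @param start Optional start as a [variance_components()].
#' @param maxit Maximum optimizer iterations.
#' @param fixed_vc Optional [variance_components()]: skip REML and condition
#'   on these components (useful for diagnostics and single-marker contrasts
#'   at known components).
#'
#' @return An object of class `panel_lmm`: the fitted [variance_components()]
#'   (`$vc`), fixed effects (`$alpha`), REML log-likelihood (`$loglik`),
#'   convergence info, and the precomputed state reused by [wald_scan()].
#' @export
fit_null_model <- function(pheno, kinship, endpoint,
                           covariates = c("sex", "lever", "chamber", "cohort", "age"),
                           center_day = FALSE, start = NULL, maxit = 2000,
                           fixed_vc = NULL) {
  des <- build_pheno_design(pheno, endpoint, covariates, center_day)
  Gn <- expand_kinship(kinship, des$strain_of_ind)

  if (des$balanced) {
    sys <- spectral_system(des$y, des$X, des$ind, des$n_ind, des$days, des$day, Gn)
    obj <- function(p) reml_neg_loglik(p, sys)
  } else {
    sys <- NULL
    obj <- function(p) reml_neg_loglik_dense(p, des$y, des$X, Gn, des$ind, des$day)
  }
  if (is.null(fixed_vc)) {
    par0 <- if (is.null(start)) default_start(des) else vc_to_theta(start)
    opt <- optim(par0, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-10))
    # polish from the first solution (Nelder-Mead restarts help near boundaries)
    opt2 <- optim(opt$par, obj, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-12))
    if (opt2$value <= opt$value) opt <- opt2
    if (!is.finite(opt$value) || opt$value >= 1e10) {
      abort(paste0("REML optimization failed to reach an admissible point (last ",
                   "objective ", format(opt$value), ")"))
    }
    vc_hat <- do.call(variance_components,
                      c(theta_to_vc(opt$par), list(check = FALSE)))
  } else {
    check_vc(fixed_vc)
    opt <- list(value = obj(vc_to_theta(fixed_vc)), convergence = 0L)
    vc_hat <- fixed_vc
  }

  # fixed effects at the optimum
  if (des$balanced) {
    q <- system_quadratics(sys, vc_hat)
  } else {
    V <- dense_V(vc_hat, Gn, des$ind, des$day)
    ch <- chol(V)
    Vi_X <- backsolve(ch, forwardsolve(t(ch), des$X))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), des$y))
    q <- list(XtVX = crossprod(des$X, Vi_X),
              XtVy = as.numeric(crossprod(des$X, Vi_y)),
              ytVy = sum(des$y * Vi_y))
  }
  C <- solve(q$XtVX)
  alpha <- as.numeric(C %*% q$XtVy)
  names(alpha) <- colnames(des$X)
  vc_hat$alpha <- alpha
  vc_hat$convergence <- opt$convergence

  structure(list(vc = vc_hat, alpha = alpha, alpha_vcov = C,
                 loglik = -opt$value, convergence = opt$convergence,
                 endpoint = endpoint, design = des, Gn = Gn, sys = sys,
                 quad = q, kinship = kinship),
            class = "panel_lmm")
}

#' @export
print.panel_lmm <- function(x, ...) {
  cat("<panel_lmm> endpoint:", x$endpoint, "| REML logLik:",
      round(x$loglik, 3), "| convergence:", x$convergence, "\n")
  print(x$vc)
  invisible(x)
}

#' @describeIn fit_null_model Variance components and fixed effects as a tibble.
#' @param x A `panel_lmm` fit.
#' @param ... Unused.
#' @export
tidy.panel_lmm <- function(x, ...) {
  bind_rows(
    tidy(x$vc) %>% mutate(kind = "variance"),
    tibble(component = names(x$alpha), structure = NA_character_,
           term = names(x$alpha), estimate = unname(x$alpha),
           kind = "fixed")
  )
}

#' @describeIn fit_null_model One-row model summary.
#' @export
glance.panel_lmm <- function(x, ...) {
  tibble(logLik = x$loglik, convergence = x$convergence,
         n_obs = x$design$N %||% length(x$design$y),
         n_individuals = x$design$n_ind, balanced = x$design$balanced)
}
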
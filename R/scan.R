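# Per-marker Wald scan machinery.
#
# Variance components are estimated once under the null and held fixed across
# markers (the standard two-stage population-structure GWAS economy). For each
# marker the strain-level genotype is broadcast to observations and its effect
# estimated by generalized least squares; partitioned-regression identities on
# the rotated system make the per-marker cost a handful of vector operations.

impute_strain_calls <- function(genotypes, strains) {
  calls <- genotypes$calls[strains, , drop = FALSE]
  mu <- colMeans(calls, na.rm = TRUE)
  nai <- which(is.na(calls), arr.ind = TRUE)
  if (nrow(nai)) calls[nai] <- mu[nai[, 2]]
  calls
}

# Precompute everything marker-independent for scans against a fitted null.
scan_prep <- function(fit) {
  des <- fit$design
  strains <- sort(unique(des$strain_of_ind))
  C <- fit$alpha_vcov
  alpha <- fit$alpha
  if (!is.null(fit$sys)) {
    sys <- fit$sys
    w <- block_weights(sys, fit$vc)
    T_ <- sys$K[1, 1]; sd_ <- sys$K[1, 2]
    t1 <- T_ * w$w11 + sd_ * w$w21
    t2 <- T_ * w$w12 + sd_ * w$w22
    cg <- T_ - (T_^2 * w$w11 + T_ * sd_ * (w$w12 + w$w21) + sd_^2 * w$w22)
    RX <- (1 - t1) * sys$A1 - t2 * sys$A2
    ry <- (1 - t1) * sys$b1 - t2 * sys$b2
    # strain indicator, rotated: W = U' S  (n_ind x n_strains)
    S <- outer(des$strain_of_ind, strains, "==") * 1.0
    W <- crossprod(sys$U, S)
    list(dense = FALSE, strains = strains, s2 = w$s2, C = C, alpha = alpha,
         XtVy = fit$quad$XtVy, sys = sys, des = des, w = w,
         t1 = t1, t2 = t2, W = W,
         A1 = sys$A1, A2 = sys$A2,
         WR = crossprod(W, RX), wy = as.numeric(crossprod(W, ry)),
         M = crossprod(W, cg * W))
  } else {
    V <- dense_V(fit$vc, fit$Gn, des$ind, des$day)
    Vi <- solve(V)
    S <- outer(des$strain_of_ind, strains, "==") * 1.0
    Sobs <- S[des$ind, , drop = FALSE]          # obs x strains
    ViX <- Vi %*% des$X
    list(dense = TRUE, strains = strains, C = C, alpha = alpha,
         XtVy = as.numeric(crossprod(des$X, Vi %*% des$y)),
         V = V, Vi = Vi, Sobs = Sobs, des = des,
         WR = crossprod(Sobs, ViX),
         wy = as.numeric(crossprod(Sobs, Vi %*% des$y)),
         M = crossprod(Sobs, Vi %*% Sobs))
  }
}

# marker-side quantities that stay fixed when only the phenotype is resampled
scan_marker_side <- function(prep, Cs) {
  s2 <- if (prep$dense) 1 else prep$s2
  gVX <- crossprod(Cs, prep$WR) / s2
  gVg <- unname(colSums(Cs * (prep$M %*% Cs))) / s2
  denom <- unname(gVg - rowSums((gVX %*% prep$C) * gVX))
  ok <- is.finite(denom) & denom > 1e-10 * pmax(gVg, 1e-300) & gVg > 0
  list(gVX = gVX, denom = denom, ok = ok)
}

# rotate an observation vector (sorted by individual, then day) to the
# eigenbasis of Gn; returns a T x n_ind matrix
rotate_obs <- function(v, T_, U) matrix(v, nrow = T_) %*% U

# spectral square roots of the per-eigenvalue T x T covariance blocks
block_sqrts <- function(sys, vc) {
  lam <- sys$lam; T_ <- sys$T_
  F_ <- cbind(1, sys$days)
  n <- length(lam)
  sq <- array(0, c(T_, T_, n)); isq <- array(0, c(T_, T_, n))
  for (l in seq_len(n)) {
    D <- matrix(c(vc$sigma1_sq * lam[l] + vc$sigma2_sq,
                  vc$sigma5_sq * lam[l] + vc$sigma6_sq,
                  vc$sigma5_sq * lam[l] + vc$sigma6_sq,
                  vc$sigma3_sq * lam[l] + vc$sigma4_sq), 2, 2)
    Vl <- vc$sigma_sq * diag(T_) + F_ %*% D %*% t(F_)
    ev <- eigen(Vl, symmetric = TRUE)
    vals <- pmax(ev$values, 1e-12)
    sq[, , l] <- ev$vectors %*% (sqrt(vals) * t(ev$vectors))
    isq[, , l] <- ev$vectors %*% ((1 / sqrt(vals)) * t(ev$vectors))
  }
  list(sq = sq, isq = isq)
}

# apply an array of T x T matrices column-wise to a T x n matrix
apply_blocks <- function(A, Z) {
  T_ <- dim(A)[1]; n <- dim(A)[3]
  out <- matrix(0, T_, n)
  for (s in seq_len(T_)) {
    out <- out + matrix(A[, s, ], T_, n) * matrix(Z[s, ], T_, n, byrow = TRUE)
  }
  out
}

# Wald statistics for a strains x markers dosage matrix against prepared state.
scan_stats <- function(prep, Cs) {
  s2 <- if (prep$dense) 1 else prep$s2
  gVX <- crossprod(Cs, prep$WR) / s2                   # m x p
  gVy <- as.numeric(crossprod(Cs, prep$wy)) / s2
  gVg <- unname(colSums(Cs * (prep$M %*% Cs))) / s2
  denom <- unname(gVg - rowSums((gVX %*% prep$C) * gVX))
  num <- gVy - as.numeric(gVX %*% prep$alpha)
  ok <- is.finite(denom) & denom > 1e-10 * pmax(gVg, 1e-300) & gVg > 0
  denom_ok <- ifelse(ok, denom, NA_real_)
  beta <- num / denom_ok
  se <- 1 / sqrt(denom_ok)
  z <- beta / se
  tibble(beta = beta, se = se, statistic = z,
         p.value = 2 * pnorm(-abs(z)), flagged = !ok)
}

#' Genome-wide Wald scan under the fitted longitudinal null model
#'
#' With the variance components fixed from [fit_null_model()], estimates each
#' marker's fixed effect (strain genotype broadcast to its mice) by
#' generalized least squares and reports the Wald Z statistic and two-sided
#' normal p-value. Missing calls are mean-imputed per marker; markers
#' collinear with the covariates are flagged with missing p-values.
#'
#' @param fit A `panel_lmm` from [fit_null_model()].
#' @param genotypes A [genotype_matrix()] covering the fit's strains.
#' @return A tibble with one row per marker: `marker`, `chrom`, `pos_bp`,
#'   `beta`, `se`, `statistic` (Z), `p.value`, `flagged`, `endpoint`.
#' @export
wald_scan <- function(fit, genotypes) {
  stopifnot(inherits(fit, "panel_lmm"), inherits(genotypes, "genotype_matrix"))
  prep <- scan_prep(fit)
  Cs <- impute_strain_calls(genotypes, prep$strains)     # strains x markers
  stats <- scan_stats(prep, Cs)
  bind_cols(genotypes$map, stats) %>% mutate(endpoint = fit$endpoint)
}

#' Permutation-based genome-wide significance threshold
#'
#' Builds the null distribution of the scan's minimum p-value and returns its
#' `fwer` empirical quantile. Two resampling schemes are available:
#'
#' * `"mvn"` (default): whitened-residual permutation for kinship-structured
#'   samples — the null-model residuals `y - X alpha` are whitened by
#'   `V^(-1/2)` on the spectral blocks, permuted, re-colored by `V^(1/2)`, and
#'   each resampled phenotype is rescanned against the original genotypes.
#'   This preserves the longitudinal/covariate structure and the
#'   marker-kinship geometry, so the scan minima are exchangeable replicates
#'   of the observed one.
#' * `"strain_label"`: permutes the strain-to-genotype assignment, keeping the
#'   phenotypes fixed. Simpler, but anticonservative when the phenotype
#'   covariance is aligned with a kinship built from the scanned markers (the
#'   permuted markers lose that alignment), so it is not the default.
#'
#' @inheritParams wald_scan
#' @param B Number of permutations (warning below 100, error below 20).
#' @param fwer Target family-wise error rate.
#' @param seed Integer seed (threshold is deterministic given the seed).
#' @param scheme Resampling scheme, see Details.
#' @return A list with `threshold` (p-value scale), `B`, `fwer`, `scheme`, and
#'   the permutation minima `min_p`.
#' @export
permutation_threshold <- function(fit, genotypes, B = 1000, fwer = 0.05,
                                  seed = 1, scheme = c("mvn", "strain_label")) {
  scheme <- match.arg(scheme)
  if (B < 20) abort("B < 20 permutations cannot estimate a 5% threshold")
  if (B < 100) warn("B < 100 permutations gives an unstable threshold")
  prep <- scan_prep(fit)
  Cs <- impute_strain_calls(genotypes, prep$strains)     # strains x markers
  set.seed(seed)
  n_s <- length(prep$strains)

  if (scheme == "strain_label") {
    min_p <- vapply(seq_len(B), function(b) {
      perm <- sample.int(n_s)
      st <- scan_stats(prep, Cs[perm, , drop = FALSE])
      min(st$p.value, na.rm = TRUE)
    }, numeric(1))
  } else if (!prep$dense) {
    mk <- scan_marker_side(prep, Cs)
    sys <- prep$sys; des <- prep$des
    T_ <- sys$T_; U <- sys$U; days <- sys$days
    Xrot <- apply(des$X, 2, function(x) as.numeric(rotate_obs(x, T_, U)))
    mu_rot <- rotate_obs(as.numeric(des$X %*% prep$alpha), T_, U)
    r_rot <- rotate_obs(des$y - as.numeric(des$X %*% prep$alpha), T_, U)
    bs <- block_sqrts(sys, fit$vc)
    z <- apply_blocks(bs$isq, r_rot)           # whitened residuals, iid N(0,1)
    zvec <- as.numeric(z)
    w <- prep$w
    min_p <- vapply(seq_len(B), function(b) {
      zb <- matrix(sample(zvec), T_)
      yrot <- apply_blocks(bs$sq, zb) + mu_rot
      b1 <- colSums(yrot)
      b2 <- as.numeric(crossprod(days, yrot))
      Xty <- as.numeric(crossprod(Xrot, as.numeric(yrot)))
      corr_Xy <- crossprod(prep$A1, w$w11 * b1 + w$w12 * b2) +
        crossprod(prep$A2, w$w21 * b1 + w$w22 * b2)
      XtVy <- (Xty - as.numeric(corr_Xy)) / prep$s2
      ry <- (1 - prep$t1) * b1 - prep$t2 * b2
      gVy <- as.numeric(crossprod(Cs, crossprod(prep$W, ry))) / prep$s2
      num <- gVy - as.numeric(mk$gVX %*% (prep$C %*% XtVy))
      zs <- ifelse(mk$ok, num / sqrt(mk$denom), NA_real_)
      min(2 * pnorm(-abs(zs)), na.rm = TRUE)
    }, numeric(1))
  } else {
    mk <- scan_marker_side(prep, Cs)
    des <- prep$des
    mu <- as.numeric(des$X %*% prep$alpha)
    ch <- chol(prep$V)                          # V = t(ch) %*% ch
    z <- forwardsolve(t(ch), des$y - mu)
    min_p <- vapply(seq_len(B), function(b) {
      yb <- mu + as.numeric(t(ch) %*% sample(z))
      Viy <- prep$Vi %*% yb
      XtVy <- as.numeric(crossprod(des$X, Viy))
      gVy <- as.numeric(crossprod(Cs, crossprod(prep$Sobs, Viy)))
      num <- gVy - as.numeric(mk$gVX %*% (prep$C %*% XtVy))
      zs <- ifelse(mk$ok, num / sqrt(mk$denom), NA_real_)
      min(2 * pnorm(-abs(zs)), na.rm = TRUE)
    }, numeric(1))
  }
  list(threshold = unname(quantile(min_p, probs = fwer, type = 1)),
       B = B, fwer = fwer, scheme = scheme, min_p = min_p)
}

#' Cluster suprathreshold markers into loci
#'
#' Significant markers (p <= `threshold`) on the same chromosome are
#' single-linkage clustered: adjacent markers less than `merge_bp` apart join
#' the same locus. Each locus reports its span and peak marker (minimum p;
#' ties broken toward the lower position).
#'
#' @param results A [wald_scan()] tibble (needs `marker`, `chrom`, `pos_bp`,
#'   `p.value`; an `endpoint` column, if present, is clustered separately).
#' @param threshold Significance threshold on the p-value scale.
#' @param merge_bp Maximum gap (bp) merged into one locus (default 2 Mb).
#' @return A tibble with one row per locus: `endpoint`, `chrom`, `start_bp`,
#'   `end_bp`, `width_bp`, `peak_marker`, `peak_bp`, `peak_p`, `n_markers`.
#' @export
call_loci <- function(results, threshold, merge_bp = 2e6) {
  if (!"endpoint" %in% names(results)) results$endpoint <- NA_character_
  sig <- results %>%
    filter(!is.na(.data$p.value), .data$p.value <= threshold) %>%
    arrange(.data$endpoint, .data$chrom, .data$pos_bp)
  if (nrow(sig) == 0) {
    return(tibble(endpoint = character(), chrom = character(),
                  start_bp = double(), end_bp = double(), width_bp = double(),
                  peak_marker = character(), peak_bp = double(),
                  peak_p = double(), n_markers = integer()))
  }
  sig %>%
    group_by(.data$endpoint, .data$chrom) %>%
    mutate(cluster = cumsum(c(1, diff(.data$pos_bp) >= merge_bp))) %>%
    group_by(.data$endpoint, .data$chrom, .data$cluster) %>%
    summarise(
      start_bp = min(.data$pos_bp), end_bp = max(.data$pos_bp),
      width_bp = max(.data$pos_bp) - min(.data$pos_bp),
      peak_marker = .data$marker[order(.data$p.value, .data$pos_bp)][1],
      peak_bp = .data$pos_bp[order(.data$p.value, .data$pos_bp)][1],
      peak_p = min(.data$p.value), n_markers = n(), .groups = "drop"
    ) %>%
    select(-"cluster")
}

#' Collapse loci across endpoints into unique loci
#'
#' Clusters the peak positions of loci from all endpoints with the same
#' single-linkage rule used by [call_loci()], giving the cross-endpoint count
#' of distinct genomic regions.
#'
#' @param loci A [call_loci()] tibble (possibly row-bound across endpoints).
#' @param merge_bp Merge distance in bp.
#' @return A tibble with one row per unique locus: `chrom`, `start_bp`,
#'   `end_bp`, `n_loci`, `endpoints`.
#' @export
unique_loci <- function(loci, merge_bp = 2e6) {
  if (nrow(loci) == 0) {
    return(tibble(chrom = character(), start_bp = double(), end_bp = double(),
                  n_loci = integer(), endpoints = character()))
  }
  loci %>%
    arrange(.data$chrom, .data$peak_bp) %>%
    group_by(.data$chrom) %>%
    mutate(cluster = cumsum(c(1, diff(.data$peak_bp) >= merge_bp))) %>%
    group_by(.data$chrom, .data$cluster) %>%
    summarise(start_bp = min(.data$peak_bp), end_bp = max(.data$peak_bp),
              n_loci = n(),
              endpoints = paste(sort(unique(.data$endpoint)), collapse = ","),
              .groups = "drop") %>%
    select(-"cluster")
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`, the usual
#' median-based inflation of association statistics relative to the null
#' chi-square(1) distribution.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return Scalar lambda.
#' @export
inflation_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) abort("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) abort("p-values must lie in (0, 1]")
  median(qchisq(p_values, df = 1, lower.tail = FALSE)) / qchisq(0.5, 1)
}

#' Allelic effect of a single marker under the longitudinal null model
#'
#' Fixed-effect contrast of the normalized endpoint between allele groups,
#' using the same generalized-least-squares machinery as [wald_scan()] for one
#' marker.
#'
#' @param fit A `panel_lmm` null fit.
#' @param genotypes A [genotype_matrix()].
#' @param marker Marker id to test.
#' @return One-row tibble: `marker`, `beta`, `se`, `statistic`, `p.value`,
#'   allele group sizes `n0`, `n1`.
#' @export
allelic_effect <- function(fit, genotypes, marker) {
  stopifnot(marker %in% genotypes$map$marker)
  prep <- scan_prep(fit)
  g <- genotypes$calls[prep$strains, marker]
  n0 <- sum(g == 0, na.rm = TRUE); n1 <- sum(g == 1, na.rm = TRUE)
  if (n0 == 0 || n1 == 0) abort("marker is monomorphic among phenotyped strains")
  gi <- g; gi[is.na(gi)] <- mean(gi, na.rm = TRUE)
  st <- scan_stats(prep, matrix(gi, ncol = 1))
  tibble(marker = marker, beta = st$beta, se = st$se,
         statistic = st$statistic, p.value = st$p.value, n0 = n0, n1 = n1)
}

#' SNP-by-infusate interaction test across two cohorts
#'
#' Stacks two cohorts (e.g., saline- and cocaine-treated panels sharing the
#' strain set), fits each cohort's longitudinal null model, and tests the
#' SNP x infusate interaction by generalized least squares on the joint fixed
#' design (covariates, infusate indicator, SNP main effect, interaction) with
#' each cohort's covariance held at its null estimate.
#'
#' @param pheno_a,pheno_b Long-format phenotype tibbles for the two cohorts.
#' @param genotypes A [genotype_matrix()].
#' @param marker Marker id.
#' @param kinship Strain kinship matrix.
#' @param endpoint Endpoint column (must exist in both tables).
#' @param covariates Fixed-effect covariates.
#' @param labels Length-2 infusate labels for the cohorts.
#' @return One-row tibble with the interaction `beta`, `se`,
#'   `statistic` (Wald Z) and `p.value`, plus the SNP main effect.
#' @export
interaction_test <- function(pheno_a, pheno_b, genotypes, marker, kinship,
                             endpoint,
                             covariates = c("sex", "lever", "chamber", "cohort", "age"),
                             labels = c("A", "B")) {
  shared <- intersect(unique(pheno_a$strain), unique(pheno_b$strain))
  if (length(shared) == 0) abort("cohorts have disjoint strain panels")
  fits <- list(fit_null_model(pheno_a, kinship, endpoint, covariates),
               fit_null_model(pheno_b, kinship, endpoint, covariates))
  phenos <- list(pheno_a, pheno_b)

  g_strain <- genotypes$calls[, marker]
  g_strain[is.na(g_strain)] <- mean(g_strain, na.rm = TRUE)

  # joint fixed design: per-cohort rows of [covariate design | infusate | g | g:infusate]
  XtVX <- 0; XtVy <- 0
  if (!identical(colnames(fits[[1]]$design$X), colnames(fits[[2]]$design$X))) {
    abort("cohort fixed designs differ; covariate levels must match to share coefficients")
  }
  for (k in 1:2) {
    des <- fits[[k]]$design
    if (!des$balanced) abort("interaction_test requires balanced cohorts")
    inf <- if (k == 1) -0.5 else 0.5
    g <- g_strain[des$strain_of_ind][des$ind]
    Xk <- cbind(des$X, infusate = inf, g = g, g_inf = g * inf)
    sysk <- spectral_system(des$y, Xk, des$ind, des$n_ind, des$days, des$day,
                            fits[[k]]$Gn)
    qk <- system_quadratics(sysk, fits[[k]]$vc)
    XtVX <- XtVX + qk$XtVX
    XtVy <- XtVy + qk$XtVy
  }
  C <- solve(XtVX)
  alpha <- as.numeric(C %*% XtVy)
  names(alpha) <- colnames(C)
  i_int <- length(alpha); i_g <- length(alpha) - 1
  z <- alpha[i_int] / sqrt(C[i_int, i_int])
  tibble(marker = marker, endpoint = endpoint,
         beta_interaction = alpha[i_int], se_interaction = sqrt(C[i_int, i_int]),
         statistic = z, p.value = 2 * pnorm(-abs(z)),
         beta_snp = alpha[i_g], labels = paste(labels, collapse = " vs "))
}
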
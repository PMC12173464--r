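#' Record of planted effects in a synthetic panel
#'
#' Keeps track of what was planted by the generators so downstream stages can
#' be tested for recovery: behavioral SNP effects, cis molecular links
#' (gene/exon/site to marker), and trans hotspot links.
#'
#' @param behavior Tibble with columns `marker`, `endpoint`, `gamma`.
#' @param cis Tibble with columns `feature`, `trait_class`, `marker`, `effect`
#'   (log2 allelic fold change for expression; logit shift for psi/phi).
#' @param hotspot Tibble with columns `marker`, `feature`, `effect`.
#'
#' @return An object of class `truth_record`.
#' @export
truth_record <- function(behavior = NULL, cis = NULL, hotspot = NULL) {
  empty_b <- tibble(marker = character(), endpoint = character(), gamma = double())
  empty_c <- tibble(feature = character(), trait_class = character(),
                    marker = character(), effect = double())
  empty_h <- tibble(marker = character(), feature = character(), effect = double())
  structure(list(behavior = if (is.null(behavior)) empty_b else as_tibble(behavior),
                 cis = if (is.null(cis)) empty_c else as_tibble(cis),
                 hotspot = if (is.null(hotspot)) empty_h else as_tibble(hotspot)),
            class = "truth_record")
}

check_truth <- function(truth, genotypes, annotation = NULL) {
  mk <- genotypes$map$marker
  bad <- setdiff(c(truth$behavior$marker, truth$cis$marker, truth$hotspot$marker), mk)
  if (length(bad)) abort(paste("planted markers not in genotype map:",
                               paste(head(bad, 3), collapse = ", ")))
  if (!is.null(annotation)) {
    feats <- c(annotation$gene_id)
    bad <- setdiff(c(truth$hotspot$feature), feats)
    if (length(bad)) abort("planted hotspot features not in annotation")
  }
  invisible(truth)
}

# expand a strain-level kinship matrix to individuals by strain membership
expand_kinship <- function(G, strain_of_individual) {
  idx <- match(strain_of_individual, rownames(G))
  if (anyNA(idx)) abort("individuals reference strains absent from kinship")
  G[idx, idx, drop = FALSE]
}

#' Assemble the individual-level covariate table for a panel design
#'
#' Sex is balanced within strain; active-lever side and chamber are
#' counterbalanced across mice; cohorts are assigned in contiguous blocks; age
#' is a uniform integer 9..14 weeks. Deterministic under `seed`.
#'
#' @param design A [panel_design()].
#' @param strain_ids Strain identifiers (defaults to the design's layout).
#' @param seed Integer seed.
#' @return A tibble with one row per mouse.
#' @export
panel_covariates <- function(design, strain_ids = NULL, seed = 1) {
  set.seed(seed + 101)
  if (is.null(strain_ids)) {
    strain_ids <- c(sprintf("I%02d", seq_len(design$n_inbred)),
                    sprintf("RI%02d", seq_len(design$n_ri)))
  }
  mps <- design$mice_per_strain
  mice <- tidyr::expand_grid(strain = strain_ids, rep = seq_len(mps)) %>%
    mutate(mouse_id = sprintf("%s_m%d", .data$strain, .data$rep),
           sex = ifelse(.data$rep %% 2 == 0, "F", "M"))
  n <- nrow(mice)
  mice %>%
    mutate(
      lever = sample(rep_len(c("left", "right"), n)),
      chamber = sample(rep_len(sprintf("box%02d", 1:8), n)),
      cohort = sprintf("c%02d", as.integer(cut(seq_len(n), design$n_cohorts))),
      age = sample(9:14, n, replace = TRUE)
    ) %>%
    select(-"rep")
}

#' Default fixed-effect values for the longitudinal simulator
#'
#' @param intercept,age,sex,lever,chamber,day Scalar fixed effects (sex,
#'   lever, chamber enter as +/- 0.5 contrasts of their two levels).
#' @param cohort_sd Standard deviation of per-cohort fixed shifts.
#' @return A named list.
#' @export
fixed_effects <- function(intercept = 0, age = 0, sex = 0, lever = 0,
                          chamber = 0, day = 0, cohort_sd = 0) {
  list(intercept = intercept, age = age, sex = sex, lever = lever,
       chamber = chamber, day = day, cohort_sd = cohort_sd)
}

#' Simulate longitudinal behavioral phenotypes from the panel model
#'
#' Draws observations from the longitudinal kinship mixed model
#' \deqn{Y_{ij} = \alpha_0 + \sum_k \gamma_k SNP_k + \alpha_1 Age_i + \alpha_2
#' Sex_i + \alpha_3 Lever_i + \alpha_4 Chamber_i + \alpha_5 Cohort_i + \alpha_6
#' Day_j + \beta_{0i} + \beta_{1i} Day_j + \epsilon_{ij}} with
#' \eqn{(\beta_0, \beta_1)} jointly Gaussian across individuals: intercept
#' covariance `sigma1_sq * Gn + sigma2_sq * I`, slope covariance
#' `sigma3_sq * Gn + sigma4_sq * I`, cross-covariance
#' `sigma5_sq * Gn + sigma6_sq * I`, where `Gn` expands the strain kinship to
#' individuals, and i.i.d. residuals with variance `sigma_sq`.
#'
#' @param genotypes A [genotype_matrix()] (strain-level; used for planted SNP
#'   effects and to define strains).
#' @param design A [panel_design()].
#' @param vc A [variance_components()] object (admissibility is checked).
#' @param fixed A [fixed_effects()] list.
#' @param planted Optional [truth_record()] with behavioral `gamma` effects.
#' @param kinship Optional precomputed strain [compute_kinship()] matrix.
#' @param endpoints Endpoint column names to simulate (independent random
#'   effect draws per endpoint, same model).
#' @param center_day If `TRUE`, day enters the generating model centered.
#' @param seed Integer seed.
#'
#' @return A long-format tibble (one row per mouse x day) with covariates and
#'   one column per endpoint.
#' @export
simulate_longitudinal <- function(genotypes, design, vc, fixed = fixed_effects(),
                                  planted = NULL, kinship = NULL,
                                  endpoints = c("infusions", "active",
                                                "pct_active", "inactive"),
                                  center_day = FALSE, seed = 1) {
  check_vc(vc)
  if (!is.null(planted)) check_truth(planted, genotypes)
  if (is.null(kinship)) kinship <- compute_kinship(genotypes)
  set.seed(seed)
  cov_tbl <- panel_covariates(design, strain_ids = rownames(genotypes$calls),
                              seed = seed)
  n_ind <- nrow(cov_tbl)
  days <- seq_len(design$n_days)
  d <- if (center_day) days - mean(days) else days

  Gn <- expand_kinship(kinship, cov_tbl$strain)
  eg <- eigen(Gn, symmetric = TRUE)
  lam <- pmax(eg$values, 0)

  cohort_fx <- setNames(rnorm(design$n_cohorts, 0, fixed$cohort_sd),
                        sprintf("c%02d", seq_len(design$n_cohorts)))
  base <- fixed$intercept +
    fixed$age * cov_tbl$age +
    fixed$sex * ifelse(cov_tbl$sex == "F", 0.5, -0.5) +
    fixed$lever * ifelse(cov_tbl$lever == "right", 0.5, -0.5) +
    fixed$chamber * ifelse(cov_tbl$chamber %in% sprintf("box%02d", 1:4), 0.5, -0.5) +
    cohort_fx[cov_tbl$cohort]

  long <- tidyr::expand_grid(cov_tbl, day = days)
  for (ep in endpoints) {
    # joint draw of (beta0, beta1): rotate by eigenvectors of Gn, draw each
    # 2-vector from its 2x2 covariance, rotate back
    z <- vapply(lam, function(l) {
      S <- matrix(c(vc$sigma1_sq * l + vc$sigma2_sq,
                    vc$sigma5_sq * l + vc$sigma6_sq,
                    vc$sigma5_sq * l + vc$sigma6_sq,
                    vc$sigma3_sq * l + vc$sigma4_sq), 2, 2)
      ev <- eigen(S, symmetric = TRUE)
      if (min(ev$values) < -1e-8) {
        abort("implied random-effect covariance is not positive semi-definite")
      }
      A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
      as.numeric(A %*% rnorm(2))
    }, numeric(2))
    beta0 <- as.numeric(eg$vectors %*% z[1, ])
    beta1 <- as.numeric(eg$vectors %*% z[2, ])

    gsum <- rep(0, n_ind)
    if (!is.null(planted)) {
      pb <- planted$behavior %>% filter(.data$endpoint == ep)
      for (r in seq_len(nrow(pb))) {
        gcall <- genotypes$calls[, pb$marker[r]]
        gcall[is.na(gcall)] <- mean(gcall, na.rm = TRUE)
        gsum <- gsum + pb$gamma[r] * gcall[match(cov_tbl$strain, rownames(genotypes$calls))]
      }
    }
    i_of <- match(long$mouse_id, cov_tbl$mouse_id)
    dj <- d[long$day]
    long[[ep]] <- base[i_of] + gsum[i_of] + fixed$day * dj +
      beta0[i_of] + beta1[i_of] * dj +
      rnorm(nrow(long), 0, sqrt(vc$sigma_sq))
  }
  long
}

#' Closed-form marginal covariance of the longitudinal model
#'
#' Assembles the dense N x N covariance of the stacked observations (sorted by
#' individual, then day): \eqn{Cov(Y_{ij}, Y_{i'j'}) = K_0[i,i'] + K_5[i,i']
#' (d_j + d_{j'}) + K_3[i,i'] d_j d_{j'} + \sigma^2 \delta_{ii'} \delta_{jj'}}
#' with `K0 = sigma1_sq Gn + sigma2_sq I`, `K5 = sigma5_sq Gn + sigma6_sq I`,
#' `K3 = sigma3_sq Gn + sigma4_sq I`. Used as the slow reference for the
#' spectral REML path and available for moment checks.
#'
#' @param vc A [variance_components()].
#' @param Gn Individual-level kinship (strain kinship expanded to individuals).
#' @param days Numeric vector of day codes shared by all individuals.
#' @return A dense `(n_ind * length(days))` square matrix.
#' @export
marginal_covariance <- function(vc, Gn, days) {
  n <- nrow(Gn)
  T_ <- length(days)
  I_n <- diag(n)
  K0 <- vc$sigma1_sq * Gn + vc$sigma2_sq * I_n
  K5 <- vc$sigma5_sq * Gn + vc$sigma6_sq * I_n
  K3 <- vc$sigma3_sq * Gn + vc$sigma4_sq * I_n
  one <- rep(1, T_)
  V <- kronecker(K0, tcrossprod(one)) +
    kronecker(K5, tcrossprod(one, days) + tcrossprod(days, one)) +
    kronecker(K3, tcrossprod(days)) +
    vc$sigma_sq * diag(n * T_)
  V
}
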
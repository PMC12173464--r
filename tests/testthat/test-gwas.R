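test_that("kinship matrix has GRM structure", {
  # identical strains are as related to each other as to themselves
  calls <- rbind(a = c(0, 1, 0, 1, 1, 0), b = c(0, 1, 0, 1, 1, 0),
                 c = c(1, 0, 1, 0, 1, 1))
  map <- tibble::tibble(marker = paste0("m", 1:6), chrom = "chr1",
                        pos_bp = 1:6 * 1000)
  g <- genotype_matrix(calls, map)
  K <- compute_kinship(g)
  expect_equal(K["a", "b"], K["a", "a"])
  expect_equal(K["a", "b"], K["b", "b"])
  expect_true(isSymmetric(unclass(K)))

  # independent genotypes: off-diagonals shrink by the law of large numbers
  set.seed(1)
  calls2 <- matrix(rbinom(40 * 1000, 1, 0.5), 40,
                   dimnames = list(paste0("s", 1:40), NULL))
  map2 <- tibble::tibble(marker = paste0("m", 1:1000), chrom = "chr1",
                         pos_bp = seq_len(1000) * 100)
  K2 <- compute_kinship(genotype_matrix(calls2, map2))
  expect_lt(mean(abs(K2[upper.tri(K2)])), 0.1)
  expect_gte(min(eigen(K2, symmetric = TRUE)$values), -1e-8)

  mono <- genotype_matrix(matrix(1, 3, 2, dimnames = list(letters[1:3], NULL)),
                          tibble::tibble(marker = c("m1", "m2"),
                                         chrom = "chr1", pos_bp = c(1, 2)))
  expect_error(compute_kinship(mono), "polymorphic")
})

test_that("marker QC applies strict MAF and missingness boundaries", {
  set.seed(2)
  n <- 100
  calls <- cbind(
    maf04  = c(rep(1, 4), rep(0, 96)),          # MAF 0.04 -> dropped
    maf05  = c(rep(1, 5), rep(0, 95)),          # MAF 0.05 -> kept (boundary)
    even   = rep(c(0, 1), 50),                  # kept
    miss11 = c(rep(NA, 11), rep(c(0, 1), length.out = 89)),  # 11% -> dropped
    miss10 = c(rep(NA, 10), rep(c(0, 1), length.out = 90))   # 10% -> kept
  )
  rownames(calls) <- paste0("s", seq_len(n))
  g <- genotype_matrix(calls, tibble::tibble(
    marker = colnames(calls), chrom = "chr1", pos_bp = 1:5 * 1e6))
  qc <- snp_qc(g)
  expect_equal(sort(colnames(qc$genotypes$calls)), sort(c("maf05", "even", "miss10")))
  expect_equal(qc$report$reason[qc$report$marker == "maf04"], "maf")
  expect_equal(qc$report$reason[qc$report$marker == "miss11"], "missing")

  only_bad <- genotype_matrix(
    calls[, "maf04", drop = FALSE],
    tibble::tibble(marker = "maf04", chrom = "chr1", pos_bp = 1e6))
  expect_error(snp_qc(only_bad), "every marker")
})

test_that("marginal covariance equals brute-force random-effect algebra", {
  # 3 strains x 2 mice x 3 days toy, explicit Z-matrix construction as oracle
  d <- panel_design(n_inbred = 3, n_ri = 0, mice_per_strain = 2, n_days = 3,
                    n_markers = 30, missing_rate = 0)
  g <- generate_genotypes(d, seed = 3)
  K <- compute_kinship(g)
  vc <- variance_components(0.4, 0.3, 0.08, 0.06, 0.1, 0.05, sigma_sq = 0.7)
  strain_of_ind <- rep(rownames(g$calls), each = 2)
  Gn <- K[strain_of_ind, strain_of_ind]
  V <- marginal_covariance(vc, Gn, 1:3)
  V_oracle <- brute_force_covariance(vc, Gn, 1:3)
  expect_lt(max(abs(V - V_oracle)), 1e-10)
})

test_that("spectral REML equals the dense objective and is invariant to shifts", {
  d <- toy_design(n_inbred = 8, n_ri = 8, mice_per_strain = 2, n_days = 4,
                  n_markers = 60)
  g <- generate_genotypes(d, seed = 4)
  K <- compute_kinship(g)
  ph <- simulate_longitudinal(g, d, toy_vc(), kinship = K,
                              endpoints = "infusions", seed = 4)
  des <- panelscan:::build_pheno_design(
    ph, "infusions", c("sex", "lever", "chamber", "cohort", "age"))
  Gn <- panelscan:::expand_kinship(K, des$strain_of_ind)
  sys <- panelscan:::spectral_system(des$y, des$X, des$ind, des$n_ind,
                                     des$days, des$day, Gn)
  for (th in list(panelscan:::vc_to_theta(toy_vc()),
                  c(-1, -2, -3, -2, 0.3, -0.2, -0.5))) {
    expect_equal(panelscan:::reml_neg_loglik(th, sys),
                 panelscan:::reml_neg_loglik_dense(th, des$y, des$X, Gn,
                                                   des$ind, des$day),
                 tolerance = 1e-8)
  }

  # adding a constant to Y leaves the REML criterion unchanged at any theta
  # (the intercept absorbs it), so no variance component can move
  des2 <- panelscan:::build_pheno_design(
    ph %>% dplyr::mutate(infusions = infusions + 100), "infusions",
    c("sex", "lever", "chamber", "cohort", "age"))
  sys2 <- panelscan:::spectral_system(des2$y, des2$X, des2$ind, des2$n_ind,
                                      des2$days, des2$day, Gn)
  for (th in list(panelscan:::vc_to_theta(toy_vc()),
                  c(-1, -2, -3, -2, 0.3, -0.2, -0.5))) {
    expect_equal(panelscan:::reml_neg_loglik(th, sys2),
                 panelscan:::reml_neg_loglik(th, sys), tolerance = 1e-8)
  }
  fit <- fit_null_model(ph, K, "infusions")
  fit2 <- fit_null_model(ph %>% dplyr::mutate(infusions = infusions + 100),
                         K, "infusions", start = fit$vc)
  for (comp in c("sigma1_sq", "sigma2_sq", "sigma3_sq", "sigma4_sq",
                 "sigma5_sq", "sigma6_sq", "sigma_sq")) {
    expect_lt(abs(fit$vc[[comp]] - fit2$vc[[comp]]), 1e-4)
  }
  expect_equal(fit2$alpha["(Intercept)"] - fit$alpha["(Intercept)"], c("(Intercept)" = 100),
               tolerance = 1e-4)
})

test_that("REML log-likelihood matches lme4 when kinship is the identity", {
  d <- panel_design(n_inbred = 12, n_ri = 0, mice_per_strain = 3, n_days = 5,
                    n_markers = 60, missing_rate = 0)
  g <- generate_genotypes(d, seed = 5)
  I_K <- identity_kinship(g)
  vc <- variance_components(0, 0.4, 0, 0.05, 0, 0.05, sigma_sq = 0.6)
  ph <- simulate_longitudinal(g, d, vc, kinship = I_K,
                              endpoints = "infusions", seed = 6)
  lf <- lmerTest::lmer(
    infusions ~ day + sex + lever + chamber + cohort + age + (1 + day | mouse_id),
    data = ph, REML = TRUE)
  vcl <- lme4::VarCorr(lf)$mouse_id
  vc_hat <- variance_components(0, vcl[1, 1], 0, vcl[2, 2], 0, vcl[1, 2],
                                sigma(lf)^2, check = FALSE)
  fit <- fit_null_model(ph, I_K, "infusions", fixed_vc = vc_hat)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-4)
  # free optimization reaches at least the same optimum
  fit2 <- fit_null_model(ph, I_K, "infusions")
  expect_gte(fit2$loglik, as.numeric(logLik(lf)) - 1e-3)
})

test_that("null model recovers boundary (zero) components", {
  d <- toy_design(missing_rate = 0)
  g <- generate_genotypes(d, seed = 7)
  K <- compute_kinship(g)
  vc0 <- variance_components(0, 0, 0, 0, 0, 0, sigma_sq = 1)
  ph <- simulate_longitudinal(g, d, vc0, kinship = K,
                              endpoints = "infusions", seed = 7)
  fit <- fit_null_model(ph, K, "infusions")
  for (comp in c("sigma1_sq", "sigma2_sq", "sigma3_sq", "sigma4_sq")) {
    expect_lte(fit$vc[[comp]], 0.05)
  }
  expect_lt(abs(fit$vc$sigma_sq - 1), 0.1)
})

test_that("Wald scan equals direct dense generalized least squares", {
  d <- panel_design(n_inbred = 5, n_ri = 0, mice_per_strain = 2, n_days = 4,
                    n_markers = 25, missing_rate = 0, n_cohorts = 2)
  g <- generate_genotypes(d, seed = 8)
  K <- compute_kinship(g)
  ph <- simulate_longitudinal(g, d, toy_vc(), kinship = K,
                              endpoints = "infusions", seed = 8)
  fit <- fit_null_model(ph, K, "infusions", covariates = c("sex", "lever"))
  sc <- wald_scan(fit, g)

  # dense oracle with explicit inverses on <= 50 observations
  des <- fit$design
  expect_lte(length(des$y), 50)
  V <- marginal_covariance(fit$vc, fit$Gn, des$days)
  Vi <- solve(V)
  calls <- panelscan:::impute_strain_calls(g, sort(unique(des$strain_of_ind)))
  testable <- which(!sc$flagged)               # markers not collinear with X
  expect_gte(length(testable), 3)
  for (j in testable[c(1, floor(length(testable) / 2), length(testable))]) {
    gobs <- calls[des$strain_of_ind, j][des$ind]
    Xg <- cbind(des$X, snp = gobs)
    A <- solve(t(Xg) %*% Vi %*% Xg)
    bet <- A %*% t(Xg) %*% Vi %*% des$y
    expect_equal(sc$beta[j], unname(bet["snp", 1]), tolerance = 1e-8)
    expect_equal(sc$se[j], unname(sqrt(A["snp", "snp"])), tolerance = 1e-8)
  }
})

test_that("null scans are calibrated on low-LD markers", {
  d <- panel_design(n_inbred = 20, n_ri = 20, mice_per_strain = 2, n_days = 5,
                    n_markers = 500, chromosome_lengths = c(chr1 = 500e6),
                    ld_corr_bp = 1e3, missing_rate = 0, n_cohorts = 4)
  g <- generate_genotypes(d, seed = 9)
  g <- snp_qc(g)$genotypes
  K <- compute_kinship(g)
  frac <- vapply(1:2, function(s) {
    ph <- simulate_longitudinal(g, d, toy_vc(), kinship = K,
                                endpoints = "infusions", seed = 9 + s)
    fit <- fit_null_model(ph, K, "infusions")
    sc <- wald_scan(fit, g)
    mean(sc$p.value < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.05), 0.02)
})

test_that("a planted effect is found and destroyed by permutation", {
  # study-scale panel; planted markers carry ~20% of strain-level variance and
  # are required to be mostly orthogonal to the leading kinship eigenvectors
  # (effects confounded with population structure are absorbed by the model by
  # design, so they are not a test of marker-level power)
  d <- panel_design(n_inbred = 32, n_ri = 52, mice_per_strain = 6,
                    n_days = 10, n_markers = 100,
                    chromosome_lengths = c(chr1 = 100e6, chr2 = 80e6),
                    missing_rate = 0, n_cohorts = 12)
  g <- snp_qc(generate_genotypes(d, seed = 10))$genotypes
  K <- compute_kinship(g)
  maf <- colMeans(g$calls)
  eg <- eigen(K, symmetric = TRUE)
  U10 <- eg$vectors[, 1:10]
  Xc <- scale(g$calls, scale = FALSE)
  ortho <- vapply(seq_len(ncol(Xc)), function(j) {
    1 - sum((crossprod(U10, Xc[, j]))^2) / sum(Xc[, j]^2)
  }, numeric(1))
  cand <- colnames(g$calls)[abs(maf - 0.5) < 0.25 & ortho > 0.5]
  hits <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    mk <- sample(cand, 1)
    tr <- truth_record(behavior = tibble::tibble(
      marker = mk, endpoint = "infusions", gamma = 0.8))
    ph <- simulate_longitudinal(g, d, toy_vc(), planted = tr, kinship = K,
                                endpoints = "infusions", seed = 300 + s)
    fit <- fit_null_model(ph, K, "infusions")
    sc <- wald_scan(fit, g)
    top <- sc$marker[which.min(sc$p.value)]
    # recovered if the top marker tags the planted one (same chromosome, close)
    m1 <- g$map[g$map$marker == mk, ]; m2 <- g$map[g$map$marker == top, ]
    hits <- hits + (m1$chrom == m2$chrom && abs(m1$pos_bp - m2$pos_bp) < 2e6)
  }
  expect_gte(hits, 18)

  # permuting strain labels destroys the top signal
  set.seed(301)
  mk <- sample(names(which(abs(maf - 0.5) < 0.25)), 1)
  tr <- truth_record(behavior = tibble::tibble(
    marker = mk, endpoint = "infusions", gamma = 0.8))
  ph <- simulate_longitudinal(g, d, toy_vc(), planted = tr, kinship = K,
                              endpoints = "infusions", seed = 301)
  fit <- fit_null_model(ph, K, "infusions")
  prep <- panelscan:::scan_prep(fit)
  Cs <- panelscan:::impute_strain_calls(g, prep$strains)
  sc <- panelscan:::scan_stats(prep, Cs)
  top_idx <- which.min(sc$p.value)
  set.seed(11)
  drops <- vapply(1:50, function(b) {
    perm <- sample.int(nrow(Cs))
    scp <- panelscan:::scan_stats(prep, Cs[perm, , drop = FALSE])
    rank(scp$p.value)[top_idx] > 0.01 * nrow(scp)
  }, logical(1))
  expect_gte(mean(drops), 0.9)
})

test_that("permutation thresholds are stable across seeds and honest for one marker", {
  d <- toy_design(n_markers = 100)
  g <- generate_genotypes(d, seed = 12)
  g <- snp_qc(g)$genotypes
  K <- compute_kinship(g)
  ph <- simulate_longitudinal(g, d, toy_vc(), kinship = K,
                              endpoints = "infusions", seed = 12)
  fit <- fit_null_model(ph, K, "infusions")
  t1 <- permutation_threshold(fit, g, B = 500, seed = 1)$threshold
  t2 <- permutation_threshold(fit, g, B = 500, seed = 2)$threshold
  expect_lt(abs(t1 - t2) / max(t1, t2), 0.25)

  # single-marker genome: no multiplicity, threshold ~ fwer
  g1 <- genotype_matrix(g$calls[, 5, drop = FALSE], g$map[5, ])
  thr1 <- permutation_threshold(fit, g1, B = 500, seed = 3)$threshold
  expect_gt(thr1, 0.02)
  expect_lt(thr1, 0.09)

  expect_error(permutation_threshold(fit, g, B = 10), "B < 20")
  expect_warning(permutation_threshold(fit, g1, B = 50, seed = 1), "B < 100")
})

test_that("power to detect a planted effect is monotone in its size", {
  d <- toy_design(mice_per_strain = 4, n_markers = 60, missing_rate = 0)
  g <- generate_genotypes(d, seed = 13)
  g <- snp_qc(g)$genotypes
  K <- compute_kinship(g)
  maf <- colMeans(g$calls)
  mk <- names(which(abs(maf - 0.5) < 0.2))[1]
  mean_absz <- vapply(c(0.15, 0.45, 1.0), function(gam) {
    zs <- vapply(1:5, function(s) {
      tr <- truth_record(behavior = tibble::tibble(
        marker = mk, endpoint = "infusions", gamma = gam))
      ph <- simulate_longitudinal(g, d, toy_vc(), planted = tr, kinship = K,
                                  endpoints = "infusions", seed = 400 + s)
      fit <- fit_null_model(ph, K, "infusions")
      abs(wald_scan(fit, g)$statistic[g$map$marker == mk])
    }, numeric(1))
    mean(zs)
  }, numeric(1))
  expect_true(all(diff(mean_absz) > 0))
})

test_that("loci are merged by the 2 Mb single-linkage rule", {
  res <- tibble::tibble(
    marker = c("a", "b", "c", "d"),
    chrom = c("chr3", "chr3", "chr5", "chr5"),
    pos_bp = c(37799968, 38178200, 10e6, 14e6),
    p.value = c(6.6e-10, 3.2e-7, 1e-8, 1e-9),
    endpoint = "inactive")
  loci <- call_loci(res, threshold = 1e-5)
  # peaks 378,232 bp apart merge into one locus; 4 Mb apart stay separate
  expect_equal(nrow(loci), 3)
  chr3 <- loci[loci$chrom == "chr3", ]
  expect_equal(chr3$n_markers, 2L)
  expect_equal(chr3$peak_marker, "a")   # smaller p wins
  expect_equal(sum(loci$chrom == "chr5"), 2)

  # width computed from the span boundaries
  res2 <- tibble::tibble(marker = c("x", "y"), chrom = "chr11",
                         pos_bp = c(66206986, 68567223),
                         p.value = c(1e-9, 1e-8), endpoint = "infusions")
  loci2 <- call_loci(res2, threshold = 1e-5, merge_bp = 3e6)
  expect_equal(loci2$width_bp, 2360237)

  expect_equal(nrow(call_loci(res, threshold = 1e-20)), 0)

  # cross-endpoint unique loci use the same clustering on peaks
  both <- dplyr::bind_rows(loci, loci %>% dplyr::mutate(endpoint = "infusions"))
  uq <- unique_loci(both)
  expect_equal(nrow(uq), 3)
})

test_that("genomic inflation factor behaves like a chi-square median ratio", {
  set.seed(14)
  p <- runif(1e5)
  expect_lt(abs(inflation_lambda(p) - 1), 0.02)

  # scaling oracle: chi-square statistics inflated 1.5x
  x <- rchisq(2e5, 1) * 1.5
  p2 <- pchisq(x, 1, lower.tail = FALSE)
  expect_lt(abs(inflation_lambda(p2) - 1.5), 0.03)

  expect_equal(inflation_lambda(rep(0.5, 200)), 1)
  expect_error(inflation_lambda(c(0.5, 0)), "0, 1")
  expect_error(inflation_lambda(c(0.5, 1.2)), "0, 1")
})
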
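#' Default variance components of the synthetic study conditions
#'
#' The generating components used by the end-to-end pipeline: strain-genetic
#' intercept variance 0.3 (giving a strain-level intercept heritability near
#' 0.3, in line with the narrow-sense heritability reported for saline
#' self-administration in this panel design), individual intercept 0.2, small
#' genetic and individual slope variances, no intercept-slope covariance, and
#' residual variance 0.5.
#'
#' @return A [variance_components()].
#' @export
default_vc <- function() {
  variance_components(sigma1_sq = 0.3, sigma2_sq = 0.2,
                      sigma3_sq = 0.02, sigma4_sq = 0.02,
                      sigma5_sq = 0, sigma6_sq = 0, sigma_sq = 0.5)
}

#' Run the full synthetic-panel analysis pipeline
#'
#' Orchestrates simulate -> normalize -> longitudinal GWAS -> molecular QTL ->
#' integration on a synthetic panel: generates genotypes and longitudinal
#' phenotypes with a planted SNP effect, normalizes endpoints per day (Blom),
#' tests time courses, fits the kinship null model, runs the Wald scan with a
#' permutation family-wise threshold and calls loci; then simulates pooled
#' RNA-seq counts with planted cis effects and a trans hotspot, quantifies and
#' maps expression/splicing/editing QTLs, and computes hotspot and enrichment
#' summaries. All outputs are returned as tibbles; set `out_dir` to also write
#' the standard TSV files.
#'
#' @param design A [panel_design()].
#' @param vc Generating [variance_components()].
#' @param gamma Planted SNP effect on the first endpoint (strain-level units
#'   of the normalized endpoint).
#' @param day_effect Fixed day slope of the generating model.
#' @param endpoints Endpoints to analyze.
#' @param B Permutations for the genome-wide threshold.
#' @param molecular Also run the molecular layer?
#' @param n_genes Genes in the synthetic annotation.
#' @param detect_prob Editing detectability (ascertainment control).
#' @param hotspot_genes Trans genes perturbed by the planted hotspot.
#' @param out_dir Optional output directory for TSVs.
#' @param seed Integer seed controlling every stochastic stage.
#' @return A list of results (see the worked example in the README).
#' @export
run_panelscan <- function(design = panel_design(), vc = default_vc(),
                          gamma = 0.8, day_effect = 0.05,
                          endpoints = c("infusions", "inactive"),
                          B = 200, molecular = TRUE, n_genes = 200,
                          detect_prob = 0.5, hotspot_genes = 25,
                          out_dir = NULL, seed = 1) {
  genotypes <- generate_genotypes(design, seed = seed)
  qc <- snp_qc(genotypes)
  genotypes <- qc$genotypes
  kinship <- compute_kinship(genotypes)

  # plant the behavioral effect at a common marker mostly orthogonal to the
  # leading kinship eigenvectors: effects confounded with population structure
  # are absorbed by the mixed model and make a poor demonstration QTL
  eg <- eigen(kinship, symmetric = TRUE)
  U10 <- eg$vectors[, seq_len(min(10, ncol(eg$vectors)))]
  Xc <- scale(impute_strain_calls(genotypes, rownames(genotypes$calls)),
              scale = FALSE)
  ortho <- vapply(seq_len(ncol(Xc)), function(j) {
    1 - sum((crossprod(U10, Xc[, j]))^2) / sum(Xc[, j]^2)
  }, numeric(1))
  poly <- qc$report %>%
    filter(.data$kept, .data$maf >= 0.3) %>%
    filter(ortho[match(.data$marker, colnames(Xc))] >
             stats::quantile(ortho, 0.5))
  set.seed(seed + 1)
  truth_b <- truth_record(behavior = tibble(
    marker = sample(poly$marker, 1), endpoint = endpoints[1], gamma = gamma))

  pheno <- simulate_longitudinal(
    genotypes, design, vc, fixed = fixed_effects(day = day_effect, cohort_sd = 0.1),
    planted = truth_b, kinship = kinship, endpoints = endpoints, seed = seed)
  pheno_n <- normalize_endpoints(pheno, endpoints)
  timecourse <- fit_timecourses(pheno_n, endpoints)

  scans <- list(); loci <- list(); thresholds <- list(); fits <- list()
  for (ep in endpoints) {
    fit <- fit_null_model(pheno_n, kinship, ep)
    scan <- wald_scan(fit, genotypes)
    thr <- permutation_threshold(fit, genotypes, B = B, seed = seed + 17)
    fits[[ep]] <- fit
    scans[[ep]] <- scan
    thresholds[[ep]] <- thr$threshold
    loci[[ep]] <- call_loci(scan, thr$threshold)
  }
  scans <- list_rbind(scans)
  loci <- list_rbind(loci)
  uniq <- unique_loci(loci)
  lambda <- inflation_lambda(scans$p.value[!is.na(scans$p.value)])

  out <- list(genotypes = genotypes, kinship = kinship, qc = qc$report,
              truth_behavior = truth_b, pheno = pheno_n,
              timecourse = timecourse, fits = fits, scans = scans,
              thresholds = thresholds, loci = loci, unique_loci = uniq,
              lambda = lambda)

  if (molecular) {
    annotation <- generate_annotation(design, n_genes = n_genes, seed = seed)
    plan <- library_plan(rownames(genotypes$calls))
    truth_m <- plant_molecular_truth(genotypes, annotation,
                                     hotspot_genes = hotspot_genes, seed = seed)
    raw <- simulate_molecular(genotypes, annotation, truth_m, plan,
                              detect_prob = detect_prob, seed = seed + 3)
    expr <- expression_filter_normalize(raw$counts, raw$lengths, plan, annotation)
    psi <- compute_psi(raw$inclusion, raw$exclusion, raw$exon_info, plan)
    editing <- compute_editing(raw$edited, raw$total, raw$site_info, plan)
    qtl_e <- map_molecular_qtl(expr, genotypes, kinship)
    qtl_s <- map_molecular_qtl(psi, genotypes, kinship)
    qtl_ed <- map_molecular_qtl(editing, genotypes, kinship)
    hotspots <- hotspot_scan(qtl_e$qtls %>% filter(!.data$cis),
                             n_markers = qtl_e$n_markers)
    out <- c(out, list(annotation = annotation, truth_molecular = truth_m,
                       expression = expr, psi = psi, editing = editing,
                       ascertainment_rate = attr(editing, "ascertainment_rate"),
                       qtl_expression = qtl_e, qtl_splicing = qtl_s,
                       qtl_editing = qtl_ed, hotspots = hotspots))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_geno_tsv(genotypes, file.path(out_dir, "geno.tsv"),
                   file.path(out_dir, "map.tsv"))
    write_pheno_tsv(pheno_n, file.path(out_dir, "pheno.tsv"))
    ps_write_tsv(scans, file.path(out_dir, "scan.tsv"))
    ps_write_tsv(loci, file.path(out_dir, "loci.tsv"))
    ps_write_tsv(timecourse, file.path(out_dir, "timecourse.tsv"))
    if (molecular) {
      write_bed(out$annotation, file.path(out_dir, "genes.bed"))
      ps_write_tsv(out$qtl_expression$qtls, file.path(out_dir, "eqtl.tsv"))
      ps_write_tsv(out$hotspots, file.path(out_dir, "hotspots.tsv"))
    }
  }
  out
}

#' Enrichment of coincident cis QTLs between two trait classes
#'
#' Cross-classifies the features tested in both classes (the default
#' "universe") by: has a significant cis QTL in class A; and has a significant
#' cis QTL in class B whose peak is coincident (< `window` bp) with the class
#' A peak (features with a class B cis QTL but no class A QTL count in the
#' margin). The 2x2 table goes to [fisher_enrichment()].
#'
#' @param peaks_a,peaks_b `peaks` tibbles from [map_molecular_qtl()]; class B
#'   features are matched to class A features via `feature_map` when the ids
#'   differ (e.g. exon -> gene).
#' @param feature_map Optional tibble with columns `feature_b`, `feature`
#'   translating class B feature ids to class A ids.
#' @param window Coincidence window in bp.
#' @return One-row tibble from [fisher_enrichment()] plus `n_coincident`.
#' @export
coincidence_enrichment <- function(peaks_a, peaks_b, feature_map = NULL,
                                   window = 2e6) {
  b <- peaks_b
  if (!is.null(feature_map)) {
    b <- b %>%
      left_join(feature_map, by = c(feature = "feature_b")) %>%
      select(-"feature") %>%
      rename(feature = "feature.y")
  }
  joined <- peaks_a %>%
    select(feature = "feature", chrom_a = "chrom", pos_a = "pos_bp",
           cis_a = "cis", sig_a = "significant") %>%
    dplyr::inner_join(
      b %>% select(feature = "feature", chrom_b = "chrom", pos_b = "pos_bp",
                   cis_b = "cis", sig_b = "significant"),
      by = "feature")
  has_a <- joined$sig_a & joined$cis_a
  has_b <- joined$sig_b & joined$cis_b
  coin <- has_a & has_b &
    coincident(joined$chrom_a, joined$pos_a, joined$chrom_b, joined$pos_b, window)
  res <- fisher_enrichment(sum(has_a & coin), sum(has_a & !coin),
                           sum(!has_a & has_b), sum(!has_a & !has_b))
  res$n_coincident <- sum(coin)
  res
}
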
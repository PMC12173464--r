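#' Synthetic gene annotation for a panel design
#'
#' Places non-overlapping gene intervals uniformly along the design's
#' chromosomes (1-based inclusive coordinates).
#'
#' @param design A [panel_design()].
#' @param n_genes Number of genes.
#' @param length_range Gene length range in bp.
#' @param seed Integer seed.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
generate_annotation <- function(design, n_genes = 100,
                                length_range = c(5e3, 2e5), seed = 1) {
  set.seed(seed + 7)
  lens <- design$chromosome_lengths
  chrom <- sample(names(lens), n_genes, replace = TRUE, prob = lens / sum(lens))
  glen <- round(runif(n_genes, length_range[1], length_range[2]))
  start <- vapply(seq_len(n_genes), function(i) {
    sample.int(max(lens[[chrom[i]]] - glen[i], 1), 1)
  }, numeric(1))
  tibble(gene_id = sprintf("g%04d", seq_len(n_genes)), chrom = chrom,
         start = start, end = start + glen - 1,
         strand = sample(c("+", "-"), n_genes, replace = TRUE)) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(gene_id = sprintf("g%04d", row_number()))
}

#' Library layout for pooled RNA-seq of a strain panel
#'
#' One pooled library per strain x sex x region x infusate combination,
#' mirroring the two-libraries-per-strain pooled design; batches are assigned
#' cyclically over strains.
#'
#' @param strains Strain ids.
#' @param sexes,regions,infusates Factor levels crossed with strains.
#' @param n_batches Number of sequencing batches.
#' @return Tibble with `library_id`, `strain`, `sex`, `region`, `infusate`,
#'   `batch`.
#' @export
library_plan <- function(strains, sexes = c("F", "M"), regions = "NAc",
                         infusates = "saline", n_batches = 4) {
  plan <- tidyr::expand_grid(strain = strains, sex = sexes, region = regions,
                             infusate = infusates)
  plan %>%
    mutate(batch = sprintf("b%02d", (match(.data$strain, strains) - 1) %% n_batches + 1),
           library_id = sprintf("lib%03d", row_number()), .before = 1) %>%
    select("library_id", "strain", "sex", "region", "infusate", "batch")
}

#' Plant molecular-QTL truth into a panel
#'
#' Picks target genes and, for each, a polymorphic marker within `cis_window`
#' of the gene for cis expression/splicing/editing effects, plus (optionally)
#' one trans hotspot marker perturbing a set of genes on other chromosomes.
#'
#' @param genotypes A [genotype_matrix()].
#' @param annotation [generate_annotation()] tibble.
#' @param n_cis_expression,n_cis_splicing,n_cis_editing Number of planted cis
#'   effects per class.
#' @param expression_log2_afc Allelic log2 fold change for cis expression
#'   effects (log2(4) = an allelic fold change of 4).
#' @param splicing_shift,editing_shift Logit-scale allelic shifts.
#' @param hotspot_genes Number of trans genes perturbed by the hotspot marker
#'   (0 disables the hotspot).
#' @param hotspot_log2fc Hotspot allelic log2 fold change on its targets.
#' @param cis_window Maximum gene-marker distance for planted cis links.
#' @param seed Integer seed.
#' @return A [truth_record()].
#' @export
plant_molecular_truth <- function(genotypes, annotation,
                                  n_cis_expression = 5, n_cis_splicing = 3,
                                  n_cis_editing = 3,
                                  expression_log2_afc = log2(4),
                                  splicing_shift = 2, editing_shift = 2,
                                  hotspot_genes = 25, hotspot_log2fc = 3,
                                  cis_window = 2e6, seed = 1) {
  set.seed(seed + 13)
  map <- genotypes$map
  p <- colMeans(genotypes$calls, na.rm = TRUE)
  poly <- map$marker[pmin(p, 1 - p) >= 0.2]

  cis_marker_for <- function(gene) {
    cand <- map %>%
      filter(.data$marker %in% poly, .data$chrom == gene$chrom,
             pmax(gene$start - .data$pos_bp, .data$pos_bp - gene$end, 0) <= cis_window)
    if (nrow(cand) == 0) return(NA_character_)
    sample(cand$marker, 1)
  }
  pick_cis <- function(n, trait_class, effect) {
    picked <- tibble()
    genes <- annotation[sample.int(nrow(annotation)), ]
    for (i in seq_len(nrow(genes))) {
      if (nrow(picked) == n) break
      mk <- cis_marker_for(genes[i, ])
      if (!is.na(mk)) {
        picked <- bind_rows(picked, tibble(feature = genes$gene_id[i],
                                           trait_class = trait_class,
                                           marker = mk, effect = effect))
      }
    }
    if (nrow(picked) < n) abort("could not place all planted cis effects")
    picked
  }
  cis <- bind_rows(
    if (n_cis_expression > 0) pick_cis(n_cis_expression, "expression", expression_log2_afc),
    if (n_cis_splicing > 0) pick_cis(n_cis_splicing, "splicing", splicing_shift),
    if (n_cis_editing > 0) pick_cis(n_cis_editing, "editing", editing_shift)
  )
  if (nrow(cis) == 0) cis <- NULL
  hotspot <- NULL
  if (hotspot_genes > 0) {
    # restrict to marker chromosomes that leave enough genes in trans
    cisf <- if (is.null(cis)) character(0) else cis$feature
    trans_count <- vapply(unique(map$chrom), function(ch) {
      sum(annotation$chrom != ch & !annotation$gene_id %in% cisf)
    }, numeric(1))
    ok_chrom <- names(trans_count)[trans_count >= hotspot_genes]
    cand <- poly[map$chrom[match(poly, map$marker)] %in% ok_chrom]
    if (length(cand) == 0) abort("not enough trans genes for the hotspot")
    hs_marker <- sample(cand, 1)
    hs_chrom <- map$chrom[map$marker == hs_marker]
    # trans targets never overlap planted cis genes
    targets <- annotation %>%
      filter(.data$chrom != hs_chrom,
             !.data$gene_id %in% (if (is.null(cis)) character(0) else cis$feature))
    hotspot <- tibble(marker = hs_marker,
                      feature = sample(targets$gene_id, hotspot_genes),
                      effect = hotspot_log2fc)
  }
  truth_record(cis = cis, hotspot = hotspot)
}

#' Simulate count-level molecular traits for a strain panel
#'
#' Transcript counts are negative binomial around gene baselines with
#' strain-level noise and planted cis/hotspot effects on the log2 scale; exon
#' inclusion and editing counts are binomial around strain-level logits with
#' planted allelic shifts; editing sites additionally undergo per-library
#' detectability thinning (a library has data with probability
#' `detect_prob`), which controls the ascertainment rate.
#'
#' @param genotypes A [genotype_matrix()].
#' @param annotation [generate_annotation()] tibble; planted cis markers must
#'   lie within 2 Mb of their target gene.
#' @param planted A [truth_record()] from [plant_molecular_truth()].
#' @param plan A [library_plan()] tibble (strains must exist in `genotypes`).
#' @param base_log2_mean,base_log2_sd Baseline transcript abundance (log2).
#' @param strain_sd Strain-level biological noise (log2 for expression, logit
#'   for psi/phi).
#' @param nb_size Negative binomial size (inverse dispersion).
#' @param lib_size_sd Log-normal library size factor sd.
#' @param psi_mean_reads,editing_mean_reads Mean per-library read depth for
#'   exon and site counts.
#' @param detect_prob Probability an editing site has data in a library.
#' @param n_exon_genes,n_editing_sites How many genes get an exon feature and
#'   how many editing sites are placed.
#' @param seed Integer seed.
#' @return A list with `counts`, `lengths`, `inclusion`, `exclusion`,
#'   `exon_info`, `edited`, `total`, `site_info`, `plan`, `truth`.
#' @export
simulate_molecular <- function(genotypes, annotation, planted, plan,
                               base_log2_mean = 6, base_log2_sd = 1.5,
                               strain_sd = 0.25, nb_size = 8,
                               lib_size_sd = 0.1,
                               psi_mean_reads = 60, editing_mean_reads = 40,
                               detect_prob = 0.5,
                               n_exon_genes = 40, n_editing_sites = 40,
                               seed = 1) {
  if (!all(plan$strain %in% rownames(genotypes$calls))) {
    abort("library plan references strains absent from the genotypes")
  }
  check_truth(planted, genotypes, annotation)
  bad <- planted$cis %>%
    left_join(annotation, by = c(feature = "gene_id")) %>%
    left_join(genotypes$map, by = "marker") %>%
    filter(.data$chrom.x != .data$chrom.y |
             pmax(.data$start - .data$pos_bp, .data$pos_bp - .data$end, 0) > 2e6)
  if (nrow(bad) > 0) abort("planted cis markers must lie within 2 Mb of their gene")
  set.seed(seed)

  n_lib <- nrow(plan)
  n_gene <- nrow(annotation)
  strains <- rownames(genotypes$calls)
  dosage <- impute_strain_calls(genotypes, strains)
  d_lib <- function(marker) dosage[plan$strain, marker]

  # --- expression ---------------------------------------------------------
  lengths <- setNames(round(runif(n_gene, 500, 10000)), annotation$gene_id)
  base <- rnorm(n_gene, base_log2_mean, base_log2_sd)
  strain_fx <- matrix(rnorm(n_gene * length(strains), 0, strain_sd),
                      n_gene, length(strains), dimnames = list(annotation$gene_id, strains))
  log2mu <- matrix(base, n_gene, n_lib) + strain_fx[, plan$strain]
  cis_e <- planted$cis %>% filter(.data$trait_class == "expression")
  for (r in seq_len(nrow(cis_e))) {
    gi <- match(cis_e$feature[r], annotation$gene_id)
    log2mu[gi, ] <- log2mu[gi, ] + cis_e$effect[r] * d_lib(cis_e$marker[r])
  }
  for (r in seq_len(nrow(planted$hotspot))) {
    gi <- match(planted$hotspot$feature[r], annotation$gene_id)
    log2mu[gi, ] <- log2mu[gi, ] +
      planted$hotspot$effect[r] * d_lib(planted$hotspot$marker[r])
  }
  size_fac <- exp(rnorm(n_lib, 0, lib_size_sd))
  mu <- sweep(2^log2mu, 2, size_fac, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = nb_size), n_gene, n_lib,
                   dimnames = list(annotation$gene_id, plan$library_id))

  # --- splicing (one measured exon per selected gene) ---------------------
  exon_genes <- annotation[sample.int(n_gene, min(n_exon_genes, n_gene)), ]
  n_ex <- nrow(exon_genes)
  exon_info <- tibble(
    feature = paste0(exon_genes$gene_id, "_e1"),
    transcript = exon_genes$gene_id, chrom = exon_genes$chrom,
    start = exon_genes$start +
      round((exon_genes$end - exon_genes$start) * runif(n_ex, 0.1, 0.8)),
  ) %>% mutate(end = .data$start + 150)
  logit_base <- qnorm(runif(n_ex, 0.3, 0.7))  # near-central inclusion
  logit <- matrix(logit_base, n_ex, n_lib) +
    matrix(rnorm(n_ex * length(strains), 0, strain_sd), n_ex,
           length(strains))[, match(plan$strain, strains)]
  cis_s <- planted$cis %>% filter(.data$trait_class == "splicing")
  for (r in seq_len(nrow(cis_s))) {
    fi <- match(cis_s$feature[r], exon_info$transcript)
    if (is.na(fi)) { # make sure planted splicing genes carry an exon
      g <- annotation[match(cis_s$feature[r], annotation$gene_id), ]
      exon_info <- bind_rows(exon_info, tibble(
        feature = paste0(g$gene_id, "_e1"), transcript = g$gene_id,
        chrom = g$chrom, start = g$start + 1000, end = g$start + 1150))
      logit <- rbind(logit, rnorm(1))
      n_ex <- n_ex + 1
      fi <- n_ex
    }
    logit[fi, ] <- logit[fi, ] + cis_s$effect[r] * d_lib(cis_s$marker[r])
  }
  total_ex <- matrix(rpois(n_ex * n_lib, psi_mean_reads), n_ex, n_lib)
  inclusion <- matrix(rbinom(n_ex * n_lib, total_ex, stats::plogis(logit)),
                      n_ex, n_lib, dimnames = list(exon_info$feature, plan$library_id))
  exclusion <- total_ex - inclusion
  dimnames(exclusion) <- dimnames(inclusion)

  # --- editing ------------------------------------------------------------
  host <- annotation[sample.int(n_gene, n_editing_sites, replace = TRUE), ]
  site_info <- tibble(
    feature = sprintf("site%03d", seq_len(n_editing_sites)),
    chrom = host$chrom,
    start = host$start + round((host$end - host$start) * runif(n_editing_sites)),
    category = sample(c("5UTR", "3UTR", "CDS", "intron", "intergenic"),
                      n_editing_sites, replace = TRUE,
                      prob = c(0.1, 0.2, 0.2, 0.35, 0.15))
  ) %>% mutate(end = .data$start)
  phi_logit <- matrix(stats::qlogis(rbeta(n_editing_sites, 2, 6)),
                      n_editing_sites, n_lib) +
    matrix(rnorm(n_editing_sites * length(strains), 0, strain_sd),
           n_editing_sites, length(strains))[, match(plan$strain, strains)]
  cis_ed <- planted$cis %>% filter(.data$trait_class == "editing")
  for (r in seq_len(nrow(cis_ed))) {
    # attach the planted editing effect to a site inside the target gene
    g <- annotation[match(cis_ed$feature[r], annotation$gene_id), ]
    si <- which(site_info$chrom == g$chrom & site_info$start >= g$start &
                  site_info$start <= g$end)[1]
    if (is.na(si)) {
      site_info <- bind_rows(site_info, tibble(
        feature = sprintf("site%03d", nrow(site_info) + 1), chrom = g$chrom,
        start = g$start + 500, end = g$start + 500, category = "3UTR"))
      phi_logit <- rbind(phi_logit, stats::qlogis(rbeta(1, 2, 6)))
      si <- nrow(site_info)
    }
    phi_logit[si, ] <- phi_logit[si, ] + cis_ed$effect[r] * d_lib(cis_ed$marker[r])
  }
  n_site <- nrow(site_info)
  total_ed <- matrix(rpois(n_site * n_lib, editing_mean_reads), n_site, n_lib)
  detected <- matrix(rbinom(n_site * n_lib, 1, detect_prob), n_site, n_lib)
  total_ed <- total_ed * detected
  edited <- matrix(rbinom(n_site * n_lib, total_ed, stats::plogis(phi_logit)),
                   n_site, n_lib, dimnames = list(site_info$feature, plan$library_id))
  dimnames(total_ed) <- dimnames(edited)

  list(counts = counts, lengths = lengths,
       inclusion = inclusion, exclusion = exclusion, exon_info = exon_info,
       edited = edited, total = total_ed, site_info = site_info,
       plan = plan, truth = planted)
}
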
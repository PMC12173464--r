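#' Are two QTL peaks coincident?
#'
#' Two peaks are coincident when they lie on the same chromosome strictly less
#' than `window` bp apart (the "< 2 Mb" proximity criterion for shared
#' signal). Vectorized; symmetric and translation-invariant in positions.
#'
#' @param chrom_a,pos_a,chrom_b,pos_b Chromosomes and positions of the peaks.
#' @param window Window in bp (default 2 Mb, strict inequality).
#' @return Logical vector.
#' @examples
#' coincident("chr3", 37799968, "chr3", 38178200)  # TRUE (gap 378,232)
#' @export
coincident <- function(chrom_a, pos_a, chrom_b, pos_b, window = 2e6) {
  if (any(is.na(chrom_a)) || any(is.na(chrom_b))) abort("unknown chromosome")
  chrom_a == chrom_b & abs(pos_a - pos_b) < window
}

#' Trans-regulation hotspots under a Poisson null
#'
#' Counts the distinct trans-regulated genes per marker among significant
#' trans QTL records, computes an upper-tail Poisson p-value per marker with
#' rate `lambda = (total trans associations) / n_markers`, adjusts by
#' Benjamini-Hochberg over markers with at least one association, and flags
#' hotspots with `n_trans_genes >= min_genes` and `q < fdr`.
#'
#' @param trans_qtls Tibble of significant trans records with `marker` and
#'   `feature` columns (e.g. the trans rows of [map_molecular_qtl()]'s
#'   `qtls`).
#' @param n_markers Total number of markers scanned.
#' @param min_genes Minimum regulated genes for a hotspot (default 20).
#' @param fdr FDR threshold for the hotspot flag.
#' @return Tibble: `marker`, `n_trans_genes`, `p.value`, `q.value`, `hotspot`.
#' @export
hotspot_scan <- function(trans_qtls, n_markers, min_genes = 20, fdr = 0.05) {
  stopifnot(n_markers >= 1)
  counts <- trans_qtls %>%
    distinct(.data$marker, .data$feature) %>%
    dplyr::count(.data$marker, name = "n_trans_genes")
  lambda <- nrow(trans_qtls) / n_markers
  if (lambda == 0 && nrow(counts) > 0) abort("zero Poisson rate with nonzero counts")
  counts %>%
    mutate(p.value = ppois(.data$n_trans_genes - 1, lambda, lower.tail = FALSE),
           q.value = p.adjust(.data$p.value, method = "BH"),
           hotspot = .data$n_trans_genes >= min_genes & .data$q.value < fdr) %>%
    arrange(dplyr::desc(.data$n_trans_genes))
}

#' Fisher exact enrichment for a 2x2 table
#'
#' The odds ratio is the cross-product `(a d) / (b c)` (reported as `Inf` for
#' degenerate tables, with the Haldane-Anscombe corrected estimate, +0.5 to
#' every cell, alongside); the two-sided p-value comes from the exact
#' hypergeometric test.
#'
#' @param a,b,c,d Non-negative integer counts (`a` = both conditions, laid out
#'   row-wise), or pass a 2x2 matrix as `a`.
#' @return One-row tibble: `or`, `or_haldane`, `p.value`, and the counts.
#' @export
fisher_enrichment <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    tab <- a
  } else {
    tab <- matrix(c(a, c, b, d), 2, 2)
  }
  if (any(tab < 0) || any(tab != round(tab))) abort("counts must be non-negative integers")
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  th <- tab + 0.5
  tibble(or = or,
         or_haldane = (th[1, 1] * th[2, 2]) / (th[1, 2] * th[2, 1]),
         p.value = fisher.test(tab)$p.value,
         a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2])
}

#' Enrichment of editing sites in mature mRNA among coincident QTLs
#'
#' Tests whether editing sites whose editing QTL coincides with an expression
#' QTL sit preferentially in mature mRNA (5'UTR, 3'UTR, CDS) rather than
#' intronic/intergenic sequence: builds the 2x2 table (mature vs not) x
#' (coincident vs not) and applies [fisher_enrichment()].
#'
#' @param sites Tibble with `category` (5UTR/3UTR/CDS/intron/intergenic,
#'   prime marks optional) and logical `coincident` columns.
#' @return One-row tibble as from [fisher_enrichment()].
#' @export
editing_region_enrichment <- function(sites) {
  stopifnot(all(c("category", "coincident") %in% names(sites)))
  if (nrow(sites) == 0) abort("no sites supplied")
  cat_norm <- gsub("[^0-9A-Za-z]", "", sites$category)
  known <- c("5UTR", "3UTR", "CDS", "intron", "intergenic")
  if (!all(cat_norm %in% known)) abort("unknown site category")
  mature <- cat_norm %in% c("5UTR", "3UTR", "CDS")
  fisher_enrichment(sum(mature & sites$coincident),
                    sum(!mature & sites$coincident),
                    sum(mature & !sites$coincident),
                    sum(!mature & !sites$coincident))
}

#' Linkage disequilibrium between two markers in an inbred panel
#'
#' Treats strain calls as haplotypes (inbred strains are effectively haploid),
#' estimates joint haplotype frequencies, and returns `D`, Lewontin's `D'`
#' (with `Dmax = min(pA qB, qA pB)` for `D > 0`, mirrored for `D < 0`),
#' `r^2 = D^2 / (pA qA pB qB)`, and the chi-square p-value from `n r^2` on 1
#' degree of freedom.
#'
#' @param geno_a,geno_b Strain genotype vectors in `{0, 1, NA}` (heterozygous
#'   0.5 calls are excluded pairwise).
#' @return One-row tibble: `d`, `d_prime`, `r2`, `n`, `statistic`, `p.value`.
#' @export
ld_stats <- function(geno_a, geno_b) {
  ok <- !is.na(geno_a) & !is.na(geno_b) & geno_a %in% c(0, 1) & geno_b %in% c(0, 1)
  a <- geno_a[ok]; b <- geno_b[ok]
  n <- length(a)
  if (n < 4) abort("ld_stats needs >= 4 strains with complete haploid calls")
  pa <- mean(a); pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) abort("monomorphic marker")
  p11 <- mean(a == 1 & b == 1)
  D <- p11 - pa * pb
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb) else min(pa * pb, (1 - pa) * (1 - pb))
  d_prime <- if (D == 0) 0 else abs(D) / dmax
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  stat <- n * r2
  tibble(d = D, d_prime = d_prime, r2 = r2, n = n, statistic = stat,
         p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
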
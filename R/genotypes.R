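#' Construct a genotype matrix object
#'
#' Genotypes are stored as a strains x markers matrix of homozygous allele
#' dosages in `{0, 1, NA}` (inbred animals carry two copies of the same
#' allele, so the dosage divided by two is 0 or 1; heterozygous calls, rare in
#' real panel data, may be supplied as 0.5), together with a marker map.
#'
#' @param calls Numeric matrix, strains in rows (rownames = strain ids),
#'   markers in columns (colnames = marker ids). Values in `{0, 0.5, 1, NA}`.
#' @param map Data frame with columns `marker`, `chrom`, `pos_bp` (1-based),
#'   one row per column of `calls`, positions strictly increasing within
#'   chromosome.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, map) {
  map <- as_tibble(map)
  stopifnot(is.matrix(calls),
            all(c("marker", "chrom", "pos_bp") %in% names(map)),
            nrow(map) == ncol(calls))
  if (is.null(rownames(calls)) || anyDuplicated(rownames(calls))) {
    abort("calls must have unique strain rownames")
  }
  bad <- !(calls %in% c(0, 0.5, 1) | is.na(calls))
  if (any(bad)) abort("genotype calls must be 0, 0.5, 1 or NA")
  incr <- map %>%
    group_by(.data$chrom) %>%
    summarise(ok = all(diff(.data$pos_bp) > 0) || n() == 1)
  if (!all(incr$ok)) abort("marker positions must be strictly increasing within chromosome")
  colnames(calls) <- map$marker
  structure(list(calls = calls, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$calls), " strains x ", ncol(x$calls),
      " markers on ", length(unique(x$map$chrom)), " chromosomes; ",
      round(100 * mean(is.na(x$calls)), 2), "% missing\n", sep = "")
  invisible(x)
}

# stationary two-state haplotype process: allele correlation between markers
# d bp apart is exp(-d / ld_corr_bp)
sim_founder_chromosome <- function(pos, ld_corr_bp) {
  m <- length(pos)
  h <- integer(m)
  h[1] <- rbinom(1, 1, 0.5)
  if (m > 1) {
    p_switch <- 0.5 * (1 - exp(-diff(pos) / ld_corr_bp))
    flips <- rbinom(m - 1, 1, p_switch)
    h <- (h[1] + c(0L, cumsum(flips))) %% 2L
  }
  h
}

#' Simulate panel genotypes
#'
#' Inbred strains receive independent founder haplotypes generated by a
#' stationary block process along each chromosome (allele correlation decays
#' exponentially with distance, producing realistic linkage disequilibrium).
#' RI strains are two-founder mosaics: a Poisson number of recombination
#' breakpoints per chromosome splits it into long identical-by-descent blocks
#' copied alternately from two distinct inbred founders. Missing calls are
#' injected completely at random at `design$missing_rate`.
#'
#' @param design A [panel_design()].
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A [genotype_matrix()] with strains named `I01..` (inbred) and
#'   `RI01..` (recombinant inbred).
#' @examples
#' g <- generate_genotypes(panel_design(n_inbred = 4, n_ri = 4, n_markers = 50), seed = 1)
#' dim(g$calls)
#' @export
generate_genotypes <- function(design, seed = 1) {
  stopifnot(inherits(design, "panel_design"))
  if (design$n_ri > 0 && design$n_inbred < 2) {
    abort("cannot build RI mosaics without at least 2 inbred founders")
  }
  set.seed(seed)
  lens <- design$chromosome_lengths
  n_per <- pmax(1, round(design$n_markers * lens / sum(lens)))
  names(n_per) <- names(lens)
  # adjust rounding so totals match
  while (sum(n_per) != design$n_markers) {
    i <- which.max(n_per)
    n_per[i] <- n_per[i] + sign(design$n_markers - sum(n_per))
  }
  map <- imap(as.list(n_per), function(m, chr) {
    tibble(chrom = chr, pos_bp = sort(sample.int(lens[[chr]], m)))
  }) %>% list_rbind()
  map <- map %>% mutate(marker = sprintf("m%05d", row_number()), .before = 1)

  strain_ids <- c(sprintf("I%02d", seq_len(design$n_inbred)),
                  sprintf("RI%02d", seq_len(design$n_ri)))
  calls <- matrix(NA_real_, design$n_strains, design$n_markers,
                  dimnames = list(strain_ids, map$marker))
  chrom_idx <- split(seq_len(nrow(map)), map$chrom)

  for (chr in names(chrom_idx)) {
    idx <- chrom_idx[[chr]]
    pos <- map$pos_bp[idx]
    founders <- matrix(0L, design$n_inbred, length(idx))
    for (s in seq_len(design$n_inbred)) {
      founders[s, ] <- sim_founder_chromosome(pos, design$ld_corr_bp)
    }
    calls[seq_len(design$n_inbred), idx] <- founders
    if (design$n_ri > 0) {
      for (s in seq_len(design$n_ri)) {
        f <- sample.int(design$n_inbred, 2)
        nb <- rpois(1, design$mean_breakpoints)
        cuts <- sort(runif(nb, 0, lens[[chr]]))
        segment <- findInterval(pos, cuts)  # 0..nb
        which_f <- f[(segment + rbinom(1, 1, 0.5)) %% 2 + 1]
        calls[design$n_inbred + s, idx] <-
          founders[cbind(which_f, seq_along(idx))]
      }
    }
  }
  if (design$missing_rate > 0) {
    miss <- runif(length(calls)) < design$missing_rate
    calls[miss] <- NA_real_
  }
  genotype_matrix(calls, map)
}

#' Marker quality control
#'
#' Removes markers with minor allele frequency below `maf_min` or missing-call
#' fraction above `miss_max`. Both comparisons are strict, so markers exactly
#' at a boundary are retained (MAF = 0.05 kept, missingness = 0.10 kept).
#'
#' @param genotypes A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param miss_max Maximum missing fraction (default 0.10).
#'
#' @return A list with `genotypes` (filtered [genotype_matrix()]) and `report`,
#'   a tibble with per-marker `maf`, `missing`, `kept` and the reason dropped.
#' @export
snp_qc <- function(genotypes, maf_min = 0.05, miss_max = 0.10) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  calls <- genotypes$calls
  p <- colMeans(calls, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(p)] <- 0
  missing <- colMeans(is.na(calls))
  kept <- maf >= maf_min & missing <= miss_max
  report <- tibble(
    marker = colnames(calls), maf = unname(maf), missing = unname(missing),
    kept = unname(kept),
    reason = dplyr::case_when(
      maf < maf_min & missing > miss_max ~ "maf+missing",
      maf < maf_min ~ "maf",
      missing > miss_max ~ "missing",
      TRUE ~ NA_character_
    )
  )
  if (!any(kept)) abort("snp_qc removed every marker")
  out <- genotype_matrix(calls[, kept, drop = FALSE],
                         genotypes$map[kept, , drop = FALSE])
  list(genotypes = out, report = report)
}

#' Genetic relatedness (kinship) matrix from genotypes
#'
#' Computes the standardized-genotype GRM `G = X_std %*% t(X_std) / m`, where
#' each marker column is mean-imputed for missing calls, centered, and scaled
#' to unit variance. Monomorphic markers carry no information and are dropped.
#' The construction guarantees symmetry and positive semi-definiteness.
#'
#' @param genotypes A [genotype_matrix()].
#' @param exclude_chrom Optional chromosome name(s) to leave out
#'   (leave-one-chromosome-out kinship).
#'
#' @return A strain x strain numeric matrix of class `c("kinship_matrix", "matrix")`.
#' @export
compute_kinship <- function(genotypes, exclude_chrom = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  keep <- !(genotypes$map$chrom %in% exclude_chrom)
  calls <- genotypes$calls[, keep, drop = FALSE]
  if (nrow(calls) < 2) abort("kinship needs at least 2 strains")
  X <- apply(calls, 2, function(x) {
    mu <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- mu
    s <- sd(x)
    if (is.na(s) || s == 0) return(rep(NA_real_, length(x)))
    (x - mu) / s
  })
  X <- X[, colSums(is.na(X)) == 0, drop = FALSE]
  if (ncol(X) == 0) abort("no polymorphic markers available for kinship")
  G <- tcrossprod(X) / ncol(X)
  dimnames(G) <- list(rownames(calls), rownames(calls))
  class(G) <- c("kinship_matrix", "matrix")
  G
}
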
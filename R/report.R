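#' QQ and Manhattan plotting tables with inflation factor
#'
#' Builds the observed-vs-expected -log10(p) table (expected quantiles
#' `(i - 0.5) / n`), the cumulative-genome-coordinate table for Manhattan
#' plots, and attaches the genomic inflation factor [inflation_lambda()].
#'
#' @param results Scan tibble with `p.value` and, for the Manhattan table,
#'   `chrom` and `pos_bp`.
#' @return A list: `qq` (tibble `expected`, `observed` on the -log10 scale),
#'   `manhattan` (tibble with `cum_bp` cumulative coordinates), `lambda`.
#' @export
qq_manhattan_tables <- function(results) {
  p <- results$p.value[!is.na(results$p.value)]
  if (length(p) == 0) abort("no p-values to plot")
  lambda <- inflation_lambda(p)
  n <- length(p)
  qq <- tibble(expected = -log10((seq_len(n) - 0.5) / n),
               observed = -log10(sort(p)))
  manhattan <- NULL
  if (all(c("chrom", "pos_bp") %in% names(results))) {
    offsets <- results %>%
      group_by(.data$chrom) %>%
      summarise(len = max(.data$pos_bp), .groups = "drop") %>%
      mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
    manhattan <- results %>%
      left_join(offsets %>% select("chrom", "offset"), by = "chrom") %>%
      mutate(cum_bp = .data$pos_bp + .data$offset,
             neglog10p = -log10(.data$p.value))
  }
  list(qq = qq, manhattan = manhattan, lambda = lambda)
}

#' Genes near each locus peak
#'
#' For every called locus, lists annotated genes within `window_bp` of the
#' peak marker, with signed distances: 0 if the peak falls inside the gene,
#' negative if the gene lies below (centromeric to) the peak, positive above;
#' magnitude is the gap between the peak and the nearest gene edge. Genes sort
#' by absolute distance, ties broken by id.
#'
#' @param loci A [call_loci()] tibble.
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param window_bp Search window around each peak.
#' @return Tibble: locus columns plus `gene_id`, `distance_bp`.
#' @export
locus_report <- function(loci, annotation, window_bp = 2e6) {
  if (nrow(loci) == 0) {
    return(tibble(endpoint = character(), chrom = character(),
                  peak_marker = character(), peak_bp = double(),
                  peak_p = double(), gene_id = character(),
                  distance_bp = double()))
  }
  map(seq_len(nrow(loci)), function(i) {
    loc <- loci[i, ]
    genes <- annotation %>% filter(.data$chrom == loc$chrom)
    signed <- dplyr::case_when(
      loc$peak_bp >= genes$start & loc$peak_bp <= genes$end ~ 0,
      genes$end < loc$peak_bp ~ -(loc$peak_bp - genes$end),
      TRUE ~ genes$start - loc$peak_bp
    )
    keep <- abs(signed) <= window_bp
    if (!any(keep)) return(NULL)
    tibble(endpoint = loc$endpoint, chrom = loc$chrom,
           peak_marker = loc$peak_marker, peak_bp = loc$peak_bp,
           peak_p = loc$peak_p,
           gene_id = genes$gene_id[keep], distance_bp = signed[keep]) %>%
      arrange(abs(.data$distance_bp), .data$gene_id)
  }) %>% list_rbind()
}
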
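# Plain-text table I/O. Dialect everywhere: UTF-8, tab-separated, "NA" for
# missing, no quoting. Internal coordinates are 1-based inclusive; BED is the
# only 0-based half-open surface and is converted at this boundary.

ps_write_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", quote = "none")
  invisible(path)
}

ps_read_tsv <- function(path, ...) {
  readr::read_tsv(path, na = "NA", show_col_types = FALSE, progress = FALSE, ...)
}

#' Write / read panel genotypes as TSV
#'
#' The calls file is a strain x marker table (first column `strain`); the map
#' file has columns `marker`, `chrom`, `pos_bp`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param calls_path,map_path Output file paths.
#' @return `read_geno_tsv()` returns a [genotype_matrix()];
#'   `write_geno_tsv()` returns the paths invisibly.
#' @export
write_geno_tsv <- function(genotypes, calls_path, map_path) {
  df <- as_tibble(genotypes$calls, rownames = "strain")
  ps_write_tsv(df, calls_path)
  ps_write_tsv(genotypes$map, map_path)
  invisible(c(calls_path, map_path))
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(calls_path, map_path) {
  df <- ps_read_tsv(calls_path)
  map <- ps_read_tsv(map_path)
  calls <- as.matrix(df[, -1])
  rownames(calls) <- df$strain
  genotype_matrix(calls, map)
}

#' Write / read long-format phenotype tables
#'
#' @param pheno Long-format tibble (`mouse_id`, `strain`, `sex`, `day`,
#'   covariates, endpoint columns).
#' @param path File path.
#' @return `read_pheno_tsv()` returns a tibble.
#' @export
write_pheno_tsv <- function(pheno, path) ps_write_tsv(pheno, path)

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) ps_read_tsv(path)

#' Write / read a numeric feature x library matrix as TSV
#'
#' First column `feature`, remaining columns one per library.
#'
#' @param mat Numeric matrix with dimnames.
#' @param path File path.
#' @return `read_matrix_tsv()` returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  ps_write_tsv(as_tibble(mat, rownames = "feature"), path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- ps_read_tsv(path)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$feature
  m
}

#' Read gene annotation from BED (0-based half-open)
#'
#' Accepts BED3+ (chrom, start, end, optional name, score, strand), converting
#' to the package's 1-based inclusive convention: `start = bed_start + 1`,
#' `end = bed_end`. Malformed or empty (end <= start) intervals raise an error
#' naming the offending line.
#'
#' @param path BED file path.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- map(seq_along(parts), function(i) {
    f <- parts[[i]]
    if (length(f) < 3) abort(paste0("BED line ", i, ": fewer than 3 fields"))
    s0 <- suppressWarnings(as.numeric(f[2])); e0 <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s0) || is.na(e0)) abort(paste0("BED line ", i, ": non-numeric coordinates"))
    if (e0 <= s0) abort(paste0("BED line ", i, ": empty interval (end <= start)"))
    tibble(gene_id = if (length(f) >= 4) f[4] else paste0("feature_", i),
           chrom = f[1], start = s0 + 1, end = e0,
           strand = if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "*")
  })
  list_rbind(rows)
}

#' Write gene annotation to BED (0-based half-open)
#'
#' Inverse of [read_bed()]: `bed_start = start - 1`, `bed_end = end`.
#'
#' @param annotation Tibble with `gene_id`, `chrom`, `start`, `end`, and
#'   optionally `strand`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(annotation, path) {
  strand <- annotation$strand %||% rep("*", nrow(annotation))
  strand[!strand %in% c("+", "-")] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   annotation$chrom, as.integer(annotation$start - 1),
                   as.integer(annotation$end), annotation$gene_id,
                   0L, strand)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a loci summary table
#'
#' Reads a TSV of called loci (as written by the pipeline, or a
#' supplementary-style table with at least `endpoint` and `chrom` columns) and
#' tallies loci per endpoint.
#'
#' @param path TSV path.
#' @return A list with `loci` (the tibble) and `counts` (loci per endpoint,
#'   plus a `total`).
#' @export
read_loci_table <- function(path) {
  loci <- ps_read_tsv(path)
  if (!"endpoint" %in% names(loci)) abort("loci table must have an endpoint column")
  counts <- loci %>% dplyr::count(.data$endpoint, name = "n_loci")
  list(loci = loci, counts = counts, total = nrow(loci))
}
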
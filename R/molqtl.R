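#' Container for normalized molecular traits
#'
#' @param values Feature x library numeric matrix (normalized expression, psi
#'   or editing ratio), rownames = feature ids, colnames = library ids.
#' @param features Tibble with `feature`, `chrom`, `start`, `end` genomic
#'   anchors (1-based inclusive), one row per matrix row.
#' @param libraries Tibble of library metadata (`library_id`, `strain`, `sex`,
#'   `region`, `infusate`, `batch`), one row per matrix column.
#' @param trait_class One of "expression", "splicing", "editing".
#' @return An object of class `molecular_trait_matrix`.
#' @export
molecular_trait_matrix <- function(values, features, libraries, trait_class) {
  features <- as_tibble(features); libraries <- as_tibble(libraries)
  trait_class <- match.arg(trait_class, c("expression", "splicing", "editing"))
  stopifnot(is.matrix(values), nrow(values) == nrow(features),
            ncol(values) == nrow(libraries),
            all(c("feature", "chrom", "start", "end") %in% names(features)),
            all(c("library_id", "strain") %in% names(libraries)))
  rownames(values) <- features$feature
  colnames(values) <- libraries$library_id
  structure(list(values = values, features = features, libraries = libraries,
                 trait_class = trait_class),
            class = "molecular_trait_matrix")
}

#' @export
print.molecular_trait_matrix <- function(x, ...) {
  cat("<molecular_trait_matrix> ", x$trait_class, ": ", nrow(x$values),
      " features x ", ncol(x$values), " libraries\n", sep = "")
  invisible(x)
}

#' Transcripts per million
#'
#' `TPM = 1e6 * (count / length) / sum(count / length)` per library.
#'
#' @param counts Feature x library count matrix.
#' @param lengths Feature lengths in bp (recycled across libraries).
#' @return Matrix of TPM values.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(all(lengths > 0), all(counts >= 0))
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) abort("library with zero total counts")
  sweep(rate, 2, tot, "/") * 1e6
}

#' Quantile normalization across libraries
#'
#' Forces every library (column) onto the common distribution of row-sorted
#' means, the plain quantile normalization used for all molecular trait
#' classes here. Missing values keep their rank position within the observed
#' values of their column.
#'
#' @param mat Feature x library matrix (may contain NA).
#' @return Quantile-normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  n <- nrow(mat)
  if (n == 1) {  # a single feature: every library maps to the common mean
    out <- mat
    out[!is.na(out)] <- mean(mat, na.rm = TRUE)
    return(out)
  }
  # reference distribution: mean of column-sorted values, interpolated onto a
  # common grid so columns with missing values are handled
  grid <- (seq_len(n) - 0.5) / n
  sorted <- apply(mat, 2, function(x) {
    x <- sort(x[!is.na(x)])
    if (length(x) == 0) return(rep(NA_real_, n))
    if (length(x) == 1) return(rep(x, n))
    stats::approx(x = (seq_along(x) - 0.5) / length(x), y = x, xout = grid,
                  rule = 2)$y
  })
  sorted <- matrix(sorted, nrow = n)
  ref <- rowMeans(sorted, na.rm = TRUE)
  out <- apply(mat, 2, function(x) {
    ok <- !is.na(x)
    m <- sum(ok)
    q <- (rank(x[ok], ties.method = "average") - 0.5) / m
    x[ok] <- stats::approx(x = grid, y = ref, xout = q, rule = 2)$y
    x
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Filter and normalize transcript counts
#'
#' Computes [tpm()] and retains transcripts with `count >= min_reads` and
#' `TPM > tpm_min` in at least `min_fraction` of the libraries of every
#' infusate x region stratum present in `libraries`; retained rows of
#' `log2(TPM + 1)` are quantile normalized within each stratum.
#'
#' @param counts Transcript x library integer matrix.
#' @param lengths Transcript lengths (bp).
#' @param libraries Library metadata tibble; strata defined by the `infusate`
#'   and `region` columns when present.
#' @param annotation Tibble with `gene_id`, `chrom`, `start`, `end` giving each
#'   transcript's anchor (matched on rownames of `counts`).
#' @param min_reads,tpm_min,min_fraction Retention rule parameters
#'   (defaults 6 reads, TPM > 0.1, 20% of libraries).
#' @return A [molecular_trait_matrix()] of class "expression", with the
#'   retention report in `attr(, "filter_report")`.
#' @export
expression_filter_normalize <- function(counts, lengths, libraries, annotation,
                                        min_reads = 6, tpm_min = 0.1,
                                        min_fraction = 0.20) {
  libraries <- as_tibble(libraries)
  stopifnot(ncol(counts) == nrow(libraries))
  tp <- tpm(counts, lengths)
  pass <- counts >= min_reads & tp > tpm_min
  strata <- interaction(
    libraries$infusate %||% rep("all", nrow(libraries)),
    libraries$region %||% rep("all", nrow(libraries)), drop = TRUE)
  frac_by_stratum <- vapply(levels(strata), function(s) {
    rowMeans(pass[, strata == s, drop = FALSE])
  }, numeric(nrow(counts)))
  keep <- apply(as.matrix(frac_by_stratum) >= min_fraction, 1, all)
  report <- tibble(feature = rownames(counts), kept = unname(keep))
  if (!any(keep)) abort("no transcripts pass the retention filter")
  vals <- log2(tp[keep, , drop = FALSE] + 1)
  for (s in levels(strata)) {
    vals[, strata == s] <- quantile_normalize(vals[, strata == s, drop = FALSE])
  }
  idx <- match(rownames(counts)[keep], annotation$gene_id)
  if (anyNA(idx)) abort("counts rows missing from annotation")
  feats <- tibble(feature = rownames(counts)[keep],
                  chrom = annotation$chrom[idx],
                  start = annotation$start[idx], end = annotation$end[idx])
  out <- molecular_trait_matrix(vals, feats, libraries, "expression")
  attr(out, "filter_report") <- report
  out
}

#' Percent spliced in (psi) from inclusion/exclusion counts
#'
#' `psi = inclusion / (inclusion + exclusion)`; libraries with zero total
#' reads get missing psi. An exon is retained if its total reads are
#' `>= min_reads` in every library and its psi has non-zero standard
#' deviation; per transcript, the retained exon with the largest psi standard
#' deviation is selected; selected rows are quantile normalized.
#'
#' @param inclusion,exclusion Exon x library count matrices.
#' @param exon_info Tibble with `feature` (exon id), `transcript`, `chrom`,
#'   `start`, `end`, matched to rows.
#' @param libraries Library metadata tibble.
#' @param min_reads Minimum total reads per library (default 5).
#' @return A [molecular_trait_matrix()] of class "splicing"; the full psi
#'   matrix and selection report are attached as attributes `psi` and
#'   `selection`.
#' @export
compute_psi <- function(inclusion, exclusion, exon_info, libraries, min_reads = 5) {
  stopifnot(all(dim(inclusion) == dim(exclusion)),
            all(inclusion >= 0), all(exclusion >= 0),
            nrow(exon_info) == nrow(inclusion))
  total <- inclusion + exclusion
  psi <- ifelse(total > 0, inclusion / total, NA_real_)
  dimnames(psi) <- list(exon_info$feature, libraries$library_id)
  sd_psi <- apply(psi, 1, sd, na.rm = TRUE)
  retained <- apply(total >= min_reads, 1, all) & !is.na(sd_psi) & sd_psi > 0
  selection <- exon_info %>%
    mutate(sd_psi = unname(sd_psi), retained = unname(retained)) %>%
    group_by(.data$transcript) %>%
    mutate(selected = .data$retained &
             .data$sd_psi == max(.data$sd_psi[.data$retained], -Inf)) %>%
    ungroup() %>%
    # one exon per transcript, first on ties
    group_by(.data$transcript) %>%
    mutate(selected = .data$selected & cumsum(.data$selected) == 1) %>%
    ungroup()
  if (!any(selection$selected)) abort("no exon passes the psi retention filter")
  sel <- which(selection$selected)
  vals <- quantile_normalize(psi[sel, , drop = FALSE])
  out <- molecular_trait_matrix(
    vals, selection[sel, c("feature", "chrom", "start", "end")],
    libraries, "splicing")
  attr(out, "psi") <- psi
  attr(out, "selection") <- selection
  out
}

#' Editing ratio (phi) and ascertainment rate
#'
#' `phi = edited / total` where `total > 0`, missing otherwise ("has data"
#' means at least one aligned read). A site is retained when the fraction of
#' libraries with data is at least `detect_threshold` (boundary inclusive).
#' The ascertainment rate is the mean, over retained sites, of the proportion
#' of libraries with data. Retained rows are quantile normalized.
#'
#' @param edited,total Site x library count matrices, `edited <= total`.
#' @param site_info Tibble with `feature`, `chrom`, `start`, `end` (and
#'   optionally a `category` column: 5'UTR/3'UTR/CDS/intron/intergenic).
#' @param libraries Library metadata tibble.
#' @param detect_threshold Minimum fraction of libraries with data.
#' @return A [molecular_trait_matrix()] of class "editing"; attributes `phi`
#'   (full ratio matrix), `ascertainment_rate`, and `report`.
#' @export
compute_editing <- function(edited, total, site_info, libraries,
                            detect_threshold = 0.10) {
  stopifnot(all(dim(edited) == dim(total)), nrow(site_info) == nrow(edited))
  if (any(edited > total)) abort("edited counts exceed total counts")
  phi <- ifelse(total > 0, edited / total, NA_real_)
  dimnames(phi) <- list(site_info$feature, libraries$library_id)
  frac_data <- rowMeans(total > 0)
  retained <- frac_data >= detect_threshold
  if (!any(retained)) abort("no editing site passes the retention filter")
  ascertainment <- mean(frac_data[retained])
  vals <- quantile_normalize(phi[retained, , drop = FALSE])
  out <- molecular_trait_matrix(
    vals, site_info[retained, intersect(names(site_info),
                                        c("feature", "chrom", "start", "end", "category"))],
    libraries, "editing")
  attr(out, "phi") <- phi
  attr(out, "ascertainment_rate") <- ascertainment
  attr(out, "report") <- tibble(feature = site_info$feature,
                                frac_libraries_with_data = unname(frac_data),
                                retained = unname(retained))
  out
}

#' Label a marker-feature pair cis or trans
#'
#' Cis means same chromosome and the marker lies within `window` bp of the
#' nearest edge of the feature interval (distance 0 inside the feature).
#'
#' @param feature_chrom,feature_start,feature_end Feature anchor (1-based
#'   inclusive).
#' @param marker_chrom,marker_pos Marker coordinates.
#' @param window Cis window in bp (default 2 Mb).
#' @return Logical vector (TRUE = cis).
#' @export
classify_cis <- function(feature_chrom, feature_start, feature_end,
                         marker_chrom, marker_pos, window = 2e6) {
  if (any(is.na(feature_chrom)) || any(is.na(marker_chrom))) {
    abort("unknown chromosome in cis classification")
  }
  dist <- pmax(feature_start - marker_pos, marker_pos - feature_end, 0)
  feature_chrom == marker_chrom & dist <= window
}

# profiled REML criterion for the single-kinship model on the eigenbasis
delta_profile_reml <- function(log_delta, lam, yr, Wr) {
  delta <- exp(log_delta)
  w <- 1 / (lam + delta)
  Ww <- Wr * w
  WtW <- crossprod(Wr, Ww)
  ch <- tryCatch(chol(WtW), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Ww, yr)))
  rss <- sum(w * (yr - Wr %*% beta)^2)
  n <- length(yr); p <- ncol(Wr)
  0.5 * ((n - p) * log(rss) - sum(log(w)) + 2 * sum(log(diag(ch))))
}

#' Map molecular QTLs with a single-kinship spectral mixed model
#'
#' Per trait, fits `y = W b + g gamma + u + e` with `u ~ N(0, sigma_g^2 Gn)`
#' and `e ~ N(0, sigma_e^2 I)`, where `Gn` is the strain kinship expanded to
#' libraries. One eigendecomposition of `Gn` is shared across all complete
#' traits; the per-trait variance ratio `delta = sigma_e^2 / sigma_g^2` is
#' optimized on the rotated one-dimensional profile, and each marker is tested
#' by a Wald t statistic with the residual variance re-profiled per marker
#' (with an identity kinship this reduces exactly to ordinary linear
#' regression). Markers are labeled cis or trans by the `cis_window` rule, and
#' per-trait significance uses a Bonferroni threshold across markers.
#'
#' @param traits A [molecular_trait_matrix()].
#' @param genotypes A [genotype_matrix()].
#' @param kinship Strain kinship matrix.
#' @param covariates Library metadata columns used as fixed effects
#'   (default batch and sex).
#' @param cis_window Cis window in bp.
#' @param alpha Per-trait significance level before Bonferroni correction.
#' @param min_libraries Traits observed in fewer libraries are skipped.
#' @return A list: `qtls` (tibble of significant marker-trait records),
#'   `peaks` (each trait's best marker), `n_markers`, `skipped`.
#' @export
map_molecular_qtl <- function(traits, genotypes, kinship,
                              covariates = c("batch", "sex"),
                              cis_window = 2e6, alpha = 0.05,
                              min_libraries = 10) {
  stopifnot(inherits(traits, "molecular_trait_matrix"),
            inherits(genotypes, "genotype_matrix"))
  libs <- traits$libraries
  if (!all(libs$strain %in% rownames(kinship))) {
    abort("libraries reference strains absent from kinship")
  }
  covariates <- intersect(covariates, names(libs))
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(libs[[v]])) > 1, logical(1))]
  W_full <- stats::model.matrix(
    stats::as.formula(paste("~", paste(c("1", covariates), collapse = " + "))),
    data = libs)
  qw <- qr(W_full)
  if (qw$rank < ncol(W_full)) {
    W_full <- W_full[, qw$pivot[seq_len(qw$rank)], drop = FALSE]
  }
  Cs <- impute_strain_calls(genotypes, sort(unique(libs$strain)))
  Gmk <- Cs[libs$strain, , drop = FALSE]          # library x marker dosages
  Gn <- expand_kinship(kinship, libs$strain)
  eg_full <- eigen(Gn, symmetric = TRUE)

  map_tbl <- genotypes$map
  n_mk <- nrow(map_tbl)
  thr <- alpha / n_mk
  vals <- traits$values
  skipped <- character(0)
  res <- vector("list", nrow(vals))

  for (i in seq_len(nrow(vals))) {
    y <- vals[i, ]
    ok <- !is.na(y)
    if (sum(ok) < min_libraries) {
      skipped <- c(skipped, rownames(vals)[i])
      next
    }
    if (all(ok)) {
      eg <- eg_full; W <- W_full; Gm <- Gmk; yv <- y
    } else {
      eg <- eigen(Gn[ok, ok], symmetric = TRUE)
      W <- W_full[ok, , drop = FALSE]
      Gm <- Gmk[ok, , drop = FALSE]
      yv <- y[ok]
    }
    lam <- pmax(eg$values, 0)
    yr <- as.numeric(crossprod(eg$vectors, yv))
    Wr <- crossprod(eg$vectors, W)
    opt <- optimize(delta_profile_reml, interval = c(-10, 10),
                    lam = lam, yr = yr, Wr = Wr)
    w <- 1 / (lam + exp(opt$minimum))
    Gr <- crossprod(eg$vectors, Gm)
    st <- rotated_marker_tests(yr, Wr, Gr, w)
    feat <- traits$features[i, ]
    res[[i]] <- st %>%
      mutate(feature = feat$feature, trait_class = traits$trait_class,
             marker = map_tbl$marker, chrom = map_tbl$chrom,
             pos_bp = map_tbl$pos_bp,
             cis = classify_cis(feat$chrom, feat$start, feat$end,
                                map_tbl$chrom, map_tbl$pos_bp, cis_window))
  }
  all_res <- list_rbind(res[!vapply(res, is.null, logical(1))])
  if (is.null(all_res) || nrow(all_res) == 0) {
    abort("no traits could be mapped")
  }
  peaks <- all_res %>%
    group_by(.data$feature) %>%
    filter(rank(.data$p.value, ties.method = "first") == 1) %>%
    ungroup() %>%
    mutate(significant = .data$p.value <= thr)
  qtls <- all_res %>% filter(.data$p.value <= thr)
  list(qtls = qtls, peaks = peaks, n_markers = n_mk, threshold = thr,
       skipped = skipped)
}

# Wald t tests of each rotated marker column with weights w = 1/(lam + delta);
# the residual variance is re-profiled per marker, so df = n - p - 1.
rotated_marker_tests <- function(yr, Wr, Gr, w) {
  n <- length(yr); p <- ncol(Wr)
  Ww <- Wr * w
  WtW <- crossprod(Wr, Ww)
  Ci <- solve(WtW)
  Wty <- as.numeric(crossprod(Ww, yr))
  bet0 <- as.numeric(Ci %*% Wty)
  r0 <- yr - as.numeric(Wr %*% bet0)          # residualized y (weighted sense)
  yPy <- sum(w * yr * r0)
  GtW <- crossprod(Gr * w, Wr)                # m x p
  Gty <- as.numeric(crossprod(Gr * w, yr))
  GtG <- unname(colSums(Gr^2 * w))
  denom <- unname(GtG - rowSums((GtW %*% Ci) * GtW))  # g' P g
  num <- Gty - as.numeric(GtW %*% bet0)       # g' P y
  ok <- is.finite(denom) & denom > 1e-10 * pmax(GtG, 1e-300)
  denom_ok <- ifelse(ok, denom, NA_real_)
  gamma <- num / denom_ok
  rss <- pmax(yPy - num^2 / denom_ok, 0)
  df <- n - p - 1
  sigma2 <- rss / df
  se <- sqrt(sigma2 / denom_ok)
  tstat <- gamma / se
  tibble(beta = gamma, se = se, statistic = tstat,
         p.value = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}
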
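#' Describe a strain-panel study design
#'
#' A `panel_design` captures the shape of a hybrid-panel experiment: how many
#' inbred and recombinant-inbred (RI) strains, how many mice per strain, how
#' many daily testing sessions, and the marker map layout. Defaults mirror the
#' study design the package emulates: 84 strains (32 inbred + 52 RI), ~6 mice
#' per strain, 10 consecutive daily sessions, autosomal markers spread over a
#' handful of chromosomes.
#'
#' @param n_inbred Number of inbred founder-type strains.
#' @param n_ri Number of recombinant inbred strains (2-founder mosaics).
#' @param mice_per_strain Mice per strain (sex-balanced within strain).
#' @param n_days Number of daily sessions; day index `j` runs 1..`n_days`.
#' @param n_markers Total biallelic markers across all chromosomes.
#' @param chromosome_lengths Named or unnamed numeric vector of chromosome
#'   lengths in bp; markers are distributed proportionally to length.
#' @param mean_breakpoints Expected recombination breakpoints per chromosome
#'   when building RI mosaics.
#' @param missing_rate Fraction of genotype calls set missing.
#' @param ld_corr_bp Correlation length (bp) of the founder-haplotype process;
#'   controls how fast linkage disequilibrium decays with distance.
#' @param n_cohorts Number of testing cohorts (nominal covariate).
#'
#' @return An object of class `panel_design` (a list).
#' @examples
#' d <- panel_design(n_inbred = 4, n_ri = 6, n_markers = 100)
#' d$n_strains
#' @export
panel_design <- function(n_inbred = 32, n_ri = 52, mice_per_strain = 6,
                         n_days = 10, n_markers = 500,
                         chromosome_lengths = c(chr1 = 120e6, chr2 = 100e6,
                                                chr3 = 90e6, chr4 = 80e6),
                         mean_breakpoints = 8, missing_rate = 0.01,
                         ld_corr_bp = 5e6, n_cohorts = 12) {
  stopifnot(n_inbred >= 0, n_ri >= 0, n_inbred + n_ri >= 2,
            mice_per_strain >= 1, n_days >= 2, n_markers >= 1,
            all(chromosome_lengths > 0), missing_rate >= 0, missing_rate < 1)
  if (n_ri > 0 && n_inbred < 2) {
    abort("RI strains need at least 2 inbred founders (n_inbred >= 2).")
  }
  if (is.null(names(chromosome_lengths))) {
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  }
  structure(
    list(n_strains = n_inbred + n_ri, n_inbred = n_inbred, n_ri = n_ri,
         mice_per_strain = mice_per_strain, n_days = n_days,
         n_markers = n_markers,
         n_chromosomes = length(chromosome_lengths),
         chromosome_lengths = chromosome_lengths,
         mean_breakpoints = mean_breakpoints, missing_rate = missing_rate,
         ld_corr_bp = ld_corr_bp, n_cohorts = n_cohorts),
    class = "panel_design"
  )
}

#' @export
print.panel_design <- function(x, ...) {
  cat("<panel_design> ", x$n_strains, " strains (", x$n_inbred, " inbred + ",
      x$n_ri, " RI), ", x$mice_per_strain, " mice/strain, ", x$n_days,
      " days, ", x$n_markers, " markers on ", x$n_chromosomes,
      " chromosomes\n", sep = "")
  invisible(x)
}

#' Variance components of the longitudinal kinship model
#'
#' Container for the seven (co)variance parameters of the longitudinal mixed
#' model: random intercepts distributed N(0, sigma1_sq G + sigma2_sq I),
#' random day slopes N(0, sigma3_sq G + sigma4_sq I), intercept-slope
#' covariance sigma5_sq G + sigma6_sq I, and i.i.d. residual variance
#' sigma_sq. `G` is the strain kinship matrix expanded to individuals.
#'
#' Admissibility requires the two 2x2 component matrices
#' `[[sigma1_sq, sigma5_sq], [sigma5_sq, sigma3_sq]]` (genetic) and
#' `[[sigma2_sq, sigma6_sq], [sigma6_sq, sigma4_sq]]` (individual) to be
#' positive semi-definite, and all variances non-negative.
#'
#' @param sigma1_sq,sigma3_sq,sigma5_sq Kinship-structured intercept variance,
#'   slope variance, and intercept-slope covariance.
#' @param sigma2_sq,sigma4_sq,sigma6_sq Individual (identity-structured)
#'   counterparts.
#' @param sigma_sq Residual variance.
#' @param alpha Optional named numeric vector of fixed effects.
#' @param check If `TRUE`, reject inadmissible components.
#'
#' @return An object of class `variance_components`.
#' @examples
#' variance_components(0.3, 0.2, 0.05, 0.05, 0, 0, 0.5)
#' @export
variance_components <- function(sigma1_sq = 0, sigma2_sq = 0, sigma3_sq = 0,
                                sigma4_sq = 0, sigma5_sq = 0, sigma6_sq = 0,
                                sigma_sq = 1, alpha = NULL, check = TRUE) {
  vc <- structure(
    list(sigma1_sq = sigma1_sq, sigma2_sq = sigma2_sq, sigma3_sq = sigma3_sq,
         sigma4_sq = sigma4_sq, sigma5_sq = sigma5_sq, sigma6_sq = sigma6_sq,
         sigma_sq = sigma_sq, alpha = alpha, convergence = NULL),
    class = "variance_components"
  )
  if (check) check_vc(vc)
  vc
}

check_vc <- function(vc) {
  with(vc, {
    if (any(c(sigma1_sq, sigma2_sq, sigma3_sq, sigma4_sq, sigma_sq) < 0)) {
      abort("variances sigma1_sq..sigma4_sq and sigma_sq must be >= 0")
    }
    if (sigma5_sq^2 > sigma1_sq * sigma3_sq + 1e-12) {
      abort(paste("genetic intercept-slope component is not PSD:",
                  "sigma5_sq^2 > sigma1_sq * sigma3_sq"))
    }
    if (sigma6_sq^2 > sigma2_sq * sigma4_sq + 1e-12) {
      abort(paste("individual intercept-slope component is not PSD:",
                  "sigma6_sq^2 > sigma2_sq * sigma4_sq"))
    }
  })
  invisible(vc)
}

#' @export
print.variance_components <- function(x, ...) {
  cat("<variance_components>\n")
  v <- unlist(x[c("sigma1_sq", "sigma2_sq", "sigma3_sq", "sigma4_sq",
                  "sigma5_sq", "sigma6_sq", "sigma_sq")])
  print(round(v, 4))
  if (!is.null(x$alpha)) {
    cat("fixed effects:\n"); print(round(x$alpha, 4))
  }
  invisible(x)
}

#' @describeIn variance_components Tidy the components into a tibble.
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @export
tidy.variance_components <- function(x, ...) {
  tibble(
    component = c("sigma1_sq", "sigma2_sq", "sigma3_sq", "sigma4_sq",
                  "sigma5_sq", "sigma6_sq", "sigma_sq"),
    structure = c("kinship", "individual", "kinship", "individual",
                  "kinship", "individual", "residual"),
    term = c("intercept", "intercept", "slope", "slope",
             "intercept-slope", "intercept-slope", "residual"),
    estimate = as.numeric(unlist(x[c("sigma1_sq", "sigma2_sq", "sigma3_sq",
                                     "sigma4_sq", "sigma5_sq", "sigma6_sq",
                                     "sigma_sq")]))
  )
}
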
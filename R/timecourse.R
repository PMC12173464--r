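#' Two-sided p-value from a t statistic
#'
#' @param t t statistic.
#' @param df Denominator degrees of freedom (> 0).
#' @return `2 * P(T_df >= |t|)`.
#' @examples
#' t_to_p(4.7, 476)   # ~3.4e-6
#' t_to_p(-0.83, 476) # ~0.41
#' @export
t_to_p <- function(t, df) {
  if (any(df <= 0)) abort("degrees of freedom must be > 0")
  2 * pt(abs(t), df, lower.tail = FALSE)
}

#' Pearson correlation test between two vectors of strain means
#'
#' Computes R on pairwise-complete observations and the two-sided p-value from
#' `t = R * sqrt(df / (1 - R^2))` on `df = n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors (paired).
#' @return A one-row tibble with `estimate` (R), `df`, `statistic`, `p.value`, `n`.
#' @export
corr_test <- function(x, y) {
  ok <- complete.cases(x, y)
  n <- sum(ok)
  if (n < 3) abort("corr_test needs at least 3 complete pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) abort("corr_test undefined for constant input")
  r <- cor(x[ok], y[ok])
  df <- n - 2
  tibble(estimate = r, df = df, statistic = r * sqrt(df / (1 - r^2)),
         p.value = r_to_p(r, df), n = n)
}

#' P-value for a Pearson correlation coefficient
#'
#' @param r Correlation coefficient.
#' @param df Degrees of freedom (`n - 2`).
#' @return Two-sided p-value.
#' @examples
#' r_to_p(0.32, 40) # ~0.04
#' @export
r_to_p <- function(r, df) {
  if (any(df <= 0)) abort("degrees of freedom must be > 0")
  if (any(abs(r) >= 1)) return(ifelse(abs(r) >= 1, 0, NA_real_))
  t_to_p(r * sqrt(df / (1 - r^2)), df)
}

#' Test an endpoint's time course with a mouse-level mixed model
#'
#' Fits, by REML, a linear mixed model of the (per-day normalized) endpoint on
#' testing day as a continuous fixed effect plus sex, active-lever side,
#' chamber, cohort and age, with a correlated random intercept and random day
#' slope per mouse (no kinship at this stage). The fixed-day t statistic uses
#' the Satterthwaite denominator degrees of freedom. If the unstructured 2x2
#' random-effect covariance is singular, the model is refit with independent
#' intercept and slope and the result is flagged.
#'
#' @param pheno Long-format tibble with columns `mouse_id`, `day`, the
#'   endpoint, and covariates `sex`, `lever`, `chamber`, `cohort`, `age` (any
#'   covariate column absent from the table is dropped from the formula).
#' @param endpoint Name of the endpoint column.
#' @return A one-row tibble: `endpoint`, `estimate` (fixed day effect), `se`,
#'   `statistic` (t), `df` (Satterthwaite), `p.value`, `singular_refit`.
#' @export
fit_timecourse <- function(pheno, endpoint) {
  stopifnot(endpoint %in% names(pheno), all(c("mouse_id", "day") %in% names(pheno)))
  covars <- intersect(c("sex", "lever", "chamber", "cohort", "age"), names(pheno))
  covars <- covars[vapply(covars, function(v) length(unique(pheno[[v]])) > 1, logical(1))]
  rhs <- paste(c("day", covars), collapse = " + ")
  f_corr <- stats::as.formula(paste0("`", endpoint, "` ~ ", rhs, " + (1 + day | mouse_id)"))
  f_diag <- stats::as.formula(paste0("`", endpoint, "` ~ ", rhs, " + (1 + day || mouse_id)"))
  dat <- pheno[!is.na(pheno[[endpoint]]), , drop = FALSE]
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(f_corr, data = dat, REML = TRUE)))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(f_diag, data = dat, REML = TRUE)))
  }
  co <- summary(fit)$coefficients["day", ]
  tibble(endpoint = endpoint,
         estimate = unname(co["Estimate"]), se = unname(co["Std. Error"]),
         statistic = unname(co["t value"]), df = unname(co["df"]),
         p.value = unname(co["Pr(>|t|)"]), singular_refit = singular)
}

#' Time-course tests for several endpoints at once
#'
#' @param pheno Long-format phenotype tibble.
#' @param endpoints Character vector of endpoint columns.
#' @return One row per endpoint, see [fit_timecourse()].
#' @export
fit_timecourses <- function(pheno, endpoints) {
  map(endpoints, ~ fit_timecourse(pheno, .x)) %>% list_rbind()
}
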
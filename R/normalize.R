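#' Blom rank-based inverse normal transformation
#'
#' Maps values to normal scores `qnorm((r - c) / (n + 1 - 2c))` with Blom's
#' constant `c = 3/8`, where `r` is the rank and `n` the number of non-missing
#' values. Tied values receive the mean of their ranks, so equal inputs map to
#' equal outputs. Missing values pass through as missing.
#'
#' @param values Numeric vector.
#' @param c_const Offset constant (Blom's 3/8 by default).
#' @return Numeric vector of the same length.
#' @examples
#' blom_transform(c(10, 20, 30))
#' @export
blom_transform <- function(values, c_const = 3 / 8) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) abort("blom_transform needs at least 2 non-missing values")
  out <- rep(NA_real_, length(values))
  x <- values[ok]
  if (length(unique(x)) == 1L) {
    warn("all values identical; Blom transform returns 0 for every value")
    out[ok] <- 0
    return(out)
  }
  r <- rank(x, ties.method = "average")
  out[ok] <- qnorm((r - c_const) / (n + 1 - 2 * c_const))
  out
}

#' Normalize behavioral endpoints day by day
#'
#' Applies [blom_transform()] separately within each testing day to the given
#' endpoint columns of a long-format phenotype table, the standard
#' normalization before longitudinal mixed-model mapping.
#'
#' @param pheno Long-format tibble with a `day` column.
#' @param endpoints Character vector of endpoint column names.
#' @return The table with the endpoint columns replaced by their per-day
#'   normal scores.
#' @export
normalize_endpoints <- function(pheno, endpoints) {
  stopifnot(all(c("day", endpoints) %in% names(pheno)))
  pheno %>%
    group_by(.data$day) %>%
    mutate(across(all_of(endpoints), blom_transform)) %>%
    ungroup()
}

#' Standardize a vector to Z scores
#'
#' `(x - mean) / sd` with the n-1 sample standard deviation; used e.g. to put
#' open-field distances on a common scale before correlating with behavioral
#' strain means.
#'
#' @param values Numeric vector (missing values ignored for the moments and
#'   passed through).
#' @return Standardized vector.
#' @export
zscore <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) abort("zscore needs at least 2 non-missing values")
  s <- sd(values[ok])
  if (s == 0) abort("zscore undefined for constant input")
  (values - mean(values[ok])) / s
}

#' Percent active lever presses
#'
#' `active / (active + inactive)`, the endpoint that normalizes lever pressing
#' for overall activity. Days with zero total presses are recorded as missing
#' (neither 0 nor 100 is defensible for 0/0).
#'
#' @param active,inactive Non-negative press counts.
#' @param percent If `TRUE` (default) return 0-100, else a proportion.
#' @return Numeric vector.
#' @export
percent_active <- function(active, inactive, percent = TRUE) {
  tot <- active + inactive
  out <- ifelse(tot > 0, active / tot, NA_real_)
  if (percent) out * 100 else out
}
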
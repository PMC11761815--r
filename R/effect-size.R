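#' Hedges' g building blocks
#'
#' Scalar machinery for the standardized mean difference with the small-sample
#' correction: degrees of freedom `m = n1 + n2 - 2`, effective sample size
#' `ntilde = n1 * n2 / (n1 + n2)`, the bias-correction factor
#' `c(m) = Gamma(m/2) / (sqrt(m/2) * Gamma((m-1)/2))`, and the shorthand
#' coefficient `a = c(m)^2 * m / (m - 2)` used throughout the variance
#' formulas. All functions are vectorized.
#'
#' `hedges_c()` is evaluated through log-gamma differences so it neither
#' overflows nor loses precision for large `m`.
#'
#' @param n1,n2 Group sample sizes (each at least 2 where a pooled SD is
#'   required).
#' @param m Degrees of freedom, `n1 + n2 - 2`.
#' @return A numeric vector.
#' @examples
#' hedges_df(15, 15)
#' effective_n(10, 30)
#' hedges_c(28)
#' hedges_a(28)
#' @name hedges-terms
NULL

#' @rdname hedges-terms
#' @export
hedges_df <- function(n1, n2) {
  check_sizes(n1, n2)
  n1 + n2 - 2
}

#' @rdname hedges-terms
#' @export
effective_n <- function(n1, n2) {
  if (any(!is.finite(n1)) || any(!is.finite(n2)) || any(n1 < 1) || any(n2 < 1)) {
    abort("`n1` and `n2` must be finite sizes of at least 1.",
          class = "metamixg_error_design")
  }
  n1 * n2 / (n1 + n2)
}

#' @rdname hedges-terms
#' @export
hedges_c <- function(m) {
  if (any(!is.finite(m)) || any(m < 1)) {
    abort("`m` must be at least 1.", class = "metamixg_error_design")
  }
  exp(lgamma(m / 2) - 0.5 * log(m / 2) - lgamma((m - 1) / 2))
}

#' @rdname hedges-terms
#' @export
hedges_a <- function(m) {
  if (any(!is.finite(m)) || any(m <= 2)) {
    abort("`m` must exceed 2 for the variance coefficient `a`.",
          class = "metamixg_error_design")
  }
  hedges_c(m)^2 * m / (m - 2)
}

check_sizes <- function(n1, n2) {
  if (any(!is.finite(n1)) || any(!is.finite(n2)) || any(n1 < 2) || any(n2 < 2)) {
    abort("Group sizes `n1` and `n2` must both be at least 2.",
          class = "metamixg_error_design")
  }
  invisible(NULL)
}

#' Hedges' g from raw group summaries
#'
#' Computes the bias-corrected standardized mean difference
#' `g = c(m) * (mean1 - mean2) / s_pooled`, with the pooled standard deviation
#' on `m = n1 + n2 - 2` degrees of freedom.
#'
#' @param mean1,mean2 Group means (outcome units).
#' @param sd1,sd2 Group standard deviations (outcome units).
#' @param n1,n2 Group sample sizes, at least 2 each.
#' @return Numeric vector of g values.
#' @examples
#' hedges_g(1, 1, 15, 0, 1, 15) # c(28), since the pooled SD is 1
#' @export
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2) {
  check_sizes(n1, n2)
  m <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / m
  if (any(sp2 <= 0)) {
    abort("Pooled standard deviation is zero; g is undefined.",
          class = "metamixg_error_degenerate")
  }
  hedges_c(m) * (mean1 - mean2) / sqrt(sp2)
}

#' Exact conditional variance of g given the true effect
#'
#' For a fixed true standardized mean difference `delta`, g is distributed as
#' `(c(m)/sqrt(ntilde))` times a noncentral t with `m` degrees of freedom and
#' noncentrality `delta * sqrt(ntilde)`. Its exact variance is
#' `(a/ntilde) * (1 + ntilde * delta^2) - delta^2` with
#' `a = c(m)^2 * m / (m - 2)`. This is also the `tau2 = 0` limit of the
#' mixture-model study-level variance.
#'
#' @param delta True standardized mean difference.
#' @param m Degrees of freedom (> 2).
#' @param ntilde Effective sample size `n1 * n2 / (n1 + n2)`.
#' @return Numeric vector of variances.
#' @examples
#' var_g_conditional(0, 28, 7.5) # a / ntilde
#' @export
var_g_conditional <- function(delta, m, ntilde) {
  a <- hedges_a(m)
  (a / ntilde) * (1 + ntilde * delta^2) - delta^2
}

#' Add derived effect-size columns to a study table
#'
#' Takes a data frame of per-study records in one of two schemas and returns a
#' tibble with the derived quantities used everywhere else in the package:
#' `m` (degrees of freedom), `ntilde` (effective size) and `a` (the variance
#' coefficient). Raw-summary rows (`mean1, sd1, n1, mean2, sd2, n2`) have `g`
#' computed with [hedges_g()]; g-level rows (`g, n1, n2`) are passed through.
#' A `study_id` column is added when absent. Row order is preserved.
#'
#' @param data A data frame with columns `g, n1, n2` or
#'   `mean1, sd1, n1, mean2, sd2, n2` (plus an optional `study_id`).
#' @return A tibble with columns `study_id, g, n1, n2, m, ntilde, a`.
#' @examples
#' add_study_terms(data.frame(g = c(0.2, 0.6), n1 = c(10, 20), n2 = c(12, 20)))
#' @export
add_study_terms <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame of per-study records.",
          class = "metamixg_error_input")
  }
  data <- tibble::as_tibble(data)
  raw_cols <- c("mean1", "sd1", "n1", "mean2", "sd2", "n2")
  if (all(raw_cols %in% names(data))) {
    data$g <- hedges_g(data$mean1, data$sd1, data$n1,
                       data$mean2, data$sd2, data$n2)
  } else if (!all(c("g", "n1", "n2") %in% names(data))) {
    abort(paste0(
      "`data` must contain either columns (g, n1, n2) or (",
      paste(raw_cols, collapse = ", "), ")."
    ), class = "metamixg_error_schema")
  }
  check_sizes(data$n1, data$n2)
  if (is.null(data[["study_id"]])) {
    data$study_id <- paste0("study_", seq_len(nrow(data)))
  }
  data |>
    dplyr::mutate(
      m = hedges_df(.data$n1, .data$n2),
      ntilde = effective_n(.data$n1, .data$n2),
      # a is undefined at m <= 2 (Gamma argument of the variance would be <= 0)
      a = dplyr::if_else(.data$m > 2,
                         hedges_c(.data$m)^2 * .data$m / pmax(.data$m - 2, 1e-12),
                         NA_real_)
    ) |>
    dplyr::relocate("study_id", "g", "n1", "n2", "m", "ntilde", "a")
}
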
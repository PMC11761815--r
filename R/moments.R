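#' Conditional and marginal density of g
#'
#' Given the true effect delta, g is `(c(m)/sqrt(ntilde))` times a noncentral
#' t with `m` degrees of freedom and noncentrality `delta * sqrt(ntilde)`;
#' `dg_conditional()` evaluates that density. `dg_marginal()` integrates it
#' over the latent distribution of delta: with the normal family the mixture
#' integral is evaluated by Gauss-Hermite quadrature (96 nodes); for a custom
#' family with an evaluable `pdf`, by adaptive quadrature over
#' `mu_delta +/- 10 * sqrt(tau2)`.
#'
#' @param g Value(s) at which to evaluate the density.
#' @param delta True standardized mean difference.
#' @param m Degrees of freedom.
#' @param ntilde Effective sample size.
#' @param latent A [latent_dist()] object (or NULL to use
#'   `latent_normal(mu_delta, tau2)`).
#' @param mu_delta,tau2 Latent mean and variance, used when `latent` is NULL.
#' @param nodes Number of Gauss-Hermite nodes for the normal family.
#' @return Numeric vector of densities.
#' @examples
#' dg_conditional(0.3, delta = 0.5, m = 28, ntilde = 7.5)
#' dg_marginal(0.3, mu_delta = 0.5, tau2 = 0.1, m = 28, ntilde = 7.5)
#' @export
dg_conditional <- function(g, delta, m, ntilde) {
  if (any(m < 1) || any(ntilde <= 0)) {
    abort("Require `m` >= 1 and `ntilde` > 0.", class = "metamixg_error_design")
  }
  s <- hedges_c(m) / sqrt(ntilde)
  suppressWarnings(dt(g / s, df = m, ncp = delta * sqrt(ntilde)) / s)
}

#' @rdname dg_conditional
#' @export
dg_marginal <- function(g, latent = NULL, mu_delta = NULL, tau2 = NULL,
                        m, ntilde, nodes = 96) {
  latent <- as_latent(latent, mu_delta, tau2)
  if (latent$tau2 == 0) {
    return(dg_conditional(g, latent$mu_delta, m, ntilde))
  }
  if (latent$family == "normal") {
    gh <- pracma::gaussHermite(nodes)
    d <- latent$mu_delta + sqrt(2 * latent$tau2) * gh$x
    w <- gh$w / sqrt(pi)
    vapply(g, function(gg) sum(w * dg_conditional(gg, d, m, ntilde)),
           numeric(1))
  } else {
    if (is.null(latent$pdf)) {
      abort("Custom latent family needs an evaluable `pdf` for the marginal density.",
            class = "metamixg_error_not_implemented")
    }
    half <- 15 * sqrt(latent$tau2)
    vapply(g, function(gg) {
      integrate(function(d) dg_conditional(gg, d, m, ntilde) * latent$pdf(d),
                latent$mu_delta - half, latent$mu_delta + half,
                rel.tol = 1e-10)$value
    }, numeric(1))
  }
}

#' Central moments of the marginal distribution of g
#'
#' `central_moment_g()` evaluates the closed-form central moment of order `r`
#' of g for one pair of sample sizes, using only gamma functions of `m` and
#' the raw moments of the latent distribution:
#' \deqn{E[(g-\mu_\Delta)^r] = \sum_{k=0}^{r} (-1)^k \binom{r}{k}
#'   \left(\frac{c(m)}{\sqrt{\tilde n}}\right)^{r-k} \mu_\Delta^{k}
#'   \left(\frac{m}{2}\right)^{(r-k)/2}
#'   \frac{\Gamma((m-(r-k))/2)}{\Gamma(m/2)}
#'   \sum_{j=0}^{\lfloor (r-k)/2\rfloor} \binom{r-k}{2j}
#'   \frac{(2j)!}{2^j j!} \tilde n^{((r-k)-2j)/2}\, E(\delta^{(r-k)-2j}).}
#' The exponent on `m/2` is `(r-k)/2`, which is the form under which the
#' `r = 2` case reduces exactly to the closed-form variance below (see the
#' methods vignette for the typography note).
#'
#' `var_g_study()`, `third_moment_g_study()` and `skewness_g_study()` are the
#' closed forms for orders 2 and 3:
#' variance `(c(m)^2 m /((m-2) ntilde)) (1 + ntilde (tau2 + mu^2)) - mu^2`,
#' and the third central moment
#' `(c(m)^3/ntilde) (m^{3/2} Gamma((m-3)/2) / (2 sqrt(2) Gamma(m/2)))
#'  (3 mu + E(delta^3) ntilde) - 3 mu sigma2 - mu^3`.
#'
#' @param r Moment order (requires `m > r`).
#' @inheritParams dg_conditional
#' @return A numeric scalar (vectorized over `m`, `ntilde` for the fixed-order
#'   helpers).
#' @examples
#' var_g_study(0.5, 0.1, m = 28, ntilde = 7.5)      # 0.24272
#' skewness_g_study(0.5, 0.1, m = 28, ntilde = 7.5) # 0.12139
#' @export
central_moment_g <- function(r, latent = NULL, mu_delta = NULL, tau2 = NULL,
                             m, ntilde) {
  latent <- as_latent(latent, mu_delta, tau2)
  stopifnot(length(r) == 1, r >= 0, r == round(r))
  if (m <= r) {
    abort("Central moment of order `r` requires `m > r`.",
          class = "metamixg_error_moment")
  }
  mu <- latent$mu_delta
  total <- 0
  for (k in 0:r) {
    rk <- r - k
    inner <- 0
    for (j in 0:floor(rk / 2)) {
      inner <- inner +
        choose(rk, 2 * j) * factorial(2 * j) / (2^j * factorial(j)) *
        ntilde^((rk - 2 * j) / 2) * latent$raw_moment(rk - 2 * j)
    }
    total <- total + (-1)^k * choose(r, k) *
      (hedges_c(m) / sqrt(ntilde))^rk * mu^k *
      (m / 2)^(rk / 2) * exp(lgamma((m - rk) / 2) - lgamma(m / 2)) * inner
  }
  total
}

#' @rdname central_moment_g
#' @param mu_delta Mean true effect.
#' @param tau2 Specific variance.
#' @export
var_g_study <- function(mu_delta, tau2, m, ntilde) {
  a <- hedges_a(m) # errors for m <= 2
  (a / ntilde) * (1 + ntilde * (tau2 + mu_delta^2)) - mu_delta^2
}

#' @rdname central_moment_g
#' @export
third_moment_g_study <- function(latent = NULL, mu_delta = NULL, tau2 = NULL,
                                 m, ntilde) {
  latent <- as_latent(latent, mu_delta, tau2)
  if (any(m <= 3)) {
    abort("Third moment requires `m > 3`.", class = "metamixg_error_moment")
  }
  mu <- latent$mu_delta
  d3 <- latent$raw_moment(3)
  s2 <- var_g_study(mu, latent$tau2, m, ntilde)
  hedges_c(m)^3 / ntilde *
    (m^1.5 * exp(lgamma((m - 3) / 2) - lgamma(m / 2)) / (2 * sqrt(2))) *
    (3 * mu + d3 * ntilde) - 3 * mu * s2 - mu^3
}

#' @rdname central_moment_g
#' @export
skewness_g_study <- function(latent = NULL, mu_delta = NULL, tau2 = NULL,
                             m, ntilde) {
  latent <- as_latent(latent, mu_delta, tau2)
  mu3 <- third_moment_g_study(latent, m = m, ntilde = ntilde)
  s2 <- var_g_study(latent$mu_delta, latent$tau2, m, ntilde)
  mu3 / s2^1.5
}

#' Moments of g study by study and at the meta-analysis level
#'
#' `study_moments()` appends the closed-form mean, variance, third central
#' moment and skewness of g to each row of a design (one row per sample-size
#' pair). `meta_moments()` returns the moments of the equal-weights finite
#' mixture over the rows: the mean is `mu_delta` for any design, the variance
#' and third central moment are the arithmetic means of the per-row values
#' (laws of total variance/cumulance: the conditional mean does not depend on
#' the sizes), and the skewness is the mixture third moment over the mixture
#' standard deviation cubed.
#'
#' @param design A data frame with columns `n1` and `n2` (one row per study
#'   design); other columns are kept.
#' @inheritParams central_moment_g
#' @return `study_moments()`: the design tibble with columns
#'   `mean, variance, mu3, skewness` added. `meta_moments()`: a one-row tibble
#'   with `mean, variance, mu3, skewness, k`.
#' @examples
#' design <- data.frame(n1 = c(5, 15), n2 = c(5, 15))
#' study_moments(design, mu_delta = 0.5, tau2 = 0.1)
#' meta_moments(design, mu_delta = 0.5, tau2 = 0.1)
#' @export
study_moments <- function(design, mu_delta = NULL, tau2 = NULL, latent = NULL) {
  latent <- as_latent(latent, mu_delta, tau2)
  design <- add_design_terms(design)
  design |>
    dplyr::mutate(
      mean = latent$mu_delta,
      variance = var_g_study(latent$mu_delta, latent$tau2, .data$m, .data$ntilde),
      mu3 = purrr::map2_dbl(.data$m, .data$ntilde,
                            ~ third_moment_g_study(latent, m = .x, ntilde = .y)),
      skewness = .data$mu3 / .data$variance^1.5
    )
}

#' @rdname study_moments
#' @export
meta_moments <- function(design, mu_delta = NULL, tau2 = NULL, latent = NULL) {
  latent <- as_latent(latent, mu_delta, tau2)
  per <- study_moments(design, latent = latent)
  variance <- mean(per$variance)
  mu3 <- mean(per$mu3)
  tibble::tibble(
    mean = latent$mu_delta,
    variance = variance,
    mu3 = mu3,
    skewness = mu3 / variance^1.5,
    k = nrow(per)
  )
}

add_design_terms <- function(design) {
  if (!is.data.frame(design) || !all(c("n1", "n2") %in% names(design))) {
    abort("`design` must be a data frame with columns `n1` and `n2`.",
          class = "metamixg_error_schema")
  }
  if (nrow(design) == 0) {
    abort("`design` must have at least one row.", class = "metamixg_error_input")
  }
  check_sizes(design$n1, design$n2)
  design <- tibble::as_tibble(design)
  design$m <- hedges_df(design$n1, design$n2)
  design$ntilde <- effective_n(design$n1, design$n2)
  design
}
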
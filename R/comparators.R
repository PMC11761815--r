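#' Conditional sampling-variance estimate for one study
#'
#' The classical random-effects pipeline estimates each study's sampling
#' variance by plugging the study's own `g` into a conditional-variance
#' formula. The `"exact"` form is Hedges' exact conditional variance
#' `(a/ntilde) * (1 + ntilde * g^2) - g^2`; the `"large-sample"` form is the
#' common approximation `1/ntilde + g^2 / (2 * (n1 + n2))`. Either way the
#' estimate increases with `|g|` at fixed sizes - the g-weight covariation
#' the mixture-model weights avoid.
#'
#' @param g Observed Hedges' g.
#' @param m Degrees of freedom (> 2 for the exact form).
#' @param ntilde Effective sample size.
#' @param form `"exact"` or `"large-sample"`.
#' @return Numeric vector of variance estimates.
#' @examples
#' var_g_plugin(0.5, m = 28, ntilde = 7.5)
#' @export
var_g_plugin <- function(g, m, ntilde, form = c("exact", "large-sample")) {
  form <- match.arg(form)
  if (form == "exact") {
    var_g_conditional(g, m, ntilde)
  } else {
    # n1 + n2 = m + 2
    1 / ntilde + g^2 / (2 * (m + 2))
  }
}

fit_dl <- function(s, level, conditional) {
  v <- var_g_plugin(s$g, s$m, s$ntilde, conditional)
  est <- dl_tau2(s$g, v)
  w <- 1 / (v + est$tau2)
  mu <- sum(w * s$g) / sum(w)
  se <- sqrt(1 / sum(w))
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  s$sigma2_g <- v + est$tau2
  s$weight <- w
  new_meta_fit(
    method = "dl", studies = s, mu_hat = mu,
    tau2_raw = est$tau2_raw, tau2 = est$tau2,
    se_mu = se, ci_mu = c(mu - zcrit * se, mu + zcrit * se), level = level
  )
}

dl_tau2 <- function(g, v) {
  w <- 1 / v
  mu_fe <- sum(w * g) / sum(w)
  q <- sum(w * (g - mu_fe)^2)
  k <- length(g)
  raw <- (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))
  list(tau2_raw = raw, tau2 = max(0, raw), q = q)
}

fit_reml <- function(s, level, conditional, tol, max_iter) {
  v <- var_g_plugin(s$g, s$m, s$ntilde, conditional)
  est <- reml_tau2(s$g, v, tol = tol, max_iter = max_iter)
  if (!est$converged) {
    abort(sprintf("REML did not converge in %d iterations (last step %.3g).",
                  max_iter, est$step),
          class = "metamixg_error_convergence")
  }
  w <- 1 / (v + est$tau2)
  mu <- sum(w * s$g) / sum(w)
  se <- sqrt(1 / sum(w))
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  s$sigma2_g <- v + est$tau2
  s$weight <- w
  new_meta_fit(
    method = "reml", studies = s, mu_hat = mu,
    tau2_raw = est$tau2, tau2 = est$tau2,
    se_mu = se, ci_mu = c(mu - zcrit * se, mu + zcrit * se), level = level,
    converged = est$converged, iterations = est$iterations
  )
}

# Fixed-point iteration on the restricted score equation:
# tau2 <- sum(w^2 ((g - mu)^2 - v)) / sum(w^2) + 1 / sum(w), floored at 0.
reml_tau2 <- function(g, v, tau2_init = max(0, var(g) - mean(v)),
                      tol = 1e-8, max_iter = 500L) {
  tau2 <- tau2_init
  step <- Inf
  for (it in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    mu <- sum(w * g) / sum(w)
    new <- max(0, sum(w^2 * ((g - mu)^2 - v)) / sum(w^2) + 1 / sum(w))
    step <- abs(new - tau2)
    tau2 <- new
    if (step < tol) {
      return(list(tau2 = tau2, converged = TRUE, iterations = it, step = step))
    }
  }
  list(tau2 = tau2, converged = FALSE, iterations = max_iter, step = step)
}

#' Pearson correlation between g values and their weights
#'
#' The diagnostic at the heart of the comparison between weighting schemes:
#' weights that covary (negatively) with the observed `g` values shrink the
#' pooled estimate. With MM weights the correlation is zero in expectation;
#' with conditional-variance weights (DL, REML) it is systematically negative.
#' Returns `NA` (not an error) when either vector is constant.
#'
#' @param g Observed g values.
#' @param weights Study weights.
#' @return A correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
weight_correlation <- function(g, weights) {
  if (length(g) < 3 || sd(g) == 0 || sd(weights) == 0 ||
      !all(is.finite(g)) || !all(is.finite(weights))) {
    return(NA_real_)
  }
  cor(g, weights)
}
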
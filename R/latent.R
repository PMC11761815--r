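#' Latent (mixing) distribution of the true effect
#'
#' The marginal law of g is a mixture of scaled noncentral-t distributions
#' over the latent distribution of the true standardized mean difference
#' delta, with mean `mu_delta` and variance `tau2`. The closed-form moment
#' formulas only touch the latent law through its raw moments
#' `E(delta^r)`, so any family with finite moments up to order 3 can be
#' supplied; the marginal density additionally needs an evaluable latent
#' density.
#'
#' `latent_normal()` is the default family. `latent_dist()` builds a custom
#' family from a raw-moment function (and optionally a density).
#'
#' @param mu_delta Mean true effect.
#' @param tau2 Specific (between-study) variance, `>= 0`.
#' @param raw_moment Function of an integer order `r` returning `E(delta^r)`;
#'   must honour `raw_moment(0) = 1`, `raw_moment(1) = mu_delta`,
#'   `raw_moment(2) = tau2 + mu_delta^2`.
#' @param pdf Optional density function of delta (needed only for
#'   [dg_marginal()] with a non-normal family).
#' @param family Label for the family.
#' @return An object of class `latent_dist`.
#' @examples
#' lat <- latent_normal(0.5, 0.1)
#' lat$raw_moment(3) # mu^3 + 3 mu tau2
#' @export
latent_normal <- function(mu_delta, tau2) {
  if (!is.finite(tau2) || tau2 < 0) {
    abort("`tau2` must be a finite non-negative variance.",
          class = "metamixg_error_input")
  }
  # raw moments of N(mu, tau2) by the recursion
  # E(d^r) = mu E(d^(r-1)) + (r-1) tau2 E(d^(r-2))
  raw_moment <- function(r) {
    stopifnot(r >= 0, r == round(r))
    mom <- c(1, mu_delta)
    if (r >= 2) {
      for (j in 2:r) mom[j + 1] <- mu_delta * mom[j] + (j - 1) * tau2 * mom[j - 1]
    }
    mom[r + 1]
  }
  structure(
    list(mu_delta = mu_delta, tau2 = tau2, family = "normal",
         raw_moment = raw_moment,
         pdf = function(x) stats::dnorm(x, mu_delta, sqrt(tau2))),
    class = "latent_dist"
  )
}

#' @rdname latent_normal
#' @export
latent_dist <- function(mu_delta, tau2, raw_moment, pdf = NULL,
                        family = "custom") {
  stopifnot(is.function(raw_moment))
  if (abs(raw_moment(0) - 1) > 1e-10 ||
      abs(raw_moment(1) - mu_delta) > 1e-8 ||
      abs(raw_moment(2) - (tau2 + mu_delta^2)) > 1e-8) {
    abort("`raw_moment` is inconsistent with `mu_delta` and `tau2`.",
          class = "metamixg_error_input")
  }
  structure(
    list(mu_delta = mu_delta, tau2 = tau2, family = family,
         raw_moment = raw_moment, pdf = pdf),
    class = "latent_dist"
  )
}

#' @export
print.latent_dist <- function(x, ...) {
  cat("<latent_dist> family:", x$family,
      " mu_delta:", format(x$mu_delta),
      " tau2:", format(x$tau2), "\n")
  invisible(x)
}

as_latent <- function(latent = NULL, mu_delta = NULL, tau2 = NULL) {
  if (inherits(latent, "latent_dist")) return(latent)
  if (is.null(latent)) return(latent_normal(mu_delta, tau2))
  abort("`latent` must be a `latent_dist` object or NULL.",
        class = "metamixg_error_input")
}
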
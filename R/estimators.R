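#' Method-of-moments plug-ins for the mixture model
#'
#' The three-step mixture-model (MM) estimation works from only the `g`
#' values, their squares and the known size terms `a_i`, `ntilde_i`:
#'
#' * `mm_plugin_second()` estimates `tau2 + mu_delta^2` by
#'   `(sum(g^2) - sum(a/ntilde)) / sum(a)` (unbiased, no truncation);
#' * `mm_plugin_mu2()` estimates `mu_delta^2` by
#'   `(mean(a)/(k-1)) * ((k*gbar^2 - sum(a/(k*ntilde))) / mean(a) -
#'    mm_plugin_second())`;
#' * `tau2_mm()` is their difference, the unbiased MM estimator of the
#'   specific variance, reported both raw and truncated at zero.
#'
#' @param data A data frame of studies with columns `g, n1, n2` (or raw
#'   summaries); derived terms are added with [add_study_terms()].
#' @return `mm_plugin_second()` and `mm_plugin_mu2()` return scalars;
#'   `tau2_mm()` a one-row tibble with `tau2_raw` and `tau2`.
#' @examples
#' toy <- data.frame(g = c(0.2, 0.5, 0.9), n1 = c(10, 15, 20), n2 = c(10, 15, 25))
#' tau2_mm(toy)
#' @export
mm_plugin_second <- function(data) {
  s <- add_study_terms(data)
  if (nrow(s) < 1) abort("Need at least one study.", class = "metamixg_error_input")
  (sum(s$g^2) - sum(s$a / s$ntilde)) / sum(s$a)
}

#' @rdname mm_plugin_second
#' @export
mm_plugin_mu2 <- function(data) {
  s <- add_study_terms(data)
  k <- nrow(s)
  if (k < 2) {
    abort("Estimating `mu_delta^2` needs at least 2 studies.",
          class = "metamixg_error_insufficient")
  }
  abar <- mean(s$a)
  gbar <- mean(s$g)
  c3 <- mm_plugin_second(s)
  abar / (k - 1) * ((k * gbar^2 - sum(s$a / (k * s$ntilde))) / abar - c3)
}

#' @rdname mm_plugin_second
#' @export
tau2_mm <- function(data) {
  raw <- mm_plugin_second(data) - mm_plugin_mu2(data)
  tibble::tibble(tau2_raw = raw, tau2 = max(0, raw))
}

#' Mixture-model study-level variances and weights
#'
#' Adds the MM study-level variance
#' `sigma2_g = (a/ntilde) * (1 + ntilde * (tau2_hat + C5)) - C5` - the
#' closed-form marginal variance with the plug-ins `C5` for `mu_delta^2` and,
#' by default, the zero-truncated `tau2_hat = max(0, C3 - C5)` for `tau2`
#' (`truncate = FALSE` uses the raw `C3` plug-in, which keeps the variance
#' unbiased but lets badly negative `tau2` draws shrink the weights and the
#' pooled standard error; see the methods vignette for the calibration
#' evidence behind the default). The plug-ins are pooled over the whole
#' sample, so a study's variance depends on its own record only through the
#' known size terms - there is no study-specific `g`-variance coupling.
#' Nonpositive variances (possible in pathological samples, essentially only
#' with `truncate = FALSE`) are floored at `eps` with a warning; a sample
#' where all variances are nonpositive is an error.
#'
#' @inheritParams mm_plugin_second
#' @param truncate Use the zero-truncated `tau2` plug-in inside the variance
#'   (default `TRUE`).
#' @param eps Floor for nonpositive variances.
#' @return The study tibble with `sigma2_g` and `weight` columns added.
#' @export
add_mm_variances <- function(data, truncate = TRUE, eps = 1e-8) {
  s <- add_study_terms(data)
  c3 <- mm_plugin_second(s)
  c5 <- mm_plugin_mu2(s)
  c3_used <- if (truncate) max(c3, c5) else c3
  v <- (s$a / s$ntilde) * (1 + s$ntilde * c3_used) - c5
  if (all(v <= 0)) {
    abort("All MM study-level variances are nonpositive; sample is degenerate.",
          class = "metamixg_error_degenerate")
  }
  if (any(v <= 0)) {
    warn(sprintf("%d nonpositive MM study-level variance(s) floored at %g.",
                 sum(v <= 0), eps))
    v <- pmax(v, eps)
  }
  s$sigma2_g <- v
  s$weight <- 1 / v
  s
}

#' Fit a random-effects meta-analysis of Hedges' g
#'
#' Front end for the three estimators compared in the package:
#' * `"mm"` - the mixture-model method of moments: unbiased `tau2` (raw and
#'   truncated), unbiased study-level variances independent of the study's own
#'   `g`, inverse-variance-weighted mean with `se^2 = 1/sum(w)` and a
#'   Student-t confidence interval on `k - 1` degrees of freedom;
#' * `"dl"` - DerSimonian-Laird, with the conditional sampling variance of
#'   each study estimated by plugging the study's own `g` into the exact
#'   Hedges formula (or the common large-sample form, see `conditional`);
#' * `"reml"` - restricted maximum likelihood for the normal-normal model on
#'   the same conditional variances.
#'
#' @inheritParams mm_plugin_second
#' @param method One of `"mm"`, `"dl"`, `"reml"`.
#' @param level Two-sided confidence level for `mu_delta` (default 0.95).
#' @param conditional Conditional-variance form for the comparators:
#'   `"exact"` (Hedges' exact variance with `g` plugged in, the default) or
#'   `"large-sample"` (`1/ntilde + g^2 / (2 (n1 + n2))`).
#' @param reml_tol,reml_max_iter Convergence tolerance and iteration cap for
#'   the REML fixed point.
#' @return An object of class `meta_fit`: a list with elements `method`,
#'   `mu_hat`, `tau2_raw`, `tau2`, `se_mu`, `ci_mu`, `level`, `k`,
#'   `g_weight_cor`, and a per-study tibble `studies` (g, sizes, variance,
#'   weight). Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' set.seed(1)
#' dat <- draw_meta_sample(k = 12, mu_delta = 0.5, tau2 = 0.1)
#' fit_meta(dat, method = "mm")
#' @export
fit_meta <- function(data, method = c("mm", "dl", "reml"), level = 0.95,
                     conditional = c("exact", "large-sample"),
                     reml_tol = 1e-8, reml_max_iter = 500L) {
  method <- match.arg(method)
  conditional <- match.arg(conditional)
  if (level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).", class = "metamixg_error_input")
  }
  s <- add_study_terms(data)
  k <- nrow(s)
  if (k < 2) {
    abort("Meta-analysis needs at least 2 studies.",
          class = "metamixg_error_insufficient")
  }
  if (any(s$m <= 2)) {
    abort("All studies must have m = n1 + n2 - 2 > 2.",
          class = "metamixg_error_design")
  }
  if (anyDuplicated(s$study_id)) {
    abort("`study_id` values must be unique.", class = "metamixg_error_input")
  }
  switch(method,
    mm = fit_mm(s, level),
    dl = fit_dl(s, level, conditional),
    reml = fit_reml(s, level, conditional, reml_tol, reml_max_iter)
  )
}

fit_mm <- function(s, level) {
  est <- tau2_mm(s)
  s <- add_mm_variances(s)
  w <- s$weight
  mu <- sum(w * s$g) / sum(w)
  se <- sqrt(1 / sum(w))
  tcrit <- qt(1 - (1 - level) / 2, df = nrow(s) - 1)
  new_meta_fit(
    method = "mm", studies = s, mu_hat = mu,
    tau2_raw = est$tau2_raw, tau2 = est$tau2,
    se_mu = se, ci_mu = c(mu - tcrit * se, mu + tcrit * se), level = level,
    converged = TRUE
  )
}

new_meta_fit <- function(method, studies, mu_hat, tau2_raw, tau2, se_mu,
                         ci_mu, level, converged = TRUE, iterations = NA_integer_) {
  structure(
    list(
      method = method,
      mu_hat = mu_hat,
      tau2_raw = tau2_raw,
      tau2 = tau2,
      se_mu = se_mu,
      ci_mu = ci_mu,
      level = level,
      k = nrow(studies),
      g_weight_cor = weight_correlation(studies$g, studies$weight),
      converged = converged,
      iterations = iterations,
      studies = studies
    ),
    class = "meta_fit"
  )
}

#' @export
print.meta_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Meta-analysis of Hedges' g (%s), k = %d studies\n",
              toupper(x$method), x$k))
  cat(sprintf("  mu_hat   = %.*f  (SE %.*f, %g%% CI %.*f to %.*f)\n",
              digits, x$mu_hat, digits, x$se_mu, 100 * x$level,
              digits, x$ci_mu[1], digits, x$ci_mu[2]))
  cat(sprintf("  tau2     = %.*f  (untruncated %.*f)\n",
              digits, x$tau2, digits, x$tau2_raw))
  cat(sprintf("  g-weight correlation: %s\n",
              ifelse(is.na(x$g_weight_cor), "undefined (constant weights)",
                     formatC(x$g_weight_cor, digits = digits, format = "f"))))
  if (!isTRUE(x$converged)) cat("  WARNING: estimator did not converge\n")
  invisible(x)
}

#' Broom-style accessors for `meta_fit` objects
#'
#' `tidy()` returns the per-study table (g, sizes, MM/comparator variance and
#' weight); `glance()` a one-row summary with the estimates, their
#' uncertainty, and the g-weight correlation diagnostic.
#'
#' @param x A `meta_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.meta_fit <- function(x, ...) {
  x$studies |>
    dplyr::select(dplyr::any_of(c("study_id", "g", "n1", "n2", "m", "ntilde",
                                  "a", "sigma2_g", "weight")))
}

#' @rdname tidy.meta_fit
#' @exportS3Method generics::glance
glance.meta_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    k = x$k,
    mu_hat = x$mu_hat,
    se_mu = x$se_mu,
    ci_low = x$ci_mu[1],
    ci_high = x$ci_mu[2],
    level = x$level,
    tau2_raw = x$tau2_raw,
    tau2 = x$tau2,
    g_weight_cor = x$g_weight_cor,
    converged = x$converged
  )
}

#' Forest-style plot of a fitted meta-analysis
#'
#' Per-study g values with approximate study-level intervals
#' (`g +/- 1.96 * sqrt(sigma2_g)`), the pooled estimate and its confidence
#' band.
#'
#' @param object A `meta_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.meta_fit <- function(object, ...) {
  s <- tidy(object) |>
    dplyr::mutate(study_id = factor(.data$study_id, levels = rev(.data$study_id)),
                  lo = .data$g - 1.96 * sqrt(.data$sigma2_g),
                  hi = .data$g + 1.96 * sqrt(.data$sigma2_g))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$g, y = .data$study_id)) +
    ggplot2::annotate("rect", xmin = object$ci_mu[1], xmax = object$ci_mu[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$mu_hat, colour = "steelblue") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), shape = 15,
                        show.legend = FALSE) +
    ggplot2::labs(
      x = "Hedges' g", y = NULL,
      title = sprintf("%s fit: mu = %.3f, tau2 = %.3f",
                      toupper(object$method), object$mu_hat, object$tau2)
    ) +
    ggplot2::theme_minimal()
}
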
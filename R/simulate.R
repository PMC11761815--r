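#' Canonical simulation design: eight equiprobable size pairs
#'
#' The benchmark set of sample-size pairs used throughout the package's
#' simulations: (5,5), (10,10), (5,15), (15,15), (10,20), (20,20), (10,30),
#' (15,25), drawn with equal probability 1/8.
#'
#' @return A tibble with columns `n1`, `n2`.
#' @export
size_pairs_default <- function() {
  tibble::tibble(
    n1 = c(5, 10, 5, 15, 10, 20, 10, 15),
    n2 = c(5, 10, 15, 15, 20, 20, 30, 25)
  )
}

#' Draw Hedges' g values for given true effects
#'
#' Two exactly equivalent sampling routes for g given the true effect(s)
#' `delta` and one pair of sizes:
#' * `"direct"`: `g = (c(m)/sqrt(ntilde)) * T` with `T` noncentral t on `m`
#'   degrees of freedom and noncentrality `delta * sqrt(ntilde)` (the exact
#'   conditional law of g);
#' * `"score"`: draw the `n1 + n2` individual scores from `N(delta, 1)` and
#'   `N(0, 1)` and compute g from the group summaries with [hedges_g()]'s
#'   formula.
#'
#' @param delta Vector of true effects (one g is drawn per element).
#' @param n1,n2 The group sample sizes.
#' @param sampling `"direct"` or `"score"`.
#' @return Numeric vector of g draws, one per `delta`.
#' @examples
#' set.seed(1)
#' g <- draw_g(rep(0.5, 1000), 15, 15)
#' mean(g)
#' @export
draw_g <- function(delta, n1, n2, sampling = c("direct", "score")) {
  sampling <- match.arg(sampling)
  check_sizes(n1, n2)
  m <- n1 + n2 - 2
  nt <- effective_n(n1, n2)
  n <- length(delta)
  if (sampling == "direct") {
    hedges_c(m) / sqrt(nt) *
      suppressWarnings(rt(n, df = m, ncp = delta * sqrt(nt)))
  } else {
    g <- numeric(n)
    chunk <- 20000L
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      d <- delta[idx]
      nc <- length(idx)
      x1 <- matrix(rnorm(nc * n1, mean = d), nrow = nc, ncol = n1)
      x2 <- matrix(rnorm(nc * n2), nrow = nc, ncol = n2)
      m1 <- rowMeans(x1)
      m2 <- rowMeans(x2)
      ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
      g[idx] <- hedges_c(m) * (m1 - m2) / sqrt(ss / m)
    }
    g
  }
}

#' Simulate one meta-analytic sample of studies
#'
#' Draws `k` studies: each study's true effect comes from the latent normal
#' `N(mu_delta, tau2)`, its sizes from `size_pairs` with probabilities `prob`
#' (equal by default), and its g from the conditional law via [draw_g()].
#'
#' @param k Number of studies.
#' @param mu_delta,tau2 Latent mean and variance of the true effects.
#' @param size_pairs Data frame of candidate `(n1, n2)` pairs.
#' @param prob Selection probabilities (default equal).
#' @param sampling Passed to [draw_g()].
#' @param seed Optional integer seed for reproducibility.
#' @return A study tibble (with derived columns, ready for [fit_meta()]).
#' @examples
#' draw_meta_sample(k = 5, mu_delta = 0.5, tau2 = 0.1, seed = 7)
#' @export
draw_meta_sample <- function(k, mu_delta, tau2,
                             size_pairs = size_pairs_default(), prob = NULL,
                             sampling = c("direct", "score"), seed = NULL) {
  sampling <- match.arg(sampling)
  if (!is.null(seed)) set.seed(seed)
  size_pairs <- add_design_terms(size_pairs)
  prob <- prob %||% rep(1 / nrow(size_pairs), nrow(size_pairs))
  if (abs(sum(prob) - 1) > 1e-8) {
    abort("`prob` must sum to 1.", class = "metamixg_error_input")
  }
  idx <- sample.int(nrow(size_pairs), k, replace = TRUE, prob = prob)
  delta <- rnorm(k, mu_delta, sqrt(tau2))
  g <- vapply(seq_len(k), function(i) {
    draw_g(delta[i], size_pairs$n1[idx[i]], size_pairs$n2[idx[i]], sampling)
  }, numeric(1))
  add_study_terms(tibble::tibble(
    study_id = paste0("study_", seq_len(k)),
    g = g,
    n1 = size_pairs$n1[idx],
    n2 = size_pairs$n2[idx]
  ))
}

#' Simulate many independent g values under the mixture model
#'
#' One g per simulated primary study: latent effect from `N(mu_delta, tau2)`,
#' sizes sampled from `size_pairs` (a single-row design gives the fixed-sizes
#' case). Used by [moment_check()].
#'
#' @inheritParams draw_meta_sample
#' @param n Number of primary studies.
#' @return A tibble with columns `g`, `n1`, `n2`.
#' @export
simulate_g <- function(n, mu_delta, tau2, size_pairs = size_pairs_default(),
                       prob = NULL, sampling = c("direct", "score"),
                       seed = NULL) {
  sampling <- match.arg(sampling)
  if (!is.null(seed)) set.seed(seed)
  size_pairs <- add_design_terms(size_pairs)
  prob <- prob %||% rep(1 / nrow(size_pairs), nrow(size_pairs))
  idx <- sample.int(nrow(size_pairs), n, replace = TRUE, prob = prob)
  delta <- rnorm(n, mu_delta, sqrt(tau2))
  g <- numeric(n)
  for (p in seq_len(nrow(size_pairs))) {
    sel <- idx == p
    if (any(sel)) {
      g[sel] <- draw_g(delta[sel], size_pairs$n1[p], size_pairs$n2[p], sampling)
    }
  }
  tibble::tibble(g = g, n1 = size_pairs$n1[idx], n2 = size_pairs$n2[idx])
}

#' Empirical versus closed-form moments of g
#'
#' Simulates `n` primary studies and compares the empirical mean, variance
#' and skewness of g with the closed-form values from the mixture model
#' ([meta_moments()]; a single-row `size_pairs` reproduces the fixed-sizes
#' case). Monte Carlo standard errors come from batch means (`n_batches`
#' equal batches).
#'
#' @inheritParams simulate_g
#' @param n_batches Number of batches for the Monte Carlo standard errors.
#' @return A tibble with one row per statistic: `statistic`, `empirical`,
#'   `theoretical`, `diff`, `mc_se`, `n`.
#' @examples
#' moment_check(n = 20000, size_pairs = data.frame(n1 = 15, n2 = 15), seed = 1)
#' @export
moment_check <- function(n = 1e6, mu_delta = 0.5, tau2 = 0.1,
                         size_pairs = size_pairs_default(), prob = NULL,
                         sampling = c("direct", "score"), seed = NULL,
                         n_batches = 100) {
  sampling <- match.arg(sampling)
  sim <- simulate_g(n, mu_delta, tau2, size_pairs, prob, sampling, seed)
  g <- sim$g
  theo <- meta_moments(size_pairs, mu_delta, tau2)
  emp_mean <- mean(g)
  emp_var <- mean((g - emp_mean)^2)
  emp_skew <- mean((g - emp_mean)^3) / emp_var^1.5
  batch <- rep(seq_len(n_batches), length.out = n)
  stats_by_batch <- vapply(seq_len(n_batches), function(b) {
    gb <- g[batch == b]
    mb <- mean(gb)
    vb <- mean((gb - mb)^2)
    c(mb, vb, mean((gb - mb)^3) / vb^1.5)
  }, numeric(3))
  mc_se <- apply(stats_by_batch, 1, sd) / sqrt(n_batches)
  tibble::tibble(
    statistic = c("mean", "variance", "skewness"),
    empirical = c(emp_mean, emp_var, emp_skew),
    theoretical = c(theo$mean, theo$variance, theo$skewness),
    diff = .data$theoretical - .data$empirical,
    mc_se = mc_se,
    n = n
  )
}

# Draw the simulation arrays for one condition: B x k matrices of g and the
# size terms, under the latent normal.
draw_condition_matrices <- function(n_reps, k, mu_delta, tau2, size_pairs,
                                    prob = NULL) {
  size_pairs <- add_design_terms(size_pairs)
  prob <- prob %||% rep(1 / nrow(size_pairs), nrow(size_pairs))
  idx <- matrix(sample.int(nrow(size_pairs), n_reps * k, replace = TRUE,
                           prob = prob), n_reps, k)
  M <- matrix(size_pairs$m[idx], n_reps, k)
  NT <- matrix(size_pairs$ntilde[idx], n_reps, k)
  A <- hedges_c(M)^2 * M / (M - 2)
  delta <- matrix(rnorm(n_reps * k, mu_delta, sqrt(tau2)), n_reps, k)
  G <- matrix(
    hedges_c(M) / sqrt(NT) *
      suppressWarnings(rt(n_reps * k, df = M, ncp = delta * sqrt(NT))),
    n_reps, k
  )
  list(G = G, A = A, NT = NT, M = M)
}

#' Monte Carlo evaluation of the estimators for one condition
#'
#' Simulates `n_reps` meta-analytic samples under one condition
#' (`mu_delta`, `tau2`, `k`, the size-pair design) and fits each with the MM,
#' DL and REML estimators, returning per-method bias, variance, RMSE,
#' confidence-interval coverage for `mu_delta`, and the mean g-weight
#' correlation. The MM coverage uses the Student-t interval on `k - 1`
#' degrees of freedom; DL and REML use the conventional normal interval.
#' `bias_tau2_raw` is the bias of the untruncated MM estimator (it equals
#' `bias_tau2` for DL/REML, whose estimators are defined truncated).
#'
#' @inheritParams draw_meta_sample
#' @param n_reps Number of replicates.
#' @param level Confidence level for the coverage column.
#' @return A tibble with one row per method.
#' @examples
#' run_condition(tau2 = 0.1, k = 15, n_reps = 200, seed = 42)
#' @export
run_condition <- function(tau2, k, n_reps = 2000, mu_delta = 0.5,
                          size_pairs = size_pairs_default(), prob = NULL,
                          level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arr <- draw_condition_matrices(n_reps, k, mu_delta, tau2, size_pairs, prob)
  fits <- list(
    mm = mm_engine(arr$G, arr$A, arr$NT),
    dl = dl_engine(arr$G, arr$A, arr$NT),
    reml = reml_engine(arr$G, arr$A, arr$NT)
  )
  crit <- c(mm = qt(1 - (1 - level) / 2, df = k - 1),
            dl = stats::qnorm(1 - (1 - level) / 2),
            reml = stats::qnorm(1 - (1 - level) / 2))
  purrr::imap_dfr(fits, function(f, method) {
    covered <- abs(f$mu - mu_delta) <= crit[[method]] * f$se
    r <- row_correlations(arr$G, f$weights)
    tibble::tibble(
      method = method,
      tau2_true = tau2,
      k = k,
      n_reps = n_reps,
      bias_mu = mean(f$mu) - mu_delta,
      se_bias_mu = sd(f$mu) / sqrt(n_reps),
      var_mu = mean((f$mu - mean(f$mu))^2),
      rmse_mu = sqrt(mean((f$mu - mu_delta)^2)),
      coverage_mu = mean(covered),
      bias_tau2 = mean(f$tau2) - tau2,
      bias_tau2_raw = mean(f$tau2_raw) - tau2,
      se_bias_tau2 = sd(f$tau2_raw) / sqrt(n_reps),
      var_tau2 = mean((f$tau2 - mean(f$tau2))^2),
      rmse_tau2 = sqrt(mean((f$tau2 - tau2)^2)),
      mean_g_weight_cor = mean(r, na.rm = TRUE)
    )
  })
}

#' Run a grid of simulation conditions
#'
#' Crosses `tau2` and `k` values (the default grid crosses
#' `tau2 = 0.1, 0.3, 0.5, 0.7, 0.9` with `k = 15, 30, 45` at
#' `mu_delta = 0.5`) and binds the per-condition summaries from
#' [run_condition()]. Each condition gets a seed derived deterministically
#' from `seed`.
#'
#' @inheritParams run_condition
#' @param tau2,k Vectors of condition values to cross.
#' @param seed Root seed; condition `i` runs with `seed + i`.
#' @return A tibble with one row per condition x method.
#' @export
run_grid <- function(tau2 = c(0.1, 0.3, 0.5, 0.7, 0.9), k = c(15, 30, 45),
                     n_reps = 2000, mu_delta = 0.5,
                     size_pairs = size_pairs_default(), prob = NULL,
                     level = 0.95, seed = 1) {
  grid <- tidyr::expand_grid(tau2 = tau2, k = k)
  purrr::pmap_dfr(
    list(grid$tau2, grid$k, seq_len(nrow(grid))),
    function(t2, kk, i) {
      run_condition(tau2 = t2, k = kk, n_reps = n_reps, mu_delta = mu_delta,
                    size_pairs = size_pairs, prob = prob, level = level,
                    seed = seed + i)
    }
  )
}

#' Nonparametric bootstrap confidence interval for tau-squared
#'
#' Percentile interval from `B` resamples of the studies (rows) drawn with
#' replacement; the chosen estimator is re-run on every resample. The lower
#' bound is nonnegative for all three estimators (all truncate at zero).
#'
#' @inheritParams fit_meta
#' @param B Number of bootstrap resamples.
#' @param seed Optional seed.
#' @return A one-row tibble with `method`, `estimate` (on the original
#'   sample, truncated), `lower`, `upper`, `level`, `B`.
#' @examples
#' dat <- draw_meta_sample(k = 10, mu_delta = 0.5, tau2 = 0.2, seed = 3)
#' bootstrap_tau2_ci(dat, B = 200, seed = 4)
#' @export
bootstrap_tau2_ci <- function(data, method = c("mm", "dl", "reml"), B = 1000,
                              level = 0.95, seed = NULL) {
  method <- match.arg(method)
  if (B < 100) abort("`B` must be at least 100.", class = "metamixg_error_input")
  if (!is.null(seed)) set.seed(seed)
  s <- add_study_terms(data)
  k <- nrow(s)
  if (k < 2) {
    abort("Bootstrap needs at least 2 studies.",
          class = "metamixg_error_insufficient")
  }
  idx <- matrix(sample.int(k, B * k, replace = TRUE), B, k)
  G <- matrix(s$g[idx], B, k)
  A <- matrix(s$a[idx], B, k)
  NT <- matrix(s$ntilde[idx], B, k)
  est <- switch(method,
    mm = mm_engine(G, A, NT)$tau2,
    dl = dl_engine(G, A, NT)$tau2,
    reml = reml_engine(G, A, NT)$tau2
  )
  bad <- !is.finite(est)
  if (mean(bad) > 0.05) {
    warn(sprintf("Bootstrap unstable: %.1f%% of resamples failed.",
                 100 * mean(bad)))
  }
  qs <- quantile(est[!bad], c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE)
  point <- switch(method,
    mm = tau2_mm(s)$tau2,
    dl = fit_meta(s, "dl")$tau2,
    reml = fit_meta(s, "reml")$tau2
  )
  tibble::tibble(method = method, estimate = point,
                 lower = qs[1], upper = qs[2], level = level, B = B)
}

#' Coverage of the bootstrap tau-squared intervals
#'
#' Directional check of the bootstrap interval behaviour: simulates `n_reps`
#' meta-analytic samples per condition, builds the percentile bootstrap
#' interval for each method on every sample, and reports the fraction
#' covering the generating `tau2`.
#'
#' @inheritParams run_condition
#' @param B Bootstrap resamples per replicate.
#' @return A tibble with one row per method: `method, tau2_true, k, coverage`.
#' @export
bootstrap_tau2_coverage <- function(tau2, k, n_reps = 500, B = 1000,
                                    mu_delta = 0.5,
                                    size_pairs = size_pairs_default(),
                                    prob = NULL, level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hits <- matrix(0, n_reps, 3, dimnames = list(NULL, c("mm", "dl", "reml")))
  for (r in seq_len(n_reps)) {
    s <- draw_meta_sample(k, mu_delta, tau2, size_pairs, prob)
    idx <- matrix(sample.int(k, B * k, replace = TRUE), B, k)
    G <- matrix(s$g[idx], B, k)
    A <- matrix(s$a[idx], B, k)
    NT <- matrix(s$ntilde[idx], B, k)
    for (method in c("mm", "dl", "reml")) {
      est <- switch(method,
        mm = mm_engine(G, A, NT)$tau2,
        dl = dl_engine(G, A, NT)$tau2,
        reml = reml_engine(G, A, NT)$tau2
      )
      qs <- quantile(est[is.finite(est)],
                     c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
      hits[r, method] <- (tau2 >= qs[1]) & (tau2 <= qs[2])
    }
  }
  tibble::tibble(
    method = colnames(hits),
    tau2_true = tau2,
    k = k,
    n_reps = n_reps,
    B = B,
    coverage = colMeans(hits)
  )
}

#' Plot a simulation-grid summary
#'
#' Lines of a chosen performance metric against the generating `tau2`,
#' faceted by `k`, one line per method.
#'
#' @param grid A tibble from [run_grid()].
#' @param metric Column to plot (e.g. `"bias_tau2"`, `"bias_mu"`,
#'   `"rmse_tau2"`, `"coverage_mu"`).
#' @return A ggplot object.
#' @export
plot_grid_summary <- function(grid, metric = "bias_tau2") {
  if (!metric %in% names(grid)) {
    abort(sprintf("Column `%s` not found in `grid`.", metric),
          class = "metamixg_error_input")
  }
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$tau2_true,
                                     y = .data[[metric]],
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$k), labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(tau^2), y = metric, colour = "method") +
    ggplot2::theme_minimal()
}
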
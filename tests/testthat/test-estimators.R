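test_that("plug-in moments match independent hand arithmetic on a 3-study toy", {
  toy <- toy3()
  # independent transcription of the formulas with raw gamma functions
  m <- toy$n1 + toy$n2 - 2
  nt <- toy$n1 * toy$n2 / (toy$n1 + toy$n2)
  a <- a_direct(m)
  g <- toy$g
  k <- 3
  c3_hand <- (sum(g^2) - sum(a / nt)) / sum(a)
  c5_hand <- (mean(a) / (k - 1)) *
    ((k * mean(g)^2 - sum(a / (k * nt))) / mean(a) - c3_hand)
  expect_equal(mm_plugin_second(toy), c3_hand, tolerance = 1e-12)
  expect_equal(mm_plugin_mu2(toy), c5_hand, tolerance = 1e-12)
  expect_equal(mm_plugin_second(toy), 0.217610837842, tolerance = 1e-9)
  expect_equal(mm_plugin_mu2(toy), 0.243333333333, tolerance = 1e-9)
  est <- tau2_mm(toy)
  expect_equal(est$tau2_raw, -0.0257224954915, tolerance = 1e-9)
  expect_equal(est$tau2, 0)
})

test_that("tau2 estimator equals the single-formula expression identically", {
  set.seed(7)
  for (rep in 1:20) {
    dat <- draw_meta_sample(k = sample(3:25, 1), mu_delta = runif(1, -0.5, 1),
                            tau2 = runif(1, 0, 0.8))
    s <- add_study_terms(dat)
    g <- s$g; a <- s$a; nt <- s$ntilde; k <- nrow(s); gbar <- mean(g)
    # the one-line unbiased estimator, written out in full
    direct <- (sum(g^2) - sum(a / nt)) / sum(a) -
      (sum(a / k) / (k - 1)) *
        ((k * gbar^2 - sum(a / (k * nt))) / sum(a / k) -
           (sum(g^2) - sum(a / nt)) / sum(a))
    expect_equal(tau2_mm(dat)$tau2_raw, direct, tolerance = 1e-12)
  }
})

test_that("estimates are invariant under reordering of the studies", {
  dat <- draw_meta_sample(k = 12, mu_delta = 0.3, tau2 = 0.2, seed = 31)
  perm <- dat[sample(nrow(dat)), ]
  expect_equal(tau2_mm(perm)$tau2_raw, tau2_mm(dat)$tau2_raw, tolerance = 1e-12)
  expect_equal(mm_plugin_mu2(perm), mm_plugin_mu2(dat), tolerance = 1e-12)
  f1 <- fit_meta(dat, "mm"); f2 <- fit_meta(perm, "mm")
  expect_equal(f1$mu_hat, f2$mu_hat, tolerance = 1e-12)
  expect_equal(f1$se_mu, f2$se_mu, tolerance = 1e-12)
})

test_that("MM study variances depend only on the size terms", {
  # equal sizes across studies -> identical variances, equal weights,
  # and the pooled estimate is the unweighted mean
  dat <- data.frame(g = c(0.1, 0.4, 0.9, 0.6), n1 = 15, n2 = 15)
  s <- add_mm_variances(dat)
  expect_true(all(abs(s$sigma2_g - s$sigma2_g[1]) < 1e-14))
  fit <- fit_meta(dat, "mm")
  expect_equal(fit$mu_hat, mean(dat$g), tolerance = 1e-12)
  # weighted residuals sum to zero; se^2 = 1 / sum(w)
  expect_lt(abs(sum(s$weight * (s$g - fit$mu_hat))), 1e-10)
  expect_equal(fit$se_mu^2, 1 / sum(s$weight), tolerance = 1e-12)
  # all-zero g: the second-moment plug-in is the stated negative constant
  zero <- data.frame(g = rep(0, 4), n1 = c(5, 10, 15, 20), n2 = c(5, 10, 15, 20))
  sz <- add_study_terms(zero)
  expect_equal(mm_plugin_second(zero), -sum(sz$a / sz$ntilde) / sum(sz$a),
               tolerance = 1e-12)
})

test_that("nonpositive study variances are floored with a warning", {
  # raw plug-in variance can go negative when tau2_raw is badly negative
  mix <- data.frame(g = c(2, 2.01), n1 = c(100, 5), n2 = c(100, 5))
  expect_warning(s <- add_mm_variances(mix, truncate = FALSE), "floored")
  expect_true(all(s$sigma2_g > 0))
  # the truncated default keeps both variances positive here
  expect_no_warning(st <- add_mm_variances(mix))
  expect_true(all(st$sigma2_g > 0))
})

test_that("truncated and raw variance plug-ins agree when tau2_raw is positive", {
  dat <- draw_meta_sample(k = 20, mu_delta = 0.5, tau2 = 0.6, seed = 99)
  if (tau2_mm(dat)$tau2_raw > 0) {
    expect_equal(add_mm_variances(dat)$sigma2_g,
                 add_mm_variances(dat, truncate = FALSE)$sigma2_g,
                 tolerance = 1e-12)
  }
})

test_that("plug-ins and the MM pipeline are unbiased across simulated meta-samples", {
  # 1e4 meta-samples, k = 30, mu = 0.5, tau2 = 0.1 over the benchmark pairs:
  # E(C3) = tau2 + mu^2 = 0.35, E(C5) = mu^2 = 0.25, E(tau2_raw) = 0.1,
  # and E(mu_hat) = 0.5.
  set.seed(202)
  B <- 1e4; k <- 30
  arr <- metamixg:::draw_condition_matrices(B, k, 0.5, 0.1, size_pairs_default())
  G <- arr$G; A <- arr$A; NT <- arr$NT
  # test-side plug-in computation, independent of mm_engine
  c3 <- (rowSums(G^2) - rowSums(A / NT)) / rowSums(A)
  gbar <- rowMeans(G)
  c5 <- (rowMeans(A) / (k - 1)) *
    ((k * gbar^2 - rowSums(A / NT) / k) / rowMeans(A) - c3)
  expect_lt(abs(mean(c3) - 0.35), 3 * sd(c3) / sqrt(B))
  expect_lt(abs(mean(c5) - 0.25), 3 * sd(c5) / sqrt(B))
  fit <- metamixg:::mm_engine(G, A, NT)
  expect_lt(abs(mean(fit$tau2_raw) - 0.1), 3 * sd(fit$tau2_raw) / sqrt(B))
  expect_lt(abs(mean(fit$mu) - 0.5), 3 * sd(fit$mu) / sqrt(B))
  # engine plug-ins agree with the scalar implementations
  expect_equal(fit$tau2_raw, c3 - c5, tolerance = 1e-12)
  # mean study variance tracks the closed-form variance for each size pair
  pairs <- add_design_terms(size_pairs_default())
  vtheo <- var_g_study(0.5, 0.1, pairs$m, pairs$ntilde)
  v_mm <- A / NT + A * c3 - c5
  for (p in c(1, 4, 8)) {
    sel <- abs(NT - pairs$ntilde[p]) < 1e-9 & abs(A - hedges_a(pairs$m[p])) < 1e-12
    vv <- v_mm[sel]
    expect_lt(abs(mean(vv) - vtheo[p]), 3 * sd(vv) / sqrt(length(vv)))
  }
})

test_that("MM weights are uncorrelated with the g values on average", {
  set.seed(303)
  B <- 4000; k <- 30
  arr <- metamixg:::draw_condition_matrices(B, k, 0.5, 0.3, size_pairs_default())
  fit <- metamixg:::mm_engine(arr$G, arr$A, arr$NT)
  r <- metamixg:::row_correlations(arr$G, fit$weights)
  expect_lt(abs(mean(r, na.rm = TRUE)), 3 * sd(r, na.rm = TRUE) / sqrt(B))
})

test_that("t-based CI for the mean effect has close-to-nominal coverage", {
  # scaled-down rerun: tau2 = 0.1, k = 15, 5000 replicates
  res <- run_condition(tau2 = 0.1, k = 15, n_reps = 5000, seed = 404)
  expect_gte(res$coverage_mu[res$method == "mm"], 0.93)
})

test_that("truncating the tau2 plug-in rescues coverage under low heterogeneity", {
  # the calibration evidence behind the weighting default: with the raw C3
  # plug-in, strongly negative tau2 draws shrink every weight and the pooled
  # SE, and the t-interval undercovers at tau2 = 0.1, k = 15
  set.seed(505)
  arr <- metamixg:::draw_condition_matrices(5000, 15, 0.5, 0.1,
                                            size_pairs_default())
  tcrit <- qt(0.975, 14)
  cov <- vapply(c(TRUE, FALSE), function(tr) {
    f <- metamixg:::mm_engine(arr$G, arr$A, arr$NT, truncate = tr)
    mean(abs(f$mu - 0.5) <= tcrit * f$se)
  }, numeric(1))
  expect_gte(cov[1], 0.93)      # truncated default holds the level
  expect_lt(cov[2], cov[1])     # raw plug-in undercovers
})

test_that("fit_meta validates its inputs", {
  expect_error(fit_meta(data.frame(g = 0.5, n1 = 10, n2 = 10)),
               class = "metamixg_error_insufficient")
  expect_error(fit_meta(data.frame(g = c(0, 1), n1 = 2, n2 = 2)),
               class = "metamixg_error_design")
  expect_error(fit_meta(toy3(), level = 1.2), class = "metamixg_error_input")
  dup <- cbind(toy3(), study_id = "s1")
  expect_error(fit_meta(dup, "mm"), class = "metamixg_error_input")
})

test_that("tidy and glance expose the fit as tibbles", {
  fit <- fit_meta(draw_meta_sample(10, 0.5, 0.1, seed = 5), "mm")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 10)
  expect_true(all(c("g", "sigma2_g", "weight") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mu_hat, fit$mu_hat)
  expect_equal(gl$tau2, max(0, gl$tau2_raw))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
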
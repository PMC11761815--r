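# Shared fixtures, built in code.

# Small deterministic study table used for hand-arithmetic checks.
toy3 <- function() {
  data.frame(g = c(0.2, 0.5, 0.9), n1 = c(10, 15, 20), n2 = c(10, 15, 25))
}

# Independent scalar helpers used as oracles: straight transcriptions of the
# defining formulas via raw gamma functions (valid for the small m used in
# tests), deliberately not the package's log-gamma code path.
c_direct <- function(m) gamma(m / 2) / (sqrt(m / 2) * gamma((m - 1) / 2))
a_direct <- function(m) c_direct(m)^2 * m / (m - 2)

# Quadrature oracle for the central moments of g: the inner expectation
# E[(g - mu)^r | delta] by adaptive quadrature of the conditional (scaled
# noncentral-t) density over the whole real line, then the outer expectation
# over the normal latent law of delta (skipped when tau2 = 0). Fully
# independent of the package's Gauss-Hermite / closed-form code paths.
central_moment_oracle <- function(r, mu, tau2, m, nt) {
  s <- c_direct(m) / sqrt(nt)
  inner <- function(d) {
    vapply(d, function(dd) {
      stats::integrate(function(g) {
        (g - mu)^r * suppressWarnings(stats::dt(g / s, df = m,
                                                ncp = dd * sqrt(nt))) / s
      }, -Inf, Inf, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  if (tau2 == 0) return(inner(mu))
  stats::integrate(function(d) inner(d) * stats::dnorm(d, mu, sqrt(tau2)),
                   mu - 12 * sqrt(tau2), mu + 12 * sqrt(tau2),
                   rel.tol = 1e-9)$value
}

# Restricted log-likelihood of the normal-normal model (up to a constant),
# for the grid-search REML oracle.
restricted_loglik <- function(tau2, g, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * g) / sum(w)
  -0.5 * sum(log(v + tau2)) - 0.5 * log(sum(w)) - 0.5 * sum(w * (g - mu)^2)
}

# Relative comparison with an absolute floor: moments that are analytically
# (near-)zero are compared on the 0.01 scale instead of blowing up the ratio.
expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol * max(abs(expected), 0.01))
}
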
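# Row-wise vectorized estimator engine used by the simulation and bootstrap
# code. Each argument is a B x k matrix (B replicates of k studies). These
# mirror fit_meta() exactly; agreement is enforced by tests.

mm_engine <- function(G, A, NT, truncate = TRUE, eps = 1e-8) {
  k <- ncol(G)
  sum_a <- rowSums(A)
  c3 <- (rowSums(G^2) - rowSums(A / NT)) / sum_a
  gbar <- rowMeans(G)
  abar <- sum_a / k
  c5 <- abar / (k - 1) *
    ((k * gbar^2 - rowSums(A / NT) / k) / abar - c3)
  tau2_raw <- c3 - c5
  c3_used <- if (truncate) pmax(c3, c5) else c3
  v <- A / NT + A * c3_used - c5                 # rowwise recycling
  v <- pmax(v, eps)
  w <- 1 / v
  sw <- rowSums(w)
  mu <- rowSums(w * G) / sw
  list(mu = mu, tau2_raw = tau2_raw, tau2 = pmax(0, tau2_raw),
       se = sqrt(1 / sw), weights = w)
}

dl_engine <- function(G, A, NT) {
  k <- ncol(G)
  V <- A / NT * (1 + NT * G^2) - G^2
  w <- 1 / V
  sw <- rowSums(w)
  mu_fe <- rowSums(w * G) / sw
  q <- rowSums(w * (G - mu_fe)^2)
  tau2_raw <- (q - (k - 1)) / (sw - rowSums(w^2) / sw)
  tau2 <- pmax(0, tau2_raw)
  wr <- 1 / (V + tau2)
  swr <- rowSums(wr)
  list(mu = rowSums(wr * G) / swr, tau2_raw = tau2_raw, tau2 = tau2,
       se = sqrt(1 / swr), weights = wr)
}

reml_engine <- function(G, A, NT, tol = 1e-8, max_iter = 500L) {
  V <- A / NT * (1 + NT * G^2) - G^2
  tau2 <- pmax(0, apply(G, 1, var) - rowMeans(V))
  active <- rep(TRUE, nrow(G))
  for (it in seq_len(max_iter)) {
    w <- 1 / (V + tau2)
    sw <- rowSums(w)
    mu <- rowSums(w * G) / sw
    new <- pmax(0, rowSums(w^2 * ((G - mu)^2 - V)) / rowSums(w^2) + 1 / sw)
    step <- abs(new - tau2)
    tau2 <- new
    active <- step >= tol
    if (!any(active)) break
  }
  w <- 1 / (V + tau2)
  sw <- rowSums(w)
  list(mu = rowSums(w * G) / sw, tau2_raw = tau2, tau2 = tau2,
       se = sqrt(1 / sw), weights = w, converged = !any(active))
}

# mean Pearson correlation between rows of G and rows of W
row_correlations <- function(G, W) {
  gc <- G - rowMeans(G)
  wc <- W - rowMeans(W)
  num <- rowSums(gc * wc)
  den <- sqrt(rowSums(gc^2) * rowSums(wc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
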
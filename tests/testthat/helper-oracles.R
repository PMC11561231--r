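# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route (brute force, enumeration, closed form)
# and never calls the package's own estimator code paths.

# Generalised least squares of beta_y on beta_x with covariance omega,
# solved by explicit whitening + ordinary least squares.
gls_oracle <- function(beta_x, beta_y, omega) {
  ch <- chol(omega)
  xw <- backsolve(ch, beta_x, transpose = TRUE)
  yw <- backsolve(ch, beta_y, transpose = TRUE)
  fit <- lm.fit(matrix(xw, ncol = 1), yw)
  theta <- unname(fit$coefficients)
  list(theta = theta, se = 1 / sqrt(sum(xw^2)))
}

# DerSimonian-Laird random-effects pooling, written out step by step.
dl_oracle <- function(beta, se) {
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bp)^2)
  k <- length(beta)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(tau2 = tau2, beta = sum(ws * beta) / sum(ws), se = sqrt(1 / sum(ws)))
}

# Colocalization posteriors by explicit enumeration of causal
# configurations in linear space (safe only for small, well-scaled input).
coloc_enum_oracle <- function(beta1, se1, beta2, se2,
                              p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                              sd1 = 0.20, sd2 = 0.15) {
  wake <- function(b, s, w) {
    r <- w^2 / (s^2 + w^2)
    sqrt(1 - r) * exp(0.5 * r * (b / s)^2)
  }
  n <- length(beta1)
  bf1 <- vapply(seq_len(n), function(i) wake(beta1[i], se1[i], sd1), 0)
  bf2 <- vapply(seq_len(n), function(i) wake(beta2[i], se2[i], sd2), 0)
  w0 <- 1
  w1 <- p1 * sum(bf1)
  w2 <- p2 * sum(bf2)
  w3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) w3 <- w3 + p1 * p2 * bf1[i] * bf2[j]
  }
  w4 <- p12 * sum(bf1 * bf2)
  w <- c(w0, w1, w2, w3, w4)
  w / sum(w)
}

# Greedy LD clumping executed literally from its definition, used to
# cross-check the package's selection on arbitrary candidate sets.
clump_oracle <- function(ids, positions, p, r, r2_threshold, window_bp) {
  ord <- order(p, positions, ids)
  ids <- ids[ord]; positions <- positions[ord]
  pool <- seq_along(ids)
  kept <- character(0)
  while (length(pool) > 0) {
    top <- pool[1]
    kept <- c(kept, ids[top])
    keep <- c()
    for (i in pool[-1]) {
      r2 <- r[ids[top], ids[i]]^2
      near <- abs(positions[i] - positions[top]) <= window_bp
      if (!(r2 > r2_threshold && near)) keep <- c(keep, i)
    }
    pool <- keep
  }
  kept
}

# Logistic regression by hand-rolled Newton-Raphson on the log-likelihood.
logit_oracle <- function(X, y, tol = 1e-10, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * W, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta, se = sqrt(diag(solve(info))))
}

# Cox partial log-likelihood (Breslow ties) evaluated directly.
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(x[d] * beta) -
      length(d) * log(sum(exp(x[risk] * beta)))
  }
  ll
}

# Small well-formed region for IO/QC tests.
make_tiny_sumstats <- function() {
  sumstats(data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chromosome = "17",
    position = c(43712597L, 43721253L, 43800000L),
    effect_allele = c("G", "A", "C"),
    other_allele = c("A", "G", "T"),
    eaf = c(0.33, 0.09, 0.5),
    beta = c(-0.04, -0.07, 0.01),
    se = c(0.01, 0.01, 0.02),
    p_value = c(1.11e-9, 7.76e-9, 0.6),
    n = 49372, stringsAsFactors = FALSE),
    trait = "exposure", effect_scale = "sd")
}
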